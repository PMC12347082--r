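# Pipeline entry points tying the modules together: simulate a cohort to
# disk, measure landmark files into a cohort table, and render the
# cohort-report tables. These functions are the package's command
# surface; inst/scripts/gnathodiff-cli.R wraps them for shell use.

log_line <- function(log, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message(msg)
  if (!is.null(log)) cat(msg, "\n", file = log, append = TRUE, sep = "")
  invisible(msg)
}

#' Simulate a synthetic cohort to disk
#'
#' Materializes a synthetic cohort as per-patient, per-timepoint,
#' per-segment landmark CSV files (plus STL meshes if requested) and a
#' manifest JSON recording the effect specification, seed, covariates,
#' and ground truth. Re-running with the same spec produces byte-identical
#' outputs.
#'
#' @param spec an [effect_spec()].
#' @param out_dir output directory (created if missing).
#' @param include_meshes also write T0/T1 STL meshes per segment.
#' @return Invisibly, the `synthetic_cohort` that was written.
#' @export
run_simulate <- function(spec, out_dir, include_meshes = FALSE) {
  stopifnot(inherits(spec, "effect_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(out_dir, "run.log")
  cat(sprintf("simulate: n_patients=%d seed=%d noise_sd=%g\n",
              spec$n_patients, spec$seed, spec$noise_sd), file = log)
  cohort <- generate_cohort(spec, include_meshes = include_meshes)
  lm_dir <- file.path(out_dir, "landmarks")
  dir.create(lm_dir, showWarnings = FALSE)
  for (p in cohort$patients) {
    for (tp in c("t0", "t1")) {
      for (seg in SEGMENTS) {
        s <- p[[tp]][[seg]]
        write_landmarks_csv(list(s), file.path(
          lm_dir, sprintf("%s_%s_%s.csv", p$id, s$timepoint, seg)))
      }
    }
    if (include_meshes) {
      mesh_dir <- file.path(out_dir, "meshes")
      dir.create(mesh_dir, showWarnings = FALSE)
      for (tp in c("t0", "t1")) {
        for (seg in names(p$meshes[[tp]])) {
          write_stl(p$meshes[[tp]][[seg]], file.path(
            mesh_dir, sprintf("%s_%s_%s.stl", p$id, toupper(tp), seg)))
        }
      }
    }
  }
  manifest <- list(
    spec = list(n_patients = spec$n_patients,
                means = spec$means, sds = spec$sds,
                noise_sd = spec$noise_sd, seed = spec$seed,
                n_sarme = spec$n_sarme,
                n_extraction_maxilla = spec$n_extraction_maxilla,
                n_extraction_mandible = spec$n_extraction_mandible),
    covariates = cohort$covariates,
    ground_truth = cohort$ground_truth)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  log_line(log, "simulate: wrote %d patients to %s", spec$n_patients, out_dir)
  invisible(cohort)
}

#' Measure a cohort of landmark files into a cohort table
#'
#' Reads per-patient T0/T1 landmark files from `dir/landmarks`, applies
#' optional surface registration per patient, and runs
#' [measure_patient()], returning (and optionally writing) one metrics
#' row per patient x segment. Patients with a missing segment file are
#' skipped with a warning and listed in the run summary. Covariate flags
#' are joined from `dir/manifest.json` when present.
#'
#' @param dir cohort directory as written by [run_simulate()] (or with
#'   the same layout).
#' @param out_csv optional path for the cohort-table CSV.
#' @param registration `"none"` (default: inputs already share a frame)
#'   or `"icp"`: per patient, the meshes
#'   `meshes/<id>_T0_<ref_segment>.stl` / `<id>_T1_<ref_segment>.stl` are
#'   registered by [icp_register()], initialized by Kabsch alignment of
#'   all name-matched T0/T1 landmarks, and the resulting transform is
#'   applied to all T0 landmarks. The reference surface must be one the
#'   two plans share (a bony non-dental structure), otherwise that
#'   structure's own plan-to-plan movement is absorbed into the frame.
#' @param ref_segment mesh label whose surfaces drive registration,
#'   default `"maxilla_reference"` (the bony non-dental maxilla).
#' @param trim_fraction,tol,max_iter ICP options, see [icp_register()].
#' @return The cohort table data.frame, invisibly if `out_csv` is given.
#' @export
run_measure <- function(dir, out_csv = NULL,
                        registration = c("none", "icp"),
                        ref_segment = "maxilla_reference",
                        trim_fraction = 0.1, tol = 1e-6, max_iter = 200L) {
  registration <- match.arg(registration)
  lm_dir <- file.path(dir, "landmarks")
  if (!dir.exists(lm_dir)) stop("no landmarks/ directory under '", dir, "'",
                                call. = FALSE)
  log <- file.path(dir, "run.log")
  files <- list.files(lm_dir, pattern = "\\.csv$", full.names = TRUE)
  sets <- unlist(lapply(files, read_landmarks), recursive = FALSE)
  pids <- unique(vapply(sets, function(s) s$patient_id, character(1)))

  covariates <- NULL
  manifest_path <- file.path(dir, "manifest.json")
  if (file.exists(manifest_path)) {
    covariates <- as.data.frame(
      jsonlite::read_json(manifest_path, simplifyVector = TRUE)$covariates)
  }

  skipped <- character(0)
  rows <- list()
  for (pid in pids) {
    mine <- Filter(function(s) s$patient_id == pid, sets)
    t0 <- Filter(function(s) s$timepoint == "T0", mine)
    t1 <- Filter(function(s) s$timepoint == "T1", mine)
    seg0 <- vapply(t0, function(s) s$segment, character(1))
    seg1 <- vapply(t1, function(s) s$segment, character(1))
    if (!all(SEGMENTS %in% seg0) || !all(SEGMENTS %in% seg1)) {
      warning(sprintf("patient %s: missing segment landmark file, skipped", pid),
              call. = FALSE)
      skipped <- c(skipped, pid)
      next
    }
    reg <- NULL
    if (registration == "icp") {
      m0p <- file.path(dir, "meshes", sprintf("%s_T0_%s.stl", pid, ref_segment))
      m1p <- file.path(dir, "meshes", sprintf("%s_T1_%s.stl", pid, ref_segment))
      if (!file.exists(m0p) || !file.exists(m1p)) {
        stop("registration requested but meshes missing for patient ", pid,
             call. = FALSE)
      }
      # initialize from all name-matched landmarks across the segments:
      # a coarse whole-plan alignment that ICP on the shared reference
      # surface then refines
      src <- do.call(rbind, lapply(SEGMENTS, function(sg)
        t0[[match(sg, seg0)]]$coords))
      tgt <- do.call(rbind, lapply(SEGMENTS, function(sg)
        t1[[match(sg, seg1)]]$coords))
      init <- kabsch_rigid(src, tgt)
      res <- icp_register(read_stl(m0p, ref_segment), read_stl(m1p, ref_segment),
                          init = init, trim_fraction = trim_fraction,
                          tol = tol, max_iter = max_iter)
      if (!is.null(res$failure)) {
        warning(sprintf("patient %s: registration failed (%s), skipped",
                        pid, res$failure), call. = FALSE)
        skipped <- c(skipped, pid)
        next
      }
      log_line(log, "measure: %s registration rms %.6g mm in %d iterations",
               pid, res$rms_residual, res$n_iterations)
      reg <- res$transform
    }
    rows[[pid]] <- measure_patient(t0, t1, registration = reg)
  }
  if (!length(rows)) stop("no patients could be measured", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(covariates)) {
    out <- merge(out, covariates, by = "patient_id", sort = FALSE)
  }
  log_line(log, "measure: %d patients measured, %d skipped%s", length(rows),
           length(skipped),
           if (length(skipped)) paste0(" (", paste(skipped, collapse = ", "), ")")
           else "")
  if (!is.null(out_csv)) {
    utils::write.csv(out, out_csv, row.names = FALSE)
    return(invisible(out))
  }
  out
}

fmt2 <- function(x) formatC(x, digits = 2, format = "f")

#' Render the cohort report tables
#'
#' From a cohort table, writes three report CSVs mirroring the standard
#' layouts — per-parameter one-sample summaries (mean, SEM, top-10%
#' value, 95% CI, p), out-of-range percentages with per-segment rotation/
#' translation means, and unpaired subgroup contrasts per covariate — plus
#' a full-precision JSON twin. CSV cells are rendered at 2 decimals, with
#' p-values below 0.001 printed `<0.001` and significant p-values marked
#' `*`.
#'
#' @param cohort cohort table data.frame (or path to its CSV).
#' @param out_dir output directory.
#' @param rot_tol,trans_tol clinical tolerances (degrees, mm).
#' @param covariates covariate columns to contrast; defaults to those of
#'   `c("sarme", "extraction_maxilla", "extraction_mandible")` present in
#'   the table.
#' @param welch use Welch's unpaired test, default `TRUE`.
#' @param alpha significance level for marking, default 0.05.
#' @return Invisibly, a list with `summary` (data.frame),
#'   `tolerance` (`tolerance_report`), and `subgroups` (data.frame or
#'   `NULL`).
#' @export
run_report <- function(cohort, out_dir, rot_tol = 4, trans_tol = 2,
                       covariates = NULL, welch = TRUE, alpha = 0.05) {
  if (is.character(cohort)) {
    cohort <- utils::read.csv(cohort, stringsAsFactors = FALSE,
                              colClasses = c(patient_id = "character"))
  }
  check_cohort(cohort)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  segs <- intersect(SEGMENTS, unique(cohort$segment))
  summary_df <- do.call(rbind, lapply(segs, function(seg) {
    rows <- cohort[cohort$segment == seg, ]
    do.call(rbind, lapply(METRIC_PARAMETERS, function(p) {
      s <- one_sample_summary(rows[[p]])
      data.frame(segment = seg, parameter = p, mean = s$mean, sem = s$sem,
                 top10_value = s$top10_value, ci_low = s$ci_low,
                 ci_high = s$ci_high, p_value = s$p_value, n = s$n,
                 stringsAsFactors = FALSE)
    }))
  }))
  tab1 <- data.frame(
    Segment = summary_df$segment, Parameter = summary_df$parameter,
    Mean = fmt2(summary_df$mean), SEM = fmt2(summary_df$sem),
    `Top 10% value` = fmt2(summary_df$top10_value),
    `CI low` = fmt2(summary_df$ci_low), `CI high` = fmt2(summary_df$ci_high),
    `p value` = paste0(format_p(summary_df$p_value),
                       ifelse(summary_df$p_value < alpha, " *", "")),
    check.names = FALSE)
  utils::write.csv(tab1, file.path(out_dir, "report_summary.csv"),
                   row.names = FALSE)

  tol <- tolerance_report(cohort, rot_tol = rot_tol, trans_tol = trans_tol)
  pct <- tol$percent
  tab2 <- data.frame(Parameter = c(ROTATION_PARAMETERS, "mean_rotations",
                                   TRANSLATION_PARAMETERS, "mean_translations"))
  for (seg in pct$segment) {
    col <- c(vapply(ROTATION_PARAMETERS, function(p)
               pct[pct$segment == seg, p], numeric(1)),
             tol$mean_rotations[[seg]],
             vapply(TRANSLATION_PARAMETERS, function(p)
               pct[pct$segment == seg, p], numeric(1)),
             tol$mean_translations[[seg]])
    tab2[[seg]] <- fmt2(col)
  }
  utils::write.csv(tab2, file.path(out_dir, "report_out_of_range.csv"),
                   row.names = FALSE)

  if (is.null(covariates)) {
    covariates <- intersect(c("sarme", "extraction_maxilla",
                              "extraction_mandible"), names(cohort))
    # a default covariate is only testable when both groups have n >= 2
    testable <- vapply(covariates, function(cv) {
      flags <- as.logical(cohort[[cv]][cohort$segment == segs[1]])
      sum(flags) >= 2 && sum(!flags) >= 2
    }, logical(1))
    covariates <- covariates[testable]
  } else {
    unknown <- setdiff(covariates, names(cohort))
    if (length(unknown)) stop("unknown covariate column(s): ",
                              paste(unknown, collapse = ", "), call. = FALSE)
  }
  subgroups <- NULL
  if (length(covariates)) {
    subgroups <- do.call(rbind, lapply(covariates, function(cv) {
      do.call(rbind, lapply(segs, function(seg) {
        do.call(rbind, lapply(METRIC_PARAMETERS, function(p) {
          r <- subgroup_test(cohort, cv, p, seg, welch = welch)
          data.frame(covariate = cv, segment = seg, parameter = p,
                     mean_diff = r$mean_diff, ci_low = r$ci_low,
                     ci_high = r$ci_high, p_value = r$p_value,
                     n_group = r$n_group, n_rest = r$n_rest,
                     stringsAsFactors = FALSE)
        }))
      }))
    }))
    tab3 <- data.frame(
      Covariate = subgroups$covariate, Segment = subgroups$segment,
      Parameter = subgroups$parameter, `Mean diff` = fmt2(subgroups$mean_diff),
      `CI low` = fmt2(subgroups$ci_low), `CI high` = fmt2(subgroups$ci_high),
      `p value` = paste0(format_p(subgroups$p_value),
                         ifelse(subgroups$p_value < alpha, " *", "")),
      check.names = FALSE)
    utils::write.csv(tab3, file.path(out_dir, "report_subgroups.csv"),
                     row.names = FALSE)
  }

  n_tests <- nrow(summary_df) + if (is.null(subgroups)) 0L else nrow(subgroups)
  jsonlite::write_json(
    list(summary = summary_df, tolerance = list(
           percent = pct, mean_rotations = as.list(tol$mean_rotations),
           mean_translations = as.list(tol$mean_translations),
           rot_tol = rot_tol, trans_tol = trans_tol),
         subgroups = subgroups, alpha = alpha, welch = welch,
         n_tests_performed = n_tests, multiple_testing_correction = "none"),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(list(summary = summary_df, tolerance = tol, subgroups = subgroups))
}
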