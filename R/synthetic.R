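# Synthetic cohort generation: per-patient T0/T1 landmark sets (and
# optional segment meshes) whose T0 -> T1 differences are known rigid
# 6-DOF displacements, so the whole measurement pipeline can be validated
# by parameter recovery.

#' Template anatomy: landmarks and simple parametric meshes
#'
#' Fixed, deterministic landmark coordinates for the nine anatomical
#' landmarks in the canonical patient frame (origin near the midface,
#' +X = patient left, +Y = anterior, +Z = cranial), bilaterally symmetric
#' about the X = 0 plane, plus simple parametric surfaces: dental arches
#' for the maxilla and mandible and a chin-like sheet for the bony
#' mandibular segment. The shapes are rigid proxies at realistic adult
#' dimensions, not anatomical reconstructions.
#'
#' @param scale global scale factor (1 = adult-sized, dimensions in mm).
#' @param mesh_points approximate vertex count per mesh.
#' @return A list with `landmarks` (list of three T0 `landmark_set`
#'   objects, one per segment) and `meshes` (list of three
#'   `segment_mesh` objects).
#' @export
template_anatomy <- function(scale = 1, mesh_points = 600L) {
  if (scale <= 0) stop("`scale` must be > 0", call. = FALSE)
  lm <- list(
    dental_maxilla = list(`16` = c(-26, 20, -62), UI = c(0, 52, -60),
                          `26` = c(26, 20, -62)),
    dental_mandible = list(`46` = c(-27, 18, -92), LI = c(0, 48, -90),
                           `36` = c(27, 18, -92)),
    bony_mandible = list(MF_R = c(-24, 25, -95), Pog = c(0, 45, -115),
                         MF_L = c(24, 25, -95))
  )
  sets <- lapply(SEGMENTS, function(seg) {
    landmark_set("template", "T0", seg,
                 lapply(lm[[seg]], function(p) p * scale))
  })
  names(sets) <- SEGMENTS
  meshes <- list(
    dental_maxilla = arch_mesh(z0 = -62, y0 = 20, depth = 32, width = 27,
                               height = 12, scale = scale, n = mesh_points,
                               label = "dental_maxilla"),
    dental_mandible = arch_mesh(z0 = -92, y0 = 18, depth = 30, width = 28,
                                height = -12, scale = scale, n = mesh_points,
                                label = "dental_mandible"),
    bony_mandible = chin_mesh(scale = scale, n = mesh_points,
                              label = "bony_mandible"),
    maxilla_reference = maxilla_reference_mesh(scale = scale, n = mesh_points)
  )
  list(landmarks = sets, meshes = meshes)
}

# parabolic dental arch swept vertically: u in [-1, 1] along the arch,
# v in [0, 1] along the crown height; low-frequency cusp-like ripples in
# all three directions give surface registration features to lock onto
arch_mesh <- function(z0, y0, depth, width, height, scale, n, label) {
  nu <- max(8L, round(sqrt(n * 3)))
  nv <- max(4L, round(n / nu))
  u <- seq(-1, 1, length.out = nu)
  v <- seq(0, 1, length.out = nv)
  g <- expand.grid(u = u, v = v)
  x <- width * g$u
  y <- y0 + depth * (1 - g$u^2) + 1.5 * cos(2 * pi * g$u)
  z <- z0 + height * g$v + 2 * sin(3 * pi * g$u) + cos(2 * pi * g$v)
  grid_mesh(cbind(x, y, z) * scale, nu, nv, label)
}

# chin-like sheet: parabolic in both directions, apex at pogonion level
chin_mesh <- function(scale, n, label) {
  nu <- max(8L, round(sqrt(n * 2)))
  nv <- max(6L, round(n / nu))
  u <- seq(-1, 1, length.out = nu)   # left-right
  v <- seq(0, 1, length.out = nv)    # cranial-caudal
  g <- expand.grid(u = u, v = v)
  x <- 26 * g$u
  z <- -95 - 22 * g$v + 1.2 * sin(3 * pi * g$u)
  y <- 25 + 22 * g$v * (1 - g$u^2) + cos(2 * pi * g$u)  # bulge toward chin
  grid_mesh(cbind(x, y, z) * scale, nu, nv, label)
}

# anterior bony maxillary wall above the dental arch: a doubly-curved
# (elliptic-paraboloid-like) shell. This is the bony non-dental reference
# region that anchors surface registration; it is identical in both plans
# by construction (the presurgically planned maxilla serves as the frame
# reference).
maxilla_reference_mesh <- function(scale, n, label = "maxilla_reference") {
  nu <- max(10L, round(sqrt(n * 1.5)))
  nv <- max(8L, round(n / nu))
  u <- seq(-1, 1, length.out = nu)   # left-right
  v <- seq(0, 1, length.out = nv)    # caudal-cranial
  g <- expand.grid(u = u, v = v)
  x <- 28 * g$u
  z <- -58 + 28 * g$v
  y <- 48 - 12 * g$u^2 - 10 * g$v^2
  grid_mesh(cbind(x, y, z) * scale, nu, nv, label)
}

grid_mesh <- function(vertices, nu, nv, label) {
  faces <- do.call(rbind, lapply(seq_len(nv - 1L), function(j) {
    do.call(rbind, lapply(seq_len(nu - 1L), function(i) {
      a <- (j - 1L) * nu + i
      rbind(c(a, a + 1L, a + nu), c(a + 1L, a + nu + 1L, a + nu))
    }))
  }))
  segment_mesh(vertices, faces, label = label)
}

#' Effect specification for synthetic cohorts
#'
#' Defines the Gaussian distribution of each segment's true T0 -> T1
#' rigid displacement: one mean and one SD per segment x parameter, plus
#' optional additive covariate effects, landmark measurement noise, and
#' the cohort composition.
#'
#' @param n_patients number of patients (default 26, the reference study
#'   size).
#' @param means,sds 3 x 6 numeric matrices (rows = segments in
#'   [SEGMENTS] order, columns = [METRIC_PARAMETERS]); degrees for
#'   rotations, mm for translations. Defaults are patterned on the
#'   reference cohort summary: means are the published per-parameter mean
#'   differences and SDs are SEM * sqrt(26) (see
#'   [reference_cohort_summary()]).
#' @param covariate_effects optional named list (by covariate) of 3 x 6
#'   matrices added to `means` for patients carrying that covariate.
#' @param noise_sd isotropic landmark measurement noise SD in mm, applied
#'   independently to every landmark coordinate at both timepoints.
#'   Default 0 (noise is an explicit choice).
#' @param n_sarme,n_extraction_maxilla,n_extraction_mandible covariate
#'   counts; defaults mirror the reference cohort composition (15, 4, 13
#'   of 26). Scaled proportionally if `n_patients` differs from 26.
#' @param seed root random seed; per-patient, per-segment substreams are
#'   derived from it by a fixed counter scheme.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(n_patients = 26L,
                        means = default_effect_means(),
                        sds = default_effect_sds(),
                        covariate_effects = NULL,
                        noise_sd = 0,
                        n_sarme = NULL, n_extraction_maxilla = NULL,
                        n_extraction_mandible = NULL,
                        seed = 1L) {
  n_patients <- as.integer(n_patients)
  if (n_patients < 1L) stop("`n_patients` must be >= 1", call. = FALSE)
  means <- as_effect_matrix(means, "means")
  sds <- as_effect_matrix(sds, "sds")
  if (any(sds < 0)) stop("`sds` must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!is.null(covariate_effects)) {
    covariate_effects <- lapply(covariate_effects, as_effect_matrix, "covariate_effects")
  }
  frac <- n_patients / 26
  pick <- function(x, default) {
    as.integer(if (is.null(x)) min(n_patients, round(default * frac)) else x)
  }
  structure(list(n_patients = n_patients, means = means, sds = sds,
                 covariate_effects = covariate_effects, noise_sd = noise_sd,
                 n_sarme = pick(n_sarme, 15),
                 n_extraction_maxilla = pick(n_extraction_maxilla, 4),
                 n_extraction_mandible = pick(n_extraction_mandible, 13),
                 seed = as.integer(seed)),
            class = "effect_spec")
}

as_effect_matrix <- function(m, arg) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(3L, 6L))) {
    stop(sprintf("`%s` must be a 3 x 6 matrix (segments x parameters)", arg),
         call. = FALSE)
  }
  if (!all(is.finite(m))) stop(sprintf("`%s` must be finite", arg), call. = FALSE)
  dimnames(m) <- list(SEGMENTS, METRIC_PARAMETERS)
  m
}

#' @rdname effect_spec
#' @export
default_effect_means <- function() {
  ref <- reference_cohort_summary()
  as_effect_matrix(t(vapply(SEGMENTS, function(seg) {
    r <- ref[ref$segment == seg, ]
    r$mean[match(METRIC_PARAMETERS, r$parameter)]
  }, numeric(6))), "means")
}

#' @rdname effect_spec
#' @export
default_effect_sds <- function() {
  ref <- reference_cohort_summary()
  as_effect_matrix(t(vapply(SEGMENTS, function(seg) {
    r <- ref[ref$segment == seg, ]
    r$sem[match(METRIC_PARAMETERS, r$parameter)] * sqrt(26)
  }, numeric(6))), "sds")
}

# deterministic substream seed for (patient, segment) under a root seed;
# kept below 2^31 - 1
substream_seed <- function(root, patient, segment_index) {
  (as.double(root) * 100003 + patient * 127 + segment_index) %% 2147483646 + 1
}

#' Generate a synthetic cohort with known ground truth
#'
#' For every patient and segment, draws a true 6-DOF displacement from
#' the spec's Gaussians (plus any covariate shifts), composes it into a
#' rigid transform rotating about the segment's T0 triangle centroid,
#' applies it to the template T0 landmarks (and meshes, if requested) to
#' produce T1, and finally perturbs every landmark coordinate at both
#' timepoints with isotropic Gaussian measurement noise. The drawn
#' displacements are stored as ground truth.
#'
#' @param spec an [effect_spec()].
#' @param include_meshes also generate per-segment T0/T1 meshes.
#' @param scale template scale passed to [template_anatomy()].
#' @return A list of class `synthetic_cohort`: `patients` (list with
#'   `id`, covariate flags, `t0`/`t1` landmark-set lists, optional
#'   `meshes`), `ground_truth` (data.frame patient x segment x parameter),
#'   `covariates` (data.frame), and `spec`.
#' @export
generate_cohort <- function(spec, include_meshes = FALSE, scale = 1) {
  stopifnot(inherits(spec, "effect_spec"))
  template <- template_anatomy(scale = scale)

  cov_df <- local({
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(substream_seed(spec$seed, 0L, 0L))
    n <- spec$n_patients
    data.frame(
      patient_id = sprintf("P%02d", seq_len(n)),
      sarme = seq_len(n) %in% sample.int(n, min(n, spec$n_sarme)),
      extraction_maxilla = seq_len(n) %in% sample.int(n, min(n, spec$n_extraction_maxilla)),
      extraction_mandible = seq_len(n) %in% sample.int(n, min(n, spec$n_extraction_mandible)),
      stringsAsFactors = FALSE)
  })

  gt_rows <- list()
  patients <- vector("list", spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    pid <- cov_df$patient_id[i]
    t0 <- list(); t1 <- list(); meshes <- NULL
    if (include_meshes) meshes <- list(t0 = list(), t1 = list())
    for (si in seq_along(SEGMENTS)) {
      seg <- SEGMENTS[si]
      old <- .Random.seed_save()
      set.seed(substream_seed(spec$seed, i, si))
      mu <- spec$means[seg, ]
      if (!is.null(spec$covariate_effects)) {
        for (cv in names(spec$covariate_effects)) {
          if (isTRUE(cov_df[[cv]][i])) mu <- mu + spec$covariate_effects[[cv]][seg, ]
        }
      }
      theta <- stats::rnorm(6, mean = mu, sd = spec$sds[seg, ])
      names(theta) <- METRIC_PARAMETERS

      base <- template$landmarks[[seg]]
      base$patient_id <- pid
      tri0 <- build_triangle(base)
      trans <- displacement_transform(theta, tri0$centroid)

      l1 <- transform_landmarks(trans, base)
      l1$timepoint <- "T1"
      if (spec$noise_sd > 0) {
        base$coords <- base$coords +
          matrix(stats::rnorm(9, 0, spec$noise_sd), 3, 3)
        l1$coords <- l1$coords +
          matrix(stats::rnorm(9, 0, spec$noise_sd), 3, 3)
      }
      .Random.seed_restore(old)

      t0[[seg]] <- base
      t1[[seg]] <- l1
      if (include_meshes) {
        m0 <- template$meshes[[seg]]
        meshes$t0[[seg]] <- m0
        meshes$t1[[seg]] <- transform_mesh(trans, m0)
      }
      gt_rows[[length(gt_rows) + 1L]] <-
        data.frame(patient_id = pid, segment = seg, t(theta),
                   stringsAsFactors = FALSE)
    }
    if (include_meshes) {
      # the planned bony maxilla is the common frame reference: identical
      # surfaces at both timepoints
      meshes$t0$maxilla_reference <- template$meshes$maxilla_reference
      meshes$t1$maxilla_reference <- template$meshes$maxilla_reference
    }
    patients[[i]] <- list(id = pid,
                          sarme = cov_df$sarme[i],
                          extraction_maxilla = cov_df$extraction_maxilla[i],
                          extraction_mandible = cov_df$extraction_mandible[i],
                          t0 = t0, t1 = t1, meshes = meshes)
  }
  structure(list(patients = patients,
                 ground_truth = do.call(rbind, gt_rows),
                 covariates = cov_df, spec = spec),
            class = "synthetic_cohort")
}

# rigid transform realizing a 6-DOF clinical displacement about a pivot:
# rotation about `pivot`, then translation (LR, AP, UD)
displacement_transform <- function(theta, pivot) {
  R <- clinical_rotation(theta[["pitch"]], theta[["roll"]], theta[["yaw"]])
  t_ <- c(theta[["trans_LR"]], theta[["trans_AP"]], theta[["trans_UD"]])
  rigid_transform(R, pivot - as.numeric(R %*% pivot) + t_)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, noise sd %.3g mm, seed %d\n",
              x$spec$n_patients, x$spec$noise_sd, x$spec$seed))
  invisible(x)
}

#' Measure a synthetic cohort end-to-end
#'
#' Runs [measure_patient()] on every patient of a synthetic cohort and
#' returns the cohort table (one row per patient x segment with the six
#' measured metrics plus covariate flags), ready for the statistics layer.
#'
#' @param cohort a `synthetic_cohort`.
#' @return A data.frame cohort table.
#' @export
measure_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  rows <- lapply(cohort$patients, function(p) {
    m <- measure_patient(p$t0, p$t1)
    m$sarme <- p$sarme
    m$extraction_maxilla <- p$extraction_maxilla
    m$extraction_mandible <- p$extraction_mandible
    m
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Parameter-recovery report
#'
#' Measures a synthetic cohort end-to-end and tabulates, per segment and
#' parameter, the bias and RMSE of the recovered per-patient metrics
#' against the stored ground truth, plus the ground-truth and estimated
#' cohort means.
#'
#' @param cohort a `synthetic_cohort`.
#' @return A data.frame with columns `segment`, `parameter`,
#'   `truth_mean`, `est_mean`, `bias`, `rmse`, `max_abs_error`.
#' @export
recovery_report <- function(cohort) {
  est <- measure_cohort(cohort)
  gt <- cohort$ground_truth
  key <- function(d) paste(d$patient_id, d$segment)
  est <- est[match(key(gt), key(est)), ]
  do.call(rbind, lapply(SEGMENTS, function(seg) {
    sel <- gt$segment == seg
    do.call(rbind, lapply(METRIC_PARAMETERS, function(p) {
      e <- est[[p]][sel] - gt[[p]][sel]
      data.frame(segment = seg, parameter = p,
                 truth_mean = mean(gt[[p]][sel]),
                 est_mean = mean(est[[p]][sel]),
                 bias = mean(e), rmse = sqrt(mean(e^2)),
                 max_abs_error = max(abs(e)),
                 stringsAsFactors = FALSE)
    }))
  }))
}
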