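# Landmark sets: named anatomical points per patient / timepoint / segment,
# plus CSV and JSON readers/writers.

#' Required landmark names per segment
#'
#' Each osteotomized segment is tracked by three named anatomical landmarks
#' (right-side, midline, left-side): the dental maxilla by the mesial
#' buccal cusps of the first molars (FDI 16, 26) and the upper incisor
#' midpoint (UI); the dental mandible by FDI 46, the lower incisor
#' midpoint (LI), and FDI 36; the bony mandibular distal segment by the
#' right mental foramen (MF_R), pogonion (Pog), and left mental foramen
#' (MF_L).
#'
#' @format Named list of character vectors, in canonical (right, midline,
#'   left) vertex order.
#' @export
SEGMENT_LANDMARKS <- list(
  dental_maxilla = c("16", "UI", "26"),
  dental_mandible = c("46", "LI", "36"),
  bony_mandible = c("MF_R", "Pog", "MF_L")
)

#' @rdname SEGMENT_LANDMARKS
#' @export
SEGMENTS <- names(SEGMENT_LANDMARKS)

#' Frame tag written to and required from landmark files
#' @keywords internal
CANONICAL_FRAME <- "canonical_patient[+X=left,+Y=anterior,+Z=cranial]"

#' Construct a landmark set
#'
#' A landmark set holds the three named landmarks of one segment for one
#' patient at one timepoint, in mm in the canonical patient frame.
#'
#' @param patient_id patient identifier (character).
#' @param timepoint `"T0"` (pretreatment plan) or `"T1"` (presurgical plan).
#' @param segment one of `"dental_maxilla"`, `"dental_mandible"`,
#'   `"bony_mandible"`.
#' @param coords named list (or 3 x 3 matrix with rownames) mapping the
#'   segment's required landmark names to xyz coordinates in mm.
#' @return An object of class `landmark_set`.
#' @examples
#' landmark_set("p01", "T0", "dental_maxilla",
#'              list(`16` = c(-25, 0, 0), UI = c(0, 30, -2), `26` = c(25, 0, 0)))
#' @export
landmark_set <- function(patient_id, timepoint, segment, coords) {
  timepoint <- match.arg(timepoint, c("T0", "T1"))
  segment <- match.arg(segment, SEGMENTS)
  required <- SEGMENT_LANDMARKS[[segment]]
  if (is.matrix(coords)) {
    nm <- rownames(coords)
    coords <- lapply(seq_len(nrow(coords)), function(i) as.numeric(coords[i, ]))
    names(coords) <- nm
  }
  if (is.null(names(coords)) || !setequal(names(coords), required)) {
    stop(sprintf("segment '%s' requires exactly landmarks {%s}; got {%s}",
                 segment, paste(required, collapse = ", "),
                 paste(names(coords), collapse = ", ")), call. = FALSE)
  }
  m <- as_point_matrix(coords[required], "coords")
  rownames(m) <- required
  structure(list(patient_id = as.character(patient_id), timepoint = timepoint,
                 segment = segment, coords = m),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> patient %s, %s, %s\n",
              x$patient_id, x$timepoint, x$segment))
  print(round(x$coords, 4))
  invisible(x)
}

#' Apply a rigid transform to a landmark set
#'
#' @param transform A `rigid_transform`.
#' @param landmarks A `landmark_set`.
#' @return The transformed `landmark_set`.
#' @export
transform_landmarks <- function(transform, landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  landmarks$coords <- apply_transform(transform, landmarks$coords)
  landmarks
}

landmark_sets_to_df <- function(sets) {
  do.call(rbind, lapply(sets, function(ls) {
    data.frame(patient_id = ls$patient_id, timepoint = ls$timepoint,
               segment = ls$segment, landmark = rownames(ls$coords),
               x_mm = ls$coords[, 1], y_mm = ls$coords[, 2],
               z_mm = ls$coords[, 3], row.names = NULL,
               stringsAsFactors = FALSE)
  }))
}

df_to_landmark_sets <- function(df) {
  required <- c("patient_id", "timepoint", "segment", "landmark",
                "x_mm", "y_mm", "z_mm")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("landmark table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(df$patient_id, df$timepoint, df$segment, drop = TRUE)
  lapply(split(df, key), function(g) {
    coords <- lapply(seq_len(nrow(g)), function(i)
      c(g$x_mm[i], g$y_mm[i], g$z_mm[i]))
    names(coords) <- g$landmark
    landmark_set(g$patient_id[1], g$timepoint[1], g$segment[1], coords)
  })
}

#' Read and write landmark files
#'
#' The CSV dialect has a `# frame: ...` comment line followed by a header
#' `patient_id,timepoint,segment,landmark,x_mm,y_mm,z_mm`; the JSON dialect
#' stores the same records under `"landmarks"` with the frame tag under
#' `"frame"`. Readers validate the frame tag: all coordinates must be
#' expressed in the canonical patient frame.
#'
#' @param path file path.
#' @param sets list of `landmark_set` objects.
#' @param format `"csv"` or `"json"` (chosen from the file extension by
#'   default).
#' @return `read_landmarks()` returns a list of `landmark_set` objects;
#'   the writers return `path` invisibly.
#' @export
read_landmarks <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$frame) || obj$frame != CANONICAL_FRAME) {
      stop("landmark file '", path, "' does not declare the canonical patient frame",
           call. = FALSE)
    }
    df <- as.data.frame(obj$landmarks)
  } else {
    first <- readLines(path, n = 1L)
    if (!grepl(CANONICAL_FRAME, first, fixed = TRUE)) {
      stop("landmark file '", path, "' does not declare the canonical patient frame",
           call. = FALSE)
    }
    df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = c(patient_id = "character"))
  }
  df_to_landmark_sets(df)
}

#' @rdname read_landmarks
#' @export
write_landmarks_csv <- function(sets, path) {
  df <- landmark_sets_to_df(sets)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# frame: ", CANONICAL_FRAME), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_landmarks
#' @export
write_landmarks_json <- function(sets, path) {
  df <- landmark_sets_to_df(sets)
  jsonlite::write_json(list(frame = CANONICAL_FRAME, landmarks = df), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
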