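# Segment meshes and STL input/output (both ASCII and binary dialects).

#' Construct a segment mesh
#'
#' A triangulated surface of one osteotomized segment. An optional region
#' mask (vertex indices) marks the reference region to be used during
#' surface registration, e.g. the bony non-dental part of the maxilla.
#'
#' @param vertices n x 3 matrix of vertex coordinates, mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param label segment identifier.
#' @param mask optional integer vector of vertex indices forming the
#'   registration region.
#' @return An object of class `segment_mesh`.
#' @export
segment_mesh <- function(vertices, faces, label = "segment", mask = NULL) {
  vertices <- as_point_matrix(vertices, "vertices")
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(vertices) < 3L) stop("mesh needs at least 3 vertices", call. = FALSE)
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range", call. = FALSE)
  }
  sv <- svd(sweep(vertices, 2, colMeans(vertices)), nu = 0, nv = 0)$d
  if (sv[2] < DEGENERACY_TOL) {
    stop("mesh vertices are collinear (degenerate geometry)", call. = FALSE)
  }
  if (!is.null(mask)) {
    mask <- unique(as.integer(mask))
    if (length(mask) == 0L || min(mask) < 1L || max(mask) > nrow(vertices)) {
      stop("mask must be a non-empty set of valid vertex indices", call. = FALSE)
    }
  }
  structure(list(vertices = vertices, faces = faces,
                 label = as.character(label), mask = mask),
            class = "segment_mesh")
}

#' @export
print.segment_mesh <- function(x, ...) {
  cat(sprintf("<segment_mesh> '%s': %d vertices, %d faces%s\n", x$label,
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$mask)) "" else
                sprintf(", mask of %d vertices", length(x$mask))))
  invisible(x)
}

#' Apply a rigid transform to a mesh
#' @param transform A `rigid_transform`.
#' @param mesh A `segment_mesh`.
#' @return The transformed `segment_mesh`.
#' @export
transform_mesh <- function(transform, mesh) {
  stopifnot(inherits(mesh, "segment_mesh"))
  mesh$vertices <- apply_transform(transform, mesh$vertices)
  mesh
}

#' Read and write STL surface files
#'
#' Supports both the ASCII and the little-endian binary STL dialects.
#' STL stores independent facets; on reading, vertices are merged exactly
#' (by identical coordinates) to recover a shared-vertex mesh.
#'
#' @param path file path.
#' @param mesh A `segment_mesh`.
#' @param label segment label for the returned mesh.
#' @param ascii write the ASCII dialect (`TRUE`) or binary (`FALSE`).
#' @return `read_stl()` returns a `segment_mesh`; `write_stl()` returns
#'   `path` invisibly.
#' @export
read_stl <- function(path, label = "segment") {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 5L)
  close(con)
  if (length(head) < 5L) stop("'", path, "' is not a valid STL file", call. = FALSE)
  is_ascii <- identical(rawToChar(head), "solid") && {
    # binary STL may also begin with "solid": check for "facet" in the text
    txt <- tryCatch(suppressWarnings(readLines(path, n = 50L)),
                    error = function(e) character(0))
    any(grepl("facet", txt, fixed = TRUE))
  }
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  if (nrow(tri) == 0L || nrow(tri) %% 3L != 0L) {
    stop("'", path, "' is corrupt: facet vertex count is not a multiple of 3",
         call. = FALSE)
  }
  key <- apply(tri, 1, paste, collapse = ",")
  idx <- match(key, unique(key))
  vertices <- tri[!duplicated(idx), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  bad <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  segment_mesh(vertices, faces[!bad, , drop = FALSE], label = label)
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vx <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vx) == 0L) stop("'", path, "' is corrupt: no vertex records", call. = FALSE)
  parts <- strsplit(trimws(vx), "\\s+")
  coords <- suppressWarnings(
    t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3))))
  if (anyNA(coords)) stop("'", path, "' is corrupt: non-numeric vertex", call. = FALSE)
  coords
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  expected <- 84 + n * 50
  if (is.na(n) || n < 0 || file.size(path) < expected) {
    stop("'", path, "' is corrupt: binary STL facet count does not match file size",
         call. = FALSE)
  }
  tri <- matrix(0, 3L * n, 3L)
  for (i in seq_len(n)) {
    vals <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
    readBin(con, "raw", 2L)
    tri[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
  }
  tri
}

#' @rdname read_stl
#' @export
write_stl <- function(mesh, path, ascii = TRUE) {
  stopifnot(inherits(mesh, "segment_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s", mesh$label), con)
    for (i in seq_len(nrow(f))) {
      p <- v[f[i, ], , drop = FALSE]
      nrm <- face_normal(p)
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", nrm[1], nrm[2], nrm[3]),
                   "    outer loop",
                   sprintf("      vertex %.9g %.9g %.9g", p[, 1], p[, 2], p[, 3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines(sprintf("endsolid %s", mesh$label), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(formatC(mesh$label, width = -80))[1:80]
    header[is.na(header)] <- as.raw(0)
    writeBin(header, con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      p <- v[f[i, ], , drop = FALSE]
      writeBin(c(face_normal(p), t(p)), con, size = 4L, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  }
  invisible(path)
}

face_normal <- function(p) {
  e1 <- p[2, ] - p[1, ]
  e2 <- p[3, ] - p[1, ]
  n <- c(e1[2] * e2[3] - e1[3] * e2[2],
         e1[3] * e2[1] - e1[1] * e2[3],
         e1[1] * e2[2] - e1[2] * e2[1])
  len <- sqrt(sum(n^2))
  if (len < 1e-12) c(0, 0, 0) else n / len
}

#' Read a region mask sidecar file
#'
#' One 1-based vertex index per line; blank lines and `#` comments ignored.
#'
#' @param path sidecar file path.
#' @return Integer vector of vertex indices.
#' @export
read_region_mask <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- trimws(sub("#.*$", "", txt))
  txt <- txt[nzchar(txt)]
  idx <- suppressWarnings(as.integer(txt))
  if (anyNA(idx)) stop("mask file '", path, "' contains non-integer lines",
                       call. = FALSE)
  idx
}

#' Derive a region mask from an axis-aligned bounding box
#'
#' @param mesh A `segment_mesh`.
#' @param xlim,ylim,zlim length-2 numeric ranges in mm; `NULL` means
#'   unbounded on that axis.
#' @return Integer vector of vertex indices inside the box.
#' @export
mask_from_bbox <- function(mesh, xlim = NULL, ylim = NULL, zlim = NULL) {
  stopifnot(inherits(mesh, "segment_mesh"))
  v <- mesh$vertices
  keep <- rep(TRUE, nrow(v))
  clip <- function(keep, col, lim) {
    if (is.null(lim)) keep else keep & v[, col] >= lim[1] & v[, col] <= lim[2]
  }
  keep <- clip(keep, 1, xlim); keep <- clip(keep, 2, ylim); keep <- clip(keep, 3, zlim)
  which(keep)
}
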