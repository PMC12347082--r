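# Surface registration: landmark-initialized trimmed iterative closest
# point (point-to-point) between segment meshes. This stands in for the
# voxel-based cranial-base registration of the imaging workflow: a
# landmark-based rigid initialization followed by surface matching on the
# bony (non-dental) reference region.

#' Rigid initialization from shared named landmarks
#'
#' Kabsch superimposition over the landmarks the two sets share by name.
#' Used to initialize surface registration (a landmark surrogate for
#' volume-based registration, which operates on image intensities and is
#' outside this package's scope).
#'
#' @param source_landmarks,target_landmarks `landmark_set` objects (any
#'   segments); at least 3 shared, non-collinear landmark names required.
#' @return A `rigid_transform` mapping source onto target.
#' @export
landmark_initialize <- function(source_landmarks, target_landmarks) {
  stopifnot(inherits(source_landmarks, "landmark_set"),
            inherits(target_landmarks, "landmark_set"))
  shared <- intersect(rownames(source_landmarks$coords),
                      rownames(target_landmarks$coords))
  if (length(shared) < 3L) {
    stop(sprintf("need >= 3 shared landmark names, found %d", length(shared)),
         call. = FALSE)
  }
  kabsch_rigid(source_landmarks$coords[shared, , drop = FALSE],
               target_landmarks$coords[shared, , drop = FALSE])
}

# Chunked brute-force nearest neighbour: for each row of `query`, the index
# of the closest row of `ref` and the squared distance. Chunking keeps the
# distance matrix small enough to stay cache- and memory-friendly.
nearest_neighbours <- function(query, ref, chunk = 512L) {
  nq <- nrow(query)
  ref_sq <- rowSums(ref^2)
  idx <- integer(nq)
  d2 <- numeric(nq)
  for (start in seq(1L, nq, by = chunk)) {
    end <- min(start + chunk - 1L, nq)
    q <- query[start:end, , drop = FALSE]
    # squared distances via the expansion |q - r|^2 = |q|^2 - 2 q.r + |r|^2
    cross <- tcrossprod(q, ref)
    d2m <- sweep(-2 * cross, 2, ref_sq, "+") + rowSums(q^2)
    j <- max.col(-d2m, ties.method = "first")
    idx[start:end] <- j
    d2[start:end] <- pmax(d2m[cbind(seq_len(nrow(d2m)), j)], 0)
  }
  list(index = idx, dist2 = d2)
}

#' Uniformly subsample mesh vertices
#'
#' Deterministic uniform subsampling (evenly spaced by vertex index) used
#' to bound registration cost on dense scans.
#'
#' @param mesh A `segment_mesh`.
#' @param n_max maximum number of vertices to keep.
#' @return Integer vector of kept vertex indices.
#' @export
subsample_vertices <- function(mesh, n_max = 5000L) {
  n <- nrow(mesh$vertices)
  if (n <= n_max) seq_len(n) else unique(round(seq(1L, n, length.out = n_max)))
}

#' Trimmed iterative closest point registration
#'
#' Point-to-point ICP with nearest-neighbour correspondences on vertices.
#' Each iteration discards the `trim_fraction` largest squared residuals
#' before the Kabsch update, making the fit robust to non-overlapping or
#' outlying geometry. If the source mesh carries a region mask, only
#' masked vertices participate (so registration can be driven by the bony
#' non-dental reference region alone). The trimmed RMS residual is
#' non-increasing across iterations.
#'
#' @param source,target `segment_mesh` objects.
#' @param init initial `rigid_transform` (e.g. from
#'   [landmark_initialize()]); identity by default.
#' @param trim_fraction fraction of worst correspondences discarded each
#'   iteration, in `[0, 0.5)`. Default 0.1.
#' @param tol convergence threshold on the change in trimmed RMS residual,
#'   mm. Default 1e-6.
#' @param max_iter iteration cap. Default 200.
#' @param n_max vertex subsampling cap per mesh (see
#'   [subsample_vertices()]). Default 5000.
#' @param gate_factor correspondence gate: registration is abandoned with
#'   a diagnostic (not an error) if the median nearest-neighbour distance
#'   at initialization exceeds `gate_factor` times the target's median
#'   vertex spacing. Default 10.
#' @return A `registration_result`: list with `transform`
#'   (`rigid_transform`), `rms_residual` (mm), `n_iterations`, `converged`,
#'   `trimmed_fraction_used`, `residual_history`, and `failure` (`NULL`,
#'   or a diagnostic string when the clouds do not overlap).
#' @export
icp_register <- function(source, target, init = identity_transform(),
                         trim_fraction = 0.1, tol = 1e-6, max_iter = 200L,
                         n_max = 5000L, gate_factor = 10) {
  stopifnot(inherits(source, "segment_mesh"), inherits(target, "segment_mesh"))
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    stop("`trim_fraction` must be in [0, 0.5)", call. = FALSE)
  }
  src_idx <- if (!is.null(source$mask)) source$mask else seq_len(nrow(source$vertices))
  if (length(src_idx) > n_max) {
    src_idx <- src_idx[unique(round(seq(1L, length(src_idx), length.out = n_max)))]
  }
  src <- source$vertices[src_idx, , drop = FALSE]
  tgt <- target$vertices[subsample_vertices(target, n_max), , drop = FALSE]

  # overlap gate: compare initial correspondence distances with the
  # target's own typical vertex spacing
  spacing <- stats::median(sqrt(nearest_self_dist2(tgt)))
  cur <- init
  moved <- apply_transform(cur, src)
  nn <- nearest_neighbours(moved, tgt)
  if (stats::median(sqrt(nn$dist2)) > gate_factor * spacing) {
    return(structure(list(transform = init, rms_residual = sqrt(mean(nn$dist2)),
                          n_iterations = 0L, converged = FALSE,
                          trimmed_fraction_used = trim_fraction,
                          residual_history = numeric(0),
                          failure = "non-overlapping point clouds (median correspondence distance exceeds gate)"),
                     class = "registration_result"))
  }

  n_keep <- max(3L, ceiling((1 - trim_fraction) * nrow(src)))
  history <- numeric(0)
  prev_rms <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    nn <- nearest_neighbours(moved, tgt)
    keep <- order(nn$dist2)[seq_len(n_keep)]
    # recompute kept residuals directly: the |q|^2 - 2 q.r + |r|^2 expansion
    # used for the search loses precision near zero
    d2 <- rowSums((moved[keep, , drop = FALSE] -
                     tgt[nn$index[keep], , drop = FALSE])^2)
    rms <- sqrt(mean(d2))
    history <- c(history, rms)
    if (abs(prev_rms - rms) < tol) {
      converged <- TRUE
      break
    }
    prev_rms <- rms
    step <- kabsch_rigid(moved[keep, , drop = FALSE],
                         tgt[nn$index[keep], , drop = FALSE])
    cur <- compose_transform(step, cur)
    moved <- apply_transform(cur, src)
  }
  structure(list(transform = cur, rms_residual = history[length(history)],
                 n_iterations = it, converged = converged,
                 trimmed_fraction_used = trim_fraction,
                 residual_history = history, failure = NULL),
            class = "registration_result")
}

# squared distance from each point to its nearest *other* point in the set
nearest_self_dist2 <- function(pts, chunk = 512L) {
  n <- nrow(pts)
  sq <- rowSums(pts^2)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    end <- min(start + chunk - 1L, n)
    q <- pts[start:end, , drop = FALSE]
    d2m <- sweep(-2 * tcrossprod(q, pts), 2, sq, "+") + rowSums(q^2)
    d2m[cbind(seq_len(nrow(d2m)), start:end)] <- Inf
    out[start:end] <- pmax(apply(d2m, 1, min), 0)
  }
  out
}

#' @export
print.registration_result <- function(x, ...) {
  cat("<registration_result>\n")
  if (!is.null(x$failure)) {
    cat("  FAILED:", x$failure, "\n")
  } else {
    cat(sprintf("  rms residual %.6g mm after %d iterations (converged: %s)\n",
                x$rms_residual, x$n_iterations, x$converged))
  }
  invisible(x)
}
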