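# Shared fixture builders. Everything is generated in code; no binary
# fixtures are stored.

# uniform random rotation via QR of a Gaussian matrix, sign-fixed to det +1
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_transform <- function(trans_scale = 10) {
  rigid_transform(random_rotation(), stats::rnorm(3, sd = trans_scale))
}

# a well-conditioned non-degenerate point set
random_points <- function(n = 5, sd = 20) {
  matrix(stats::rnorm(3 * n, sd = sd), n, 3)
}

# landmark sets for one synthetic patient at T0 (template anatomy)
template_t0 <- function(patient_id = "p01") {
  sets <- template_anatomy()$landmarks
  lapply(sets, function(s) { s$patient_id <- patient_id; s })
}

# displace a T0 landmark-set list by per-segment 6-DOF ground truth
# (rotation about each segment's triangle centroid), returning T1 sets
displace_t0 <- function(t0, truth) {
  lapply(t0, function(s) {
    th <- truth[[s$segment]]
    ctr <- colMeans(s$coords)
    R <- clinical_rotation(th[1], th[2], th[3])
    tr <- rigid_transform(R, ctr - as.numeric(R %*% ctr) + th[4:6])
    s1 <- transform_landmarks(tr, s)
    s1$timepoint <- "T1"
    s1
  })
}

# small cohort table with hand-enterable values for the stats layer
toy_cohort <- function(values_by_segment) {
  do.call(rbind, lapply(names(values_by_segment), function(seg) {
    v <- values_by_segment[[seg]]
    n <- nrow(v)
    data.frame(patient_id = sprintf("P%02d", seq_len(n)), segment = seg,
               pitch = v[, 1], roll = v[, 2], yaw = v[, 3],
               trans_LR = v[, 4], trans_AP = v[, 5], trans_UD = v[, 6],
               stringsAsFactors = FALSE)
  }))
}
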