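# Independent oracles and programmatic fixtures shared across the suite.

# Exact two-sided Mann-Whitney p by full enumeration of all rank assignments
# (tie-free samples only). Counts assignments with U at least as extreme as
# observed on both tails.
mw_enumeration_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  u_of <- function(idx_a) {
    av <- pooled[idx_a]; bv <- pooled[-idx_a]
    sum(outer(av, bv, ">"))
  }
  u_obs <- u_of(seq_len(na))
  all_u <- apply(utils::combn(na + nb, na), 2, u_of)
  mu <- na * nb / 2
  mean(abs(all_u - mu) >= abs(u_obs - mu) - 1e-9)
}

# Signed polygon area by fan triangulation from the first vertex.
fan_area_oracle <- function(poly) {
  x <- poly[, 1] - poly[1, 1]
  y <- poly[, 2] - poly[1, 2]
  n <- nrow(poly)
  s <- 0
  for (i in 2:(n - 1))
    s <- s + (x[i] * y[i + 1] - x[i + 1] * y[i]) / 2
  s
}

# Star-shaped (hence simple) random polygon: sorted angles, random radii.
random_simple_polygon <- function(n) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, 0.2, 2)
  cbind(r * cos(th), r * sin(th))
}

# Uniformly random 3D rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Planar ellipse loop in a known tilted frame; returns points and the normal.
make_tilted_ellipse <- function(a = 1, b = 0.5, n = 400) {
  R <- random_rotation()
  u1 <- R[, 1]; u2 <- R[, 2]; normal <- R[, 3]
  th <- seq(0, 2 * pi, length.out = n)
  pts <- outer(a * cos(th), u1) + outer(b * sin(th), u2)
  list(points = pts, normal = normal, u1 = u1, u2 = u2)
}

# Write a minimal WFDB format-16 header/data fixture; returns the record path
# (without extension). Signal matrix in mV; one interleaved .dat.
write_wfdb_fixture <- function(dir, name, sig_mv, fs = 1000, gain = 10000,
                               leads = c("vx", "vy", "vz")) {
  sig_mv <- as.matrix(sig_mv)
  nsig <- ncol(sig_mv)
  adu <- round(sig_mv * gain)
  stopifnot(max(abs(adu)) < 32768)
  hea <- file.path(dir, paste0(name, ".hea"))
  dat <- paste0(name, ".dat")
  lines <- c(sprintf("%s %d %g %d", name, nsig, fs, nrow(sig_mv)),
             vapply(seq_len(nsig), function(j)
               sprintf("%s 16 %d(0)/mV 16 0 %d 0 0 %s",
                       dat, gain, as.integer(adu[1, j]), leads[j]), ""))
  writeLines(lines, hea)
  inter <- as.integer(t(adu))
  writeBin(inter, file.path(dir, dat), size = 2L, endian = "little")
  file.path(dir, name)
}

# The desk-scale study cohort (the generator defaults) and its feature
# table, computed once per test session and reused by the screening,
# stacking and acceptance checks.
.study_cache <- new.env(parent = emptyenv())

study_feature_table <- function() {
  if (is.null(.study_cache$ft)) {
    cfg <- synthetic_config(seed = 20260901)
    cohort <- generate_cohort(cfg)
    .study_cache$cohort <- cohort
    .study_cache$ft <- cohort_features(cohort$records)
  }
  .study_cache$ft
}

study_cohort <- function() {
  study_feature_table()
  .study_cache$cohort
}
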