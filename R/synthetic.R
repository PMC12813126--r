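#' Configuration for the synthetic VCG cohort generator
#'
#' The generator emulates the aspects of real Frank-lead recordings that the
#' downstream pipeline measures: beat trains at ECG-like sampling rates whose
#' QRS and T loops are planar ellipses in randomly tilted planes with known
#' area, perimeter and tracing speed; class-dependent morphology (MI records
#' have reduced QRS-loop area and reduced T-loop tracing velocity, the two
#' hallmark infarction shifts the feature screen should recover); slow
#' sinusoidal baseline wander; and additive white measurement noise.
#'
#' @param n_mi,n_hc Number of MI / healthy-control records.
#' @param fs Sampling rate in Hz.
#' @param duration_s Record duration in seconds.
#' @param heart_rate_bpm Length-2 range; each record draws its rate uniformly.
#' @param qrs_radius_mv,t_radius_mv Major half-axis of the QRS / T ellipse in
#'   mV (minor half-axis is half the major).
#' @param qrs_duration_ms,t_duration_ms Loop tracing durations.
#' @param mi_qrs_area_scale Multiplier in (0,1] applied to the QRS loop area
#'   of MI records, realized by shrinking the minor half-axis: the enclosed
#'   area scales by exactly this factor while the loop's peak amplitude (and
#'   hence arc length and velocities, approximately) is preserved, so the
#'   area feature carries the infarction signature.
#' @param mi_t_velocity_scale Multiplier in (0,1] applied to the T-loop
#'   tracing speed of MI records, split between a modest size reduction
#'   (half-axes by `scale^0.3`) and slowed tracing (duration by
#'   `scale^-0.7`), mirroring the combination of lower T amplitude and
#'   delayed repolarization; the product scales every velocity statistic by
#'   exactly the factor.
#' @param wander_amp_mv,wander_freq_hz Baseline-wander sinusoid amplitude and
#'   frequency; the default 0.15 Hz sits below the ~0.416 Hz Savitzky-Golay
#'   cutoff so detrending should remove it.
#' @param noise_sd_mv Additive white-noise standard deviation.
#' @param record_scale_sd,loop_scale_sd Log-normal standard deviations of the
#'   between-record amplitude heterogeneity: each record draws one global
#'   amplitude factor (`record_scale_sd`) plus independent QRS and T loop
#'   size factors (`loop_scale_sd`), emulating inter-patient variability so
#'   the two classes overlap instead of separating trivially.
#' @param seed Master seed; identical configurations generate bit-identical
#'   cohorts.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_mi = 40, n_hc = 40, fs = 1000, duration_s = 10,
                             heart_rate_bpm = c(60, 90),
                             qrs_radius_mv = 1.2, t_radius_mv = 0.35,
                             qrs_duration_ms = 90, t_duration_ms = 160,
                             mi_qrs_area_scale = 0.5, mi_t_velocity_scale = 0.6,
                             wander_amp_mv = 0.1, wander_freq_hz = 0.15,
                             noise_sd_mv = 0.003, record_scale_sd = 0.15,
                             loop_scale_sd = 0.08, seed = 1L) {
  cfg <- list(n_mi = n_mi, n_hc = n_hc, fs = fs, duration_s = duration_s,
              heart_rate_bpm = heart_rate_bpm,
              qrs_radius_mv = qrs_radius_mv, t_radius_mv = t_radius_mv,
              qrs_duration_ms = qrs_duration_ms, t_duration_ms = t_duration_ms,
              mi_qrs_area_scale = mi_qrs_area_scale,
              mi_t_velocity_scale = mi_t_velocity_scale,
              wander_amp_mv = wander_amp_mv, wander_freq_hz = wander_freq_hz,
              noise_sd_mv = noise_sd_mv, record_scale_sd = record_scale_sd,
              loop_scale_sd = loop_scale_sd, seed = as.integer(seed))
  scales <- c(cfg$mi_qrs_area_scale, cfg$mi_t_velocity_scale)
  if (any(scales <= 0) || any(scales > 1))
    stopf("MI effect scales must lie in (0, 1]")
  if (cfg$wander_amp_mv < 0 || cfg$noise_sd_mv < 0 ||
      cfg$qrs_radius_mv < 0 || cfg$t_radius_mv < 0)
    stopf("amplitudes must be >= 0")
  if (cfg$fs <= 0 || cfg$duration_s <= 0) stopf("fs and duration_s must be > 0")
  class(cfg) <- "synthetic_config"
  cfg
}

# random right-handed orthonormal frame (u1, u2, normal), seeded by caller
random_frame <- function() {
  repeat {
    a <- stats::rnorm(3); b <- stats::rnorm(3)
    u1 <- a / sqrt(sum(a^2))
    b <- b - sum(b * u1) * u1
    nb <- sqrt(sum(b^2))
    if (nb > 1e-8) break
  }
  u2 <- b / nb
  n <- c(u1[2] * u2[3] - u1[3] * u2[2],
         u1[3] * u2[1] - u1[1] * u2[3],
         u1[1] * u2[2] - u1[2] * u2[1])
  list(u1 = u1, u2 = u2, normal = n)
}

# exact ellipse perimeter (numerical quadrature of the arc integrand)
ellipse_perimeter <- function(a, b) {
  4 * stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                       0, pi / 2, rel.tol = 1e-10)$value
}

# ellipse traced from and back to the origin: P(theta) = a(1-cos)u1 + b sin u2,
# peak |P| = 2a at theta = pi (the R/T apex), enclosed area = pi a b
ellipse_points <- function(a, b, n, frame) {
  th <- seq(0, 2 * pi, length.out = n)
  outer(a * (1 - cos(th)), frame$u1) + outer(b * sin(th), frame$u2)
}

#' Generate a labeled synthetic VCG cohort with ground truth
#'
#' @param config A [synthetic_config()].
#' @return A list with `records` (list of [vcg_record]) and `truth` (list of
#'   per-record ground truth: `r_peak_samples`, per-beat `true_qrs_area` in
#'   mV^2 and `true_t_mean_velocity` in mV/s, the QRS/T plane normals, and
#'   `label`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  labels <- c(rep("MI", config$n_mi), rep("HC", config$n_hc))
  ids <- sprintf("%s%03d", tolower(labels), c(seq_len(config$n_mi), seq_len(config$n_hc)))
  records <- vector("list", length(labels))
  truth <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    g <- with_seed(derive_seed(config$seed, paste0("record-", ids[i])),
                   generate_record(config, ids[i], labels[i]))
    records[[i]] <- g$record
    truth[[i]] <- g$truth
  }
  list(records = records, truth = truth)
}

generate_record <- function(config, record_id, label) {
  fs <- config$fs
  n <- round(fs * config$duration_s)
  mi <- identical(label, "MI")
  nq <- max(8L, round(fs * config$qrs_duration_ms / 1000))
  # T velocity effect: size shrinks by scale^0.3, tracing slows by scale^-0.7
  t_size <- if (mi) config$mi_t_velocity_scale^0.3 else 1
  t_dur_s <- config$t_duration_ms / 1000 *
    (if (mi) config$mi_t_velocity_scale^-0.7 else 1)
  nt <- max(8L, round(fs * t_dur_s))
  # between-record (inter-patient) amplitude heterogeneity, fixed per record
  amp <- exp(stats::rnorm(1, 0, config$record_scale_sd))
  qrs_amp <- amp * exp(stats::rnorm(1, 0, config$loop_scale_sd))
  t_amp <- amp * exp(stats::rnorm(1, 0, config$loop_scale_sd))
  qrs_a0 <- config$qrs_radius_mv * qrs_amp
  # QRS area effect sits on the minor half-axis (peak amplitude preserved)
  qrs_b_scale <- if (mi) config$mi_qrs_area_scale else 1
  t_a0 <- config$t_radius_mv * t_amp * t_size
  hr <- stats::runif(1, config$heart_rate_bpm[1], config$heart_rate_bpm[2])
  rr0 <- 60 / hr * fs
  frame_q <- random_frame()
  frame_t <- random_frame()
  sig <- matrix(0, nrow = n, ncol = 3)
  t_on <- round(0.180 * fs)                 # T apex window start after R
  tail_need <- t_on + nt                    # samples needed after each R
  r <- round(0.5 * fs)
  r_peaks <- integer(0)
  qrs_area <- numeric(0); t_meanvel <- numeric(0)
  while (r - nq %/% 2 >= 1 && r + tail_need <= n) {
    jit <- function() 1 + stats::runif(1, -0.05, 0.05)   # <=5% beat variability
    aq <- qrs_a0 * jit(); bq <- 0.5 * aq * qrs_b_scale
    at <- t_a0 * jit(); bt <- 0.5 * at
    qi <- (r - nq %/% 2) + seq_len(nq) - 1L
    sig[qi, ] <- sig[qi, ] + ellipse_points(aq, bq, nq, frame_q)
    ti <- (r + t_on) + seq_len(nt) - 1L
    sig[ti, ] <- sig[ti, ] + ellipse_points(at, bt, nt, frame_t)
    r_peaks <- c(r_peaks, r)
    qrs_area <- c(qrs_area, pi * aq * bq)
    t_meanvel <- c(t_meanvel, ellipse_perimeter(at, bt) / t_dur_s)
    r <- r + round(rr0 * jit())
  }
  if (length(r_peaks) == 0L)
    stopf("degenerate synthetic config: no beat fits in %.3g s at %g bpm",
          config$duration_s, hr)
  tvec <- (seq_len(n) - 1) / fs
  for (j in 1:3) {
    phase <- stats::runif(1, 0, 2 * pi)
    sig[, j] <- sig[, j] +
      config$wander_amp_mv * sin(2 * pi * config$wander_freq_hz * tvec + phase) +
      stats::rnorm(n, sd = config$noise_sd_mv)
  }
  list(record = vcg_record(sig[, 1], sig[, 2], sig[, 3], fs = fs,
                           record_id = record_id, label = label),
       truth = list(record_id = record_id, label = label,
                    r_peak_samples = r_peaks,
                    true_qrs_area = qrs_area,
                    true_t_mean_velocity = t_meanvel,
                    qrs_plane_normal = frame_q$normal,
                    t_plane_normal = frame_t$normal))
}

#' Write a generated cohort as CSV records plus a ground-truth JSON sidecar
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly. One `<record_id>.csv` per record plus
#'   `ground_truth.json` mapping record ids to R peaks, per-beat truths and
#'   labels.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$records)
    write_csv_record(rec, file.path(dir, paste0(rec$record_id, ".csv")))
  gt <- lapply(cohort$truth, function(tr)
    tr[c("label", "r_peak_samples", "true_qrs_area", "true_t_mean_velocity")])
  names(gt) <- vapply(cohort$truth, `[[`, "", "record_id")
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}
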