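#' Delineation constants
#'
#' Fixed physiologic windows used to cut each detected beat into its QRS and
#' T loops: QRS = R +/- `qrs_half_ms`; T = `[R + t_on_ms, R + min(t_off_ms_cap,
#' t_off_rr_frac * RR)]`. The R-peak detector uses an adaptive threshold of
#' `threshold_frac` times the rolling 2-s maximum of the spatial magnitude
#' with a `refractory_ms` lockout.
#'
#' @param qrs_half_ms Half-width of the QRS window in ms.
#' @param t_on_ms T-window onset after R in ms.
#' @param t_off_ms_cap Maximum T-window offset after R in ms.
#' @param t_off_rr_frac T-window offset cap as a fraction of the RR interval.
#' @param refractory_ms Detector refractory period in ms.
#' @param threshold_frac Detector threshold as a fraction of the rolling max.
#' @return A list of class `delineation_config`.
#' @export
delineation_config <- function(qrs_half_ms = 60, t_on_ms = 120,
                               t_off_ms_cap = 450, t_off_rr_frac = 0.7,
                               refractory_ms = 200, threshold_frac = 0.5) {
  structure(list(qrs_half_ms = qrs_half_ms, t_on_ms = t_on_ms,
                 t_off_ms_cap = t_off_ms_cap, t_off_rr_frac = t_off_rr_frac,
                 refractory_ms = refractory_ms, threshold_frac = threshold_frac),
            class = "delineation_config")
}

#' Spatial magnitude of a VCG record
#'
#' Element-wise Euclidean norm `sqrt(x^2 + y^2 + z^2)` of the cardiac vector,
#' used for R-peak detection.
#'
#' @param record A [vcg_record].
#' @return Numeric vector in mV.
#' @export
spatial_magnitude <- function(record) {
  stopifnot(inherits(record, "vcg_record"))
  sqrt(record$x^2 + record$y^2 + record$z^2)
}

#' Detect R peaks on a spatial-magnitude series
#'
#' Local maxima exceeding an adaptive threshold (`threshold_frac` times the
#' rolling 2-s maximum), with a refractory lockout. May return an empty
#' vector.
#'
#' @param magnitude Numeric series (mV), e.g. from [spatial_magnitude()].
#' @param fs Sampling rate in Hz.
#' @param config A [delineation_config()].
#' @return Strictly increasing integer sample indices.
#' @export
detect_r_peaks <- function(magnitude, fs, config = delineation_config()) {
  n <- length(magnitude)
  if (n < fs / 2) stopf("series too short for R-peak detection (%d samples)", n)
  thr <- config$threshold_frac * rolling_max(magnitude, round(2 * fs))
  m <- magnitude
  is_max <- c(FALSE, diff(m) > 0) & c(m[-n] >= m[-1], FALSE)
  cand <- which(is_max & m > thr & m > 0)
  if (length(cand) == 0L) return(integer(0))
  refr <- round(config$refractory_ms / 1000 * fs)
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= refr) {
      keep <- c(keep, i)
      last <- i
    } else if (m[i] > m[keep[length(keep)]]) {
      keep[length(keep)] <- i          # larger peak inside refractory wins
      last <- i
    }
  }
  keep
}

#' Cut a record into per-beat QRS and T loop point sets
#'
#' Per beat, the QRS loop holds the samples within `qrs_half_ms` of the R
#' peak and the T loop the samples from `t_on_ms` after R to
#' `min(t_off_ms_cap, t_off_rr_frac * RR)` after R. Beats whose windows
#' exceed the record, or with a preceding RR below 300 ms, are dropped
#' (counted in the `dropped` attribute).
#'
#' @param record A [vcg_record] (normally the detrended record).
#' @param r_peaks Increasing sample indices from [detect_r_peaks()].
#' @param config A [delineation_config()].
#' @return List of `beat_loops` objects, each with `r_index`, `qrs_points`
#'   and `t_points` (n x 3 matrices in mV) and `rr_prev_ms`; attribute
#'   `dropped` counts discarded beats.
#' @export
segment_beats <- function(record, r_peaks, config = delineation_config()) {
  stopifnot(inherits(record, "vcg_record"))
  fs <- record$fs
  n <- length(record$x)
  qh <- round(config$qrs_half_ms / 1000 * fs)
  t_on <- round(config$t_on_ms / 1000 * fs)
  rr <- diff(c(NA, r_peaks))
  # the last beat has no following beat: use the preceding RR (or cap) for it
  rr_ms <- rr / fs * 1000
  beats <- list()
  dropped <- 0L
  for (k in seq_along(r_peaks)) {
    r <- r_peaks[k]
    rr_k <- if (k > 1) rr_ms[k] else Inf
    t_off <- round(min(config$t_off_ms_cap,
                       if (is.finite(rr_k)) config$t_off_rr_frac * rr_k
                       else config$t_off_ms_cap) / 1000 * fs)
    if (is.finite(rr_k) && rr_k < 300) { dropped <- dropped + 1L; next }
    if (r - qh < 1 || r + t_off > n) { dropped <- dropped + 1L; next }
    qrs_idx <- (r - qh):(r + qh)
    t_idx <- (r + t_on):(r + t_off)
    if (length(qrs_idx) < 4 || length(t_idx) < 4) { dropped <- dropped + 1L; next }
    beats[[length(beats) + 1L]] <- structure(
      list(r_index = r,
           qrs_points = record_points(record, qrs_idx),
           t_points = record_points(record, t_idx),
           rr_prev_ms = rr_k),
      class = "beat_loops")
  }
  attr(beats, "dropped") <- dropped
  beats
}
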