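#' Savitzky-Golay baseline filter specification
#'
#' The baseline-wander remover fits a long-window low-order local polynomial
#' (Savitzky-Golay smooth) to each lead and subtracts it. The defaults --
#' window of 1201 samples, order 2, at 1 kHz -- give an approximate cutoff
#' of 0.416 Hz, below typical respiratory wander but far below QRS content.
#'
#' @param window Odd positive window length in samples.
#' @param order Polynomial order, `< window`.
#' @param fs Sampling rate in Hz.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(window = 1201, order = 2, fs = 1000) {
  window <- as.integer(window); order <- as.integer(order)
  if (window < 1L || window %% 2L == 0L) stopf("window must be odd and positive")
  if (order < 0L || order >= window) stopf("order must satisfy 0 <= order < window")
  if (fs <= 0) stopf("fs must be > 0")
  structure(list(window = window, order = order, fs = fs), class = "filter_spec")
}

#' Approximate cutoff frequency of the Savitzky-Golay baseline smoother
#'
#' For the second-order smoother the approximate -3 dB point is
#' `fs / (2 * window)`; at the default window of 1201 samples and 1 kHz this
#' is approximately 0.416 Hz.
#'
#' @param spec A [filter_spec()].
#' @return Cutoff frequency in Hz.
#' @export
sg_cutoff <- function(spec) {
  stopifnot(inherits(spec, "filter_spec"))
  spec$fs / (2 * spec$window)
}

#' Remove baseline wander from a VCG record
#'
#' Estimates the slowly fluctuating baseline of each lead with a
#' Savitzky-Golay local-polynomial smooth and subtracts it. Edges are handled
#' by evaluating the polynomial fitted on the first/last full window at the
#' off-center positions (no zero padding), so the first and last half-window
#' are free of padding transients. The decomposition is exactly additive:
#' `detrended + baseline` reconstructs the input to float precision.
#'
#' @param record A [vcg_record].
#' @param spec A [filter_spec()]. If the record is shorter than the window,
#'   the window is shrunk to the largest odd value `<=` the record length and
#'   a warning is issued.
#' @return A list with `detrended` and `baseline`, both [vcg_record]s.
#' @export
remove_baseline <- function(record, spec = filter_spec(fs = record$fs)) {
  stopifnot(inherits(record, "vcg_record"), inherits(spec, "filter_spec"))
  n <- length(record$x)
  w <- spec$window
  if (n < w) {
    w <- if (n %% 2L == 1L) n else n - 1L
    warning(sprintf("record %s (%d samples) shorter than SG window %d; shrunk to %d",
                    record$record_id, n, spec$window, w))
    if (w <= spec$order) stopf("record too short for SG order %d", spec$order)
  }
  smooth <- function(v) signal::sgolayfilt(v, p = spec$order, n = w)
  base <- list(x = smooth(record$x), y = smooth(record$y), z = smooth(record$z))
  det <- list(x = record$x - base$x, y = record$y - base$y, z = record$z - base$z)
  list(
    detrended = vcg_record(det$x, det$y, det$z, fs = record$fs,
                           record_id = record$record_id, label = record$label),
    baseline = vcg_record(base$x, base$y, base$z, fs = record$fs,
                          record_id = paste0(record$record_id, "_baseline"),
                          label = record$label))
}
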