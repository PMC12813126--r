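#' Construct a three-lead VCG record
#'
#' A `vcg_record` holds the three synchronized orthogonal (Frank) lead series
#' X, Y, Z in millivolts together with the sampling rate. All downstream
#' stages (baseline removal, beat segmentation, loop features) operate on
#' this container.
#'
#' @param x,y,z Numeric vectors of equal length: lead voltages in mV.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param record_id Identifier string.
#' @param label Class tag: `"MI"`, `"HC"` or `"unknown"`.
#' @return An object of class `vcg_record` with fields `record_id`, `fs`,
#'   `x`, `y`, `z`, `label`.
#' @export
vcg_record <- function(x, y, z, fs, record_id = "record", label = "unknown") {
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  if (length(x) < 1L || length(x) != length(y) || length(x) != length(z))
    stopf("leads x, y, z must have identical length >= 1 (got %d, %d, %d)",
          length(x), length(y), length(z))
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stopf("fs must be a positive scalar (Hz)")
  label <- match.arg(label, c("MI", "HC", "unknown"))
  structure(
    list(record_id = as.character(record_id), fs = as.numeric(fs),
         x = x, y = y, z = z, label = label),
    class = "vcg_record")
}

#' @export
print.vcg_record <- function(x, ...) {
  cat(sprintf("<vcg_record> %s: %d samples @ %g Hz (%.2f s), label=%s\n",
              x$record_id, length(x$x), x$fs, length(x$x) / x$fs, x$label))
  invisible(x)
}

#' @export
length.vcg_record <- function(x) length(x$x)

#' Loop points of a record segment as an n x 3 matrix (columns X, Y, Z)
#' @noRd
record_points <- function(record, idx = seq_along(record$x)) {
  cbind(x = record$x[idx], y = record$y[idx], z = record$z[idx])
}

#' The 12 canonical loop-morphology feature names, in screening-table order
#'
#' Order matches the published ranking table of the feature set: standard
#' deviation of T-loop velocity first, T-loop area last.
#' @return Character vector of length 12.
#' @export
feature_names <- function() {
  c("stdVelT", "areaQRS", "stdVelQRS", "maxVecT", "arcQRS", "maxVelQRS",
    "meanVelT", "meanVelQRS", "maxVelT", "maxGravQRS", "maxVecQRS", "areaT")
}
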