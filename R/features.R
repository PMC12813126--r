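#' Fit the least-squares optimal plane of a 3D loop
#'
#' Centers the loop at its centroid and takes the singular value
#' decomposition of the centered point matrix; the first two right singular
#' vectors span the optimal plane, the third is its normal.
#'
#' @param points n x 3 numeric matrix of ordered loop points (mV).
#' @return A list of class `optimal_plane` with `centroid` (length 3),
#'   `axes` (3 x 3 orthonormal matrix, columns w1, w2, w3) and
#'   `singular_values` (descending, non-negative).
#' @export
fit_optimal_plane <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stopf("optimal plane needs >= 3 points")
  centroid <- colMeans(points)
  xc <- sweep(points, 2, centroid)
  if (max(abs(xc)) < 1e-12) stopf("degenerate loop: all points identical")
  sv <- svd(xc, nu = 0)
  structure(list(centroid = centroid, axes = sv$v, singular_values = sv$d),
            class = "optimal_plane")
}

#' Project loop points onto an optimal plane
#'
#' `points2d[i, ] = ((points[i] - centroid) . w1, (points[i] - centroid) . w2)`
#' -- the first two principal components of the centered loop.
#'
#' @param points n x 3 matrix.
#' @param plane An `optimal_plane` from [fit_optimal_plane()].
#' @return n x 2 matrix of in-plane coordinates (mV).
#' @export
project_to_plane <- function(points, plane) {
  stopifnot(inherits(plane, "optimal_plane"))
  sweep(as.matrix(points), 2, plane$centroid) %*% plane$axes[, 1:2]
}

#' Discrete arc length of a sampled curve
#'
#' Sum of Euclidean step lengths over consecutive points (2D or 3D). The
#' curve is treated as open: no closing segment from last to first point.
#'
#' @param points n x d matrix, n >= 2.
#' @return Length in mV.
#' @export
arc_length <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stopf("arc length needs >= 2 points")
  sum(sqrt(rowSums(diff(points)^2)))
}

#' Maximum loop vector (independent per-lead maxima)
#'
#' `sqrt(max(X)^2 + max(Y)^2 + max(Z)^2)` with each maximum taken
#' independently per lead over the loop window. Note the per-lead maxima need
#' not occur at the same instant, so this is not in general the largest
#' instantaneous vector magnitude; set `strict_max_norm = TRUE` for
#' `max ||point||` instead.
#'
#' @param points n x 3 matrix of raw (uncentered) loop points.
#' @param strict_max_norm Use the maximum instantaneous magnitude instead of
#'   the per-lead-maxima formula.
#' @return mV.
#' @export
max_vector <- function(points, strict_max_norm = FALSE) {
  points <- as.matrix(points)
  if (nrow(points) < 1) stopf("max_vector needs >= 1 point")
  if (strict_max_norm) return(max(sqrt(rowSums(points^2))))
  sqrt(sum(apply(points, 2, max)^2))
}

#' Maximum distance from the loop centroid
#'
#' The center of gravity is the per-lead mean of the loop points; returns the
#' largest Euclidean distance from it to any loop point.
#'
#' @param points n x 3 matrix, n >= 2.
#' @return mV.
#' @export
max_centroid_distance <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stopf("max_centroid_distance needs >= 2 points")
  g <- colMeans(points)
  max(sqrt(rowSums(sweep(points, 2, g)^2)))
}

#' Loop tracing-velocity statistics
#'
#' Per-sample speed is the forward-difference step length scaled by the
#' sampling rate, `||p[i+1] - p[i]|| * fs` (mV/s); returns its maximum,
#' arithmetic mean and population standard deviation.
#'
#' @param points n x d matrix, n >= 2.
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector `c(maxVel, meanVel, stdVel)`.
#' @export
velocity_stats <- function(points, fs) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stopf("velocity needs >= 2 points")
  v <- sqrt(rowSums(diff(points)^2)) * fs
  m <- mean(v)
  c(maxVel = max(v), meanVel = m, stdVel = sqrt(mean((v - m)^2)))
}

#' Area enclosed by a projected loop (shoelace formula)
#'
#' `0.5 * |sum (x[i] + x[i+1]) (y[i] - y[i+1])|` over consecutive vertices
#' with the polygon closed (last paired with first). For self-intersecting
#' loops this is the absolute signed area, not the geometric union.
#'
#' @param points2d n x 2 matrix, n >= 3.
#' @return mV^2.
#' @export
loop_area <- function(points2d) {
  p <- as.matrix(points2d)
  if (nrow(p) < 3) stopf("loop area needs >= 3 points")
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * abs(sum((x + xn) * (y - yn)))
}

#' Compute the 12 loop-morphology features for one beat
#'
#' Arc length and area of the QRS loop are computed on its optimal-plane
#' projection, the T-loop area on the T loop's own projection; maximum loop
#' vectors use the raw per-lead maxima; the centroid distance and velocity
#' statistics use the raw 3D points.
#'
#' @param beat A `beat_loops` object from [segment_beats()], or any list
#'   with `qrs_points` and `t_points` matrices.
#' @param fs Sampling rate in Hz.
#' @param strict_max_norm See [max_vector()].
#' @return Named numeric vector over [feature_names()].
#' @export
beat_features <- function(beat, fs, strict_max_norm = FALSE) {
  qp <- as.matrix(beat$qrs_points)
  tp <- as.matrix(beat$t_points)
  plane_q <- fit_optimal_plane(qp)
  plane_t <- fit_optimal_plane(tp)
  q2 <- project_to_plane(qp, plane_q)
  t2 <- project_to_plane(tp, plane_t)
  vq <- velocity_stats(qp, fs)
  vt <- velocity_stats(tp, fs)
  out <- c(stdVelT = unname(vt["stdVel"]),
           areaQRS = loop_area(q2),
           stdVelQRS = unname(vq["stdVel"]),
           maxVecT = max_vector(tp, strict_max_norm),
           arcQRS = arc_length(q2),
           maxVelQRS = unname(vq["maxVel"]),
           meanVelT = unname(vt["meanVel"]),
           meanVelQRS = unname(vq["meanVel"]),
           maxVelT = unname(vt["maxVel"]),
           maxGravQRS = max_centroid_distance(qp),
           maxVecQRS = max_vector(qp, strict_max_norm),
           areaT = loop_area(t2))
  out[feature_names()]
}

#' Aggregate per-beat feature vectors to one record-level vector
#'
#' @param beat_matrix Matrix or data frame with one row per beat and the 12
#'   feature columns, or a list of per-beat vectors.
#' @param method `"median"` (default, robust to the outlying beats that are
#'   deliberately retained) or `"mean"`.
#' @return Named numeric vector over [feature_names()].
#' @export
record_features <- function(beat_matrix, method = c("median", "mean")) {
  method <- match.arg(method)
  if (is.list(beat_matrix) && !is.data.frame(beat_matrix))
    beat_matrix <- do.call(rbind, beat_matrix)
  beat_matrix <- as.matrix(beat_matrix)
  if (nrow(beat_matrix) < 1) stopf("record_features needs >= 1 beat")
  agg <- apply(beat_matrix[, feature_names(), drop = FALSE], 2,
               if (method == "median") stats::median else mean)
  agg[feature_names()]
}

#' Extract the record-level feature vector from a raw VCG record
#'
#' Full single-record pipeline: baseline removal, R-peak detection on the
#' spatial magnitude, beat segmentation, per-beat features, and record-level
#' aggregation.
#'
#' @param record A [vcg_record].
#' @param spec A [filter_spec()]; defaults to the standard 1201-sample
#'   order-2 smoother at the record's sampling rate.
#' @param delineation A [delineation_config()].
#' @param aggregate Aggregation rule passed to [record_features()].
#' @return Named feature vector, with attribute `n_beats`.
#' @export
extract_features <- function(record, spec = filter_spec(fs = record$fs),
                             delineation = delineation_config(),
                             aggregate = "median") {
  det <- remove_baseline(record, spec)$detrended
  mag <- spatial_magnitude(det)
  peaks <- detect_r_peaks(mag, det$fs, delineation)
  beats <- segment_beats(det, peaks, delineation)
  if (length(beats) == 0L)
    stopf("no usable beats found in record %s", record$record_id)
  bf <- t(vapply(beats, beat_features, numeric(12), fs = det$fs))
  out <- record_features(bf, aggregate)
  attr(out, "n_beats") <- length(beats)
  out
}

#' Extract the feature table for a whole cohort
#'
#' @param records List of [vcg_record]s.
#' @param ... Passed to [extract_features()].
#' @return Data frame with `record_id`, `label` and the 12 feature columns.
#' @export
cohort_features <- function(records, ...) {
  rows <- lapply(records, function(rec) {
    fv <- extract_features(rec, ...)
    cbind(data.frame(record_id = rec$record_id, label = rec$label,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)))
  })
  do.call(rbind, rows)
}
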