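test_that("optimal plane recovers exact planarity, centroid and normal", {
  pts <- cbind(c(0, 2, 0, 2), c(0, 0, 2, 2), rep(2, 4))
  pl <- fit_optimal_plane(pts)
  expect_equal(pl$centroid, c(1, 1, 2), ignore_attr = TRUE)
  expect_lt(pl$singular_values[3], 1e-9)
  expect_equal(abs(pl$axes[, 3]), c(0, 0, 1), tolerance = 1e-9)
  expect_equal(sort(pl$singular_values, decreasing = TRUE), pl$singular_values)
  expect_equal(crossprod(pl$axes), diag(3), tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(fit_optimal_plane(matrix(1, 5, 3)), "degenerate")

  set.seed(41)
  for (rep in 1:5) {
    el <- make_tilted_ellipse(a = 1.3, b = 0.4, n = 200)
    pl2 <- fit_optimal_plane(el$points)
    expect_lt(min(sum((pl2$axes[, 3] - el$normal)^2),
                  sum((pl2$axes[, 3] + el$normal)^2)), 1e-12)
  }
})

test_that("plane projection is the stated dot-product map and an isometry on planar loops", {
  set.seed(42)
  el <- make_tilted_ellipse(n = 60)
  pl <- fit_optimal_plane(el$points)
  p2 <- project_to_plane(el$points, pl)
  expect_equal(nrow(p2), 60)
  # brute-force oracle
  oracle <- t(apply(el$points, 1, function(p)
    c(sum((p - pl$centroid) * pl$axes[, 1]), sum((p - pl$centroid) * pl$axes[, 2]))))
  expect_equal(p2, oracle, ignore_attr = TRUE)
  # centroid projects to the origin
  expect_equal(as.numeric(project_to_plane(rbind(pl$centroid), pl)), c(0, 0),
               tolerance = 1e-12)
  # pairwise distances preserved for exactly planar loops
  d3 <- dist(el$points); d2 <- dist(p2)
  expect_lt(max(abs(d3 - d2)), 1e-9)
})

test_that("arc length sums open-curve step lengths", {
  th <- seq(0, 2 * pi, length.out = 1000)
  circ <- cbind(cos(th), sin(th))
  expect_equal(arc_length(circ), 2 * pi, tolerance = 1e-3)
  expect_equal(arc_length(rbind(c(0, 0), c(3, 4))), 5)
  set.seed(43)
  poly <- matrix(rnorm(30), ncol = 3)
  oracle <- sum(vapply(1:9, function(i) sqrt(sum((poly[i + 1, ] - poly[i, ])^2)), 0))
  expect_equal(arc_length(poly), oracle)
  expect_error(arc_length(poly[1, , drop = FALSE]), ">= 2")
})

test_that("max_vector follows the literal per-lead-maxima formula", {
  expect_equal(max_vector(rbind(c(1, 2, 2))), 3)
  two <- rbind(c(3, 0, 0), c(0, 4, 0))
  expect_equal(max_vector(two), 5)                     # non-simultaneous maxima
  expect_equal(max_vector(two, strict_max_norm = TRUE), 4)
  set.seed(44)
  pts <- matrix(rnorm(60), ncol = 3)
  expect_equal(max_vector(pts),
               sqrt(max(pts[, 1])^2 + max(pts[, 2])^2 + max(pts[, 3])^2))
})

test_that("max centroid distance matches exhaustive search", {
  th <- seq(0, 2 * pi, length.out = 400)
  circ <- cbind(cos(th[-400]), sin(th[-400]), 0)
  expect_equal(max_centroid_distance(circ), 1, tolerance = 1e-6)
  sq <- rbind(c(1, 1, 0), c(-1, 1, 0), c(-1, -1, 0), c(1, -1, 0))
  expect_equal(max_centroid_distance(sq), sqrt(2))
  set.seed(45)
  pts <- matrix(rnorm(90), ncol = 3)
  g <- colMeans(pts)
  oracle <- max(vapply(seq_len(nrow(pts)), function(i)
    sqrt(sum((pts[i, ] - g)^2)), 0))
  expect_equal(max_centroid_distance(pts), oracle)
})

test_that("velocity statistics use fs-scaled forward differences", {
  line <- cbind(seq(0, 0.099, by = 0.001), 0, 0)
  v <- velocity_stats(line, fs = 1000)
  expect_equal(unname(v), c(1, 1, 0), tolerance = 1e-9)
  # circle of radius r traced uniformly in d seconds: mean speed 2*pi*r/d
  r <- 0.8; d <- 0.25; fs <- 1000
  th <- seq(0, 2 * pi, length.out = d * fs)
  circ <- cbind(r * cos(th), r * sin(th), 0)
  v2 <- velocity_stats(circ, fs)
  expect_equal(unname(v2["meanVel"]), 2 * pi * r / d, tolerance = 1e-2)
  set.seed(46)
  pts <- matrix(rnorm(45), ncol = 3)
  sp <- vapply(1:14, function(i) sqrt(sum((pts[i + 1, ] - pts[i, ])^2)) * 100, 0)
  v3 <- velocity_stats(pts, fs = 100)
  expect_equal(unname(v3), c(max(sp), mean(sp), sqrt(mean((sp - mean(sp))^2))))
})

test_that("loop area is the closed shoelace sum", {
  expect_equal(loop_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 1)
  expect_equal(loop_area(rbind(c(0, 0), c(1, 0), c(0, 1))), 0.5)
  # a figure-eight collapses to |signed| area, here zero
  expect_equal(loop_area(rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))), 0)
  set.seed(47)
  for (rep in 1:20) {
    poly <- random_simple_polygon(sample(4:40, 1))
    expect_equal(loop_area(poly), abs(fan_area_oracle(poly)), tolerance = 1e-12)
  }
})

test_that("beat features recover analytic ellipse geometry", {
  set.seed(48)
  a <- 1.1; b <- 0.55
  el_q <- make_tilted_ellipse(a, b, n = 120)
  el_t <- make_tilted_ellipse(0.4, 0.2, n = 300)
  beat <- list(qrs_points = el_q$points, t_points = el_t$points)
  fv <- beat_features(beat, fs = 1000)
  expect_equal(unname(fv["areaQRS"]), pi * a * b, tolerance = 0.01)
  per <- 4 * a * integrate(function(t) sqrt(1 - (1 - (b / a)^2) * sin(t)^2),
                           0, pi / 2)$value
  expect_equal(unname(fv["arcQRS"]), per, tolerance = 0.01)
  expect_identical(names(fv), feature_names())
  expect_true(all(is.finite(fv)))
})

test_that("features scale correctly under voltage doubling", {
  set.seed(49)
  beat <- list(qrs_points = make_tilted_ellipse(1, 0.5, 100)$points + 0.2,
               t_points = make_tilted_ellipse(0.4, 0.2, 200)$points + 0.1)
  beat2 <- list(qrs_points = 2 * beat$qrs_points, t_points = 2 * beat$t_points)
  f1 <- beat_features(beat, 1000); f2 <- beat_features(beat2, 1000)
  linear <- c("stdVelT", "stdVelQRS", "maxVecT", "arcQRS", "maxVelQRS",
              "meanVelT", "meanVelQRS", "maxVelT", "maxGravQRS", "maxVecQRS")
  expect_equal(unname(f2[linear]), unname(2 * f1[linear]), tolerance = 1e-9)
  expect_equal(unname(f2[c("areaQRS", "areaT")]),
               unname(4 * f1[c("areaQRS", "areaT")]), tolerance = 1e-9)
})

test_that("all features except max_vector are rigid-motion invariant", {
  set.seed(50)
  for (rep in 1:5) {
    beat <- list(
      qrs_points = make_tilted_ellipse(1.2, 0.6, 90)$points +
        matrix(rnorm(90 * 3, sd = 0.01), ncol = 3),
      t_points = make_tilted_ellipse(0.4, 0.2, 200)$points +
        matrix(rnorm(200 * 3, sd = 0.005), ncol = 3))
    R <- random_rotation(); shift <- rnorm(3)
    rot <- function(p) sweep(p %*% t(R), 2, shift, "+")
    beat_r <- list(qrs_points = rot(beat$qrs_points), t_points = rot(beat$t_points))
    f1 <- beat_features(beat, 1000); f2 <- beat_features(beat_r, 1000)
    inv <- setdiff(feature_names(), c("maxVecQRS", "maxVecT"))
    expect_equal(unname(f2[inv]), unname(f1[inv]), tolerance = 1e-6)
    # max_vector is defined by the literal per-lead formula, not invariance
    expect_equal(unname(f2["maxVecQRS"]), max_vector(beat_r$qrs_points))
  }
})

test_that("record aggregation is the per-feature median (or mean)", {
  set.seed(51)
  one <- matrix(rnorm(12), 1, 12, dimnames = list(NULL, feature_names()))
  expect_equal(record_features(one), one[1, ])
  three <- matrix(rnorm(36), 3, 12, dimnames = list(NULL, feature_names()))
  three[, "arcQRS"] <- c(1, 2, 9)
  expect_equal(unname(record_features(three)["arcQRS"]), 2)
  expect_equal(unname(record_features(three, "mean")["arcQRS"]), 4)
  same <- three[c(1, 1, 1), ]
  expect_equal(record_features(same), three[1, ])
})

test_that("planar loops keep their arc length under projection", {
  set.seed(52)
  el <- make_tilted_ellipse(0.9, 0.33, 150)
  pl <- fit_optimal_plane(el$points)
  expect_lt(abs(arc_length(project_to_plane(el$points, pl)) -
                arc_length(el$points)), 1e-9)
})
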