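# Biplane reconstruction: spline resampling, triangulation round trips and
# scale calibration.

helix <- function(n = 80) {
  t <- seq(0, 4 * pi, length.out = n)
  cbind(0.01 * cos(t), 0.01 * sin(t), 0.002 * t - 0.012)
}

test_that("spline resampling preserves lines, circles and arc length", {
  # collinear input stays collinear
  line <- cbind(seq(0, 1, length.out = 10), seq(0, 2, length.out = 10))
  rs <- fit_spline_resample(line, 0.05)
  d <- rs[, 2] - 2 * rs[, 1]
  expect_lt(max(abs(d)), 1e-9)
  # circle samples resample onto the circle within 0.1% of the radius
  th <- seq(0, 2 * pi, length.out = 60)
  circ <- cbind(cos(th), sin(th))
  rc <- fit_spline_resample(circ, 0.02)
  expect_lt(max(abs(sqrt(rowSums(rc^2)) - 1)), 1e-3)
  # arc length is conserved within 1%
  arc_in <- sum(sqrt(rowSums(diff(circ)^2)))
  arc_out <- sum(sqrt(rowSums(diff(rc)^2)))
  expect_lt(abs(arc_out / arc_in - 1), 0.01)
  # spacing is uniform within 10% away from the endpoints
  sp <- sqrt(rowSums(diff(rc)^2))
  expect_lt(max(abs(sp / stats::median(sp) - 1)), 0.1)
  expect_error(fit_spline_resample(line[1:3, ], 0.05), "at least 4")
})

test_that("a straight catheter triangulates exactly under parallel-beam views", {
  line <- cbind(seq(-0.02, 0.02, length.out = 30),
                seq(-0.01, 0.01, length.out = 30),
                seq(-0.02, 0.02, length.out = 30))
  vs <- gen_biplane_views(line,
                          projection_view(0, source_dist = 1e4),
                          projection_view(90, source_dist = 1e4))
  rec <- match_and_triangulate(vs$viewA, vs$viewB)
  # exact perpendicular distance to the true line
  a <- line[1, ]; dvec <- line[30, ] - line[1, ]; dvec <- dvec / sqrt(sum(dvec^2))
  offs <- sweep(rec$points, 2, a)
  par <- offs %*% dvec
  perp <- offs - par %*% t(dvec)
  expect_lt(sqrt(mean(rowSums(perp^2))), 1e-6)
})

test_that("helix round trip recovers the curve within the arc step", {
  hx <- helix()
  for (sep in c(45, 90)) {
    vs <- gen_biplane_views(hx, projection_view(0), projection_view(sep))
    rec <- match_and_triangulate(vs$viewA, vs$viewB)
    expect_lt(reconstruction_rmse(rec, hx), rec$arc_step)
    expect_equal(rec$dropped, 0)
  }
})

test_that("pixel noise degrades but does not break the reconstruction", {
  hx <- helix()
  rmse <- vapply(1:5, function(s) {
    vs <- gen_biplane_views(hx, projection_view(0), projection_view(70),
                            noise_px = 0.5, seed = s)
    reconstruction_rmse(match_and_triangulate(vs$viewA, vs$viewB), hx)
  }, 0)
  expect_true(all(is.finite(rmse)))
  expect_true(all(rmse < 5e-3))
  # conditioning: shallow view separation is worse than orthogonal views
  rmse_shallow <- mean(vapply(1:5, function(s) {
    vs <- suppressWarnings(gen_biplane_views(hx, projection_view(0),
                                             projection_view(10),
                                             noise_px = 0.5, seed = s))
    reconstruction_rmse(suppressWarnings(
      match_and_triangulate(vs$viewA, vs$viewB)), hx)
  }, 0))
  expect_gt(rmse_shallow, mean(rmse))
  vs10 <- gen_biplane_views(hx, projection_view(0), projection_view(10))
  expect_warning(match_and_triangulate(vs10$viewA, vs10$viewB), "45")
})

test_that("scale calibration recovers the known electrode span", {
  hx <- helix()
  vs <- gen_biplane_views(hx, projection_view(0), projection_view(90))
  rec <- match_and_triangulate(vs$viewA, vs$viewB)
  span <- sqrt(sum((rec$points[nrow(rec$points), ] - rec$points[1, ])^2))
  # already at scale
  expect_equal(calibrate_scale(rec, span)$scale, 1, tolerance = 1e-12)
  # uniformly shrunk by 0.8: scale 1.25 restores the span
  shrunk <- rec
  shrunk$points <- rec$points * 0.8
  cal <- calibrate_scale(shrunk, known_span = span)
  expect_equal(cal$scale, 1.25, tolerance = 1e-9)
  new_span <- sqrt(sum((cal$points[nrow(cal$points), ] - cal$points[1, ])^2))
  expect_equal(new_span, span, tolerance = 1e-12)
  # degenerate span
  degen <- rec; degen$points <- matrix(1, 5, 3)
  expect_error(calibrate_scale(degen, 0.039), "degenerate")
})

test_that("projection and triangulation of a point are mutually consistent", {
  pt <- matrix(c(0.004, -0.006, 0.008), 1, 3)
  curve <- rbind(pt - c(0.001, 0, 0.001), pt, pt + c(0.001, 0, 0.001),
                 pt + c(0.002, 0, 0.002))
  vs <- gen_biplane_views(curve, projection_view(0), projection_view(90))
  rec <- match_and_triangulate(vs$viewA, vs$viewB, arc_step = 5e-4)
  d <- min(sqrt(rowSums(sweep(rec$points, 2, as.numeric(pt))^2)))
  expect_lt(d, 5e-4)
  # seeded noise is reproducible
  v1 <- gen_biplane_views(curve, projection_view(0), projection_view(90),
                          noise_px = 0.5, seed = 9)
  v2 <- gen_biplane_views(curve, projection_view(0), projection_view(90),
                          noise_px = 0.5, seed = 9)
  expect_identical(v1$viewA$trace, v2$viewA$trace)
})
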