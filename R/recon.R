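# Biplane fluoroscopic catheter reconstruction.
#
# Each view is a point X-ray source and a detector plane; manual catheter
# traces (pixel polylines) are spline-resampled at 1-mm arc increments,
# matched across views at equal height along the shared vertical axis, and
# each matched pair is triangulated as the least-squares intersection
# (midpoint of the common perpendicular) of the two source-detector rays.
# The known return-electrode span calibrates the global scale.

#' Projection view geometry
#'
#' The detector's in-plane `v` axis is the shared patient-vertical (world
#' z); `u` completes the right-handed frame with the viewing direction.
#'
#' @param view_angle_deg rotation of the imaging chain about the vertical
#'   axis, degrees.
#' @param source_dist distance from isocentre to the X-ray source, m.
#' @param detector_dist distance from isocentre to the detector plane, m.
#' @param pixel_spacing detector pixel pitch, m/pixel.
#' @return object of class `pfa_projection_view` (without a trace; see
#'   [gen_biplane_views()]).
#' @export
projection_view <- function(view_angle_deg, source_dist = 1.0,
                            detector_dist = 0.4, pixel_spacing = 0.25e-3) {
  a <- view_angle_deg * pi / 180
  nrm <- c(cos(a), sin(a), 0)              # source -> detector direction
  v <- list(view_angle = view_angle_deg,
            source_position = -nrm * source_dist,
            detector_origin = nrm * detector_dist,
            u_axis = c(-sin(a), cos(a), 0),
            v_axis = c(0, 0, 1),
            normal = nrm,
            pixel_spacing = pixel_spacing,
            trace = NULL)
  class(v) <- "pfa_projection_view"
  v
}

# world coordinates of trace pixels on the detector plane
trace_world <- function(view, trace = view$trace) {
  ps <- view$pixel_spacing
  cbind(view$detector_origin[1] + trace[, 1] * ps * view$u_axis[1] +
          trace[, 2] * ps * view$v_axis[1],
        view$detector_origin[2] + trace[, 1] * ps * view$u_axis[2] +
          trace[, 2] * ps * view$v_axis[2],
        view$detector_origin[3] + trace[, 1] * ps * view$u_axis[3] +
          trace[, 2] * ps * view$v_axis[3])
}

#' Cubic-spline fit and uniform arc-length resampling of a polyline
#'
#' Natural cubic splines through the points, parameterised by cumulative
#' chord length, then resampled at (approximately) uniform arc-length
#' steps.
#'
#' @param trace matrix (n x d), d >= 2; pixel or world coordinates.
#' @param step arc-length step in the trace's units.
#' @return matrix of resampled points; consecutive spacing within 10% of
#'   `step` away from the endpoints.
#' @export
fit_spline_resample <- function(trace, step) {
  trace <- as.matrix(trace)
  if (nrow(trace) < 4) stop("spline fit requires at least 4 trace points",
                            call. = FALSE)
  s <- c(0, cumsum(sqrt(rowSums(diff(trace)^2))))
  if (any(diff(s) <= 0)) {
    keep <- c(TRUE, diff(s) > 0)
    trace <- trace[keep, , drop = FALSE]
    s <- s[keep]
  }
  fns <- lapply(seq_len(ncol(trace)), function(d)
    stats::splinefun(s, trace[, d], method = "natural"))
  # dense evaluation, then re-parameterise by arc length of the spline
  sd_ <- seq(0, max(s), length.out = max(200L, 20L * length(s)))
  dense <- vapply(fns, function(f) f(sd_), numeric(length(sd_)))
  arc <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  n_out <- max(2L, round(max(arc) / step) + 1L)
  tgt <- seq(0, max(arc), length.out = n_out)
  si <- stats::approx(arc, sd_, xout = tgt)$y
  vapply(fns, function(f) f(si), numeric(length(si)))
}

#' Match two views and triangulate the 3-D catheter
#'
#' Primary-spline points are matched to the secondary spline at equal
#' height along the shared vertical axis (linear interpolation within the
#' bracketing segment; among multiple crossings the one giving the smallest
#' ray-ray miss distance wins). Matched ray pairs are triangulated at the
#' midpoint of their common perpendicular.
#'
#' @param viewA,viewB [projection_view()] objects with `trace` set
#'   (pixels).
#' @param arc_step resampling step on the detector, m.
#' @return object of class `pfa_catheter3d`: `points` (n x 3, m),
#'   `dropped` (count of unmatched points), `miss_dist` (per-point ray miss
#'   distance, m).
#' @export
match_and_triangulate <- function(viewA, viewB, arc_step = 1e-3) {
  sep <- abs(viewA$view_angle - viewB$view_angle) %% 360
  sep <- min(sep, 360 - sep)
  if (sep < 45)
    warning(sprintf("views only %.0f deg apart (< 45): poor conditioning", sep))
  wa <- fit_spline_resample(trace_world(viewA), arc_step)
  wb <- fit_spline_resample(trace_world(viewB), arc_step)
  Sa <- viewA$source_position; Sb <- viewB$source_position
  yb <- wb[, 3]
  pts <- NULL; miss <- numeric(0); dropped <- 0L
  tol <- viewB$pixel_spacing
  for (i in seq_len(nrow(wa))) {
    ya <- wa[i, 3]
    cross <- which((yb[-length(yb)] - ya) * (yb[-1] - ya) <= 0)
    cands <- NULL
    if (length(cross)) {
      for (s in cross) {
        t <- if (yb[s + 1] == yb[s]) 0.5 else (ya - yb[s]) / (yb[s + 1] - yb[s])
        cands <- rbind(cands, wb[s, ] + t * (wb[s + 1, ] - wb[s, ]))
      }
    } else {
      j <- which.min(abs(yb - ya))
      if (abs(yb[j] - ya) <= tol) cands <- wb[j, , drop = FALSE]
    }
    if (is.null(cands)) { dropped <- dropped + 1L; next }
    best <- NULL; bestd <- Inf
    for (r in seq_len(nrow(cands))) {
      tri <- .ray_midpoint(Sa, wa[i, ], Sb, cands[r, ])
      if (tri$dist < bestd) { bestd <- tri$dist; best <- tri$point }
    }
    pts <- rbind(pts, best)
    miss <- c(miss, bestd)
  }
  out <- list(points = pts, dropped = dropped, miss_dist = miss,
              arc_step = arc_step, scale = 1)
  class(out) <- "pfa_catheter3d"
  out
}

# least-squares intersection (common-perpendicular midpoint) of rays
# S1 + t d1 and S2 + s d2
.ray_midpoint <- function(S1, P1, S2, P2) {
  d1 <- (P1 - S1) / sqrt(sum((P1 - S1)^2))
  d2 <- (P2 - S2) / sqrt(sum((P2 - S2)^2))
  w0 <- S1 - S2
  a <- 1; b <- sum(d1 * d2); c <- 1
  d <- sum(d1 * w0); e <- sum(d2 * w0)
  den <- a * c - b * b
  if (abs(den) < 1e-12) {           # nearly parallel rays
    t <- -d; s <- 0
  } else {
    t <- (b * e - c * d) / den
    s <- (a * e - b * d) / den
  }
  q1 <- S1 + t * d1; q2 <- S2 + s * d2
  list(point = (q1 + q2) / 2, dist = sqrt(sum((q1 - q2)^2)))
}

#' Calibrate the reconstruction scale from a known electrode span
#'
#' Applies a uniform scale about the polyline centroid so that the
#' reconstructed span (distance between the first and last points unless
#' given) equals the known span of the return-catheter electrodes.
#'
#' @param recon a [match_and_triangulate()] result.
#' @param known_span true electrode span, m.
#' @param measured_span reconstructed span; default end-to-end distance.
#' @return the reconstruction, rescaled, with `scale` recorded.
#' @export
calibrate_scale <- function(recon, known_span, measured_span = NULL) {
  p <- recon$points
  if (is.null(measured_span))
    measured_span <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  if (measured_span < 1e-9)
    stop("reconstructed span is degenerate; cannot calibrate", call. = FALSE)
  sc <- known_span / measured_span
  ctr <- colMeans(p)
  recon$points <- sweep(sweep(p, 2, ctr), 2, rep(sc, 3), `*`) +
    matrix(ctr, nrow(p), 3, byrow = TRUE)
  recon$scale <- recon$scale * sc
  recon
}

#' RMSE of a reconstruction against a ground-truth curve
#'
#' Distance of each reconstructed point to the nearest point of the
#' (densely resampled) true curve.
#'
#' @param recon a [match_and_triangulate()] result.
#' @param truth matrix (n x 3) of true curve points, m.
#' @return RMSE in metres.
#' @export
reconstruction_rmse <- function(recon, truth) {
  tr <- fit_spline_resample(truth, max(1e-4, recon$arc_step / 10))
  d <- vapply(seq_len(nrow(recon$points)), function(i)
    min(sqrt(rowSums((tr - matrix(recon$points[i, ], nrow(tr), 3,
                                  byrow = TRUE))^2))), 0)
  sqrt(mean(d^2))
}
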