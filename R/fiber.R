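# Rule-based myocardial fiber architecture.
#
# The transmural (sheet) direction is the gradient of a Laplace solution U
# (U = 1 endocardium, U = 0 epicardium, basal plane insulated). The wall
# depth parameter beta = D_epi / (D_epi + D_endo) interpolates the fiber
# helix angle linearly between +80 deg (endocardium) and -40 deg
# (epicardium), measured from the circumferential direction; the frame is
# obtained by rotating the (apico-basal, circumferential) pair about the
# sheet axis.

#' Solve the transmural Laplace coordinate
#'
#' Solves `Laplace(U) = 0` on the myocardium with `U = 1` on the endocardial
#' surface and `U = 0` on the epicardial surface; the basal truncation plane
#' and catheter contact are insulated. Nodal values are clipped to `[0, 1]`
#' (trilinear elements on strongly graded cells may overshoot the maximum
#' principle by discretization error).
#'
#' @param mesh classified mesh with endocardial/epicardial surfaces present.
#' @return object of class `pfa_transmural` with nodal `U` (NA outside the
#'   myocardium) and the myocardial cell index.
#' @export
solve_transmural <- function(mesh) {
  surf <- myocardial_surfaces(mesh)
  if (is.null(surf$endo$nodes) || is.null(surf$epi$nodes))
    stop("missing endocardium/epicardium boundary tags", call. = FALSE)
  cells <- which(mesh$region == REGION["myocardium"])
  endo <- sort(unique(as.vector(surf$endo$nodes)))
  epi <- sort(unique(as.vector(surf$epi$nodes)))
  epi <- setdiff(epi, endo)
  active <- sort(unique(as.vector(cell_nodes(mesh, cells))))
  K <- fem_stiffness(mesh, cells, matrix(1, length(cells), 1))
  sol <- fem_solve_dirichlet(K, active, c(endo, epi),
                             c(rep(1, length(endo)), rep(0, length(epi))))
  U <- sol$V
  U[!is.na(U)] <- pmin(pmax(U[!is.na(U)], 0), 1)
  out <- list(U = U, cells = cells, surfaces = surf)
  class(out) <- "pfa_transmural"
  out
}

#' Wall distances and the transmural depth parameter
#'
#' Per myocardial cell, distance to the nearest epicardial and endocardial
#' face centre and `beta = D_epi / (D_epi + D_endo)` (1 at the endocardium,
#' 0 at the epicardium).
#'
#' @param mesh classified mesh.
#' @param tf optional [solve_transmural()] result to extend (reuses its
#'   surface extraction).
#' @return the `pfa_transmural` object with `D_epi`, `D_endo`, `beta` added.
#' @export
wall_distances <- function(mesh, tf = NULL) {
  if (is.null(tf)) {
    surf <- myocardial_surfaces(mesh)
    tf <- list(cells = which(mesh$region == REGION["myocardium"]),
               surfaces = surf)
    class(tf) <- "pfa_transmural"
  }
  surf <- tf$surfaces
  if (is.null(surf$endo$centers) || is.null(surf$epi$centers))
    stop("missing endocardium/epicardium boundary tags", call. = FALSE)
  pts <- cell_centers(mesh, tf$cells)
  tf$D_endo <- .min_dist(pts, surf$endo$centers)
  tf$D_epi <- .min_dist(pts, surf$epi$centers)
  tot <- tf$D_epi + tf$D_endo
  if (any(tot <= 0))
    stop("degenerate geometry: element with zero wall thickness", call. = FALSE)
  tf$beta <- tf$D_epi / tot
  tf
}

# chunked nearest-point distance (n points x m candidates)
.min_dist <- function(pts, cand, chunk = 256L) {
  c2 <- rowSums(cand^2)
  out <- numeric(nrow(pts))
  for (s in seq(1, nrow(pts), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(pts))
    p <- pts[s:e, , drop = FALSE]
    d2 <- outer(rowSums(p^2), c2, "+") - 2 * p %*% t(cand)
    out[s:e] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  out
}

#' Build per-element fiber frames
#'
#' The sheet axis is the normalized transmural gradient; the second axis is
#' the global apico-basal direction (+z) projected orthogonal to the sheet
#' axis; the third (circumferential) completes the right-handed triad. The
#' pair is then rotated about the sheet axis by
#' `theta = beta * theta_endo + (1 - beta) * theta_epi`; the rotated third
#' axis is the fiber direction. Positive `theta` rotates from circumferential
#' toward apico-basal counterclockwise as seen from outside the epicardium
#' (flip with `rot_sign`).
#'
#' @param mesh classified mesh.
#' @param tf [solve_transmural()] + [wall_distances()] result (with `U` and
#'   `beta`).
#' @param theta_endo,theta_epi fiber helix angles (degrees) at the
#'   endocardium and epicardium.
#' @param rot_sign +1 or -1; handedness of the rotation.
#' @return object of class `pfa_fiber_frame`: `cells`, unit vectors
#'   `e_sheet`, `e_fiber`, `e_normal` (n x 3), `theta` (degrees) and `beta`.
#' @export
build_frames <- function(mesh, tf, theta_endo = 80, theta_epi = -40,
                         rot_sign = 1, on_degenerate = c("error", "drop")) {
  if (is.null(tf$U)) stop("transmural coordinate missing: run solve_transmural()")
  if (is.null(tf$beta)) stop("beta missing: run wall_distances()")
  on_degenerate <- match.arg(on_degenerate)
  cells <- tf$cells
  beta <- tf$beta
  g <- fem_gradient(mesh, cells, tf$U)
  gn <- sqrt(rowSums(g^2))
  bad <- which(gn < 1e-10)
  if (length(bad)) {
    if (on_degenerate == "error")
      stop(sprintf("frame degeneracy: |grad U| < 1e-10 in %d element(s), first cell %d",
                   length(bad), cells[bad[1]]), call. = FALSE)
    warning(sprintf("dropping %d element(s) with degenerate transmural gradient (treated isotropically downstream)",
                    length(bad)))
    keep <- setdiff(seq_along(cells), bad)
    cells <- cells[keep]; g <- g[keep, , drop = FALSE]
    gn <- gn[keep]; beta <- beta[keep]
  }
  e1 <- g / gn
  # apico-basal reference projected orthogonal to the sheet axis
  ez <- c(0, 0, 1)
  v <- cbind(-e1[, 1] * e1[, 3], -e1[, 2] * e1[, 3], 1 - e1[, 3]^2)
  vn <- sqrt(rowSums(v^2))
  deg <- vn < 1e-6
  if (any(deg)) {
    warning(sprintf("apico-basal axis nearly parallel to grad U in %d element(s); using fallback axis",
                    sum(deg)))
    w <- cbind(1 - e1[deg, 1]^2, -e1[deg, 1] * e1[deg, 2], -e1[deg, 1] * e1[deg, 3])
    v[deg, ] <- w
    vn[deg] <- sqrt(rowSums(w^2))
  }
  e2 <- v / vn
  e3 <- .cross3(e1, e2)
  theta <- beta * theta_endo + (1 - beta) * theta_epi
  th <- rot_sign * theta * pi / 180
  ct <- cos(th); st <- sin(th)
  rot <- function(vv) {
    kxv <- .cross3(e1, vv)
    kdv <- rowSums(e1 * vv)
    vv * ct + kxv * st + e1 * (kdv * (1 - ct))
  }
  e_fiber <- rot(e3)
  e_normal <- rot(e2)
  out <- list(cells = cells, e_sheet = e1, e_fiber = e_fiber,
              e_normal = e_normal, theta = theta, beta = beta,
              theta_endo = theta_endo, theta_epi = theta_epi,
              rot_sign = rot_sign)
  class(out) <- "pfa_fiber_frame"
  out
}

.cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Fiber frames for a mesh in one call
#'
#' Convenience wrapper: transmural solve, wall distances, frames.
#' @inheritParams build_frames
#' @export
fiber_frames <- function(mesh, theta_endo = 80, theta_epi = -40, rot_sign = 1) {
  tf <- solve_transmural(mesh)
  tf <- wall_distances(mesh, tf)
  build_frames(mesh, tf, theta_endo, theta_epi, rot_sign,
               on_degenerate = "drop")
}
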