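# Structured hexahedral finite-element core.
#
# Two mesh flavours share one assembly path:
#  * tensor-product grids (graded Cartesian; the main domain) with a fast
#    closed-form per-element stiffness,
#  * mapped structured grids (node coordinates given explicitly, e.g. a
#    spherical-shell patch used for verification) with full isoparametric
#    quadrature.

# reference hex node signs (standard VTK ordering)
.hex_xi   <- c(-1,  1,  1, -1, -1,  1, 1, -1)
.hex_eta  <- c(-1, -1,  1,  1, -1, -1, 1,  1)
.hex_zeta <- c(-1, -1, -1, -1,  1,  1, 1,  1)

# dN/d(xi,eta,zeta) for the 8 trilinear shape functions at (xi,eta,zeta)
.hex_dN <- function(xi, eta, zeta) {
  cbind(.hex_xi   * (1 + .hex_eta * eta) * (1 + .hex_zeta * zeta),
        .hex_eta  * (1 + .hex_xi  * xi)  * (1 + .hex_zeta * zeta),
        .hex_zeta * (1 + .hex_xi  * xi)  * (1 + .hex_eta  * eta)) / 8
}

# 2x2x2 Gauss points on [-1,1]^3 (weights all 1)
.hex_gauss <- local({
  g <- 1 / sqrt(3)
  as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g), zeta = c(-g, g)))
})

# M[[a]][[b]] (8x8) with entries sum_q dN_q[i,a] * dN_q[j,b]; used by the
# tensor-grid fast path: K_e = sum_ab sigma_ab * (4 detJ / (h_a h_b)) * M_ab
.hex_M <- local({
  M <- vector("list", 3)
  for (a in 1:3) M[[a]] <- vector("list", 3)
  for (a in 1:3) for (b in 1:3) {
    acc <- matrix(0, 8, 8)
    for (q in seq_len(nrow(.hex_gauss))) {
      dN <- .hex_dN(.hex_gauss[q, 1], .hex_gauss[q, 2], .hex_gauss[q, 3])
      acc <- acc + dN[, a] %o% dN[, b]
    }
    M[[a]][[b]] <- acc
  }
  M
})

#' Create a tensor-product structured mesh
#'
#' Cells are axis-aligned boxes defined by three vectors of grid-line
#' coordinates. This is the container every physics module operates on;
#' region/segment labels are attached by the geometry module.
#'
#' @param xs,ys,zs strictly increasing numeric vectors of grid-line
#'   coordinates in metres (length = number of cells + 1 per axis).
#' @return an object of class `pfa_mesh` with cell counts, cell centres,
#'   cell sizes, volumes and an (initially all-`bulk`) region labelling.
#' @export
tensor_mesh <- function(xs, ys, zs) {
  stopifnot(all(diff(xs) > 0), all(diff(ys) > 0), all(diff(zs) > 0))
  nx <- length(xs) - 1L; ny <- length(ys) - 1L; nz <- length(zs) - 1L
  cx <- (xs[-1] + xs[-length(xs)]) / 2
  cy <- (ys[-1] + ys[-length(ys)]) / 2
  cz <- (zs[-1] + zs[-length(zs)]) / 2
  hx <- diff(xs); hy <- diff(ys); hz <- diff(zs)
  ne <- nx * ny * nz
  m <- list(
    type = "tensor", xs = xs, ys = ys, zs = zs,
    nx = nx, ny = ny, nz = nz, n_cells = ne,
    n_nodes = (nx + 1L) * (ny + 1L) * (nz + 1L),
    cx = cx, cy = cy, cz = cz, hx = hx, hy = hy, hz = hz,
    region = rep.int(REGION["bulk"], ne))
  class(m) <- "pfa_mesh"
  m
}

#' Create a mapped structured mesh from explicit node coordinates
#'
#' Same logical (i,j,k) structure as [tensor_mesh()] but with arbitrary node
#' positions; assembly uses full isoparametric quadrature. Used for
#' curvilinear verification domains (e.g. spherical shells).
#'
#' @param node_xyz matrix `(nx+1)(ny+1)(nz+1) x 3` of node coordinates, node
#'   index running fastest over i, then j, then k.
#' @param nx,ny,nz cell counts per logical axis.
#' @export
mapped_mesh <- function(node_xyz, nx, ny, nz) {
  stopifnot(nrow(node_xyz) == (nx + 1) * (ny + 1) * (nz + 1))
  ne <- nx * ny * nz
  m <- list(type = "mapped", node_xyz = node_xyz,
            nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
            n_cells = ne, n_nodes = nrow(node_xyz),
            region = rep.int(REGION["bulk"], ne))
  class(m) <- "pfa_mesh"
  m
}

#' @export
print.pfa_mesh <- function(x, ...) {
  cat(sprintf("pfa_mesh (%s): %d x %d x %d cells (%d), %d nodes\n",
              x$type, x$nx, x$ny, x$nz, x$n_cells, x$n_nodes))
  tb <- table(factor(x$region, levels = REGION, labels = names(REGION)))
  tb <- tb[tb > 0]
  cat("  regions:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' Cell indexing on the structured grid
#'
#' `cell_index()` maps logical (i, j, k) positions to linear cell ids;
#' `cell_ijk()` is its inverse; `cell_sizes()` returns per-cell edge lengths
#' of a tensor mesh.
#'
#' @param mesh a `pfa_mesh`.
#' @param i,j,k 1-based logical coordinates.
#' @return `cell_index()`: integer ids; `cell_ijk()`: n x 3 integer matrix;
#'   `cell_sizes()`: n x 3 matrix of edge lengths (m).
#' @export
cell_index <- function(mesh, i, j, k) {
  i + (j - 1L) * mesh$nx + (k - 1L) * mesh$nx * mesh$ny
}

#' @rdname cell_index
#' @param e cell index vector.
#' @export
cell_ijk <- function(mesh, e) {
  e0 <- e - 1L
  i <- e0 %% mesh$nx
  j <- (e0 %/% mesh$nx) %% mesh$ny
  k <- e0 %/% (mesh$nx * mesh$ny)
  cbind(i = i + 1L, j = j + 1L, k = k + 1L)
}

node_index <- function(mesh, i, j, k) {
  i + (j - 1L) * (mesh$nx + 1L) + (k - 1L) * (mesh$nx + 1L) * (mesh$ny + 1L)
}

# nE x 8 matrix of node ids for the given cells (default: all)
cell_nodes <- function(mesh, cells = seq_len(mesh$n_cells)) {
  ijk <- cell_ijk(mesh, cells)
  i <- ijk[, 1]; j <- ijk[, 2]; k <- ijk[, 3]
  di <- c(0L, 1L, 1L, 0L, 0L, 1L, 1L, 0L)
  dj <- c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L)
  dk <- c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L)
  out <- matrix(0L, length(cells), 8L)
  for (a in 1:8) out[, a] <- node_index(mesh, i + di[a], j + dj[a], k + dk[a])
  out
}

#' Cell centres of a mesh
#' @param mesh a `pfa_mesh`.
#' @param cells optional cell index vector.
#' @return matrix n x 3 (metres).
#' @export
cell_centers <- function(mesh, cells = seq_len(mesh$n_cells)) {
  if (mesh$type == "tensor") {
    ijk <- cell_ijk(mesh, cells)
    cbind(mesh$cx[ijk[, 1]], mesh$cy[ijk[, 2]], mesh$cz[ijk[, 3]])
  } else {
    en <- cell_nodes(mesh, cells)
    out <- matrix(0, length(cells), 3)
    for (a in 1:8) out <- out + mesh$node_xyz[en[, a], , drop = FALSE]
    out / 8
  }
}

#' @rdname cell_index
#' @param cells cell index vector.
#' @export
cell_sizes <- function(mesh, cells = seq_len(mesh$n_cells)) {
  stopifnot(mesh$type == "tensor")
  ijk <- cell_ijk(mesh, cells)
  cbind(mesh$hx[ijk[, 1]], mesh$hy[ijk[, 2]], mesh$hz[ijk[, 3]])
}

#' Cell volumes
#' @param mesh a `pfa_mesh`.
#' @param cells optional cell index vector.
#' @return numeric vector of volumes in m^3.
#' @export
cell_volumes <- function(mesh, cells = seq_len(mesh$n_cells)) {
  if (mesh$type == "tensor") {
    h <- cell_sizes(mesh, cells)
    h[, 1] * h[, 2] * h[, 3]
  } else {
    en <- cell_nodes(mesh, cells)
    X <- lapply(1:3, function(d) {
      out <- matrix(0, length(cells), 8)
      for (a in 1:8) out[, a] <- mesh$node_xyz[en[, a], d]
      out
    })
    vol <- numeric(length(cells))
    for (q in seq_len(nrow(.hex_gauss))) {
      dN <- .hex_dN(.hex_gauss[q, 1], .hex_gauss[q, 2], .hex_gauss[q, 3])
      J <- array(0, c(length(cells), 3, 3))
      for (d in 1:3) for (r in 1:3) J[, d, r] <- X[[d]] %*% dN[, r]
      vol <- vol + .det3(J)
    }
    vol
  }
}

# determinant of nE stacked 3x3 matrices
.det3 <- function(J) {
  J[, 1, 1] * (J[, 2, 2] * J[, 3, 3] - J[, 2, 3] * J[, 3, 2]) -
  J[, 1, 2] * (J[, 2, 1] * J[, 3, 3] - J[, 2, 3] * J[, 3, 1]) +
  J[, 1, 3] * (J[, 2, 1] * J[, 3, 2] - J[, 2, 2] * J[, 3, 1])
}

# inverse of nE stacked 3x3 matrices (given precomputed det)
.inv3 <- function(J, detJ) {
  inv <- array(0, dim(J))
  inv[, 1, 1] <- (J[, 2, 2] * J[, 3, 3] - J[, 2, 3] * J[, 3, 2]) / detJ
  inv[, 1, 2] <- (J[, 1, 3] * J[, 3, 2] - J[, 1, 2] * J[, 3, 3]) / detJ
  inv[, 1, 3] <- (J[, 1, 2] * J[, 2, 3] - J[, 1, 3] * J[, 2, 2]) / detJ
  inv[, 2, 1] <- (J[, 2, 3] * J[, 3, 1] - J[, 2, 1] * J[, 3, 3]) / detJ
  inv[, 2, 2] <- (J[, 1, 1] * J[, 3, 3] - J[, 1, 3] * J[, 3, 1]) / detJ
  inv[, 2, 3] <- (J[, 1, 3] * J[, 2, 1] - J[, 1, 1] * J[, 2, 3]) / detJ
  inv[, 3, 1] <- (J[, 2, 1] * J[, 3, 2] - J[, 2, 2] * J[, 3, 1]) / detJ
  inv[, 3, 2] <- (J[, 1, 2] * J[, 3, 1] - J[, 1, 1] * J[, 3, 2]) / detJ
  inv[, 3, 3] <- (J[, 1, 1] * J[, 2, 2] - J[, 1, 2] * J[, 2, 1]) / detJ
  inv
}

#' Assemble the conduction stiffness matrix
#'
#' Trilinear hexahedral finite elements; full-tensor conductivity per cell.
#'
#' @param mesh a `pfa_mesh`.
#' @param cells cells to assemble over (conducting subdomain).
#' @param sigma nE x 6 matrix of symmetric tensor components
#'   (xx, yy, zz, xy, xz, yz), S/m; a single column is taken as isotropic.
#' @return sparse symmetric stiffness matrix over all mesh nodes.
#' @export
fem_stiffness <- function(mesh, cells, sigma) {
  sigma <- as.matrix(sigma)
  if (ncol(sigma) == 1) sigma <- cbind(sigma, sigma, sigma, 0, 0, 0)
  stopifnot(nrow(sigma) == length(cells), ncol(sigma) == 6)
  en <- cell_nodes(mesh, cells)
  nE <- length(cells)
  Kv <- matrix(0, nE, 64)          # local matrices, column-major (i fastest)
  comp <- rbind(c(1, 1, 1), c(2, 2, 2), c(3, 3, 3),
                c(4, 1, 2), c(5, 1, 3), c(6, 2, 3))
  if (mesh$type == "tensor") {
    h <- cell_sizes(mesh, cells)
    detJ <- h[, 1] * h[, 2] * h[, 3] / 8
    for (r in seq_len(nrow(comp))) {
      ci <- comp[r, 1]; a <- comp[r, 2]; b <- comp[r, 3]
      coef <- sigma[, ci] * detJ * 4 / (h[, a] * h[, b])
      Mab <- .hex_M[[a]][[b]]
      if (a != b) Mab <- Mab + t(.hex_M[[a]][[b]])  # sigma symmetric: ab + ba
      Kv <- Kv + coef %o% as.vector(Mab)
    }
  } else {
    X <- lapply(1:3, function(d) {
      out <- matrix(0, nE, 8)
      for (a in 1:8) out[, a] <- mesh$node_xyz[en[, a], d]
      out
    })
    S <- array(0, c(nE, 3, 3))
    S[, 1, 1] <- sigma[, 1]; S[, 2, 2] <- sigma[, 2]; S[, 3, 3] <- sigma[, 3]
    S[, 1, 2] <- S[, 2, 1] <- sigma[, 4]
    S[, 1, 3] <- S[, 3, 1] <- sigma[, 5]
    S[, 2, 3] <- S[, 3, 2] <- sigma[, 6]
    for (q in seq_len(nrow(.hex_gauss))) {
      dN <- .hex_dN(.hex_gauss[q, 1], .hex_gauss[q, 2], .hex_gauss[q, 3])
      J <- array(0, c(nE, 3, 3))
      for (d in 1:3) for (r in 1:3) J[, d, r] <- X[[d]] %*% dN[, r]
      detJ <- .det3(J)
      invJ <- .inv3(J, detJ)
      # B[e, a, i] = dN_a/dx_i = sum_j dN[a, j] invJ[e, j, i]
      B <- array(0, c(nE, 8, 3))
      for (a in 1:8) for (i in 1:3)
        B[, a, i] <- dN[a, 1] * invJ[, 1, i] + dN[a, 2] * invJ[, 2, i] +
                     dN[a, 3] * invJ[, 3, i]
      SB <- array(0, c(nE, 8, 3))  # SB[e, a, i] = sum_k B[e,a,k] S[e,k,i]
      for (a in 1:8) for (i in 1:3)
        SB[, a, i] <- B[, a, 1] * S[, 1, i] + B[, a, 2] * S[, 2, i] +
                      B[, a, 3] * S[, 3, i]
      for (jj in 1:8) for (ii in 1:8) {
        Kv[, ii + 8 * (jj - 1)] <- Kv[, ii + 8 * (jj - 1)] + detJ *
          (SB[, ii, 1] * B[, jj, 1] + SB[, ii, 2] * B[, jj, 2] +
           SB[, ii, 3] * B[, jj, 3])
      }
    }
  }
  ii <- en[, rep(1:8, times = 8)]
  jj <- en[, rep(1:8, each = 8)]
  Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj), x = as.vector(Kv),
                       dims = c(mesh$n_nodes, mesh$n_nodes))
}

#' Solve the assembled system with Dirichlet boundary values
#'
#' Solves `K V = 0` with prescribed values on `fixed` nodes; only
#' `active_nodes` (nodes of conducting cells) participate.
#' Jacobi-preconditioned conjugate gradients with optional warm start
#' through `state$x` (an environment).
#'
#' @param K stiffness matrix from [fem_stiffness()].
#' @param active_nodes nodes of the conducting subdomain.
#' @param fixed,fixed_val Dirichlet node ids and values.
#' @param state optional environment carrying the warm-start solution.
#' @param tol,maxit conjugate-gradient controls.
#' @return list: `V` (length n_nodes, NA on inactive nodes), `residual`
#'   (`K V`, the reaction currents at constrained nodes), `cg_iters`.
#' @export
fem_solve_dirichlet <- function(K, active_nodes, fixed, fixed_val,
                                state = NULL, tol = 1e-8, maxit = 30000L) {
  free <- setdiff(active_nodes, fixed)
  Kff <- K[free, free]
  rhs <- as.numeric(-K[free, fixed, drop = FALSE] %*% fixed_val)
  d <- Matrix::diag(Kff)
  if (any(d <= 0))
    stop("singular system: electrodes disconnected or no conducting path",
         call. = FALSE)
  x0 <- NULL
  if (!is.null(state) && !is.null(state$x) && length(state$x) == length(free))
    x0 <- state$x
  res <- cg_solve(Kff, rhs, x0 = x0, tol = tol, maxit = maxit)
  if (!is.null(state)) state$x <- res$x
  V <- rep(NA_real_, nrow(K))
  V[free] <- res$x
  V[fixed] <- fixed_val
  Vz <- V; Vz[is.na(Vz)] <- 0
  r <- as.numeric(K %*% Vz)
  list(V = V, residual = r, cg_iters = res$iters)
}

#' Per-cell gradient of a nodal field
#'
#' @param mesh a `pfa_mesh`.
#' @param cells cell index vector.
#' @param V nodal values.
#' @return nE x 3 matrix of gradients evaluated at cell centres.
#' @export
fem_gradient <- function(mesh, cells, V) {
  en <- cell_nodes(mesh, cells)
  Vn <- matrix(V[en], nrow(en), 8)
  dNc <- cbind(.hex_xi, .hex_eta, .hex_zeta) / 8
  gref <- Vn %*% dNc                     # d/d(xi,eta,zeta)
  if (mesh$type == "tensor") {
    h <- cell_sizes(mesh, cells)
    cbind(gref[, 1] * 2 / h[, 1], gref[, 2] * 2 / h[, 2], gref[, 3] * 2 / h[, 3])
  } else {
    X <- lapply(1:3, function(d) {
      out <- matrix(0, nrow(en), 8)
      for (a in 1:8) out[, a] <- mesh$node_xyz[en[, a], d]
      out
    })
    dN <- .hex_dN(0, 0, 0)
    J <- array(0, c(nrow(en), 3, 3))
    for (d in 1:3) for (r in 1:3) J[, d, r] <- X[[d]] %*% dN[, r]
    invJ <- .inv3(J, .det3(J))
    out <- matrix(0, nrow(en), 3)
    for (i in 1:3)
      out[, i] <- gref[, 1] * invJ[, 1, i] + gref[, 2] * invJ[, 2, i] +
                  gref[, 3] * invJ[, 3, i]
    out
  }
}

#' Build a graded grid-line vector for one axis
#'
#' Produces grid lines spanning `lim` with uniform fine spacing inside each
#' refinement window and geometric coarsening (ratio `growth`, capped at
#' `h_max`) in between and towards the domain edges.
#'
#' @param lim length-2 domain limits (m).
#' @param windows list of `c(lo, hi, h)` refinement windows (m).
#' @param h_max maximum cell size away from the windows (m).
#' @param growth geometric growth ratio between neighbouring cells.
#' @return numeric vector of grid-line coordinates.
#' @export
graded_axis <- function(lim, windows = list(), h_max, growth = 1.5) {
  stopifnot(length(lim) == 2, lim[2] > lim[1], h_max > 0, growth > 1)
  if (length(windows) == 0)
    return(seq(lim[1], lim[2], length.out = max(2L, ceiling(diff(lim) / h_max) + 1L)))
  # piecewise-minimum spacing over elementary intervals between window edges
  edges <- sort(unique(c(vapply(windows, `[`, 0, 1), vapply(windows, `[`, 0, 2))))
  edges <- edges[edges > lim[1] & edges < lim[2]]
  edges <- c(lim[1], edges, lim[2])
  merged <- list()
  for (k in seq_len(length(edges) - 1)) {
    lo <- edges[k]; hi <- edges[k + 1]; mid <- (lo + hi) / 2
    hs <- vapply(windows, function(w)
      if (mid >= w[1] && mid <= w[2]) w[3] else Inf, 0)
    h <- min(hs)
    if (!is.finite(h)) next
    last <- if (length(merged)) merged[[length(merged)]] else NULL
    if (!is.null(last) && abs(last[2] - lo) < 1e-12 && last[3] == h)
      merged[[length(merged)]] <- c(last[1], hi, h)
    else merged <- c(merged, list(c(lo, hi, h)))
  }
  if (length(merged) == 0)
    return(seq(lim[1], lim[2], length.out = max(2L, ceiling(diff(lim) / h_max) + 1L)))
  ramp <- function(h0, h1, gap) {
    # cell sizes across a gap, growing from h0 (capped h_max) and shrinking
    # back to h1; scaled to fit exactly
    if (gap <= 1e-12) return(numeric(0))
    grow <- function(h) {
      s <- numeric(0); x <- 0
      while (x < gap) { h <- min(h * growth, h_max); s <- c(s, h); x <- x + h }
      s
    }
    a <- grow(h0); b <- grow(h1)
    # take from both ends until they cover the gap
    sizes <- numeric(0); ia <- 1; ib <- 1; covered <- 0
    left <- numeric(0); right <- numeric(0)
    while (covered < gap) {
      ha <- if (ia <= length(a)) a[ia] else h_max
      hb <- if (ib <= length(b)) b[ib] else h_max
      if (ha <= hb) { left <- c(left, ha); covered <- covered + ha; ia <- ia + 1 }
      else { right <- c(hb, right); covered <- covered + hb; ib <- ib + 1 }
    }
    sizes <- c(left, right)
    sizes * gap / sum(sizes)
  }
  sizes <- numeric(0)
  w1 <- merged[[1]]
  sizes <- c(sizes, rev(ramp(w1[3], h_max, w1[1] - lim[1])))
  for (k in seq_along(merged)) {
    w <- merged[[k]]
    nfin <- max(1L, round((w[2] - w[1]) / w[3]))
    sizes <- c(sizes, rep((w[2] - w[1]) / nfin, nfin))
    if (k < length(merged)) {
      nxt <- merged[[k + 1]]
      sizes <- c(sizes, ramp(w[3], nxt[3], nxt[1] - w[2]))
    }
  }
  wl <- merged[[length(merged)]]
  sizes <- c(sizes, ramp(wl[3], h_max, lim[2] - wl[2]))
  cumsum(c(lim[1], sizes))
}

#' Diagonal-preconditioned conjugate gradients
#'
#' @param A sparse symmetric positive-definite matrix.
#' @param b right-hand side.
#' @param x0 optional starting vector.
#' @param tol relative residual tolerance.
#' @param maxit iteration cap.
#' @return list with the solution `x` and `iters`.
#' @export
cg_solve <- function(A, b, x0 = NULL, tol = 1e-8, maxit = 500L) {
  d <- Matrix::diag(A)
  x <- if (is.null(x0)) numeric(length(b)) else x0
  r <- b - as.numeric(A %*% x)
  z <- r / d
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b * b)) + 1e-300
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r * r)) <= tol * bnorm) return(list(x = x, iters = it))
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  warning("cg_solve: not converged in ", maxit, " iterations")
  list(x = x, iters = maxit)
}
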