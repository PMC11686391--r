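# Idealized biventricular + IVC + bulk domain on a graded hexahedral grid.
#
# The ventricles are two coaxial ellipsoids truncated at the basal plane
# (papillary muscles and trabeculations neglected); the RV is a thinner
# crescent shell from a third, offset ellipsoid; the IVC is a cylinder in the
# surrounding bulk. Catheters are voxelised capsules/cylinders; the ablation
# tip is indented rigidly into the wall (boolean subtraction, no mechanics).
# Conventions: LV long axis = +z, base at high z, right-handed, SI metres.

#' Geometry and catheter parameters
#'
#' All lengths in metres. Defaults describe a porcine-scale LV: cavity semi
#' axes 20 x 20 x 42 mm, epicardial 29 x 29 x 50 mm (8-9 mm wall), truncated
#' 10 mm above centre; an 8 F (2.67 mm) focal catheter with a 5 mm tip
#' electrode indented 0.5 mm into the wall; a decapolar return catheter in a
#' 9 mm-radius IVC. The exact heart dimensions are configurable assumptions:
#' in the animals they were obtained by scaling the schematic to MRI.
#'
#' @param lv_endo_semi_axes,lv_epi_semi_axes LV cavity/epicardial semi-axes.
#' @param rv_on include the RV crescent shell (geometry realism only; RV is
#'   excluded from segment labelling).
#' @param rv_center,rv_epi_semi_axes,rv_wall RV shell ellipsoid and thickness.
#' @param basal_truncation_height z of the basal plane relative to centre.
#' @param ivc_radius,ivc_center_xy,ivc_zlim IVC cylinder.
#' @param bulk_factor bulk box size as a multiple of the heart+IVC box.
#' @param abl_catheter_diameter,abl_tip_length,abl_shaft_length ablation
#'   catheter (8 F, 5 mm tip electrode).
#' @param ret_catheter_diameter,ret_electrode_count,ret_electrode_length,ret_electrode_gaps,ret_span_center
#'   return catheter: 10 bands, 2 mm long, alternating 2/6 mm gaps.
#' @param ret_pressed press the return catheter against the IVC wall
#'   (worst-case cooling geometry).
#' @param indentation_depth rigid tip indentation into the wall.
#' @param mesh_resolution target edge length near the ablation tip.
#' @param ivc_resolution target edge length in the IVC/return-electrode zone.
#' @param h_max,growth far-field cell size cap and grading ratio.
#' @return object of class `pfa_geometry_params`.
#' @export
geometry_params <- function(
    lv_endo_semi_axes = c(0.020, 0.020, 0.042),
    lv_epi_semi_axes  = c(0.029, 0.029, 0.050),
    rv_on = TRUE,
    rv_center = c(-0.014, 0, -0.004),
    rv_epi_semi_axes = c(0.040, 0.031, 0.045),
    rv_wall = 0.005,
    basal_truncation_height = 0.010,
    ivc_radius = 0.009,
    ivc_center_xy = c(0.048, 0),
    ivc_zlim = c(-0.045, 0.055),
    bulk_factor = 2.2,
    abl_catheter_diameter = 2.67e-3,
    abl_tip_length = 5e-3,
    abl_shaft_length = 0.020,
    ret_catheter_diameter = 2.33e-3,
    ret_electrode_count = 10L,
    ret_electrode_length = 2e-3,
    ret_electrode_gaps = c(2e-3, 6e-3),
    ret_span_center = 0,
    ret_pressed = TRUE,
    indentation_depth = 0.5e-3,
    mesh_resolution = 0.9e-3,
    ivc_resolution = 2e-3,
    h_max = 0.028,
    growth = 1.6) {
  p <- as.list(environment())
  if (any(p$lv_epi_semi_axes <= p$lv_endo_semi_axes))
    stop("invalid geometry: epicardial semi-axes must exceed endocardial ones",
         call. = FALSE)
  lens <- c(p$lv_endo_semi_axes, p$lv_epi_semi_axes, p$ivc_radius,
            p$abl_catheter_diameter, p$abl_tip_length, p$mesh_resolution,
            p$indentation_depth)
  if (any(lens <= 0)) stop("invalid geometry: all lengths must be positive",
                           call. = FALSE)
  if (p$indentation_depth >= min(p$lv_epi_semi_axes - p$lv_endo_semi_axes))
    stop("invalid geometry: indentation exceeds wall thickness", call. = FALSE)
  class(p) <- "pfa_geometry_params"
  p
}

# z-centres of the 10 return-electrode bands and their [lo, hi] ranges
ret_band_ranges <- function(params) {
  n <- params$ret_electrode_count
  el <- params$ret_electrode_length
  gaps <- rep_len(params$ret_electrode_gaps, n - 1)
  starts <- cumsum(c(0, el + gaps))
  span <- starts[n] + el
  lo <- starts - span / 2 + params$ret_span_center
  cbind(lo = lo, hi = lo + el)
}

#' Endocardial site and outward normal of a segment centre
#'
#' @param params a [geometry_params()].
#' @param segment_id integer 1-13.
#' @return list with `endo_point` (m) and the outward unit `normal`.
#' @export
segment_site <- function(params, segment_id) {
  stopifnot(segment_id >= 1, segment_id <= 13)
  a <- params$lv_endo_semi_axes[1]; b <- params$lv_endo_semi_axes[2]
  ce <- params$lv_endo_semi_axes[3]
  h <- params$basal_truncation_height
  zb <- segment_z_bounds(params)
  if (segment_id == 13) {
    p0 <- c(0, 0, -ce)
    d <- c(0, 0, -1)
  } else {
    lev <- (segment_id - 1) %/% 4        # 0 basal, 1 mid, 2 apical
    sec <- (segment_id - 1) %% 4 + 1     # 1 ant(+y), 2 sept(-x), 3 lat(+x), 4 post(-y)
    zr <- list(c(zb["z1"], h), c(zb["z2"], zb["z1"]), c(zb["z0"], zb["z2"]))[[lev + 1]]
    z0 <- mean(zr)
    phi <- c(pi / 2, pi, 0, -pi / 2)[sec]
    rho <- sqrt(max(0, 1 - (z0 / ce)^2))
    p0 <- c(a * rho * cos(phi), b * rho * sin(phi), z0)
    d <- c(2 * p0[1] / a^2, 2 * p0[2] / b^2, 2 * p0[3] / ce^2)
    d <- d / sqrt(sum(d^2))
  }
  list(endo_point = p0, normal = d)
}

#' Long-axis boundaries of the segment levels
#'
#' @param params a [geometry_params()].
#' @param cap_frac fraction of the long axis assigned to the apical cap.
#' @return named vector: `z0` (cap top), `z2` (apical/mid), `z1`
#'   (mid/basal), metres.
#' @export
segment_z_bounds <- function(params, cap_frac = 0.2) {
  ce <- params$lv_endo_semi_axes[3]
  h <- params$basal_truncation_height
  z0 <- -ce + cap_frac * (h + ce)
  step <- (h - z0) / 3
  c(z0 = z0, z2 = z0 + step, z1 = z0 + 2 * step)
}

# default grid with refinement at the target segment's tip and the IVC band;
# ivc_fine additionally refines the return-catheter neighbourhood radially
# (needed to resolve the thin high-field shells around the electrode bands)
heart_grid <- function(params, segment_id = 8, ivc_fine = FALSE,
                       ivc_fine_h = 1e-3) {
  site <- segment_site(params, segment_id)
  tip <- site$endo_point + params$indentation_depth * site$normal
  hf <- params$mesh_resolution
  hi <- params$ivc_resolution
  rtip <- 0.008
  icx <- params$ivc_center_xy[1]; icy <- params$ivc_center_xy[2]
  ir <- params$ivc_radius
  bands <- ret_band_ranges(params)
  # heart + IVC bounding box
  epi <- params$lv_epi_semi_axes
  bb <- rbind(c(-epi[1], epi[1]), c(-epi[2], epi[2]),
              c(-epi[3], params$basal_truncation_height))
  if (params$rv_on) {
    bb[, 1] <- pmin(bb[, 1], params$rv_center - params$rv_epi_semi_axes)
    bb[, 2] <- pmax(bb[, 2], params$rv_center + params$rv_epi_semi_axes)
  }
  bb[1, ] <- range(bb[1, ], icx - ir, icx + ir)
  bb[2, ] <- range(bb[2, ], icy - ir, icy + ir)
  bb[3, ] <- range(bb[3, ], params$ivc_zlim)
  ctr <- rowMeans(bb); hw <- (bb[, 2] - bb[, 1]) / 2 * params$bulk_factor
  lim <- cbind(ctr - hw, ctr + hw)
  # snap the IVC z-window to multiples of ivc_resolution so that electrode
  # band edges coincide with grid lines
  zi0 <- floor((min(bands) - 2 * hi) / hi) * hi
  zi1 <- ceiling((max(bands) + 2 * hi) / hi) * hi
  xwin <- list(c(tip[1] - rtip, tip[1] + rtip, hf),
               c(icx - ir - hi, icx + ir + hi, hi))
  ywin <- list(c(tip[2] - rtip, tip[2] + rtip, hf),
               c(icy - ir - hi, icy + ir + hi, hi))
  zwin <- list(c(tip[3] - rtip, tip[3] + rtip, hf), c(zi0, zi1, hi))
  if (ivc_fine) {
    rr <- params$ret_catheter_diameter / 2
    ax <- if (params$ret_pressed) icx - (ir - rr) else icx
    xwin <- c(xwin, list(c(ax - 5e-3, ax + 5e-3, ivc_fine_h)))
    ywin <- c(ywin, list(c(icy - 5e-3, icy + 5e-3, ivc_fine_h)))
    zf0 <- floor(min(bands) / ivc_fine_h) * ivc_fine_h - 2 * ivc_fine_h
    zf1 <- ceiling(max(bands) / ivc_fine_h) * ivc_fine_h + 2 * ivc_fine_h
    zwin <- c(zwin, list(c(zf0, zf1, ivc_fine_h)))
  }
  xs <- graded_axis(lim[1, ], xwin, h_max = params$h_max, growth = params$growth)
  ys <- graded_axis(lim[2, ], ywin, h_max = params$h_max, growth = params$growth)
  zs <- graded_axis(lim[3, ], zwin, h_max = params$h_max, growth = params$growth)
  list(xs = xs, ys = ys, zs = zs)
}

.in_ellipsoid <- function(p, semi, center = c(0, 0, 0)) {
  ((p[, 1] - center[1]) / semi[1])^2 + ((p[, 2] - center[2]) / semi[2])^2 +
    ((p[, 3] - center[3]) / semi[3])^2 <= 1
}

#' Build the computational domain
#'
#' Classifies the cells of a graded hexahedral grid into myocardium (LV shell
#' and optional RV crescent), LV cavity blood, IVC blood, bulk tissue and
#' return-catheter body, and records the return-electrode bands. The ablation
#' catheter is added separately with [place_catheter()].
#'
#' @param params a [geometry_params()] object.
#' @param segment_id segment whose tip neighbourhood gets the fine grid zone
#'   (the catheter is expected to be placed there).
#' @param grid optional list (xs, ys, zs) of grid lines overriding the default
#'   graded grid.
#' @param ivc_fine refine the return-catheter neighbourhood radially to
#'   ~1 mm (resolves the thin high-field shells around the electrode bands
#'   for blood-exposure accounting).
#' @return a `pfa_mesh` with `region`, `rv_flag`, `cavity_flag`, `elec`
#'   (0 none, 2 return electrode) and `params` attached.
#' @export
build_domain <- function(params, segment_id = 8, grid = NULL,
                         ivc_fine = FALSE) {
  if (!inherits(params, "pfa_geometry_params")) stop("params must come from geometry_params()")
  if (is.null(grid)) grid <- heart_grid(params, segment_id, ivc_fine = ivc_fine)
  mesh <- tensor_mesh(grid$xs, grid$ys, grid$zs)
  p <- cell_centers(mesh)
  h <- params$basal_truncation_height
  below <- p[, 3] <= h
  reg <- rep.int(REGION["bulk"], mesh$n_cells)
  rv_flag <- logical(mesh$n_cells)
  cavity <- logical(mesh$n_cells)

  in_epi <- .in_ellipsoid(p, params$lv_epi_semi_axes) & below
  in_endo <- .in_ellipsoid(p, params$lv_endo_semi_axes) & below
  reg[in_epi & !in_endo] <- REGION["myocardium"]
  reg[in_endo] <- REGION["blood_lv"]

  if (params$rv_on) {
    rv_endo_semi <- params$rv_epi_semi_axes - params$rv_wall
    in_rv_epi <- .in_ellipsoid(p, params$rv_epi_semi_axes, params$rv_center) & below
    in_rv_endo <- .in_ellipsoid(p, rv_endo_semi, params$rv_center) & below
    sel_shell <- in_rv_epi & !in_rv_endo & !in_epi
    reg[sel_shell] <- REGION["myocardium"]
    rv_flag[sel_shell] <- TRUE
    sel_cav <- in_rv_endo & !in_epi
    reg[sel_cav] <- REGION["bulk"]
    cavity[sel_cav] <- TRUE
  }

  icx <- params$ivc_center_xy[1]; icy <- params$ivc_center_xy[2]
  in_ivc <- (p[, 1] - icx)^2 + (p[, 2] - icy)^2 <= params$ivc_radius^2 &
    p[, 3] >= params$ivc_zlim[1] & p[, 3] <= params$ivc_zlim[2] &
    reg == REGION["bulk"] & !cavity
  reg[in_ivc] <- REGION["blood_ivc"]

  elec <- integer(mesh$n_cells)
  # return catheter: straight, parallel to z inside the IVC. Cell centres
  # inside the circle give an unbiased voxel surface; on grids too coarse
  # for that, fall back to footprint overlap so the shaft stays at least
  # one cell wide.
  rr <- params$ret_catheter_diameter / 2
  ax <- if (params$ret_pressed) icx - (params$ivc_radius - rr) else icx
  in_ret <- (p[, 1] - ax)^2 + (p[, 2] - icy)^2 <= rr^2 &
    reg == REGION["blood_ivc"]
  if (!any(in_ret)) {
    ijk0 <- cell_ijk(mesh, seq_len(mesh$n_cells))
    hx2 <- mesh$hx[ijk0[, 1]] / 2; hy2 <- mesh$hy[ijk0[, 2]] / 2
    ddx <- pmax(abs(p[, 1] - ax) - hx2, 0)
    ddy <- pmax(abs(p[, 2] - icy) - hy2, 0)
    in_ret <- ddx^2 + ddy^2 <= rr^2 & reg == REGION["blood_ivc"]
  }
  reg[in_ret] <- REGION["catheter_body"]
  bands <- ret_band_ranges(params)
  ijk <- cell_ijk(mesh, seq_len(mesh$n_cells))
  z_lo <- mesh$zs[ijk[, 3]]; z_hi <- mesh$zs[ijk[, 3] + 1L]
  in_band <- rep(FALSE, mesh$n_cells)
  for (r in seq_len(nrow(bands)))     # z-extent overlap: robust to coarse cells
    in_band <- in_band | (z_lo < bands[r, 2] & z_hi > bands[r, 1])
  elec[in_ret & in_band] <- 2L

  mesh$region <- reg
  mesh$rv_flag <- rv_flag
  mesh$cavity_flag <- cavity
  mesh$elec <- elec
  mesh$params <- params
  mesh$ret_axis_xy <- c(ax, icy)
  mesh$region0 <- reg      # pristine copy: place_catheter() is idempotent
  mesh$elec0 <- elec
  mesh
}

#' Assign the 13 LV myocardial segments
#'
#' Partition: 3 long-axis levels (basal, mid, apical) x 4 circumferential
#' sectors (anterior +y, septal -x, lateral +x, posterior -y) plus an apical
#' cap. Ids: `4*level + sector` with level 0 basal, plus cap = 13. RV-shell
#' elements are labelled 0 (no ablations delivered there).
#'
#' @param mesh mesh from [build_domain()].
#' @return the mesh with `segment_id` (integer per cell, 0 outside the LV).
#' @export
assign_segments <- function(mesh) {
  if (is.null(mesh$params)) stop("mesh has no geometry params; build with build_domain()")
  params <- mesh$params
  p <- cell_centers(mesh)
  seg <- integer(mesh$n_cells)
  myo <- mesh$region == REGION["myocardium"] & !mesh$rv_flag
  zb <- segment_z_bounds(params)
  z <- p[myo, 3]
  lev <- ifelse(z >= zb["z1"], 0L, ifelse(z >= zb["z2"], 1L, 2L))
  ang <- atan2(p[myo, 2], p[myo, 1])
  sec <- ifelse(ang > pi / 4 & ang <= 3 * pi / 4, 1L,          # anterior
         ifelse(ang > 3 * pi / 4 | ang <= -3 * pi / 4, 2L,     # septal
         ifelse(ang > -pi / 4 & ang <= pi / 4, 3L, 4L)))       # lateral / posterior
  s <- 4L * lev + sec
  s[z < zb["z0"]] <- 13L
  seg[myo] <- s
  mesh$segment_id <- seg
  mesh
}

#' Place the ablation catheter at a segment
#'
#' The catheter axis is the analytic endocardial surface normal at the
#' segment centre; the hemispherically-capped 5 mm tip electrode is indented
#' `indentation_depth` into the wall by boolean subtraction and the
#' insulating shaft extends back into the cavity. Placement starts from the
#' pristine classification, so placing twice is idempotent.
#'
#' @param mesh mesh from [build_domain()] (ideally built with matching
#'   `segment_id` so the tip sits in the fine grid zone).
#' @param segment_id integer 1-13.
#' @param params optional override of the mesh's geometry params.
#' @return the mesh with catheter cells labelled and `abl` placement info.
#' @export
place_catheter <- function(mesh, segment_id, params = mesh$params) {
  stopifnot(segment_id >= 1, segment_id <= 13)
  site <- segment_site(params, segment_id)
  p0 <- site$endo_point; d <- site$normal
  rc <- params$abl_catheter_diameter / 2
  front <- p0 + params$indentation_depth * d
  c1 <- front - rc * d                       # tip cap centre
  c2 <- c1 - (params$abl_tip_length - rc) * d
  c3 <- c2 - params$abl_shaft_length * d
  reg <- mesh$region0
  elec <- mesh$elec0
  p <- cell_centers(mesh)
  # candidate cells near the catheter line
  lo <- pmin(front, c3) - 2 * rc; hi <- pmax(front, c3) + 2 * rc
  cand <- which(p[, 1] >= lo[1] & p[, 1] <= hi[1] &
                p[, 2] >= lo[2] & p[, 2] <= hi[2] &
                p[, 3] >= lo[3] & p[, 3] <= hi[3])
  if (length(cand) == 0) stop("catheter placement failed: segment outside mesh")
  dseg <- function(pts, a, b) {
    ab <- b - a
    tt <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2] +
           (pts[, 3] - a[3]) * ab[3]) / sum(ab^2)
    tt <- pmin(pmax(tt, 0), 1)
    sqrt((pts[, 1] - a[1] - tt * ab[1])^2 + (pts[, 2] - a[2] - tt * ab[2])^2 +
         (pts[, 3] - a[3] - tt * ab[3])^2)
  }
  pc <- p[cand, , drop = FALSE]
  tip_cells <- cand[dseg(pc, c2, c1) <= rc]
  shaft_cells <- cand[dseg(pc, c3, c2) <= rc]
  if (length(tip_cells) == 0)
    stop("catheter placement failed: tip not resolved by the grid (refine mesh_resolution)")
  reg[shaft_cells] <- REGION["catheter_body"]
  reg[tip_cells] <- REGION["catheter_body"]
  elec[shaft_cells] <- 0L
  elec[tip_cells] <- 1L
  mesh$region <- reg
  mesh$elec <- elec
  mesh$abl <- list(segment_id = segment_id, endo_point = p0, axis = d,
                   tip_front = front, tip_cap_center = c1, tip_back = c2)
  mesh
}

# nodes on the interface between electrode cells (elec == which) and
# conducting cells
electrode_nodes <- function(mesh, which) {
  sel <- mesh$elec == which & mesh$region == REGION["catheter_body"]
  if (!any(sel)) stop("no electrode cells with elec == ", which)
  cond <- mesh$region != REGION["catheter_body"] | mesh$elec > 0L
  cond[sel] <- FALSE
  faces <- .adjacent_faces(mesh, sel, cond)
  sort(unique(as.vector(faces$nodes)))
}

# Dirichlet node set for an immersed electrode: nodes strictly inside the
# electrode geometry, eroded by about half a local cell so the equipotential
# surface is carried by the metal-conductivity cells rather than the voxel
# hull (removes the +h/2 surface bias). Falls back to the interface nodes on
# grids too coarse to erode.
electrode_dirichlet_nodes <- function(mesh, which) {
  sel <- which(mesh$elec == which & mesh$region == REGION["catheter_body"])
  if (!length(sel)) stop("no electrode cells with elec == ", which)
  nodes <- sort(unique(as.vector(cell_nodes(mesh, sel))))
  nxyz <- node_xyz(mesh, nodes)
  prm <- mesh$params
  inside <- NULL
  if (which == 1L && !is.null(mesh$abl)) {
    rc <- prm$abl_catheter_diameter / 2
    shrink <- min(rc / 2, prm$mesh_resolution * 0.75)
    a <- mesh$abl$tip_back; b <- mesh$abl$tip_cap_center
    ab <- b - a
    tt <- ((nxyz[, 1] - a[1]) * ab[1] + (nxyz[, 2] - a[2]) * ab[2] +
           (nxyz[, 3] - a[3]) * ab[3]) / sum(ab^2)
    tt <- pmin(pmax(tt, 0), 1)
    d <- sqrt((nxyz[, 1] - a[1] - tt * ab[1])^2 +
              (nxyz[, 2] - a[2] - tt * ab[2])^2 +
              (nxyz[, 3] - a[3] - tt * ab[3])^2)
    inside <- nodes[d <= rc - shrink]
  } else if (which == 2L) {
    rr <- prm$ret_catheter_diameter / 2
    shrink <- min(rr / 2, prm$ivc_resolution * 0.75)
    bands <- ret_band_ranges(prm)
    d <- sqrt((nxyz[, 1] - mesh$ret_axis_xy[1])^2 +
              (nxyz[, 2] - mesh$ret_axis_xy[2])^2)
    inb <- rep(FALSE, length(nodes))
    for (r in seq_len(nrow(bands)))
      inb <- inb | (nxyz[, 3] >= bands[r, 1] & nxyz[, 3] <= bands[r, 2])
    inside <- nodes[d <= rr - shrink & inb]
    if (length(inside) < 10) inside <- nodes[d <= rr & inb]
  }
  if (is.null(inside) || length(inside) < 4) electrode_nodes(mesh, which)
  else inside
}

# node coordinates (tensor meshes)
node_xyz <- function(mesh, nodes) {
  stopifnot(mesh$type == "tensor")
  nnx <- mesh$nx + 1L; nny <- mesh$ny + 1L
  n0 <- nodes - 1L
  i <- n0 %% nnx + 1L
  j <- (n0 %/% nnx) %% nny + 1L
  k <- n0 %/% (nnx * nny) + 1L
  cbind(mesh$xs[i], mesh$ys[j], mesh$zs[k])
}

# faces between cells in maskA and neighbouring cells in maskB.
# Returns face node ids (n x 4), face centres (n x 3), the maskA-side cell,
# the maskB-side cell and the face axis.
.adjacent_faces <- function(mesh, maskA, maskB) {
  nx <- mesh$nx; ny <- mesh$ny; nz <- mesh$nz
  nodes <- NULL; centers <- NULL; cellsA <- integer(0); cellsB <- integer(0)
  axes <- integer(0)
  ijk_all <- cell_ijk(mesh, seq_len(mesh$n_cells))
  add <- function(eA, eB, axis) {
    if (length(eA) == 0) return()
    iA <- ijk_all[eA, , drop = FALSE]
    iB <- ijk_all[eB, , drop = FALSE]
    # shared face plane index along `axis` = max of the two cells' low corner
    fi <- pmax(iA[, axis], iB[, axis])
    if (axis == 1) {
      nd <- cbind(node_index(mesh, fi, iA[, 2], iA[, 3]),
                  node_index(mesh, fi, iA[, 2] + 1L, iA[, 3]),
                  node_index(mesh, fi, iA[, 2], iA[, 3] + 1L),
                  node_index(mesh, fi, iA[, 2] + 1L, iA[, 3] + 1L))
      ct <- cbind(mesh$xs[fi], mesh$cy[iA[, 2]], mesh$cz[iA[, 3]])
    } else if (axis == 2) {
      nd <- cbind(node_index(mesh, iA[, 1], fi, iA[, 3]),
                  node_index(mesh, iA[, 1] + 1L, fi, iA[, 3]),
                  node_index(mesh, iA[, 1], fi, iA[, 3] + 1L),
                  node_index(mesh, iA[, 1] + 1L, fi, iA[, 3] + 1L))
      ct <- cbind(mesh$cx[iA[, 1]], mesh$ys[fi], mesh$cz[iA[, 3]])
    } else {
      nd <- cbind(node_index(mesh, iA[, 1], iA[, 2], fi),
                  node_index(mesh, iA[, 1] + 1L, iA[, 2], fi),
                  node_index(mesh, iA[, 1], iA[, 2] + 1L, fi),
                  node_index(mesh, iA[, 1] + 1L, iA[, 2] + 1L, fi))
      ct <- cbind(mesh$cx[iA[, 1]], mesh$cy[iA[, 2]], mesh$zs[fi])
    }
    nodes <<- rbind(nodes, nd)
    centers <<- rbind(centers, ct)
    cellsA <<- c(cellsA, eA); cellsB <<- c(cellsB, eB)
    axes <<- c(axes, rep.int(axis, length(eA)))
  }
  e <- seq_len(mesh$n_cells)
  i <- ijk_all[, 1]; j <- ijk_all[, 2]; k <- ijk_all[, 3]
  # +x neighbours
  selx <- i < nx
  eL <- e[selx]; eR <- eL + 1L
  m <- maskA[eL] & maskB[eR]; add(eL[m], eR[m], 1L)
  m <- maskA[eR] & maskB[eL]; add(eR[m], eL[m], 1L)
  sely <- j < ny
  eL <- e[sely]; eR <- eL + nx
  m <- maskA[eL] & maskB[eR]; add(eL[m], eR[m], 2L)
  m <- maskA[eR] & maskB[eL]; add(eR[m], eL[m], 2L)
  selz <- k < nz
  eL <- e[selz]; eR <- eL + nx * ny
  m <- maskA[eL] & maskB[eR]; add(eL[m], eR[m], 3L)
  m <- maskA[eR] & maskB[eL]; add(eR[m], eL[m], 3L)
  list(nodes = nodes, centers = centers, cellsA = cellsA, cellsB = cellsB,
       axes = axes)
}

#' Tagged boundary surfaces of the myocardium
#'
#' Extracts the endocardial faces (myocardium against LV blood, or against
#' the RV cavity for the RV shell), the epicardial faces (myocardium against
#' bulk, excluding the basal truncation plane) and the basal faces.
#'
#' @param mesh a classified mesh.
#' @return list of face sets (`nodes`, `centers`, `cellsA`) for `endo`,
#'   `epi`, `base`.
#' @export
myocardial_surfaces <- function(mesh) {
  myo <- mesh$region == REGION["myocardium"]
  blood_side <- mesh$region == REGION["blood_lv"] |
    (mesh$region == REGION["bulk"] & mesh$cavity_flag)
  endo <- .adjacent_faces(mesh, myo, blood_side)
  bulk_side <- mesh$region == REGION["bulk"] & !mesh$cavity_flag
  epi <- .adjacent_faces(mesh, myo, bulk_side)
  h <- mesh$params$basal_truncation_height
  if (!is.null(epi$centers)) {
    is_base <- epi$axes == 3L & abs(epi$centers[, 3] - h) < 1e-6
    base <- lapply(list(nodes = epi$nodes, centers = epi$centers,
                        cellsA = epi$cellsA),
                   function(x) if (is.matrix(x)) x[is_base, , drop = FALSE] else x[is_base])
    epi <- list(nodes = epi$nodes[!is_base, , drop = FALSE],
                centers = epi$centers[!is_base, , drop = FALSE],
                cellsA = epi$cellsA[!is_base])
  } else base <- NULL
  list(endo = endo, epi = epi, base = base)
}

#' Total volume of a region
#' @param mesh a classified mesh.
#' @param region region name (see [REGION]).
#' @return volume in m^3.
#' @export
region_volume <- function(mesh, region) {
  sel <- mesh$region == REGION[[region]]
  if (!any(sel)) return(0)
  sum(cell_volumes(mesh, which(sel)))
}
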