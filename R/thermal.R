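# Pulsed Joule heating, convective cooling and thermal damage.
#
# Energy balance rho*C*(dT/dt + u . grad T) = div(k grad T) + Q with
# Q = ONOFF * duty * sigma * E^2 gated on the pulse trains. Blood motion is a
# stationary fully developed laminar profile (parabolic in circular
# channels; a cross-section Poisson solve when the return catheter makes the
# IVC lumen eccentric). Discretization: cell-centred finite volumes on the
# same grid as the field solve; implicit diffusion (Jacobi-CG), explicit
# first-order upwind advection sub-stepped to the CFL limit. Damage is
# scored with the thermal-dose rule (>= 55 degC for >= 1 s cumulative) and
# the Arrhenius integral (Omega >= 1, 63% cell death).

#' Blood-flow scenario
#'
#' @param label `"low"` or `"high"`; selects the default mean LV velocity
#'   (3 / 9 cm/s at the ablation-catheter level) and IVC volumetric flow
#'   (15 / 37 ml/s).
#' @param lv_mean_velocity,ivc_flow_rate,blood_viscosity overrides (SI).
#' @return object of class `pfa_flow_scenario`.
#' @export
flow_scenario <- function(label = c("low", "high"),
                          lv_mean_velocity = NULL, ivc_flow_rate = NULL,
                          blood_viscosity = 0.0035) {
  label <- match.arg(label)
  if (is.null(lv_mean_velocity))
    lv_mean_velocity <- if (label == "low") 0.03 else 0.09
  if (is.null(ivc_flow_rate))
    ivc_flow_rate <- if (label == "low") 15e-6 else 37e-6
  s <- list(label = label, lv_mean_velocity = lv_mean_velocity,
            ivc_flow_rate = ivc_flow_rate, blood_viscosity = blood_viscosity)
  class(s) <- "pfa_flow_scenario"
  s
}

#' Analytic Poiseuille profile in a circular pipe
#'
#' @param r radial position(s), m.
#' @param R pipe radius, m.
#' @param u_mean cross-sectional mean velocity, m/s.
#' @return axial velocity `2 * u_mean * (1 - (r/R)^2)`, zero outside the
#'   lumen; the centreline velocity is exactly twice the mean.
#' @export
poiseuille_profile <- function(r, R, u_mean) {
  ifelse(r <= R, 2 * u_mean * (1 - (r / R)^2), 0)
}

#' Build the stationary blood velocity field
#'
#' LV cavity: axial (apex-directed) flow with a parabolic radial shape
#' scaled per z-slice to a constant volumetric flow equal to
#' `lv_mean_velocity` times the cavity cross-section at the
#' ablation-catheter level, tapered over the apical quarter where the flow
#' leaves through the outlet. IVC: fully developed axial profile obtained
#' from the cross-section Poisson problem (-Lap w = const, no-slip on wall
#' and return catheter), scaled to `ivc_flow_rate`; for an unobstructed
#' circular lumen this reproduces the Poiseuille profile.
#'
#' @param mesh classified mesh.
#' @param scenario a [flow_scenario()].
#' @return the scenario with `uz` (per-cell axial velocity, m/s; zero
#'   outside blood) and bookkeeping fields added.
#' @export
build_velocity_field <- function(mesh, scenario = flow_scenario("low")) {
  uz <- numeric(mesh$n_cells)
  p <- cell_centers(mesh)
  ijk <- cell_ijk(mesh, seq_len(mesh$n_cells))
  ax_area <- mesh$hx[ijk[, 1]] * mesh$hy[ijk[, 2]]

  # ---- LV cavity -------------------------------------------------------
  lv <- which(mesh$region == REGION["blood_lv"])
  if (length(lv)) {
    prm <- mesh$params
    a <- prm$lv_endo_semi_axes[1]; ce <- prm$lv_endo_semi_axes[3]
    z_apex <- -ce; z_base <- prm$basal_truncation_height
    z_cath <- if (!is.null(mesh$abl)) mesh$abl$endo_point[3] else
      (z_apex + z_base) / 2
    kk <- ijk[lv, 3]
    # reference flow: mean velocity times cavity area at the catheter level
    k_cath <- findInterval(z_cath, mesh$zs, all.inside = TRUE)
    A0 <- sum(ax_area[lv][kk == k_cath])
    if (A0 <= 0) A0 <- max(vapply(split(ax_area[lv], kk), sum, 0))
    Q0 <- scenario$lv_mean_velocity * A0
    z_out <- z_apex + 0.25 * (z_base - z_apex)   # distributed apical outlet
    for (k in unique(kk)) {
      sel <- lv[kk == k]
      z <- mesh$cz[k]
      Rz <- a * sqrt(max(1e-6, 1 - (z / ce)^2))
      shape <- pmax(0, 1 - (p[sel, 1]^2 + p[sel, 2]^2) / Rz^2)
      wsum <- sum(shape * ax_area[sel])
      if (wsum <= 0) next
      Qk <- Q0 * min(1, max(0, (z - z_apex) / (z_out - z_apex)))
      uz[sel] <- -shape * Qk / wsum
    }
  }

  # ---- IVC -------------------------------------------------------------
  ivc <- which(mesh$region == REGION["blood_ivc"])
  if (length(ivc)) {
    kk <- ijk[ivc, 3]
    kmid <- as.integer(stats::median(kk))
    foot <- ivc[kk == kmid]                 # lumen footprint at mid-span
    n <- length(foot)
    fi <- ijk[foot, 1]; fj <- ijk[foot, 2]
    key <- paste(fi, fj)
    idx <- seq_len(n)
    names(idx) <- key
    hx <- mesh$hx[fi]; hy <- mesh$hy[fj]
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    diag_acc <- numeric(n)
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      nb <- idx[paste(fi + d[1], fj + d[2])]
      coef <- 1 / (if (d[1] != 0) hx^2 else hy^2)
      has <- !is.na(nb)
      # neighbour in the lumen: standard 5-point coupling; otherwise the
      # face is a wall (no-slip, w = 0 at half-cell distance)
      diag_acc[has] <- diag_acc[has] + coef[has]
      diag_acc[!has] <- diag_acc[!has] + 2 * coef[!has]
      ii <- c(ii, idx[has]); jj <- c(jj, nb[has]); xx <- c(xx, -coef[has])
    }
    A <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                              x = c(xx, diag_acc), dims = c(n, n))
    w <- as.numeric(Matrix::solve(A, rep(1, n)))
    w <- pmax(w, 0)
    phi <- sum(w * ax_area[foot])
    scale <- scenario$ivc_flow_rate / phi
    # same cross-section applies along the straight cylinder
    wmap <- w * scale
    names(wmap) <- key
    uz[ivc] <- wmap[paste(ijk[ivc, 1], ijk[ivc, 2])]
    uz[ivc][is.na(uz[ivc])] <- 0
  }

  scenario$uz <- uz
  scenario
}

#' Thermal material properties per region
#'
#' Myocardium rho = 1081 kg/m^3, C = 3686 J/(kg K), k rising linearly 0.12%
#' per degC from 0.56 W/(m K); blood 1050 / 3617 / 0.52; bulk (connective)
#' tissue 1027 / 2372 / 0.39. Catheter body and electrode use generic
#' polymer / platinum values (generic catheter materials; they only
#' buffer heat locally).
#'
#' @param k_myo_0 myocardial conductivity at 37 degC.
#' @param k_myo_slope linear temperature coefficient (1/degC).
#' @return object of class `pfa_thermal_materials` with per-region vectors.
#' @export
thermal_materials <- function(k_myo_0 = 0.56, k_myo_slope = 0.0012) {
  m <- list(
    rho = c(myocardium = 1081, blood_lv = 1050, blood_ivc = 1050,
            bulk = 1027, catheter_body = 1100),
    C   = c(myocardium = 3686, blood_lv = 3617, blood_ivc = 3617,
            bulk = 2372, catheter_body = 1500),
    k0  = c(myocardium = k_myo_0, blood_lv = 0.52, blood_ivc = 0.52,
            bulk = 0.39, catheter_body = 0.25),
    k_electrode = 71, rho_electrode = 21450, C_electrode = 133,
    k_myo_slope = k_myo_slope)
  stopifnot(all(unlist(m[c("rho", "C", "k0")]) > 0))
  class(m) <- "pfa_thermal_materials"
  m
}

#' Pulse-train heating schedule
#'
#' `n_trains` ON windows of `train_on_duration`, separated by 2.5 s pauses
#' extended to 5 s after every 4th train; solver time steps at `base_dt`
#' with additional steps just before and after each train boundary.
#'
#' @param protocol a [pulse_protocol()].
#' @param base_dt base time step, s.
#' @param trailing time simulated after the last train, s.
#' @param on_substeps sub-steps inside each ON window.
#' @param eps event-step offset, s.
#' @return object of class `pfa_heat_schedule` with `events` (t_on, t_off)
#'   and the full `times` vector.
#' @export
build_schedule <- function(protocol, base_dt = 0.25, trailing = 5,
                           on_substeps = 4L, eps = 1e-3) {
  n <- protocol$n_trains
  t_on <- numeric(n); t_off <- numeric(n)
  t <- 0
  for (i in seq_len(n)) {
    t_on[i] <- t
    t_off[i] <- t + protocol$train_on_duration
    gap <- if (i %% 4 == 0) protocol$pause_every_4 else protocol$pause_between_trains
    t <- t_off[i] + gap
  }
  t_end <- t_off[n] + trailing
  times <- seq(0, t_end, by = base_dt)
  extra <- c(t_on, t_off, pmax(0, t_on - eps), pmin(t_end, t_off + eps))
  for (i in seq_len(n)) {
    if (on_substeps > 1)
      extra <- c(extra, seq(t_on[i], t_off[i], length.out = on_substeps + 1L))
  }
  times <- sort(unique(round(c(times, extra, t_end), 6)))
  s <- list(events = data.frame(t_on = round(t_on, 6), t_off = round(t_off, 6)),
            times = times, base_dt = base_dt, duty = protocol$duty,
            trailing = trailing)
  class(s) <- "pfa_heat_schedule"
  s
}

#' Transient pulsed-heating solve
#'
#' Advances the energy balance over the schedule on the thermally active
#' subdomain (heart + IVC bounding box plus `box_margin`). The Joule source
#' uses the field solution's per-cell `sigma * E^2`, gated by the schedule
#' and scaled by the duty factor; myocardial electrical conductivity carries
#' the exponential temperature factor, and the stationary field is re-solved
#' whenever the power-weighted temperature change implies a total-current
#' change above `refresh_tol` (evaluated at train starts).
#'
#' @param mesh classified mesh with catheters placed.
#' @param field a [solve_field()] result on the same mesh.
#' @param flow a [build_velocity_field()] result.
#' @param schedule a [build_schedule()] result.
#' @param materials a [thermal_materials()].
#' @param model the [conductivity_model()] used for the field.
#' @param frames fiber frames (needed for field refreshes).
#' @param protocol the [pulse_protocol()]; required for field refreshes.
#' @param probe_depths depths (m) below the tip-tissue interface, along the
#'   catheter axis, at which temperature traces are recorded.
#' @param box_margin margin of the thermally active box, m.
#' @param refresh_tol relative total-current change triggering a field
#'   re-solve.
#' @param T0 initial/inflow temperature, degC.
#' @param quiet suppress progress messages.
#' @return object of class `pfa_heat`: `times`, stored myocardial
#'   temperatures `T_store` (cells x times), `probes` (data.frame), per-cell
#'   running maxima, electrode-interface maxima and bookkeeping.
#' @export
solve_heat <- function(mesh, field, flow, schedule, materials = thermal_materials(),
                       model = conductivity_model(), frames = NULL,
                       protocol = NULL, probe_depths = c(1e-3, 3e-3, 7e-3),
                       box_margin = 0.012, refresh_tol = 0.01, T0 = 37,
                       quiet = TRUE) {
  p <- cell_centers(mesh)
  heart <- mesh$region != REGION["bulk"] | mesh$cavity_flag
  bb <- rbind(range(p[heart, 1]), range(p[heart, 2]), range(p[heart, 3]))
  act <- which(p[, 1] >= bb[1, 1] - box_margin & p[, 1] <= bb[1, 2] + box_margin &
               p[, 2] >= bb[2, 1] - box_margin & p[, 2] <= bb[2, 2] + box_margin &
               p[, 3] >= bb[3, 1] - box_margin & p[, 3] <= bb[3, 2] + box_margin)
  nA <- length(act)
  loc <- integer(mesh$n_cells); loc[act] <- seq_len(nA)
  reg <- mesh$region[act]
  regname <- names(REGION)[reg]
  vol <- cell_volumes(mesh, act)
  rho <- materials$rho[regname]
  Cp <- materials$C[regname]
  k0 <- materials$k0[regname]
  is_elec <- mesh$elec[act] > 0L
  rho[is_elec] <- materials$rho_electrode
  Cp[is_elec] <- materials$C_electrode
  k0[is_elec] <- materials$k_electrode
  mC <- rho * Cp * vol
  myo_loc <- which(reg == REGION["myocardium"])

  # ---- source term -----------------------------------------------------
  sigE2 <- function(fieldsol, Tcel) {
    fm <- match(act, fieldsol$cells)
    e2 <- rowSums(fieldsol$E_vec^2)[fm]
    # f_E lives on the myocardial subset of the field's cells; remap onto
    # the myocardial subset of the thermal box
    amyo <- act[mesh$region[act] == REGION["myocardium"]]
    fmyo <- fieldsol$cells[mesh$region[fieldsol$cells] == REGION["myocardium"]]
    fEv <- fieldsol$f_E[match(amyo, fmyo)]
    sig <- cell_sigma(mesh, act, frames, NULL,
                      fE = fEv, Tcel = Tcel, model = model)
    # scalar sigma in the field direction: E.(sigma E)/|E|^2
    ev <- fieldsol$E_vec[fm, , drop = FALSE]
    num <- sig[, 1] * ev[, 1]^2 + sig[, 2] * ev[, 2]^2 + sig[, 3] * ev[, 3]^2 +
      2 * (sig[, 4] * ev[, 1] * ev[, 2] + sig[, 5] * ev[, 1] * ev[, 3] +
           sig[, 6] * ev[, 2] * ev[, 3])
    q <- ifelse(is.na(fm) | e2 <= 0, 0, num)      # sigma_eff * E^2, W/m^3
    q[is.na(q)] <- 0
    q
  }

  # ---- diffusion operator ---------------------------------------------
  ijk <- cell_ijk(mesh, act)
  face_pairs <- function(axis) {
    nvec <- c(mesh$nx, mesh$ny, mesh$nz)
    stride <- c(1L, mesh$nx, mesh$nx * mesh$ny)[axis]
    sel <- which(ijk[, axis] < nvec[axis])
    nb <- act[sel] + stride
    ok <- nb <= mesh$n_cells & loc[nb] > 0L
    cbind(a = loc[act[sel[ok]]], b = loc[nb[ok]], axis = axis)
  }
  fp <- rbind(face_pairs(1L), face_pairs(2L), face_pairs(3L))
  hA <- cell_sizes(mesh, act)
  face_geom <- function(fpx) {
    a <- fpx[, 1]; b <- fpx[, 2]; axd <- fpx[, 3]
    A <- numeric(nrow(fpx)); da <- numeric(nrow(fpx)); db <- numeric(nrow(fpx))
    for (d in 1:3) {
      s <- axd == d
      oth <- setdiff(1:3, d)
      A[s] <- hA[a[s], oth[1]] * hA[a[s], oth[2]]
      da[s] <- hA[a[s], d] / 2; db[s] <- hA[b[s], d] / 2
    }
    list(A = A, da = da, db = db)
  }
  fg <- face_geom(fp)
  build_L <- function(kc) {
    g <- fg$A / (fg$da / kc[fp[, 1]] + fg$db / kc[fp[, 2]])
    Matrix::sparseMatrix(
      i = c(fp[, 1], fp[, 2], fp[, 1], fp[, 2]),
      j = c(fp[, 1], fp[, 2], fp[, 2], fp[, 1]),
      x = c(g, g, -g, -g), dims = c(nA, nA))
  }

  # ---- advection (upwind, z-direction flow) ---------------------------
  uz <- flow$uz[act]
  blood <- reg %in% REGION[c("blood_lv", "blood_ivc")]
  zfaces <- fp[fp[, 3] == 3L, , drop = FALSE]
  zA <- fg$A[fp[, 3] == 3L]
  bsel <- blood[zfaces[, 1]] | blood[zfaces[, 2]]
  zfaces <- zfaces[bsel, , drop = FALSE]; zA <- zA[bsel]
  Fz <- 0.5 * (uz[zfaces[, 1]] + uz[zfaces[, 2]]) * zA   # >0: a -> b (+z)
  # boundary inflow faces: blood cells whose upwind neighbour (w.r.t. local
  # velocity) is outside the active blood set carry inflow at T0
  up_of <- ifelse(Fz > 0, zfaces[, 1], zfaces[, 2])
  dn_of <- ifelse(Fz > 0, zfaces[, 2], zfaces[, 1])
  Fabs <- abs(Fz)
  keepf <- Fabs > 0
  up_of <- up_of[keepf]; dn_of <- dn_of[keepf]; Fabs <- Fabs[keepf]
  # inflow from outside the mesh top/bottom: handled via cells whose
  # vertical extent borders the inactive zone; approximate by fixing blood
  # cells at the LV base plane and IVC inlet to T0 during advection
  prm <- mesh$params
  inflow_cells <- which((reg == REGION["blood_lv"] &
                           abs(p[act, 3] - prm$basal_truncation_height) <
                             1.5 * hA[, 3]) |
                        (reg == REGION["blood_ivc"] &
                           p[act, 3] < prm$ivc_zlim[1] + 1.5 * hA[, 3]))
  infl_sum <- numeric(nA)
  if (length(Fabs)) {
    tmp <- tapply(Fabs, dn_of, sum)
    infl_sum[as.integer(names(tmp))] <- tmp
  }
  cfl_dt <- suppressWarnings(min(vol[infl_sum > 0] / infl_sum[infl_sum > 0]))
  if (!is.finite(cfl_dt)) cfl_dt <- Inf
  advect <- function(Tv, dt) {
    if (!is.finite(cfl_dt) || length(Fabs) == 0) return(Tv)
    nsub <- max(1L, ceiling(dt / (0.8 * cfl_dt)))
    dts <- dt / nsub
    for (s in seq_len(nsub)) {
      # advective (non-conservative) upwind form: each cell relaxes toward
      # its upwind donors; bounded even where the profile construction is
      # not exactly divergence-free
      agg <- rowsum(Fabs * (Tv[up_of] - Tv[dn_of]) * dts, dn_of)
      dT <- numeric(nA)
      dT[as.integer(rownames(agg))] <- agg[, 1]
      Tv <- Tv + dT / vol
      Tv[inflow_cells] <- T0
    }
    Tv
  }

  # ---- probes ----------------------------------------------------------
  if (is.null(mesh$abl)) stop("ablation catheter not placed")
  dvec <- mesh$abl$axis; front <- mesh$abl$tip_front
  probe_pts <- t(vapply(probe_depths, function(dd) front + dd * dvec,
                        numeric(3)))
  probe_w <- .interp_weights(mesh, probe_pts, loc)
  for (ip in seq_along(probe_depths)) {
    cl <- probe_w[[ip]]$cells
    rg <- mesh$region[act[cl[which.max(probe_w[[ip]]$w)]]]
    if (rg != REGION["myocardium"])
      stop(sprintf("probe at %.1f mm is outside the myocardium",
                   probe_depths[ip] * 1e3))
  }

  # electrode/blood interface cells
  abl_if <- which(blood & .adjacent_to(mesh, act, loc, mesh$elec == 1L))
  ret_if <- which(blood & .adjacent_to(mesh, act, loc, mesh$elec == 2L))

  # ---- time stepping ---------------------------------------------------
  times <- schedule$times
  nt <- length(times)
  Tv <- rep(T0, nA)
  T_store <- matrix(NA_real_, length(myo_loc), nt)
  T_store[, 1] <- T0
  probes <- matrix(T0, nt, length(probe_depths))
  maxT <- Tv
  kcur <- k0
  L <- build_L(kcur)
  T_at_L <- Tv
  q37 <- sigE2(field, NULL)
  T_at_refresh <- Tv
  refreshes <- 0L
  fstate <- field$state
  fld <- field
  on_iv <- cbind(schedule$events$t_on, schedule$events$t_off)
  pw <- q37 * vol; pw_sum <- sum(pw)
  myo_mask_loc <- reg == REGION["myocardium"]
  for (it in 2:nt) {
    t0 <- times[it - 1]; t1 <- times[it]; dt <- t1 - t0
    tm <- (t0 + t1) / 2
    on <- any(tm > on_iv[, 1] & tm < on_iv[, 2])
    is_train_start <- any(abs(t0 - on_iv[, 1]) < 1e-9)
    if (is_train_start && !is.null(frames) && !is.null(protocol)) {
      dI <- model$temp_coeff_sigma *
        sum(pw * (Tv - T_at_refresh)) / pw_sum
      if (abs(dI) > refresh_tol) {
        Tfull <- rep(T0, mesh$n_cells); Tfull[act] <- Tv
        fld <- solve_field(mesh, frames = frames, protocol = protocol,
                           model = model, Tcel = Tfull, state = fstate)
        q37 <- sigE2(fld, NULL)
        pw <- q37 * vol; pw_sum <- sum(pw)
        T_at_refresh <- Tv
        refreshes <- refreshes + 1L
        if (!quiet) message(sprintf("t=%.2f s: field refreshed (I = %.2f A)",
                                    t0, fld$total_current))
      }
    }
    # rebuild diffusion operator when myocardial k(T) has drifted
    if (max(abs(Tv - T_at_L)) > 2) {
      kcur <- k0
      kcur[myo_mask_loc] <- materials$k0["myocardium"] *
        (1 + materials$k_myo_slope * (Tv[myo_mask_loc] - 37))
      L <- build_L(kcur)
      T_at_L <- Tv
    }
    Tadv <- advect(Tv, dt)
    b <- mC / dt * Tadv
    if (on) {
      q <- q37
      fTm <- exp(model$temp_coeff_sigma * (Tv[myo_mask_loc] - 37))
      q[myo_mask_loc] <- q[myo_mask_loc] * fTm
      b <- b + schedule$duty * q * vol
    }
    A <- Matrix::Diagonal(x = mC / dt) + L
    Tv <- cg_solve(A, b, x0 = Tadv, tol = 1e-10, maxit = 2000L)$x
    maxT <- pmax(maxT, Tv)
    T_store[, it] <- Tv[myo_loc]
    for (ip in seq_along(probe_depths))
      probes[it, ip] <- sum(Tv[probe_w[[ip]]$cells] * probe_w[[ip]]$w)
    if (!quiet && it %% 50 == 0)
      message(sprintf("t = %.2f s / %.2f s, max T = %.2f degC",
                      t1, times[nt], max(Tv)))
  }
  out <- list(times = times, T_store = T_store,
              store_cells = act[myo_loc],
              probes = data.frame(depth_mm = rep(probe_depths * 1e3, each = nt),
                                  time_s = rep(times, length(probe_depths)),
                                  T_degC = as.vector(probes)),
              probe_depths = probe_depths,
              maxT = maxT, active_cells = act,
              abl_interface_maxT = if (length(abl_if)) max(maxT[abl_if]) else NA_real_,
              ret_interface_maxT = if (length(ret_if)) max(maxT[ret_if]) else NA_real_,
              field_refreshes = refreshes, final_field = fld,
              schedule = schedule, T0 = T0)
  class(out) <- "pfa_heat"
  out
}

#' @export
print.pfa_heat <- function(x, ...) {
  cat(sprintf("pfa_heat: %d steps over %.1f s, %d stored myocardial cells\n",
              length(x$times), max(x$times), nrow(x$T_store)))
  pk <- probe_max_temperatures(x)
  cat("  probe maxima:",
      paste(sprintf("%.0f mm: %.1f degC", pk$depth_mm, pk$max_T), collapse = ", "),
      "\n")
  cat(sprintf("  electrode/blood interface maxima: abl %.1f, return %.1f degC\n",
              x$abl_interface_maxT, x$ret_interface_maxT))
  invisible(x)
}

# trilinear interpolation weights from cell-centred values
.interp_weights <- function(mesh, pts, loc) {
  out <- vector("list", nrow(pts))
  for (r in seq_len(nrow(pts))) {
    w <- list(cells = integer(0), w = numeric(0))
    ix <- findInterval(pts[r, 1], mesh$cx); ix <- min(max(ix, 1L), mesh$nx - 1L)
    iy <- findInterval(pts[r, 2], mesh$cy); iy <- min(max(iy, 1L), mesh$ny - 1L)
    iz <- findInterval(pts[r, 3], mesh$cz); iz <- min(max(iz, 1L), mesh$nz - 1L)
    tx <- (pts[r, 1] - mesh$cx[ix]) / (mesh$cx[ix + 1] - mesh$cx[ix])
    ty <- (pts[r, 2] - mesh$cy[iy]) / (mesh$cy[iy + 1] - mesh$cy[iy])
    tz <- (pts[r, 3] - mesh$cz[iz]) / (mesh$cz[iz + 1] - mesh$cz[iz])
    tx <- min(max(tx, 0), 1); ty <- min(max(ty, 0), 1); tz <- min(max(tz, 0), 1)
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      e <- cell_index(mesh, ix + dx, iy + dy, iz + dz)
      wt <- (if (dx) tx else 1 - tx) * (if (dy) ty else 1 - ty) *
            (if (dz) tz else 1 - tz)
      le <- loc[e]
      if (le > 0L && wt > 0) {
        w$cells <- c(w$cells, le); w$w <- c(w$w, wt)
      }
    }
    w$w <- w$w / sum(w$w)
    out[[r]] <- w
  }
  out
}

# which active cells are face-adjacent to cells satisfying `mask` (global)
.adjacent_to <- function(mesh, act, loc, mask) {
  res <- logical(length(act))
  strides <- c(1L, mesh$nx, mesh$nx * mesh$ny)
  ijk <- cell_ijk(mesh, act)
  nvec <- c(mesh$nx, mesh$ny, mesh$nz)
  for (d in 1:3) {
    up_ok <- ijk[, d] < nvec[d]
    dn_ok <- ijk[, d] > 1L
    nb_up <- act + strides[d]
    nb_dn <- act - strides[d]
    res[up_ok] <- res[up_ok] | mask[nb_up[up_ok]]
    res[dn_ok] <- res[dn_ok] | mask[nb_dn[dn_ok]]
  }
  res
}

#' Thermal-dose damage volume
#'
#' Myocardial volume whose cumulative time at or above `T_thr` reaches
#' `t_thr`. Non-contiguous exceedance intervals accumulate (the conservative
#' reading of "reached 55 degC or more for 1 s or more").
#'
#' @param history a [solve_heat()] result.
#' @param mesh the mesh.
#' @param T_thr temperature threshold, degC.
#' @param t_thr required cumulative time, s.
#' @return volume, mm^3.
#' @export
thermal_dose_volume <- function(history, mesh, T_thr = 55, t_thr = 1) {
  dt <- diff(history$times)
  if (max(dt) > t_thr)
    stop(sprintf("stored step (%.2f s) exceeds the damage time (%.2f s)",
                 max(dt), t_thr), call. = FALSE)
  Tm <- history$T_store
  mid <- (Tm[, -1, drop = FALSE] + Tm[, -ncol(Tm), drop = FALSE]) / 2
  above <- mid >= T_thr
  ttime <- as.numeric(above %*% dt)
  sel <- ttime >= t_thr
  if (!any(sel)) return(0)
  sum(cell_volumes(mesh, history$store_cells[sel])) * 1e9
}

#' Arrhenius damage integral and volume
#'
#' `Omega(t) = integral A * exp(-deltaE / (R * T_K))` dt accumulated by the
#' trapezoidal rule over the stored history; damage volume is the myocardial
#' volume with `Omega >= 1` (cell-death probability >= 63%).
#'
#' @param history a [solve_heat()] result.
#' @param mesh the mesh.
#' @param A frequency factor, 1/s.
#' @param deltaE activation energy, J/mol.
#' @return list with `omega` (per stored cell), `arrhenius_volume_mm3`,
#'   `dose_volume_mm3` (55 degC / 1 s rule) and the constants.
#' @export
arrhenius_damage <- function(history, mesh, A = 2.94e39, deltaE = 2.596e5) {
  TK <- history$T_store + 273.15
  rate <- A * exp(-deltaE / (.R_GAS * TK))
  dt <- diff(history$times)
  mid <- (rate[, -1, drop = FALSE] + rate[, -ncol(rate), drop = FALSE]) / 2
  omega <- as.numeric(mid %*% dt)
  sel <- omega >= 1
  vol <- if (any(sel))
    sum(cell_volumes(mesh, history$store_cells[sel])) * 1e9 else 0
  list(omega = omega, arrhenius_volume_mm3 = vol,
       dose_volume_mm3 = thermal_dose_volume(history, mesh),
       A = A, deltaE = deltaE, R = .R_GAS)
}

#' Per-depth maximum probe temperatures
#'
#' @param history a [solve_heat()] result.
#' @param depths_mm optional subset of probe depths (mm).
#' @return data.frame `depth_mm`, `max_T` (degC).
#' @export
probe_max_temperatures <- function(history, depths_mm = NULL) {
  pr <- history$probes
  agg <- tapply(pr$T_degC, pr$depth_mm, max)
  out <- data.frame(depth_mm = as.numeric(names(agg)), max_T = as.numeric(agg))
  if (!is.null(depths_mm)) out <- out[out$depth_mm %in% depths_mm, , drop = FALSE]
  out[order(out$depth_mm), , drop = FALSE]
}
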