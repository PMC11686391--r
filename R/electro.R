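# Stationary nonlinear conduction model.
#
# Myocardial conductivity is anisotropic (0.5 S/m along fibers, anisotropy
# ratio 1.34) and field dependent: a smoothed-Heaviside factor f_E rises from
# 1 to EF = 2.65 across a 500 V/cm-wide transition centred at 550 V/cm,
# capturing the conductivity increase caused by membrane electroporation.
# Scar is isotropic 1 S/m and blended linearly via the scar function. The
# nonlinearity is resolved by under-relaxed Picard iteration on f_E.

#' Conductivity model parameters
#'
#' @param sigma_par conductivity along fibers, S/m.
#' @param anisotropy_ratio sigma_par / sigma_perp.
#' @param sigma_perp_override if non-NULL, use this perpendicular
#'   conductivity instead of `sigma_par / anisotropy_ratio` (the two differ
#'   in the third decimal; the formula is the default).
#' @param EF electroporation conductivity increase factor.
#' @param E_center,E_width centre and width of the f_E transition, V/cm.
#' @param sigma_blood,sigma_bulk,sigma_scar isotropic conductivities, S/m.
#' @param sigma_metal effective conductivity of electrode-metal cells in the
#'   immersed-electrode formulation (large enough to render the electrode
#'   equipotential; not a physical metal conductivity).
#' @param temp_coeff_sigma exponential temperature coefficient of myocardial
#'   conductivity, 1/degC.
#' @return object of class `pfa_conductivity_model`.
#' @export
conductivity_model <- function(sigma_par = 0.5, anisotropy_ratio = 1.34,
                               sigma_perp_override = NULL,
                               EF = 2.65, E_center = 550, E_width = 500,
                               sigma_blood = 0.7, sigma_bulk = 0.38,
                               sigma_scar = 1.0, temp_coeff_sigma = 0.015,
                               sigma_metal = 1e4) {
  stopifnot(sigma_par > 0, anisotropy_ratio > 0, EF >= 1, E_width > 0,
            sigma_blood > 0, sigma_bulk > 0, sigma_scar > 0, sigma_metal > 0)
  m <- as.list(environment())
  m$sigma_perp <- if (is.null(sigma_perp_override)) sigma_par / anisotropy_ratio
                  else sigma_perp_override
  class(m) <- "pfa_conductivity_model"
  m
}

#' Pulse protocol
#'
#' Voltage-controlled delivery of `n_trains` biphasic pulse trains. Each
#' train lasts `train_on_duration` during which Joule heating is gated on and
#' scaled by the waveform duty factor; trains are separated by 2.5 s pauses,
#' extended to 5 s after every 4th train.
#'
#' @param amplitude generator voltage (V); the electrode sees
#'   `amplitude * (1 - voltage_drop_fraction)` after the internal wire drop.
#' @param n_trains number of pulse trains.
#' @param voltage_drop_fraction catheter wire voltage drop (default 3%).
#' @param train_on_duration length of one train's ON window (s). The train
#'   of biphasic pulses lasts about 100 ms; the remainder of the ~2 s
#'   delivery window carries no current.
#' @param duty fraction of the ON window during which current actually flows
#'   (cumulative biphasic pulse time / ON window). The default 0.0042
#'   (~0.42 ms of active waveform per 100-ms train; ~200 J per 16-train
#'   application at 1500 V) is the generator's unprinted waveform parameter,
#'   calibrated once against the published depth-temperature maxima within
#'   the physically admissible range. Orders of magnitude more active time
#'   would deposit kilojoules and heat the near-electrode tissue by hundreds
#'   of kelvin.
#' @param pause_between_trains,pause_every_4 inter-train pauses (s).
#' @return object of class `pfa_pulse_protocol`.
#' @export
pulse_protocol <- function(amplitude = 1500, n_trains = 16,
                           voltage_drop_fraction = 0.03,
                           train_on_duration = 0.1, duty = 0.0042,
                           pause_between_trains = 2.5, pause_every_4 = 5.0) {
  stopifnot(amplitude > 0, n_trains >= 1, duty > 0, duty <= 1,
            train_on_duration > 0)
  p <- as.list(environment())
  class(p) <- "pfa_pulse_protocol"
  p
}

#' Scar field from a normalized intensity map
#'
#' Mirrors the late-gadolinium-enhancement convention: intensity below
#' `thr_low` is healthy (f_scar = 0), above `thr_high` dense scar
#' (f_scar = 1), linear in between (heterogeneous/border zone).
#'
#' @param intensity normalized intensity in `[0, 1]` per myocardial cell (or
#'   per mesh cell; non-myocardial entries are ignored).
#' @param thr_low,thr_high intensity thresholds (fractions of maximum).
#' @return object of class `pfa_scar_field` with `f_scar` per cell.
#' @export
scar_field <- function(intensity, thr_low = 0.40, thr_high = 0.60) {
  stopifnot(thr_high > thr_low)
  f <- (intensity - thr_low) / (thr_high - thr_low)
  f <- pmin(pmax(f, 0), 1)
  s <- list(f_scar = f, source_intensity = intensity,
            thr_low = thr_low, thr_high = thr_high)
  class(s) <- "pfa_scar_field"
  s
}

#' Electroporation conductivity factor
#'
#' Smoothed Heaviside with two continuous derivatives (quintic smoothstep)
#' rising from 1 to `EF` across `[E_center - E_width/2, E_center + E_width/2]`.
#'
#' @param E_mag field magnitude, V/cm.
#' @param model a [conductivity_model()].
#' @return dimensionless factor in `[1, EF]`.
#' @export
field_factor <- function(E_mag, model = conductivity_model()) {
  lo <- model$E_center - model$E_width / 2
  t <- (E_mag - lo) / model$E_width
  t <- pmin(pmax(t, 0), 1)
  s <- t * t * t * (t * (t * 6 - 15) + 10)
  1 + (model$EF - 1) * s
}

#' Local conductivity tensor
#'
#' Healthy myocardium: eigenvalue `sigma_par * f_E` along the fiber axis and
#' `sigma_perp * f_E` along sheet and sheet-normal, optionally multiplied by
#' `exp(temp_coeff_sigma * (T - 37))`. Scar blends in isotropically:
#' `sigma = f_scar * sigma_scar * I + (1 - f_scar) * sigma_healthy(E, T)`.
#'
#' @param e_fiber unit fiber direction (length-3).
#' @param E_mag field magnitude, V/cm.
#' @param f_scar scar blend weight in `[0, 1]`.
#' @param T_cel temperature in degC, or `NULL` for the isothermal model.
#' @param model a [conductivity_model()].
#' @return symmetric 3x3 conductivity tensor, S/m.
#' @export
sigma_tensor <- function(e_fiber, E_mag, f_scar = 0, T_cel = NULL,
                         model = conductivity_model()) {
  stopifnot(abs(sum(e_fiber^2) - 1) < 1e-6, f_scar >= 0, f_scar <= 1)
  fE <- field_factor(E_mag, model)
  fT <- if (is.null(T_cel)) 1 else exp(model$temp_coeff_sigma * (T_cel - 37))
  healthy <- fE * fT * (model$sigma_perp * diag(3) +
    (model$sigma_par - model$sigma_perp) * (e_fiber %o% e_fiber))
  f_scar * model$sigma_scar * diag(3) + (1 - f_scar) * healthy
}

# vectorised per-cell symmetric tensor components (xx, yy, zz, xy, xz, yz)
# for all conducting cells of a classified mesh.
#   frames: pfa_fiber_frame or NULL (myocardium treated as isotropic sigma_par)
#   fE:     per-myocardial-cell field factor (subset order = which(myo))
#   Tcel:   per-cell temperature or NULL
cell_sigma <- function(mesh, cells, frames = NULL, scar = NULL, fE = 1,
                       Tcel = NULL, model = conductivity_model()) {
  reg <- mesh$region[cells]
  n <- length(cells)
  sig <- matrix(0, n, 6)
  iso <- function(sel, val) {
    sig[sel, 1] <<- val; sig[sel, 2] <<- val; sig[sel, 3] <<- val
  }
  iso(reg == REGION["blood_lv"] | reg == REGION["blood_ivc"], model$sigma_blood)
  iso(reg == REGION["bulk"], model$sigma_bulk)
  if (!is.null(mesh$elec))
    iso(reg == REGION["catheter_body"] & mesh$elec[cells] > 0L, model$sigma_metal)
  myo <- reg == REGION["myocardium"]
  if (any(myo)) {
    mcells <- cells[myo]
    fT <- if (is.null(Tcel)) 1 else exp(model$temp_coeff_sigma * (Tcel[mcells] - 37))
    fEv <- rep_len(fE, sum(myo))
    sp <- model$sigma_perp; dpar <- model$sigma_par - model$sigma_perp
    if (is.null(frames)) {
      hxx <- hyy <- hzz <- fEv * fT * model$sigma_par
      hxy <- hxz <- hyz <- 0
    } else {
      idx <- match(mcells, frames$cells)
      f <- frames$e_fiber[idx, , drop = FALSE]
      # cells without a frame (degenerate transmural gradient in thin,
      # coarsely resolved wall) get the direction-averaged conductivity
      orphan <- is.na(idx)
      if (any(orphan)) {
        iso_val <- (model$sigma_par + 2 * model$sigma_perp) / 3
        f[orphan, ] <- 0
      }
      base <- fEv * fT
      hxx <- base * (sp + dpar * f[, 1]^2)
      hyy <- base * (sp + dpar * f[, 2]^2)
      hzz <- base * (sp + dpar * f[, 3]^2)
      hxy <- base * dpar * f[, 1] * f[, 2]
      hxz <- base * dpar * f[, 1] * f[, 3]
      hyz <- base * dpar * f[, 2] * f[, 3]
      if (any(orphan)) {
        hxx[orphan] <- hyy[orphan] <- hzz[orphan] <- base[orphan] * iso_val
      }
    }
    fs <- if (is.null(scar)) 0 else scar$f_scar[mcells]
    sig[myo, 1] <- fs * model$sigma_scar + (1 - fs) * hxx
    sig[myo, 2] <- fs * model$sigma_scar + (1 - fs) * hyy
    sig[myo, 3] <- fs * model$sigma_scar + (1 - fs) * hzz
    sig[myo, 4] <- (1 - fs) * hxy
    sig[myo, 5] <- (1 - fs) * hxz
    sig[myo, 6] <- (1 - fs) * hyz
  }
  sig
}

#' Solve the stationary nonlinear conduction problem
#'
#' Dirichlet potential `amplitude * (1 - voltage_drop_fraction)` on the
#' ablation-tip electrode surface, 0 V on the return-electrode bands,
#' zero-flux elsewhere. The field-dependent myocardial conductivity is
#' resolved by Picard iteration with under-relaxation 0.5 on the
#' electroporation factor, converged when the relative change in total
#' current drops below `tol`.
#'
#' @param mesh classified mesh with catheters placed.
#' @param frames optional fiber frames from [build_frames()]; if `NULL`, the
#'   myocardium is treated as isotropic at `sigma_par`.
#' @param scar optional [scar_field()].
#' @param protocol a [pulse_protocol()].
#' @param model a [conductivity_model()].
#' @param Tcel optional per-cell temperature (degC) entering the myocardial
#'   conductivity exponentially.
#' @param tol relative total-current convergence tolerance.
#' @param max_iter maximum Picard iterations.
#' @param relax under-relaxation factor on f_E.
#' @param state optional solver state from a previous call (warm start and
#'   reused symbolic factorization).
#' @param quiet suppress iteration messages.
#' @return object of class `pfa_field`: nodal potential `V`, per-cell field
#'   `E_vec` (V/m) and `E_mag_Vcm`, `total_current` (A), currents at both
#'   electrodes, iteration count and final residual. `cells` gives the
#'   conducting-cell index the per-cell arrays refer to.
#' @export
solve_field <- function(mesh, frames = NULL, scar = NULL,
                        protocol = pulse_protocol(), model = conductivity_model(),
                        Tcel = NULL, tol = 1e-3, max_iter = 50L, relax = 0.5,
                        state = NULL, quiet = TRUE) {
  immersed <- !is.null(mesh$params)
  an <- if (immersed) electrode_dirichlet_nodes(mesh, 1L) else electrode_nodes(mesh, 1L)
  rn <- if (immersed) electrode_dirichlet_nodes(mesh, 2L) else electrode_nodes(mesh, 2L)
  v_abl <- protocol$amplitude * (1 - protocol$voltage_drop_fraction)
  fixed <- c(an, rn)
  fixed_val <- c(rep(v_abl, length(an)), rep(0, length(rn)))
  cells <- which(mesh$region != REGION["catheter_body"] |
                   (if (immersed) mesh$elec > 0L else FALSE))
  myo <- mesh$region[cells] == REGION["myocardium"]
  active <- sort(unique(as.vector(cell_nodes(mesh, cells))))
  cache <- if (!is.null(state)) state else new.env()
  fE <- if (!is.null(cache$fE)) cache$fE else rep(1, sum(myo))
  I_prev <- NA_real_
  sol <- NULL; E <- NULL; Emag <- NULL
  iters <- 0L; res <- NA_real_
  repeat {
    iters <- iters + 1L
    sig <- cell_sigma(mesh, cells, frames, scar, fE, Tcel, model)
    K <- fem_stiffness(mesh, cells, sig)
    sol <- fem_solve_dirichlet(K, active, fixed, fixed_val, state = cache)
    I_abl <- sum(sol$residual[an])
    E <- -fem_gradient(mesh, cells, sol$V)
    Emag <- vm_to_vcm(sqrt(rowSums(E^2)))
    fE_new <- field_factor(Emag[myo], model)
    res <- if (is.na(I_prev)) Inf else abs(I_abl - I_prev) / abs(I_abl)
    if (!quiet) message(sprintf("picard %d: I = %.3f A, rel change %.2e",
                                iters, I_abl, res))
    if (res < tol || iters >= max_iter) break
    fE <- fE + relax * (fE_new - fE)
    I_prev <- I_abl
  }
  if (res >= tol)
    stop(sprintf("field solve did not converge: residual %.2e after %d iterations",
                 res, iters))
  cache$fE <- fE
  I_abl <- sum(sol$residual[an])
  I_ret <- sum(sol$residual[rn])
  out <- list(V = sol$V, E_vec = E, E_mag_Vcm = Emag, cells = cells,
              total_current = abs(I_abl), I_abl = I_abl, I_ret = I_ret,
              picard_iterations = iters, residual = res,
              f_E = fE, abl_nodes = an, ret_nodes = rn, state = cache,
              amplitude = protocol$amplitude, v_applied = v_abl)
  class(out) <- "pfa_field"
  out
}

#' @export
print.pfa_field <- function(x, ...) {
  cat(sprintf("pfa_field: %.0f V applied, I = %.2f A (%d Picard iterations)\n",
              x$v_applied, x$total_current, x$picard_iterations))
  cat(sprintf("  charge balance |I_abl + I_ret| / I = %.2e\n",
              abs(x$I_abl + x$I_ret) / abs(x$I_abl)))
  invisible(x)
}

#' Blood volume exposed to high field
#'
#' Instantaneous (single-train) blood-pool volumes with field magnitude above
#' each threshold, per blood region and total.
#'
#' @param solution a [solve_field()] result.
#' @param mesh the mesh it was computed on.
#' @param thresholds field thresholds, V/cm.
#' @return data.frame with columns `threshold_Vcm`, `lv_mm3`, `ivc_mm3`,
#'   `total_mm3`.
#' @export
blood_exposure_volumes <- function(solution, mesh, thresholds = c(1000, 1500)) {
  reg <- mesh$region[solution$cells]
  vol <- cell_volumes(mesh, solution$cells)
  lv <- reg == REGION["blood_lv"]
  ivc <- reg == REGION["blood_ivc"]
  out <- lapply(thresholds, function(thr) {
    sel <- solution$E_mag_Vcm >= thr
    c(lv = sum(vol[lv & sel]), ivc = sum(vol[ivc & sel]))
  })
  out <- do.call(rbind, out)
  data.frame(threshold_Vcm = thresholds,
             lv_mm3 = out[, "lv"] * 1e9,
             ivc_mm3 = out[, "ivc"] * 1e9,
             total_mm3 = (out[, "lv"] + out[, "ivc"]) * 1e9)
}
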