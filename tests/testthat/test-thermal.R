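# Pulsed heating: schedules, analytic flow profiles, energy accounting and
# the two damage metrics.

# all-myocardium cube with a fabricated field; the "catheter" is virtual
# (only probe geometry), heating comes from the prescribed E field.
thermal_fixture <- function(n = 8, L = 0.008, E_Vcm = 100) {
  m <- box_mesh(n, n, n, L)
  m$region <- rep.int(REGION["myocardium"], m$n_cells)
  m$elec <- integer(m$n_cells)
  m$rv_flag <- logical(m$n_cells)
  m$cavity_flag <- rep(TRUE, m$n_cells)   # exclude the box from inflow logic
  m$params <- geometry_params()
  m$abl <- list(segment_id = 8, endo_point = c(0, L / 2, L / 2),
                axis = c(1, 0, 0), tip_front = c(0, L / 2, L / 2),
                tip_cap_center = c(0, L / 2, L / 2),
                tip_back = c(0, L / 2, L / 2))
  sol <- fake_solution(m, seq_len(m$n_cells), rep(E_Vcm, m$n_cells))
  list(mesh = m, sol = sol)
}

still_flow <- function(mesh) {
  f <- flow_scenario("low")
  f$uz <- numeric(mesh$n_cells)
  f
}

test_that("schedules have the right train count, pauses and event steps", {
  s16 <- build_schedule(pulse_protocol(n_trains = 16))
  expect_equal(nrow(s16$events), 16)
  gaps <- s16$events$t_on[-1] - s16$events$t_off[-16]
  expect_equal(gaps[4], 5)                      # after every 4th train: 5 s
  expect_equal(gaps[1], 2.5)
  expect_equal(unique(round(gaps[-c(4, 8, 12)], 9)), 2.5)
  s1 <- build_schedule(pulse_protocol(n_trains = 1))
  expect_equal(nrow(s1$events), 1)
  expect_true(all(diff(s1$times) > 0))
  expect_true(all(s16$events$t_on %in% s16$times))
  expect_true(all(s16$events$t_off %in% s16$times))
})

test_that("Poiseuille profile has an exactly 2x peak-to-mean ratio", {
  R <- 0.005; um <- 0.03
  expect_equal(poiseuille_profile(0, R, um), 2 * um)
  r <- seq(0, R, length.out = 2000)
  u_mean <- sum(poiseuille_profile(r, R, um) * 2 * pi * r) /
    sum(2 * pi * r)
  expect_lt(abs(u_mean / um - 1), 1e-3)
  expect_equal(poiseuille_profile(1.1 * R, R, um), 0)
})

test_that("channel fluxes match the prescribed flow rates", {
  p <- geometry_params(lv_endo_semi_axes = c(0.012, 0.012, 0.020),
                       lv_epi_semi_axes = c(0.017, 0.017, 0.025),
                       rv_on = FALSE, ivc_center_xy = c(0.030, 0),
                       ivc_radius = 0.005, ivc_zlim = c(-0.02, 0.024))
  g <- list(xs = seq(-0.018, 0.038, by = 1.25e-3),
            ys = seq(-0.018, 0.018, by = 1.25e-3),
            zs = seq(-0.026, 0.026, by = 1.25e-3))
  mesh <- build_domain(p, grid = g)
  sc <- flow_scenario("low", lv_mean_velocity = 0.03, ivc_flow_rate = 5e-6)
  fl <- build_velocity_field(mesh, sc)
  # IVC: integrated flux through the mid cross-section equals the set flow
  ivc <- which(mesh$region == REGION["blood_ivc"])
  ijk <- cell_ijk(mesh, ivc)
  kmid <- as.integer(stats::median(ijk[, 3]))
  sel <- ivc[ijk[, 3] == kmid]
  ar <- cell_sizes(mesh, sel)
  expect_lt(abs(sum(fl$uz[sel] * ar[, 1] * ar[, 2]) / 5e-6 - 1), 0.01)
  # LV: slice-average speed at the reference level equals the set mean
  lv <- which(mesh$region == REGION["blood_lv"])
  ijk_lv <- cell_ijk(mesh, lv)
  k0 <- findInterval(-0.005, mesh$zs)
  sel_lv <- lv[ijk_lv[, 3] == k0]
  arl <- cell_sizes(mesh, sel_lv)
  u_mean <- sum(abs(fl$uz[sel_lv]) * arl[, 1] * arl[, 2]) /
    sum(arl[, 1] * arl[, 2])
  expect_lt(abs(u_mean / 0.03 - 1), 0.05)
  # no-slip: zero outside blood
  expect_true(all(fl$uz[mesh$region == REGION["bulk"]] == 0))
})

test_that("a source-free run stays at body temperature", {
  fx <- thermal_fixture(E_Vcm = 0)
  sch <- build_schedule(pulse_protocol(n_trains = 2), trailing = 1)
  h <- solve_heat(fx$mesh, fx$sol, still_flow(fx$mesh), sch,
                  probe_depths = c(1e-3, 3e-3))
  expect_lt(max(abs(h$T_store - 37)), 1e-8)
  pk <- probe_max_temperatures(h)
  expect_equal(pk$max_T, c(37, 37), tolerance = 1e-8)
})

test_that("insulated uniform heating matches the lumped closed form", {
  fx <- thermal_fixture(E_Vcm = 100)
  prot <- pulse_protocol(n_trains = 1, train_on_duration = 1, duty = 1)
  sch <- build_schedule(prot, trailing = 0.5)
  h <- solve_heat(fx$mesh, fx$sol, still_flow(fx$mesh), sch,
                  model = conductivity_model(temp_coeff_sigma = 1e-12))
  q <- 0.5 * vcm_to_vm(100)^2                  # sigma_par * E^2, W/m^3
  dT_exact <- q * 1 / (1081 * 3686)
  i_end <- which.min(abs(h$times - 1))
  expect_lt(max(abs((h$T_store[, i_end] - 37) / dT_exact - 1)), 0.01)
})

test_that("total enthalpy rise equals the time-integrated source power", {
  fx <- thermal_fixture(n = 10)
  # non-uniform field decaying from one face
  x <- cell_centers(fx$mesh)[, 1]
  E <- 300 * exp(-x / 0.002)
  sol <- fake_solution(fx$mesh, seq_len(fx$mesh$n_cells), E)
  prot <- pulse_protocol(n_trains = 2, train_on_duration = 0.5, duty = 0.5)
  sch <- build_schedule(prot, trailing = 0.5)
  h <- solve_heat(fx$mesh, sol, still_flow(fx$mesh), sch,
                  model = conductivity_model(temp_coeff_sigma = 1e-12))
  vol <- cell_volumes(fx$mesh)
  mC <- 1081 * 3686 * vol
  enthalpy <- sum(mC * (h$T_store[, ncol(h$T_store)] - 37))
  q <- 0.5 * vcm_to_vm(E)^2
  energy_in <- sum(q * vol) * 0.5 * 0.5 * 2    # duty * t_on * n_trains
  expect_lt(abs(enthalpy / energy_in - 1), 0.02)
  # deeper probes never exceed shallower maxima for near-face heating
  pk <- probe_max_temperatures(h)
  expect_true(all(diff(pk$max_T) <= 1e-9))
})

test_that("thermal dose accumulates non-contiguous exceedance time", {
  m <- box_mesh(2, 1, 1, 0.002, 0.001, 0.001)
  m$region <- rep.int(REGION["myocardium"], m$n_cells)
  times <- seq(0, 2, by = 0.1)
  mk <- function(trace) {
    structure(list(times = times,
                   T_store = matrix(trace, 1, length(times), byrow = TRUE),
                   store_cells = 1L),
              class = "pfa_heat")
  }
  # 55.5 for 0.5 s, dip to 54, then 55.5 for 0.6 s: cumulative 1.1 s counts
  tr <- rep(37, length(times))
  tr[times >= 0.2 & times <= 0.7] <- 55.5
  tr[times >= 1.2 & times <= 1.8] <- 55.5
  expect_gt(thermal_dose_volume(mk(tr), m), 0)
  # uniform 56 held 2 s: qualifies; uniform 54: never
  expect_equal(thermal_dose_volume(mk(rep(56, length(times))), m),
               cell_volumes(m)[1] * 1e9, tolerance = 1e-9)
  expect_equal(thermal_dose_volume(mk(rep(54, length(times))), m), 0)
  # a single 0.5-s excursion does not reach the 1-s dose
  tr2 <- rep(37, length(times)); tr2[times >= 0.5 & times <= 1.0] <- 55.5
  expect_equal(thermal_dose_volume(mk(tr2), m), 0)
  # stored step coarser than the damage time is refused
  bad <- structure(list(times = c(0, 2, 4),
                        T_store = matrix(56, 1, 3), store_cells = 1L),
                   class = "pfa_heat")
  expect_error(thermal_dose_volume(bad, m), "step")
})

test_that("Arrhenius integral matches its closed form", {
  m <- box_mesh(1, 1, 1, 0.001)
  m$region <- REGION[["myocardium"]]
  A <- 2.94e39; dE <- 2.596e5; R <- 8.314
  mk <- function(Tc, t_end, n = 201) {
    structure(list(times = seq(0, t_end, length.out = n),
                   T_store = matrix(Tc, 1, n), store_cells = 1L),
              class = "pfa_heat")
  }
  # constant temperature: Omega = A t exp(-dE / (R T_K))
  for (Tc in c(50, 55, 60)) {
    h <- mk(Tc, 10)
    om <- arrhenius_damage(h, m)$omega
    expect_equal(om, A * 10 * exp(-dE / (R * (Tc + 273.15))),
                 tolerance = 1e-10)
  }
  # time to Omega = 1 at 55 degC, from the closed form, flags the volume
  t1 <- 1 / (A * exp(-dE / (R * 328.15)))
  d_lo <- arrhenius_damage(mk(55, 0.95 * t1), m)
  d_hi <- arrhenius_damage(mk(55, 1.05 * t1), m)
  expect_equal(d_lo$arrhenius_volume_mm3, 0)
  expect_gt(d_hi$arrhenius_volume_mm3, 0)
  # body temperature: negligible damage over clinical times
  expect_lt(arrhenius_damage(mk(37, 120), m)$omega, 1e-2)
  # Omega is nondecreasing along any trace
  tr <- structure(list(times = seq(0, 10, by = 0.1),
                       T_store = matrix(37 + 25 * sin(seq(0, 10, by = 0.1)),
                                        1, 101),
                       store_cells = 1L), class = "pfa_heat")
  rate <- 2.94e39 * exp(-2.596e5 / (8.314 * (tr$T_store + 273.15)))
  expect_true(all(rate >= 0))
})
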