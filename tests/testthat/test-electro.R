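# Nonlinear conduction model: the electroporation factor, conductivity
# tensors, the Picard solve against closed-form conductors, and exposure
# accounting.

test_that("electroporation factor has the smoothed-Heaviside shape", {
  m <- conductivity_model()
  expect_equal(field_factor(0, m), 1)
  expect_equal(field_factor(2000, m), 2.65)
  expect_equal(field_factor(550, m), (1 + 2.65) / 2)   # centre symmetry
  expect_equal(field_factor(300, m), 1)                 # at the lower edge
  expect_equal(field_factor(800, m), 2.65)              # at the upper edge
  E <- seq(0, 2000, by = 5)
  expect_true(all(diff(field_factor(E, m)) >= 0))
})

test_that("conductivity tensor eigenvalues follow fiber, scar and temperature", {
  m <- conductivity_model()
  ef <- c(1, 0, 0)
  s0 <- sigma_tensor(ef, E_mag = 0, model = m)
  expect_equal(sort(eigen(s0)$values), sort(c(0.5, rep(0.5 / 1.34, 2))),
               tolerance = 1e-12)
  # dense scar: isotropic 1 S/m regardless of field
  s1 <- sigma_tensor(ef, E_mag = 1200, f_scar = 1, model = m)
  expect_equal(s1, diag(3), tolerance = 1e-12)
  # 37 degC is the identity temperature
  expect_equal(sigma_tensor(ef, 0, T_cel = 37, model = m), s0,
               tolerance = 1e-12)
  # 10 degC above body: exp(0.15) on the healthy part
  s2 <- sigma_tensor(ef, 0, T_cel = 47, model = m)
  expect_equal(s2, s0 * exp(0.15), tolerance = 1e-12)
  # printed-value override for the perpendicular conductivity
  m375 <- conductivity_model(sigma_perp_override = 0.375)
  expect_equal(m375$sigma_perp, 0.375)
  expect_error(sigma_tensor(c(1, 1, 0), 0, model = m))   # not a unit vector
})

test_that("parallel-plate conduction is uniform and matches the closed form", {
  m <- plate_mesh(interior = "bulk")
  model <- conductivity_model(sigma_bulk = 0.38)
  prot <- pulse_protocol(amplitude = 100, voltage_drop_fraction = 0)
  sol <- solve_field(m, protocol = prot, model = model)
  d <- m$gap
  E_exp <- vm_to_vcm(100 / d)
  inner <- m$region[sol$cells] != REGION["catheter_body"]
  expect_lt(max(abs(sol$E_mag_Vcm[inner] / E_exp - 1)), 0.01)
  A <- diff(range(m$ys)) * diff(range(m$zs))
  expect_lt(abs(sol$total_current / (0.38 * 100 / d * A) - 1), 0.01)
  expect_lt(abs(sol$I_abl + sol$I_ret) / abs(sol$I_abl), 0.005)
})

test_that("field-dependent slab matches the 1-D fixed-point oracle", {
  # choose the voltage so E sits inside the transition region
  m <- plate_mesh(interior = "myocardium")
  model <- conductivity_model()
  d <- m$gap
  V0 <- 550 * 100 * d          # E = 550 V/cm, the transition centre
  prot <- pulse_protocol(amplitude = V0, voltage_drop_fraction = 0)
  sol <- solve_field(m, protocol = prot, model = model)
  # 1-D oracle: uniform E = V0/d; sigma = sigma_par * f_E(E); I = sigma E A
  E_or <- V0 / d
  sig_or <- model$sigma_par * field_factor(vm_to_vcm(E_or), model)
  A <- diff(range(m$ys)) * diff(range(m$zs))
  expect_lt(abs(sol$total_current / (sig_or * E_or * A) - 1), 0.01)
  inner <- m$region[sol$cells] == REGION["myocardium"]
  expect_lt(max(abs(sol$E_mag_Vcm[inner] / vm_to_vcm(E_or) - 1)), 0.01)
})

test_that("with the field factor frozen the solve is linear in amplitude", {
  m <- plate_mesh(interior = "myocardium")
  model <- conductivity_model(EF = 1)     # freeze sigma(E)
  s1 <- solve_field(m, protocol = pulse_protocol(amplitude = 500,
                                                 voltage_drop_fraction = 0),
                    model = model)
  s2 <- solve_field(m, protocol = pulse_protocol(amplitude = 1000,
                                                 voltage_drop_fraction = 0),
                    model = model)
  expect_equal(s2$total_current, 2 * s1$total_current, tolerance = 1e-6)
  expect_equal(s2$E_mag_Vcm, 2 * s1$E_mag_Vcm, tolerance = 1e-6)
})

test_that("with sigma(E) active the current grows superlinearly in amplitude", {
  m <- plate_mesh(interior = "myocardium")
  model <- conductivity_model()
  d <- m$gap
  amps <- c(0.6, 1, 1.4) * 550 * 100 * d   # across the transition
  I <- vapply(amps, function(a)
    solve_field(m, protocol = pulse_protocol(amplitude = a,
                                             voltage_drop_fraction = 0),
                model = model)$total_current, 0)
  expect_true(all(diff(I) > 0))
  expect_gt(I[3] / I[1], amps[3] / amps[1])   # superlinear through transition
})

test_that("a conductive scar layer carries lower field than its neighbours", {
  # series conductors: J equal, E inversely proportional to sigma
  m <- plate_mesh(nx = 18, interior = "myocardium")
  x <- cell_centers(m)[, 1]
  L <- max(m$xs)
  intensity <- ifelse(x > 0.4 * L & x < 0.6 * L, 0.9, 0)  # dense mid layer
  scar <- scar_field(intensity)
  prot <- pulse_protocol(amplitude = 50, voltage_drop_fraction = 0)
  sol <- solve_field(m, scar = scar, protocol = prot)
  myo <- m$region[sol$cells] == REGION["myocardium"]
  in_scar <- scar$f_scar[sol$cells] == 1 & myo
  healthy <- scar$f_scar[sol$cells] == 0 & myo
  expect_lt(mean(sol$E_mag_Vcm[in_scar]), mean(sol$E_mag_Vcm[healthy]))
  # ratio matches the conductivity ratio (1.0 vs 0.5 S/m at low field)
  expect_lt(abs(mean(sol$E_mag_Vcm[in_scar]) /
                mean(sol$E_mag_Vcm[healthy]) - 0.5), 0.05)
})

test_that("scar field thresholds produce the three-zone blend", {
  s <- scar_field(c(0.1, 0.4, 0.5, 0.6, 0.9))
  expect_equal(s$f_scar, c(0, 0, 0.5, 1, 1))
  expect_true(all(s$f_scar >= 0 & s$f_scar <= 1))
})

test_that("blood exposure volumes are monotone and bounded", {
  m <- box_mesh(4, 4, 4, 0.004)
  m$region <- rep.int(REGION["blood_lv"], m$n_cells)
  m$region[1:16] <- REGION["blood_ivc"]
  E <- seq(100, 2500, length.out = m$n_cells)
  sol <- fake_solution(m, seq_len(m$n_cells), E)
  be <- blood_exposure_volumes(sol, m, thresholds = c(0, 500, 1000, 3000))
  expect_equal(be$total_mm3[1], sum(cell_volumes(m)) * 1e9, tolerance = 1e-9)
  expect_equal(be$total_mm3[4], 0)
  expect_true(all(diff(be$total_mm3) <= 0))
  expect_equal(be$total_mm3, be$lv_mm3 + be$ivc_mm3, tolerance = 1e-9)
})
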