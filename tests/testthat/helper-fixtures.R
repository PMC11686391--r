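# Shared fixtures. Everything is built in code; the heavier coarse-domain
# study is computed once per test run and cached.

# uniform tensor mesh over a box (metres)
box_mesh <- function(nx, ny, nz, Lx, Ly = Lx, Lz = Lx, origin = c(0, 0, 0)) {
  tensor_mesh(seq(origin[1], origin[1] + Lx, length.out = nx + 1),
              seq(origin[2], origin[2] + Ly, length.out = ny + 1),
              seq(origin[3], origin[3] + Lz, length.out = nz + 1))
}

# parallel-plate conduction fixture: catheter-body layers at the x-extremes
# act as the two electrodes, the interior is a single region.
plate_mesh <- function(nx = 12, ny = 6, nz = 6, L = 0.02,
                       interior = "bulk") {
  m <- box_mesh(nx, ny, nz, L, L * ny / nx, L * nz / nx)
  ijk <- cell_ijk(m, seq_len(m$n_cells))
  m$region <- rep.int(REGION[[interior]], m$n_cells)
  m$elec <- integer(m$n_cells)
  m$region[ijk[, 1] == 1L] <- REGION["catheter_body"]
  m$elec[ijk[, 1] == 1L] <- 1L
  m$region[ijk[, 1] == nx] <- REGION["catheter_body"]
  m$elec[ijk[, 1] == nx] <- 2L
  m$gap <- m$xs[nx] - m$xs[2]       # electrode separation
  m
}

# myocardial slab with blood on one x-face (endocardium) and bulk on the
# other (epicardium); params attached so surface tagging works.
slab_mesh <- function(nx = 22, ny = 6, nz = 6, L = 0.01) {
  m <- box_mesh(nx, ny, nz, L, L * ny / nx, L * nz / nx)
  ijk <- cell_ijk(m, seq_len(m$n_cells))
  m$region <- rep.int(REGION["myocardium"], m$n_cells)
  m$region[ijk[, 1] == 1L] <- REGION["blood_lv"]
  m$region[ijk[, 1] == nx] <- REGION["bulk"]
  m$elec <- integer(m$n_cells)
  m$rv_flag <- logical(m$n_cells)
  m$cavity_flag <- logical(m$n_cells)
  m$params <- geometry_params()
  m$wall_x <- c(m$xs[2], m$xs[nx])  # endo and epi plane positions
  m
}

# spherical-shell patch as a mapped mesh; returns mesh + boundary node sets
# and the patch solid angle
sphere_patch <- function(r1, r2, nr = 24, nt = 8, np = 8,
                         theta_deg = c(50, 90), phi_deg = c(0, 40)) {
  rs <- exp(seq(log(r1), log(r2), length.out = nr + 1))
  ts <- seq(theta_deg[1], theta_deg[2], length.out = nt + 1) * pi / 180
  ps <- seq(phi_deg[1], phi_deg[2], length.out = np + 1) * pi / 180
  g <- expand.grid(r = rs, t = ts, p = ps)
  xyz <- cbind(g$r * sin(g$t) * cos(g$p), g$r * sin(g$t) * sin(g$p),
               g$r * cos(g$t))
  m <- mapped_mesh(xyz, nr, nt, np)
  nid <- array(seq_len(m$n_nodes), c(nr + 1, nt + 1, np + 1))
  list(mesh = m, inner = as.vector(nid[1, , ]),
       outer = as.vector(nid[nr + 1, , ]),
       solid_angle = (cos(theta_deg[1] * pi / 180) -
                      cos(theta_deg[2] * pi / 180)) *
         diff(phi_deg) * pi / 180)
}

# fabricated field solution over an explicit cell set (for volume accounting
# and inversion tests that need a controllable E field)
fake_solution <- function(mesh, cells, E_mag_Vcm) {
  structure(list(cells = cells, E_mag_Vcm = E_mag_Vcm,
                 E_vec = cbind(vcm_to_vm(E_mag_Vcm), 0, 0),
                 f_E = rep(1, sum(mesh$region[cells] == REGION["myocardium"])),
                 total_current = NA_real_),
            class = "pfa_field")
}

# the coarse end-to-end LET study is expensive; compute once per run
.fixture_env <- new.env()
coarse_let_study <- function() {
  if (is.null(.fixture_env$let)) {
    .fixture_env$let <- suppressWarnings(run_let_study(
      params = coarse_geometry_params(),
      doses = data.frame(amplitude = 1500, n_trains = 16),
      true_let = 450, lesions_per_dose = 12, sigma_log = 0.15, seed = 42))
  }
  .fixture_env$let
}
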