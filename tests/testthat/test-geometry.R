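# Domain construction: analytic shell volumes, the 13-segment partition and
# catheter placement geometry.

# small test heart with a uniform grid over the shell's bounding box
test_params <- function(...) {
  geometry_params(lv_endo_semi_axes = c(0.012, 0.012, 0.020),
                  lv_epi_semi_axes = c(0.017, 0.017, 0.025),
                  rv_on = FALSE, ivc_center_xy = c(0.030, 0),
                  ivc_radius = 0.005, ivc_zlim = c(-0.02, 0.03), ...)
}

uniform_grid <- function(h, lim = 0.018, zlim = c(-0.026, 0.026)) {
  list(xs = seq(-lim, lim, by = h), ys = seq(-lim, lim, by = h),
       zs = seq(zlim[1], zlim[2], by = h))
}

test_that("untruncated shells match the analytic ellipsoid-shell volume", {
  p <- test_params(basal_truncation_height = 0.026)  # above the shell: no cut
  mesh <- build_domain(p, grid = uniform_grid(0.8e-3))
  v_num <- region_volume(mesh, "myocardium")
  v_exact <- 4 / 3 * pi * (prod(p$lv_epi_semi_axes) - prod(p$lv_endo_semi_axes))
  expect_lt(abs(v_num / v_exact - 1), 0.02)
  v_cav <- region_volume(mesh, "blood_lv")
  expect_lt(abs(v_cav / (4 / 3 * pi * prod(p$lv_endo_semi_axes)) - 1), 0.02)
})

test_that("truncation at the centre halves the shell volume", {
  p_half <- test_params(basal_truncation_height = 0)
  g <- uniform_grid(0.7e-3)
  v_half <- region_volume(build_domain(p_half, grid = g), "myocardium")
  v_exact <- 2 / 3 * pi * (prod(p_half$lv_epi_semi_axes) -
                           prod(p_half$lv_endo_semi_axes))
  expect_lt(abs(v_half / v_exact - 1), 0.02)
})

test_that("volumes converge under 2x refinement and regions partition the box", {
  p <- test_params(basal_truncation_height = 0.026)
  v1 <- region_volume(build_domain(p, grid = uniform_grid(1.6e-3)), "myocardium")
  v2 <- region_volume(build_domain(p, grid = uniform_grid(0.8e-3)), "myocardium")
  expect_lt(abs(v1 / v2 - 1), 0.02)
  mesh <- build_domain(p, grid = uniform_grid(1.6e-3))
  total <- sum(vapply(names(REGION), function(r) region_volume(mesh, r), 0))
  box <- diff(range(mesh$xs)) * diff(range(mesh$ys)) * diff(range(mesh$zs))
  expect_equal(total, box, tolerance = 1e-10)
})

test_that("degenerate or non-positive geometry is rejected", {
  expect_error(geometry_params(lv_epi_semi_axes = c(0.019, 0.019, 0.041)),
               "epicardial")
  expect_error(geometry_params(ivc_radius = -1), "positive")
  expect_error(geometry_params(indentation_depth = 0.02), "indentation")
})

test_that("segment labelling is a 13-part partition of the LV myocardium", {
  p <- test_params()
  mesh <- assign_segments(build_domain(p, grid = uniform_grid(0.8e-3)))
  myo <- mesh$region == REGION["myocardium"] & !mesh$rv_flag
  seg <- mesh$segment_id[myo]
  expect_setequal(unique(seg), 1:13)
  expect_true(all(mesh$segment_id[!myo] == 0L))
  v_seg <- sum(cell_volumes(mesh, which(mesh$segment_id > 0)))
  expect_equal(v_seg, region_volume(mesh, "myocardium"), tolerance = 1e-10)
  # a mid-height anterior-wall point carries the (mid, anterior) label
  zb <- segment_z_bounds(p)
  z_mid <- mean(c(zb["z2"], zb["z1"]))
  pt <- c(0, (p$lv_endo_semi_axes[2] + p$lv_epi_semi_axes[2]) / 2 *
            sqrt(1 - (z_mid / p$lv_endo_semi_axes[3])^2), z_mid)
  i <- findInterval(pt[1], mesh$xs); j <- findInterval(pt[2], mesh$ys)
  k <- findInterval(pt[3], mesh$zs)
  expect_equal(mesh$segment_id[cell_index(mesh, i, j, k)], 5L)  # 4*1 + 1
})

test_that("catheter axis follows the surface normal and placement is idempotent", {
  p <- test_params(mesh_resolution = 0.8e-3)
  mesh <- assign_segments(build_domain(p, grid = uniform_grid(0.8e-3)))
  m1 <- place_catheter(mesh, 8)
  # analytic outward normal at the mid-posterior site
  site <- segment_site(p, 8)
  ang <- acos(abs(sum(m1$abl$axis * site$normal))) * 180 / pi
  expect_lt(ang, 2)
  # apical-cap placement aligns with the long axis
  m13 <- place_catheter(mesh, 13)
  expect_lt(acos(abs(m13$abl$axis[3])) * 180 / pi, 2)
  # idempotency: placing twice gives identical classification
  m2 <- place_catheter(m1, 8)
  expect_identical(m1$region, m2$region)
  expect_identical(m1$elec, m2$elec)
  # tip front sits indentation_depth beyond the endocardial surface
  f <- m1$abl$tip_front
  r_ell <- sqrt(sum((f / p$lv_endo_semi_axes)^2))
  expect_gt(r_ell, 1)   # outside the cavity, i.e. inside the wall
  d_surf <- sqrt(sum((f - m1$abl$endo_point)^2))
  expect_lt(abs(d_surf - p$indentation_depth), 1e-9)
  expect_error(place_catheter(mesh, 14))
})

test_that("return electrodes form bands and surfaces carry consistent tags", {
  p <- test_params()
  g <- list(xs = seq(-0.018, 0.038, by = 1e-3),
            ys = seq(-0.018, 0.018, by = 1e-3),
            zs = seq(-0.026, 0.026, by = 1e-3))
  mesh <- build_domain(p, grid = g)
  expect_gt(sum(mesh$elec == 2L), 0)
  # distinct z-clusters of electrode cells = number of bands resolvable
  zc <- sort(unique(round(cell_centers(mesh, which(mesh$elec == 2L))[, 3], 6)))
  expect_gte(length(zc), 2)
  surf <- myocardial_surfaces(mesh)
  expect_gt(nrow(surf$endo$nodes), 0)
  expect_gt(nrow(surf$epi$nodes), 0)
  # endo faces touch blood, epi faces touch bulk
  expect_true(all(mesh$region[surf$endo$cellsA] == REGION["myocardium"]))
  expect_true(all(mesh$region[surf$epi$cellsA] == REGION["myocardium"]))
  # base faces lie in the truncation plane
  if (!is.null(surf$base) && nrow(surf$base$centers) > 0)
    expect_true(all(abs(surf$base$centers[, 3] - p$basal_truncation_height) < 1e-9))
})
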