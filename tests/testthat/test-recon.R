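test_that("a zero sinogram reconstructs to zero attenuation", {
  g <- make_geometry("VCT40", scale = 0.1)
  ph <- water_phantom()
  prot <- scan_protocol("axial_full", views_per_rotation = 48L)
  sino <- simulate_scan(g, ph, prot, quiet_flux())
  sino$projections[] <- 0
  grid <- recon_grid(32L, fov = 500, slice_z = 0, slice_thickness = 2)
  vol <- reconstruct(sino, grid)
  expect_equal(max(abs(vol$data + 1000)), 0, tolerance = 1e-9) # mu = 0
})

test_that("water and air calibrate on full, half and helical scans", {
  ph <- water_phantom(radius = 150)
  grid <- recon_grid(96L, fov = 500, slice_z = 0, slice_thickness = 2)
  water <- roi_mask(grid, radius = 40)
  air <- roi_mask(grid, radius = 245) & !roi_mask(grid, radius = 175)
  off <- roi_mask(grid, center = c(60, -40), radius = 20)
  for (nm in c("VCT40", "DFSSD")) {
    g <- make_geometry(nm, scale = 0.1)
    for (mode in c("axial_full", "axial_half")) {
      sino <- simulate_scan(g, ph, scan_protocol(mode,
                                                 views_per_rotation = 98L),
                            quiet_flux())
      vol <- reconstruct(sino, grid)
      expect_lt(abs(mean(vol$data[, , 1][water])), 5)
      expect_lt(abs(mean(vol$data[, , 1][off])), 5)
      expect_lt(abs(mean(vol$data[, , 1][air]) + 1000), 10)
    }
    hel <- simulate_scan(g, ph, scan_protocol(
      "helical", pitch = 0.75, views_per_rotation = 98L,
      z_start = -200, z_end = 200), quiet_flux())
    vol <- reconstruct(hel, grid)
    expect_lt(abs(mean(vol$data[, , 1][water])), 5)
    expect_lt(abs(mean(vol$data[, , 1][off])), 5)
  }
})

test_that("cone exponent zero is bit-identical to the plain-FDK control", {
  g <- make_geometry("DFSSD", scale = 0.1)
  ph <- flat_rod_phantom()
  sino <- simulate_scan(g, ph, scan_protocol("axial_half",
                                             views_per_rotation = 98L),
                        quiet_flux())
  grid <- recon_grid(48L, fov = 500, slice_z = c(0, 20),
                     slice_thickness = 2)
  v0 <- reconstruct(sino, grid, recon_settings(cone_exponent = 0))
  vf <- reconstruct(sino, grid, recon_settings(weighting = "fdk"))
  expect_identical(v0$data, vf$data)
  v2 <- reconstruct(sino, grid, recon_settings(cone_exponent = 2))
  expect_false(identical(v0$data, v2$data))
})

test_that("reconstruction is deterministic for a fixed sinogram", {
  g <- make_geometry("VCT40", scale = 0.1)
  ph <- water_phantom(radius = 100)
  sino <- simulate_scan(g, ph, scan_protocol("axial_full",
                                             views_per_rotation = 48L),
                        flux_model(noise = TRUE), seed = 3)
  grid <- recon_grid(48L, fov = 500, slice_z = 0, slice_thickness = 2)
  expect_identical(reconstruct(sino, grid)$data,
                   reconstruct(sino, grid)$data)
})

test_that("the central slice matches an independent 2D fan-beam FBP", {
  # z-invariant phantom: every row sees the same fan data, so the 3D chain
  # must agree with a from-scratch 2D implementation
  g <- make_geometry("VCT40", scale = 0.25)
  ph <- flat_rod_phantom()
  prot <- scan_protocol("axial_full", views_per_rotation = 246L)
  sino <- simulate_scan(g, ph, prot, quiet_flux())
  grid <- recon_grid(96L, fov = 400, slice_z = 0, slice_thickness = 1)
  vol <- reconstruct(sino, grid, recon_settings(kernel = "ramp"))

  # ---- independent 2D fan-beam FBP (own kernel, own backprojection) ----
  sched <- sino$schedule
  nch <- g$n_channels
  gam <- (seq_len(nch) - 1 - (nch - 1) / 2) * g$dgamma
  rmid <- g$n_rows %/% 2 # central rows straddle z = 0 symmetrically
  pfan <- (sino$projections[, rmid, ] + sino$projections[, rmid + 1L, ]) / 2
  m <- seq(-(nch - 1), nch - 1)
  ker <- numeric(length(m))
  ker[m == 0] <- 1 / (8 * g$dgamma^2)
  odd <- m %% 2 != 0
  ker[odd] <- -1 / (2 * pi^2 * sin(m[odd] * g$dgamma)^2)
  co <- (seq_len(96) - 1 - 95 / 2) * grid$pix
  img <- matrix(0, 96, 96)
  dbeta <- 2 * pi / 246
  X <- matrix(co, 96, 96)
  Y <- matrix(co, 96, 96, byrow = TRUE)
  for (v in seq_len(nrow(sched))) {
    b <- sched$beta[v]
    q <- convolve(pfan[, v] * g$R * cos(gam), rev(ker), type = "open")
    q <- q[nch:(2 * nch - 1)] * g$dgamma
    Sx <- -g$R * sin(b); Sy <- g$R * cos(b)
    wx <- X - Sx; wy <- Y - Sy
    L2 <- wx^2 + wy^2
    gv <- atan2(-(wx * cos(b) + wy * sin(b)), wx * sin(b) - wy * cos(b))
    cf <- gv / g$dgamma + (nch - 1) / 2 # 0-based channel coordinate
    ci <- floor(cf)
    fr <- cf - ci
    ok <- ci >= 0 & ci <= nch - 2
    val <- matrix(0, 96, 96)
    val[ok] <- (1 - fr[ok]) * q[ci[ok] + 1] + fr[ok] * q[ci[ok] + 2]
    img <- img + 0.5 * val / L2 # full scan: each line measured twice
  }
  img <- img * 2 * dbeta
  hu2d <- 1000 * (img - 0.0193) / 0.0193
  body <- roi_mask(grid, radius = 130)
  expect_lt(sqrt(mean((vol$data[, , 1][body] - hu2d[body])^2)), 1)
})

test_that("cone artifacts grow with the z-offset of an off-center ball", {
  bg <- data.frame(kind = "elliptic_cylinder", cx = 0, cy = 0, cz = 0,
                   p1 = 200, p2 = 200, p3 = 100, ux = 0, uy = 0, uz = 1,
                   delta_mu = 0.0193, material = "water")
  g <- make_geometry("VCT140", scale = 0.1)
  rmse <- vapply(c(0, 30, 60), function(zb) {
    ball <- data.frame(kind = "ellipsoid", cx = 80, cy = 0, cz = zb,
                       p1 = 15, p2 = 15, p3 = 15, ux = 0, uy = 0, uz = 1,
                       delta_mu = 0.9 * 0.0193, material = "teflon")
    ph <- ct_phantom(rbind(bg, ball))
    sino <- simulate_scan(g, ph, scan_protocol("axial_full",
                                               views_per_rotation = 98L),
                          quiet_flux())
    grid <- recon_grid(96L, fov = 450, slice_z = zb, slice_thickness = 2)
    vol <- reconstruct(sino, grid)
    truth <- voxelize(ph, grid, supersample = 2L)
    mask <- roi_mask(grid, radius = 180) & !dfsct:::dilate_mask(
      abs(truth$data[, , 1]) > 50, 2L)
    artifact_score(vol$data[, , 1], truth$data[, , 1], mask)
  }, numeric(1))
  expect_true(all(diff(rmse) > 0))
})

test_that("slices outside the scanned coverage are rejected by name", {
  g <- make_geometry("VCT40", scale = 0.1)
  ph <- water_phantom()
  sino <- simulate_scan(g, ph, scan_protocol("axial_full",
                                             views_per_rotation = 24L),
                        quiet_flux())
  err <- tryCatch(reconstruct(sino, recon_grid(32L, slice_z = c(0, 30))),
                  error = function(e) conditionMessage(e))
  expect_match(err, "30")
  expect_no_match(err, "outside.*0,")
})

test_that("full-scan noise maps of a uniform cylinder are isotropic", {
  g <- make_geometry("VCT40", scale = 0.1)
  ph <- water_phantom(radius = 150)
  clean_sino <- simulate_scan(g, ph, scan_protocol(
    "axial_full", views_per_rotation = 98L), quiet_flux())
  grid <- recon_grid(64L, fov = 500, slice_z = 0, slice_thickness = 2)
  clean <- reconstruct(clean_sino, grid)
  diffs <- vapply(1:12, function(s) {
    noisy <- reconstruct(add_projection_noise(clean_sino, flux_model(),
                                              seed = s), grid)
    noisy$data[, , 1] - clean$data[, , 1]
  }, matrix(0, 64, 64))
  sdmap <- apply(diffs, c(1, 2), sd)
  co <- grid_coords <- (seq_len(64) - 1 - 63 / 2) * grid$pix
  r <- sqrt(outer(co^2, co^2, "+"))
  ang <- atan2(matrix(co, 64, 64, byrow = TRUE), matrix(co, 64, 64))
  ring <- r > 40 & r < 90
  sector <- cut(ang[ring], breaks = seq(-pi, pi, length.out = 9))
  bysec <- tapply(sdmap[ring], sector, mean)
  expect_lt((max(bysec) - min(bysec)) / mean(bysec), 0.25)
})
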