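test_that("geometry presets carry the published system parameters", {
  for (nm in c("VCT40", "VCT140", "DFSSD")) {
    g <- make_geometry(nm)
    expect_equal(g$R, 541)
    expect_equal(g$D, 408)
    expect_equal(g$n_channels, 888L)
    expect_equal(g$channel_pitch_iso, 0.58)
    expect_equal(g$row_pitch_iso, 0.625)
    expect_equal(g$n_rows * g$row_pitch_iso, g$collimation, tolerance = 1e-9)
    expect_equal(g$fan_angle, 888 * 0.58 / 541)
  }
  expect_equal(make_geometry("VCT40")$n_rows, 64L)
  expect_equal(make_geometry("VCT140")$n_rows, 224L)
  expect_equal(make_geometry("DFSSD")$n_rows, 160L)
  expect_equal(make_geometry("DFSSD")$spots$z_offset, c(-45, 45))
  expect_equal(make_geometry("VCT40")$spots$z_offset, 0)
  # physical z-width of the VCT140 detector by similar triangles
  g <- make_geometry("VCT140")
  expect_equal(g$n_rows * g$row_pitch_phys, 140 * (541 + 408) / 541,
               tolerance = 1e-9)
  expect_error(make_geometry("VCT9000"), "valid names")
})

test_that("scaling preserves fan angle and collimation", {
  g <- make_geometry("VCT140", scale = 0.25)
  expect_equal(g$fan_angle, 888 * 0.58 / 541)
  expect_equal(g$n_rows * g$row_pitch_iso, 140, tolerance = 1e-9)
  expect_equal(g$n_channels, 222L)
  expect_error(scale_geometry(g, 2), "scale")
})

test_that("iso-plane coverage matches the closed form and edge-ray oracle", {
  expect_equal(z_coverage_at_iso(make_geometry("VCT40")), 40)
  expect_equal(z_coverage_at_iso(make_geometry("VCT140")), 140)
  g <- make_geometry("DFSSD")
  cov <- z_coverage_at_iso(g)
  # closed form: W + d * D/(R+D)
  expect_equal(cov, 100 + 90 * 408 / (541 + 408), tolerance = 1e-9)
  expect_equal(round(cov / 10) * 10, 140)
  # brute-force union of all extreme-ray iso crossings
  hw <- 100 * (541 + 408) / 541 / 2
  f <- 541 / (541 + 408)
  ends <- lapply(c(-45, 45), function(s) sort(s + (c(-hw, hw) - s) * f))
  brute <- diff(range(unlist(ends))) # intervals overlap for this preset
  expect_true(ends[[1]][2] >= ends[[2]][1]) # overlapping, union is the range
  expect_equal(cov, brute, tolerance = 1e-9)
  # spot separation 0 degenerates to a single-source 100 mm system
  g0 <- g
  g0$spots$z_offset <- c(0, 0)
  expect_equal(z_coverage_at_iso(g0), 100, tolerance = 1e-9)
})

test_that("cone angles of rays and z-locations follow the geometry", {
  g40 <- make_geometry("VCT40")
  g140 <- make_geometry("VCT140")
  # central rows straddle the plane symmetrically
  expect_equal(cone_angle_of_ray(g40, 1, 32) + cone_angle_of_ray(g40, 1, 33),
               0, tolerance = 1e-12)
  # edge rows: atan applied to the outermost row center at iso
  expect_equal(cone_angle_of_ray(g140, 1, 224),
               atan((70 - 0.625 / 2) / 541) * 180 / pi, tolerance = 1e-9)
  expect_equal(cone_angle_of_ray(g140, 1, 224), 7.37, tolerance = 0.05)
  expect_equal(cone_angle_of_ray(g40, 1, 64), 2.12, tolerance = 0.05)
  expect_error(cone_angle_of_ray(g40, 1, 65), "detector")

  gd <- make_geometry("DFSSD")
  expect_equal(min_cone_angle_at_z(gd, 45), 0)
  expect_equal(min_cone_angle_at_z(gd, -45), 0)
  expect_equal(min_cone_angle_at_z(gd, 0), atan(45 / 541) * 180 / pi)
  expect_equal(min_cone_angle_at_z(gd, 0), 4.76, tolerance = 0.01)
  expect_equal(min_cone_angle_at_z(g140, 0), 0)
  expect_error(min_cone_angle_at_z(g40, 30), "coverage")
  # the dual-spot worst case beats the wide single-source worst case
  zs <- seq(-69, 69, by = 0.5)
  expect_lt(max(min_cone_angle_at_z(gd, zs)),
            cone_angle_of_ray(g140, 1, 224))
})

test_that("evaluation slices sit at the published locations", {
  s40 <- evaluation_slices(make_geometry("VCT40"))
  expect_equal(sort(s40$z[s40$label == "edge"]), c(-19.6875, 19.6875))
  expect_equal(sort(s40$z[s40$label == "intermediate"]), c(-10, 10))
  s140 <- evaluation_slices(make_geometry("VCT140"))
  expect_equal(max(s140$z), 69.6875)
  sd <- evaluation_slices(make_geometry("DFSSD"))
  expect_equal(sd$z[sd$label == "center"], 0)
  expect_equal(sort(sd$z[sd$label == "intermediate"]), c(-22.5, 22.5))
  expect_equal(sum(sd$label == "edge"), 2) # one per coverage end
  expect_equal(max(sd$z), 69.03, tolerance = 0.01)
})

test_that("view schedules respect counts, spacing and tube-load budget", {
  gd <- make_geometry("DFSSD")
  g40 <- make_geometry("VCT40")
  full <- scan_protocol("axial_full")
  sch <- build_view_schedule(gd, full)
  expect_equal(nrow(sch), 1968L)
  expect_equal(sum(sch$mas), 240, tolerance = 1e-9)
  for (s in 1:2) {
    b <- sch$beta[sch$spot == s]
    expect_equal(sum(sch$mas[sch$spot == s]), 120, tolerance = 1e-9)
    expect_equal(diff(b), rep(2 * pi / 984, length(b) - 1), tolerance = 1e-12)
  }
  # strict alternation, second spot offset by half a view period
  expect_equal(sch$spot[1:6], c(1L, 2L, 1L, 2L, 1L, 2L))
  expect_equal(sch$beta[2] - sch$beta[1], pi / 984, tolerance = 1e-12)

  half <- build_view_schedule(g40, scan_protocol("axial_half"))
  rng <- pi + g40$fan_angle
  expect_equal(nrow(half), floor(rng / (2 * pi / 984) + 1e-9) + 1)
  expect_lte(max(half$beta), rng)
  expect_equal(diff(half$beta), rep(2 * pi / 984, nrow(half) - 1),
               tolerance = 1e-12)

  hel <- build_view_schedule(g40, scan_protocol(
    "helical", pitch = 0.5, z_start = -50, z_end = 50))
  # table advances pitch * collimation per 2 pi of beta
  i <- c(1L, 1L + 984L)
  expect_equal(diff(hel$z_table[i]), 0.5 * 40, tolerance = 1e-9)
  expect_error(build_view_schedule(g40, scan_protocol(
    "helical", pitch = 0.5, z_start = 0, z_end = 30)), "collimation")
})

test_that("protocol validation rejects inconsistent settings", {
  expect_error(scan_protocol("helical"), "pitch")
  expect_error(scan_protocol("axial_full", pitch = 0.5), "helical")
  expect_error(scan_protocol("axial_half", total_mas = -1), "total_mas")
})
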