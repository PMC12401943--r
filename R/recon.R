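#' Reconstruction settings
#'
#' @param cone_exponent Exponent `k` of the cone-angle-dependent pixel-wise
#'   weight `cos^k(kappa)` used to blend contributions across focal spots;
#'   `k = 0` disables cone weighting and reduces the algorithm to plain FDK.
#' @param kernel `"standard"` (ramp with a Hann apodization cut off at 80%
#'   of Nyquist, the shared smooth kernel of the study) or `"ramp"` (pure
#'   band-limited ramp).
#' @param taper Nominal smoothness (degrees) of the helical per-voxel view
#'   window ends. The implementation realizes the smooth taper with
#'   Parker-form weights on each 180-degrees-plus-fan segment, whose
#'   sine-squared ramps are fan-angle wide and guarantee exact redundancy;
#'   the parameter is retained for interface compatibility.
#' @param weighting `"cone"` (default) or `"fdk"`, a control path that
#'   forces `cone_exponent = 0`.
#' @return A `ct_recon_settings` object.
#' @export
recon_settings <- function(cone_exponent = 2, kernel = c("standard", "ramp"),
                           taper = 10, weighting = c("cone", "fdk")) {
  kernel <- match.arg(kernel)
  weighting <- match.arg(weighting)
  if (cone_exponent < 0) stop("cone_exponent must be >= 0")
  if (taper <= 0) stop("taper must be positive")
  if (weighting == "fdk") cone_exponent <- 0
  structure(list(cone_exponent = cone_exponent, kernel = kernel,
                 taper = taper, weighting = weighting),
            class = "ct_recon_settings")
}

#' Cosine pre-weighting of a projection
#'
#' Scales each detector element by `cos(gamma) * cos(kappa)` where `gamma`
#' is the channel angle and `kappa` the cone angle of the element's ray at
#' the given focal spot -- the standard FDK pre-weight for curved detectors.
#'
#' @param projection A `row x channel` matrix.
#' @param geometry A `ct_geometry`.
#' @param spot Focal spot index.
#' @return The weighted `row x channel` matrix.
#' @export
cosine_preweight <- function(projection, geometry, spot = 1L) {
  stopifnot(nrow(projection) == geometry$n_rows,
            ncol(projection) == geometry$n_channels)
  cg <- cos(channel_gammas(geometry))
  ck <- cos(cone_angle_of_ray(geometry, spot, seq_len(geometry$n_rows)) *
              pi / 180)
  projection * outer(ck, cg)
}

# Band-limited equiangular ramp kernel (spatial domain), offsets -n+1..n-1:
# g(0) = 1/(8 dg^2); g(m) = -1 / (2 pi^2 sin^2(m dg)) for odd m; 0 for even.
equiangular_ramp_kernel <- function(n, dgamma) {
  m <- seq(-(n - 1), n - 1)
  g <- numeric(length(m))
  g[m == 0] <- 1 / (8 * dgamma^2)
  odd <- m %% 2 != 0
  g[odd] <- -1 / (2 * pi^2 * sin(m[odd] * dgamma)^2)
  g
}

# frequency response (length M, wrapped) of the kernel plus apodization
ramp_filter_response <- function(n, dgamma, kernel) {
  M <- 2^ceiling(log2(2 * n))
  m <- seq(-(n - 1), n - 1)
  g <- equiangular_ramp_kernel(n, dgamma)
  gw <- numeric(M)
  gw[(m %% M) + 1] <- g
  G <- Re(fft(gw))
  if (kernel == "standard") {
    f <- c(seq(0, M / 2), seq(M / 2 - 1, 1)) / M  # cycles/sample
    fc <- 0.8 * 0.5
    A <- ifelse(f <= fc, 0.5 * (1 + cos(pi * f / fc)), 0)
    G <- G * A
  }
  G
}

#' Equiangular ramp filtering of projection rows
#'
#' Frequency-domain filtering along the channel direction with the
#' equiangular ramp kernel (the classic `(gamma/sin gamma)^2`-modified
#' band-limited ramp), zero-padded to at least twice the row length. The
#' `"standard"` kernel applies a Hann apodization rolled off to zero at 80%
#' of the Nyquist frequency. The result includes the `dgamma` quadrature
#' factor and is linear in its input.
#'
#' @param rows A numeric vector (one detector row) or a matrix with channels
#'   along the first dimension; columns are filtered independently.
#' @param dgamma Channel angular pitch, rad.
#' @param kernel `"standard"` or `"ramp"`.
#' @return Filtered vector/matrix of the same shape.
#' @export
ramp_filter <- function(rows, dgamma, kernel = c("standard", "ramp")) {
  kernel <- match.arg(kernel)
  vec <- is.null(dim(rows))
  x <- if (vec) matrix(rows, ncol = 1) else rows
  n <- nrow(x)
  M <- 2^ceiling(log2(2 * n))
  G <- ramp_filter_response(n, dgamma, kernel)
  xp <- rbind(x, matrix(0, M - n, ncol(x)))
  Q <- mvfft(mvfft(xp) * G, inverse = TRUE) / M
  out <- Re(Q[seq_len(n), , drop = FALSE]) * dgamma
  if (vec) out[, 1] else out
}

#' Parker short-scan weights
#'
#' Standard smooth Parker weights for an equiangular short scan spanning
#' `[0, pi + 2 gamma_m]`. Conjugate rays `(beta, gamma)` and
#' `(beta + pi - 2 gamma, -gamma)` receive weights summing to 1; weights are
#' 0 outside the scan range.
#'
#' @param beta Gantry angle(s) measured from the start of the short scan,
#'   rad.
#' @param gamma Channel angle(s), rad.
#' @param gamma_m Fan half-angle, rad.
#' @return Weight(s) in `[0, 1]`.
#' @export
parker_weights <- function(beta, gamma, gamma_m) {
  n <- max(length(beta), length(gamma))
  cpp_parker_weights(rep_len(as.numeric(beta), n),
                     rep_len(as.numeric(gamma), n), gamma_m)
}

#' Cone-angle-dependent pixel weight
#'
#' The pixel-wise 3D weight `cos^k(kappa)` applied to a view's contribution
#' to a voxel, where `kappa` is the cone angle of the ray from the view's
#' focal spot to the voxel. [reconstruct()] normalizes these weights per
#' voxel across the focal spots measuring the corresponding pose, so the
#' spot with the smaller cone angle dominates where beams overlap.
#'
#' @param geometry A `ct_geometry`.
#' @param spot Focal spot index.
#' @param point Voxel position, length-3 (mm).
#' @param beta Gantry angle of the view, rad.
#' @param k Cone exponent.
#' @param z_table Table position of the view, mm.
#' @return Unnormalized weight in `(0, 1]`.
#' @export
cone_weight <- function(geometry, spot, point, beta = 0, k = 2,
                        z_table = 0) {
  S <- c(-geometry$R * sin(beta), geometry$R * cos(beta),
         z_table + geometry$spots$z_offset[spot])
  L <- sqrt((point[1] - S[1])^2 + (point[2] - S[2])^2)
  dz <- point[3] - S[3]
  (L / sqrt(L^2 + dz^2))^k
}

#' Weighted cone-beam filtered backprojection
#'
#' Reconstructs HU slices from a sinogram: cosine pre-weighting, in-plane
#' redundancy weighting, row-wise equiangular ramp filtering, then
#' voxel-driven backprojection with bilinear detector interpolation and
#' inverse-square distance weighting. Redundancy weights are applied before
#' filtering, which keeps the short-scan identity exact: Parker weights for
#' axial half scans, the 1/2 factor for full scans, and -- for helical
#' scans -- per-slice Parker-form weights on the 180-degrees-plus-fan
#' segment centered on each spot's crossing angle. The pixel-wise stage
#' blends contributions across focal spots with cone-angle weights
#' `cos^k(kappa)` normalized per voxel (dual-spot data are merged in one
#' accumulation; with `k = 0` or a single source this reduces to plain
#' FDK / Parker FBP).
#'
#' @param sinogram A `ct_sinogram`.
#' @param grid A [recon_grid()].
#' @param settings A [recon_settings()].
#' @return A `ct_volume` in HU with provenance (geometry, protocol, seed,
#'   settings) and the per-voxel pixel-weight sums in
#'   `provenance$weight_sum`.
#' @export
reconstruct <- function(sinogram, grid, settings = recon_settings()) {
  stopifnot(inherits(sinogram, "ct_sinogram"), inherits(grid, "ct_grid"))
  g <- sinogram$geometry
  sched <- sinogram$schedule
  mode <- attr(sched, "mode")
  feed <- attr(sched, "feed")
  check_slices_in_coverage(sinogram, grid)
  cg <- cos(channel_gammas(g))
  gammas <- channel_gammas(g)
  gm <- g$fan_angle / 2
  ck_by_spot <- lapply(seq_len(nrow(g$spots)), function(s)
    cos(cone_angle_of_ray(g, s, seq_len(g$n_rows)) * pi / 180))
  G <- ramp_filter_response(g$n_channels, g$dgamma, settings$kernel)
  M <- length(G)
  pad <- matrix(0, M - g$n_channels, g$n_rows)
  p <- sinogram$projections
  preweight <- function(v) # R cos(gamma) cos(kappa); channel fastest
    p[, , v] * (g$R * cg) *
      rep(ck_by_spot[[sched$spot[v]]], each = g$n_channels)
  filt <- function(pw) {
    Q <- mvfft(mvfft(rbind(pw, pad)) * G, inverse = TRUE) / M
    Re(Q[seq_len(g$n_channels), , drop = FALSE]) * g$dgamma
  }
  bp <- backproject_args(sinogram, grid, settings)
  dbeta_spot <- 2 * pi / attr(sched, "views_per_rotation")
  nz <- length(grid$slice_z)
  beta0 <- min(sched$beta)
  run_bp <- function(q, views, slice_z, blend) {
    a <- bp
    a$slice_z <- slice_z
    a$blend <- blend
    do.call(cpp_backproject,
            c(list(q = as.vector(q), nview = length(views),
                   beta = sched$beta[views],
                   spot_idx = as.integer(sched$spot[views]) - 1L,
                   z_table = sched$z_table[views]),
              a))
  }
  mu <- array(0, c(grid$nx, grid$ny, nz))
  wsum <- array(0, c(grid$nx, grid$ny, nz))
  if (mode != "helical") {
    q <- array(0, dim(p))
    for (v in seq_len(dim(p)[3])) {
      pw <- preweight(v)
      if (mode == "axial_half") {
        pw <- pw * parker_weights(sched$beta[v] - beta0, gammas, gm)
      } else {
        pw <- pw * 0.5 # every line is measured twice per full rotation
      }
      q[, , v] <- filt(pw)
    }
    res <- run_bp(q, seq_len(dim(p)[3]), grid$slice_z, TRUE)
    mu[] <- res$vol
    wsum[] <- res$wsum
  } else {
    for (iz in seq_len(nz)) {
      hv <- helical_view_weights(g, sched, grid$slice_z[iz], settings)
      q <- array(0, c(g$n_channels, g$n_rows, length(hv$views)))
      for (i in seq_along(hv$views))
        q[, , i] <- filt(preweight(hv$views[i]) * hv$weights[, i])
      res <- run_bp(q, hv$views, grid$slice_z[iz], FALSE)
      mu[, , iz] <- array(res$vol, dim(mu)[1:2])
      wsum[, , iz] <- array(res$wsum, dim(mu)[1:2])
    }
  }
  mu <- 2 * dbeta_spot * mu # exact short-scan scaling
  hu <- 1000 * (mu - sinogram$mu_water) / sinogram$mu_water
  new_ct_volume(hu, grid, list(
    geometry = g$name, mode = mode, pitch = sinogram$protocol$pitch,
    seed = sinogram$seed, noisy = sinogram$noisy,
    settings = unclass(settings),
    weight_sum = wsum))
}

# shared parameter block for the C++ backprojector / weight probes
backproject_args <- function(sinogram, grid = NULL,
                             settings = recon_settings()) {
  g <- sinogram$geometry
  sched <- sinogram$schedule
  args <- list(spots_z = g$spots$z_offset, R = g$R, D = g$D,
               dgamma = g$dgamma, row_pitch_phys = g$row_pitch_phys,
               nrow_det = g$n_rows, nchan = g$n_channels,
               cone_k = settings$cone_exponent,
               zt_ref = sched$z_table[1])
  if (!is.null(grid))
    args <- c(list(nx = grid$nx, ny = grid$ny, fov = grid$fov,
                   slice_z = grid$slice_z), args)
  args
}

#' Generalized per-slice redundancy weights for helical scans
#'
#' Every measurement of an in-plane line through a slice -- multi-turn
#' repeats (`beta + 2 pi n`), conjugates (`beta + pi - 2 gamma + 2 pi n`)
#' and, for the dual-spot geometry, the other focal spot's poses -- shares
#' unit weight. A measurement's score is a raised-cosine apodization of the
#' slice's detector-track position (1 at the detector center, 0 at the
#' physical z-edge) times `cos^k` of the iso-reference cone angle, so
#' oblique or nearly-truncated poses are down-weighted wherever redundancy
#' exists while isolated measurements keep full weight. At low
#' pitch this uses all redundant rotations, which is what drives the noise
#' drop of helical scans relative to axial half scans.
#'
#' @param geometry A `ct_geometry`.
#' @param schedule A helical `ct_schedule`.
#' @param slice_z Slice location, mm.
#' @param settings A [recon_settings()].
#' @return List with `views` (indices of views with nonzero weight) and
#'   `weights` (`n_channels x length(views)` matrix).
#' @export
helical_view_weights <- function(geometry, schedule, slice_z,
                                 settings = recon_settings()) {
  g <- geometry
  sched <- schedule
  feed <- attr(sched, "feed")
  dbeta <- 2 * pi / attr(sched, "views_per_rotation")
  k <- (g$R + g$D) / g$R
  hw <- det_half_width_phys(g)
  beta1 <- sched$beta[1]
  zt1 <- sched$z_table[1]
  bmin <- min(sched$beta) - dbeta / 2
  bmax <- max(sched$beta) + dbeta / 2
  kk <- settings$cone_exponent
  cfun <- function(b, s) {
    zt <- zt1 + feed * (b - beta1) / (2 * pi)
    track <- s + (slice_z - zt - s) * k
    u <- abs(track) / hw
    # raised-cosine detector apodization: full weight at the detector
    # center, zero at the physical z-edge, so redundant measurements of a
    # line resolve strongly in favour of the least oblique pose
    tp <- ifelse(u >= 1, 0, 0.5 * (1 + cos(pi * u)))
    tp[b < bmin | b > bmax] <- 0
    if (kk > 0) tp <- tp * cos(atan((slice_z - zt - s) / g$R))^kk
    tp
  }
  spots <- g$spots$z_offset
  gammas <- channel_gammas(g)
  cv <- cfun(sched$beta, spots[sched$spot])
  views <- which(cv > 0)
  W <- matrix(0, g$n_channels, length(views))
  for (i in seq_along(views)) {
    v <- views[i]
    b <- sched$beta[v]
    den <- 0
    for (s in spots) {
      # window center of spot s for this slice (detector track = 0)
      bc <- beta1 + 2 * pi * (slice_z - s - zt1) / feed
      n0 <- round((bc - b) / (2 * pi))
      n0g <- round((bc - (b + pi - 2 * gammas)) / (2 * pi))
      for (dn in -1:1) {
        den <- den + cfun(b + 2 * pi * (n0 + dn), s)
        den <- den + cfun(b + pi - 2 * gammas + 2 * pi * (n0g + dn), s)
      }
    }
    W[, i] <- cv[v] / den
  }
  list(views = views, weights = W)
}

#' Applied pixel weight of a single measurement of an axial scan
#'
#' The normalized weight `w / Omega` that [reconstruct()] applies to the
#' measurement of a voxel taken by a given spot at a given gantry angle:
#' `w` is the measurement's cone-angle weight and `Omega` the sum of `w`
#' over the focal spots whose beam covers the voxel at the same pose.
#' Summed over a pose's measurements these weights are exactly 1 -- the
#' "effective redundancy one" normalization of the dual-spot merge. (For
#' helical scans the corresponding per-line normalization happens in
#' [helical_view_weights()].)
#'
#' @param sinogram A `ct_sinogram` (supplies geometry and schedule).
#' @param point Voxel position, length-3 mm.
#' @param beta Gantry angle of the measurement, rad.
#' @param spot Spot index (1-based).
#' @param settings A [recon_settings()].
#' @return Applied weight in `[0, 1]`, or `NA` if the pose does not measure
#'   the point.
#' @export
applied_view_weight <- function(sinogram, point, beta, spot = 1L,
                                settings = recon_settings()) {
  a <- backproject_args(sinogram, NULL, settings)
  do.call(cpp_applied_weight,
          c(list(point[1], point[2], point[3], beta, as.integer(spot) - 1L),
            a[.bp_order]))
}

# reorder backproject_args to the positional C++ signature
.bp_order <- c("spots_z", "R", "D", "dgamma", "row_pitch_phys", "nrow_det",
               "nchan", "cone_k", "zt_ref")

check_slices_in_coverage <- function(sinogram, grid) {
  g <- sinogram$geometry
  sched <- sinogram$schedule
  mode <- attr(sched, "mode")
  if (mode == "helical") {
    # a slice is reconstructable when at least one spot's full on-detector
    # window (the table interval over which the slice's detector track
    # stays within the physical rows) lies inside the scanned table range
    k <- (g$R + g$D) / g$R
    hw <- det_half_width_phys(g)
    zt_lo <- min(sched$z_table)
    zt_hi <- max(sched$z_table)
    bad <- vapply(grid$slice_z, function(z) {
      ok <- FALSE
      for (s in g$spots$z_offset) {
        w_lo <- z - s - (hw - s) / k
        w_hi <- z - s + (hw + s) / k
        if (w_lo >= zt_lo - 1e-9 && w_hi <= zt_hi + 1e-9) ok <- TRUE
      }
      !ok
    }, logical(1))
  } else {
    ivs <- lapply(seq_len(nrow(g$spots)),
                  function(i) spot_coverage_interval(g, i))
    bad <- vapply(grid$slice_z, function(z)
      !any(vapply(ivs, function(iv)
        z >= iv[1] - 1e-9 && z <= iv[2] + 1e-9, logical(1))), logical(1))
  }
  if (any(bad))
    stop("slice z outside scanned coverage: ",
         paste(signif(grid$slice_z[bad], 5), collapse = ", "), " mm")
  invisible(TRUE)
}
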