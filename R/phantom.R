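# kind codes shared with the C++ ray tracer
.prim_kinds <- c(ellipsoid = 1, elliptic_cylinder = 2, circular_rod = 3,
                 cone_frustum = 4)

#' Construct an analytic phantom from a primitive table
#'
#' A phantom is an ordered list of additive primitives: each ray integral is
#' the sum over primitives of chord length times `delta_mu`, with the water
#' background contributing its full attenuation `mu_water`. Overlaps add --
#' there is no priority or overwrite -- which keeps line integrals
#' closed-form and order-independent.
#'
#' @param primitives Data frame with columns `kind` (one of "ellipsoid",
#'   "elliptic_cylinder", "circular_rod", "cone_frustum"), `cx`, `cy`, `cz`
#'   (center, mm), `p1`, `p2`, `p3` (semi-axes / radius / half-length, mm;
#'   see [line_integral()]), `ux`, `uy`, `uz` (unit axis for rods and
#'   frusta), `delta_mu` (mm^-1) and `material`.
#' @param mu_water Linear attenuation of water at the effective energy,
#'   mm^-1. The first primitive is taken as the background envelope and must
#'   carry `delta_mu = mu_water`.
#' @param check_containment If `TRUE`, verify that every insert lies inside
#'   the background envelope (surface-sampled test).
#' @return A `ct_phantom` object.
#' @export
ct_phantom <- function(primitives, mu_water = 0.0193,
                       check_containment = TRUE) {
  req <- c("kind", "cx", "cy", "cz", "p1", "p2", "p3", "ux", "uy", "uz",
           "delta_mu", "material")
  if (!all(req %in% names(primitives)))
    stop("primitives must have columns: ", paste(req, collapse = ", "))
  if (!all(primitives$kind %in% names(.prim_kinds)))
    stop("unknown primitive kind(s): ",
         paste(setdiff(primitives$kind, names(.prim_kinds)), collapse = ", "))
  need3 <- primitives$kind %in% c("ellipsoid", "elliptic_cylinder",
                                  "cone_frustum")
  if (any(primitives$p1 <= 0 | primitives$p2 <= 0) ||
      any(primitives$p3[need3] <= 0))
    stop("all primitive dimensions must be positive")
  ph <- structure(list(primitives = primitives, mu_water = mu_water),
                  class = "ct_phantom")
  if (check_containment && nrow(primitives) > 1L) {
    bad <- which(!vapply(seq_len(nrow(primitives))[-1], function(i) {
      insert_inside_background(primitives[1, ], primitives[i, ])
    }, logical(1))) + 1L
    if (length(bad))
      stop("insert(s) escape the background envelope: ",
           paste(bad, collapse = ", "))
  }
  ph
}

#' @export
print.ct_phantom <- function(x, ...) {
  cat(sprintf("Analytic phantom: %d primitives (background + %d inserts), mu_water = %g mm^-1\n",
              nrow(x$primitives), nrow(x$primitives) - 1L, x$mu_water))
  print(table(x$primitives$material))
  invisible(x)
}

# numeric matrix handed to C++
prim_matrix <- function(phantom) {
  p <- phantom$primitives
  cbind(.prim_kinds[p$kind], p$cx, p$cy, p$cz, p$p1, p$p2, p$p3,
        p$ux, p$uy, p$uz, p$delta_mu)
}

# surface-sample an insert and test containment in the background envelope
# (elliptic cylinder assumed for the background, matching the body phantom)
insert_inside_background <- function(bg, ins, n = 24L, tol = 1e-6) {
  stopifnot(bg$kind == "elliptic_cylinder")
  pts <- primitive_surface_points(ins, n)
  inside <- (pts[, 1] - bg$cx)^2 / bg$p1^2 + (pts[, 2] - bg$cy)^2 / bg$p2^2 <=
    1 + tol
  inside <- inside & abs(pts[, 3] - bg$cz) <= bg$p3 + tol
  all(inside)
}

primitive_surface_points <- function(p, n = 24L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-1L]
  if (p$kind == "ellipsoid") {
    ph <- seq(-pi / 2, pi / 2, length.out = 9L)
    g <- expand.grid(th = th, ph = ph)
    cbind(p$cx + p$p1 * cos(g$ph) * cos(g$th),
          p$cy + p$p2 * cos(g$ph) * sin(g$th),
          p$cz + p$p3 * sin(g$ph))
  } else if (p$kind == "elliptic_cylinder") {
    g <- expand.grid(th = th, z = c(-p$p3, 0, p$p3))
    cbind(p$cx + p$p1 * cos(g$th), p$cy + p$p2 * sin(g$th), p$cz + g$z)
  } else {
    u <- c(p$ux, p$uy, p$uz)
    w1 <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    v1 <- w1 - sum(w1 * u) * u; v1 <- v1 / sqrt(sum(v1^2))
    v2 <- c(u[2] * v1[3] - u[3] * v1[2], u[3] * v1[1] - u[1] * v1[3],
            u[1] * v1[2] - u[2] * v1[1])
    ctr <- c(p$cx, p$cy, p$cz)
    if (p$kind == "circular_rod") {
      g <- expand.grid(th = th, a = c(-p$p2, 0, p$p2))
      r <- p$p1
      t(ctr + t(outer(g$a, u) + r * cos(g$th) %o% v1 + r * sin(g$th) %o% v2))
    } else { # cone_frustum: radius p1 at axial -p3, p2 at +p3
      g <- expand.grid(th = th, a = c(-p$p3, 0, p$p3))
      rm <- (p$p1 + p$p2) / 2; sl <- (p$p2 - p$p1) / (2 * p$p3)
      r <- rm + sl * g$a
      t(ctr + t(outer(g$a, u) + (r * cos(g$th)) %o% v1 +
                  (r * sin(g$th)) %o% v2))
    }
  }
}

#' Analytic helical body phantom
#'
#' A 450 x 300 x 160 mm water torso (elliptic cylinder, semi-axes 225 x
#' 150 mm) carrying two families of inserts chosen to provoke cone-beam
#' artifacts: high-density Teflon rods near the periphery, tilted out of the
#' xy-plane like ribs, and two low-density cone frusta near the center
#' emulating the lung domes, whose cross-section varies strongly along z.
#'
#' Rod centers sit on the ellipse at `ring_frac` of the torso semi-axes,
#' azimuthally uniform, with their z-positions staggered along a spiral
#' spanning `ring_z_span` so that -- like a rib cage -- high-contrast
#' longitudinal gradients exist throughout the phantom's 160 mm extent.
#' Each rod's axis is the local ellipse tangent tilted out of plane by an
#' angle drawn uniformly from `tilt_range` (degrees) using the seeded
#' generator, so a fixed seed yields an identical phantom.
#'
#' @param n_rods Number of Teflon rods.
#' @param rod_radius,rod_length Rod radius and full length, mm.
#' @param tilt_range Two-element range of rod tilt angles from the xy-plane,
#'   degrees.
#' @param ring_frac Radial position of the rod ring as a fraction of the
#'   torso semi-axes.
#' @param ring_z_span z-extent (mm) over which the rod centers are
#'   staggered (the default leaves room for the steepest tilt inside the
#'   torso's 160 mm).
#' @param cone_base_radius,cone_apex_radius,cone_height Lung-dome frustum
#'   dimensions, mm.
#' @param cone_x Lung insert center offset along x, mm (placed at +/-
#'   `cone_x`).
#' @param seed Seed for the rod tilt draw.
#' @param mu_water Water attenuation, mm^-1 (70 keV effective energy).
#' @param teflon_hu,lung_hu Nominal insert contrasts in HU.
#' @return A `ct_phantom` with 1 background + `n_rods` + 2 inserts.
#' @export
helical_body_phantom <- function(n_rods = 12L, rod_radius = 6,
                                 rod_length = 120,
                                 tilt_range = c(10, 35), ring_frac = 0.8,
                                 ring_z_span = 76,
                                 cone_base_radius = 45, cone_apex_radius = 5,
                                 cone_height = 120, cone_x = 70, seed = 1L,
                                 mu_water = 0.0193, teflon_hu = 900,
                                 lung_hu = -700) {
  a <- 225; b <- 150; hz <- 80
  bg <- data.frame(kind = "elliptic_cylinder", cx = 0, cy = 0, cz = 0,
                   p1 = a, p2 = b, p3 = hz, ux = 0, uy = 0, uz = 1,
                   delta_mu = mu_water, material = "water")
  rows <- list(bg)
  if (n_rods > 0) {
    tilts <- withr::with_seed(seed,
      runif(n_rods, tilt_range[1], tilt_range[2])) * pi / 180
    phis <- 2 * pi * (seq_len(n_rods) - 1) / n_rods
    zs <- if (n_rods > 1)
      seq(-ring_z_span / 2, ring_z_span / 2, length.out = n_rods) else 0
    for (i in seq_len(n_rods)) {
      ctr <- c(ring_frac * a * cos(phis[i]), ring_frac * b * sin(phis[i]),
               zs[i])
      tang <- c(-a * sin(phis[i]), b * cos(phis[i]), 0)
      tang <- tang / sqrt(sum(tang^2))
      ax <- cos(tilts[i]) * tang + sin(tilts[i]) * c(0, 0, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "circular_rod", cx = ctr[1], cy = ctr[2], cz = ctr[3],
        p1 = rod_radius, p2 = rod_length / 2, p3 = 0,
        ux = ax[1], uy = ax[2], uz = ax[3],
        delta_mu = teflon_hu / 1000 * mu_water, material = "teflon")
    }
  }
  for (sgn in c(-1, 1)) {
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "cone_frustum", cx = sgn * cone_x, cy = 0, cz = 0,
      p1 = cone_base_radius, p2 = cone_apex_radius, p3 = cone_height / 2,
      ux = 0, uy = 0, uz = sgn,
      delta_mu = lung_hu / 1000 * mu_water, material = "lung")
  }
  ct_phantom(do.call(rbind, rows), mu_water = mu_water)
}

#' Uniform water cylinder phantom
#'
#' A single z-aligned water cylinder, used for flux calibration, noise
#' uniformity and water/air HU calibration checks.
#'
#' @param radius Cylinder radius, mm.
#' @param half_length Half-extent in z, mm.
#' @param mu_water Water attenuation, mm^-1.
#' @return A `ct_phantom`.
#' @export
water_cylinder_phantom <- function(radius = 150, half_length = 200,
                                   mu_water = 0.0193) {
  ct_phantom(data.frame(
    kind = "elliptic_cylinder", cx = 0, cy = 0, cz = 0,
    p1 = radius, p2 = radius, p3 = half_length, ux = 0, uy = 0, uz = 1,
    delta_mu = mu_water, material = "water"), mu_water = mu_water)
}

#' Exact line integrals through an analytic phantom
#'
#' Closed-form quadratic ray-primitive intersection: the integral is the sum
#' over primitives of chord length times `delta_mu` (cone frusta are solved
#' as a quadric capped by planes). A ray missing every primitive returns 0.
#'
#' @param phantom A `ct_phantom`.
#' @param origin,direction Numeric length-3 vectors or n x 3 matrices;
#'   directions must be unit length.
#' @param tmin,tmax Integration bounds along the ray (mm); defaults cover
#'   the forward half-line.
#' @return Dimensionless path attenuation(s), length n.
#' @export
line_integral <- function(phantom, origin, direction, tmin = 0, tmax = Inf) {
  stopifnot(inherits(phantom, "ct_phantom"))
  o <- matrix(as.numeric(origin), ncol = 3)
  d <- matrix(as.numeric(direction), ncol = 3)
  if (nrow(o) == 1L && nrow(d) > 1L) o <- o[rep(1, nrow(d)), , drop = FALSE]
  if (nrow(d) == 1L && nrow(o) > 1L) d <- d[rep(1, nrow(o)), , drop = FALSE]
  nrm <- sqrt(rowSums(d^2))
  if (any(abs(nrm - 1) > 1e-8)) stop("directions must be unit vectors")
  tmax[!is.finite(tmax)] <- 1e7
  cpp_line_integrals(prim_matrix(phantom), o, d,
                     as.numeric(tmin), as.numeric(tmax))
}

#' Reconstruction / voxelization grid
#'
#' @param nx,ny In-plane grid size (voxels); the voxel pitch is `fov/nx`.
#' @param fov Reconstructed field of view, mm (500 mm display FOV by
#'   default).
#' @param slice_z z-locations of the slices, mm.
#' @param slice_thickness Slice thickness, mm (used by [voxelize()] for z
#'   averaging).
#' @return A `ct_grid` object.
#' @export
recon_grid <- function(nx = 256L, ny = nx, fov = 500, slice_z = 0,
                       slice_thickness = 0.625) {
  if (nx < 1 || ny < 1 || !length(slice_z)) stop("empty reconstruction grid")
  structure(list(nx = as.integer(nx), ny = as.integer(ny), fov = fov,
                 pix = fov / nx, slice_z = as.numeric(slice_z),
                 slice_thickness = slice_thickness),
            class = "ct_grid")
}

# voxel center coordinates (mm) along x (index fastest) and y
grid_coords <- function(grid) {
  list(x = (seq_len(grid$nx) - 1 - (grid$nx - 1) / 2) * grid$pix,
       y = (seq_len(grid$ny) - 1 - (grid$ny - 1) / 2) * grid$pix)
}

#' Voxelized ground-truth HU volume
#'
#' Per-voxel mean HU via supersampled point evaluation of the analytic
#' phantom: each voxel is sampled on an `supersample`^3 grid (spanning the
#' voxel in x/y and the slice thickness in z) and the attenuation values are
#' averaged, then converted with HU = 1000 (mu - mu_water)/mu_water.
#'
#' @param phantom A `ct_phantom`.
#' @param grid A [recon_grid()].
#' @param supersample Sampling factor per axis (>= 1).
#' @return A `ct_volume` with HU data of dim `c(nx, ny, nslices)`.
#' @export
voxelize <- function(phantom, grid, supersample = 2L) {
  stopifnot(inherits(phantom, "ct_phantom"), inherits(grid, "ct_grid"))
  if (supersample < 1) stop("supersampling factor must be >= 1")
  pm <- prim_matrix(phantom)
  co <- grid_coords(grid)
  n <- as.integer(supersample)
  off <- ((seq_len(n) - 0.5) / n - 0.5)
  vol <- array(0, c(grid$nx, grid$ny, length(grid$slice_z)))
  base <- as.matrix(expand.grid(x = co$x, y = co$y))
  for (iz in seq_along(grid$slice_z)) {
    acc <- numeric(nrow(base))
    for (ox in off) for (oy in off) for (oz in off) {
      pts <- cbind(base[, 1] + ox * grid$pix, base[, 2] + oy * grid$pix,
                   grid$slice_z[iz] + oz * grid$slice_thickness)
      acc <- acc + cpp_point_mu(pm, pts)
    }
    vol[, , iz] <- acc / n^3
  }
  hu <- 1000 * (vol - phantom$mu_water) / phantom$mu_water
  new_ct_volume(hu, grid, list(kind = "ground_truth",
                               supersample = n))
}

new_ct_volume <- function(data, grid, provenance = list()) {
  structure(list(data = data, grid = grid, provenance = provenance),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("CT volume: %d x %d x %d voxels, %.3g mm pitch, slices at {%s} mm\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$grid$pix,
              paste(signif(x$grid$slice_z, 4), collapse = ", ")))
  cat(sprintf("  HU range [%.1f, %.1f]; provenance: %s\n",
              min(x$data), max(x$data),
              if (length(x$provenance)) paste(names(x$provenance),
                                              collapse = ", ") else "none"))
  invisible(x)
}
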