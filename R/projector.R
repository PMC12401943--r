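#' Monoenergetic flux model with bowtie modulation
#'
#' Expected detected counts for an element at channel angle `gamma` are
#' `lambda = photons_per_mas * mas_per_view * b(gamma) * exp(-p)` where `p`
#' is the line integral and `b` the bowtie transmission. The bowtie is an
#' idealized body attenuator that pre-compensates a 300 mm water cylinder:
#' `b(gamma) = exp(-mu_ref * (L(0) - L(gamma)))` with `L` the chord of the
#' cylinder along the fan ray, so `b(0) = 1` and `b` is even in `gamma`.
#' With noise enabled, measured counts are Poisson; the log conversion is
#' guarded by a photon floor of `floor_counts` before the logarithm.
#'
#' @param photons_per_mas Unattenuated photons per mAs per detector element
#'   at iso (calibration constant; the default gives tens-of-HU noise in a
#'   body phantom at 240 mAs).
#' @param bowtie `"body"` (300 mm water-equalizing profile) or `"none"`.
#' @param noise Logical; simulate Poisson statistics.
#' @param bowtie_water_diameter Diameter of the equalized water cylinder, mm.
#' @param mu_ref Water attenuation used inside the bowtie profile, mm^-1.
#' @param floor_counts Photon floor applied before the log.
#' @return A `ct_flux` object.
#' @export
flux_model <- function(photons_per_mas = 2e5, bowtie = c("body", "none"),
                       noise = TRUE, bowtie_water_diameter = 300,
                       mu_ref = 0.0193, floor_counts = 0.5) {
  bowtie <- match.arg(bowtie)
  if (photons_per_mas <= 0) stop("photons_per_mas must be positive")
  structure(list(photons_per_mas = photons_per_mas, bowtie = bowtie,
                 noise = noise,
                 bowtie_water_diameter = bowtie_water_diameter,
                 mu_ref = mu_ref, floor_counts = floor_counts),
            class = "ct_flux")
}

#' Bowtie transmission profile
#'
#' @param flux A [flux_model()].
#' @param gamma Channel angle(s), rad.
#' @param R Source-to-iso distance, mm.
#' @return Transmission factor(s) in (0, 1].
#' @export
bowtie_transmission <- function(flux, gamma, R = 541) {
  if (flux$bowtie == "none") return(rep(1, length(gamma)))
  rb <- flux$bowtie_water_diameter / 2
  chord <- function(g) 2 * sqrt(pmax(0, rb^2 - (R * sin(g))^2))
  exp(-flux$mu_ref * (chord(0) - chord(gamma)))
}

# noiseless line-integral array for a schedule, dim (channel, row, view)
forward_project_schedule <- function(geometry, phantom, schedule) {
  pm <- prim_matrix(phantom)
  spot_z <- geometry$spots$z_offset[schedule$spot]
  p <- cpp_forward_project(pm, geometry$R, geometry$D, schedule$beta,
                           spot_z, schedule$z_table, geometry$n_rows,
                           geometry$n_channels, geometry$dgamma,
                           geometry$row_pitch_phys)
  array(p, c(geometry$n_channels, geometry$n_rows, nrow(schedule)))
}

channel_gammas <- function(geometry) {
  (seq_len(geometry$n_channels) - 1 - (geometry$n_channels - 1) / 2) *
    geometry$dgamma
}

#' Simulate a full scan
#'
#' Computes exact line integrals for every view of the schedule, then (if
#' the flux model has noise enabled) draws Poisson counts per element and
#' log-converts back to noisy line integrals. Helical views translate the
#' phantom through the gantry via the schedule's table positions. For the
#' dual-spot geometry each view carries half the per-view tube load of a
#' single-source scan, so the total flux per rotation is matched.
#'
#' @param geometry A `ct_geometry`.
#' @param phantom A `ct_phantom`.
#' @param protocol A `ct_protocol`.
#' @param flux A [flux_model()].
#' @param seed Seed for the Poisson draw (ignored when noise is disabled).
#' @return A `ct_sinogram`: list with `projections` (array `channel x row x
#'   view` of log line integrals), `schedule`, `geometry`, `protocol`,
#'   `flux`, `mu_water`, `seed`, `noisy`.
#' @export
simulate_scan <- function(geometry, phantom, protocol, flux = flux_model(),
                          seed = 1L) {
  stopifnot(inherits(geometry, "ct_geometry"),
            inherits(phantom, "ct_phantom"),
            inherits(protocol, "ct_protocol"))
  schedule <- build_view_schedule(geometry, protocol)
  p <- forward_project_schedule(geometry, phantom, schedule)
  sino <- structure(list(projections = p, schedule = schedule,
                         geometry = geometry, protocol = protocol,
                         flux = flux, mu_water = phantom$mu_water,
                         seed = NULL, noisy = FALSE),
                    class = "ct_sinogram")
  if (isTRUE(flux$noise)) sino <- add_projection_noise(sino, flux, seed)
  sino
}

#' Resample Poisson noise onto a noiseless sinogram
#'
#' Applies the flux model's forward transmission and Poisson sampling to an
#' existing noiseless sinogram, allowing many noise realizations without
#' re-tracing rays.
#'
#' @param sinogram A noiseless `ct_sinogram`.
#' @param flux A [flux_model()]; defaults to the sinogram's own.
#' @param seed Seed for the Poisson draw.
#' @return A noisy `ct_sinogram`.
#' @export
add_projection_noise <- function(sinogram, flux = sinogram$flux, seed = 1L) {
  stopifnot(inherits(sinogram, "ct_sinogram"))
  if (isTRUE(sinogram$noisy)) stop("sinogram already carries noise")
  g <- sinogram$geometry
  b <- bowtie_transmission(flux, channel_gammas(g), g$R)
  dims <- dim(sinogram$projections)
  # scale per element: N0 * mas_view * b(gamma)
  mas <- rep(sinogram$schedule$mas, each = dims[1] * dims[2])
  scale <- flux$photons_per_mas * mas * as.vector(b) # b recycles over rows/views
  lambda <- scale * exp(-as.vector(sinogram$projections))
  counts <- withr::with_seed(as.integer(seed), rpois(length(lambda), lambda))
  phat <- -log(pmax(counts, flux$floor_counts) / scale)
  out <- sinogram
  out$projections <- array(phat, dims)
  out$flux <- flux
  out$seed <- as.integer(seed)
  out$noisy <- TRUE
  out
}

#' Simulate a single projection view
#'
#' @param geometry A `ct_geometry`.
#' @param phantom A `ct_phantom`.
#' @param view One row of a view schedule (data frame with `beta`, `spot`,
#'   `z_table`, `mas`).
#' @param flux A [flux_model()].
#' @param seed Seed for the Poisson draw.
#' @return A `row x channel` matrix of (noisy) log line integrals.
#' @export
simulate_view <- function(geometry, phantom, view, flux = flux_model(),
                          seed = 1L) {
  stopifnot(nrow(view) == 1L)
  p <- forward_project_schedule(geometry, phantom, view)[, , 1]
  if (isTRUE(flux$noise)) {
    b <- bowtie_transmission(flux, channel_gammas(geometry), geometry$R)
    scale <- flux$photons_per_mas * view$mas * b # recycles over rows
    lambda <- scale * exp(-p)
    counts <- withr::with_seed(as.integer(seed),
                               rpois(length(lambda), as.vector(lambda)))
    p <- array(-log(pmax(counts, flux$floor_counts) / as.vector(scale)),
               dim(p))
  }
  t(p)
}

#' @export
print.ct_sinogram <- function(x, ...) {
  d <- dim(x$projections)
  cat(sprintf("CT sinogram: %s %s, %d views x %d rows x %d channels, %s\n",
              x$geometry$name, x$protocol$mode, d[3], d[2], d[1],
              if (x$noisy) sprintf("Poisson noise (seed %d)", x$seed)
              else "noiseless"))
  invisible(x)
}
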