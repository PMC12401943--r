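#' CT system geometry presets
#'
#' Builds one of the three simulated system geometries. All three share a
#' source-to-iso distance of 541 mm, an iso-to-detector distance of 408 mm and
#' a curved equiangular detector with 888 channels of 0.58 mm pitch at
#' iso-center. They differ in z-collimation (40 / 140 / 100 mm at iso) and in
#' the number of focal spots: `VCT40` and `VCT140` have a single spot on the
#' mid-plane, `DFSSD` has two spots at z = -45 and +45 mm sharing the one
#' detector. Detector rows are 0.625 mm at iso (64 / 224 / 160 rows).
#'
#' @param name One of `"VCT40"`, `"VCT140"`, `"DFSSD"`.
#' @param scale Optional resolution scale in (0, 1]; values below 1 decimate
#'   detector channels and rows while preserving the fan angle and the
#'   collimation (see [scale_geometry()]).
#' @return A `ct_geometry` object: a list with source/detector distances
#'   (`R`, `D`, mm), a `spots` data frame (`id`, `z_offset` mm), and detector
#'   fields `n_channels`, `channel_pitch_iso`, `dgamma` (rad), `fan_angle`
#'   (rad), `n_rows`, `row_pitch_iso`, `row_pitch_phys`, `collimation` (mm).
#' @examples
#' g <- make_geometry("DFSSD")
#' g$spots$z_offset            # -45, +45
#' z_coverage_at_iso(g)        # about 138.7 mm
#' @export
make_geometry <- function(name, scale = 1) {
  valid <- c("VCT40", "VCT140", "DFSSD")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid)) {
    stop("unknown geometry '", paste(name, collapse = ","),
         "'; valid names: ", paste(valid, collapse = ", "))
  }
  R <- 541; D <- 408
  collim <- switch(name, VCT40 = 40, VCT140 = 140, DFSSD = 100)
  spots <- if (name == "DFSSD") {
    data.frame(id = 1:2, z_offset = c(-45, 45))
  } else {
    data.frame(id = 1L, z_offset = 0)
  }
  chan_pitch <- 0.58
  row_pitch <- 0.625
  geom <- structure(list(
    name = name,
    R = R, D = D,
    spots = spots,
    n_channels = 888L,
    channel_pitch_iso = chan_pitch,
    dgamma = chan_pitch / R,
    fan_angle = 888L * chan_pitch / R,
    n_rows = as.integer(round(collim / row_pitch)),
    row_pitch_iso = row_pitch,
    row_pitch_phys = row_pitch * (R + D) / R,
    collimation = collim,
    scale = 1
  ), class = "ct_geometry")
  if (scale != 1) geom <- scale_geometry(geom, scale)
  geom
}

#' Decimate a geometry to desk scale
#'
#' Reduces the channel count by `scale` and the row count by `row_scale`
#' while keeping the fan angle and the z-collimation fixed (pitches grow
#' accordingly), so the geometric relations under study -- cone angles,
#' coverage, redundancy -- are unchanged. Rows are decimated more gently by
#' default (`sqrt(scale)`) because the z-sampling carries the longitudinal
#' gradients that drive cone-beam artifacts.
#'
#' @param geometry A `ct_geometry`.
#' @param scale Scale factor in (0, 1].
#' @param row_scale Row decimation factor in (0, 1]; default `sqrt(scale)`.
#' @return A rescaled `ct_geometry`.
#' @export
scale_geometry <- function(geometry, scale, row_scale = sqrt(scale)) {
  stopifnot(inherits(geometry, "ct_geometry"))
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0 || scale > 1)
    stop("scale must be a single number in (0, 1]")
  g <- geometry
  g$n_channels <- max(8L, as.integer(round(g$n_channels * scale)))
  g$dgamma <- g$fan_angle / g$n_channels
  g$channel_pitch_iso <- g$dgamma * g$R
  g$n_rows <- max(2L, as.integer(round(g$n_rows * row_scale)))
  g$row_pitch_iso <- g$collimation / g$n_rows
  g$row_pitch_phys <- g$row_pitch_iso * (g$R + g$D) / g$R
  g$scale <- geometry$scale * scale
  g
}

#' @export
print.ct_geometry <- function(x, ...) {
  cat(sprintf("CT geometry '%s': R=%g mm, D=%g mm, %d spot(s) at z={%s} mm\n",
              x$name, x$R, x$D, nrow(x$spots),
              paste(x$spots$z_offset, collapse = ", ")))
  cat(sprintf("  detector: %d channels x %d rows, %.4g x %.4g mm at iso, ",
              x$n_channels, x$n_rows, x$channel_pitch_iso, x$row_pitch_iso))
  cat(sprintf("collimation %g mm, fan %.2f deg\n",
              x$collimation, x$fan_angle * 180 / pi))
  invisible(x)
}

# physical detector z half-width (mm)
det_half_width_phys <- function(geometry) {
  geometry$collimation * (geometry$R + geometry$D) / geometry$R / 2
}

# iso-plane z-interval illuminated by one spot:
# z_iso = s + (z_d - s) R/(R+D) over the physical detector extent
spot_coverage_interval <- function(geometry, spot) {
  s <- geometry$spots$z_offset[spot]
  hw <- det_half_width_phys(geometry)
  f <- geometry$R / (geometry$R + geometry$D)
  sort(s + (c(-hw, hw) - s) * f)
}

#' z-axis coverage at iso-center
#'
#' Length of the union over focal spots of the iso-plane z-interval each spot
#' illuminates through the shared detector. For a single-source geometry this
#' equals the collimation; for the dual-spot geometry the two shifted
#' intervals union to collimation + separation * D/(R+D), about 138.7 mm,
#' i.e. roughly 140 mm.
#'
#' @param geometry A `ct_geometry`.
#' @return Coverage length in mm.
#' @export
z_coverage_at_iso <- function(geometry) {
  stopifnot(inherits(geometry, "ct_geometry"))
  ivs <- lapply(seq_len(nrow(geometry$spots)),
                function(i) spot_coverage_interval(geometry, i))
  interval_union_length(ivs)
}

# length of the union of closed intervals given as list of c(lo, hi)
interval_union_length <- function(ivs) {
  m <- do.call(rbind, ivs)
  m <- m[order(m[, 1]), , drop = FALSE]
  tot <- 0; cur <- m[1, ]
  for (i in seq_len(nrow(m))[-1]) {
    if (m[i, 1] <= cur[2]) cur[2] <- max(cur[2], m[i, 2])
    else { tot <- tot + cur[2] - cur[1]; cur <- m[i, ] }
  }
  tot + cur[2] - cur[1]
}

#' Cone angle of a measured ray
#'
#' Signed angle (degrees) between the ray from a focal spot to a detector row
#' center and the axial plane through that spot.
#'
#' @param geometry A `ct_geometry`.
#' @param spot Spot index (1-based row of `geometry$spots`).
#' @param row Detector row index (1-based).
#' @return Angle in degrees.
#' @export
cone_angle_of_ray <- function(geometry, spot, row) {
  stopifnot(inherits(geometry, "ct_geometry"))
  if (any(row < 1 | row > geometry$n_rows)) stop("row outside the detector")
  s <- geometry$spots$z_offset[spot]
  z_phys <- (row - (geometry$n_rows + 1) / 2) * geometry$row_pitch_phys
  atan2(z_phys - s, geometry$R + geometry$D) * 180 / pi
}

#' Effective cone angle at an iso z-location
#'
#' The minimum over the spots covering `z_iso` of the absolute cone angle of
#' the ray through the rotation-axis point at that z. This ranks slice
#' difficulty: for the dual-spot geometry it is zero at z = +/-45 mm and
#' largest (4.76 deg) on the mid-plane, versus 7.37 deg at the edge of the
#' 140 mm single-source detector.
#'
#' @param geometry A `ct_geometry`.
#' @param z_iso z-location on the rotation axis, mm.
#' @return Effective cone angle in degrees.
#' @export
min_cone_angle_at_z <- function(geometry, z_iso) {
  stopifnot(inherits(geometry, "ct_geometry"))
  vapply(z_iso, function(z) {
    angs <- numeric(0)
    for (i in seq_len(nrow(geometry$spots))) {
      iv <- spot_coverage_interval(geometry, i)
      if (z >= iv[1] - 1e-9 && z <= iv[2] + 1e-9) {
        s <- geometry$spots$z_offset[i]
        angs <- c(angs, abs(atan2(z - s, geometry$R) * 180 / pi))
      }
    }
    if (!length(angs))
      stop("z = ", z, " mm is outside the iso-plane coverage of ",
           geometry$name)
    min(angs)
  }, numeric(1))
}

#' Evaluation slice locations
#'
#' The z-locations at which image quality is scored, labelled by their role.
#' For single-source geometries: the center slice (zero cone angle), the
#' intermediate slices at +/- a quarter of the collimation, and the edge
#' slices at the outermost row centers (maximum cone angle). For the
#' dual-spot geometry the cone angle grows towards both the detector center
#' and the coverage ends, so the set is: center (z = 0, the largest cone
#' angle), intermediate slices midway between the mid-plane and each spot
#' plane (+/-22.5 mm), and the two coverage-edge locations.
#'
#' @param geometry A `ct_geometry`.
#' @return A data frame with columns `label` ("center", "intermediate",
#'   "edge"), `side` (-1, 0, +1) and `z` (mm).
#' @export
evaluation_slices <- function(geometry) {
  stopifnot(inherits(geometry, "ct_geometry"))
  if (nrow(geometry$spots) == 1L) {
    w <- geometry$collimation
    edge <- w / 2 - geometry$row_pitch_iso / 2
    df <- data.frame(
      label = c("edge", "intermediate", "center", "intermediate", "edge"),
      side = c(-1, -1, 0, 1, 1),
      z = c(-edge, -w / 4, 0, w / 4, edge))
  } else {
    s <- max(geometry$spots$z_offset)
    # outermost row center of the outer spot, mapped to iso
    hw <- det_half_width_phys(geometry)
    zp <- hw - geometry$row_pitch_phys / 2
    f <- geometry$R / (geometry$R + geometry$D)
    edge <- s + (zp - s) * f
    df <- data.frame(
      label = c("edge", "intermediate", "center", "intermediate", "edge"),
      side = c(-1, -1, 0, 1, 1),
      z = c(-edge, -s / 2, 0, s / 2, edge))
  }
  df
}

#' Scan protocol
#'
#' @param mode One of `"axial_half"`, `"axial_full"`, `"helical"`.
#' @param pitch Helical pitch factor (table feed per rotation divided by
#'   collimation); required for, and only for, helical mode.
#' @param views_per_rotation Views per rotation per focal spot (984 at full
#'   scale).
#' @param total_mas Total tube load per rotation summed over spots, mAs.
#' @param rotation_time Gantry rotation time in seconds (metadata only; the
#'   phantom is static).
#' @param z_start,z_end Helical table start/end positions, mm.
#' @return A `ct_protocol` object.
#' @export
scan_protocol <- function(mode = c("axial_half", "axial_full", "helical"),
                          pitch = NULL, views_per_rotation = 984L,
                          total_mas = 240,
                          rotation_time = if (identical(mode, "helical")) 0.5 else 0.35,
                          z_start = NULL, z_end = NULL) {
  mode <- match.arg(mode)
  if (mode == "helical") {
    if (is.null(pitch) || !is.numeric(pitch) || pitch <= 0)
      stop("helical mode requires a positive pitch factor")
  } else if (!is.null(pitch)) {
    stop("pitch is only meaningful for helical mode")
  }
  if (total_mas <= 0) stop("total_mas must be positive")
  structure(list(mode = mode, pitch = pitch,
                 views_per_rotation = as.integer(views_per_rotation),
                 total_mas = total_mas, rotation_time = rotation_time,
                 z_start = z_start, z_end = z_end),
            class = "ct_protocol")
}

#' @export
print.ct_protocol <- function(x, ...) {
  cat(sprintf("CT protocol '%s'%s: %d views/rotation/spot, %g mAs/rotation\n",
              x$mode,
              if (!is.null(x$pitch)) sprintf(" pitch %g", x$pitch) else "",
              x$views_per_rotation, x$total_mas))
  invisible(x)
}

#' Build the time-ordered view schedule for a scan
#'
#' Views are spaced exactly `2*pi/views_per_rotation` apart per spot. An
#' axial full scan covers one rotation; an axial half scan covers 180 degrees
#' plus the full fan angle (the minimum complete short-scan set, about 234.5
#' degrees at full scale); a helical scan advances the table by
#' `pitch * collimation` per rotation from `z_start` to `z_end`. For the
#' dual-spot geometry the two spots fire in strict alternation, the second
#' spot offset by half a view period, doubling the view count; the per-view
#' tube load is halved so the total flux per rotation stays at
#' `total_mas`.
#'
#' @param geometry A `ct_geometry`.
#' @param protocol A `ct_protocol`.
#' @return A `ct_schedule`: data frame with columns `view` (time order),
#'   `beta` (gantry angle, rad), `spot` (1-based index into
#'   `geometry$spots`), `z_table` (mm) and `mas`.
#' @export
build_view_schedule <- function(geometry, protocol) {
  stopifnot(inherits(geometry, "ct_geometry"),
            inherits(protocol, "ct_protocol"))
  vpr <- protocol$views_per_rotation
  nspot <- nrow(geometry$spots)
  dbeta <- 2 * pi / vpr
  mas_view <- protocol$total_mas / (vpr * nspot)
  if (protocol$mode == "axial_full") {
    n <- vpr
    betas <- (seq_len(n) - 1) * dbeta
    zt <- rep(0, n)
  } else if (protocol$mode == "axial_half") {
    rng <- pi + geometry$fan_angle
    n <- floor(rng / dbeta + 1e-9) + 1
    betas <- (seq_len(n) - 1) * dbeta
    zt <- rep(0, n)
  } else {
    if (is.null(protocol$z_start) || is.null(protocol$z_end))
      stop("helical mode requires z_start and z_end")
    feed <- protocol$pitch * geometry$collimation
    span <- protocol$z_end - protocol$z_start
    if (span < geometry$collimation)
      stop("helical range (", span, " mm) is shorter than one collimation (",
           geometry$collimation, " mm)")
    n <- floor(span / feed * vpr + 1e-9) + 1
    betas <- (seq_len(n) - 1) * dbeta
    zt <- protocol$z_start + feed * betas / (2 * pi)
  }
  sched <- data.frame(beta = betas, spot = 1L,
                      z_table = zt, mas = mas_view)
  if (nspot == 2L) {
    s2 <- sched
    s2$beta <- s2$beta + dbeta / 2
    s2$spot <- 2L
    if (protocol$mode == "helical")
      s2$z_table <- protocol$z_start + (protocol$pitch * geometry$collimation) *
        s2$beta / (2 * pi)
    sched <- rbind(sched, s2)
    sched <- sched[order(sched$beta), ]
  }
  sched$view <- seq_len(nrow(sched))
  rownames(sched) <- NULL
  sched <- sched[, c("view", "beta", "spot", "z_table", "mas")]
  class(sched) <- c("ct_schedule", "data.frame")
  attr(sched, "mode") <- protocol$mode
  attr(sched, "views_per_rotation") <- vpr
  attr(sched, "feed") <- if (protocol$mode == "helical")
    protocol$pitch * geometry$collimation else 0
  sched
}
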