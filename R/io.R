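#' Write / read a reconstructed or ground-truth volume
#'
#' Volumes are stored as NIfTI (voxel size in the header) with a JSON
#' sidecar (`<path>.json`) echoing grid and provenance for reproducibility.
#'
#' @param volume A `ct_volume`.
#' @param path Output path (`.nii` / `.nii.gz`).
#' @return `path`, invisibly (`read_volume` returns a `ct_volume`).
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  g <- volume$grid
  dz <- if (length(g$slice_z) > 1) diff(g$slice_z[1:2]) else
    g$slice_thickness
  img <- RNifti::asNifti(volume$data, pixdim = c(g$pix, g$pix, abs(dz)))
  RNifti::writeNifti(img, path)
  side <- volume$provenance
  side$weight_sum <- NULL
  jsonlite::write_json(list(grid = unclass(g), provenance = side),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- structure(side$grid, class = "ct_grid")
  # NIfTI drops trailing singleton dimensions; restore from the grid
  new_ct_volume(array(as.numeric(img),
                      c(grid$nx, grid$ny, length(grid$slice_z))),
                grid, as.list(side$provenance))
}

#' Write / read a sinogram
#'
#' The projection array is stored as NIfTI (channel, row, view) and the view
#' schedule plus geometry/protocol/flux/seed metadata as a JSON sidecar, so
#' a scan can be round-tripped and reconstructed later.
#'
#' @param sinogram A `ct_sinogram`.
#' @param path Output path (`.nii` / `.nii.gz`).
#' @return `path`, invisibly (`read_sinogram` returns a `ct_sinogram`).
#' @export
write_sinogram <- function(sinogram, path) {
  stopifnot(inherits(sinogram, "ct_sinogram"))
  RNifti::writeNifti(RNifti::asNifti(sinogram$projections), path)
  sched <- as.data.frame(sinogram$schedule)
  meta <- list(
    geometry = sinogram$geometry$name,
    geometry_scale = sinogram$geometry$scale,
    protocol = unclass(sinogram$protocol),
    flux = unclass(sinogram$flux),
    mu_water = sinogram$mu_water,
    seed = sinogram$seed, noisy = sinogram$noisy,
    schedule = sched,
    schedule_mode = attr(sinogram$schedule, "mode"),
    schedule_feed = attr(sinogram$schedule, "feed"),
    views_per_rotation = attr(sinogram$schedule, "views_per_rotation"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  img <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  geom <- make_geometry(meta$geometry, scale = meta$geometry_scale)
  pr <- meta$protocol
  protocol <- scan_protocol(pr$mode, pitch = pr$pitch,
                            views_per_rotation = pr$views_per_rotation,
                            total_mas = pr$total_mas,
                            rotation_time = pr$rotation_time,
                            z_start = pr$z_start, z_end = pr$z_end)
  sched <- meta$schedule
  class(sched) <- c("ct_schedule", "data.frame")
  attr(sched, "mode") <- meta$schedule_mode
  attr(sched, "feed") <- meta$schedule_feed
  attr(sched, "views_per_rotation") <- meta$views_per_rotation
  fl <- meta$flux
  flux <- flux_model(fl$photons_per_mas, fl$bowtie, fl$noise,
                     fl$bowtie_water_diameter, fl$mu_ref, fl$floor_counts)
  structure(list(projections = array(as.numeric(img), dim(img)),
                 schedule = sched, geometry = geom, protocol = protocol,
                 flux = flux, mu_water = meta$mu_water,
                 seed = meta$seed, noisy = isTRUE(meta$noisy)),
            class = "ct_sinogram")
}

#' Serialize a phantom to / from YAML
#'
#' @param phantom A `ct_phantom`.
#' @param path YAML file path.
#' @return `path` invisibly; `read_phantom_yaml` returns a `ct_phantom`.
#' @export
write_phantom_yaml <- function(phantom, path) {
  stopifnot(inherits(phantom, "ct_phantom"))
  yaml::write_yaml(list(mu_water = phantom$mu_water,
                        primitives = phantom$primitives), path,
                  precision = 15)
  invisible(path)
}

#' @rdname write_phantom_yaml
#' @export
read_phantom_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  prims <- as.data.frame(y$primitives)
  ct_phantom(prims, mu_water = y$mu_water)
}

#' Write the image-quality report
#'
#' Writes the tidy report as JSON and a wide comparison table as CSV: one
#' row per protocol/slice, one column per geometry with the noise value and
#' (for non-reference geometries) the percent deviation from the reference
#' in parentheses; dual-entry slices are joined with "/".
#'
#' @param report Tidy data frame from [run_study()] (columns `geometry`,
#'   `protocol`, `slice`, `side`, `z`, `noise`, `artifact`, `uniformity`).
#' @param csv_path,json_path Output paths.
#' @param reference Reference geometry for the percent deviations.
#' @return The CSV path, invisibly.
#' @export
write_iq_report <- function(report, csv_path, json_path = NULL,
                            reference = "VCT40") {
  if (!is.null(json_path))
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA)
  geoms <- unique(report$geometry)
  keys <- unique(report[, c("protocol", "slice")])
  fmt_cell <- function(rows, refval) {
    if (!nrow(rows)) return("")
    vals <- vapply(seq_len(nrow(rows)), function(i) {
      v <- rows$noise[i]
      if (!is.null(refval) && !is.na(refval) && length(refval) == 1 &&
          rows$geometry[i] != reference)
        sprintf("%.1f (%+.1f%%)", v, percent_deviation(v, refval))
      else sprintf("%.1f", v)
    }, character(1))
    paste(vals, collapse = "/")
  }
  tab <- data.frame(protocol = keys$protocol, slice = keys$slice)
  for (g in geoms) {
    tab[[g]] <- vapply(seq_len(nrow(keys)), function(i) {
      rows <- report[report$geometry == g &
                       report$protocol == keys$protocol[i] &
                       report$slice == keys$slice[i], , drop = FALSE]
      refrows <- report[report$geometry == reference &
                          report$protocol == keys$protocol[i] &
                          report$slice == keys$slice[i], , drop = FALSE]
      refval <- if (nrow(refrows)) mean(refrows$noise) else NA_real_
      fmt_cell(rows, refval)
    }, character(1))
  }
  write.csv(tab, csv_path, row.names = FALSE)
  invisible(csv_path)
}
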