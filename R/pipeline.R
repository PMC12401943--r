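#' Study configuration
#'
#' @param geometries Character vector of geometry names to simulate.
#' @param protocols Character vector of protocol labels: `"axial_half"`,
#'   `"axial_full"` or `"helical_<pitch>"` (e.g. `"helical_0.5"`).
#' @param scale Desk-scale factor in (0, 1]: decimates detector channels,
#'   rows and views per rotation while preserving fan angle, collimation and
#'   the dual-spot 2x view ratio.
#' @param nx Reconstruction grid size (`nx` x `nx` over a 500 mm FOV).
#' @param seed Master seed (phantom tilts and noise realizations).
#' @param out_dir Output directory.
#' @param photons_per_mas Flux calibration constant.
#' @param noise Simulate a noisy run next to the noiseless one.
#' @param supersample Ground-truth voxelization supersampling.
#' @param phantom Named list of [helical_body_phantom()] overrides.
#' @return A `ct_study_config`.
#' @export
study_config <- function(geometries = c("VCT40", "VCT140", "DFSSD"),
                         protocols = c("axial_half", "helical_0.5",
                                       "helical_0.75", "helical_1.0"),
                         scale = 0.25, nx = 256L, seed = 17L,
                         out_dir = file.path(tempdir(), "dfsct_study"),
                         photons_per_mas = 2e5, noise = TRUE,
                         supersample = 2L, phantom = list()) {
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  ok <- grepl("^(axial_half|axial_full|helical_[0-9.]+)$", protocols)
  if (!all(ok)) stop("malformed protocol label(s): ",
                     paste(protocols[!ok], collapse = ", "))
  structure(list(geometries = geometries, protocols = protocols,
                 scale = scale, nx = as.integer(nx), seed = as.integer(seed),
                 out_dir = out_dir, photons_per_mas = photons_per_mas,
                 noise = noise, supersample = as.integer(supersample),
                 phantom = phantom),
            class = "ct_study_config")
}

#' Read / write a study configuration as YAML
#' @param path YAML file.
#' @param config A `ct_study_config`.
#' @return A `ct_study_config` (`write_study_config`: `path`, invisibly).
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(study_config, y)
}

#' @rdname read_study_config
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

scaled_views <- function(scale) max(16L, as.integer(round(984 * scale)))

# slice set used for helical comparisons: a fixed absolute-z set shared by
# all geometries (helical coverage is unbounded, so matched z is the natural
# matching)
helical_eval_slices <- function() {
  data.frame(label = c("edge", "intermediate", "center", "intermediate",
                       "edge"),
             side = c(-1, -1, 0, 1, 1),
             z = c(-69, -35, 0, 35, 69))
}

parse_protocol <- function(label, geometry, scale, slice_z) {
  vpr <- scaled_views(scale)
  if (label %in% c("axial_half", "axial_full"))
    return(scan_protocol(label, views_per_rotation = vpr))
  pitch <- as.numeric(sub("^helical_", "", label))
  feed <- pitch * geometry$collimation
  # table range covering every slice's full on-detector window
  margin <- geometry$collimation / 2 +
    max(abs(geometry$spots$z_offset)) *
      (1 + geometry$R / (geometry$R + geometry$D)) + feed * 0.05
  z0 <- min(slice_z) - margin
  z1 <- max(slice_z) + margin
  if (z1 - z0 < geometry$collimation) {
    mid <- (z0 + z1) / 2
    z0 <- mid - geometry$collimation / 2
    z1 <- mid + geometry$collimation / 2
  }
  scan_protocol("helical", pitch = pitch, views_per_rotation = vpr,
                z_start = z0, z_end = z1)
}

# max |smoothed (recon - truth) profile| at y = 0 within the central body
uniformity_deviation <- function(clean, truth, slice = 1L) {
  d <- clean$data[, , slice] - truth$data[, , slice]
  pr <- line_profile(d, y = 0, window = 5L, grid = clean$grid)
  max(abs(pr$hu[abs(pr$x) <= 0.7 * 225]))
}

run_cell <- function(geom, label, phantom, config, out_cell) {
  slices <- if (grepl("^helical", label)) helical_eval_slices()
            else evaluation_slices(geom)
  protocol <- parse_protocol(label, geom, config$scale, slices$z)
  grid <- recon_grid(config$nx, fov = 500, slice_z = slices$z,
                     slice_thickness = geom$row_pitch_iso)
  flux_off <- flux_model(config$photons_per_mas, noise = FALSE)
  clean_sino <- simulate_scan(geom, phantom, protocol, flux_off)
  clean <- reconstruct(clean_sino, grid)
  truth <- voxelize(phantom, grid, supersample = config$supersample)
  noisy <- NULL
  if (config$noise) {
    flux_on <- flux_model(config$photons_per_mas, noise = TRUE)
    noisy_sino <- add_projection_noise(clean_sino, flux_on,
                                       seed = config$seed)
    noisy <- reconstruct(noisy_sino, grid)
  }
  dir.create(out_cell, recursive = TRUE, showWarnings = FALSE)
  write_sinogram(clean_sino, file.path(out_cell, "sinogram.nii.gz"))
  write_volume(clean, file.path(out_cell, "recon_noiseless.nii.gz"))
  if (!is.null(noisy))
    write_volume(noisy, file.path(out_cell, "recon_noisy.nii.gz"))
  write_volume(truth, file.path(out_cell, "ground_truth.nii.gz"))
  cell_figures(clean, noisy, truth, slices, out_cell)
  rows <- lapply(seq_len(nrow(slices)), function(i) {
    # single-source geometries are z-symmetric: report the non-negative side;
    # the dual-spot geometry reports both coverage-edge values
    if (slices$side[i] < 0 &&
        !(nrow(geom$spots) == 2L && slices$label[i] == "edge" &&
          !grepl("^helical", label))) return(NULL)
    mask <- artifact_mask(truth, phantom, slice = i)
    data.frame(
      geometry = geom$name, protocol = label, slice = slices$label[i],
      side = slices$side[i], z = slices$z[i],
      noise = if (!is.null(noisy))
        roi_noise(noisy, clean, slice = i, phantom = phantom) else NA_real_,
      artifact = artifact_score(clean, truth, mask, slice = i),
      uniformity = uniformity_deviation(clean, truth, slice = i))
  })
  do.call(rbind, rows)
}

cell_figures <- function(clean, noisy, truth, slices, out_cell) {
  win <- function(img) pmin(pmax((img - 40 + 200) / 400, 0), 1) # WW400/WL40
  grDevices::png(file.path(out_cell, "slices.png"),
                 width = 240 * nrow(slices), height = 260)
  op <- graphics::par(mfrow = c(1, nrow(slices)), mar = c(1, 1, 2, 1))
  for (i in seq_len(nrow(slices)))
    graphics::image(win(clean$data[, , i]), col = grDevices::gray.colors(256),
                    axes = FALSE, zlim = c(0, 1),
                    main = sprintf("%s z=%g", slices$label[i], slices$z[i]))
  graphics::par(op)
  grDevices::dev.off()
  iedge <- which(slices$label == "edge")[1]
  pr <- line_profile(clean, y = 0, window = 5L, slice = iedge)
  pt <- line_profile(truth, y = 0, window = 5L, slice = iedge)
  grDevices::png(file.path(out_cell, "profile_edge.png"), 640, 420)
  graphics::plot(pr$x, pr$hu, type = "l", xlab = "x (mm)", ylab = "HU",
                 main = "edge-slice profile (5-voxel moving average)")
  graphics::lines(pt$x, pt$hu, lty = 2)
  graphics::legend("topright", c("reconstruction", "ground truth"),
                   lty = 1:2, bty = "n")
  grDevices::dev.off()
}

#' Run the full comparative study
#'
#' Executes the geometry x protocol matrix of the study at the configured
#' scale: for each cell a noiseless and (optionally) a noisy acquisition are
#' simulated, reconstructed at the evaluation slices, and scored (ROI noise
#' differenced against the noiseless run, artifact RMSE against the
#' voxelized truth, profile uniformity deviation). Writes per-cell
#' sinograms, volumes and figures, the comparison table (CSV, with percent
#' deviations from VCT40 in parentheses) plus a tidy JSON report, and a
#' manifest with seeds and file checksums. Failures are recorded per cell
#' and the matrix continues.
#'
#' @param config A [study_config()].
#' @return Invisibly, a list with `report` (tidy data frame), `table_csv`,
#'   `manifest` and `errors`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "ct_study_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  phantom <- do.call(helical_body_phantom,
                     modifyList(list(seed = config$seed), config$phantom))
  write_phantom_yaml(phantom, file.path(config$out_dir, "phantom.yaml"))
  rows <- list(); errors <- list()
  for (gname in config$geometries) {
    geom <- make_geometry(gname, scale = config$scale)
    for (label in config$protocols) {
      cell <- paste(gname, label, sep = "_")
      out_cell <- file.path(config$out_dir, cell)
      res <- tryCatch(run_cell(geom, label, phantom, config, out_cell),
                      error = function(e) e)
      if (inherits(res, "error")) {
        errors[[cell]] <- conditionMessage(res)
        warning("cell ", cell, " failed: ", conditionMessage(res),
                call. = FALSE)
      } else rows[[cell]] <- res
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  csv <- file.path(config$out_dir, "iq_report.csv")
  write_iq_report(report, csv, file.path(config$out_dir, "iq_report.json"))
  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    package = "dfsct",
    version = as.character(utils::packageVersion("dfsct")),
    config = unclass(config),
    seed = config$seed,
    errors = errors,
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(list(report = report, table_csv = csv,
                 manifest = file.path(config$out_dir, "manifest.json"),
                 errors = errors))
}
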