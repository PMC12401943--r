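#' ROI noise (HU standard deviation)
#'
#' Standard deviation of HU inside a circular ROI of a slice, after
#' subtracting the matched noiseless reconstruction so that noise is
#' isolated from deterministic artifact structure. If a phantom is given,
#' the ROI is rejected when it overlaps any insert.
#'
#' @param noisy,clean `ct_volume`s on the same grid (clean may be `NULL` to
#'   measure raw standard deviation).
#' @param slice Slice index.
#' @param center ROI center `c(x, y)` in mm (default 60 mm above the phantom
#'   center, inside the uniform torso region).
#' @param radius ROI radius, mm (default a 40 mm circle).
#' @param phantom Optional `ct_phantom` used to verify the ROI avoids
#'   inserts.
#' @return Noise standard deviation in HU.
#' @export
roi_noise <- function(noisy, clean = NULL, slice = 1L, center = c(0, 60),
                      radius = 20, phantom = NULL) {
  stopifnot(inherits(noisy, "ct_volume"))
  if (!is.null(phantom)) {
    ins <- phantom$primitives[-1, , drop = FALSE]
    if (nrow(ins)) {
      th <- seq(0, 2 * pi, length.out = 33)[-33]
      rr <- c(0, radius / 2, radius)
      pts <- do.call(rbind, lapply(rr, function(r)
        cbind(center[1] + r * cos(th), center[2] + r * sin(th),
              noisy$grid$slice_z[slice])))
      dmu <- cpp_point_mu(prim_matrix(
        ct_phantom(rbind(phantom$primitives[1, ], ins),
                   mu_water = phantom$mu_water,
                   check_containment = FALSE)), pts) -
        cpp_point_mu(prim_matrix(ct_phantom(phantom$primitives[1, ],
                                            mu_water = phantom$mu_water,
                                            check_containment = FALSE)), pts)
      if (any(abs(dmu) > 1e-12))
        stop("ROI overlaps a phantom insert; move or shrink the ROI")
    }
  }
  img <- noisy$data[, , slice]
  if (!is.null(clean)) {
    stopifnot(inherits(clean, "ct_volume"),
              all(dim(clean$data)[1:2] == dim(noisy$data)[1:2]))
    img <- img - clean$data[, , slice]
  }
  co <- grid_coords(noisy$grid)
  m <- outer(co$x - center[1], co$y - center[2],
             function(dx, dy) dx^2 + dy^2) <= radius^2
  sd(img[m])
}

#' Percent deviation from a reference value
#'
#' `100 * (value - reference) / reference`, reported to one decimal, the
#' convention used for the parenthesized noise deviations of the study's
#' comparison table.
#'
#' @param value,reference Numeric; `reference` must be nonzero.
#' @param digits Decimals to round to (1 by default; `NA` for no rounding).
#' @return Percent deviation(s).
#' @export
percent_deviation <- function(value, reference, digits = 1) {
  if (any(reference == 0)) stop("reference value must be nonzero")
  pd <- 100 * (value - reference) / reference
  if (!is.na(digits)) pd <- round(pd, digits)
  pd
}

#' Maximum absolute noise deviation versus a reference geometry
#'
#' Takes a tidy noise report (one row per geometry/slice measurement) and
#' returns the maximum absolute percent deviation of `geometry`'s slice
#' noise from the reference geometry's matched slice label. Slice labels
#' with several measurements (the dual-spot geometry reports one edge value
#' per coverage end) contribute all their values.
#'
#' @param report Data frame with columns `geometry`, `slice` and `noise`.
#' @param geometry Geometry to score.
#' @param reference Reference geometry (default `"VCT40"`).
#' @return Maximum absolute percent deviation (%).
#' @export
max_noise_deviation <- function(report, geometry, reference = "VCT40") {
  stopifnot(all(c("geometry", "slice", "noise") %in% names(report)))
  tst <- report[report$geometry == geometry, ]
  ref <- report[report$geometry == reference, ]
  if (!nrow(tst) || !nrow(ref))
    stop("report lacks rows for ", geometry, " and/or ", reference)
  if (!all(tst$slice %in% ref$slice))
    stop("missing reference slices: ",
         paste(setdiff(tst$slice, ref$slice), collapse = ", "))
  devs <- vapply(seq_len(nrow(tst)), function(i) {
    r <- ref$noise[match(tst$slice[i], ref$slice)]
    abs(percent_deviation(tst$noise[i], r))
  }, numeric(1))
  max(devs)
}

#' Horizontal line profile with moving-average smoothing
#'
#' HU values along a horizontal line of a slice, smoothed by a centered
#' moving average of the given (odd) width; windows shrink symmetrically at
#' the profile ends.
#'
#' @param volume A `ct_volume` (or a plain matrix plus `grid`).
#' @param y Line position in mm (nearest grid row is used).
#' @param window Moving-average width in voxels (odd; 1 = raw profile).
#' @param slice Slice index.
#' @param grid Required when `volume` is a plain matrix.
#' @return Data frame with `x` (mm) and `hu`.
#' @export
line_profile <- function(volume, y = 0, window = 5L, slice = 1L,
                         grid = NULL) {
  if (inherits(volume, "ct_volume")) {
    img <- volume$data[, , slice]
    grid <- volume$grid
  } else img <- volume
  if (window %% 2 != 1) stop("window must be odd")
  co <- grid_coords(grid)
  iy <- which.min(abs(co$y - y))
  raw <- img[, iy]
  h <- (window - 1) / 2
  n <- length(raw)
  sm <- vapply(seq_len(n), function(i) {
    k <- min(h, i - 1, n - i) # shrink symmetrically at the edges
    mean(raw[(i - k):(i + k)])
  }, numeric(1))
  data.frame(x = co$x, hu = sm)
}

#' Artifact score: masked RMSE against the voxelized ground truth
#'
#' Root-mean-square HU error of a noiseless reconstruction against the
#' voxelized truth within a mask, quantifying cone-beam shading/streaks and
#' image non-uniformity as one number per slice.
#'
#' @param image,truth Slice matrices (or `ct_volume`s, compared at `slice`)
#'   on matched grids.
#' @param mask Logical matrix; typically [artifact_mask()].
#' @param slice Slice index when volumes are passed.
#' @return RMSE in HU.
#' @export
artifact_score <- function(image, truth, mask, slice = 1L) {
  if (inherits(image, "ct_volume")) image <- image$data[, , slice]
  if (inherits(truth, "ct_volume")) truth <- truth$data[, , slice]
  stopifnot(all(dim(image) == dim(truth)), all(dim(mask) == dim(image)))
  if (!any(mask)) stop("empty artifact mask")
  sqrt(mean((image[mask] - truth[mask])^2))
}

#' Scoring mask for artifact RMSE
#'
#' Interior of the torso (background ellipse shrunk by `shrink`) minus the
#' inserts dilated by `dilate` voxels, so insert edge gradients do not
#' dominate the score.
#'
#' @param truth Ground-truth `ct_volume` (from [voxelize()]).
#' @param phantom The `ct_phantom` that produced it.
#' @param slice Slice index.
#' @param shrink Fractional shrink of the body outline.
#' @param dilate Dilation radius (voxels) around inserts.
#' @param hu_threshold |HU| above which a voxel counts as insert.
#' @return Logical `nx x ny` matrix.
#' @export
artifact_mask <- function(truth, phantom, slice = 1L, shrink = 0.8,
                          dilate = 2L, hu_threshold = 50) {
  bg <- phantom$primitives[1, ]
  co <- grid_coords(truth$grid)
  body <- outer(co$x, co$y, function(x, y)
    (x - bg$cx)^2 / (shrink * bg$p1)^2 + (y - bg$cy)^2 / (shrink * bg$p2)^2) <= 1
  ins <- abs(truth$data[, , slice]) > hu_threshold
  body & !dilate_mask(ins, dilate)
}

dilate_mask <- function(m, r) {
  if (r < 1) return(m)
  out <- m
  nx <- nrow(m); ny <- ncol(m)
  for (dx in -r:r) for (dy in -r:r) {
    if (dx == 0 && dy == 0) next
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    xt <- max(1, 1 - dx):min(nx, nx - dx)
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    yt <- max(1, 1 - dy):min(ny, ny - dy)
    out[xt, yt] <- out[xt, yt] | m[xs, ys]
  }
  out
}
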