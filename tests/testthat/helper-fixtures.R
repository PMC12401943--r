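# shared fixtures: small phantoms and geometries used across test files

water_phantom <- function(radius = 150, half_length = 250)
  water_cylinder_phantom(radius = radius, half_length = half_length)

# a z-invariant phantom (long z-aligned rods in the torso) for fan-beam
# limit checks: every detector row sees identical data
flat_rod_phantom <- function() {
  bg <- data.frame(kind = "elliptic_cylinder", cx = 0, cy = 0, cz = 0,
                   p1 = 225, p2 = 150, p3 = 300, ux = 0, uy = 0, uz = 1,
                   delta_mu = 0.0193, material = "water")
  rods <- do.call(rbind, lapply(c(0, 120, 240), function(deg) {
    phi <- deg * pi / 180
    data.frame(kind = "circular_rod",
               cx = 120 * cos(phi), cy = 80 * sin(phi), cz = 0,
               p1 = 10, p2 = 290, p3 = 0, ux = 0, uy = 0, uz = 1,
               delta_mu = 0.9 * 0.0193, material = "teflon")
  }))
  ct_phantom(rbind(bg, rods), mu_water = 0.0193)
}

roi_mask <- function(grid, center = c(0, 0), radius = 25) {
  co <- expand.grid(x = (seq_len(grid$nx) - 1 - (grid$nx - 1) / 2) * grid$pix,
                    y = (seq_len(grid$ny) - 1 - (grid$ny - 1) / 2) * grid$pix)
  matrix((co$x - center[1])^2 + (co$y - center[2])^2 <= radius^2,
         grid$nx, grid$ny)
}

quiet_flux <- function(...) flux_model(noise = FALSE, ...)
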