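# shared fixtures: small grids and a coarse, fast subject configuration

# coarse subject: same anatomy as the default generator but 6 x 6 x 5 mm
# voxels, so basis assembly and solves run in well under a second
coarse_config <- function(seed = 7, ...) {
  subject_config(seed = seed, spacing = c(6, 6, 5), ...)
}

# tiny constant-geometry field map + all-true mask
tiny_field <- function(values, dims = c(4, 4, 4), spacing = c(2, 2, 2)) {
  field_map(array(values, dims), spacing = spacing)
}

tiny_mask <- function(dims = c(4, 4, 4), spacing = c(2, 2, 2),
                      data = TRUE) {
  brain_mask(array(data, dims), spacing = spacing)
}

# internal geometry helpers, re-exposed for tests
grid_geometry_for_test <- function(spacing, fov) {
  unicshim:::grid_geometry(spacing, fov)
}

voxel_centers_for_test <- function(geom, which = NULL) {
  unicshim:::voxel_centers(geom, which)
}

# random unit vector
runit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# random evaluation points at 20-150 mm from a loop center
points_near_loop <- function(n, center, r_min = 20, r_max = 150) {
  r <- runif(n, r_min, r_max)
  dir <- matrix(rnorm(3 * n), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  sweep(dir * r, 2, center, "+")
}

# random points kept at least `min_wire` mm away from the loop's wire ring
points_near_wire <- function(n, loop, min_wire = 20, r_min = 20,
                             r_max = 150) {
  out <- matrix(0, 0, 3)
  while (nrow(out) < n) {
    cand <- points_near_loop(2 * n, loop$center, r_min, r_max)
    rel <- sweep(cand, 2, loop$center)
    zu <- rel %*% loop$normal
    rho <- sqrt(pmax(0, rowSums(rel^2) - zu^2))
    dw <- sqrt((rho - loop$radius)^2 + zu^2)
    out <- rbind(out, cand[dw >= min_wire, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}
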