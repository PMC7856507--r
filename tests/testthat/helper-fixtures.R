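# geometric fixtures built in code

# solid sphere mask on an isotropic grid, centred mid-grid
sphere_mask <- function(radius_mm, voxel_mm = 1, margin_mm = 6,
                        name = "body") {
  half <- ceiling((radius_mm + margin_mm) / voxel_mm)
  n <- 2L * half + 1L
  coord <- (seq_len(n) - 1 - half) * voxel_mm
  cx <- array(coord, c(n, n, n))
  cy <- aperm(cx, c(2, 1, 3))
  cz <- aperm(cx, c(3, 2, 1))
  structure_mask(cx^2 + cy^2 + cz^2 <= radius_mm^2, rep(voxel_mm, 3),
                 name = name)
}

sphere_band_cc <- function(outer_mm, inner_mm) {
  4 * pi / 3 * (outer_mm^3 - inner_mm^3) / 1000
}

# uniform-dose grid over given dims
uniform_grid <- function(dose, dims = c(10, 10, 10), voxel_mm = 1) {
  dose_grid(array(dose, dims), rep(voxel_mm, 3))
}

full_mask <- function(dims = c(10, 10, 10), voxel_mm = 1) {
  structure_mask(array(TRUE, dims), rep(voxel_mm, 3))
}

# random dose grid + mask pair for oracle checks
random_grid_mask <- function(dims, voxel_mm = 1, max_gy = 70,
                             p_mask = 0.6) {
  g <- dose_grid(array(stats::runif(prod(dims), 0, max_gy), dims),
                 rep(voxel_mm, 3))
  m <- structure_mask(array(stats::runif(prod(dims)) < p_mask, dims),
                      rep(voxel_mm, 3))
  list(grid = g, mask = m)
}

# random step-function cumulative DVH (edges from 0, non-increasing volume)
random_dvh <- function(n_bins = 40, vmax_cc = 20, dmax_gy = 70) {
  edges <- seq(0, dmax_gy, length.out = n_bins)
  vols <- sort(stats::runif(n_bins - 1, 0, vmax_cc), decreasing = TRUE)
  as_dvh(edges, c(vols, 0))
}
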