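test_that("dose_grid and structure_mask validate their invariants", {
  expect_error(dose_grid(array(-1, c(2, 2, 2)), c(1, 1, 1)), ">= 0")
  expect_error(dose_grid(array(1, c(2, 2, 2)), c(1, 0, 1)), "spacing")
  expect_error(dose_grid(matrix(1, 2, 2), c(1, 1, 1)), "3-D")
  g <- dose_grid(array(2, c(4, 4, 4)), c(1.5, 1.5, 3))
  expect_equal(voxel_volume_cc(g), 1.5 * 1.5 * 3 / 1000)
  m <- structure_mask(array(TRUE, c(4, 4, 4)), c(1.5, 1.5, 3))
  expect_equal(mask_volume_cc(m), 64 * 1.5 * 1.5 * 3 / 1000)
})

test_that("congruence check names the mismatching field", {
  a <- uniform_grid(1, c(4, 4, 4))
  expect_error(cumulative_dvh(a, full_mask(c(5, 4, 4))), "dim")
  expect_error(cumulative_dvh(a, full_mask(c(4, 4, 4), voxel_mm = 2)),
               "spacing")
  b <- structure_mask(array(TRUE, c(4, 4, 4)), c(1, 1, 1),
                      origin = c(1, 0, 0))
  expect_error(cumulative_dvh(a, b), "origin")
})

test_that("sphere shells reproduce analytic volumes within voxelization tolerance", {
  body <- sphere_mask(50, voxel_mm = 1)
  sh <- build_shells(body, list(c(0, 2), c(2, 4)))
  expect_equal(mask_volume_cc(sh$shell_0_2), sphere_band_cc(50, 48),
               tolerance = 0.05)
  expect_equal(mask_volume_cc(sh$shell_2_4), sphere_band_cc(48, 46),
               tolerance = 0.05)
  # disjoint, subsets of body, superficial shell touches the boundary
  expect_false(any(sh$shell_0_2$voxels & sh$shell_2_4$voxels))
  expect_true(all(sh$shell_0_2$voxels <= body$voxels))
  expect_true(all(sh$shell_2_4$voxels <= body$voxels))
})

test_that("shell bands tile the eroded body exactly", {
  set.seed(7)
  body <- sphere_mask(20, voxel_mm = 1, margin_mm = 4)
  sh <- build_shells(body, list(c(0, 2), c(2, 4)))
  depth <- depth_below_surface(body)
  eroded4 <- body$voxels & depth > 4
  union <- sh$shell_0_2$voxels | sh$shell_2_4$voxels
  expect_identical(union, body$voxels & !eroded4)
})

test_that("a half-space slab yields exactly the top layers", {
  slab <- array(FALSE, c(20, 20, 20))
  slab[, , 1:15] <- TRUE
  sh <- build_shells(structure_mask(slab, c(1, 1, 1)), list(c(0, 2)))
  z <- which(sh$shell_0_2$voxels, arr.ind = TRUE)[, 3]
  expect_setequal(unique(z), c(14, 15))
  expect_equal(sum(sh$shell_0_2$voxels), 2 * 400)
})

test_that("degenerate shell inputs error", {
  one <- array(FALSE, c(9, 9, 9)); one[5, 5, 5] <- TRUE
  expect_error(build_shells(structure_mask(one, c(1, 1, 1))),
               "too small to erode")
  expect_error(build_shells(structure_mask(array(FALSE, c(5, 5, 5)),
                                           c(1, 1, 1))), "empty")
  big <- structure_mask(array(TRUE, c(10, 10, 10)), c(5, 5, 5))
  expect_error(build_shells(big, list(c(0, 2))), "axis x")
})

test_that("hole-filling removes internal cavities before depth is measured", {
  body <- sphere_mask(15, voxel_mm = 1, margin_mm = 4)
  holey <- body$voxels
  ctr <- (dim(holey)[1] + 1) / 2
  holey[ctr + (-2:2), ctr + (-2:2), ctr + (-2:2)] <- FALSE
  sh_holey <- build_shells(structure_mask(holey, c(1, 1, 1)))
  sh_solid <- build_shells(body)
  expect_identical(sh_holey$shell_0_2$voxels, sh_solid$shell_0_2$voxels)
})

test_that("cumulative DVH matches the voxelwise brute-force oracle", {
  set.seed(42)
  rg <- random_grid_mask(c(10, 10, 10))
  dvh <- cumulative_dvh(rg$grid, rg$mask, bin_width_gy = 0.5)
  doses <- rg$grid$values[rg$mask$voxels]
  vv <- voxel_volume_cc(rg$grid)
  for (t in sample(dvh$dose_gy, 100, replace = TRUE)) {
    expect_equal(dvh$volume_cc[match(t, dvh$dose_gy)],
                 sum(doses >= t) * vv, tolerance = 1e-12)
  }
  # conservation: differential bins sum to structure volume
  expect_equal(sum(differential_dvh(dvh)$volume_cc),
               attr(dvh, "total_volume_cc"), tolerance = 1e-9)
  # curve shape invariants
  expect_true(all(diff(dvh$volume_cc) <= 0))
  expect_equal(dvh$volume_cc[1], mask_volume_cc(rg$mask))
  expect_equal(dvh$volume_cc[nrow(dvh)], 0)
})

test_that("uniform and two-level DVHs give the expected steps", {
  dvh <- cumulative_dvh(uniform_grid(60), full_mask())
  expect_equal(dvh$volume_cc[dvh$dose_gy <= 60],
               rep(1, sum(dvh$dose_gy <= 60)))
  expect_equal(dvh$volume_cc[dvh$dose_gy > 60],
               rep(0, sum(dvh$dose_gy > 60)))
  vals <- array(30, c(10, 10, 20)); vals[, , 1:10] <- 60
  dvh2 <- cumulative_dvh(dose_grid(vals, c(1, 1, 1)),
                         full_mask(c(10, 10, 20)))
  vol_at <- function(dvh, dose) {
    dvh$volume_cc[which.min(abs(dvh$dose_gy - dose))]
  }
  expect_equal(vol_at(dvh2, 0), 2)
  expect_equal(vol_at(dvh2, 30.05), 1)
  expect_equal(vol_at(dvh2, 60.05), 0)
  expect_error(cumulative_dvh(uniform_grid(60),
                              structure_mask(array(FALSE, c(10, 10, 10)),
                                             c(1, 1, 1))), "empty")
})

test_that("dose at hottest area inverts the DVH", {
  dvh <- cumulative_dvh(uniform_grid(45.3), full_mask())
  expect_equal(dose_at_hottest_area(dvh, 0.05, 2), 45.3, tolerance = 0.06)
  # 4 cc at 50 Gy + 16 cc at 30 Gy; the 25 cm2 x 2 mm = 5 cm3 volume
  # reaches into the 30 Gy region
  vals <- array(30, c(10, 20, 100)); vals[, , 1:20] <- 50
  dvh2 <- cumulative_dvh(dose_grid(vals, c(1, 1, 1)),
                         full_mask(c(10, 20, 100)))
  expect_equal(dose_at_hottest_area(dvh2, 25, 2), 30, tolerance = 0.06)
  expect_error(dose_at_hottest_area(dvh2, 200, 2), "exceeds")
})

test_that("dose at hottest area is non-increasing in area", {
  set.seed(9)
  for (i in 1:5) {
    dvh <- random_dvh()
    areas <- seq(0.05, 50, length.out = 20)
    total <- attr(dvh, "total_volume_cc")
    areas <- areas[areas * 0.2 <= total]
    d <- vapply(areas, function(a) dose_at_hottest_area(dvh, a, 2),
                numeric(1))
    expect_true(all(diff(d) <= 1e-9))
  }
})

test_that("isodose area converts hot volume to area through thickness", {
  body <- sphere_mask(20, voxel_mm = 1, margin_mm = 4)
  sh <- build_shells(body, list(c(0, 2)))
  shell <- sh$shell_0_2
  cold <- uniform_grid(10, dim(shell$voxels))
  expect_equal(isodose_area(cold, shell)$area_cm2, 0)
  hot <- uniform_grid(50, dim(shell$voxels))
  expect_equal(isodose_area(hot, shell)$area_cm2,
               mask_volume_cc(shell) / 0.2)
  # 6 cm3 of a 2 mm shell at or above threshold -> 30 cm2
  vv <- voxel_volume_cc(hot)
  n_hot <- round(6 / vv)
  vals <- array(10, dim(shell$voxels))
  vals[which(shell$voxels)[seq_len(n_hot)]] <- 45
  part <- isodose_area(dose_grid(vals, shell$spacing), shell)
  expect_equal(part$area_cm2, 30, tolerance = 0.01)
  expect_equal(sum(part$mask$voxels), n_hot)
})

test_that("DVH CSV export is tidy long format", {
  dvh <- cumulative_dvh(uniform_grid(10), full_mask())
  path <- tempfile(fileext = ".csv")
  write_dvh_csv(list(shell = dvh), path)
  df <- utils::read.csv(path)
  expect_named(df, c("structure", "dose_gy", "volume_cc"))
  expect_equal(nrow(df), nrow(dvh))
  expect_equal(unique(df$structure), "shell")
})

test_that("NIfTI round trip preserves dose values and spacing", {
  g <- dose_grid(array(runif(4 * 5 * 6, 0, 60), c(4, 5, 6)),
                 c(1.5, 1.5, 1.5))
  path <- tempfile(fileext = ".nii.gz")
  write_dose_nifti(g, path)
  g2 <- read_dose_nifti(path)
  expect_equal(g2$values, g$values, tolerance = 1e-6)
  expect_equal(g2$spacing, g$spacing)
})
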