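#' Head-phantom specification
#'
#' Parameters of the synthetic spherical head phantom with an embedded
#' spherical target (PTV) and a plan-like dose distribution: prescription
#' dose inside the PTV with a smooth exponential lateral/depth falloff
#' outside it. The superficial scalp dose therefore increases with PTV size
#' and proximity to the surface, which drives the interpatient spread of
#' skin NTCP.
#'
#' @param head_radius_mm radius of the spherical head (default 80).
#' @param voxel_mm isotropic voxel edge length; must be <= 2 mm so 2-mm
#'   scalp shells stay resolvable.
#' @param ptv_radius_mm radius of the spherical PTV.
#' @param ptv_center_depth_mm depth of the PTV centre below the head
#'   surface (along the +x axis).
#' @param prescription_gy total prescribed dose (default 60, normo-
#'   fractionated at 2 Gy per fraction).
#' @param dose_falloff_mm distance over which dose falls to 1/e of the
#'   prescription outside the PTV (default 30).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(head_radius_mm = 80, voxel_mm = 2,
                         ptv_radius_mm = 30, ptv_center_depth_mm = 40,
                         prescription_gy = 60, dose_falloff_mm = 30) {
  if (voxel_mm > 2) {
    stop("`voxel_mm` must be <= 2 mm (scalp-shell resolvability)",
         call. = FALSE)
  }
  if (voxel_mm <= 0 || head_radius_mm <= 0 || ptv_radius_mm <= 0 ||
      dose_falloff_mm <= 0) {
    stop("phantom dimensions must be > 0", call. = FALSE)
  }
  if (prescription_gy < 0) stop("`prescription_gy` must be >= 0", call. = FALSE)
  # farthest PTV point from the head centre must stay inside the head
  offset <- head_radius_mm - ptv_center_depth_mm
  if (abs(offset) + ptv_radius_mm >= head_radius_mm) {
    stop("PTV extends outside the head", call. = FALSE)
  }
  structure(list(head_radius_mm = head_radius_mm, voxel_mm = voxel_mm,
                 ptv_radius_mm = ptv_radius_mm,
                 ptv_center_depth_mm = ptv_center_depth_mm,
                 prescription_gy = prescription_gy,
                 dose_falloff_mm = dose_falloff_mm),
            class = "phantom_spec")
}

#' Generate a head phantom with a plan-like base dose
#'
#' Builds the body and PTV masks and the electrode-free base dose grid for
#' a [phantom_spec()], plus the precomputed surface geometry (per-voxel
#' depth below the surface and unit directions of the superficial band)
#' used by [apply_enhancement()]. Fully deterministic.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `head_phantom`: list with `spec`, `body`,
#'   `ptv` (structure masks), `dose` (the base [dose_grid()]), `depth`
#'   (numeric array, mm), `center_mm`, and the surface band (`band_idx`,
#'   `band_dirs`, `band_depth`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  R <- spec$head_radius_mm
  vox <- spec$voxel_mm
  margin <- 4 * vox
  half <- ceiling((R + margin) / vox)
  n <- 2L * half + 1L
  coord <- (seq_len(n) - 1 - half) * vox # head centre at the middle voxel
  cx <- array(coord, dim = c(n, n, n))
  cy <- aperm(cx, c(2, 1, 3))
  cz <- aperm(cx, c(3, 2, 1))
  r2 <- cx^2 + cy^2 + cz^2
  body_vox <- r2 <= R^2
  body <- structure_mask(body_vox, rep(vox, 3), rep(-half * vox, 3), "body")

  ptv_center <- c(R - spec$ptv_center_depth_mm, 0, 0)
  dptv <- sqrt((cx - ptv_center[1])^2 + (cy - ptv_center[2])^2 +
                 (cz - ptv_center[3])^2)
  ptv <- structure_mask(dptv <= spec$ptv_radius_mm, rep(vox, 3),
                        rep(-half * vox, 3), "ptv")
  if (!any(ptv$voxels & body$voxels) || any(ptv$voxels & !body$voxels)) {
    stop("PTV outside the head", call. = FALSE)
  }

  excess <- pmax(dptv - spec$ptv_radius_mm, 0)
  dose_vals <- spec$prescription_gy * exp(-excess / spec$dose_falloff_mm)
  dose <- dose_grid(dose_vals, rep(vox, 3), rep(-half * vox, 3))

  depth <- depth_below_surface(body)
  band_max_mm <- 6
  band_idx <- which(body_vox & depth <= band_max_mm)
  rnorm_band <- sqrt(r2[band_idx])
  band_dirs <- cbind(cx[band_idx], cy[band_idx], cz[band_idx]) / rnorm_band
  structure(list(spec = spec, body = body, ptv = ptv, dose = dose,
                 depth = depth, center_mm = c(0, 0, 0),
                 band_idx = band_idx, band_dirs = band_dirs,
                 band_depth = depth[band_idx]),
            class = "head_phantom")
}

#' Transducer-array layout on the head surface
#'
#' Four arrays (anterior, posterior, left, right), each a 3 x 3 grid of
#' disk electrodes, placed on the spherical head surface. Each array has a
#' local tangent frame (major/minor axes); from fixation period to fixation
#' period the whole array is displaced in that plane by a zero-mean
#' bivariate normal offset with standard deviations 1.1 cm along the major
#' axis and 0.7 cm along the minor axis.
#'
#' @param electrode_diameter_mm diameter of one disk electrode (default 20).
#' @param pitch_mm centre-to-centre spacing of the 3 x 3 electrode grid.
#' @param placement_sd_major_cm,placement_sd_minor_cm placement-variation
#'   standard deviations along the principal axes (cm).
#' @param halo_radius_mm geodesic radius around the array centre within
#'   which the adhesive patch produces the smaller halo enhancement.
#' @return object of class `electrode_layout`.
#' @export
electrode_layout <- function(electrode_diameter_mm = 20, pitch_mm = 22,
                             placement_sd_major_cm = 1.1,
                             placement_sd_minor_cm = 0.7,
                             halo_radius_mm = 45) {
  normals <- rbind(anterior = c(0, 1, 0), posterior = c(0, -1, 0),
                   left = c(-1, 0, 0), right = c(1, 0, 0))
  # major variation axis: in-plane, chosen as the head's superior-inferior
  # great-circle direction for lateral arrays and left-right for the
  # anterior/posterior arrays
  major <- rbind(anterior = c(1, 0, 0), posterior = c(1, 0, 0),
                 left = c(0, 0, 1), right = c(0, 0, 1))
  minor <- t(vapply(seq_len(4), function(i) {
    v <- c(normals[i, 2] * major[i, 3] - normals[i, 3] * major[i, 2],
           normals[i, 3] * major[i, 1] - normals[i, 1] * major[i, 3],
           normals[i, 1] * major[i, 2] - normals[i, 2] * major[i, 1])
    v / sqrt(sum(v^2))
  }, numeric(3)))
  rownames(minor) <- rownames(normals)
  structure(list(normals = normals, major = major, minor = minor,
                 n_arrays = 4L, n_electrodes = 9L,
                 electrode_diameter_mm = electrode_diameter_mm,
                 pitch_mm = pitch_mm,
                 placement_sd_major_cm = placement_sd_major_cm,
                 placement_sd_minor_cm = placement_sd_minor_cm,
                 halo_radius_mm = halo_radius_mm),
            class = "electrode_layout")
}

#' Sample fixation-to-fixation array placements
#'
#' Draws per-array tangent-plane offsets for `n_fixation_periods`
#' re-fixations: independent zero-mean bivariate normal offsets with SDs
#' (1.1, 0.7) cm along each array's major/minor axes by default.
#'
#' @param layout an [electrode_layout()].
#' @param n_fixation_periods number of placements to draw (>= 1).
#' @param seed integer seed; placements are reproducible given the seed.
#' @return list of `n_fixation_periods` placement matrices (4 arrays x 2
#'   offsets, mm, columns `major`/`minor`).
#' @export
sample_placements <- function(layout, n_fixation_periods, seed) {
  stopifnot(inherits(layout, "electrode_layout"), n_fixation_periods >= 1)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  withr_seed(seed, draw_placements(layout, n_fixation_periods))
}

# evaluate `expr` under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Nominal (zero-offset) placement
#' @param layout an [electrode_layout()].
#' @return a 4 x 2 zero offset matrix.
#' @export
nominal_placement <- function(layout = electrode_layout()) {
  m <- matrix(0, layout$n_arrays, 2,
              dimnames = list(rownames(layout$normals), c("major", "minor")))
  m
}

#' Placement nearest the average position
#'
#' The virtually fixed array position used by scenario 3: the sampled
#' placement minimizing the summed squared tangent-plane distance to the
#' mean of all sampled placements (the "nearest to average" snap).
#'
#' @param placements list of placement matrices from [sample_placements()].
#' @return one placement matrix from the list.
#' @export
nearest_average_placement <- function(placements) {
  stopifnot(length(placements) >= 1)
  avg <- Reduce(`+`, placements) / length(placements)
  d2 <- vapply(placements, function(p) sum((p - avg)^2), numeric(1))
  placements[[which.min(d2)]]
}

#' Parametric electrode dose-enhancement model
#'
#' The dosimetric effect of the arrays on the superficial scalp is modelled
#' as a multiplicative dose gain confined to the surface: `buildup_gain`
#' directly under an electrode disk, the smaller `halo_gain` under the
#' adhesive patch outside the disks, both decaying linearly with depth to
#' zero at `decay_depth_mm` (enhancement never reaches beyond 6 mm). The
#' default gains keep the shell-average dose increase under the arrays
#' below 8.5% outside the hottest 1 cm^2.
#'
#' @param buildup_gain fractional surface dose increase under an electrode
#'   footprint (default 0.085).
#' @param halo_gain fractional increase under the array patch outside the
#'   disks (default 0.03).
#' @param decay_depth_mm depth (mm) at which the gain reaches zero
#'   (default 4).
#' @return object of class `enhancement_model`.
#' @export
enhancement_model <- function(buildup_gain = 0.085, halo_gain = 0.03,
                              decay_depth_mm = 4) {
  if (buildup_gain < 0 || halo_gain < 0) {
    stop("gains must be >= 0", call. = FALSE)
  }
  if (decay_depth_mm <= 0 || decay_depth_mm > 6) {
    stop("`decay_depth_mm` must lie in (0, 6]", call. = FALSE)
  }
  structure(list(buildup_gain = buildup_gain, halo_gain = halo_gain,
                 decay_depth_mm = decay_depth_mm),
            class = "enhancement_model")
}

# unit direction vectors of the 36 electrode centres (and 4 array centres)
# for one placement, on a sphere of radius R
electrode_directions <- function(layout, placement, R) {
  offs <- layout$pitch_mm * c(-1, 0, 1)
  grid <- expand.grid(u = offs, v = offs)
  elec <- vector("list", layout$n_arrays)
  array_dirs <- matrix(NA_real_, layout$n_arrays, 3)
  for (i in seq_len(layout$n_arrays)) {
    nrm <- layout$normals[i, ]
    u <- layout$major[i, ]
    v <- layout$minor[i, ]
    du <- placement[i, 1]
    dv <- placement[i, 2]
    ctr <- R * nrm + du * u + dv * v
    array_dirs[i, ] <- ctr / sqrt(sum(ctr^2))
    e <- t(vapply(seq_len(nrow(grid)), function(k) {
      p <- R * nrm + (du + grid$u[k]) * u + (dv + grid$v[k]) * v
      p / sqrt(sum(p^2))
    }, numeric(3)))
    elec[[i]] <- e
  }
  list(electrodes = do.call(rbind, elec), arrays = array_dirs)
}

#' Apply electrode dose enhancement for one placement
#'
#' Multiplies the base dose by (1 + gain) within the superficial band:
#' voxels whose geodesic surface position lies under an electrode disk get
#' the buildup gain, voxels under the array patch but outside the disks get
#' the halo gain, scaled by the linear depth profile. All other voxels are
#' returned bit-identical.
#'
#' @param phantom a [generate_phantom()] result.
#' @param placement a 4 x 2 offset matrix (mm), e.g. one element of
#'   [sample_placements()].
#' @param model an [enhancement_model()].
#' @param layout an [electrode_layout()].
#' @param base optional [dose_grid()] to enhance (defaults to the
#'   phantom's base dose); must be congruent with the phantom grid.
#' @return a [dose_grid()].
#' @export
apply_enhancement <- function(phantom, placement,
                              model = enhancement_model(),
                              layout = electrode_layout(),
                              base = phantom$dose) {
  stopifnot(inherits(phantom, "head_phantom"),
            inherits(model, "enhancement_model"))
  check_congruent(phantom$dose, base)
  gain <- enhancement_gain(phantom, placement, model, layout)
  vals <- base$values
  vals[phantom$band_idx] <- vals[phantom$band_idx] * (1 + gain)
  dose_grid(vals, base$spacing, base$origin)
}

# per-band-voxel fractional gain for one placement
enhancement_gain <- function(phantom, placement, model, layout) {
  R <- phantom$spec$head_radius_mm
  dirs <- electrode_directions(layout, placement, R)
  # geodesic distance on the sphere = R * angle between unit directions
  cos_elec <- phantom$band_dirs %*% t(dirs$electrodes)
  best <- cos_elec[cbind(seq_len(nrow(cos_elec)), max.col(cos_elec))]
  min_elec <- R * acos(pmin(1, best))
  cos_arr <- phantom$band_dirs %*% t(dirs$arrays)
  best_a <- cos_arr[cbind(seq_len(nrow(cos_arr)), max.col(cos_arr))]
  min_arr <- R * acos(pmin(1, best_a))
  under_disk <- min_elec <= layout$electrode_diameter_mm / 2
  in_patch <- min_arr <= layout$halo_radius_mm
  w <- pmax(0, 1 - phantom$band_depth / model$decay_depth_mm)
  w * ifelse(under_disk, model$buildup_gain,
             ifelse(in_patch, model$halo_gain, 0))
}
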