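#' Cumulative dose-volume histogram
#'
#' Reduces the doses of all voxels inside a structure to the cumulative DVH:
#' the volume (cm^3) receiving at least each dose level. The curve starts at
#' the full structure volume at 0 Gy and is non-increasing.
#'
#' @param grid a [dose_grid()].
#' @param mask a [structure_mask()] congruent with `grid`; must be non-empty.
#' @param bin_width_gy dose bin width in Gy (default 0.05, below the
#'   rounding precision of clinically reported hot-spot doses).
#' @return A tibble of class `dvh` with columns `dose_gy` (bin edges, from
#'   0 to just above the maximum dose) and `volume_cc` (volume at or above
#'   the edge dose), and attributes `total_volume_cc`, `structure`,
#'   `bin_width_gy`.
#' @examples
#' g <- dose_grid(array(60, dim = c(10, 10, 10)), c(1, 1, 1))
#' m <- structure_mask(array(TRUE, dim = c(10, 10, 10)), c(1, 1, 1))
#' dvh <- cumulative_dvh(g, m)
#' dose_at_hottest_area(dvh, area_cm2 = 0.05)
#' @export
cumulative_dvh <- function(grid, mask, bin_width_gy = 0.05) {
  stopifnot(inherits(grid, "dose_grid"), inherits(mask, "structure_mask"))
  if (bin_width_gy <= 0) stop("`bin_width_gy` must be > 0", call. = FALSE)
  check_congruent(grid, mask, "grid and mask")
  if (!any(mask$voxels)) {
    stop(sprintf("structure '%s' is empty", mask$name), call. = FALSE)
  }
  dvh_from_doses(grid$values[mask$voxels], voxel_volume_cc(grid),
                 bin_width_gy, structure = mask$name)
}

# cumulative DVH from a bare vector of voxel doses
dvh_from_doses <- function(doses, voxel_cc, bin_width_gy,
                           structure = "structure") {
  # last edge strictly above the maximum dose, so the curve always ends at 0
  edges <- seq(0, by = bin_width_gy,
               length.out = ceiling(max(doses) / bin_width_gy) + 2)
  # voxels with dose in [edge_k, edge_{k+1}) land in bin k; the tail-reversed
  # cumulative count is the volume at or above each edge
  bin <- findInterval(doses, edges)
  counts <- tabulate(bin, nbins = length(edges))
  vol <- rev(cumsum(rev(counts))) * voxel_cc
  new_dvh(tibble::tibble(dose_gy = edges, volume_cc = vol),
          total_volume_cc = length(doses) * voxel_cc,
          structure = structure,
          bin_width_gy = bin_width_gy)
}

new_dvh <- function(df, total_volume_cc, structure = "structure",
                    bin_width_gy = NA_real_) {
  structure(df,
            total_volume_cc = total_volume_cc,
            structure = structure,
            bin_width_gy = bin_width_gy,
            class = c("dvh", class(df)))
}

#' Construct a DVH directly from dose levels and volumes
#'
#' Useful for step-function DVHs given as dose/volume pairs (e.g. published
#' or tabulated histograms) rather than computed from a grid.
#'
#' @param dose_gy monotone increasing dose edges (Gy), starting at 0.
#' @param volume_cc non-increasing volumes at or above each edge (cm^3).
#' @return A `dvh` tibble.
#' @export
as_dvh <- function(dose_gy, volume_cc) {
  if (is.unsorted(dose_gy, strictly = TRUE)) {
    stop("`dose_gy` must be strictly increasing", call. = FALSE)
  }
  if (any(diff(volume_cc) > 1e-12)) {
    stop("`volume_cc` must be non-increasing", call. = FALSE)
  }
  bw <- if (length(dose_gy) > 1) min(diff(dose_gy)) else NA_real_
  new_dvh(tibble::tibble(dose_gy = as.numeric(dose_gy),
                         volume_cc = as.numeric(volume_cc)),
          total_volume_cc = volume_cc[1], bin_width_gy = bw)
}

#' Differential DVH bins
#'
#' Converts a cumulative DVH into differential bins with bin-centre doses,
#' the form needed by the power-mean (gEUD) and effective-volume reductions.
#' Bin volumes sum to the structure volume.
#'
#' @param dvh a `dvh`.
#' @return tibble with columns `dose_gy` (bin centre) and `volume_cc`.
#' @export
differential_dvh <- function(dvh) {
  d <- dvh$dose_gy
  v <- dvh$volume_cc
  n <- length(d)
  if (n < 2) {
    return(tibble::tibble(dose_gy = d, volume_cc = v))
  }
  tibble::tibble(dose_gy = (d[-n] + d[-1]) / 2,
                 volume_cc = v[-n] - v[-1]) # last edge volume is 0 by design
}

#' Minimum dose in the hottest area of a skin layer
#'
#' The hot-spot metric D_x-cm2: the lowest dose within the hottest `x` cm^2
#' of a layer of given thickness. The area is converted to a volume through
#' the layer thickness (area x thickness), and the DVH is inverted at that
#' volume with linear interpolation between bin edges.
#'
#' @param dvh a `dvh` for the layer.
#' @param area_cm2 hot-spot area in cm^2 (e.g. 0.05 or 25).
#' @param thickness_mm layer thickness in mm (default 2, the scalp-shell
#'   convention).
#' @return dose in Gy; non-increasing in `area_cm2`.
#' @export
dose_at_hottest_area <- function(dvh, area_cm2, thickness_mm = 2) {
  stopifnot(area_cm2 > 0, thickness_mm > 0)
  target_cc <- area_cm2 * thickness_mm / 10
  total <- attr(dvh, "total_volume_cc")
  if (target_cc > total + 1e-9) {
    stop(sprintf(
      "requested %.3g cm^2 x %.3g mm = %.3g cm^3 exceeds structure volume %.3g cm^3",
      area_cm2, thickness_mm, target_cc, total), call. = FALSE)
  }
  dose_at_volume(dvh, target_cc)
}

#' Dose at a given cumulative volume
#'
#' Inverts the cumulative DVH: the highest dose received by at least
#' `volume_cc` of the structure, interpolating linearly between bin edges.
#'
#' @param dvh a `dvh`.
#' @param volume_cc volume (cm^3), within (0, total volume].
#' @return dose in Gy.
#' @export
dose_at_volume <- function(dvh, volume_cc) {
  d <- dvh$dose_gy
  v <- dvh$volume_cc
  if (volume_cc <= v[length(v)]) return(d[length(d)])
  # last index where the curve still holds at least the target volume
  i <- max(which(v >= volume_cc))
  if (i == length(v) || v[i] == volume_cc) return(d[i])
  # interpolate on the falling segment between edges i and i+1
  d[i] + (v[i] - volume_cc) / (v[i] - v[i + 1]) * (d[i + 1] - d[i])
}

#' Area of a skin layer at or above a dose threshold
#'
#' The isodose-area metric behind V40 maps: the layer volume receiving at
#' least `threshold_gy`, converted to surface area through the layer
#' thickness, together with the voxel mask of that region for
#' visualisation or export.
#'
#' @param grid a [dose_grid()].
#' @param shell a [structure_mask()] for the layer; non-empty.
#' @param threshold_gy dose threshold in Gy (default 40).
#' @param thickness_mm layer thickness in mm (default 2).
#' @return list with `area_cm2` and `mask` (a `structure_mask` of shell
#'   voxels at or above the threshold).
#' @export
isodose_area <- function(grid, shell, threshold_gy = 40, thickness_mm = 2) {
  stopifnot(inherits(grid, "dose_grid"), inherits(shell, "structure_mask"))
  check_congruent(grid, shell, "grid and shell")
  if (!any(shell$voxels)) stop("empty shell mask", call. = FALSE)
  hot <- shell$voxels & grid$values >= threshold_gy
  m <- structure_mask(hot, shell$spacing, shell$origin,
                      name = sprintf("%s_ge_%gGy", shell$name, threshold_gy))
  list(area_cm2 = mask_volume_cc(m) / (thickness_mm / 10), mask = m)
}

#' Write DVHs to CSV
#'
#' Long-format export with columns `structure`, `dose_gy`, `volume_cc`.
#'
#' @param dvhs a single `dvh` or a named list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dvh_csv <- function(dvhs, path) {
  if (inherits(dvhs, "dvh")) dvhs <- list(dvhs)
  rows <- purrr::imap(dvhs, function(dvh, nm) {
    structure_name <- attr(dvh, "structure")
    if (!is.null(nm) && nzchar(nm) && !is.numeric(nm)) structure_name <- nm
    tibble::tibble(structure = structure_name,
                   dose_gy = dvh$dose_gy, volume_cc = dvh$volume_cc)
  })
  utils::write.csv(dplyr::bind_rows(rows), path, row.names = FALSE)
  invisible(path)
}

#' Plot a cumulative DVH
#'
#' @param object a `dvh`.
#' @param relative plot volume as percent of structure volume.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.dvh <- function(object, relative = FALSE, ...) {
  df <- tibble::as_tibble(object)
  ylab <- "Volume at or above dose (cm³)"
  if (relative) {
    df$volume_cc <- 100 * df$volume_cc / attr(object, "total_volume_cc")
    ylab <- "Volume at or above dose (%)"
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$dose_gy, .data$volume_cc)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "Dose (Gy)", y = ylab,
                  title = attr(object, "structure")) +
    ggplot2::theme_minimal()
}
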