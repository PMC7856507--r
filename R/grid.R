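#' 3-D dose grid
#'
#' A dose grid is a 3-D scalar raster of absorbed dose (Gy) on a regular
#' voxel lattice, the substrate for all accumulation, shell and DVH
#' operations. Axis order is (x, y, z); coordinates refer to voxel centres
#' in physical millimetres.
#'
#' @param values 3-D numeric array of voxel doses in Gy; all values must be
#'   non-negative.
#' @param spacing numeric length-3, voxel edge lengths in mm (x, y, z);
#'   all strictly positive.
#' @param origin numeric length-3, physical position (mm) of the centre of
#'   voxel `[1, 1, 1]`.
#' @return An object of class `dose_grid`: a list with elements `values`,
#'   `spacing`, `origin`.
#' @examples
#' g <- dose_grid(array(2, dim = c(4, 4, 4)), spacing = c(1, 1, 1))
#' voxel_volume_cc(g)
#' @export
dose_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as_raster3d(values)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive voxel edge lengths (mm)",
         call. = FALSE)
  }
  if (length(origin) != 3 || any(!is.finite(origin))) {
    stop("`origin` must be a finite length-3 position (mm)", call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE) || anyNA(values)) {
    stop("dose values must be finite and >= 0 Gy", call. = FALSE)
  }
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "dose_grid")
}

#' Boolean structure mask
#'
#' A structure mask is a boolean raster congruent with a [dose_grid()],
#' marking the voxels belonging to a contoured structure (body, PTV, scalp
#' shell, ...).
#'
#' @param voxels 3-D logical array.
#' @param spacing,origin grid geometry, as in [dose_grid()].
#' @param name label for the structure.
#' @return An object of class `structure_mask`.
#' @examples
#' m <- structure_mask(array(TRUE, dim = c(4, 4, 4)), c(1, 1, 1),
#'                     name = "body")
#' mask_volume_cc(m)
#' @export
structure_mask <- function(voxels, spacing, origin = c(0, 0, 0),
                           name = "structure") {
  voxels <- as_raster3d(voxels, logical = TRUE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3 || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive voxel edge lengths (mm)",
         call. = FALSE)
  }
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 name = as.character(name)[1]),
            class = "structure_mask")
}

as_raster3d <- function(x, logical = FALSE) {
  if (is.null(dim(x))) stop("expected a 3-D array", call. = FALSE)
  if (length(dim(x)) != 3) stop("expected a 3-D array", call. = FALSE)
  if (logical) {
    storage.mode(x) <- "logical"
  } else {
    storage.mode(x) <- "double"
  }
  x
}

raster_of <- function(x) if (inherits(x, "dose_grid")) x$values else x$voxels

#' Voxel volume of a grid or mask, in cm^3
#' @param x a `dose_grid` or `structure_mask`.
#' @return scalar volume of one voxel (cm^3).
#' @export
voxel_volume_cc <- function(x) prod(x$spacing) / 1000

#' Structure volume in cm^3
#' @param mask a `structure_mask`.
#' @return voxel count times voxel volume (cm^3).
#' @export
mask_volume_cc <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  sum(mask$voxels) * voxel_volume_cc(mask)
}

# Two rasters are combinable only on exact metadata equality; a mismatch
# names the offending field so silent resampling can never happen.
check_congruent <- function(a, b, what = "grids") {
  if (!identical(dim(raster_of(a)), dim(raster_of(b)))) {
    stop(sprintf("incongruent %s: `dim` differs (%s vs %s)", what,
                 paste(dim(raster_of(a)), collapse = "x"),
                 paste(dim(raster_of(b)), collapse = "x")), call. = FALSE)
  }
  if (!identical(a$spacing, b$spacing)) {
    stop(sprintf("incongruent %s: `spacing` differs", what), call. = FALSE)
  }
  if (!identical(a$origin, b$origin)) {
    stop(sprintf("incongruent %s: `origin` differs", what), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %s voxels, spacing %s mm, dose %.2f-%.2f Gy\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> '%s': %d voxels (%.2f cm^3) of %s\n",
              x$name, sum(x$voxels), mask_volume_cc(x),
              paste(dim(x$voxels), collapse = "x")))
  invisible(x)
}

#' Physical voxel-centre coordinates along each axis
#' @param x a `dose_grid` or `structure_mask`.
#' @return list of numeric vectors `x`, `y`, `z` (mm).
#' @export
grid_coords <- function(x) {
  d <- dim(raster_of(x))
  list(x = x$origin[1] + (seq_len(d[1]) - 1) * x$spacing[1],
       y = x$origin[2] + (seq_len(d[2]) - 1) * x$spacing[2],
       z = x$origin[3] + (seq_len(d[3]) - 1) * x$spacing[3])
}

#' Read or write a dose grid as NIfTI
#'
#' Maps the internal axis-ordered array plus spacing onto a NIfTI-1 raster
#' via the RNifti package. Dose in Gy is stored as the voxel intensity.
#'
#' @param grid a `dose_grid`.
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `read_dose_nifti()` returns a `dose_grid`;
#'   `write_dose_nifti()` returns `path` invisibly.
#' @export
write_dose_nifti <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_dose_nifti
#' @export
read_dose_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- attr(img, "pixdim")[1:3]
  dose_grid(array(as.numeric(img), dim = dim(img)[1:3]), spacing = sp)
}
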