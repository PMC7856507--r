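#' Accumulate per-fraction dose grids
#'
#' Voxelwise weighted sum of congruent per-fraction dose grids, the
#' accumulation step of a fractionated course. Linear: accumulating the
#' concatenation of two fraction lists equals the sum of the two
#' accumulations.
#'
#' @param fractions list of [dose_grid()]s, all congruent.
#' @param weights per-fraction non-negative weights; default 1 for each
#'   (plain summation).
#' @return a `course_dose`: list with `grid` (the accumulated
#'   [dose_grid()]) and `fractions_accumulated`.
#' @export
accumulate <- function(fractions, weights = rep(1, length(fractions))) {
  if (length(fractions) == 0) stop("no fractions to accumulate", call. = FALSE)
  if (length(weights) != length(fractions)) {
    stop("`weights` must match the number of fractions", call. = FALSE)
  }
  if (any(weights < 0)) stop("`weights` must be >= 0", call. = FALSE)
  ref <- fractions[[1]]
  for (f in fractions[-1]) check_congruent(ref, f)
  acc <- array(0, dim = dim(ref$values))
  for (i in seq_along(fractions)) {
    acc <- acc + weights[i] * fractions[[i]]$values
  }
  course_dose(dose_grid(acc, ref$spacing, ref$origin),
              fractions_accumulated = length(fractions))
}

course_dose <- function(grid, prescription_gy = NA_real_,
                        fractions_accumulated = NA_integer_) {
  structure(list(grid = grid, prescription_gy = prescription_gy,
                 fractions_accumulated = fractions_accumulated),
            class = "course_dose")
}

#' @export
print.course_dose <- function(x, ...) {
  cat(sprintf("<course_dose> prescription %s Gy over %s fractions\n",
              format(x$prescription_gy), format(x$fractions_accumulated)))
  print(x$grid)
  invisible(x)
}

#' Prescription renormalization factor
#'
#' When only the fractions with pre-fraction imaging enter the accumulation,
#' the accumulated distribution is rescaled so the prescription is restored:
#' N = prescription / (number of imaged fractions x prescribed dose per
#' fraction).
#'
#' @param prescription_gy total prescribed dose (Gy).
#' @param n_fractions_with_imaging number of fractions entering the
#'   accumulation.
#' @param dose_per_fraction_gy prescribed dose per fraction (Gy).
#' @return the scalar factor N.
#' @examples
#' renormalization_factor(60, 28, 2) # 60/56
#' @export
renormalization_factor <- function(prescription_gy, n_fractions_with_imaging,
                                   dose_per_fraction_gy) {
  if (prescription_gy <= 0 || dose_per_fraction_gy <= 0) {
    stop("doses must be > 0", call. = FALSE)
  }
  if (n_fractions_with_imaging <= 0) {
    stop("`n_fractions_with_imaging` must be > 0", call. = FALSE)
  }
  prescription_gy / (n_fractions_with_imaging * dose_per_fraction_gy)
}

#' Electrode-positioning scenario definitions
#'
#' The five positioning conditions compared by the pipeline:
#' \describe{
#'   \item{1}{no electrodes;}
#'   \item{2}{electrodes at varying observed positions;}
#'   \item{3}{electrodes virtually fixed at the position nearest the
#'     average placement;}
#'   \item{4}{2/5 of fractions as scenario 1 plus 3/5 as scenario 3;}
#'   \item{5}{2/5 of fractions as scenario 1 plus 3/5 as scenario 2.}
#' }
#' The fraction mixes are implemented as deterministic convex dose
#' combinations of the accumulated component courses.
#'
#' @param id scenario id, 1-5.
#' @return a `scenario_spec`: tibble with columns `source` (one of
#'   `no_electrodes`, `varying_positions`, `fixed_average_position`) and
#'   `weight` (summing to 1), plus attribute `id`.
#' @export
scenario_spec <- function(id) {
  id <- as.integer(id)
  if (!id %in% 1:5) stop("scenario `id` must be 1-5", call. = FALSE)
  comp <- switch(id,
    tibble::tibble(source = "no_electrodes", weight = 1),
    tibble::tibble(source = "varying_positions", weight = 1),
    tibble::tibble(source = "fixed_average_position", weight = 1),
    tibble::tibble(source = c("no_electrodes", "fixed_average_position"),
                   weight = c(2 / 5, 3 / 5)),
    tibble::tibble(source = c("no_electrodes", "varying_positions"),
                   weight = c(2 / 5, 3 / 5)))
  structure(comp, id = id, class = c("scenario_spec", class(comp)))
}

#' Build a scenario dose from component courses
#'
#' Voxelwise convex combination of the accumulated component courses
#' according to a [scenario_spec()]; scenarios 1-3 are pass-throughs of a
#' single source.
#'
#' @param spec a [scenario_spec()] (or scenario id 1-5).
#' @param courses named list of `course_dose` objects; names must cover
#'   every `source` in the spec (`no_electrodes`, `varying_positions`,
#'   `fixed_average_position` as needed).
#' @return a `course_dose` for the scenario.
#' @export
build_scenario <- function(spec, courses) {
  if (!inherits(spec, "scenario_spec")) spec <- scenario_spec(spec)
  missing_src <- setdiff(spec$source, names(courses))
  if (length(missing_src) > 0) {
    stop(sprintf("missing component course(s): %s",
                 paste(missing_src, collapse = ", ")), call. = FALSE)
  }
  if (abs(sum(spec$weight) - 1) > 1e-9) {
    stop("scenario weights must sum to 1", call. = FALSE)
  }
  comps <- courses[spec$source]
  ref <- comps[[1]]$grid
  for (cd in comps[-1]) check_congruent(ref, cd$grid)
  acc <- array(0, dim = dim(ref$values))
  for (i in seq_along(comps)) {
    acc <- acc + spec$weight[i] * comps[[i]]$grid$values
  }
  course_dose(dose_grid(acc, ref$spacing, ref$origin),
              prescription_gy = comps[[1]]$prescription_gy,
              fractions_accumulated = comps[[1]]$fractions_accumulated)
}
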