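#' Published cohort tables of the PriCoTTF phase I/II dosimetric study
#'
#' The package ships the per-patient, per-scenario dosimetric summary
#' tables published for the first seven patients of the PriCoTTF phase
#' I/II trial: hot-spot doses D0.05cm2 and D25cm2 of the superficial scalp
#' layer, skin NTCP (percent) of the 0-2 mm layer, and the gEUD of the
#' 0-2 mm and 2-4 mm layers, each under the five electrode-positioning
#' scenarios. These are the reference inputs for the table-reproduction
#' workflow and the desk-scale statistical checks.
#'
#' @param table one of `"d005cm2_gy"`, `"d25cm2_gy"`, `"ntcp_pct"`,
#'   `"geud_0_2_gy"`, `"geud_2_4_gy"`.
#' @return `trial_table()`: a tibble with columns `patient`, `ptv_cc`,
#'   `scenario_1` ... `scenario_5`. `trial_cohort()`: the long cohort
#'   table with one row per patient x scenario and columns `patient`,
#'   `scenario`, `ptv_cc`, `d005cm2_gy`, `d25cm2_gy`, `geud_0_2_gy`,
#'   `geud_2_4_gy`, `ntcp_fraction` (NTCP as a fraction, not percent).
#' @examples
#' head(trial_cohort())
#' @export
trial_table <- function(table = c("d005cm2_gy", "d25cm2_gy", "ntcp_pct",
                                  "geud_0_2_gy", "geud_2_4_gy")) {
  table <- match.arg(table)
  path <- system.file("extdata", paste0("trial_", table, ".csv"),
                      package = "scalpdose", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected <- c("patient", "ptv_cc", paste0("scenario_", 1:5))
  if (!identical(names(df), expected)) {
    stop(sprintf("malformed fixture '%s': unexpected columns", table),
         call. = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    vals <- unlist(df[i, -1])
    if (anyNA(vals) || any(!is.finite(vals)) || any(vals < 0)) {
      stop(sprintf("malformed fixture '%s': bad value in row %d", table, i),
           call. = FALSE)
    }
  }
  tibble::as_tibble(df)
}

#' @rdname trial_table
#' @export
trial_cohort <- function() {
  longify <- function(name, value_name) {
    trial_table(name) |>
      tidyr::pivot_longer(dplyr::starts_with("scenario_"),
                          names_to = "scenario", names_prefix = "scenario_",
                          names_transform = as.integer,
                          values_to = value_name)
  }
  out <- longify("d005cm2_gy", "d005cm2_gy") |>
    dplyr::left_join(longify("d25cm2_gy", "d25cm2_gy"),
                     by = c("patient", "ptv_cc", "scenario")) |>
    dplyr::left_join(longify("geud_0_2_gy", "geud_0_2_gy"),
                     by = c("patient", "ptv_cc", "scenario")) |>
    dplyr::left_join(longify("geud_2_4_gy", "geud_2_4_gy"),
                     by = c("patient", "ptv_cc", "scenario")) |>
    dplyr::left_join(longify("ntcp_pct", "ntcp_pct"),
                     by = c("patient", "ptv_cc", "scenario"))
  out |>
    dplyr::mutate(ntcp_fraction = .data$ntcp_pct / 100) |>
    dplyr::select("patient", "scenario", "ptv_cc", "d005cm2_gy",
                  "d25cm2_gy", "geud_0_2_gy", "geud_2_4_gy",
                  "ntcp_fraction") |>
    dplyr::arrange(.data$patient, .data$scenario)
}

#' Reproduce the published cohort results from the packaged tables
#'
#' Recomputes, from the packaged gEUD and NTCP tables, every quantity the
#' statistical layer derives from them: the NTCP of each patient/scenario
#' cell from its 0-2 mm gEUD through the Lyman model (with the skin
#' defaults), the multiplicative scenario factors with confidence
#' intervals, the scenario-1 NTCP summary, the gEUD/NTCP rank correlation,
#' and the gEUD depth gradients between the 0-2 and 2-4 mm layers. Each
#' NTCP cell is flagged pass/fail at an absolute probability tolerance.
#'
#' @param params an [lkb_params()] set (skin defaults).
#' @param tol absolute tolerance, in probability units, for a recomputed
#'   NTCP cell against its published value (default 2e-4).
#' @return list of class `table_reproduction`: `ntcp_cells` (per-cell
#'   tibble with `ntcp_printed_pct`, `ntcp_computed_pct`, `abs_dev`,
#'   `pass`), `n_pass`/`n_cells`, `factors` (scenario factors 3v1, 2v1,
#'   5v1), `summary_sc1`, `spearman_geud_ntcp`, `gradients` (per-scenario
#'   and overall mean Gy/mm).
#' @export
reproduce_tables <- function(params = lkb_params(), tol = 2e-4) {
  cohort <- trial_cohort()
  cells <- cohort |>
    dplyr::mutate(
      ntcp_printed_pct = 100 * .data$ntcp_fraction,
      ntcp_computed_pct = 100 * lyman_ntcp(.data$geud_0_2_gy, params),
      abs_dev = abs(.data$ntcp_computed_pct - .data$ntcp_printed_pct) / 100,
      pass = .data$abs_dev <= tol) |>
    dplyr::select("patient", "scenario", "geud_0_2_gy", "ntcp_printed_pct",
                  "ntcp_computed_pct", "abs_dev", "pass")

  fit <- log_ntcp_anova(cohort)
  factors <- dplyr::bind_rows(scenario_factor(fit, 3, 1),
                              scenario_factor(fit, 2, 1),
                              scenario_factor(fit, 5, 1))

  grads <- cohort |>
    dplyr::mutate(grad_gy_mm = depth_gradient(.data$geud_0_2_gy,
                                              .data$geud_2_4_gy, 2)) |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(mean_gy_mm = mean(.data$grad_gy_mm), .groups = "drop")

  structure(list(
    ntcp_cells = cells,
    n_pass = sum(cells$pass), n_cells = nrow(cells), tol = tol,
    factors = factors,
    summary_sc1 = cohort_summary(cohort, 1),
    spearman_geud_ntcp = spearman_rank(cohort$geud_0_2_gy,
                                       cohort$ntcp_fraction),
    gradients = grads,
    mean_gradient_sc1_3 = mean(grads$mean_gy_mm[grads$scenario %in% 1:3])),
    class = "table_reproduction")
}

#' @export
print.table_reproduction <- function(x, ...) {
  cat(sprintf("<table_reproduction> NTCP cells: %d/%d within %.1e\n",
              x$n_pass, x$n_cells, x$tol))
  if (x$n_pass < x$n_cells) {
    bad <- x$ntcp_cells[!x$ntcp_cells$pass, ]
    cat("  failing cells:\n")
    print(bad)
  }
  cat("scenario factors:\n")
  print(x$factors)
  cat(sprintf("scenario 1 NTCP: min %.4f%%, median %.4f%%, max %.4f%%\n",
              x$summary_sc1$min_pct, x$summary_sc1$median_pct,
              x$summary_sc1$max_pct))
  cat(sprintf("Spearman gEUD vs NTCP: %.2f\n", x$spearman_geud_ntcp))
  cat(sprintf("mean gEUD depth gradient, scenarios 1-3: %.2f Gy/mm\n",
              x$mean_gradient_sc1_3))
  invisible(x)
}

#' Batch NTCP from a gEUD table
#'
#' CSV-friendly batch mode: takes rows of (patient, scenario, gEUD) and
#' returns the Lyman NTCP in percent for each.
#'
#' @param table data frame with a `geud_gy` column (other columns carried
#'   through).
#' @param params an [lkb_params()] set.
#' @return the input tibble with an added `ntcp_pct` column.
#' @export
batch_ntcp <- function(table, params = lkb_params()) {
  if (!"geud_gy" %in% names(table)) {
    stop("`table` needs a `geud_gy` column", call. = FALSE)
  }
  dplyr::mutate(tibble::as_tibble(table),
                ntcp_pct = 100 * lyman_ntcp(.data$geud_gy, params))
}
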