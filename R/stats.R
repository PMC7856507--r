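#' Two-way ANOVA on log NTCP
#'
#' Fits the additive fixed-effects model ln(NTCP) ~ patient + scenario by
#' least squares on a complete balanced patient x scenario table. NTCP
#' itself is heavily right-skewed across patients; its logarithm is
#' compatible with normality, so all scenario comparisons are carried out
#' on the log scale and reported as multiplicative factors
#' (see [scenario_factor()]). For a balanced design the scenario effects
#' are the scenario means of ln NTCP minus the grand mean.
#'
#' @param table cohort metric table: a data frame with columns `patient`,
#'   `scenario` and `ntcp_fraction` (one row per cell, complete over the
#'   chosen scenarios). All NTCP values must be > 0; values below `floor`
#'   are raised to it with a warning.
#' @param scenarios subset of scenario ids to fit (default: all present).
#' @param floor guard against log(0) for underflowing synthetic NTCPs.
#' @return object of class `ntcp_anova`: list with the `lm` fit, the
#'   scenario/patient effect tables, `sigma2` (residual mean square) and
#'   `df_residual`.
#' @export
log_ntcp_anova <- function(table, scenarios = NULL, floor = 1e-12) {
  need <- c("patient", "scenario", "ntcp_fraction")
  if (!all(need %in% names(table))) {
    stop("`table` needs columns patient, scenario, ntcp_fraction",
         call. = FALSE)
  }
  df <- tibble::as_tibble(table)
  if (!is.null(scenarios)) df <- df[df$scenario %in% scenarios, ]
  tab <- table(df$patient, df$scenario)
  if (any(tab != 1)) {
    stop("design must be complete and balanced: every patient x scenario cell exactly once",
         call. = FALSE)
  }
  if (any(df$ntcp_fraction <= 0)) {
    stop("all NTCP values must be > 0 to take logarithms; floor zero cells upstream",
         call. = FALSE)
  }
  if (any(df$ntcp_fraction < floor)) {
    warning(sprintf("%d NTCP value(s) below %g floored before logging",
                    sum(df$ntcp_fraction < floor), floor))
    df$ntcp_fraction <- pmax(df$ntcp_fraction, floor)
  }
  df$log_ntcp <- log(df$ntcp_fraction)
  df$patient <- factor(df$patient)
  df$scenario <- factor(df$scenario)
  fit <- stats::lm(log_ntcp ~ patient + scenario, data = df)
  grand <- mean(df$log_ntcp)
  sc_eff <- df |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(mean_log_ntcp = mean(.data$log_ntcp), .groups = "drop") |>
    dplyr::mutate(effect = .data$mean_log_ntcp - grand)
  pat_eff <- df |>
    dplyr::group_by(.data$patient) |>
    dplyr::summarise(mean_log_ntcp = mean(.data$log_ntcp), .groups = "drop") |>
    dplyr::mutate(effect = .data$mean_log_ntcp - grand)
  structure(list(fit = fit, data = df,
                 scenario_effects = sc_eff, patient_effects = pat_eff,
                 grand_mean = grand,
                 sigma2 = sum(stats::residuals(fit)^2) / fit$df.residual,
                 df_residual = fit$df.residual,
                 n_patients = nlevels(df$patient),
                 n_scenarios = nlevels(df$scenario)),
            class = "ntcp_anova")
}

#' @export
print.ntcp_anova <- function(x, ...) {
  cat(sprintf(
    "<ntcp_anova> ln(NTCP) ~ patient + scenario: %d patients x %d scenarios, residual df %d\n",
    x$n_patients, x$n_scenarios, x$df_residual))
  print(x$scenario_effects)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname log_ntcp_anova
#' @param x an `ntcp_anova` fit.
#' @param ... unused.
#' @export
tidy.ntcp_anova <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(dplyr::rename(x$scenario_effects, level = "scenario"),
                  term = "scenario", .before = 1),
    dplyr::mutate(dplyr::rename(x$patient_effects, level = "patient"),
                  term = "patient", .before = 1)) |>
    dplyr::mutate(level = as.character(.data$level))
}

#' @rdname log_ntcp_anova
#' @export
glance.ntcp_anova <- function(x, ...) {
  a <- stats::anova(x$fit)
  tibble::tibble(
    sigma2 = x$sigma2, df_residual = x$df_residual,
    p_patient = a["patient", "Pr(>F)"],
    p_scenario = a["scenario", "Pr(>F)"],
    r_squared = summary(x$fit)$r.squared)
}

#' Plot an ntcp_anova fit
#'
#' Observed log10 NTCP per patient across scenarios with the additive-model
#' predictions overlaid.
#'
#' @param object an `ntcp_anova`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ntcp_anova <- function(object, ...) {
  df <- object$data
  df$fitted <- stats::fitted(object$fit)
  ggplot2::ggplot(df, ggplot2::aes(.data$scenario,
                                   .data$log_ntcp / log(10),
                                   group = .data$patient,
                                   colour = .data$patient)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted / log(10)),
                       linetype = "dashed") +
    ggplot2::labs(x = "Scenario", y = "log10 NTCP", colour = "Patient") +
    ggplot2::theme_minimal()
}

#' Multiplicative scenario effect on NTCP
#'
#' The factor by which scenario `a` changes the NTCP relative to scenario
#' `b`: exp of the difference of scenario effects from a [log_ntcp_anova()]
#' fit. In a balanced design this equals the geometric mean over patients
#' of the per-patient NTCP ratios. The 95% confidence interval uses the
#' residual mean square of the fit with its residual degrees of freedom;
#' the p-value tests factor = 1.
#'
#' @param fit an `ntcp_anova`.
#' @param a,b scenario ids to compare (`a` relative to `b`).
#' @param conf_level confidence level (default 0.95).
#' @return one-row tibble of class `factor_estimate`: `scenario_a`,
#'   `scenario_b`, `factor`, `conf_lo`, `conf_hi`, `p_value`.
#' @export
scenario_factor <- function(fit, a, b, conf_level = 0.95) {
  stopifnot(inherits(fit, "ntcp_anova"))
  eff <- fit$scenario_effects
  lv <- as.character(eff$scenario)
  if (!as.character(a) %in% lv || !as.character(b) %in% lv) {
    stop("both scenarios must be present in the fit", call. = FALSE)
  }
  est <- eff$effect[lv == as.character(a)] - eff$effect[lv == as.character(b)]
  if (identical(as.character(a), as.character(b))) {
    out <- tibble::tibble(scenario_a = a, scenario_b = b, factor = 1,
                          conf_lo = 1, conf_hi = 1, p_value = NA_real_)
    return(structure(out, class = c("factor_estimate", class(out))))
  }
  se <- sqrt(2 * fit$sigma2 / fit$n_patients)
  tq <- stats::qt(1 - (1 - conf_level) / 2, fit$df_residual)
  p <- 2 * stats::pt(-abs(est / se), fit$df_residual)
  out <- tibble::tibble(scenario_a = a, scenario_b = b,
                        factor = exp(est),
                        conf_lo = exp(est - tq * se),
                        conf_hi = exp(est + tq * se),
                        p_value = p)
  structure(out, class = c("factor_estimate", class(out)))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, the measure used to relate
#' gEUD (or hot-spot dose) to NTCP across patients and scenarios.
#'
#' @param x,y equal-length numeric vectors, length >= 3.
#' @return the correlation coefficient.
#' @export
spearman_rank <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rank correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

#' Kolmogorov-Smirnov normality check with Lilliefors correction
#'
#' One-sample KS test against a normal with estimated mean and SD
#' (Lilliefors), reporting the P value in the coarse bands conventional for
#' tabulated normality checks: below 0.01, 0.01-0.15, above 0.15.
#'
#' @param values numeric vector, n >= 5.
#' @return tibble with `statistic`, `p_value` and `p_band` (factor with
#'   levels `"<0.01"`, `"0.01-0.15"`, `">0.15"`).
#' @export
ks_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 5) stop("need at least 5 values", call. = FALSE)
  t <- nortest::lillie.test(values)
  band <- cut(t$p.value, breaks = c(0, 0.01, 0.15, 1),
              labels = c("<0.01", "0.01-0.15", ">0.15"),
              include.lowest = TRUE)
  tibble::tibble(statistic = unname(t$statistic),
                 p_value = t$p.value, p_band = band)
}

#' Cohort NTCP summary for one scenario
#'
#' Order statistics of the NTCP column, reported in percent.
#'
#' @param table cohort metric table with `scenario` and `ntcp_fraction`.
#' @param scenario scenario id.
#' @return tibble with `scenario`, `n`, `min_pct`, `median_pct`, `max_pct`.
#' @export
cohort_summary <- function(table, scenario) {
  rows <- table[table$scenario == scenario, ]
  if (nrow(rows) == 0) stop("no rows for that scenario", call. = FALSE)
  ntcp <- rows$ntcp_fraction
  tibble::tibble(scenario = scenario, n = length(ntcp),
                 min_pct = 100 * min(ntcp),
                 median_pct = 100 * stats::median(ntcp),
                 max_pct = 100 * max(ntcp))
}
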