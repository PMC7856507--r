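#' Lyman-Kutcher-Burman parameter set
#'
#' Container for the parameters of the Lyman probit NTCP model with
#' Kutcher-Burman volume reduction: the uniform whole-organ tolerance dose
#' `td50_ref`, the relative slope `m`, the volume-effect exponent `n`, and
#' the reference organ expressed as a skin area times layer thickness.
#'
#' The default is the Burman fit of the Emami tolerance data for skin
#' necrosis/ulceration — TD50 = 70 Gy for a 100 cm^2 reference area of
#' skin, m = 0.12, n = 0.10 — with the 2 mm layer-thickness convention used
#' to convert skin area to volume. Accumulated physical dose enters the
#' model directly (no fractionation correction); see [eqd2()] for an
#' optional linear-quadratic transform.
#'
#' @param td50_ref dose (Gy) giving 50% complication probability for
#'   uniform irradiation of the whole reference organ.
#' @param m relative slope of the probit dose response (0 < m < 1).
#' @param n volume-effect exponent (0 < n <= 1); small n = serial-like,
#'   hot-spot dominated response.
#' @param reference_area_cm2 area of the reference skin organ (cm^2).
#' @param reference_thickness_mm layer thickness (mm) converting that area
#'   to the reference volume.
#' @return object of class `lkb_params`.
#' @examples
#' p <- lkb_params()
#' lyman_ntcp(70, p) # 0.5 by construction
#' @export
lkb_params <- function(td50_ref = 70, m = 0.12, n = 0.10,
                       reference_area_cm2 = 100,
                       reference_thickness_mm = 2) {
  if (td50_ref <= 0) stop("`td50_ref` must be > 0", call. = FALSE)
  if (m <= 0 || m >= 1) stop("`m` must lie in (0, 1)", call. = FALSE)
  if (n <= 0 || n > 1) stop("`n` must lie in (0, 1]", call. = FALSE)
  if (reference_area_cm2 <= 0 || reference_thickness_mm <= 0) {
    stop("reference organ dimensions must be > 0", call. = FALSE)
  }
  structure(list(td50_ref = td50_ref, m = m, n = n,
                 reference_area_cm2 = reference_area_cm2,
                 reference_thickness_mm = reference_thickness_mm),
            class = "lkb_params")
}

#' @export
print.lkb_params <- function(x, ...) {
  cat(sprintf(
    "<lkb_params> TD50 = %g Gy, m = %g, n = %g, reference organ %g cm^2 x %g mm\n",
    x$td50_ref, x$m, x$n, x$reference_area_cm2, x$reference_thickness_mm))
  invisible(x)
}

reference_volume_cc <- function(params) {
  params$reference_area_cm2 * params$reference_thickness_mm / 10
}

#' Generalized equivalent uniform dose (Luxton form)
#'
#' The gEUD is the uniform dose to the whole reference organ that would be
#' isotoxic to the inhomogeneous dose actually delivered to the structure:
#' a power mean over differential DVH bins,
#' \deqn{gEUD = \left(\sum_i \frac{v_i}{V_{ref}} D_i^{1/n}\right)^{n},}
#' with bin-centre doses \eqn{D_i}, bin volumes \eqn{v_i}, and partial
#' volumes taken relative to the reference organ volume. The part of the
#' reference organ outside the structure contributes zero dose, so a
#' structure smaller than the reference organ dilutes the gEUD.
#'
#' @param dvh a [cumulative_dvh()] (or [as_dvh()]) for the structure.
#' @param params an [lkb_params()] set.
#' @return gEUD in Gy. Never exceeds the maximum structure dose; scales
#'   linearly with a uniform scaling of all doses.
#' @export
geud <- function(dvh, params = lkb_params()) {
  bins <- differential_dvh(dvh)
  v_ref <- reference_volume_cc(params)
  if (v_ref <= 0) stop("reference organ volume is zero", call. = FALSE)
  if (any(bins$dose_gy < 0)) stop("negative dose in DVH", call. = FALSE)
  keep <- bins$volume_cc > 0
  if (!any(keep)) return(0)
  d <- bins$dose_gy[keep]
  v <- bins$volume_cc[keep]
  # log-space power mean; 1/n is large (10 for skin) so D^(1/n) overflows
  # double precision for clinically ordinary doses if computed naively
  a <- 1 / params$n
  lse <- log(sum((v / v_ref) * exp(a * (log(d) - log(max(d))))))
  exp(params$n * lse + log(max(d)))
}

#' Kutcher-Burman effective partial volume
#'
#' Reduces an inhomogeneous DVH to the fraction of the reference organ
#' which, irradiated uniformly at the maximum structure dose, is isoeffective:
#' \deqn{v_{eff} = \sum_i \frac{v_i}{V_{ref}} (D_i / D_{max})^{1/n}.}
#' The Lyman NTCP computed from \eqn{(D_{max}, v_{eff})} with the
#' volume-scaled tolerance \eqn{TD50(v) = TD50 \cdot v^{-n}} equals the NTCP
#' computed from the gEUD (the two reductions are algebraically linked by
#' \eqn{gEUD = D_{max} \, v_{eff}^{\,n}}).
#'
#' @inheritParams geud
#' @return effective volume as a fraction of the reference organ, in (0, 1]
#'   when the structure fits inside the reference organ.
#' @export
kutcher_burman_veff <- function(dvh, params = lkb_params()) {
  bins <- differential_dvh(dvh)
  keep <- bins$volume_cc > 0
  d <- bins$dose_gy[keep]
  v <- bins$volume_cc[keep]
  if (length(d) == 0 || max(d) <= 0) {
    stop("effective volume undefined: maximum dose is zero", call. = FALSE)
  }
  v_ref <- reference_volume_cc(params)
  sum((v / v_ref) * exp((1 / params$n) * (log(d) - log(max(d)))))
}

#' Lyman NTCP from a (generalized) uniform dose
#'
#' The Lyman probit model: NTCP = Phi(t) with
#' t = (gEUD - TD50) / (m TD50), Phi the standard normal CDF. With the skin
#' defaults this maps the gEUD of a scalp layer to the probability of skin
#' necrosis/ulceration.
#'
#' @param geud_gy uniform-equivalent dose in Gy (vectorised).
#' @param params an [lkb_params()] set.
#' @return probability in \code{[0, 1]}, strictly increasing in `geud_gy`.
#' @examples
#' lyman_ntcp(c(32.85, 51.71)) # printed as 0.0005% and 1.47%
#' @export
lyman_ntcp <- function(geud_gy, params = lkb_params()) {
  if (any(geud_gy < 0)) stop("`geud_gy` must be >= 0", call. = FALSE)
  stats::pnorm((geud_gy - params$td50_ref) / (params$m * params$td50_ref))
}

#' Lyman NTCP via the effective-volume route
#'
#' Evaluates the model from the maximum dose and the Kutcher-Burman
#' effective volume, using the volume-scaled tolerance
#' TD50(v) = TD50 v^(-n). Agrees with [lyman_ntcp()] applied to [geud()]
#' to within numerical precision; kept as an independent route.
#'
#' @param dmax_gy maximum structure dose (Gy).
#' @param veff effective partial volume (fraction of the reference organ).
#' @param params an [lkb_params()] set.
#' @return probability in \code{[0, 1]}.
#' @export
lyman_ntcp_veff <- function(dmax_gy, veff, params = lkb_params()) {
  td50_v <- params$td50_ref * veff^(-params$n)
  stats::pnorm((dmax_gy - td50_v) / (params$m * td50_v))
}

#' Full radiobiological reduction of a DVH
#'
#' Convenience wrapper returning gEUD, effective volume, maximum dose and
#' NTCP for one structure DVH in a single row.
#'
#' @inheritParams geud
#' @return one-row tibble with columns `geud_gy`, `veff`, `dmax_gy`,
#'   `ntcp`.
#' @export
radiobiology <- function(dvh, params = lkb_params()) {
  g <- geud(dvh, params)
  v <- kutcher_burman_veff(dvh, params)
  bins <- differential_dvh(dvh)
  dmax <- if (any(bins$volume_cc > 0)) max(bins$dose_gy[bins$volume_cc > 0]) else 0
  tibble::tibble(geud_gy = g, veff = v, dmax_gy = dmax,
                 ntcp = lyman_ntcp(g, params))
}

#' gEUD depth gradient between two scalp layers
#'
#' The per-mm increase of gEUD from a superficial to a deeper layer, using
#' the separation of the layer centres (2 mm for adjacent 2-mm shells with
#' centres at 1 and 3 mm depth).
#'
#' @param geud_superficial,geud_deep gEUD (Gy) of the shallower and deeper
#'   layer; vectorised.
#' @param layer_center_separation_mm separation of layer centres (mm).
#' @return gradient in Gy per mm.
#' @export
depth_gradient <- function(geud_superficial, geud_deep,
                           layer_center_separation_mm = 2) {
  if (layer_center_separation_mm <= 0) {
    stop("`layer_center_separation_mm` must be > 0", call. = FALSE)
  }
  (geud_deep - geud_superficial) / layer_center_separation_mm
}

#' Equi-effective dose in 2-Gy fractions
#'
#' Optional linear-quadratic conversion of a physical dose delivered in
#' `n_fractions` to the isoeffective dose in 2-Gy fractions. Off by default
#' throughout the package: accumulated physical dose enters the Lyman model
#' directly.
#'
#' @param dose_gy total physical dose (Gy); vectorised.
#' @param n_fractions number of fractions it was delivered in.
#' @param alpha_beta tissue alpha/beta ratio (Gy).
#' @return EQD2 in Gy.
#' @export
eqd2 <- function(dose_gy, n_fractions, alpha_beta) {
  stopifnot(n_fractions > 0, alpha_beta > 0)
  d <- dose_gy / n_fractions
  dose_gy * (d + alpha_beta) / (2 + alpha_beta)
}
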