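#' Assay configuration for absorbance-based rate determination
#'
#' @param extinction_coefficient molar extinction coefficient of the product
#'   (1/M/cm; default 15800, the 380 nm value for the ring-opened product).
#' @param path_length cuvette path length (cm).
#' @param enzyme_concentration total enzyme concentration (M).
#' @param wavelength informational (nm).
#' @return list of class \code{assay_config}.
#' @export
assay_config <- function(extinction_coefficient = 15800, path_length = 1,
                         enzyme_concentration = 1e-8, wavelength = 380) {
  stopifnot(extinction_coefficient > 0, path_length > 0,
            enzyme_concentration > 0)
  structure(list(extinction_coefficient = extinction_coefficient,
                 path_length = path_length,
                 enzyme_concentration = enzyme_concentration,
                 wavelength = wavelength),
            class = "assay_config")
}

#' Convert an absorbance slope to a reaction rate
#'
#' Blank-corrected Beer-Lambert conversion:
#' \code{rate = (dA/dt - blank) / (epsilon * l)}. Negative corrected slopes
#' are returned as negative rates with a flag rather than clipped.
#'
#' @param dA_dt absorbance slope (1/s).
#' @param blank_dA_dt blank slope under identical conditions (1/s).
#' @param assay an \code{\link{assay_config}}.
#' @return list with \code{rate} (M/s) and \code{negative} flag.
#' @export
absorbance_to_rate <- function(dA_dt, blank_dA_dt = 0, assay = assay_config()) {
  rate <- (dA_dt - blank_dA_dt) /
    (assay$extinction_coefficient * assay$path_length)
  list(rate = rate, negative = rate < 0)
}

#' Fit the Michaelis-Menten equation to a rate profile
#'
#' Unweighted nonlinear least squares of
#' \code{v = kcat * E0 * S / (KM + S)} with starting values from a
#' linearized Hanes fit; parameter standard errors come from the covariance
#' of the fit. When the largest substrate concentration does not exceed the
#' fitted KM the result is flagged as curvature-poor (saturation not
#' reached), which inflates the kcat uncertainty.
#'
#' @param concentrations substrate concentrations (mM).
#' @param rates observed rates (M/s).
#' @param enzyme_conc total enzyme concentration E0 (M).
#' @return object of class \code{kinetic_parameters}: \code{kcat, kcat_err}
#'   (1/s), \code{KM, KM_err} (mM), \code{efficiency, efficiency_err}
#'   (1/M/s), \code{curvature_poor}, \code{fit}.
#' @export
fit_michaelis_menten <- function(concentrations, rates, enzyme_conc) {
  S <- as.numeric(concentrations); v <- as.numeric(rates)
  if (length(S) != length(v)) stop("concentrations and rates differ in length")
  if (length(S) < 4) stop("need at least 4 points to fit")
  if (length(unique(S)) < 2) stop("need at least 2 distinct concentrations")
  stopifnot(enzyme_conc > 0)
  if (stats::var(v) == 0)
    stop("fit error: rates show no dependence on substrate concentration")
  # Hanes linearization S/v = S/Vmax + KM/Vmax for starting values
  ok <- v > 0
  if (sum(ok) >= 2) {
    hl <- lm(I(S[ok] / v[ok]) ~ S[ok])
    vmax0 <- unname(1 / coef(hl)[2])
    km0 <- unname(coef(hl)[1] * vmax0)
  } else { vmax0 <- NA; km0 <- NA }
  if (!is.finite(vmax0) || vmax0 <= 0) vmax0 <- max(v) * 1.5
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(S)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * S / (KM + S),
                      start = list(Vmax = vmax0, KM = km0),
                      lower = c(1e-12, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("fit error: ", conditionMessage(e), call. = FALSE))
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA, NA))
  kcat <- unname(cf["Vmax"]) / enzyme_conc
  kcat_err <- unname(se[1]) / enzyme_conc
  KM <- unname(cf["KM"])
  KM_err <- unname(se[2])
  # kcat/KM in 1/M/s with first-order error propagation (KM in mM -> M)
  eff <- kcat / (KM * 1e-3)
  eff_err <- eff * sqrt((kcat_err / kcat)^2 + (KM_err / KM)^2)
  structure(list(kcat = kcat, kcat_err = kcat_err, KM = KM, KM_err = KM_err,
                 efficiency = eff, efficiency_err = eff_err,
                 curvature_poor = max(S) < KM, fit = fit),
            class = "kinetic_parameters")
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat(sprintf("kcat = %.3g +/- %.2g 1/s; KM = %.3g +/- %.2g mM; kcat/KM = %.4g 1/M/s%s\n",
              x$kcat, x$kcat_err, x$KM, x$KM_err, x$efficiency,
              if (isTRUE(x$curvature_poor)) " [curvature-poor: max(S) < KM]" else ""))
  invisible(x)
}

#' Activation free energy from a turnover number (Eyring equation)
#'
#' Transition-state theory with unit transmission coefficient:
#' \code{dG_act = R T ln(kB T / (h kcat))}.
#'
#' @param kcat turnover number (1/s, > 0).
#' @param T temperature (K, default 298.15).
#' @return activation free energy (kcal/mol).
#' @seealso \code{\link{kcat_from_barrier}} for the exact inverse.
#' @export
activation_free_energy <- function(kcat, T = physical_constants$T_default) {
  if (any(kcat <= 0)) stop("kcat must be positive")
  pc <- physical_constants
  pc$R * T * log(pc$k_B * T / (pc$h * kcat))
}

#' Turnover number from an activation free energy
#'
#' Inverse of \code{\link{activation_free_energy}}:
#' \code{kcat = (kB T / h) exp(-dG_act / (R T))}.
#'
#' @param dG_act activation free energy (kcal/mol).
#' @param T temperature (K).
#' @return kcat (1/s).
#' @export
kcat_from_barrier <- function(dG_act, T = physical_constants$T_default) {
  pc <- physical_constants
  (pc$k_B * T / pc$h) * exp(-dG_act / (pc$R * T))
}

#' Extrapolate kinetic parameters to zero cosolvent
#'
#' Ordinary least-squares line of a catalytic parameter against the
#' acetonitrile (v/v) percentage; the intercept estimates the parameter in
#' the absence of cosolvent.
#'
#' @param acn_percent cosolvent percentages (>= 2 distinct values).
#' @param values parameter values at those percentages.
#' @return list with \code{value_at_zero}, \code{stderr} (of the
#'   intercept), \code{slope}, \code{slope_stderr}, \code{fit}.
#' @export
extrapolate_to_zero_cosolvent <- function(acn_percent, values) {
  x <- as.numeric(acn_percent); y <- as.numeric(values)
  if (length(x) != length(y)) stop("inputs differ in length")
  if (length(unique(x)) < 2)
    stop("need at least 2 distinct cosolvent levels to extrapolate")
  fit <- lm(y ~ x)
  sm <- summary(fit)$coefficients
  list(value_at_zero = unname(coef(fit)[1]),
       stderr = unname(sm[1, 2]),
       slope = unname(coef(fit)[2]),
       slope_stderr = if (nrow(sm) > 1) unname(sm[2, 2]) else NA_real_,
       fit = fit)
}
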