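#' Growth-rate parameters
#'
#' The inverse growth rate r (years per unit of log-volume growth; tumour
#' volume multiplies by e every r years) is gamma distributed across women.
#' We parameterise the gamma by its mean `mu` and a dispersion `psi` so that
#' the shape is `tau1 = 1/psi` and the rate `tau2 = tau1/mu`. Larger `mu`
#' means slower-growing tumours; `psi` is the squared coefficient of
#' variation of r.
#'
#' @param mu Mean inverse growth rate, years (> 0).
#' @param psi Dispersion (squared CV) of the inverse growth rate (> 0).
#' @return An object of class `nm_growth` with fields `mu`, `psi`, `tau1`
#'   (gamma shape) and `tau2` (gamma rate).
#' @examples
#' gp <- growth_params(mu = 1.158, psi = 0.476)
#' gp$tau1 / gp$tau2  # equals mu
#' @export
growth_params <- function(mu, psi) {
  stopifnot(is.numeric(mu), length(mu) == 1L, mu > 0,
            is.numeric(psi), length(psi) == 1L, psi > 0)
  tau1 <- 1 / psi
  structure(list(mu = mu, psi = psi, tau1 = tau1, tau2 = tau1 / mu),
            class = "nm_growth")
}

#' Metastatic-seeding parameters
#'
#' Viable metastatic seeding follows a non-homogeneous Poisson process whose
#' cumulative intensity, expressed in time since tumour onset, is
#' \eqn{\Lambda(t, r) = \sigma (t/r)^{k+1}}. `sigma` is the seeding scale on
#' this transformed parameterisation; `k` is the power-law exponent linking
#' the number of cell divisions to the seeding rate (capturing the effect of
#' accumulating genomic instability) and is conventionally fixed at 4. The raw
#' per-division scale is the derived quantity
#' \eqn{\sigma^* = \sigma (k+1) \log(2)^{k+1}}.
#'
#' @param sigma Seeding scale on the transformed parameterisation (> 0).
#' @param k Power-law exponent (>= -1). Default 4.
#' @return An object of class `nm_seeding` with fields `sigma`, `k` and the
#'   derived `sigma_star`.
#' @examples
#' seeding_params(sigma = exp(-17.681))
#' @export
seeding_params <- function(sigma, k = 4) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma > 0,
            is.numeric(k), length(k) == 1L, k >= -1)
  structure(list(sigma = sigma, k = k,
                 sigma_star = sigma * (k + 1) * log(2)^(k + 1)),
            class = "nm_seeding")
}

#' Symptomatic-detection parameters
#'
#' The hazard of symptomatic detection of the primary tumour is proportional
#' to current tumour volume, \eqn{h_V(v) = \eta v} for v above the minimum
#' detectable volume. `eta` is reported (and optimised) as `-log(eta)` for
#' numerical convenience.
#'
#' @param eta Symptomatic-detection hazard coefficient, per mm^3 per year
#'   (> 0). Exactly one of `eta`, `neg_log_eta` must be given.
#' @param neg_log_eta Alternative specification, `-log(eta)`.
#' @return An object of class `nm_detection` with fields `eta`, `neg_log_eta`.
#' @examples
#' detection_params(neg_log_eta = 9.792)
#' @export
detection_params <- function(eta = NULL, neg_log_eta = NULL) {
  if (is.null(eta) == is.null(neg_log_eta))
    stop("supply exactly one of 'eta' and 'neg_log_eta'")
  if (is.null(eta)) eta <- exp(-neg_log_eta)
  stopifnot(is.numeric(eta), length(eta) == 1L, eta > 0)
  structure(list(eta = eta, neg_log_eta = -log(eta)), class = "nm_detection")
}

#' Screening-sensitivity parameters
#'
#' Mammography sensitivity is a logistic function of tumour diameter d (mm):
#' `expit(beta0 + beta1 * d)` for d above the minimum detectable diameter, and
#' 0 at or below it. `beta0` is the intercept and `beta1` the per-mm slope
#' (some reports label the same two coefficients beta1 and beta2; the I/O and
#' documentation here always use intercept/slope).
#'
#' @param beta0 Logistic intercept (dimensionless).
#' @param beta1 Logistic slope, per mm (> 0: sensitivity increases with size).
#' @return An object of class `nm_screening`.
#' @examples
#' screening_params(beta0 = -4.713, beta1 = 0.426)
#' @export
screening_params <- function(beta0, beta1) {
  stopifnot(is.numeric(beta0), length(beta0) == 1L, is.finite(beta0),
            is.numeric(beta1), length(beta1) == 1L, beta1 > 0)
  structure(list(beta0 = beta0, beta1 = beta1), class = "nm_screening")
}

#' Metastasis-detection size parameter
#'
#' A seeded metastasis is deemed clinically detected when it reaches a fixed
#' diameter `d_m` (mm), estimated as a model parameter. The corresponding
#' volume `v_m` follows the spherical convention.
#'
#' @param d_m Metastasis detection diameter, mm (> d_cell).
#' @param const Size constants, see [size_constants()].
#' @return An object of class `nm_metastasis` with fields `d_m`, `v_m`.
#' @examples
#' metastasis_params(d_m = 0.907)
#' @export
metastasis_params <- function(d_m, const = size_constants()) {
  stopifnot(is.numeric(d_m), length(d_m) == 1L, d_m > const$d_cell)
  structure(list(d_m = d_m, v_m = diameter_to_volume(d_m)),
            class = "nm_metastasis")
}

#' Full model parameter set
#'
#' Bundles all model components: growth, symptomatic detection, screening
#' sensitivity, seeding, metastasis size and the treatment effect `phi2` (the
#' multiplicative factor on the metastasis inverse growth rate while on
#' treatment; `phi2 > 1` means slower metastatic growth). The pre- and
#' post-treatment factors are fixed at 1 in the main three-period analysis.
#'
#' @param mu,psi Growth: mean and dispersion of the inverse growth rate.
#' @param neg_log_eta Symptomatic detection: `-log(eta)`.
#' @param beta0,beta1 Screening sensitivity: logistic intercept and slope.
#' @param sigma Seeding scale (transformed parameterisation).
#' @param phi2 Treatment effect on the metastasis inverse growth rate (> 0).
#' @param d_m Metastasis detection diameter, mm.
#' @param k Seeding power-law exponent, fixed (default 4).
#' @param const Size constants, see [size_constants()].
#' @return An object of class `nm_params`, a list with components `growth`,
#'   `detection`, `screening`, `seeding`, `metastasis`, `phi2`, `const`.
#' @examples
#' theta <- reference_params()
#' theta$growth$mu
#' @export
model_params <- function(mu, psi, neg_log_eta, beta0, beta1, sigma, phi2, d_m,
                         k = 4, const = size_constants()) {
  stopifnot(is.numeric(phi2), length(phi2) == 1L, phi2 > 0)
  structure(
    list(growth = growth_params(mu, psi),
         detection = detection_params(neg_log_eta = neg_log_eta),
         screening = screening_params(beta0, beta1),
         seeding = seeding_params(sigma, k = k),
         metastasis = metastasis_params(d_m, const = const),
         phi2 = phi2,
         const = const),
    class = "nm_params")
}

#' @export
print.nm_params <- function(x, ...) {
  cat("Natural-history model parameters\n")
  cat(sprintf("  growth:     mu = %.4g, psi = %.4g (tau1 = %.4g, tau2 = %.4g)\n",
              x$growth$mu, x$growth$psi, x$growth$tau1, x$growth$tau2))
  cat(sprintf("  detection:  -log(eta) = %.4g\n", x$detection$neg_log_eta))
  cat(sprintf("  screening:  beta0 = %.4g, beta1 = %.4g\n",
              x$screening$beta0, x$screening$beta1))
  cat(sprintf("  seeding:    log(sigma) = %.4g, k = %g\n",
              log(x$seeding$sigma), x$seeding$k))
  cat(sprintf("  treatment:  phi2 = %.4g\n", x$phi2))
  cat(sprintf("  metastasis: d_m = %.4g mm\n", x$metastasis$d_m))
  invisible(x)
}

#' Reference parameter set
#'
#' A parameter set representative of maximum-likelihood estimates for an ER+
#' breast-cancer cohort under biennial screening. Used throughout the package
#' as the default warm start for fitting, as the default synthetic-cohort
#' generator setting, and in examples. These values are a convenience
#' reference, not ground truth for any new data set.
#'
#' @param ... Overrides passed on to [model_params()] components (any of
#'   `mu`, `psi`, `neg_log_eta`, `beta0`, `beta1`, `sigma`, `phi2`, `d_m`,
#'   `k`).
#' @return An object of class `nm_params`.
#' @examples
#' reference_params()
#' reference_params(phi2 = 1)  # no treatment effect
#' @export
reference_params <- function(...) {
  defaults <- list(mu = 1.158, psi = 0.476, neg_log_eta = 9.792,
                   beta0 = -4.713, beta1 = 0.426, sigma = exp(-17.681),
                   phi2 = 2.414, d_m = 0.907, k = 4)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  do.call(model_params, defaults)
}
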