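# cache for generalized Gauss-Laguerre rules, keyed by (alpha, order)
.nm_cache <- new.env(parent = emptyenv())

gauss_laguerre_rule <- function(alpha, order) {
  key <- sprintf("gl_%.12g_%d", alpha, order)
  rule <- .nm_cache[[key]]
  if (is.null(rule)) {
    rule <- pracma::gaussLaguerre(order, alpha - 1)
    .nm_cache[[key]] <- rule
  }
  rule
}

#' Tumour size at symptomatic detection under stable disease
#'
#' With volume-proportional symptomatic detection hazard \eqn{\eta v} (for v
#' above the minimum detectable volume `v0`) and a gamma inverse growth rate,
#' the stationary density of tumour volume at symptomatic detection is the
#' Pareto-type law \eqn{f(v) = \eta \tau_1 \tau_2^{\tau_1} (\tau_2 +
#' \eta(v - v_0))^{-(\tau_1+1)}} for v > v0. `size_symptomatic_cdf()` is its
#' closed-form distribution function and `size_symptomatic_quantile()` the
#' inverse (used for inversion sampling).
#'
#' @param v Tumour volume, mm^3. Vectorised. Values at or below `v0` are
#'   outside the support and return density 0.
#' @param p Probabilities for the quantile function.
#' @param gp Growth parameters.
#' @param dp Detection parameters.
#' @param const Size constants.
#' @return Density per mm^3, probability, or volume in mm^3.
#' @examples
#' gp <- growth_params(1.158, 0.476); dp <- detection_params(neg_log_eta = 9.792)
#' size_symptomatic_density(diameter_to_volume(15), gp, dp)
#' @export
size_symptomatic_density <- function(v, gp, dp, const = size_constants()) {
  out <- numeric(length(v))
  ok <- v > const$v0
  out[ok] <- dp$eta * gp$tau1 * gp$tau2^gp$tau1 *
    (gp$tau2 + dp$eta * (v[ok] - const$v0))^(-(gp$tau1 + 1))
  out
}

#' @rdname size_symptomatic_density
#' @export
size_symptomatic_cdf <- function(v, gp, dp, const = size_constants()) {
  out <- numeric(length(v))
  ok <- v > const$v0
  out[ok] <- 1 - (gp$tau2 / (gp$tau2 + dp$eta * (v[ok] - const$v0)))^gp$tau1
  out
}

#' @rdname size_symptomatic_density
#' @export
size_symptomatic_quantile <- function(p, gp, dp, const = size_constants()) {
  stopifnot(all(p >= 0), all(p < 1))
  const$v0 + gp$tau2 * ((1 - p)^(-1 / gp$tau1) - 1) / dp$eta
}

#' Size distribution among asymptomatic prevalent cases
#'
#' Under the stable-disease assumption the density of tumour volume in the
#' asymptomatic population is proportional to the symptomatic-detection size
#' density divided by the symptomatic hazard,
#' \eqn{f_V(v) \propto f_{V_{det}}(v) / (\eta v)}. The normalising constant
#' \eqn{C(\theta) = \int_{v_0}^\infty f_{V_{det}}(u)/(\eta u)\, du} depends on
#' the model parameters and is therefore retained in the screen-detected
#' likelihood; it is evaluated by adaptive quadrature
#' ([asymptomatic_norm_const()]).
#'
#' @inheritParams size_symptomatic_density
#' @param log Return the log density?
#' @return Density per mm^3 (a proper density on v > v0).
#' @examples
#' gp <- growth_params(1.158, 0.476); dp <- detection_params(neg_log_eta = 9.792)
#' asymptomatic_size_density(diameter_to_volume(10), gp, dp)
#' @export
asymptomatic_size_density <- function(v, gp, dp, const = size_constants(),
                                      log = FALSE) {
  cc <- asymptomatic_norm_const(gp, dp, const)
  dens <- size_symptomatic_density(v, gp, dp, const) / (dp$eta * v * cc)
  if (log) base::log(dens) else dens
}

#' @rdname asymptomatic_size_density
#' @export
asymptomatic_norm_const <- function(gp, dp, const = size_constants()) {
  f <- function(u) size_symptomatic_density(u, gp, dp, const) / (dp$eta * u)
  stats::integrate(f, const$v0, Inf, rel.tol = 1e-10)$value
}

#' Inverse-growth-rate distribution given tumour size
#'
#' Conditional on a tumour of volume v (whether observed at symptomatic
#' detection or asymptomatic at screening — the two laws coincide under
#' stable disease), the inverse growth rate is gamma with shape
#' \eqn{\tau_1 + 1} and rate \eqn{\tau_2 + \eta(v - v_0)}: the gamma prior
#' updated by the volume-proportional detection process. Larger tumours at
#' detection are evidence of faster growth (smaller r).
#'
#' @param v Tumour volume, mm^3 (> v0).
#' @param gp Growth parameters.
#' @param dp Detection parameters.
#' @param const Size constants.
#' @param order Number of generalised Gauss-Laguerre nodes.
#' @return `growth_rate_posterior()`: a list with `shape`, `rate`, `mean` and
#'   `density(r)`. `posterior_quadrature()`: a list with `nodes` (values of
#'   r) and `weights` (summing to 1) such that `sum(weights * g(nodes))`
#'   approximates the posterior expectation of a smooth `g`.
#' @examples
#' gp <- growth_params(1.158, 0.476); dp <- detection_params(neg_log_eta = 9.792)
#' post <- growth_rate_posterior(diameter_to_volume(20), gp, dp)
#' post$mean
#' q <- posterior_quadrature(diameter_to_volume(20), gp, dp)
#' sum(q$weights * q$nodes)  # matches post$mean
#' @export
growth_rate_posterior <- function(v, gp, dp, const = size_constants()) {
  if (any(v <= const$v0)) stop("v must exceed the minimum detectable volume")
  shape <- gp$tau1 + 1
  rate <- gp$tau2 + dp$eta * (v - const$v0)
  list(shape = shape, rate = rate, mean = shape / rate,
       density = function(r) stats::dgamma(r, shape = shape, rate = rate))
}

#' @rdname growth_rate_posterior
#' @export
posterior_quadrature <- function(v, gp, dp, const = size_constants(),
                                 order = 60) {
  post <- growth_rate_posterior(v, gp, dp, const)
  rule <- gauss_laguerre_rule(post$shape, order)
  list(nodes = rule$x / post$rate, weights = rule$w / gamma(post$shape))
}
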