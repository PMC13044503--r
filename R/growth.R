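#' Exponential tumour growth
#'
#' A tumour starts from a single cell at onset and grows exponentially in
#' volume: \eqn{V(t, r) = V_{cell} e^{t/r}}, with t the time since onset in
#' years and r the inverse growth rate (years per unit of log-volume growth).
#' `time_to_volume()` is the exact inverse.
#'
#' @param t Years since onset (>= 0). Vectorised.
#' @param r Inverse growth rate, years (> 0).
#' @param v Volume in mm^3 (>= the single-cell volume).
#' @param const Size constants, see [size_constants()].
#' @return Volume in mm^3, or years since onset.
#' @examples
#' volume_at_time(0, r = 1.2)                       # single-cell volume
#' time_to_volume(diameter_to_volume(20), r = 1)    # years to reach 20 mm
#' @export
volume_at_time <- function(t, r, const = size_constants()) {
  if (any(t < 0)) stop("t must be non-negative")
  if (any(r <= 0)) stop("r must be positive")
  const$v_cell * exp(t / r)
}

#' @rdname volume_at_time
#' @export
time_to_volume <- function(v, r, const = size_constants()) {
  if (any(v < const$v_cell)) stop("v must be at least the single-cell volume")
  if (any(r <= 0)) stop("r must be positive")
  r * log(v / const$v_cell)
}

#' Tumour volume doubling times implied by the growth parameters
#'
#' A tumour with inverse growth rate r doubles its volume every
#' \eqn{r \log 2} years. With r gamma distributed, the population mean
#' doubling time is \eqn{\mu \log 2} years and the median follows from the
#' gamma quantile function. Returned in days (365.25 days/year).
#'
#' @param gp Growth parameters, see [growth_params()].
#' @return Doubling time in days.
#' @examples
#' gp <- growth_params(1.158, 0.476)
#' doubling_time_mean_days(gp)    # ~293 days
#' doubling_time_median_days(gp)  # ~248 days
#' @export
doubling_time_mean_days <- function(gp) {
  gp$mu * log(2) * 365.25
}

#' @rdname doubling_time_mean_days
#' @export
doubling_time_median_days <- function(gp) {
  stats::qgamma(0.5, shape = gp$tau1, rate = gp$tau2) * log(2) * 365.25
}

#' Time to first viable metastatic seeding
#'
#' Viable seeding events form a non-homogeneous Poisson process, with
#' intensity proportional to a power k of the number of cell divisions, up to
#' the diagnosis of the primary tumour (surgery removes the source; the
#' caller is responsible for truncating at the onset-to-diagnosis time). On
#' the transformed parameterisation the time Ts since onset to the first
#' viable seeding has survival \eqn{S(t_s) = \exp(-\sigma (t_s/r)^{k+1})},
#' hazard \eqn{h(t_s) = \sigma (k+1) t_s^k / r^{k+1}} and density
#' \eqn{f = h S}.
#'
#' @param ts Years since tumour onset (>= 0). Vectorised (recycled with `r`).
#' @param r Inverse growth rate, years (> 0).
#' @param sp Seeding parameters, see [seeding_params()].
#' @return Probability, hazard (per year) or density (per year).
#' @examples
#' sp <- seeding_params(sigma = exp(-17.681))
#' seeding_survival(10, r = 1.2, sp)
#' @export
seeding_survival <- function(ts, r, sp) {
  if (any(ts < 0)) stop("ts must be non-negative")
  exp(-sp$sigma * (ts / r)^(sp$k + 1))
}

#' @rdname seeding_survival
#' @export
seeding_hazard <- function(ts, r, sp) {
  if (any(ts < 0)) stop("ts must be non-negative")
  sp$sigma * (sp$k + 1) * ts^sp$k / r^(sp$k + 1)
}

#' @rdname seeding_survival
#' @export
seeding_density <- function(ts, r, sp) {
  seeding_hazard(ts, r, sp) * seeding_survival(ts, r, sp)
}

#' Random draws from the natural-history building blocks
#'
#' Inversion samplers for the latent quantities of the model, driven by R's
#' global random number stream (use [set.seed()] for reproducibility):
#' `sample_inverse_growth_rate()` draws r from its gamma law;
#' `sample_first_seeding()` draws the time since onset to first viable
#' seeding, \eqn{T_s = r (E/\sigma)^{1/(k+1)}} with E standard exponential
#' (untruncated: compare with the onset-to-diagnosis time to decide whether
#' seeding occurred); `sample_symptomatic_detection()` draws the time since
#' onset to symptomatic detection under the volume-proportional hazard
#' \eqn{\eta V(t)}, i.e. \eqn{t = r \log(1 + E/(\eta V_{cell} r))}.
#'
#' @param n Number of draws.
#' @param gp Growth parameters.
#' @param r Inverse growth rate(s), recycled to length `n`.
#' @param sp Seeding parameters.
#' @param dp Detection parameters, see [detection_params()].
#' @param const Size constants.
#' @return Numeric vector of length `n` (years, or r in years).
#' @examples
#' set.seed(1)
#' mean(sample_inverse_growth_rate(1000, growth_params(1.158, 0.476)))
#' @export
sample_inverse_growth_rate <- function(n, gp) {
  stats::rgamma(n, shape = gp$tau1, rate = gp$tau2)
}

#' @rdname sample_inverse_growth_rate
#' @export
sample_first_seeding <- function(n, r, sp) {
  e <- stats::rexp(n)
  r * (e / sp$sigma)^(1 / (sp$k + 1))
}

#' @rdname sample_inverse_growth_rate
#' @export
sample_symptomatic_detection <- function(n, r, dp, const = size_constants()) {
  e <- stats::rexp(n)
  r * log1p(e / (dp$eta * const$v_cell * r))
}
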