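transformed_names <- c("log_mu", "log_psi", "neg_log_eta", "beta0", "beta1",
                       "log_sigma", "log_phi2", "log_dm")

#' Transform model parameters to and from the unconstrained fitting scale
#'
#' Positive parameters are optimised on the log scale; the symptomatic
#' hazard coefficient as `-log(eta)`. The vector layout is
#' `(log_mu, log_psi, neg_log_eta, beta0, beta1, log_sigma, log_phi2,
#' log_dm)`. The round trip is exact.
#'
#' @param params An `nm_params` object.
#' @param vec A named or unnamed numeric vector of length 8 in the layout
#'   above.
#' @param k,const Fixed constants carried through the back-transformation.
#' @return A numeric vector, or an `nm_params`.
#' @examples
#' v <- params_to_transformed(reference_params())
#' transformed_to_params(v)
#' @export
params_to_transformed <- function(params) {
  stats::setNames(
    c(log(params$growth$mu), log(params$growth$psi),
      params$detection$neg_log_eta, params$screening$beta0,
      params$screening$beta1, log(params$seeding$sigma),
      log(params$phi2), log(params$metastasis$d_m)),
    transformed_names)
}

#' @rdname params_to_transformed
#' @export
transformed_to_params <- function(vec, k = 4, const = size_constants()) {
  stopifnot(length(vec) == 8L)
  vec <- unname(vec)
  model_params(mu = exp(vec[1]), psi = exp(vec[2]), neg_log_eta = vec[3],
               beta0 = vec[4], beta1 = vec[5], sigma = exp(vec[6]),
               phi2 = exp(vec[7]), d_m = exp(vec[8]), k = k, const = const)
}

#' Maximum-likelihood fit of the natural-history model
#'
#' Maximises the cohort log-likelihood over the 8 transformed parameters
#' (the pre- and post-treatment factors are fixed at 1 and the seeding
#' exponent k at its configured value) with Nelder-Mead, which is
#' derivative-free and robust to the ridge-shaped likelihood surface in
#' `(log_phi2, log_dm)`. For cohorts without screening information the
#' gamma shape and rate are not separately identifiable; `restrict =
#' "tau_equal"` imposes `tau1 = tau2` (i.e. `mu = 1`) and drops `log_mu`,
#' `beta0` and `beta1` from the optimisation.
#'
#' @param cohort A cohort, see [as_cohort()].
#' @param init Starting parameters (default [reference_params()], a warm
#'   start representative of fitted ER+ cohorts).
#' @param quad_order Quadrature order for the growth-rate integral.
#' @param restrict `"none"` or `"tau_equal"`.
#' @param control Passed to [stats::optim()] (`maxit`, `reltol` and
#'   `parscale` defaulted).
#' @param restarts Nelder-Mead restarts from the terminal point if the
#'   simplex degenerates before convergence (default 2).
#' @param hessian Compute a numeric Hessian at the optimum?
#' @return An object of class `nm_fit`: `params` (estimates on the natural
#'   scale), `transformed` (estimates on the fitting scale), `loglik`,
#'   `converged`, `n_evaluations`, `restrict`, `quad_order`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(simulation_config(n_patients = 500, seed = 1))
#' fit <- fit_natmets(cohort)
#' fit$params
#' }
#' @export
fit_natmets <- function(cohort, init = reference_params(), quad_order = 60,
                        restrict = c("none", "tau_equal"),
                        control = list(), restarts = 2, hessian = FALSE) {
  restrict <- match.arg(restrict)
  validate_cohort(cohort)
  k <- init$seeding$k
  const <- init$const
  v0 <- params_to_transformed(init)
  free <- if (restrict == "tau_equal") {
    v0["log_mu"] <- 0
    !(transformed_names %in% c("log_mu", "beta0", "beta1"))
  } else rep(TRUE, 8L)

  n_eval <- 0L
  objective <- function(x) {
    n_eval <<- n_eval + 1L
    full <- v0
    full[free] <- x
    # invalid regions of the transformed space (e.g. a non-positive
    # sensitivity slope) are rejected, not fatal
    theta <- try(transformed_to_params(full, k = k, const = const),
                 silent = TRUE)
    if (inherits(theta, "try-error")) return(1e10)
    ll <- suppressWarnings(cohort_loglik(cohort, theta, quad_order))
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  ctrl <- utils::modifyList(list(maxit = 3000, reltol = 1e-9), control)
  if (is.null(ctrl$parscale))
    ctrl$parscale <- pmax(abs(v0[free]), 0.25)
  opt <- stats::optim(v0[free], objective, method = "Nelder-Mead",
                      control = ctrl)
  # Nelder-Mead can stall with a degenerate simplex (code 10); restarting
  # from the terminal point rebuilds the simplex and usually completes
  for (restart in seq_len(restarts)) {
    if (opt$convergence == 0L) break
    opt <- stats::optim(opt$par, objective, method = "Nelder-Mead",
                        control = ctrl)
  }
  full <- v0
  full[free] <- opt$par
  out <- list(params = transformed_to_params(full, k = k, const = const),
              transformed = full, loglik = -opt$value,
              converged = opt$convergence == 0L,
              n_evaluations = n_eval, restrict = restrict,
              quad_order = quad_order, free = free)
  if (hessian)
    out$hessian <- stats::optimHess(opt$par, objective)
  if (!out$converged)
    warning("optimiser did not converge (code ", opt$convergence,
            "); estimates returned with converged = FALSE")
  structure(out, class = "nm_fit")
}

#' @export
print.nm_fit <- function(x, ...) {
  cat(sprintf("Natural-history model fit (log-likelihood %.3f, %sconverged, %d evaluations)\n",
              x$loglik, if (x$converged) "" else "NOT ", x$n_evaluations))
  print(x$params)
  if (!is.null(x$ci)) {
    cat("Bootstrap 95% percentile intervals (transformed scale):\n")
    print(round(x$ci, 4))
  }
  invisible(x)
}

#' Nonparametric bootstrap confidence intervals
#'
#' Resamples patients with replacement, refits from the point estimate, and
#' returns percentile intervals on the transformed scale. Replicates that
#' fail to converge are recorded and excluded. Each replicate uses a seed
#' derived from `seed`, so results are reproducible and independent of
#' evaluation order.
#'
#' @param cohort The cohort that was fitted.
#' @param fit An `nm_fit` from [fit_natmets()].
#' @param B Number of bootstrap replicates (1500 for production-quality
#'   intervals; far fewer suffice for smoke testing).
#' @param seed Master seed.
#' @param level Confidence level (default 0.95).
#' @param control Optimiser control for the replicate fits.
#' @return The `nm_fit` augmented with `replicates` (B x 8 matrix on the
#'   transformed scale, `NA` rows for failures), `ci` (percentile bounds)
#'   and `n_failed`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(simulation_config(n_patients = 500, seed = 1))
#' fit <- fit_natmets(cohort)
#' fit <- bootstrap_natmets(cohort, fit, B = 25, seed = 2)
#' fit$ci
#' }
#' @export
bootstrap_natmets <- function(cohort, fit, B = 1500, seed = 1, level = 0.95,
                              control = list(maxit = 1000)) {
  stopifnot(inherits(fit, "nm_fit"), B >= 1)
  n <- nrow(cohort)
  reps <- matrix(NA_real_, B, 8L,
                 dimnames = list(NULL, transformed_names))
  set.seed(seed)
  sub_seeds <- sample.int(2^31 - 1, B)
  failed <- 0L
  for (b in seq_len(B)) {
    set.seed(sub_seeds[b])
    idx <- sample.int(n, n, replace = TRUE)
    rb <- try(fit_natmets(cohort[idx, , drop = FALSE], init = fit$params,
                          quad_order = fit$quad_order,
                          restrict = fit$restrict, control = control),
              silent = TRUE)
    if (inherits(rb, "try-error") || !rb$converged) {
      failed <- failed + 1L
    } else {
      reps[b, ] <- rb$transformed
    }
  }
  alpha <- (1 - level) / 2
  ok <- stats::complete.cases(reps)
  ci <- t(apply(reps[ok, , drop = FALSE], 2, stats::quantile,
                probs = c(alpha, 1 - alpha), names = FALSE))
  colnames(ci) <- paste0(c("lower_", "upper_"), format(100 * level), "%")
  fit$replicates <- reps
  fit$ci <- ci
  fit$n_failed <- failed
  fit$bootstrap_seed <- seed
  fit
}
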