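# Quadrature scaffolding for the r-integral. The integrand T(w|r,v)H(r) is
# only piecewise smooth in r: the cure clamp of the W law introduces a kink
# (and, for event records, a jump of the density to zero) at
# r = g(w)/log(v_m/v_cell), a second kink at r = g(w)/log(v_m/v) when the
# tumour is below the metastasis-detection size, and each recorded screen
# adds a kink where its back-calculated diameter crosses the detectability
# floor. A global smooth rule converges poorly across such points, so the
# integral is assembled from Gauss-Legendre panels between the record's own
# breakpoints plus a shifted Gauss-Laguerre tail, all weighted by the
# gamma posterior density of r given tumour size.
piecewise_rules <- function(order) {
  m <- max(8L, as.integer(round(order / 4)))
  m_tail <- max(16L, as.integer(round(order / 2)))
  key <- sprintf("pw_%d", order)
  rule <- .nm_cache[[key]]
  if (is.null(rule)) {
    leg <- pracma::gaussLegendre(m, 0, 1)
    lag <- pracma::gaussLaguerre(m_tail, 0)
    rule <- list(xl = leg$x, wl = leg$w, xt = lag$x, wt = lag$w)
    .nm_cache[[key]] <- rule
  }
  rule
}

loglik_contributions <- function(cohort, params, quad_order = 60,
                                 extend_history = TRUE, screen_interval = 2) {
  const <- params$const
  gp <- params$growth; dp <- params$detection; scp <- params$screening
  sp <- params$seeding; mp <- params$metastasis
  kp1 <- sp$k + 1

  n <- nrow(cohort)
  d_det <- cohort$diameter_mm
  v <- diameter_to_volume(d_det)
  w <- cohort$followup_years
  t1 <- cohort$treat_start_years
  t2 <- cohort$treat_stop_years - cohort$treat_start_years
  ev <- cohort$event

  shape <- gp$tau1 + 1
  rate <- gp$tau2 + dp$eta * (v - const$v0)

  # discounted time since diagnosis and active phi at the follow-up time
  # (right-continuous at period boundaries); per-record treatment timing
  # enters only through (treat_start, treat_stop) with a common phi2
  g <- pmin(w, t1) + pmin(pmax(w - t1, 0), t2) / params$phi2 +
    pmax(w - t1 - t2, 0)
  phi_w <- ifelse(t2 > 0 & w >= t1 & w < t1 + t2, params$phi2, 1)
  cap <- log(v / const$v_cell)
  logvm <- log(v / mp$v_m)

  lags <- parse_screen_lags(cohort$screen_lags_years)
  nlag <- lengths(lags)
  l_max <- max(c(nlag, 0L))
  lag_mat <- matrix(0, n, l_max)
  for (l in seq_len(l_max)) {
    idx <- nlag >= l
    lag_mat[idx, l] <- vapply(lags[idx], `[[`, numeric(1), l)
  }

  # per-record breakpoints of the integrand, padded with zeros (a zero-width
  # panel contributes nothing): the W-law clamp radii and the recorded
  # screens' detectability-floor kinks, plus fixed posterior quantiles so
  # that the bulk of the gamma mass is covered by Legendre panels and the
  # Laguerre rule only handles the far tail
  bk <- cbind(g / log(mp$v_m / const$v_cell),
              ifelse(v < mp$v_m, g / log(mp$v_m / v), 0))
  if (l_max > 0) {
    kink <- lag_mat / (3 * log(d_det / const$d0))
    kink[lag_mat == 0 | !is.finite(kink) | kink < 0] <- 0
    bk <- cbind(bk, kink)
  }
  x_q <- stats::qgamma(c(0.05, 0.25, 0.5, 0.75, 0.92, 0.995), shape = shape)
  bk <- cbind(bk, outer(1 / rate, x_q))
  bk[!is.finite(bk) | bk < 0] <- 0
  bk <- t(apply(bk, 1, sort))

  rule <- piecewise_rules(quad_order)
  m <- length(rule$xl); m_tail <- length(rule$xt)
  n_piece <- ncol(bk)
  M <- n_piece * m + m_tail
  R <- matrix(0, n, M)
  WT <- matrix(0, n, M)
  lo <- numeric(n)
  for (p in seq_len(n_piece)) {
    hi <- bk[, p]
    width <- hi - lo
    cols <- ((p - 1L) * m + 1L):(p * m)
    R[, cols] <- lo + outer(width, rule$xl)
    WT[, cols] <- outer(width, rule$wl) *
      stats::dgamma(R[, cols, drop = FALSE], shape = shape, rate = rate)
    lo <- hi
  }
  tail_cols <- (n_piece * m + 1L):M
  R[, tail_cols] <- lo + outer(1 / rate, rule$xt)
  # Laguerre weights absorb e^{-x}; restore it against the gamma density in
  # log space to avoid overflow of e^{x} at the far nodes
  lw <- stats::dgamma(R[, tail_cols, drop = FALSE], shape = shape,
                      rate = rate, log = TRUE) +
    rep(rule$xt, each = n) - log(rate)
  WT[, tail_cols] <- rep(rule$wt, each = n) * exp(lw)

  # seeding-clock argument of the W law, clamped to [0, log(v/v_cell)]
  A <- logvm + g / R
  Ac <- pmin(pmax(A, 0), cap)
  S <- exp(-sp$sigma * Ac^kp1)

  # negative-screen history factors: recorded screens, plus the regular-
  # screener ladder extension beyond the oldest recorded one (charges
  # slow-growth parameter values for the screening exposure a long-lived
  # asymptomatic tumour must have survived)
  H <- history_factor_matrix(d_det, lags, R, scp, const,
                             extend_history, screen_interval, weights = WT)

  # event-type factor: density for events, survival for right-censored,
  # the (r-free) atom at w = 0 for metastases present at primary diagnosis
  TT <- S
  i_ev <- which(ev == "mets")
  if (length(i_ev)) {
    h <- sp$sigma * kp1 * A[i_ev, , drop = FALSE]^sp$k /
      (phi_w[i_ev] * R[i_ev, , drop = FALSE])
    Ae <- A[i_ev, , drop = FALSE]
    h[Ae <= 0 | Ae >= cap[i_ev]] <- 0
    TT[i_ev, ] <- h * S[i_ev, , drop = FALSE]
  }
  i_atom <- which(ev == "mets_at_dx")
  if (length(i_atom))
    TT[i_atom, ] <- W_atom(v[i_atom], mp, sp)

  integral <- rowSums(TT * H * WT)

  # size-at-detection factor by mode of detection. For screen-detected
  # cases the size factor is the unnormalised asymptomatic prevalence mass
  # f_Vdet(v)/(eta*v): the probability of carrying an asymptomatic tumour at
  # a screen is proportional to the expected asymptomatic sojourn, which
  # cancels the normaliser of the asymptomatic size density; only the
  # parameter-free screening-interval constant is dropped. Dropping instead
  # the parameter-dependent sojourn mass would misweight the two detection
  # modes and bias the growth parameters.
  base <- log(size_symptomatic_density(v, gp, dp, const))
  i_scr <- which(cohort$mode == "screen")
  if (length(i_scr)) {
    base[i_scr] <- log(screen_sensitivity(d_det[i_scr], scp, const)) +
      base[i_scr] - log(dp$eta * v[i_scr])
  }

  ll <- base + ifelse(integral > 0, log(pmax(integral, 1e-323)), -Inf)
  ll
}

#' Per-patient and cohort log-likelihood
#'
#' The likelihood contribution of a patient is the joint density of tumour
#' size at diagnosis and metastasis-free follow-up, conditional on the mode
#' of detection and screening history. For a symptomatically detected
#' patient it is \eqn{f_{V_{det}}(v) \int T(w \mid r, v)\, P(\text{negative
#' screens} \mid v, r)\, f(r \mid v)\, dr}; for a screen-detected patient the
#' size factor is instead the screening sensitivity at diagnosis times the
#' asymptomatic prevalence mass \eqn{f_{V_{det}}(v)/(\eta v)} (the
#' asymptomatic-size density scaled by the expected asymptomatic sojourn, so
#' that the two detection modes are weighted as the single data-generating
#' process implies). The event factor T is the W density for an observed metastasis,
#' the W survival for a right-censored patient, and the r-free atom at w = 0
#' for a metastasis already present at primary diagnosis (left-censored).
#' Integration over the inverse growth rate uses piecewise Gaussian
#' quadrature against the gamma law of r given tumour size, with panels
#' split at the integrand's own breakpoints (the cure clamp of the W law and
#' the detectability floor of each back-calculated screen), so that every
#' panel is smooth.
#'
#' `cohort_loglik()` sums the per-record contributions; a record whose
#' contribution underflows to `-Inf` (e.g. an event time beyond the maximum
#' metastasis-detection time at every quadrature node) makes the sum `-Inf`
#' and is listed in the `bad_records` attribute.
#'
#' Women with a recorded screening history are treated as regular screeners:
#' the biennial ladder of negative screens is extended beyond the oldest
#' recorded one (each older screen's negativity probability is
#' back-calculated, reaching 1 once the implied diameter is undetectable).
#' This charges slow-growth parameter values for the screening exposure a
#' long-lived asymptomatic tumour must have survived; without it the
#' likelihood is improper along the slow-growth direction. Set
#' `extend_history = FALSE` to condition on the recorded screens only.
#'
#' @param rec A single-row cohort (see [as_cohort()]).
#' @param cohort A cohort.
#' @param params Model parameters, see [model_params()].
#' @param quad_order Quadrature budget for the growth-rate integral: each
#'   smooth panel uses `quad_order / 4` Gauss-Legendre nodes and the tail
#'   `quad_order / 2` Gauss-Laguerre nodes (default 60).
#' @param extend_history Extend each recorded screening ladder indefinitely
#'   at `screen_interval` (default `TRUE`).
#' @param screen_interval Spacing of the extended ladder, years (default 2).
#' @param contributions Return the per-record vector instead of the sum?
#' @return Log-likelihood (scalar, or vector if `contributions = TRUE`).
#' @examples
#' theta <- reference_params()
#' cohort <- simulate_cohort(simulation_config(n_patients = 100, seed = 1))
#' cohort_loglik(cohort, theta)
#' @export
cohort_loglik <- function(cohort, params, quad_order = 60,
                          extend_history = TRUE, screen_interval = 2,
                          contributions = FALSE) {
  stopifnot(nrow(cohort) >= 1L)
  ll <- loglik_contributions(cohort, params, quad_order, extend_history,
                             screen_interval)
  if (contributions) return(ll)
  out <- sum(ll)
  if (!is.finite(out)) {
    bad <- which(!is.finite(ll))
    attr(out, "bad_records") <- bad
    warning("non-finite contribution for record(s): ",
            paste(utils::head(bad, 10L), collapse = ", "))
  }
  out
}

#' @rdname cohort_loglik
#' @export
loglik_symptomatic <- function(rec, params, quad_order = 60,
                               extend_history = TRUE, screen_interval = 2) {
  stopifnot(nrow(rec) == 1L, rec$mode == "symptomatic")
  loglik_contributions(rec, params, quad_order, extend_history,
                       screen_interval)
}

#' @rdname cohort_loglik
#' @export
loglik_screen_detected <- function(rec, params, quad_order = 60,
                                   extend_history = TRUE,
                                   screen_interval = 2) {
  stopifnot(nrow(rec) == 1L, rec$mode == "screen")
  loglik_contributions(rec, params, quad_order, extend_history,
                       screen_interval)
}
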