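# shared internals: per-patient posterior quadrature nodes and history-
# weighted integration weights, and the discounted clock for the three-period
# schedule (vectorised over patients at a scalar time)
patient_quadrature <- function(cohort, params, quad_order,
                               extend_history = TRUE, screen_interval = 2) {
  const <- params$const
  gp <- params$growth; dp <- params$detection
  v <- diameter_to_volume(cohort$diameter_mm)
  shape <- gp$tau1 + 1
  rate <- gp$tau2 + dp$eta * (v - const$v0)
  rule <- gauss_laguerre_rule(shape, quad_order)
  R <- outer(1 / rate, rule$x)
  lags <- parse_screen_lags(cohort$screen_lags_years)
  wq <- matrix(rule$w / gamma(shape), nrow(cohort), quad_order, byrow = TRUE)
  H <- history_factor_matrix(cohort$diameter_mm, lags, R, params$screening,
                             const, extend_history, screen_interval,
                             weights = wq)
  list(R = R, wqH = H * rep(rule$w / gamma(shape), each = nrow(cohort)),
       v = v, cap = log(v / const$v_cell))
}

g_main <- function(t, t1, t2, phi2) {
  pmin(t, t1) + pmin(pmax(t - t1, 0), t2) / phi2 + pmax(t - t1 - t2, 0)
}

# on-treatment indicator at time t (right-continuous: the instant treatment
# starts counts as treated, the instant it stops as untreated)
treatment_status <- function(cohort, t) {
  on <- cohort$treat_stop_years > cohort$treat_start_years &
    t >= cohort$treat_start_years & t < cohort$treat_stop_years
  ifelse(on, "treated", "untreated")
}

#' Predicted metastasis-free survival for a patient profile
#'
#' The model-based survival curve for time from primary diagnosis to
#' metastasis detection, conditional on no distant metastasis at diagnosis,
#' for a given tumour diameter, screening history and treatment schedule:
#' \deqn{\tilde S(w) = \frac{\int S_W(w \mid r, v)\, P(\mathrm{neg.\
#' screens} \mid v, r)\, f(r \mid v)\, dr}{\int S_W(0 \mid r, v)\,
#' P(\mathrm{neg.\ screens} \mid v, r)\, f(r \mid v)\, dr}.}
#' Starts at 1, is non-increasing, and is bounded below by the conditional
#' cure fraction.
#'
#' @param diameter_mm Primary tumour diameter at diagnosis, mm.
#' @param screen_lags Times of prior negative screens, years before
#'   diagnosis (may be empty).
#' @param sched Treatment schedule, see [treatment_schedule()].
#' @param params Model parameters.
#' @param times Evaluation times, years since diagnosis (ascending, >= 0).
#' @param quad_order Quadrature order.
#' @return A data frame with columns `time` and `surv`.
#' @examples
#' s5 <- main_schedule(0, 5, reference_params()$phi2)
#' predict_mfs(20, c(1, 3, 5), s5, reference_params(), times = c(5, 10))
#' @export
predict_mfs <- function(diameter_mm, screen_lags, sched, params,
                        times = seq(0, 15, by = 0.1), quad_order = 60) {
  stopifnot(diameter_mm > params$const$d0, all(times >= 0),
            !is.unsorted(times), inherits(sched, "nm_schedule"))
  const <- params$const
  v <- diameter_to_volume(diameter_mm)
  mp <- params$metastasis
  post <- growth_rate_posterior(v, params$growth, params$detection, const)
  rule <- piecewise_rules(quad_order)
  x_q <- stats::qgamma(c(0.05, 0.25, 0.5, 0.75, 0.92, 0.995),
                       shape = post$shape) / post$rate
  f <- function(r, w) {
    history_negative_probability(v, r, screen_lags, params$screening, const) *
      W_survival(w, r, v, sched, mp, params$seeding, const) *
      post$density(r)
  }
  num <- vapply(c(0, times), function(w) {
    # panel quadrature split at the integrand's own breakpoints: the W-law
    # clamp radii, the screens' detectability-floor kinks, and fixed
    # posterior quantiles covering the bulk of the gamma mass
    g_w <- discounted_time(sched, w)
    bk <- c(g_w / log(mp$v_m / const$v_cell),
            if (v < mp$v_m) g_w / log(mp$v_m / v),
            screen_lags / (3 * log(diameter_mm / const$d0)), x_q)
    bk <- sort(unique(pmax(bk[is.finite(bk)], 0)))
    lo <- c(0, bk)
    hi <- bk
    total <- 0
    for (p in seq_along(hi)) {
      width <- hi[p] - lo[p]
      if (width > 0)
        total <- total + width *
          sum(rule$wl * f(lo[p] + width * rule$xl, w))
    }
    b_last <- max(c(0, bk))
    r_tail <- b_last + rule$xt / post$rate
    total + sum(rule$wt * exp(log(f(r_tail, w)) + rule$xt -
                                log(post$rate)))
  }, numeric(1))
  data.frame(time = times, surv = num[-1] / num[1])
}

#' Compare 5- versus 10-year treatment durations across tumour sizes
#'
#' Computes paired predicted metastasis-free survival curves under two
#' hypothetical treatment durations (treatment starting at diagnosis) for a
#' set of tumour diameters, together with the area between each pair of
#' curves — the expected metastasis-free time gained per patient by the
#' longer duration over the evaluation horizon. The screening history is
#' the standard scenario of a regular biennial screener: a screen-detected
#' case has prior negative screens at 2, 4, 6, ... years; a symptomatic case
#' at 1, 3, 5, ... years (most recent screen one year before diagnosis).
#'
#' @param diameters Tumour diameters at diagnosis, mm.
#' @param params Model parameters.
#' @param mode `"symptomatic"` or `"screen"` detection scenario.
#' @param durations Two treatment durations, years (default `c(5, 10)`).
#' @param n_prior_screens Number of prior negative screens (default 3).
#' @param screen_interval Years between screens (default 2).
#' @param horizon End of the evaluation grid, years (default 15).
#' @param dt Grid step, years.
#' @param quad_order Quadrature order.
#' @return A list with `curves` (long data frame: `diameter_mm`,
#'   `duration`, `time`, `surv`) and `gain` (data frame: `diameter_mm`,
#'   `gain_years`, the area between the paired curves).
#' @examples
#' cmp <- compare_durations(c(10, 20), reference_params(), dt = 0.5)
#' cmp$gain
#' @export
compare_durations <- function(diameters, params,
                              mode = c("symptomatic", "screen"),
                              durations = c(5, 10), n_prior_screens = 3,
                              screen_interval = 2, horizon = 15, dt = 0.1,
                              quad_order = 60) {
  mode <- match.arg(mode)
  stopifnot(length(durations) == 2L, durations[1] < durations[2])
  first_lag <- if (mode == "symptomatic") screen_interval / 2 else
    screen_interval
  lags <- first_lag + screen_interval * (seq_len(n_prior_screens) - 1)
  times <- seq(0, horizon, by = dt)
  curves <- list()
  gain <- numeric(length(diameters))
  for (i in seq_along(diameters)) {
    s <- lapply(durations, function(dur)
      predict_mfs(diameters[i], lags, main_schedule(0, dur, params$phi2),
                  params, times, quad_order))
    for (j in 1:2)
      curves[[length(curves) + 1L]] <-
        data.frame(diameter_mm = diameters[i], duration = durations[j],
                   time = times, surv = s[[j]]$surv)
    gain[i] <- pracma::trapz(times, s[[2]]$surv - s[[1]]$surv)
  }
  list(curves = do.call(rbind, curves),
       gain = data.frame(diameter_mm = diameters, gain_years = gain))
}

#' Extended Kaplan-Meier estimator under treatment switching
#'
#' Product-limit survival per treatment group in which the risk sets are
#' re-evaluated at every event time according to each patient's current
#' treatment status: \eqn{S_k(t) = \prod_{j: t_j \le t} (1 - d_{jk} /
#' n_{jk})} with \eqn{n_{jk}} the number at risk in group k just before
#' event time \eqn{t_j} and \eqn{d_{jk}} the events in group k at
#' \eqn{t_j}. With no switching it reduces to the standard Kaplan-Meier
#' estimator. Patients with metastases at primary diagnosis are excluded.
#'
#' @param cohort A cohort.
#' @param group_fn A function `(cohort, t)` returning the group label of
#'   each patient at time t. Default: current treatment status
#'   (`"treated"` / `"untreated"`).
#' @return A data frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `surv` (one row per group and event time).
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_patients = 500, seed = 9))
#' km <- extended_km(cohort)
#' head(km)
#' @export
extended_km <- function(cohort, group_fn = treatment_status) {
  cohort <- cohort[cohort$event != "mets_at_dx", , drop = FALSE]
  ev_times <- sort(unique(cohort$followup_years[cohort$event == "mets"]))
  if (!length(ev_times)) stop("no metastatic events in cohort")
  groups <- sort(unique(unlist(lapply(c(0, ev_times),
                                      function(t) group_fn(cohort, t)))))
  out <- list()
  for (k in groups) {
    surv <- 1
    rows <- vector("list", length(ev_times))
    for (j in seq_along(ev_times)) {
      tj <- ev_times[j]
      lab <- group_fn(cohort, tj)
      at_risk <- cohort$followup_years >= tj & lab == k
      n_jk <- sum(at_risk)
      d_jk <- sum(at_risk & cohort$event == "mets" &
                    cohort$followup_years == tj)
      if (n_jk == 0L && d_jk > 0L)
        stop("event at t = ", tj, " in group '", k, "' with empty risk set")
      if (n_jk > 0L) surv <- surv * (1 - d_jk / n_jk)
      rows[[j]] <- data.frame(group = k, time = tj, n_risk = n_jk,
                              n_event = d_jk, surv = surv)
    }
    out[[k]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Model-based analogue of the extended Kaplan-Meier estimator
#'
#' For goodness of fit, mimics [extended_km()] with model-predicted
#' conditional survival: time is divided into intervals of length `dt`; at
#' the start of each interval the observed at-risk sets are split by
#' current treatment status, the model-predicted conditional probability of
#' surviving the interval (given survival so far, tumour size, screening
#' history and the patient's own treatment schedule) is averaged within
#' each group, and the sequential products of these averages form smooth
#' curves comparable with the extended Kaplan-Meier steps.
#'
#' @param cohort A cohort (patients with metastases at diagnosis are
#'   excluded).
#' @param params Model parameters (typically a fit's estimates).
#' @param dt Interval length in years (default 0.1).
#' @param t_max End of the grid (default: last follow-up time).
#' @param group_fn Grouping rule as in [extended_km()].
#' @param quad_order Quadrature order.
#' @param extend_history,screen_interval Regular-screener ladder extension of
#'   each patient's recorded screening history, as in [cohort_loglik()].
#' @return A data frame with columns `group`, `time`, `surv`. Over intervals
#'   in which a group's risk set is empty the curve is carried flat, just as
#'   an event-free interval leaves the product-limit estimator unchanged.
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_patients = 300, seed = 9))
#' mk <- model_based_km(cohort, reference_params(), dt = 0.5, t_max = 10)
#' head(mk)
#' @export
model_based_km <- function(cohort, params, dt = 0.1, t_max = NULL,
                           group_fn = treatment_status, quad_order = 40,
                           extend_history = TRUE, screen_interval = 2) {
  cohort <- cohort[cohort$event != "mets_at_dx", , drop = FALSE]
  if (is.null(t_max)) t_max <- max(cohort$followup_years)
  grid <- seq(0, t_max, by = dt)
  pq <- patient_quadrature(cohort, params, quad_order, extend_history,
                           screen_interval)
  sp <- params$seeding; mp <- params$metastasis
  t1 <- cohort$treat_start_years
  t2 <- cohort$treat_stop_years - cohort$treat_start_years
  num <- function(t) {  # marginal survival numerator per patient
    a <- log(pq$v / mp$v_m) + g_main(t, t1, t2, params$phi2) / pq$R
    a <- pmin(pmax(a, 0), pq$cap)
    rowSums(pq$wqH * exp(-sp$sigma * a^(sp$k + 1)))
  }
  S_grid <- matrix(vapply(grid, num, numeric(nrow(cohort))),
                   nrow = nrow(cohort))                # n x length(grid)
  groups <- sort(unique(unlist(lapply(grid, function(t) group_fn(cohort, t)))))
  out <- list()
  for (k in groups) {
    surv <- numeric(length(grid))
    surv[1] <- 1
    for (m in seq_len(length(grid) - 1L)) {
      tm <- grid[m]
      lab <- group_fn(cohort, tm)
      at_risk <- cohort$followup_years >= tm & lab == k
      # an interval with an empty risk set contributes no factor, exactly as
      # an event-free interval contributes none to the product-limit steps
      fac <- if (any(at_risk))
        mean(S_grid[at_risk, m + 1L] / S_grid[at_risk, m]) else 1
      surv[m + 1L] <- surv[m] * fac
    }
    out[[k]] <- data.frame(group = k, time = grid, surv = surv)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
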