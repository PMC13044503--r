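#' Mammography screening sensitivity
#'
#' The probability that a tumour of diameter d (mm) is detected at a screen,
#' modelled as `expit(beta0 + beta1 * d)` for d above the minimum detectable
#' diameter `d0` and exactly 0 at or below it.
#'
#' @param d Tumour diameter at the screen, mm (>= 0). Vectorised.
#' @param scp Screening parameters, see [screening_params()].
#' @param const Size constants.
#' @return Detection probability.
#' @examples
#' scp <- screening_params(-4.713, 0.426)
#' screen_sensitivity(c(5, 10, 15), scp)  # 0.070, 0.389, 0.843
#' @export
screen_sensitivity <- function(d, scp, const = size_constants()) {
  if (any(d < 0)) stop("d must be non-negative")
  ifelse(d > const$d0, stats::plogis(scp$beta0 + scp$beta1 * d), 0)
}

#' Probability of an observed series of negative screens
#'
#' Given the volume at diagnosis and the inverse growth rate r, deterministic
#' exponential growth back-calculates the tumour diameter at each earlier
#' screen: a screen attended `lag` years before diagnosis saw diameter
#' \eqn{d(\Delta) = d_{det} e^{-\Delta/(3r)}} (volume scales as diameter
#' cubed). The probability that all recorded screens were negative is the
#' product of `1 - sensitivity` over the back-calculated diameters; screens
#' predating tumour onset (back-calculated volume below one cell) or below
#' the detectable diameter contribute a factor of 1. Screen outcomes are
#' conditionally independent given the size trajectory.
#'
#' @param v_det Tumour volume at diagnosis, mm^3.
#' @param r Inverse growth rate(s), years. Vectorised.
#' @param lags Times of attended screens before diagnosis, years (positive).
#'   May be empty.
#' @param scp Screening parameters.
#' @param const Size constants.
#' @return Probability in (0, 1], one per value of `r`.
#' @examples
#' scp <- screening_params(-4.713, 0.426)
#' history_negative_probability(diameter_to_volume(20), 1.2, c(1, 3, 5), scp)
#' @export
history_negative_probability <- function(v_det, r, lags, scp,
                                         const = size_constants()) {
  if (length(lags) == 0L) return(rep(1, length(r)))
  if (any(lags <= 0)) stop("screen lags must be positive")
  d_det <- volume_to_diameter(v_det)
  out <- rep(1, length(r))
  for (lag in lags) {
    d <- d_det * exp(-lag / (3 * r))
    out <- out * (1 - screen_sensitivity(d, scp, const))
  }
  out
}

# Negative-history factors for a set of records evaluated on a node matrix R
# (records x integration nodes): product over each record's recorded screen
# lags of 1 - sensitivity at the back-calculated diameter, optionally
# extending the ladder beyond the oldest recorded screen at screen_interval
# (the regular-screener assumption). A screen whose back-calculated diameter
# is at or below d0 contributes 1; the extension therefore terminates at
# lag >= 3r*log(d/d0).
history_factor_matrix <- function(d_det, lags, R, scp, const,
                                  extend_history = TRUE, screen_interval = 2,
                                  weights = NULL) {
  n <- length(d_det)
  M <- ncol(R)
  nlag <- lengths(lags)
  H <- matrix(1, n, M)
  for (l in seq_len(max(c(nlag, 0L)))) {
    idx <- which(nlag >= l)
    lag_l <- vapply(lags[idx], `[[`, numeric(1), l)
    d_back <- d_det[idx] * exp(-lag_l / (3 * R[idx, , drop = FALSE]))
    sens <- (d_back > const$d0) / (1 + exp(-(scp$beta0 + scp$beta1 * d_back)))
    H[idx, ] <- H[idx, , drop = FALSE] * (1 - sens)
  }
  if (extend_history && any(nlag > 0L)) {
    has <- nlag > 0L
    l0 <- numeric(n)
    l0[has] <- vapply(lags[has], max, numeric(1))
    lim <- 3 * R * log(d_det / const$d0)
    lim[!has, ] <- -Inf
    k <- 0L
    act <- which(l0 + screen_interval < lim)
    if (length(act) && !is.null(weights)) {
      # entries with negligible integration weight cannot influence the
      # integral: leave their deep-ladder factors at 1
      rmax <- do.call(pmax, c(asplit(abs(weights), 2), list(0)))
      act <- act[abs(weights[act]) > rmax[(act - 1L) %% n + 1L] * 1e-14]
    }
    if (length(act)) {
      row <- (act - 1L) %% n + 1L
      d_a <- d_det[row]; r_a <- R[act]; l0_a <- l0[row]; lim_a <- lim[act]
      h_a <- rep(1, length(act))
      while (length(act) && k < 200L) {
        k <- k + 1L
        lag_a <- l0_a + k * screen_interval
        d_back <- d_a * exp(-lag_a / (3 * r_a))
        h_a <- h_a * (1 - 1 / (1 + exp(-(scp$beta0 + scp$beta1 * d_back))))
        live <- lag_a + screen_interval < lim_a & h_a > 1e-60
        if (!all(live)) {
          drop_i <- act[!live]
          H[drop_i] <- H[drop_i] * h_a[!live]
          act <- act[live]; d_a <- d_a[live]; r_a <- r_a[live]
          l0_a <- l0_a[live]; lim_a <- lim_a[live]; h_a <- h_a[live]
        }
      }
      if (length(act)) H[act] <- H[act] * h_a
    }
  }
  H
}

#' Simulate screen outcomes along a tumour trajectory
#'
#' Applies the size-dependent sensitivity independently at each scheduled
#' screen: a screen held `t` years after tumour onset sees diameter
#' \eqn{d_{cell} e^{t/(3r)}} and is positive with probability
#' [screen_sensitivity()]; screens before onset are always negative. Uses
#' R's global random number stream.
#'
#' @param screen_times Times of scheduled screens, years since tumour onset
#'   (may be negative for screens predating onset), sorted ascending.
#' @param r Inverse growth rate, years.
#' @param scp Screening parameters.
#' @param const Size constants.
#' @return A list with `first_positive` (time since onset of the first
#'   positive screen, or `Inf` if none) and `negatives` (times of the
#'   negative screens preceding it).
#' @examples
#' set.seed(1)
#' simulate_screen_outcomes(seq(-2, 12, by = 2), r = 1.2,
#'                          scp = screening_params(-4.713, 0.426))
#' @export
simulate_screen_outcomes <- function(screen_times, r, scp,
                                     const = size_constants()) {
  if (is.unsorted(screen_times)) stop("screen_times must be sorted")
  d <- ifelse(screen_times > 0,
              const$d_cell * exp(screen_times / (3 * r)), 0)
  sens <- screen_sensitivity(pmax(d, 0), scp, const)
  pos <- stats::runif(length(screen_times)) < sens
  first <- which(pos)[1]
  if (is.na(first)) {
    list(first_positive = Inf, negatives = screen_times)
  } else {
    list(first_positive = screen_times[first],
         negatives = screen_times[seq_len(first - 1L)])
  }
}
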