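#' Treatment schedule with period-specific growth factors
#'
#' Follow-up after primary diagnosis is divided into J consecutive periods by
#' ordered boundary times; during period j the metastasis inverse growth rate
#' is multiplied by `phis[j]`. The main analysis uses J = 3 periods: an
#' untreated lead-in of length t1 (`phi = 1`), a treatment period of length t2
#' (`phi = phi2`) and an untreated tail (`phi = 1`); a four-period variant
#' adds a carryover window after treatment ends. Zero-length periods are
#' dropped, so degenerate inputs (t1 = 0, or t2 = 0 for never-treated
#' patients) collapse cleanly.
#'
#' @param boundaries Strictly increasing non-negative period boundaries,
#'   years after primary diagnosis (length J - 1; may be empty for a single
#'   period).
#' @param phis J positive multiplicative inverse-growth-rate factors, one per
#'   period.
#' @return An object of class `nm_schedule` with fields `boundaries`, `phis`
#'   and the precomputed discounted times `g_bounds` at each boundary.
#' @seealso [main_schedule()] for the three-period constructor,
#'   [carryover_schedule()] for the four-period variant.
#' @examples
#' treatment_schedule(c(0.25, 5.25), c(1, 2.4, 1))
#' @export
treatment_schedule <- function(boundaries, phis) {
  boundaries <- as.numeric(boundaries)
  phis <- as.numeric(phis)
  if (length(phis) != length(boundaries) + 1L)
    stop("need length(phis) == length(boundaries) + 1")
  if (any(boundaries < 0)) stop("boundaries must be non-negative")
  if (any(phis <= 0)) stop("phis must be positive")
  if (is.unsorted(boundaries)) stop("boundaries must be strictly increasing")
  # drop zero-length periods (repeated boundaries, or a leading boundary at 0)
  lens <- diff(c(0, boundaries))
  keep <- lens > 0
  if (length(boundaries)) {
    boundaries <- boundaries[keep]
    phis <- c(phis[c(keep, FALSE)], phis[length(phis)])
  }
  if (is.unsorted(boundaries, strictly = TRUE))
    stop("boundaries must be strictly increasing")
  # merge adjacent periods with identical phi (keeps g piecewise minimal)
  if (length(boundaries)) {
    sep <- diff(phis) != 0
    boundaries <- boundaries[sep]
    phis <- phis[c(sep, TRUE)]
  }
  g_bounds <- cumsum(diff(c(0, boundaries)) / phis[seq_along(boundaries)])
  structure(list(boundaries = boundaries, phis = phis, g_bounds = g_bounds),
            class = "nm_schedule")
}

#' @param t1 Years from diagnosis to treatment start (>= 0).
#' @param t2 Treatment duration in years (>= 0; 0 means never treated).
#' @param phi2 Inverse-growth-rate factor while on treatment (> 0).
#' @rdname treatment_schedule
#' @export
main_schedule <- function(t1, t2, phi2) {
  stopifnot(t1 >= 0, t2 >= 0, phi2 > 0)
  treatment_schedule(c(t1, t1 + t2), c(1, phi2, 1))
}

#' @param phi3 Inverse-growth-rate factor during the carryover window, whose
#'   length equals the treatment duration `t2`.
#' @rdname treatment_schedule
#' @export
carryover_schedule <- function(t1, t2, phi2, phi3) {
  stopifnot(t1 >= 0, t2 >= 0, phi2 > 0, phi3 > 0)
  treatment_schedule(c(t1, t1 + t2, t1 + 2 * t2), c(1, phi2, phi3, 1))
}

#' @export
print.nm_schedule <- function(x, ...) {
  lo <- c(0, x$boundaries)
  hi <- c(x$boundaries, Inf)
  cat("Treatment schedule (", length(x$phis), " period(s))\n", sep = "")
  for (j in seq_along(x$phis))
    cat(sprintf("  (%.3g, %.3g]: phi = %.4g\n", lo[j], hi[j], x$phis[j]))
  invisible(x)
}

# period index for each w: right-continuous (w on a boundary belongs to the
# later period; the two branches agree there by continuity)
period_index <- function(sched, w) {
  findInterval(w, sched$boundaries, left.open = FALSE) + 1L
}

#' Phi-discounted time since diagnosis
#'
#' The piecewise-linear clock \eqn{g(w) = \sum_{i<j} L_i/\phi_i +
#' (w - b_{j-1})/\phi_j} that accumulates follow-up time divided by the
#' period factor; the log-volume gained by a metastasis between diagnosis and
#' w is `g(w)/r`. Continuous, strictly increasing, with inverse
#' [discounted_time_inverse()].
#'
#' @param sched An `nm_schedule`.
#' @param w Follow-up times since diagnosis, years (>= 0). Vectorised.
#' @param g Discounted times to invert (>= 0). Vectorised.
#' @return Years (same length as input).
#' @examples
#' s <- main_schedule(0.25, 5, 2.414)
#' discounted_time_inverse(s, discounted_time(s, c(0.1, 3, 9)))
#' @export
discounted_time <- function(sched, w) {
  if (any(w < 0)) stop("w must be non-negative")
  j <- period_index(sched, w)
  g0 <- c(0, sched$g_bounds)
  b0 <- c(0, sched$boundaries)
  g0[j] + (w - b0[j]) / sched$phis[j]
}

#' @rdname discounted_time
#' @export
discounted_time_inverse <- function(sched, g) {
  if (any(g < 0)) stop("g must be non-negative")
  j <- findInterval(g, sched$g_bounds, left.open = FALSE) + 1L
  g0 <- c(0, sched$g_bounds)
  b0 <- c(0, sched$boundaries)
  b0[j] + (g - g0[j]) * sched$phis[j]
}
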