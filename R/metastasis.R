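#' Metastasis volume under a period-wise treatment effect
#'
#' A metastasis seeded at time `ts` (since onset) grows from a single cell
#' with the same inverse growth rate r as the primary tumour; after primary
#' diagnosis its growth clock runs at rate \eqn{1/\phi_j} in treatment period
#' j. Its volume w years after diagnosis is therefore
#' \eqn{V_{cell} \exp\{(t_{det} - t_s)/r + g(w)/r\}} with g the discounted
#' time of [discounted_time()].
#'
#' @param w Years since primary diagnosis (>= 0). Vectorised.
#' @param r Inverse growth rate, years (> 0).
#' @param ts Seeding time, years since onset (0 <= ts <= t_det).
#' @param t_det Onset-to-diagnosis time of the primary tumour, years.
#' @param sched Treatment schedule, see [treatment_schedule()].
#' @param const Size constants.
#' @return Volume in mm^3.
#' @examples
#' s <- main_schedule(0.25, 5, 2.414)
#' metastasis_volume(c(0, 2, 8), r = 1.2, ts = 4, t_det = 10, sched = s)
#' @export
metastasis_volume <- function(w, r, ts, t_det, sched, const = size_constants()) {
  if (any(ts < 0) || any(ts > t_det)) stop("need 0 <= ts <= t_det")
  const$v_cell * exp((t_det - ts) / r + discounted_time(sched, w) / r)
}

#' Map between seeding time and metastasis detection time
#'
#' Given the growth model, the time W from primary diagnosis to metastasis
#' detection (the first seeded metastasis reaching volume `v_m`) is a
#' deterministic, piecewise-linear function of the seeding time Ts, with
#' slope \eqn{\phi_j} on period j. `w_given_seeding()` maps ts to w (0 when
#' the metastasis is already at or beyond `v_m` at diagnosis);
#' `ts_given_w()` is its inverse on w > 0,
#' \eqn{t_s = r \log(v_{det}/v_m) + g(w)}.
#'
#' @param ts Seeding time, years since onset (0 <= ts <= t_det). Vectorised.
#' @param w Years since diagnosis (> 0 for `ts_given_w`). Vectorised.
#' @param r Inverse growth rate (> 0).
#' @param t_det Onset-to-diagnosis time, years.
#' @param v_det Primary tumour volume at diagnosis, mm^3.
#' @param sched Treatment schedule.
#' @param mp Metastasis size parameter, see [metastasis_params()].
#' @param const Size constants.
#' @return Years.
#' @examples
#' s <- main_schedule(0.25, 5, 2.414)
#' mp <- metastasis_params(0.907)
#' w <- w_given_seeding(6, r = 1.2, t_det = 10, sched = s, mp = mp)
#' ts_given_w(w, r = 1.2, v_det = volume_at_time(10, 1.2), sched = s, mp = mp)
#' @export
w_given_seeding <- function(ts, r, t_det, sched, mp, const = size_constants()) {
  if (any(ts < 0) || any(ts > t_det)) stop("need 0 <= ts <= t_det")
  g_target <- r * log(mp$v_m / const$v_cell) - (t_det - ts)
  discounted_time_inverse(sched, pmax(g_target, 0))
}

#' @rdname w_given_seeding
#' @export
ts_given_w <- function(w, r, v_det, sched, mp, const = size_constants()) {
  ts <- r * log(v_det / mp$v_m) + discounted_time(sched, w)
  if (any(ts < 0))
    stop("w implies seeding before onset (log of non-positive volume ratio)")
  ts
}

# branch argument A(w) = log(v/v_m) + g(w)/r, the seeding clock ts/r expressed
# through w; the W law is the seeding law evaluated at A, clamped to
# [0, log(v/v_cell)] (no seeding before onset, none after diagnosis)
w_branch_argument <- function(w, r, v_det, sched, mp) {
  log(v_det / mp$v_m) + discounted_time(sched, w) / r
}

#' Distribution of time from primary diagnosis to metastasis detection
#'
#' The law of W given the inverse growth rate r and primary volume at
#' diagnosis `v_det`, under a treatment schedule. It is a cure model with
#' three pieces of probability mass: an atom at w = 0 (metastasis already at
#' detectable volume when the primary is diagnosed; only possible when
#' `v_det > v_m`), a continuous density on (0, W_max], and a terminal cure
#' mass \eqn{\exp(-\sigma \log(v_{det}/V_{cell})^{k+1})} — the probability of
#' no viable seeding before diagnosis, which depends on neither r nor the
#' treatment schedule. `W_max` (the detection time had seeding occurred at
#' the instant of diagnosis) caps the support: the hazard is zero beyond it.
#'
#' All evaluations use right-continuous period branches; at a period boundary
#' both branches agree by continuity.
#'
#' @param w Years since diagnosis (>= 0). Vectorised (recycled with `r`).
#' @param r Inverse growth rate (> 0).
#' @param v_det Primary tumour volume at diagnosis, mm^3 (> v_cell).
#' @param sched Treatment schedule.
#' @param mp Metastasis size parameter.
#' @param sp Seeding parameters.
#' @param const Size constants.
#' @return Probability (survival/atom/cure), density or hazard (per year).
#' @examples
#' s <- main_schedule(0.25, 5, 2.414)
#' mp <- metastasis_params(0.907); sp <- seeding_params(exp(-17.681))
#' v <- diameter_to_volume(20)
#' W_survival(c(0, 5, 10), r = 1.2, v_det = v, sched = s, mp = mp, sp = sp)
#' @export
W_survival <- function(w, r, v_det, sched, mp, sp, const = size_constants()) {
  if (any(w < 0)) stop("w must be non-negative")
  a <- w_branch_argument(w, r, v_det, sched, mp)
  a <- pmin(pmax(a, 0), log(v_det / const$v_cell))
  exp(-sp$sigma * a^(sp$k + 1))
}

#' @rdname W_survival
#' @export
W_density <- function(w, r, v_det, sched, mp, sp, const = size_constants()) {
  W_hazard(w, r, v_det, sched, mp, sp, const) *
    W_survival(w, r, v_det, sched, mp, sp, const)
}

#' @rdname W_survival
#' @export
W_hazard <- function(w, r, v_det, sched, mp, sp, const = size_constants()) {
  if (any(w < 0)) stop("w must be non-negative")
  a <- w_branch_argument(w, r, v_det, sched, mp)
  phij <- sched$phis[period_index(sched, w)]
  h <- sp$sigma * (sp$k + 1) * a^sp$k / (phij * r)
  h[a <= 0 | a >= log(v_det / const$v_cell)] <- 0
  h
}

#' @rdname W_survival
#' @export
W_max <- function(r, sched, mp, const = size_constants()) {
  discounted_time_inverse(sched, r * log(mp$v_m / const$v_cell))
}

#' @rdname W_survival
#' @export
W_atom <- function(v_det, mp, sp) {
  1 - exp(-sp$sigma * pmax(log(v_det / mp$v_m), 0)^(sp$k + 1))
}

#' @rdname W_survival
#' @export
cure_fraction <- function(v_det, sp, const = size_constants()) {
  if (any(v_det <= const$v_cell)) stop("v_det must exceed the single-cell volume")
  exp(-sp$sigma * log(v_det / const$v_cell)^(sp$k + 1))
}
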