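sched3 <- main_schedule(t1 = 0.25, t2 = 5, phi2 = 2.414)
mp <- metastasis_params(0.907)
sp <- seeding_params(exp(-17.681), k = 4)
v20 <- diameter_to_volume(20)

test_that("treatment schedules validate and collapse degenerate periods", {
  s <- treatment_schedule(c(1, 6), c(1, 2, 1))
  expect_equal(s$phis, c(1, 2, 1))
  # a zero-length lead-in or treatment period is dropped
  expect_equal(main_schedule(0, 5, 2)$phis, c(2, 1))
  expect_equal(main_schedule(0.25, 0, 2)$phis, 1)
  expect_equal(carryover_schedule(0.25, 3, 2.4, 1.5)$boundaries,
               c(0.25, 3.25, 6.25))
  expect_error(treatment_schedule(c(2, 1), c(1, 2, 1)), "increasing")
  expect_error(treatment_schedule(1, c(1, -2)), "positive")
  # the discounted clock and its inverse round-trip
  w <- c(0, 0.1, 0.25, 2, 5.25, 9)
  expect_equal(discounted_time_inverse(sched3, discounted_time(sched3, w)), w,
               tolerance = 1e-12)
})

test_that("metastasis volume is continuous, increasing, and collapses when phi = 1", {
  r <- 1.1; ts <- 4; t_det <- 9
  w <- seq(0, 12, by = 0.05)
  mv <- metastasis_volume(w, r, ts, t_det, sched3)
  expect_true(all(diff(mv) > 0))
  # continuity at both period boundaries
  for (b in sched3$boundaries) {
    expect_equal(metastasis_volume(b - 1e-9, r, ts, t_det, sched3),
                 metastasis_volume(b, r, ts, t_det, sched3),
                 tolerance = 1e-8)
  }
  expect_equal(metastasis_volume(0, r, ts, t_det, sched3),
               ref_const$v_cell * exp((t_det - ts) / r))
  s1 <- main_schedule(0.25, 5, 1)
  expect_equal(metastasis_volume(w, r, ts, t_det, s1),
               ref_const$v_cell * exp((t_det - ts + w) / r))
  expect_error(metastasis_volume(1, r, ts = 10, t_det = 9, sched3), "ts")
})

test_that("seeding time and metastasis detection time are mutual inverses", {
  r <- 0.8; t_det <- 10; v_det <- volume_at_time(t_det, r)
  ts <- seq(0.2, t_det, length.out = 25)
  w <- w_given_seeding(ts, r, t_det, sched3, mp)
  keep <- w > 0
  expect_equal(ts_given_w(w[keep], r, v_det, sched3, mp), ts[keep],
               tolerance = 1e-10)
  # phi = 1 algebraic simplification
  s1 <- main_schedule(0.25, 5, 1)
  expect_equal(w_given_seeding(ts, r, t_det, s1, mp),
               pmax(r * log(mp$v_m / ref_const$v_cell) - (t_det - ts), 0))
  # seeding at the instant of diagnosis reaches v_m at W_max
  expect_equal(w_given_seeding(t_det, r, t_det, sched3, mp),
               W_max(r, sched3, mp))
})

test_that("the W law has the cure-model structure", {
  r <- 1.2
  # the atom at w = 0 is free of r
  expect_equal(W_survival(0, r, v20, sched3, mp, sp),
               exp(-sp$sigma * log(v20 / mp$v_m)^5))
  expect_equal(W_survival(0, 5 * r, v20, sched3, mp, sp),
               W_survival(0, r, v20, sched3, mp, sp))
  expect_equal(W_atom(v20, mp, sp), 1 - W_survival(0, r, v20, sched3, mp, sp))
  # the terminal survival equals the cure fraction, free of r and of phi
  wbig <- W_max(r, sched3, mp) + 1
  expect_equal(W_survival(wbig, r, v20, sched3, mp, sp),
               cure_fraction(v20, sp))
  for (phi in c(0.5, 1, 3.7)) {
    s <- main_schedule(0.5, 4, phi)
    expect_equal(W_survival(W_max(r, s, mp) + 1, r, v20, s, mp, sp),
                 cure_fraction(v20, sp), tolerance = 1e-14)
  }
  # a tumour below v_m at diagnosis has no atom
  v_small <- diameter_to_volume(0.8)
  expect_equal(W_atom(v_small, mp, sp), 0)
  expect_equal(W_survival(0, r, v_small, sched3, mp, sp), 1)
})

test_that("atom + integrated density + cure mass account for all probability", {
  set.seed(77)
  for (i in 1:12) {
    r <- runif(1, 0.3, 2.5)
    v <- diameter_to_volume(runif(1, 5, 45))
    s <- main_schedule(runif(1, 0, 1), runif(1, 0, 8), runif(1, 0.8, 4))
    sp_i <- seeding_params(exp(runif(1, -19, -16)), k = 4)
    wmax <- W_max(r, s, mp)
    dens_mass <- stats::integrate(
      function(w) W_density(w, r, v, s, mp, sp_i),
      0, wmax, rel.tol = 1e-10, subdivisions = 500L)$value
    total <- W_atom(v, mp, sp_i) + dens_mass + cure_fraction(v, sp_i)
    expect_equal(total, 1, tolerance = 1e-6)
  }
})

test_that("survival is right-continuous, non-increasing and continuous at boundaries", {
  r <- 0.9
  w <- seq(0, 20, by = 0.01)
  S <- W_survival(w, r, v20, sched3, mp, sp)
  expect_true(all(diff(S) <= 1e-15))
  for (b in sched3$boundaries) {
    expect_equal(W_survival(b - 1e-9, r, v20, sched3, mp, sp),
                 W_survival(b, r, v20, sched3, mp, sp), tolerance = 1e-10)
    expect_equal(W_survival(b + 1e-9, r, v20, sched3, mp, sp),
                 W_survival(b, r, v20, sched3, mp, sp), tolerance = 1e-10)
  }
  # hazard is zero beyond W_max
  expect_equal(W_hazard(W_max(r, sched3, mp) + 0.5, r, v20, sched3, mp, sp), 0)
  expect_error(W_survival(-0.1, r, v20, sched3, mp, sp), "non-negative")
})

test_that("density equals hazard times survival and matches the change of variables", {
  r <- 1.4; t_det <- time_to_volume(v20, r)
  w <- seq(0.05, 0.98 * W_max(r, sched3, mp), length.out = 60)
  f <- W_density(w, r, v20, sched3, mp, sp)
  expect_equal(f, W_hazard(w, r, v20, sched3, mp, sp) *
                 W_survival(w, r, v20, sched3, mp, sp), tolerance = 1e-10)
  # f_W(w) = f_Ts(ts(w)) * dts/dw with dts/dw = 1/phi_j on period j
  ts <- ts_given_w(w, r, v20, sched3, mp)
  j <- findInterval(w, sched3$boundaries) + 1L
  f_cov <- seeding_density(ts, r, sp) / sched3$phis[j]
  expect_equal(f, f_cov, tolerance = 1e-10)
})

test_that("slower metastatic growth during treatment can only delay detection", {
  r <- 1.0
  s_trt <- main_schedule(0.25, 5, 2.414)
  s_no <- main_schedule(0.25, 5, 1)
  w <- seq(0.26, 20, by = 0.1)
  expect_true(all(W_survival(w, r, v20, s_trt, mp, sp) >=
                    W_survival(w, r, v20, s_no, mp, sp) - 1e-15))
})

test_that("a single period reproduces the multi-period formulas exactly", {
  r <- 0.7
  s1 <- treatment_schedule(numeric(0), 1)
  w <- seq(0, 15, by = 0.25)
  a <- pmin(pmax(log(v20 / mp$v_m) + w / r, 0), log(v20 / ref_const$v_cell))
  expect_equal(W_survival(w, r, v20, s1, mp, sp), exp(-sp$sigma * a^5))
  s3 <- main_schedule(3, 4, 1)  # phi = 1 throughout
  expect_equal(W_survival(w, r, v20, s3, mp, sp),
               W_survival(w, r, v20, s1, mp, sp))
})
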