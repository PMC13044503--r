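test_that("a metastasis at diagnosis factorises into size density and atom", {
  rec <- make_record(mode = "symptomatic", diameter_mm = 24,
                     followup_years = 0, event = "mets_at_dx")
  v <- diameter_to_volume(24)
  analytic <- log(size_symptomatic_density(v, ref_theta$growth,
                                           ref_theta$detection)) +
    log(W_atom(v, ref_theta$metastasis, ref_theta$seeding))
  expect_equal(loglik_symptomatic(rec, ref_theta), analytic,
               tolerance = 1e-9)
})

test_that("without a treatment effect the likelihood ignores treatment timing", {
  theta1 <- reference_params(phi2 = 1)
  rec_a <- make_record(followup_years = 7, event = "mets",
                       treat_start_years = 0.1, treat_stop_years = 2)
  rec_b <- make_record(followup_years = 7, event = "mets",
                       treat_start_years = 1.5, treat_stop_years = 9)
  expect_equal(loglik_symptomatic(rec_a, theta1),
               loglik_symptomatic(rec_b, theta1), tolerance = 1e-12)
})

test_that("quadrature contributions match adaptive integration on randomised records", {
  set.seed(301)
  for (i in 1:22) {
    mode <- sample(c("symptomatic", "screen"), 1)
    event <- sample(c("mets", "censored", "mets_at_dx"), 1,
                    prob = c(0.4, 0.4, 0.2))
    d <- runif(1, 6, 40)
    t1 <- runif(1, 0, 0.5); t2 <- runif(1, 0, 8)
    w <- if (event == "mets_at_dx") 0 else runif(1, 0.2, 12)
    nlag <- sample(0:4, 1)
    lags <- if (nlag) paste(round(sort(runif(nlag, 0.5, 9)), 3),
                            collapse = ";") else ""
    rec <- make_record(mode = mode, diameter_mm = d, screen_lags_years = lags,
                       treat_start_years = t1, treat_stop_years = t1 + t2,
                       followup_years = w, event = event)
    # recorded-history integrand: every breakpoint is a quadrature panel
    # boundary, so agreement is tight
    got <- cohort_loglik(rec, ref_theta, extend_history = FALSE,
                         contributions = TRUE)
    want <- record_loglik_bruteforce(rec, ref_theta, extend_history = FALSE)
    if (is.finite(want)) {
      expect_equal(got, want, tolerance = 1e-6,
                   label = sprintf("record %d (%s/%s)", i, mode, event))
    } else {
      expect_true(!is.finite(got))
    }
    # with the regular-screener ladder the integrand gains one small kink
    # per unrecorded screen; those are not panel boundaries, which bounds
    # the attainable accuracy of the fixed-order panels
    got_x <- cohort_loglik(rec, ref_theta, contributions = TRUE)
    want_x <- record_loglik_bruteforce(rec, ref_theta)
    if (is.finite(want_x)) {
      expect_equal(got_x, want_x, tolerance = 5e-4,
                   label = sprintf("extended record %d", i))
    }
  }
})

test_that("an unobservably small screen-detected tumour is impossible", {
  rec <- make_record(mode = "screen", diameter_mm = 0.4)
  expect_identical(loglik_screen_detected(rec, ref_theta), -Inf)
})

test_that("the cohort log-likelihood is a stable, order-invariant sum", {
  cohort <- simulate_cohort(simulation_config(n_patients = 80, seed = 12))
  ll <- cohort_loglik(cohort, ref_theta)
  expect_equal(ll, sum(cohort_loglik(cohort, ref_theta,
                                     contributions = TRUE)))
  set.seed(1)
  perm <- sample(nrow(cohort))
  expect_equal(cohort_loglik(cohort[perm, ], ref_theta), ll,
               tolerance = 1e-12)
  # single-record cohort equals the per-record operation
  one <- cohort[3, , drop = FALSE]
  fun <- if (one$mode == "screen") loglik_screen_detected else
    loglik_symptomatic
  expect_equal(cohort_loglik(one, ref_theta), fun(one, ref_theta))
  # bit-for-bit reproducibility
  expect_identical(cohort_loglik(cohort, ref_theta),
                   cohort_loglik(cohort, ref_theta))
})

test_that("a model-impossible record is flagged, not silently absorbed", {
  # a metastasis cannot be present at diagnosis if the primary itself is
  # smaller than the metastasis-detection size: the w = 0 atom is exactly 0
  rec <- make_record(diameter_mm = 0.8, followup_years = 0,
                     event = "mets_at_dx")
  expect_warning(ll <- cohort_loglik(rec, ref_theta), "non-finite")
  expect_identical(as.numeric(ll), -Inf)
  expect_equal(attr(ll, "bad_records"), 1L)
})

test_that("the true parameters outscore random perturbations on simulated data", {
  cohort <- simulate_cohort(simulation_config(n_patients = 400, seed = 21))
  ll_true <- cohort_loglik(cohort, ref_theta, quad_order = 40)
  v_true <- params_to_transformed(ref_theta)
  set.seed(22)
  worse <- 0L
  for (i in 1:50) {
    v <- v_true * (1 + runif(8, -0.2, 0.2))
    ll <- suppressWarnings(
      cohort_loglik(cohort, transformed_to_params(v), quad_order = 40))
    if (ll <= ll_true) worse <- worse + 1L
  }
  expect_equal(worse, 50L)
})
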