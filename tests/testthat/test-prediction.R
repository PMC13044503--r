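test_that("predicted metastasis-free survival is a proper conditional survival", {
  s5 <- main_schedule(0, 5, ref_theta$phi2)
  times <- seq(0, 30, by = 0.5)
  pr <- predict_mfs(20, c(1, 3, 5), s5, ref_theta, times)
  expect_equal(pr$surv[1], 1)
  expect_true(all(diff(pr$surv) <= 1e-12))
  # bounded below by the conditional cure fraction
  v <- diameter_to_volume(20)
  cond_cure <- cure_fraction(v, ref_theta$seeding) /
    (1 - W_atom(v, ref_theta$metastasis, ref_theta$seeding))
  expect_true(all(pr$surv >= cond_cure - 1e-9))
  expect_equal(pr$surv[length(times)], cond_cure, tolerance = 1e-3)
})

test_that("treatment-duration comparison behaves as the model dictates", {
  cmp <- compare_durations(c(5, 20, 30), ref_theta, mode = "symptomatic",
                           dt = 0.25, quad_order = 40)
  cur <- cmp$curves
  for (d in c(5, 20, 30)) {
    s5 <- cur[cur$diameter_mm == d & cur$duration == 5, ]
    s10 <- cur[cur$diameter_mm == d & cur$duration == 10, ]
    # identical while both schedules are identical, never worse afterwards
    expect_equal(s5$surv[s5$time <= 5], s10$surv[s10$time <= 5],
                 tolerance = 1e-10)
    expect_true(all(s10$surv >= s5$surv - 1e-12))
  }
  expect_true(all(cmp$gain$gain_years >= 0))
  # survival gain from extending treatment is larger for large tumours
  # (monotone over small-to-moderate sizes; at very large sizes most
  # metastases surface during the shared first five years, so the gain can
  # turn over — only the small-vs-large ordering is asserted)
  expect_lt(cmp$gain$gain_years[1], cmp$gain$gain_years[3])
  expect_lt(cmp$gain$gain_years[1], cmp$gain$gain_years[2])
  # no treatment effect -> no gain anywhere
  cmp1 <- compare_durations(20, reference_params(phi2 = 1), dt = 0.5,
                            quad_order = 40)
  expect_equal(max(abs(cmp1$gain$gain_years)), 0, tolerance = 1e-12)
})

test_that("screen-detected profiles predict no worse survival than symptomatic ones", {
  # observed behaviour at the reference parameters: conditioning on screen
  # detection (negative screens closer to diagnosis) shifts the growth-rate
  # posterior and history weights towards better prognosis
  s5 <- main_schedule(0, 5, ref_theta$phi2)
  times <- seq(0, 15, by = 0.5)
  scr <- predict_mfs(20, c(2, 4, 6), s5, ref_theta, times)
  sym <- predict_mfs(20, c(1, 3, 5), s5, ref_theta, times)
  expect_true(all(scr$surv >= sym$surv - 1e-9))
})

test_that("extended Kaplan-Meier reduces to the standard estimator without switching", {
  co <- simulate_cohort(simulation_config(n_patients = 600, seed = 71))
  co <- co[co$event != "mets_at_dx", ]
  # freeze everyone in a single group
  km <- extended_km(co, group_fn = function(cohort, t)
    rep("all", nrow(cohort)))
  sf <- survival::survfit(
    survival::Surv(followup_years, event == "mets") ~ 1, data = co)
  at_events <- summary(sf, times = km$time)
  expect_equal(km$surv, at_events$surv, tolerance = 1e-12)
})

test_that("extended Kaplan-Meier matches a hand-worked switching example", {
  df <- rbind(
    make_record(patient_id = "1", treat_start_years = 0,
                treat_stop_years = 10, followup_years = 1, event = "mets"),
    make_record(patient_id = "2", treat_start_years = 2,
                treat_stop_years = 10, followup_years = 3, event = "mets"),
    make_record(patient_id = "3", treat_start_years = 0,
                treat_stop_years = 2, followup_years = 5, event = "censored"),
    make_record(patient_id = "4", treat_start_years = 0,
                treat_stop_years = 10, followup_years = 4, event = "censored"),
    make_record(patient_id = "5", treat_start_years = 0,
                treat_stop_years = 0, followup_years = 5, event = "mets"))
  km <- extended_km(as_cohort(df))
  trt <- km[km$group == "treated", ]
  unt <- km[km$group == "untreated", ]
  # worked product-limit: treated risk sets {1,3,4}, {2,4}, {} at t = 1, 3, 5
  expect_equal(trt$surv, c(2 / 3, 1 / 3, 1 / 3))
  expect_equal(trt$n_risk, c(3L, 2L, 0L))
  # untreated risk sets {2,5}, {3,5}, {3,5}; the only event is patient 5
  expect_equal(unt$surv, c(1, 1, 1 / 2))
  # two patients, one event at t = 1
  toy <- as_cohort(rbind(
    make_record(patient_id = "a", followup_years = 1, event = "mets",
                treat_start_years = 0, treat_stop_years = 0),
    make_record(patient_id = "b", followup_years = 2, event = "censored",
                treat_start_years = 0, treat_stop_years = 0)))
  km_toy <- extended_km(toy)
  expect_equal(km_toy$surv[km_toy$group == "untreated"], 0.5)
})

test_that("the model-based analogue is discretisation-stable and self-consistent", {
  co <- simulate_cohort(simulation_config(n_patients = 400, seed = 72))
  mk1 <- model_based_km(co, ref_theta, dt = 0.1, t_max = 10)
  mk2 <- model_based_km(co, ref_theta, dt = 0.05, t_max = 10)
  common <- intersect(mk1$time, mk2$time)
  for (g in unique(mk1$group)) {
    a <- mk1$surv[mk1$group == g][match(common, mk1$time[mk1$group == g])]
    b <- mk2$surv[mk2$group == g][match(common, mk2$time[mk2$group == g])]
    ok <- !is.na(a) & !is.na(b)
    expect_lt(max(abs(a - b)[ok]), 0.002)
  }
  # a single-patient cohort reproduces that patient's own conditional survival
  one <- co[co$event == "censored" & co$followup_years > 5, ][1, , drop = FALSE]
  mk <- model_based_km(one, ref_theta, dt = 0.5, t_max = 5, quad_order = 60,
                       group_fn = function(cohort, t) rep("all", nrow(cohort)),
                       extend_history = FALSE)
  sched <- main_schedule(one$treat_start_years,
                         one$treat_stop_years - one$treat_start_years,
                         ref_theta$phi2)
  lags <- as.numeric(strsplit(one$screen_lags_years, ";")[[1]])
  lags <- lags[!is.na(lags)]
  # model_based_km averages with the smooth Gauss-Laguerre rule while
  # predict_mfs uses the exact panel rule, so agreement is quadrature-limited
  pr <- predict_mfs(one$diameter_mm, lags, sched, ref_theta, times = mk$time)
  expect_equal(mk$surv, pr$surv, tolerance = 5e-4)
})

test_that("model-based and extended Kaplan-Meier curves agree on simulated data", {
  co <- simulate_cohort(simulation_config(n_patients = 2500, seed = 73))
  km <- extended_km(co)
  mk <- model_based_km(co, ref_theta, dt = 0.25, t_max = 10, quad_order = 40)
  for (g in c("treated", "untreated")) {
    kg <- km[km$group == g & km$time <= 10, ]
    mg <- mk[mk$group == g, ]
    pred <- approx(mg$time, mg$surv, xout = kg$time, rule = 2)$y
    # within Monte Carlo bands of the product-limit estimator
    expect_lt(max(abs(kg$surv - pred), na.rm = TRUE), 0.03)
  }
})
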