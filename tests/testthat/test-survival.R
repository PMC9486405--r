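test_that("horizon censoring truncates strictly beyond the horizon", {
  out <- censor_at_horizon(c(40, 12, 36), c(1, 1, 1), 36)
  expect_equal(out$time, c(36, 12, 36))
  expect_equal(out$event, c(0L, 1L, 1L)) # event at exactly 36 is kept
  expect_error(censor_at_horizon(c(-1, 5), c(1, 0)), "non-negative")
  set.seed(3)
  t <- rexp(200, 0.02)
  cens <- censor_at_horizon(t, rbinom(200, 1, 0.7), 36)
  expect_true(all(cens$time <= 36))
  expect_true(all(cens$event[cens$time == 36 & t > 36] == 0))
})

test_that("KM estimates match hand product-limit computations", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(1, 2 / 3, 1 / 3, 0))
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$survival[km2$time %in% c(1, 3)], c(2 / 3, 0))
  none <- km_estimate(c(4, 8, 2), c(0, 0, 0))
  expect_true(all(none$survival == 1))

  set.seed(21)
  t <- round(rexp(150, 0.05), 1)
  e <- rbinom(150, 1, 0.6)
  km3 <- km_estimate(t, e)
  oracle <- oracle_km(t, e)
  expect_equal(km3$survival[match(oracle$time, km3$time)], oracle$survival,
               tolerance = 1e-12)
})

test_that("KM equals the empirical survivor function without censoring", {
  set.seed(8)
  t <- rexp(300, 0.04)
  km <- km_estimate(t, rep(1, 300))
  at <- km$time[km$time > 0]
  expect_equal(km$survival[km$time > 0], vapply(at, function(x) mean(t > x),
                                                numeric(1)),
               tolerance = 1e-12)
})

test_that("log-rank matches the O-E formula and its degenerate cases", {
  t1 <- c(2, 4, 6, 8, 10)
  t2 <- c(1, 3, 5, 7, 9)
  res <- logrank_test(c(t1, t2), rep(1, 10), rep(c("a", "b"), each = 5))
  expect_equal(res$statistic,
               oracle_logrank(t1, rep(1, 5), t2, rep(1, 5)),
               tolerance = 1e-10)

  same <- logrank_test(rep(c(1, 2, 3), 2), rep(1, 6), rep(c("a", "b"), 3))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)

  silent <- logrank_test(c(1, 2, 3, 4), rep(0, 4), rep(c("a", "b"), 2))
  expect_equal(silent$statistic, 0)
  expect_equal(silent$p_value, 1)
})

test_that("cox fits recover null and non-null effects with sane output shape", {
  set.seed(10)
  n <- 1500
  arm <- rep(c("ctrl", "exp"), each = n / 2)
  cohort <- tibble::tibble(
    time = rexp(n, 0.02 * ifelse(arm == "exp", 2, 1)), event = 1, arm = arm)
  res <- cox_fit(cohort, "arm", survival_config(horizon = 1e6))
  expect_equal(res$term, "arm")
  expect_equal(res$reference, "ctrl")
  expect_lt(res$ci_low, res$hr)
  expect_gt(res$ci_high, res$hr)
  # exponential limit: HR ~ ratio of event rates = 2
  expect_equal(res$hr, 2, tolerance = 0.15)

  null_cohort <- cohort
  null_cohort$arm <- sample(arm)
  res0 <- cox_fit(null_cohort, "arm", survival_config(horizon = 1e6))
  expect_equal(res0$hr, 1, tolerance = 0.15)

  expect_error(cox_fit(cohort, "missing_cov"), "Unknown covariate")
  one_level <- cohort
  one_level$arm <- "ctrl"
  expect_error(cox_fit(one_level, "arm"), "2 observed levels")
})

test_that("two-group log-rank matches the Cox score test asymptotically", {
  set.seed(19)
  n <- 2000
  arm <- rep(c("a", "b"), each = n / 2)
  t <- rexp(n, 0.03 * ifelse(arm == "b", 1.5, 1))
  lr <- logrank_test(t, rep(1, n), arm)
  fit <- survival::coxph(survival::Surv(t, rep(1, n)) ~ arm)
  score <- summary(fit)$sctest["test"]
  expect_lt(abs(lr$statistic - score) / score, 0.05)
})

test_that("log-hazard-ratio bias is small across true effects", {
  set.seed(61)
  n <- 2000
  for (true_hr in c(1, 1.5, 2.4)) {
    est <- replicate(200, {
      x <- rbinom(n, 1, 0.5)
      t <- rexp(n, 0.02 * true_hr^x)
      fit <- survival::coxph(survival::Surv(t, rep(1, n)) ~ x)
      unname(fit$coefficients)
    })
    expect_lt(abs(mean(est) - log(true_hr)), 0.05)
  }
})

test_that("the stratified survival report mirrors the expected layout", {
  sim <- simulate_cohort(small_sim(n = 400, seed = 71))
  res <- subgroup_survival_analysis(sim$cohort)
  tab <- tidy(res)
  expect_setequal(unique(tab$stratum), c("oral_cavity_N0", "oral_cavity_N+"))
  expect_true(all(c("gender", "smoker", "hpv", "radiation", "t_binary",
                    "stage_binary", "mesenchymal_binary", "age_binary") %in%
                    tab$term[tab$analysis == "univariate"]))
  # multivariate models: T stage + subtype in N0; subtype + age in N+
  mv0 <- tab[tab$analysis == "multivariate" & tab$stratum == "oral_cavity_N0", ]
  expect_setequal(mv0$term, c("t_binary", "mesenchymal_binary"))
  mvp <- tab[tab$analysis == "multivariate" & tab$stratum == "oral_cavity_N+", ]
  expect_setequal(mvp$term, c("mesenchymal_binary", "age_binary"))
  # the age reference row is labelled with the observed low range
  age_ref <- unique(tab$reference[tab$term == "age_binary"])
  expect_match(age_ref, "^[0-9]+-[0-9]+$")
  # KM subsets present with log-rank results
  expect_setequal(names(res$km_curves),
                  c("oral_cavity", "non_oral_cavity",
                    "non_oral_cavity_hpv_negative"))
  expect_equal(nrow(res$logrank), 3)
  expect_true(all(res$logrank$p_value >= 0 & res$logrank$p_value <= 1))
})

test_that("small strata are flagged rather than dropped", {
  sim <- simulate_cohort(small_sim(n = 60, seed = 81))
  res <- subgroup_survival_analysis(sim$cohort,
                                    survival_config(min_stratum = 1000))
  expect_true(all(!is.na(tidy(res)$flag)))
})
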