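test_that("closed-form fits: intercept-only and saturated one-factor models", {
  tab <- as_event_table(valid_event_rows(3, males = c(10, 20, 30)))
  m <- fit_attendance(tab, terms = character(0), outcome = "males")
  expect_equal(unname(m$coefficients), log(20), tolerance = 1e-10)
  expect_equal(predict_mean(m, list()), 20, tolerance = 1e-8)

  # log-link with a saturated factor: fitted cell means = observed cell means
  df <- valid_event_rows(6, males = c(8, 10, 12, 36, 40, 44))
  df$trainer_gender <- rep(c("female", "male"), each = 3)
  tab2 <- as_event_table(df)
  m2 <- fit_attendance(tab2, terms = "trainer_gender", outcome = "males")
  expect_equal(predict_mean(m2, list(trainer_gender = "female")), 10,
               tolerance = 1e-8)
  expect_equal(predict_mean(m2, list(trainer_gender = "male")), 40,
               tolerance = 1e-8)
})

test_that("point estimates match the standard GLM and conserve the total", {
  ev <- generate_events(generator_config(n_events = 600, seed = 13))
  m <- fit_attendance(ev, c("trainer_gender", "time_bin", "venue", "division"),
                      "males")
  # independent route: formula-based quasi-Poisson fit on the same data
  dat <- as.data.frame(ev)
  for (f in c("trainer_gender", "time_bin", "venue", "division"))
    dat[[f]] <- factor(dat[[f]], levels = event_schema()[[f]])
  ref <- stats::glm(males ~ trainer_gender + time_bin + venue + division,
                    data = dat, family = stats::quasipoisson())
  expect_equal(unname(sort(m$coefficients)),
               unname(sort(stats::coef(ref))), tolerance = 1e-7)
  expect_equal(m$phi, summary(ref)$dispersion, tolerance = 1e-4)
  expect_equal(unname(sort(sqrt(diag(m$vcov)))),
               unname(sort(sqrt(diag(stats::vcov(ref))))), tolerance = 1e-4)
  # score identity with an intercept: fitted total = observed total
  expect_equal(m$fitted_sum, m$observed_sum, tolerance = 1e-6)
  # covariance is symmetric positive semidefinite
  expect_equal(m$vcov, t(m$vcov))
  expect_true(all(eigen(m$vcov, symmetric = TRUE)$values > -1e-10))
})

test_that("equidispersed counts give a dispersion estimate near 1", {
  im <- list(coefficients = c("(Intercept)" = log(25),
                              "time_bin=11_to_1530" = -0.2,
                              "time_bin=after_1530" = 0.4),
             dispersion = 1, terms = "time_bin")
  cfg <- generator_config(n_events = 5000, true_male_model = im,
                          true_female_model = im, female_zero_excess = 0,
                          seed = 19)
  ev <- generate_events(cfg)
  m <- fit_attendance(ev, "time_bin", "males")
  expect_gt(m$phi, 0.9)
  expect_lt(m$phi, 1.1)
})

test_that("predictions evaluate exp(x'beta) with delta-method errors", {
  ev <- generate_events(generator_config(n_events = 500, seed = 21))
  m <- fit_attendance(ev, c("trainer_gender", "venue", "division"), "males")
  conf <- list(trainer_gender = "male", venue = "marketplace",
               division = "khulna")
  co <- m$coefficients
  manual <- exp(co[["(Intercept)"]] + co[["trainer_gender=male"]] +
                co[["venue=marketplace"]] + co[["division=khulna"]])
  expect_equal(unname(predict_mean(m, conf)), unname(manual), tolerance = 1e-12)

  ps <- predict_mean(m, conf, se = TRUE)
  x <- as.numeric(names(co) %in% c("(Intercept)", "trainer_gender=male",
                                   "venue=marketplace", "division=khulna"))
  expect_equal(unname(ps[["se"]]),
               unname(manual * sqrt(drop(t(x) %*% m$vcov %*% x))),
               tolerance = 1e-10)
  expect_error(predict_mean(m, list(trainer_gender = "male")), "missing a level")

  # all-zero coefficients predict exp(0) = 1
  m0 <- m
  m0$coefficients[] <- 0
  expect_equal(unname(predict_mean(m0, conf)), 1)
})

test_that("combined predictions: sums, shares and boundary cases", {
  mk <- function(intercept, outcome) {
    structure(list(outcome = outcome, terms = character(0),
                   coefficients = c("(Intercept)" = intercept),
                   phi = 1, vcov = matrix(0.01, 1, 1), n_obs = 10, n_coef = 1,
                   converged = TRUE, schema = event_schema()),
              class = "attendance_model")
  }
  p <- predict_total(mk(log(100), "males"), mk(log(22), "females"), list())
  expect_equal(p$total, 122)
  expect_equal(p$proportion_female, 22 / 122, tolerance = 1e-12)
  # equal means -> share one half
  p2 <- predict_total(mk(log(30), "males"), mk(log(30), "females"), list())
  expect_equal(p2$proportion_female, 0.5)
  # vanishing predictions -> share 0, flagged
  p3 <- predict_total(mk(-2000, "males"), mk(-2000, "females"), list())
  expect_equal(p3$proportion_female, 0)
  expect_true(p3$zero_total)
})

test_that("serialized models reproduce predictions exactly", {
  ev <- generate_events(generator_config(n_events = 400, seed = 25))
  m <- fit_attendance(ev, c("trainer_gender", "time_bin", "month"), "females")
  f <- tempfile(fileext = ".json")
  model_to_json(m, f)
  m2 <- model_from_json(f)
  conf <- list(trainer_gender = "female", time_bin = "before_11",
               month = "jan2019")
  expect_equal(predict_mean(m, conf), predict_mean(m2, conf),
               tolerance = 1e-12)
  expect_equal(predict_mean(m, conf, se = TRUE),
               predict_mean(m2, conf, se = TRUE), tolerance = 1e-12)
  expect_equal(m2$phi, m$phi)
})

test_that("degenerate designs are rejected with diagnostics", {
  tab <- as_event_table(valid_event_rows(40))
  # duplicated factor -> aliased columns named in the error
  expect_error(fit_attendance(tab, c("division", "division"), "males"),
               "aliased.*division", ignore.case = TRUE)
  small <- as_event_table(valid_event_rows(2))
  expect_error(fit_attendance(small, "venue", "males"), "more observations")
})
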