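test_that("Kaplan-Meier matches hand product-limit computations", {
  ## single event at t = 2 among four subjects
  km <- kaplan_meier(c(2, 3, 4, 5), c(1, 0, 0, 0))
  expect_equal(km_eval(km, 1.9), 1)
  expect_equal(km_eval(km, 2), 3 / 4)
  ## no events: flat at one
  km0 <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_equal(km_eval(km0, c(0.5, 2.5, 10)), c(1, 1, 1))
  ## worked five-subject example
  km5 <- kaplan_meier(1:5, c(1, 0, 1, 1, 0))
  expect_equal(km_eval(km5, 1), 4 / 5)
  expect_equal(km_eval(km5, 3), 8 / 15)
  expect_equal(km_eval(km5, 4), 4 / 15)
  expect_error(kaplan_meier(numeric(0), numeric(0)), "empty")
})

test_that("Kaplan-Meier agrees with survival::survfit on tied data", {
  set.seed(10)
  time <- sample(1:8, 60, replace = TRUE)
  event <- rbinom(60, 1, 0.6)
  km <- kaplan_meier(time, event)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  expect_equal(km_eval(km, sf$time), sf$surv, tolerance = 1e-12)
})

test_that("censoring weights reduce to one without censoring and match hand KM", {
  w <- censoring_weights(c(1, 2, 3), c(1, 1, 1), horizons = 2)
  expect_equal(w$per_subject, rep(1, 3))
  expect_equal(unname(w$at_horizon), 1)
  ## all censored at the same time, horizon before it
  w2 <- censoring_weights(rep(5, 4), rep(0, 4), horizons = 3)
  expect_equal(unname(w2$at_horizon), 1)
  ## six-subject mixed example, hand censoring-KM:
  ## censorings at 2 and 4 give G(2) = 4/5, G(4) = 8/15
  w3 <- censoring_weights(1:6, c(1, 0, 1, 0, 1, 1), horizons = 3.5)
  expect_equal(w3$per_subject, c(1, 0, 5 / 4, 0, 15 / 8, 15 / 8))
  expect_equal(unname(w3$at_horizon), 5 / 4)
})

test_that("Brier score matches the brute-force oracle and its closed cases", {
  set.seed(11)
  n <- 50
  time <- rexp(n)
  event <- rbinom(n, 1, 0.6)
  s_hat <- runif(n)
  t0 <- median(time)
  expect_equal(brier_score(s_hat, time, event, t0),
               brute_brier(s_hat, time, event, t0), tolerance = 1e-10)
  ## at t = 0 both indicator sets are empty/trivial given S-hat(0) = 1
  expect_equal(brier_score(rep(1, n), time, event, 0), 0)
  ## perfect prediction on uncensored data scores zero
  ev <- rep(1L, n)
  perfect <- as.numeric(time > t0)
  expect_equal(brier_score(perfect, time, ev, t0), 0)
  ## and without censoring the score is the plain mean squared error
  expect_equal(brier_score(s_hat, time, ev, t0),
               mean((s_hat - (time > t0))^2), tolerance = 1e-12)
})

test_that("concordance matches the pairwise oracle and closed cases", {
  set.seed(12)
  for (rep in 1:5) {
    n <- 20
    time <- rexp(n)
    event <- rbinom(n, 1, 0.7)
    s_hat <- runif(n)
    t0 <- quantile(time, 0.6, names = FALSE)
    got <- suppressWarnings(c_index(s_hat, time, event, t0))
    want <- brute_cindex(s_hat, time, event, t0)
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(got, want, tolerance = 1e-12)
  }
  ## perfectly concordant predictions, no censoring
  time <- 1:10
  s_hat <- (1:10) / 11
  expect_equal(c_index(s_hat, time, rep(1L, 10), 5), 1)
  ## all-tied predictions are degenerate and score zero
  tied <- c_index(rep(0.5, 10), time, rep(1L, 10), 5)
  expect_equal(as.numeric(tied), 0)
  expect_true(isTRUE(attr(tied, "degenerate")))
  ## invariance under strictly monotone transforms of the predictions
  set.seed(13)
  s2 <- runif(10)
  expect_equal(c_index(s2, time, rep(1L, 10), 5),
               c_index(qlogis(s2 / 2 + 0.25), time, rep(1L, 10), 5))
  expect_warning(c_index(s2, time, rep(1L, 10), 20), "no comparable")
})

test_that("evaluation horizons are quantiles of uncensored times only", {
  q <- eval_times(1:100, rep(1L, 100))
  expect_equal(unname(q), c(25.75, 50.5, 75.25))
  expect_equal(unname(eval_times(c(7, 1, 9), c(1, 0, 0))), rep(7, 3))
  ## censored records never shift the horizons
  q2 <- eval_times(c(1:100, 200, 300), c(rep(1L, 100), 0L, 0L))
  expect_equal(q, q2)
  expect_error(eval_times(1:5, rep(0L, 5)), "no uncensored")
})

test_that("identical folds yield identical metrics under a fixed model", {
  m <- stub_model(rates = c(0.5, 2), probs = c(0.4, 0.6))
  set.seed(14)
  time <- rexp(40); event <- rbinom(40, 1, 0.7)
  x <- matrix(rnorm(80), 40, 2)
  t0 <- median(time)
  s_hat <- predict(m, x, times = t0)$survival[, 1]
  a <- brier_score(s_hat, time, event, t0)
  b <- brier_score(s_hat, time, event, t0)
  expect_identical(a, b)
  ca <- suppressWarnings(c_index(s_hat, time, event, t0))
  cb <- suppressWarnings(c_index(s_hat, time, event, t0))
  expect_identical(ca, cb)
})

test_that("cross-validation reports recomputable means over seeded folds", {
  sim <- simulate_clustered(sim_config(n_subjects = 300, seed = 41))
  cv <- suppressWarnings(do.call(cross_validate,
    c(list(x = sim$x, time = sim$time, event = sim$event, k = 2,
           n_folds = 2L, seed = 3), quick_fit_args)))
  expect_equal(unname(cv$brier_mean), unname(colMeans(cv$brier)))
  expect_equal(unname(cv$cindex_mean), unname(colMeans(cv$cindex)))
  expect_length(cv$horizons, 3)
  expect_true(all(cv$brier >= 0, na.rm = TRUE))
  js <- cv_report_json(cv)
  expect_true(jsonlite::validate(js))
})
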