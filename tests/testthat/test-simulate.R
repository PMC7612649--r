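test_that("clustered cohorts honour their configuration", {
  ## no censoring target: every record is an event
  sim0 <- simulate_clustered(sim_config(n_subjects = 500, seed = 61,
                                        censoring_rate_target = 0))
  expect_true(all(sim0$event == 1))
  ## seeded determinism
  a <- simulate_clustered(sim_config(n_subjects = 300, seed = 62))
  b <- simulate_clustered(sim_config(n_subjects = 300, seed = 62))
  expect_identical(a$time, b$time)
  expect_identical(a$true_labels, b$true_labels)
  ## sharpness zero: labels independent of covariates, frequencies uniform
  s0 <- simulate_clustered(sim_config(n_subjects = 4000, seed = 63,
                                      assignment_sharpness = 0))
  tab <- table(s0$true_labels) / 4000
  expect_true(all(abs(tab - 0.5) < 3 * sqrt(0.25 / 4000)))
  expect_error(sim_config(censoring_rate_target = 1), "censoring_rate_target")
})

test_that("uniform censoring calibration hits the target fraction", {
  sim <- simulate_clustered(sim_config(n_subjects = 20000, seed = 64,
                                       censoring_rate_target = 0.345))
  frac <- mean(sim$event == 0)
  expect_gte(frac, 0.325)
  expect_lte(frac, 0.365)
  ## censored observations sit strictly below their latent event times by
  ## construction: the observed time of censored records is the censor draw
  expect_true(all(sim$time[sim$event == 0] <= max(sim$time)))
})

test_that("per-cluster empirical survival converges to the Weibull truth", {
  cfg <- sim_config(n_subjects = 1e5, seed = 65, censoring_rate_target = 0)
  sim <- simulate_clustered(cfg)
  for (k in 1:2) {
    ix <- sim$true_labels == k
    km <- kaplan_meier(sim$time[ix], sim$event[ix])
    truth <- exp(-cumulative_hazard(sim$true_heads[[k]], km$time))
    expect_lt(max(abs(km$surv - truth)), 0.02)
  }
})

test_that("generated cohorts satisfy the dataset invariants", {
  sim <- simulate_clustered(sim_config(n_subjects = 200, seed = 66))
  ds <- survival_dataset(sim$x, sim$time, sim$event)
  expect_equal(ds$n, 200)
  expect_true(all(ds$event %in% 0:1))
})

test_that("the non-linear generator degenerates to exponential when b is one", {
  n <- 20000
  sim <- simulate_nonlinear_nonph(n, seed = 67, censoring_rate_target = 0,
                                  a_fun = function(X) rep(2, nrow(X)),
                                  b_fun = function(X) rep(1, nrow(X)))
  ## Lambda = 2t: unit mean 1/2, se = 1/(2 sqrt(n))
  expect_lt(abs(mean(sim$time) - 0.5), 3 * 0.5 / sqrt(n))
})

test_that("inverse-transform sampling reproduces the closed-form law", {
  n <- 1e4
  a0 <- 0.7; b0 <- 1.6
  sim <- simulate_nonlinear_nonph(n, seed = 68, censoring_rate_target = 0,
                                  a_fun = function(X) rep(a0, nrow(X)),
                                  b_fun = function(X) rep(b0, nrow(X)))
  cdf <- function(t) 1 - exp(-a0 * t^b0 / b0)
  ks <- suppressWarnings(stats::ks.test(sim$time, cdf))
  expect_gt(ks$p.value, 0.01)
  ## identical seeds give identical cohorts
  s1 <- simulate_nonlinear_nonph(100, seed = 69)
  s2 <- simulate_nonlinear_nonph(100, seed = 69)
  expect_identical(s1$time, s2$time)
  expect_identical(s1$event, s2$event)
})

test_that("the non-linear cohort is censored near its design rate", {
  sim <- simulate_nonlinear_nonph(20000, seed = 70)
  expect_lt(abs(mean(sim$event == 0) - 0.345), 0.02)
})
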