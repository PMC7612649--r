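test_that("hard assignment takes the argmax with lowest-index ties", {
  m <- stub_model(rates = c(1, 2, 3), probs = c(0.2, 0.5, 0.3),
                  n_covariates = 1L)
  ha <- hard_assign(m, matrix(0, 4, 1))
  expect_equal(ha$labels, rep(2L, 4))
  m2 <- stub_model(rates = c(1, 2), probs = c(0.5, 0.5), n_covariates = 1L)
  expect_equal(hard_assign(m2, matrix(0, 3, 1))$labels, rep(1L, 3))
  m3 <- stub_model(rates = 1, probs = 1, n_covariates = 1L)
  expect_equal(hard_assign(m3, matrix(0, 5, 1))$labels, rep(1L, 5))
})

test_that("cluster summaries recompute shares, censoring and KM medians", {
  one <- cluster_summaries(rep(1L, 6), c(2, 4, 6, 1, 3, 5),
                           c(1, 1, 1, 0, 0, 0))
  expect_equal(one$population_pct, 100)
  expect_equal(one$censored_pct, 50)
  ## events at 2, 4, 6 with no censoring: S drops to 1/3 at the second event
  ev3 <- cluster_summaries(rep(1L, 3), c(2, 4, 6), c(1, 1, 1))
  expect_equal(ev3$median_survival, 4)
  expect_false(ev3$median_censored)
  ## a cluster whose curve never reaches 0.5 reports "> last observed time"
  high <- cluster_summaries(rep(1L, 4), c(1, 2, 3, 9), c(1, 0, 0, 0))
  expect_true(high$median_censored)
  expect_equal(high$median_survival, 9)
  expect_match(paste(capture.output(print(high)), collapse = " "), ">9",
               fixed = TRUE)
  ## two clusters: shares sum to 100 and covariate means are plain averages
  x <- data.frame(age = c(50, 60, 70, 80))
  two <- cluster_summaries(c(1L, 1L, 2L, 2L), c(1, 2, 3, 4), c(1, 1, 1, 1),
                           x = x)
  expect_equal(sum(two$population_pct), 100, tolerance = 1e-10)
  expect_equal(two$mean_age, c(55, 75))
})

test_that("log-rank test matches the hand hypergeometric table", {
  ## identical groups: no observed-minus-expected signal
  t_a <- c(1, 2, 3, 4); e_a <- c(1, 0, 1, 1)
  same <- logrank_test(t_a, e_a, t_a, e_a)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  ## A events at 1, 2; B events at 3, 4; O_A - E_A = 7/6, V = 17/36
  lr <- logrank_test(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
  expect_equal(lr$statistic, 49 / 17, tolerance = 1e-10)
  expect_equal(lr$p_value, pchisq(49 / 17, 1, lower.tail = FALSE))
  ## invariance to group relabelling
  ab <- logrank_test(c(1, 3, 5), c(1, 1, 0), c(2, 4, 9), c(1, 0, 1))
  ba <- logrank_test(c(2, 4, 9), c(1, 0, 1), c(1, 3, 5), c(1, 1, 0))
  expect_equal(ab$statistic, ba$statistic)
  expect_error(logrank_test(numeric(0), numeric(0), 1, 1), "non-empty")
  expect_error(logrank_test(1:3, rep(0, 3), 4:6, rep(0, 3)), "no events")
})

test_that("log-rank power: exponential rates 1 vs 4 are almost always detected", {
  reject <- vapply(1:100, function(seed) {
    set.seed(seed)
    a <- rexp(200, 1); b <- rexp(200, 4)
    logrank_test(a, rep(1L, 200), b, rep(1L, 200))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.95)
})

test_that("permutation importance isolates the covariates that drive assignment", {
  ## network reading only the first covariate, with a hard threshold
  m <- rand_neural_model(17, k = 2L, p = 3L)
  a <- m$assignment
  a$V[[1]][] <- 0; a$V[[1]][1, 1] <- 50
  a$d[[1]][] <- 0; a$d[[1]][1] <- 25        # relu active iff 50*x1 + 25 > 0
  a$V_out[] <- 0; a$V_out[1, 1] <- 1; a$d_out <- c(0, 0.5)
  a$mu[] <- 0; a$sd[] <- 1
  m$assignment <- a
  set.seed(18)
  X <- matrix(rnorm(600), 200, 3)
  pi <- permutation_importance(m, X, n_repeats = 20, seed = 1)
  driver <- pi$importance[pi$covariate == "x1"]
  others <- pi$importance[pi$covariate != "x1"]
  expect_equal(others, c(0, 0))
  ## label = 1{x1 > -0.5}: permuting a Bernoulli(p) column flips a label
  ## with probability 2 p (1 - p)
  p1 <- mean(X[, 1] > -0.5)
  expect_equal(driver, 2 * p1 * (1 - p1), tolerance = 0.05)
  ## reproducible given the seed
  pi2 <- permutation_importance(m, X, n_repeats = 20, seed = 1)
  expect_identical(pi, pi2)
  ## a constant assignment network has no important covariates
  m0 <- rand_neural_model(19, k = 2L)
  m0$assignment$V_out[] <- 0
  pi0 <- permutation_importance(m0, X, n_repeats = 3, seed = 2)
  expect_equal(pi0$importance, c(0, 0, 0))
})

test_that("the elbow rule picks the point of maximum curvature", {
  expect_equal(survmixnet:::elbow_index(c(100, 60, 55, 54)), 2L)
  expect_true(is.na(survmixnet:::elbow_index(c(10, 8, 6, 4))))   # linear
  expect_true(is.na(survmixnet:::elbow_index(c(3, 1))))
})

test_that("select_k returns a valid elbow result on a small cohort", {
  sim <- simulate_clustered(sim_config(n_subjects = 250, seed = 51))
  args <- c(list(x = sim$x, time = sim$time, event = sim$event,
                 k_range = c(2L, 3L), n_folds = 2L, seed = 4),
            quick_fit_args[c("n_hidden_hazard", "n_hidden_assign",
                             "latent_dim")],
            list(n_epochs = 6L, patience = 6L))
  res <- suppressWarnings(do.call(select_k, args))
  expect_s3_class(res, "elbow_result")
  expect_true(res$selected_k %in% c(2L, 3L))
  expect_equal(res$profile$k, c(2L, 3L))
  expect_true(all(is.finite(res$profile$nll)))
  lone <- suppressWarnings(do.call(select_k,
    utils::modifyList(args, list(k_range = 2L))))
  expect_equal(lone$selected_k, 2L)
})

test_that("pairwise log-rank covers every cluster pair", {
  set.seed(20)
  labels <- rep(1:3, each = 30)
  time <- rexp(90, rate = rep(c(0.2, 1, 5), each = 30))
  event <- rbinom(90, 1, 0.8)
  pw <- pairwise_logrank(labels, time, event)
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$p_value >= 0 & pw$p_value <= 1))
  js <- cluster_report_json(cluster_summaries(labels, time, event),
                            logrank = pw)
  expect_true(jsonlite::validate(js))
})
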