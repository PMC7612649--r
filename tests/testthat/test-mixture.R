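test_that("assignment probabilities lie on the simplex and are deterministic", {
  m <- rand_neural_model(1, k = 3L, p = 3L)
  X <- matrix(rnorm(60), 20, 3)
  a <- assign_probs(m, X)
  expect_true(all(a >= 0))
  expect_equal(rowSums(a), rep(1, 20), tolerance = 1e-6)
  ## identical rows map to identical probabilities
  X2 <- X[c(1, 1, 5, 5), ]
  a2 <- assign_probs(m, X2)
  expect_identical(a2[1, ], a2[2, ])
  expect_identical(a2[3, ], a2[4, ])
  expect_error(assign_probs(m, matrix(0, 2, 5)), "covariate")
})

test_that("a zeroed final assignment layer yields the uniform mixture", {
  m <- rand_neural_model(2, k = 4L)
  m$assignment$V_out[] <- 0
  m$assignment$d_out[] <- 0
  a <- assign_probs(m, matrix(rnorm(15), 5, 3))
  expect_equal(a, matrix(0.25, 5, 4), tolerance = 1e-12)
})

test_that("survival curves start at one, stay in [0,1] and decrease", {
  for (seed in 1:25) {
    m <- rand_neural_model(seed, k = sample(1:3, 1))
    X <- matrix(rnorm(6 * 3), 6, 3)
    tt <- c(0, sort(runif(10, 0, m$t_max)))
    pr <- predict(m, X, times = tt)
    expect_equal(pr$survival[, 1], rep(1, 6))
    expect_true(all(pr$survival >= 0 & pr$survival <= 1))
    expect_true(all(apply(pr$survival, 1, function(s) all(diff(s) <= 1e-12))))
    ## Eq.-style identity: survival = cluster_probs %*% exp(-Lambda)
    expect_equal(pr$survival, pr$cluster_probs %*% pr$cluster_survival,
                 tolerance = 1e-12)
    ## convexity: the mixture lies between the extreme component survivals
    lo <- apply(pr$cluster_survival, 2, min)
    hi <- apply(pr$cluster_survival, 2, max)
    for (i in 1:6) {
      expect_true(all(pr$survival[i, ] >= lo - 1e-12))
      expect_true(all(pr$survival[i, ] <= hi + 1e-12))
    }
  }
})

test_that("a one-component mixture ignores the covariates", {
  m <- rand_neural_model(5, k = 1L)
  tt <- c(0.2, 0.9, 1.7)
  pr <- predict(m, matrix(rnorm(9), 3, 3), times = tt)
  expect_equal(pr$survival[1, ], pr$survival[2, ])
  expect_equal(pr$survival[1, ],
               exp(-cumulative_hazard(m$heads[[1]], tt)))
})

test_that("fixed-weight exponential mixture matches the hand computation", {
  m <- stub_model(rates = c(1, 2), probs = c(0.3, 0.7))
  pr <- predict(m, matrix(0, 1, 2), times = 1)
  expect_equal(as.numeric(pr$survival), 0.3 * exp(-1) + 0.7 * exp(-2),
               tolerance = 1e-12)
})

test_that("mixture density matches closed forms and -dS/dt", {
  ## unit-rate exponential component
  m1 <- stub_model(rates = 1, probs = 1)
  tt <- c(0.5, 1, 2)
  expect_equal(as.numeric(mixture_density(m1, matrix(0, 1, 2), tt)),
               exp(-tt), tolerance = 1e-12)
  ## degenerate weights select the rate-2 component
  m2 <- stub_model(rates = c(2, 5), probs = c(1, 0))
  expect_equal(as.numeric(mixture_density(m2, matrix(0, 1, 2), tt)),
               2 * exp(-2 * tt), tolerance = 1e-12)
  ## neural mixture: density equals the negative survival slope
  m <- rand_neural_model(9, k = 2L)
  X <- matrix(rnorm(6), 2, 3)
  t0 <- c(0.4, 1.1)
  eps <- 1e-5
  sp <- predict(m, X, times = t0 + eps)$survival
  sm <- predict(m, X, times = t0 - eps)$survival
  fd <- -(diag(sp) - diag(sm)) / (2 * eps)
  dens <- diag(mixture_density(m, X, t0))
  expect_lt(max(abs(dens - fd) / pmax(abs(fd), 1e-12)), 1e-3)
  expect_error(mixture_density(m, X, 0), "positive")
})

test_that("the mixture density integrates to the event probability", {
  m <- rand_neural_model(11, k = 2L)
  x <- matrix(rnorm(3), 1, 3)
  Tmax <- m$t_max
  grid <- seq(1e-6, Tmax, length.out = 4001)
  dens <- as.numeric(mixture_density(m, x, grid))
  quad <- sum((dens[-1] + dens[-length(dens)]) / 2 * diff(grid))
  s_end <- predict(m, x, times = Tmax)$survival[1, 1]
  expect_equal(quad, 1 - s_end, tolerance = 1e-2)
})
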