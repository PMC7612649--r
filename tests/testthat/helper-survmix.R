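# Builders and independent oracles shared across the test files.

rand_head <- function(seed, n_layers = 2L, n_hidden = 5L, latent_dim = 3L,
                      t_max = 2) {
  set.seed(seed)
  hazard_head(n_layers, n_hidden, latent_dim, t_max = t_max)
}

# Mixture with exponential stub components Lambda_k(t) = rate_k * t
# (a Weibull head with shape 1 and scale 1/rate) and fixed mixture weights.
stub_model <- function(rates, probs = rep(1 / length(rates), length(rates)),
                       n_covariates = 2L) {
  heads <- lapply(rates, function(r) weibull_head(1, 1 / r))
  mixture_model(heads, probs, n_covariates = n_covariates)
}

rand_neural_model <- function(seed, k = 2L, p = 3L, n_layers = 2L,
                              n_hidden = 4L, latent_dim = 3L, t_max = 2) {
  set.seed(seed)
  heads <- lapply(seq_len(k), function(i)
    hazard_head(n_layers, n_hidden, latent_dim, t_max = t_max))
  assn <- survmixnet:::new_mlp_assignment(p, k, n_layers = 1L, n_hidden = 4L,
                                          dropout = 0)
  m <- mixture_model(heads, assn, n_covariates = p)
  m$t_max <- t_max
  m
}

# Naive linear-form censored mixture log-likelihood (no log-domain tricks):
# the direct evaluation of the event-density and survival contributions.
naive_loglik <- function(model, x, time, event) {
  alpha <- assign_probs(model, x)
  total <- 0
  for (i in seq_along(time)) {
    acc <- 0
    for (k in seq_len(model$n_clusters)) {
      lam_cum <- cumulative_hazard(model$heads[[k]], time[i])
      s_k <- exp(-lam_cum)
      if (event[i] == 1) {
        lam <- max(instantaneous_hazard(model$heads[[k]], time[i]), 1e-10)
        acc <- acc + alpha[i, k] * lam * s_k
      } else {
        acc <- acc + alpha[i, k] * s_k
      }
    }
    total <- total + log(acc)
  }
  total
}

# Element-by-element Brier score, written independently of the package's
# vectorised implementation (explicit loop over subjects, censoring KM by
# hand through kaplan_meier on the flipped indicator).
brute_brier <- function(s_hat, time, event, t) {
  n <- length(time)
  G <- kaplan_meier(time, 1 - event)
  tot <- 0
  for (i in seq_len(n)) {
    if (event[i] == 1 && time[i] <= t) {
      g <- km_eval(G, time[i], left = TRUE)
      w <- if (g > 0) 1 / g else 0
      tot <- tot + w * s_hat[i]^2
    }
    if (time[i] > t) {
      g <- km_eval(G, t)
      w <- if (g > 0) 1 / g else 0
      tot <- tot + w * (1 - s_hat[i])^2
    }
  }
  tot / n
}

# Exhaustive double-loop time-dependent concordance.
brute_cindex <- function(s_hat, time, event, t) {
  n <- length(time)
  G <- kaplan_meier(time, 1 - event)
  num <- 0
  wsum <- 0
  nrisk <- sum(time > t)
  for (i in seq_len(n)) {
    if (event[i] != 1 || time[i] > t) next
    g <- km_eval(G, time[i], left = TRUE)
    w <- if (g > 0) 1 / g else 0
    wsum <- wsum + w
    for (j in seq_len(n)) {
      if (time[j] > t && s_hat[j] > s_hat[i]) num <- num + w
    }
  }
  if (nrisk * wsum == 0) return(NA_real_)
  num / (nrisk * wsum)
}

rand_survdata <- function(seed, n = 30L, cens = 0.4) {
  set.seed(seed)
  time <- rexp(n, 0.5)
  event <- rbinom(n, 1L, 1 - cens)
  event[time == 0] <- 0L
  list(time = time, event = event)
}

quick_fit_args <- list(n_hidden_hazard = 16L, n_hidden_assign = 16L,
                       latent_dim = 4L, n_epochs = 25L, patience = 10L,
                       batch_size = 64L)
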