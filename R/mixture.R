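## Assignment networks: map covariates to mixture probabilities.
## Two kinds exist: an MLP with ReLU hidden layers, inter-layer dropout
## (training only) and a softmax output; and a constant assignment giving
## every subject the same probability vector (useful for reference models
## and degenerate K = 1 mixtures).

new_mlp_assignment <- function(n_in, n_clusters, n_layers = 2L, n_hidden = 50L,
                               dropout = 0.1, mu = rep(0, n_in),
                               sd = rep(1, n_in)) {
  stopifnot(n_layers >= 1L, n_hidden >= 1L, dropout >= 0, dropout < 1)
  V <- vector("list", n_layers)
  d <- vector("list", n_layers)
  fan <- n_in
  for (j in seq_len(n_layers)) {
    V[[j]] <- matrix(stats::rnorm(n_hidden * fan, sd = sqrt(2 / fan)),
                     n_hidden, fan)
    d[[j]] <- numeric(n_hidden)
    fan <- n_hidden
  }
  structure(list(V = V, d = d,
                 V_out = matrix(stats::rnorm(n_clusters * fan,
                                             sd = sqrt(1 / fan)),
                                n_clusters, fan),
                 d_out = numeric(n_clusters),
                 dropout = dropout, n_layers = as.integer(n_layers),
                 n_hidden = as.integer(n_hidden),
                 n_clusters = as.integer(n_clusters),
                 mu = mu, sd = sd),
            class = "mlp_assignment")
}

new_constant_assignment <- function(probs) {
  probs <- as.numeric(probs)
  stopifnot(all(probs >= 0), abs(sum(probs) - 1) < 1e-8)
  structure(list(probs = probs, n_clusters = length(probs)),
            class = "constant_assignment")
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

## Forward pass; masks (training dropout) is a list of n x n_hidden 0/1
## matrices already scaled by 1/(1-p), or NULL for evaluation mode.
mlp_forward <- function(net, X, masks = NULL, cache = FALSE) {
  Xs <- sweep(sweep(X, 2L, net$mu, "-"), 2L, net$sd, "/")
  A <- Xs
  Hs <- if (cache) vector("list", net$n_layers) else NULL
  Zs <- if (cache) vector("list", net$n_layers) else NULL
  for (j in seq_len(net$n_layers)) {
    Z <- A %*% t(net$V[[j]])
    Z <- sweep(Z, 2L, net$d[[j]], "+")
    A <- pmax(Z, 0)
    if (!is.null(masks)) A <- A * masks[[j]]
    if (cache) { Zs[[j]] <- Z; Hs[[j]] <- A }
  }
  logits <- A %*% t(net$V_out)
  logits <- sweep(logits, 2L, net$d_out, "+")
  out <- list(logits = logits, probs = softmax_rows(logits))
  if (cache) { out$Xs <- Xs; out$Zs <- Zs; out$Hs <- Hs }
  out
}

## Reverse pass from the logits adjoint; returns parameter gradients.
mlp_backward <- function(net, fw, glogits, masks = NULL) {
  Ltop <- if (net$n_layers > 0L) fw$Hs[[net$n_layers]] else fw$Xs
  gV_out <- crossprod(glogits, Ltop)
  gd_out <- colSums(glogits)
  G <- glogits %*% net$V_out
  gV <- vector("list", net$n_layers)
  gd <- vector("list", net$n_layers)
  for (j in net$n_layers:1) {
    if (!is.null(masks)) G <- G * masks[[j]]
    G <- G * (fw$Zs[[j]] > 0)
    inp <- if (j == 1L) fw$Xs else fw$Hs[[j - 1L]]
    gV[[j]] <- crossprod(G, inp)
    gd[[j]] <- colSums(G)
    if (j > 1L) G <- G %*% net$V[[j]]
  }
  list(V = gV, d = gd, V_out = gV_out, d_out = gd_out)
}

#' Mixture probabilities for a set of subjects
#'
#' Evaluates the assignment network in deterministic mode (dropout off) and
#' returns the softmax cluster probabilities, one row per subject on the
#' probability simplex.
#'
#' @param model A fitted or constructed [mixture_model()].
#' @param x Covariate matrix or data frame with the model's covariates.
#' @return Numeric matrix (subjects x K); rows are non-negative and sum to 1.
#' @export
assign_probs <- function(model, x) {
  stopifnot(inherits(model, "survmix"))
  X <- resolve_covariates(model, x)
  n <- nrow(X)
  K <- model$n_clusters
  a <- model$assignment
  if (inherits(a, "constant_assignment")) {
    matrix(a$probs, n, K, byrow = TRUE)
  } else {
    mlp_forward(a, X)$probs
  }
}

resolve_covariates <- function(model, x) {
  if (is.data.frame(x)) {
    if (!is.null(model$covariate_names) &&
        all(model$covariate_names %in% names(x)))
      x <- x[model$covariate_names]
    x <- as.matrix(x)
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  storage.mode(x) <- "double"
  p <- model$n_covariates
  if (!is.null(p) && ncol(x) != p)
    stop(sprintf("expected %d covariate columns, got %d", p, ncol(x)),
         call. = FALSE)
  x
}

#' Assemble a survival mixture model
#'
#' Combines K hazard heads with an assignment rule into a model evaluating
#' the individual survival function S(t | x) = sum_k alpha_k(x) exp(-Lambda_k(t)).
#' Heads never read the covariates (they define population-level cluster
#' distributions) and the assignment never reads time. Models are normally
#' produced by [survmixnet()]; this constructor exists for building reference
#' models from parametric heads and fixed mixture weights.
#'
#' @param heads List of hazard heads ([hazard_head()] or [weibull_head()]).
#' @param assignment Either a numeric probability vector of length K (a
#'   covariate-independent assignment) or an internal MLP assignment object.
#' @param covariate_names Optional character vector naming the covariates.
#' @param n_covariates Number of covariate columns the model accepts.
#' @return Object of class `"survmix"`.
#' @examples
#' m <- mixture_model(list(weibull_head(1, 1), weibull_head(1, 0.5)),
#'                    assignment = c(0.3, 0.7), n_covariates = 2)
#' predict(m, matrix(0, 1, 2), times = 1)$survival
#' @export
mixture_model <- function(heads, assignment, covariate_names = NULL,
                          n_covariates = NULL) {
  stopifnot(is.list(heads), length(heads) >= 1L,
            all(vapply(heads, inherits, logical(1), "hazard_head")))
  K <- length(heads)
  if (is.numeric(assignment)) {
    stopifnot(length(assignment) == K)
    assignment <- new_constant_assignment(assignment)
  }
  stopifnot(assignment$n_clusters == K)
  if (is.null(n_covariates) && inherits(assignment, "mlp_assignment"))
    n_covariates <- ncol(assignment$V[[1L]])
  structure(list(heads = heads, assignment = assignment,
                 n_clusters = K,
                 covariate_names = covariate_names,
                 n_covariates = n_covariates,
                 t_max = if (inherits(heads[[1L]], "nn_hazard_head"))
                   heads[[1L]]$t_max else NULL),
            class = "survmix")
}

## K x T matrix of cumulative hazards over a time grid.
head_lambda_matrix <- function(model, times) {
  do.call(rbind, lapply(model$heads, cumulative_hazard, t = times))
}

head_rate_matrix <- function(model, times) {
  do.call(rbind, lapply(model$heads, instantaneous_hazard, t = times))
}

#' Predict survival curves from a mixture model
#'
#' @param object A `"survmix"` model.
#' @param newx Covariate matrix or data frame (subjects x covariates).
#' @param times Non-negative evaluation times.
#' @param ... Unused.
#' @return Object of class `"survmix_pred"` with elements `times`,
#'   `survival` (subjects x times, values in \[0, 1\], non-increasing in
#'   time, 1 at t = 0), `cluster_probs` (subjects x K, rows on the simplex)
#'   and `cluster_survival` (K x times, the population-level component
#'   survival curves exp(-Lambda_k)).
#' @export
predict.survmix <- function(object, newx, times, ...) {
  times <- check_times(times)
  alpha <- assign_probs(object, newx)
  Lam <- head_lambda_matrix(object, times)
  Sk <- exp(-Lam)
  S <- alpha %*% Sk
  S[] <- pmin(pmax(S, 0), 1)   # softmax rows sum to 1 only up to one ulp
  structure(list(times = times,
                 survival = S,
                 cluster_probs = alpha,
                 cluster_survival = Sk),
            class = "survmix_pred")
}

#' Event density under the mixture
#'
#' Evaluates sum_k alpha_k(x) lambda_k(t) exp(-Lambda_k(t)), the probability
#' density of an event at time t for a subject with covariates x; this is
#' the uncensored likelihood integrand and equals -dS/dt.
#'
#' @inheritParams assign_probs
#' @param times Positive evaluation times.
#' @return Non-negative matrix (subjects x times).
#' @export
mixture_density <- function(model, x, times) {
  times <- check_times(times)
  if (any(times <= 0))
    stop("the event density is evaluated at strictly positive times",
         call. = FALSE)
  alpha <- assign_probs(model, x)
  Lam <- head_lambda_matrix(model, times)
  rate <- head_rate_matrix(model, times)
  alpha %*% (rate * exp(-Lam))
}

#' @export
print.survmix <- function(x, ...) {
  cat(sprintf("Survival mixture model: %d component(s)", x$n_clusters))
  if (inherits(x$heads[[1L]], "nn_hazard_head")) {
    cfg <- x$heads[[1L]]$config
    cat(sprintf(", neural hazard heads (%d x %d, latent %d)",
                cfg$n_layers, cfg$n_hidden, cfg$latent_dim))
  }
  cat("\n")
  if (inherits(x$assignment, "mlp_assignment")) {
    a <- x$assignment
    cat(sprintf("Assignment network: %d layer(s) x %d nodes, dropout %.2f\n",
                a$n_layers, a$n_hidden, a$dropout))
  } else {
    cat("Assignment: fixed probabilities (",
        paste(signif(x$assignment$probs, 3), collapse = ", "), ")\n", sep = "")
  }
  if (!is.null(x$covariate_names))
    cat("Covariates:", paste(x$covariate_names, collapse = ", "), "\n")
  if (!is.null(x$best_val_nll))
    cat(sprintf("Held-out NLL at early stop: %.5f\n", x$best_val_nll))
  invisible(x)
}

#' @export
print.survmix_pred <- function(x, ...) {
  cat(sprintf("Survival prediction: %d subject(s) x %d time(s), %d component(s)\n",
              nrow(x$survival), length(x$times), ncol(x$cluster_probs)))
  invisible(x)
}
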