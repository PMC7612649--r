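#' Fit a survival mixture of monotone neural hazard networks
#'
#' Maximises the exact right-censored log-likelihood of a K-component
#' mixture in which each component's cumulative hazard is a positive,
#' monotone-in-time neural network with a learnable latent cluster code, and
#' a covariate-driven softmax network assigns subjects to components.
#' Optimisation uses Adam on shuffled mini-batches with an early-stopping
#' split (a stratified fraction of the data held out on the event
#' indicator); the returned parameters are the snapshot with the lowest
#' held-out negative log-likelihood. Covariates are z-scored with
#' training-split statistics stored in the model; times are rescaled by the
#' largest observed time for numerical conditioning of the tanh layers, and
#' all reported hazards are in original time units.
#'
#' @param x Covariate matrix or data frame (subjects x covariates).
#' @param time Non-negative observed times.
#' @param event 0/1 event indicator (0 = right-censored).
#' @param k Number of mixture components (the tuning grid spans 2-5).
#' @param n_layers_hazard,n_hidden_hazard Architecture of each hazard head
#'   (grids: layers 1-3, nodes 50 or 100).
#' @param latent_dim Size of the latent cluster code (grid: 10, 50, 100).
#' @param n_layers_assign,n_hidden_assign Architecture of the assignment
#'   network (same grid as the heads).
#' @param dropout Inter-layer dropout rate of the assignment network during
#'   training; predictions always run in deterministic mode.
#' @param learning_rate Adam step size (grid: 1e-3 or 1e-4).
#' @param batch_size Mini-batch size (grid: 100 or 250).
#' @param n_epochs Maximum number of epochs (default 1000).
#' @param patience Epochs without held-out improvement before stopping.
#' @param val_fraction Fraction held out for early stopping (default 0.10),
#'   stratified on the event indicator.
#' @param seed Optional integer; fixes initialisation, the early-stopping
#'   split, batch shuffling and dropout, making the fit fully reproducible.
#' @param verbose Print per-epoch losses.
#' @return A `"survmix"` model with the fitted heads and assignment network,
#'   plus `history` (a data frame of per-epoch training and held-out NLL),
#'   `best_val_nll`, and the resolved configuration.
#' @examples
#' sim <- simulate_clustered(sim_config(n_subjects = 300, seed = 7))
#' fit <- survmixnet(sim$x, sim$time, sim$event, k = 2,
#'                   n_hidden_hazard = 20, n_hidden_assign = 20,
#'                   n_epochs = 30, seed = 1)
#' predict(fit, sim$x[1:3, ], times = c(0, 1, 2))$survival
#' @export
survmixnet <- function(x, time, event, k = 2L,
                       n_layers_hazard = 2L, n_hidden_hazard = 50L,
                       latent_dim = 10L,
                       n_layers_assign = 2L, n_hidden_assign = 50L,
                       dropout = 0.1,
                       learning_rate = 1e-3, batch_size = 100L,
                       n_epochs = 1000L, patience = 50L,
                       val_fraction = 0.1, seed = NULL,
                       verbose = FALSE) {
  validate_surv_triplet(time, event)
  if (length(time) < 2L) stop("need at least 2 records", call. = FALSE)
  if (!any(event == 1))
    stop(paste("all records are censored: the likelihood degenerates",
               "toward a zero hazard"), call. = FALSE)
  stopifnot(k >= 1L, val_fraction > 0, val_fraction < 1)
  if (!is.null(seed)) set.seed(seed)

  cn <- if (is.data.frame(x)) names(x) else colnames(x)
  X <- if (is.data.frame(x)) as.matrix(x) else x
  storage.mode(X) <- "double"
  if (nrow(X) != length(time)) stop("x rows must match time", call. = FALSE)
  if (anyNA(X) || any(!is.finite(X)))
    stop("covariates must be finite with no missing values", call. = FALSE)
  if (is.null(cn)) cn <- paste0("x", seq_len(ncol(X)))

  n <- length(time)
  t_max <- max(time)
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1

  ## stratified early-stopping split on the event indicator
  val_idx <- unlist(lapply(split(seq_len(n), event), function(ix) {
    m <- max(1L, round(length(ix) * val_fraction))
    if (length(ix) <= 1L) return(integer(0))
    sample(ix, min(m, length(ix) - 1L))
  }), use.names = FALSE)
  train_idx <- setdiff(seq_len(n), val_idx)
  if (length(val_idx) == 0L) val_idx <- train_idx  # tiny-data fallback

  heads <- lapply(seq_len(k), function(i)
    hazard_head(n_layers_hazard, n_hidden_hazard, latent_dim, t_max = t_max))
  assignment <- new_mlp_assignment(ncol(X), k, n_layers_assign,
                                   n_hidden_assign, dropout,
                                   mu = mu, sd = sdv)
  model <- mixture_model(heads, assignment, covariate_names = cn,
                         n_covariates = ncol(X))
  model$t_max <- t_max

  skeleton <- model_params(model)
  theta <- pack_params(skeleton)
  adam <- list(m = numeric(length(theta)), v = numeric(length(theta)),
               t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)

  Xtr <- X[train_idx, , drop = FALSE]
  ttr <- time[train_idx]; dtr <- event[train_idx]
  Xva <- X[val_idx, , drop = FALSE]
  tva <- time[val_idx]; dva <- event[val_idx]
  ntr <- length(ttr)
  p_drop <- assignment$dropout
  n_lay <- assignment$n_layers
  n_hid <- assignment$n_hidden

  best_val <- Inf
  best_theta <- theta
  stall <- 0L
  hist_epoch <- integer(0)
  hist_train <- numeric(0)
  hist_val <- numeric(0)

  for (epoch in seq_len(n_epochs)) {
    ord <- sample.int(ntr)
    starts <- seq(1L, ntr, by = batch_size)
    ep_nll <- 0
    for (st in starts) {
      ix <- ord[st:min(st + batch_size - 1L, ntr)]
      nb <- length(ix)
      masks <- if (p_drop > 0) {
        lapply(seq_len(n_lay), function(j)
          matrix(stats::rbinom(nb * n_hid, 1L, 1 - p_drop) / (1 - p_drop),
                 nb, n_hid))
      } else NULL
      res <- batch_nll_grad(model, Xtr[ix, , drop = FALSE], ttr[ix], dtr[ix],
                            masks = masks)
      grad <- pack_params(list(heads = res$ghead, assign = res$gassign))
      adam$t <- adam$t + 1L
      adam$m <- adam$beta1 * adam$m + (1 - adam$beta1) * grad
      adam$v <- adam$beta2 * adam$v + (1 - adam$beta2) * grad^2
      mhat <- adam$m / (1 - adam$beta1^adam$t)
      vhat <- adam$v / (1 - adam$beta2^adam$t)
      theta <- theta - learning_rate * mhat / (sqrt(vhat) + adam$eps)
      model <- set_model_params(model, unpack_params(theta, skeleton))
      ep_nll <- ep_nll + res$nll * nb
    }
    val_nll <- batch_nll_grad(model, Xva, tva, dva, want_grad = FALSE)$nll
    hist_epoch <- c(hist_epoch, epoch)
    hist_train <- c(hist_train, ep_nll / ntr)
    hist_val <- c(hist_val, val_nll)
    if (verbose)
      message(sprintf("epoch %4d  train %.5f  val %.5f", epoch,
                      ep_nll / ntr, val_nll))
    if (is.finite(val_nll) && val_nll < best_val) {
      best_val <- val_nll
      best_theta <- theta
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }

  model <- set_model_params(model, unpack_params(best_theta, skeleton))
  model$history <- data.frame(epoch = hist_epoch, train_nll = hist_train,
                              val_nll = hist_val)
  model$best_val_nll <- best_val
  model$config <- list(k = k, n_layers_hazard = n_layers_hazard,
                       n_hidden_hazard = n_hidden_hazard,
                       latent_dim = latent_dim,
                       n_layers_assign = n_layers_assign,
                       n_hidden_assign = n_hidden_assign,
                       dropout = dropout, learning_rate = learning_rate,
                       batch_size = batch_size, n_epochs = n_epochs,
                       patience = patience, val_fraction = val_fraction,
                       seed = seed)
  model
}

#' Default hyper-parameter grid
#'
#' The random-search grid used for model selection: learning rate 1e-3 or
#' 1e-4, batch size 100 or 250, 1-3 layers of 50 or 100 nodes for both the
#' hazard heads and the assignment network, 2-5 mixture components, and a
#' latent code of size 10, 50 or 100.
#'
#' @return Named list of candidate values per tunable argument of
#'   [survmixnet()].
#' @export
default_grid <- function() {
  list(learning_rate = c(1e-3, 1e-4),
       batch_size = c(100L, 250L),
       n_layers_hazard = 1:3,
       n_hidden_hazard = c(50L, 100L),
       n_layers_assign = 1:3,
       n_hidden_assign = c(50L, 100L),
       k = 2:5,
       latent_dim = c(10L, 50L, 100L))
}

#' Random hyper-parameter search
#'
#' Samples `n_iter` configurations uniformly (each grid dimension
#' independently), fits each with [survmixnet()], ranks them by the
#' held-out negative log-likelihood reached at early stopping, and refits
#' the best configuration. Deterministic given `seed`.
#'
#' @param x,time,event As in [survmixnet()].
#' @param grid Named list of candidate values; see [default_grid()]. Values
#'   fixed across the search can be supplied via `...`.
#' @param n_iter Number of sampled configurations (default 100).
#' @param seed Integer seed controlling sampling and every fit.
#' @param ... Further arguments passed to every [survmixnet()] call
#'   (e.g. `n_epochs`, `patience`).
#' @return List with `model` (refit of the best configuration),
#'   `best_config`, and `results` (a data frame of sampled configurations
#'   and their held-out NLL).
#' @export
random_search <- function(x, time, event, grid = default_grid(),
                          n_iter = 100L, seed = NULL, ...) {
  stopifnot(length(grid) >= 1L, all(lengths(grid) >= 1L))
  dots <- list(...)
  if (!is.null(seed)) set.seed(seed)
  configs <- lapply(seq_len(n_iter), function(i)
    lapply(grid, function(v) v[[sample.int(length(v), 1L)]]))
  fit_seeds <- sample.int(.Machine$integer.max, n_iter)
  nll <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    fit <- tryCatch(
      do.call(survmixnet, c(list(x = x, time = time, event = event,
                                 seed = fit_seeds[i]), configs[[i]], dots)),
      error = function(e) NULL)
    nll[i] <- if (is.null(fit)) Inf else fit$best_val_nll
  }
  if (all(!is.finite(nll))) stop("every sampled configuration failed")
  best <- which.min(nll)
  model <- do.call(survmixnet, c(list(x = x, time = time, event = event,
                                      seed = fit_seeds[best]),
                                 configs[[best]], dots))
  results <- cbind(do.call(rbind.data.frame, lapply(configs, as.data.frame)),
                   val_nll = nll)
  list(model = model, best_config = configs[[best]], results = results)
}
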