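## Exact right-censored mixture log-likelihood.
##
## Uncensored subjects contribute log sum_k alpha_k(x) lambda_k(t) exp(-Lambda_k(t));
## censored subjects contribute log sum_k alpha_k(x) exp(-Lambda_k(t)).
## Both are evaluated in the log domain with a max shift so that large
## cumulative hazards cannot underflow the linear-form products.

LAMBDA_FLOOR <- 1e-10  # floor on the instantaneous hazard inside log()

row_logsumexp <- function(M) {
  mx <- apply(M, 1L, max)
  mx + log(rowSums(exp(M - mx)))
}

validate_surv_triplet <- function(time, event) {
  if (length(time) == 0L) stop("empty dataset", call. = FALSE)
  if (length(event) != length(time))
    stop("time and event lengths differ", call. = FALSE)
  if (any(time < 0)) stop("negative times", call. = FALSE)
  if (!all(event %in% c(0, 1)))
    stop("event indicator must be 0 (censored) or 1 (event)", call. = FALSE)
  if (any(event == 1 & time == 0))
    stop(paste("event recorded at t = 0: the cumulative hazard is anchored",
               "at zero so the event density vanishes there"), call. = FALSE)
  invisible(TRUE)
}

#' Right-censored log-likelihood of a survival mixture
#'
#' Sums, over subjects, the log of the mixture event density at the observed
#' time (events) or of the mixture survival at the censoring time (censored
#' records). Computed in the log domain via a max-shifted log-sum-exp so the
#' value stays finite even when every component survival underflows in
#' linear form. The instantaneous hazard is floored at `1e-10` inside the
#' logarithm to guard exact zeros.
#'
#' @param model A `"survmix"` model.
#' @param x Covariate matrix or data frame.
#' @param time Non-negative observed times.
#' @param event 0/1 indicator (1 = event, 0 = right-censored).
#' @return Scalar log-likelihood (a sum, not a mean).
#' @export
log_likelihood <- function(model, x, time, event) {
  validate_surv_triplet(time, event)
  X <- resolve_covariates(model, x)
  stopifnot(nrow(X) == length(time))
  alpha <- assign_probs(model, X)
  K <- model$n_clusters
  n <- length(time)
  C <- matrix(0, n, K)
  unc <- event == 1
  for (k in seq_len(K)) {
    C[, k] <- -cumulative_hazard(model$heads[[k]], time)
    if (any(unc)) {
      lam <- instantaneous_hazard(model$heads[[k]], time[unc])
      C[unc, k] <- C[unc, k] + log(pmax(lam, LAMBDA_FLOOR))
    }
  }
  sum(row_logsumexp(log(alpha) + C))
}

## ---- fused training path ------------------------------------------------
##
## Mean negative log-likelihood of a batch and its gradient with respect to
## every parameter, sharing the layer caches between the forward and reverse
## passes. X must already match the model's covariates; masks are dropout
## masks for the assignment net (NULL in evaluation mode).

batch_nll_grad <- function(model, X, time, event, masks = NULL,
                           want_grad = TRUE) {
  n <- length(time)
  K <- model$n_clusters
  t_max <- model$t_max
  s <- time / t_max
  unc <- event == 1

  afw <- mlp_forward(model$assignment, X, masks = masks, cache = want_grad)
  alpha <- afw$probs

  fws <- vector("list", K)
  Lam <- matrix(0, n, K)
  Ydot <- matrix(0, n, K)
  for (k in seq_len(K)) {
    fw <- head_forward(model$heads[[k]], s, tangent = TRUE, cache = want_grad)
    fws[[k]] <- fw
    Lam[, k] <- fw$y - head_origin(model$heads[[k]])
    Ydot[, k] <- fw$ydot
  }
  ## hazard in original units is ydot / t_max; floor it inside the log
  floor_s <- LAMBDA_FLOOR * t_max
  C <- -Lam
  if (any(unc)) {
    C[unc, ] <- C[unc, ] + log(pmax(Ydot[unc, , drop = FALSE], floor_s)) -
      log(t_max)
  }
  M <- log(alpha) + C
  ll <- row_logsumexp(M)
  nll <- -mean(ll)
  if (!want_grad) return(list(nll = nll))

  post <- exp(M - ll)                    # responsibilities, rows sum to 1
  sc <- -1 / n
  glogits <- sc * (post - alpha)
  gLam <- -sc * post                     # d nll / d Lambda_ik = post/n
  gYdot <- matrix(0, n, K)
  if (any(unc)) {
    act <- Ydot[unc, , drop = FALSE] > floor_s
    gYdot[unc, ] <- sc * post[unc, , drop = FALSE] /
      pmax(Ydot[unc, , drop = FALSE], floor_s) * act
  }

  ghead <- vector("list", K)
  for (k in seq_len(K)) {
    ghead[[k]] <- head_backward(model$heads[[k]], fws[[k]],
                                gL = gLam[, k], gD = gYdot[, k])
  }
  gassign <- mlp_backward(model$assignment, afw, glogits, masks = masks)
  list(nll = nll, ghead = ghead, gassign = gassign)
}

## ---- parameter packing --------------------------------------------------

model_params <- function(model) {
  list(heads = lapply(model$heads, function(h)
         h[c("Wt", "Wu", "b", "w_out", "u_out", "b_out", "l")]),
       assign = model$assignment[c("V", "d", "V_out", "d_out")])
}

set_model_params <- function(model, params) {
  for (k in seq_along(model$heads))
    model$heads[[k]][names(params$heads[[k]])] <- params$heads[[k]]
  model$assignment[names(params$assign)] <- params$assign
  model
}

pack_params <- function(params) unlist(params, use.names = FALSE)

unpack_params <- function(flat, skeleton) {
  pos <- 0L
  fill <- function(x) {
    if (is.list(x)) {
      lapply(x, fill)
    } else {
      k <- length(x)
      v <- flat[(pos + 1L):(pos + k)]
      pos <<- pos + k
      attributes(v) <- attributes(x)
      v
    }
  }
  out <- fill(skeleton)
  stopifnot(pos == length(flat))
  out
}
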