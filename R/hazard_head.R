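#' Positive reparameterisation of raw network weights
#'
#' Weights on every path from the time input to the output of a cumulative
#' hazard head must be non-negative so that the head is monotone
#' non-decreasing in time. Rather than constraining the optimiser, raw
#' unconstrained parameters are squared element-wise. Squaring is smooth
#' everywhere (unlike the absolute value) and allows an effective weight to
#' reach exactly zero.
#'
#' @param raw Numeric vector, matrix or array of unconstrained parameters.
#' @return Object of the same shape with non-negative entries, `raw^2`.
#' @examples
#' reparam_positive(c(-3, 0, 2))  # 9 0 4
#' @export
reparam_positive <- function(raw) {
  raw * raw
}

## tanh derivatives expressed through the activation value h = tanh(z):
##   sigma'  = 1 - h^2
##   sigma'' = -2 h (1 - h^2)

#' Construct a monotone neural cumulative-hazard head
#'
#' A feed-forward network mapping (time, latent cluster code) to a scalar.
#' Weights on the time path are kept non-negative by squaring
#' ([reparam_positive()]), the activation is tanh (strictly increasing and
#' smooth, so the time derivative of the network exists everywhere), and the
#' cumulative hazard is anchored at the origin by subtracting the network
#' value at time zero. The latent code enters each hidden layer through an
#' unconstrained linear map, which conditions the head on its cluster without
#' breaking monotonicity in time.
#'
#' Time is internally rescaled by `t_max` (the largest observed time of the
#' training split) so that the tanh layers operate on inputs of order one;
#' hazards are returned in original time units via the chain rule.
#'
#' @param n_layers Number of hidden layers (the tuning grid uses 1-3).
#' @param n_hidden Nodes per hidden layer (grid: 50 or 100).
#' @param latent_dim Length of the learnable latent cluster code (grid: 10,
#'   50 or 100).
#' @param t_max Largest training time; times are mapped to `t / t_max`.
#' @param init_sd Standard deviation of the raw weight initialisation on the
#'   time path. Effective weights are squared raws, so their typical size is
#'   `init_sd^2`.
#' @return An object of class `c("nn_hazard_head", "hazard_head")` holding
#'   raw weight matrices `Wt` (time path, constrained by squaring), latent
#'   input maps `Wu`, biases `b`, the output layer (`w_out`, `u_out`,
#'   `b_out`) and the latent code `l`.
#' @seealso [cumulative_hazard()], [instantaneous_hazard()]
#' @export
hazard_head <- function(n_layers = 2L, n_hidden = 50L, latent_dim = 10L,
                        t_max = 1, init_sd = NULL) {
  stopifnot(n_layers >= 1L, n_hidden >= 1L, latent_dim >= 1L, t_max > 0)
  if (is.null(init_sd)) init_sd <- 1 / sqrt(n_hidden)
  Wt <- vector("list", n_layers)
  Wu <- vector("list", n_layers)
  b <- vector("list", n_layers)
  Wt[[1L]] <- matrix(stats::rnorm(n_hidden, sd = sqrt(init_sd)), n_hidden, 1L)
  Wu[[1L]] <- matrix(stats::rnorm(n_hidden * latent_dim,
                                  sd = 1 / sqrt(latent_dim)),
                     n_hidden, latent_dim)
  b[[1L]] <- stats::rnorm(n_hidden, sd = 0.1)
  if (n_layers > 1L) {
    for (j in 2:n_layers) {
      Wt[[j]] <- matrix(stats::rnorm(n_hidden * n_hidden, sd = sqrt(init_sd)),
                        n_hidden, n_hidden)
      Wu[[j]] <- matrix(stats::rnorm(n_hidden * latent_dim,
                                     sd = 1 / sqrt(latent_dim)),
                        n_hidden, latent_dim)
      b[[j]] <- stats::rnorm(n_hidden, sd = 0.1)
    }
  }
  structure(list(
    config = list(n_layers = as.integer(n_layers),
                  n_hidden = as.integer(n_hidden),
                  latent_dim = as.integer(latent_dim),
                  activation = "tanh"),
    Wt = Wt, Wu = Wu, b = b,
    w_out = stats::rnorm(n_hidden, sd = sqrt(init_sd)),
    u_out = stats::rnorm(latent_dim, sd = 1 / sqrt(latent_dim)),
    b_out = 0,
    l = stats::rnorm(latent_dim),
    t_max = t_max
  ), class = c("nn_hazard_head", "hazard_head"))
}

#' Closed-form Weibull hazard head
#'
#' A parametric head with cumulative hazard `(t / scale)^shape`. Used as the
#' generating truth of the clustered cohort simulator and as a reference
#' distribution in checks; it supports the same evaluation generics as the
#' neural head.
#'
#' @param shape,scale Positive Weibull parameters.
#' @return Object of class `c("weibull_hazard", "hazard_head")`.
#' @export
weibull_head <- function(shape, scale) {
  stopifnot(shape > 0, scale > 0)
  structure(list(shape = shape, scale = scale),
            class = c("weibull_hazard", "hazard_head"))
}

#' Evaluate the cumulative hazard of a head
#'
#' @param head A hazard head ([hazard_head()] or [weibull_head()]).
#' @param t Non-negative times in original units.
#' @param ... Passed to methods.
#' @return Non-negative vector, non-decreasing in `t` and exactly 0 at
#'   `t = 0` (the network value at the origin is subtracted).
#' @export
cumulative_hazard <- function(head, t, ...) UseMethod("cumulative_hazard")

#' Evaluate the instantaneous hazard of a head
#'
#' For a neural head this is the exact derivative of the network with
#' respect to time (forward-mode differentiation through the layers),
#' converted back to original time units by the chain rule.
#'
#' @inheritParams cumulative_hazard
#' @return Non-negative vector, d(cumulative hazard)/dt at `t`.
#' @export
instantaneous_hazard <- function(head, t, ...) UseMethod("instantaneous_hazard")

check_times <- function(t) {
  if (!is.numeric(t)) stop("times must be numeric", call. = FALSE)
  if (anyNA(t) || any(!is.finite(t))) stop("times must be finite", call. = FALSE)
  if (any(t < 0)) stop("negative times are outside the hazard domain", call. = FALSE)
  as.numeric(t)
}

warn_extrapolation <- function(t, t_max) {
  if (any(t > t_max * (1 + 1e-8))) {
    warning(sprintf(
      "evaluating beyond the largest training time (%.6g): extrapolating",
      t_max), call. = FALSE)
  }
}

## Forward pass of one neural head over a vector of *scaled* times s.
## Returns the raw network value y (before origin anchoring), the time
## tangent ydot = dy/ds when requested, and the per-layer caches needed by
## the reverse pass. H[[j]] is n x n_hidden; Hd[[j]] its tangent.
head_forward <- function(head, s, tangent = TRUE, cache = FALSE) {
  L <- head$config$n_layers
  n <- length(s)
  l <- head$l
  H <- vector("list", L)
  Hd <- if (tangent) vector("list", L) else NULL
  Zd <- if (tangent && cache) vector("list", L) else NULL
  a1 <- as.vector(head$Wt[[1L]])^2
  c1 <- as.vector(head$Wu[[1L]] %*% l) + head$b[[1L]]
  Z <- outer(s, a1)
  Z <- sweep(Z, 2L, c1, "+")
  H[[1L]] <- tanh(Z)
  if (tangent) {
    Zdot <- matrix(a1, n, length(a1), byrow = TRUE)
    Hd[[1L]] <- (1 - H[[1L]]^2) * Zdot
    if (cache) Zd[[1L]] <- Zdot
  }
  if (L > 1L) {
    for (j in 2:L) {
      Aj <- head$Wt[[j]]^2
      cj <- as.vector(head$Wu[[j]] %*% l) + head$b[[j]]
      Z <- H[[j - 1L]] %*% t(Aj)
      Z <- sweep(Z, 2L, cj, "+")
      H[[j]] <- tanh(Z)
      if (tangent) {
        Zdot <- Hd[[j - 1L]] %*% t(Aj)
        Hd[[j]] <- (1 - H[[j]]^2) * Zdot
        if (cache) Zd[[j]] <- Zdot
      }
    }
  }
  aout <- head$w_out^2
  y <- as.vector(H[[L]] %*% aout) + sum(head$u_out * l) + head$b_out
  out <- list(y = y)
  if (tangent) out$ydot <- as.vector(Hd[[L]] %*% aout)
  if (cache) {
    out$H <- H
    out$Hd <- Hd
    out$Zd <- Zd
    out$s <- s
  }
  out
}

## Network value at the origin (s = 0), used for anchoring.
head_origin <- function(head) {
  head_forward(head, 0, tangent = FALSE)$y
}

#' @rdname cumulative_hazard
#' @export
cumulative_hazard.nn_hazard_head <- function(head, t, ...) {
  t <- check_times(t)
  if (!all(vapply(head$Wt, function(w) all(is.finite(w)), logical(1))))
    stop("non-finite head parameters", call. = FALSE)
  warn_extrapolation(t, head$t_max)
  s <- t / head$t_max
  fw <- head_forward(head, s, tangent = FALSE)
  lam <- fw$y - head_origin(head)
  ## anchoring makes Lambda(0) zero analytically; snap rounding residue
  lam[t == 0] <- 0
  lam
}

#' @rdname instantaneous_hazard
#' @export
instantaneous_hazard.nn_hazard_head <- function(head, t, ...) {
  t <- check_times(t)
  warn_extrapolation(t, head$t_max)
  s <- t / head$t_max
  fw <- head_forward(head, s, tangent = TRUE)
  fw$ydot / head$t_max
}

#' @rdname cumulative_hazard
#' @export
cumulative_hazard.weibull_hazard <- function(head, t, ...) {
  t <- check_times(t)
  (t / head$scale)^head$shape
}

#' @rdname instantaneous_hazard
#' @export
instantaneous_hazard.weibull_hazard <- function(head, t, ...) {
  t <- check_times(t)
  (head$shape / head$scale) * (t / head$scale)^(head$shape - 1)
}

#' @export
print.nn_hazard_head <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Monotone neural hazard head: %d layer(s) x %d nodes, latent dim %d, t_max = %g\n",
    cfg$n_layers, cfg$n_hidden, cfg$latent_dim, x$t_max))
  invisible(x)
}

#' @export
print.weibull_hazard <- function(x, ...) {
  cat(sprintf("Weibull hazard head: shape %g, scale %g\n", x$shape, x$scale))
  invisible(x)
}

## ---- reverse pass -------------------------------------------------------
##
## Given adjoints gL (d loss / d Lambda_i) and gD (d loss / d ydot_i) for a
## batch evaluated at scaled times s, accumulate gradients with respect to
## every head parameter. Lambda_i = y(s_i) - y(0); the tangent graph
## ydot = dy/ds is differentiated a second time, which is where the second
## derivative of tanh enters.
##
## Returns a list mirroring the parameter slots (Wt, Wu, b, w_out, u_out,
## b_out, l) with gradients w.r.t. the *raw* parameters (chain rule through
## the squaring reparameterisation applied at the end).
head_backward <- function(head, fw, gL, gD = NULL) {
  L <- head$config$n_layers
  H <- fw$H
  Hd <- fw$Hd
  Zd <- fw$Zd
  s <- fw$s
  n <- length(s)
  l <- head$l
  aout <- head$w_out^2
  use_tangent <- !is.null(gD)
  if (!use_tangent) gD <- numeric(n)

  gA <- vector("list", L)      # grads w.r.t. effective (squared) weights
  gWu <- vector("list", L)
  gb <- vector("list", L)
  gl <- numeric(length(l))

  g_aout <- as.vector(crossprod(H[[L]], gL))
  if (use_tangent) g_aout <- g_aout + as.vector(crossprod(Hd[[L]], gD))
  sgL <- sum(gL)
  g_uout <- sgL * l
  g_bout <- sgL
  gl <- gl + sgL * head$u_out

  Q <- gL %o% aout                      # adjoint of H[[L]]
  P <- if (use_tangent) gD %o% aout else NULL   # adjoint of Hd[[L]]

  for (j in L:1) {
    Hj <- H[[j]]
    Sp <- 1 - Hj^2
    if (use_tangent) {
      Spp <- -2 * Hj * Sp
      Rj <- P * Sp                      # adjoint of Zdot_j
      ZA <- Q * Sp + P * Zd[[j]] * Spp  # total adjoint of Z_j
    } else {
      Rj <- NULL
      ZA <- Q * Sp
    }
    if (j == 1L) {
      g <- colSums(ZA * s)
      if (use_tangent) g <- g + colSums(Rj)
      gA[[1L]] <- matrix(g, ncol = 1L)
    } else {
      g <- crossprod(ZA, H[[j - 1L]])
      if (use_tangent) g <- g + crossprod(Rj, Hd[[j - 1L]])
      gA[[j]] <- g
      Aj <- head$Wt[[j]]^2
      Q <- ZA %*% Aj
      if (use_tangent) P <- Rj %*% Aj
    }
    cadj <- colSums(ZA)
    gb[[j]] <- cadj
    gWu[[j]] <- cadj %o% l
    gl <- gl + as.vector(crossprod(head$Wu[[j]], cadj))
  }

  ## origin anchor: Lambda = y(s) - y(0); total coefficient of y(0) is -sum(gL)
  g0 <- -sgL
  if (g0 != 0) {
    fw0 <- head_forward(head, 0, tangent = FALSE, cache = TRUE)
    H0 <- lapply(fw0$H, as.vector)
    g_aout <- g_aout + g0 * H0[[L]]
    g_uout <- g_uout + g0 * l
    g_bout <- g_bout + g0
    gl <- gl + g0 * head$u_out
    q <- g0 * aout
    for (j in L:1) {
      za <- q * (1 - H0[[j]]^2)
      if (j > 1L) {
        gA[[j]] <- gA[[j]] + za %o% H0[[j - 1L]]
        q <- as.vector(crossprod(head$Wt[[j]]^2, za))
      }
      ## j == 1: s = 0 kills the gradient through the time weight
      gb[[j]] <- gb[[j]] + za
      gWu[[j]] <- gWu[[j]] + za %o% l
      gl <- gl + as.vector(crossprod(head$Wu[[j]], za))
    }
  }

  ## chain rule through the squaring reparameterisation
  gWt <- vector("list", L)
  for (j in 1:L) gWt[[j]] <- 2 * head$Wt[[j]] * gA[[j]]
  list(Wt = gWt, Wu = gWu, b = gb,
       w_out = 2 * head$w_out * g_aout,
       u_out = g_uout, b_out = g_bout, l = gl)
}
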