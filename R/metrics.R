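#' Kaplan-Meier product-limit estimate
#'
#' Non-parametric estimate of a survival function from right-censored data.
#' Ties at a time point are processed jointly, with events counted before
#' censorings leave the risk set. The returned curve is a right-continuous
#' step function equal to 1 before the first event time.
#'
#' @param time Non-negative observed times.
#' @param event 0/1 indicator (1 = event).
#' @return Object of class `"km_curve"` with `time` (distinct observed
#'   times), `n_risk`, `n_event`, `n_censor` and `surv`, plus the largest
#'   observed time in `t_max`.
#' @seealso [km_eval()] to evaluate the step function.
#' @export
kaplan_meier <- function(time, event) {
  if (length(time) == 0L) stop("empty input", call. = FALSE)
  stopifnot(length(event) == length(time), all(time >= 0),
            all(event %in% c(0, 1)))
  ut <- sort(unique(time))
  d <- vapply(ut, function(u) sum(event[time == u] == 1), numeric(1))
  c0 <- vapply(ut, function(u) sum(event[time == u] == 0), numeric(1))
  n_risk <- length(time) - c(0, cumsum(d + c0)[-length(ut)])
  surv <- cumprod(1 - d / n_risk)
  structure(list(time = ut, n_risk = n_risk, n_event = d, n_censor = c0,
                 surv = surv, t_max = max(time)),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve
#'
#' @param km A `"km_curve"`.
#' @param t Times at which to read the step function.
#' @param left If `TRUE`, return the left limit S(t-) (the value just
#'   before `t`), as used for censoring weights at event times.
#' @return Survival values in \[0, 1\].
#' @export
km_eval <- function(km, t, left = FALSE) {
  idx <- if (left) findInterval(t, km$time, left.open = TRUE)
         else findInterval(t, km$time)
  c(1, km$surv)[idx + 1L]
}

#' Median survival time of a Kaplan-Meier curve
#'
#' First time at which the curve reaches 0.5 or below; `NA` (with attribute
#' `censored_above` set to the largest observed time) when the curve never
#' crosses 0.5.
#'
#' @param km A `"km_curve"`.
#' @return Scalar median, or `NA` flagged with `attr(, "censored_above")`.
#' @export
km_median <- function(km) {
  hit <- which(km$surv <= 0.5)
  if (length(hit) == 0L)
    return(structure(NA_real_, censored_above = km$t_max))
  km$time[hit[1L]]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d distinct times, %d events, %d censored\n",
              length(x$time), sum(x$n_event), sum(x$n_censor)))
  med <- km_median(x)
  if (is.na(med)) cat(sprintf("Median survival: > %g\n",
                              attr(med, "censored_above")))
  else cat(sprintf("Median survival: %g\n", med))
  invisible(x)
}

#' Inverse-probability-of-censoring weights
#'
#' Estimates the censoring survival function G by Kaplan-Meier with the
#' event indicator flipped, then weights event subjects by 1/G(t-) (the
#' left limit at their event time) and each evaluation horizon t by 1/G(t).
#' Subjects whose G is zero at their time receive weight 0 and are excluded
#' from weighted sums (a message reports how many). With no censoring in the
#' data all weights are 1.
#'
#' @param time,event Observed times and 0/1 event indicator.
#' @param horizons Optional evaluation times for the horizon weights.
#' @return List with `per_subject` (weight for each record; 0 for censored
#'   records, which never enter IPCW sums) and `at_horizon` (named vector
#'   over `horizons`).
#' @export
censoring_weights <- function(time, event, horizons = NULL) {
  stopifnot(length(time) == length(event))
  G <- kaplan_meier(time, 1 - event)
  g_left <- km_eval(G, time, left = TRUE)
  w <- numeric(length(time))
  ev <- event == 1
  w[ev] <- ifelse(g_left[ev] > 0, 1 / g_left[ev], 0)
  n_dropped <- sum(ev & g_left == 0)
  if (n_dropped > 0)
    message(sprintf(
      "%d event subject(s) beyond the censoring support received weight 0",
      n_dropped))
  at_h <- NULL
  if (!is.null(horizons)) {
    gh <- km_eval(G, horizons)
    at_h <- ifelse(gh > 0, 1 / gh, 0)
    names(at_h) <- as.character(horizons)
  }
  list(per_subject = w, at_horizon = at_h)
}

#' Time-dependent Brier score with censoring weights
#'
#' BS(t) = (1/n) * sum_i \[ w(t_i) 1\{event_i, t_i <= t\} S(t|x_i)^2 +
#' w(t) 1\{t_i > t\} (1 - S(t|x_i))^2 \], with w the inverse probability of
#' censoring weights of [censoring_weights()] and n the full sample size.
#' Lower is better; with no censoring it reduces to the mean squared error
#' of the predicted survival against the observed status at t.
#'
#' @param pred Predicted survival probabilities at horizon `t`: either a
#'   numeric vector (one value per subject) or a `"survmix_pred"` whose
#'   `times` contain `t`.
#' @param time,event Observed times and 0/1 event indicator.
#' @param t Evaluation horizon.
#' @return Scalar Brier score.
#' @export
brier_score <- function(pred, time, event, t) {
  s_hat <- pred_at(pred, t)
  n <- length(time)
  stopifnot(length(s_hat) == n, t >= 0)
  cw <- censoring_weights(time, event, horizons = t)
  term1 <- cw$per_subject * (event == 1 & time <= t) * s_hat^2
  term2 <- cw$at_horizon[[1L]] * (time > t) * (1 - s_hat)^2
  sum(term1 + term2) / n
}

#' Cumulative time-dependent concordance index
#'
#' IPCW-weighted generalisation of the ROC-AUC to right-censored survival:
#' among pairs where subject i has an event at or before horizon t and
#' subject j is still at risk after t, the proportion (weighted by
#' w(t_i) = 1/G(t_i-)) in which the model ranks them correctly, i.e.
#' predicts a higher survival at t for j. Ties in the predicted survival
#' count zero (strict inequality). The i index runs over uncensored
#' subjects only; censored subjects cannot anchor a comparable pair because
#' their event time is unknown.
#'
#' @inheritParams brier_score
#' @return Concordance in \[0, 1\], or `NA` (flagged with a warning) when no
#'   comparable pair exists. If all predictions are tied the value is 0 and
#'   carries the attribute `degenerate = TRUE`.
#' @export
c_index <- function(pred, time, event, t) {
  s_hat <- pred_at(pred, t)
  n <- length(time)
  stopifnot(length(s_hat) == n)
  cw <- censoring_weights(time, event)
  w <- cw$per_subject
  is_i <- event == 1 & time <= t         # uncensored, event before horizon
  at_risk <- time > t
  denom <- sum(at_risk) * sum(w[is_i])
  if (denom == 0) {
    warning("no comparable pair at this horizon", call. = FALSE)
    return(NA_real_)
  }
  num <- 0
  for (i in which(is_i)) {
    num <- num + w[i] * sum(at_risk & s_hat > s_hat[i])
  }
  out <- num / denom
  if (num == 0 && length(unique(s_hat)) == 1L)
    attr(out, "degenerate") <- TRUE
  out
}

pred_at <- function(pred, t) {
  if (inherits(pred, "survmix_pred")) {
    j <- which(abs(pred$times - t) <= 1e-12 * max(1, abs(t)))
    if (length(j) == 0L)
      stop("prediction object does not cover the requested horizon",
           call. = FALSE)
    as.vector(pred$survival[, j[1L]])
  } else {
    as.numeric(pred)
  }
}

#' Quantile evaluation horizons
#'
#' Evaluation times for the survival metrics: the 0.25, 0.5 and 0.75
#' empirical quantiles (linear interpolation between order statistics) of
#' the uncensored subjects' event times. Censored records never affect the
#' horizons.
#'
#' @param time,event Observed times and 0/1 event indicator.
#' @param quantiles Probabilities (default `c(0.25, 0.5, 0.75)`).
#' @return Named numeric vector of horizons.
#' @export
eval_times <- function(time, event, quantiles = c(0.25, 0.5, 0.75)) {
  ev <- time[event == 1]
  if (length(ev) == 0L) stop("no uncensored events", call. = FALSE)
  q <- stats::quantile(ev, probs = quantiles, type = 7, names = FALSE)
  names(q) <- paste0("q", quantiles)
  q
}

#' Cross-validated survival metrics
#'
#' Splits the data into `n_folds` folds (deterministic given `seed`), fits
#' the mixture on each training part and computes the time-dependent Brier
#' score and concordance index on the held-out fold at the 0.25/0.5/0.75
#' quantile horizons of the full data's uncensored event times (horizons are
#' computed once so they are comparable across folds). A fold without events
#' is flagged with `NA` metrics and a warning.
#'
#' @param x,time,event Data as in [survmixnet()].
#' @param k Number of mixture components.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed for the fold split and every fold's fit.
#' @param horizons Optional explicit horizons; default [eval_times()].
#' @param ... Passed to [survmixnet()].
#' @return Object of class `"survmix_cv"`: `horizons`, per-fold matrices
#'   `brier` and `cindex` (folds x horizons), their means and standard
#'   deviations, and the per-fold test indices.
#' @export
cross_validate <- function(x, time, event, k = 2L, n_folds = 5L,
                           seed = NULL, horizons = NULL, ...) {
  stopifnot(n_folds >= 2L)
  X <- if (is.data.frame(x)) as.matrix(x) else x
  n <- length(time)
  if (!is.null(seed)) set.seed(seed)
  fold_of <- sample(rep_len(seq_len(n_folds), n))
  if (is.null(horizons)) horizons <- eval_times(time, event)
  nh <- length(horizons)
  brier <- matrix(NA_real_, n_folds, nh,
                  dimnames = list(NULL, names(horizons)))
  cindex <- brier
  folds <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    te <- which(fold_of == f)
    tr <- which(fold_of != f)
    folds[[f]] <- te
    if (!any(event[te] == 1)) {
      warning(sprintf("fold %d has no events; metrics set to NA", f),
              call. = FALSE)
      next
    }
    fit <- survmixnet(X[tr, , drop = FALSE], time[tr], event[tr], k = k,
                      seed = if (is.null(seed)) NULL else seed + f, ...)
    pr <- suppressWarnings(
      predict(fit, X[te, , drop = FALSE], times = horizons))
    for (j in seq_len(nh)) {
      brier[f, j] <- brier_score(pr$survival[, j], time[te], event[te],
                                 horizons[j])
      cindex[f, j] <- suppressWarnings(
        c_index(pr$survival[, j], time[te], event[te], horizons[j]))
    }
  }
  structure(list(horizons = horizons, brier = brier, cindex = cindex,
                 brier_mean = colMeans(brier, na.rm = TRUE),
                 brier_sd = apply(brier, 2L, stats::sd, na.rm = TRUE),
                 cindex_mean = colMeans(cindex, na.rm = TRUE),
                 cindex_sd = apply(cindex, 2L, stats::sd, na.rm = TRUE),
                 folds = folds, k = k),
            class = "survmix_cv")
}

#' @export
print.survmix_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, %d components\n",
              nrow(x$brier), x$k))
  tab <- rbind(
    `C-index (mean)` = x$cindex_mean, `C-index (sd)` = x$cindex_sd,
    `Brier (mean)` = x$brier_mean, `Brier (sd)` = x$brier_sd)
  colnames(tab) <- sprintf("t=%.3g", x$horizons)
  print(round(tab, 4))
  invisible(x)
}

#' Serialise a cross-validation report to JSON
#'
#' @param cv A `"survmix_cv"` object.
#' @param path Optional file path; if omitted the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
cv_report_json <- function(cv, path = NULL) {
  rep <- list(
    horizons = as.list(stats::setNames(as.numeric(cv$horizons),
                                       names(cv$horizons))),
    metrics = lapply(c(cindex = "cindex", brier = "brier"), function(m) {
      list(per_fold = unname(as.data.frame(cv[[m]])),
           mean = as.numeric(cv[[paste0(m, "_mean")]]),
           sd = as.numeric(cv[[paste0(m, "_sd")]]))
    }))
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
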