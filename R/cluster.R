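#' Hard cluster allocation
#'
#' Assigns each subject to the component with the highest estimated cluster
#' probability. Exact ties break to the lowest cluster index.
#'
#' @param model A `"survmix"` model.
#' @param x Covariate matrix or data frame.
#' @return Object of class `"cluster_assignment"`: `labels` (integers in
#'   1..K) and `posteriors` (subjects x K simplex matrix).
#' @export
hard_assign <- function(model, x) {
  post <- assign_probs(model, x)
  structure(list(labels = max.col(post, ties.method = "first"),
                 posteriors = post),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Hard cluster assignment:\n")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Per-cluster survival summaries
#'
#' For each cluster: the Kaplan-Meier median survival time (flagged as
#' "greater than the last observed time" when the curve never reaches 0.5),
#' the percentage of the cohort in the cluster, the percentage of censored
#' subjects, and the mean of each requested covariate.
#'
#' @param labels Integer cluster labels (e.g. from [hard_assign()]), or a
#'   `"cluster_assignment"`.
#' @param time,event Observed times and 0/1 event indicator.
#' @param x Optional covariate matrix/data frame for per-cluster means.
#' @param covariates Optional character subset of covariate columns.
#' @return Data frame of class `"cluster_summary"`, one row per cluster,
#'   with columns `cluster`, `n`, `population_pct`, `censored_pct`,
#'   `median_survival`, `median_censored` and one `mean_<name>` column per
#'   covariate.
#' @export
cluster_summaries <- function(labels, time, event, x = NULL,
                              covariates = NULL) {
  if (inherits(labels, "cluster_assignment")) labels <- labels$labels
  stopifnot(length(labels) == length(time), length(time) == length(event))
  if (!is.null(x)) {
    x <- as.data.frame(x)
    if (!is.null(covariates)) x <- x[covariates]
  }
  ks <- sort(unique(labels))
  n <- length(labels)
  rows <- lapply(ks, function(k) {
    ix <- labels == k
    nk <- sum(ix)
    if (nk == 0L) {
      warning(sprintf("cluster %d is empty", k), call. = FALSE)
      return(data.frame(cluster = k, n = 0L, population_pct = 0,
                        censored_pct = NA_real_,
                        median_survival = NA_real_, median_censored = NA))
    }
    med <- km_median(kaplan_meier(time[ix], event[ix]))
    out <- data.frame(cluster = k, n = nk,
                      population_pct = 100 * nk / n,
                      censored_pct = 100 * mean(event[ix] == 0),
                      median_survival = if (is.na(med))
                        attr(med, "censored_above") else as.numeric(med),
                      median_censored = is.na(med))
    if (!is.null(x)) {
      mns <- colMeans(x[ix, , drop = FALSE])
      out[paste0("mean_", names(mns))] <- as.list(mns)
    }
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cluster_summary", "data.frame")
  out
}

#' @export
print.cluster_summary <- function(x, ...) {
  tab <- as.data.frame(x)
  tab$median_survival <- ifelse(
    x$median_censored %in% TRUE,
    paste0(">", signif(x$median_survival, 6)),
    as.character(signif(x$median_survival, 6)))
  tab$median_censored <- NULL
  tab$population_pct <- sprintf("%.2f %%", x$population_pct)
  tab$censored_pct <- sprintf("%.2f %%", x$censored_pct)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' Serialise a cluster report
#'
#' Writes the per-cluster summary table and, for K > 1, all pairwise
#' log-rank tests as JSON, alongside the plain-text table.
#'
#' @param summary A `"cluster_summary"`.
#' @param logrank Optional data frame of pairwise log-rank results (as
#'   produced by [pairwise_logrank()]).
#' @param path Optional file path for the JSON.
#' @return JSON string (invisibly when written to file).
#' @export
cluster_report_json <- function(summary, logrank = NULL, path = NULL) {
  rep <- list(clusters = as.data.frame(summary))
  if (!is.null(logrank)) rep$logrank = as.data.frame(logrank)
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Two-sample log-rank test
#'
#' Mantel-Haenszel log-rank chi-square with 1 degree of freedom comparing
#' the survival distributions of two groups; ties are handled by the
#' hypergeometric variance. The p-value is the chi-square upper tail.
#'
#' @param time_a,event_a First group's times and 0/1 indicators.
#' @param time_b,event_b Second group.
#' @return List with `statistic`, `p_value` and `df = 1`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0L || length(time_b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  if (sum(event_a == 1) + sum(event_b == 1) == 0L)
    stop("no events in the pooled sample: the log-rank test is undefined",
         call. = FALSE)
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c(0L, 1L), c(length(time_a), length(time_b)))
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ grp)
  stat <- as.numeric(sd_fit$chisq)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' All pairwise log-rank tests across clusters
#'
#' Runs [logrank_test()] for every pair of clusters. No multiplicity
#' correction is applied; all p-values are reported so users can adjust.
#'
#' @param labels Cluster labels or a `"cluster_assignment"`.
#' @param time,event Observed times and 0/1 indicator.
#' @return Data frame with columns `cluster_a`, `cluster_b`, `statistic`,
#'   `p_value`.
#' @export
pairwise_logrank <- function(labels, time, event) {
  if (inherits(labels, "cluster_assignment")) labels <- labels$labels
  ks <- sort(unique(labels))
  pairs <- utils::combn(ks, 2L, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(p) {
    a <- labels == p[1L]; b <- labels == p[2L]
    lr <- logrank_test(time[a], event[a], time[b], event[b])
    data.frame(cluster_a = p[1L], cluster_b = p[2L],
               statistic = lr$statistic, p_value = lr$p_value)
  }))
}

#' Permutation importance of covariates for cluster membership
#'
#' Measures how much each covariate drives the assignment network: the
#' covariate's column is permuted across subjects and the hard cluster
#' labels are recomputed; the score is the mean fraction of subjects whose
#' label changes over `n_repeats` permutations ("disagreement"). A covariate
#' the network ignores scores 0 up to Monte-Carlo noise. Alternatively
#' (`score = "nll"`) the score is the mean increase in negative
#' log-likelihood per subject, which requires `time` and `event`.
#'
#' @param model A `"survmix"` model.
#' @param x Covariate matrix or data frame.
#' @param n_repeats Number of permutations per covariate.
#' @param seed Optional integer seed.
#' @param score `"disagreement"` (default) or `"nll"`.
#' @param time,event Needed for `score = "nll"`.
#' @return Data frame of class `"permutation_importance"` with columns
#'   `covariate`, `importance` and `sd` (across repeats).
#' @export
permutation_importance <- function(model, x, n_repeats = 10L, seed = NULL,
                                   score = c("disagreement", "nll"),
                                   time = NULL, event = NULL) {
  score <- match.arg(score)
  stopifnot(n_repeats >= 1L)
  if (!is.null(seed)) set.seed(seed)
  X <- resolve_covariates(model, x)
  n <- nrow(X)
  base_labels <- hard_assign(model, X)$labels
  if (score == "nll") {
    stopifnot(!is.null(time), !is.null(event))
    base_nll <- -log_likelihood(model, X, time, event) / n
  }
  nm <- model$covariate_names
  if (is.null(nm)) nm <- paste0("x", seq_len(ncol(X)))
  res <- lapply(seq_len(ncol(X)), function(j) {
    sc <- vapply(seq_len(n_repeats), function(r) {
      Xp <- X
      Xp[, j] <- Xp[sample.int(n), j]
      if (score == "disagreement") {
        mean(hard_assign(model, Xp)$labels != base_labels)
      } else {
        -log_likelihood(model, Xp, time, event) / n - base_nll
      }
    }, numeric(1))
    data.frame(covariate = nm[j], importance = mean(sc),
               sd = if (n_repeats > 1L) stats::sd(sc) else NA_real_)
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  class(out) <- c("permutation_importance", "data.frame")
  out
}

## Elbow rule: index of maximum discrete curvature (second difference) of a
## fit-quality sequence; with fewer than 3 points or no positive curvature
## there is no elbow.
elbow_index <- function(values) {
  m <- length(values)
  if (m < 3L) return(NA_integer_)
  curv <- values[1:(m - 2L)] - 2 * values[2:(m - 1L)] + values[3:m]
  if (max(curv) <= 0) return(NA_integer_)
  which.max(curv) + 1L
}

#' Select the number of mixture components by the elbow rule
#'
#' Fits the mixture for each candidate K, records the held-out negative
#' log-likelihood (averaged over cross-validation folds), and selects the K
#' at maximum curvature of the NLL curve (largest discrete second
#' difference). With fewer than three candidates no curvature exists and the
#' minimum-NLL K is returned; a curve with no positive curvature (e.g.
#' linear in K) has no elbow and yields the smallest K with a warning.
#'
#' @param x,time,event Data as in [survmixnet()].
#' @param k_range Candidate numbers of components (default 2:5).
#' @param n_folds Cross-validation folds for the held-out NLL (default 3).
#' @param seed Integer seed (fold split and fits).
#' @param ... Passed to [survmixnet()].
#' @return Object of class `"elbow_result"`: data frame `profile` with
#'   `k` and `nll`, and `selected_k`.
#' @export
select_k <- function(x, time, event, k_range = 2:5, n_folds = 3L,
                     seed = NULL, ...) {
  stopifnot(length(k_range) >= 1L)
  X <- if (is.data.frame(x)) as.matrix(x) else x
  n <- length(time)
  if (!is.null(seed)) set.seed(seed)
  fold_of <- sample(rep_len(seq_len(n_folds), n))
  nll <- vapply(seq_along(k_range), function(i) {
    k <- k_range[i]
    per_fold <- vapply(seq_len(n_folds), function(f) {
      tr <- fold_of != f
      te <- !tr
      fit <- survmixnet(X[tr, , drop = FALSE], time[tr], event[tr], k = k,
                        seed = if (is.null(seed)) NULL else seed + 1000L * i + f,
                        ...)
      -suppressWarnings(
        log_likelihood(fit, X[te, , drop = FALSE], time[te], event[te])) /
        sum(te)
    }, numeric(1))
    mean(per_fold)
  }, numeric(1))
  if (length(k_range) == 1L) {
    sel <- k_range
  } else {
    ei <- elbow_index(nll)
    if (is.na(ei)) {
      if (length(k_range) < 3L) {
        sel <- k_range[which.min(nll)]
      } else {
        warning("no elbow in the held-out NLL curve; returning the smallest K",
                call. = FALSE)
        sel <- min(k_range)
      }
    } else {
      sel <- k_range[ei]
    }
  }
  structure(list(profile = data.frame(k = k_range, nll = nll),
                 selected_k = sel),
            class = "elbow_result")
}

#' @export
print.elbow_result <- function(x, ...) {
  cat("Held-out NLL by number of components:\n")
  print(x$profile, row.names = FALSE)
  cat("Selected K:", x$selected_k, "\n")
  invisible(x)
}
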