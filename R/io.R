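#' Construct and validate a survival dataset
#'
#' The package's tabular data container: a covariate matrix plus observed
#' time and event indicator per subject. Validation enforces finite
#' covariates, non-negative times, a 0/1 event indicator (a single risk),
#' and rejects events recorded at t = 0, where the anchored cumulative
#' hazard forces a zero event density.
#'
#' @param x Numeric covariate matrix or data frame.
#' @param time Non-negative observed times.
#' @param event 0/1 event indicator.
#' @param covariate_names Optional covariate names (default from `x`).
#' @return Object of class `"survival_dataset"` with elements `x`, `time`,
#'   `event`, `covariate_names`, `n`.
#' @export
survival_dataset <- function(x, time, event, covariate_names = NULL) {
  if (is.data.frame(x)) {
    if (is.null(covariate_names)) covariate_names <- names(x)
    x <- as.matrix(x)
  }
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  storage.mode(x) <- "double"
  if (is.null(covariate_names)) {
    covariate_names <- colnames(x)
    if (is.null(covariate_names))
      covariate_names <- paste0("x", seq_len(ncol(x)))
  }
  colnames(x) <- covariate_names
  if (nrow(x) != length(time) || length(time) != length(event))
    stop("x, time and event must have matching lengths", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop("covariates contain missing or non-finite values", call. = FALSE)
  bad <- which(!(event %in% c(0, 1)))
  if (length(bad) > 0L)
    stop(sprintf(paste("event indicator must be 0 or 1 (single risk);",
                       "first offending row: %d"), bad[1L]), call. = FALSE)
  validate_surv_triplet(time, event)
  structure(list(x = x, time = as.numeric(time), event = as.integer(event),
                 covariate_names = covariate_names, n = nrow(x)),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("Survival dataset: %d subjects, %d covariates, %.1f%% censored\n",
              x$n, ncol(x$x), 100 * mean(x$event == 0)))
  cat("Covariates:", paste(x$covariate_names, collapse = ", "), "\n")
  invisible(x)
}

#' Load a survival dataset from CSV
#'
#' Reads a delimited table with one row per subject, maps the time and
#' event columns, treats the remaining numeric columns (or an explicit
#' subset) as covariates, drops rows with missing values (reporting the
#' count), and validates the result.
#'
#' @param path CSV file with a header row.
#' @param time_col,event_col Column names of the observed time and the 0/1
#'   event indicator.
#' @param covariates Optional character vector selecting covariate columns;
#'   default: every other numeric column.
#' @return A [survival_dataset()].
#' @export
read_survival <- function(path, time_col = "time", event_col = "event",
                          covariates = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path)
  for (col in c(time_col, event_col))
    if (!col %in% names(df))
      stop(sprintf("column '%s' not present in %s", col, path), call. = FALSE)
  if (is.null(covariates)) {
    rest <- setdiff(names(df), c(time_col, event_col))
    covariates <- rest[vapply(df[rest], is.numeric, logical(1))]
    if (length(covariates) == 0L)
      stop("no numeric covariate columns found", call. = FALSE)
  } else if (!all(covariates %in% names(df))) {
    stop("requested covariate columns missing from the file", call. = FALSE)
  }
  if (!all(vapply(df[covariates], is.numeric, logical(1))))
    stop("non-numeric covariate columns", call. = FALSE)
  keep <- stats::complete.cases(df[c(covariates, time_col, event_col)])
  if (any(!keep))
    message(sprintf("dropped %d row(s) with missing values", sum(!keep)))
  df <- df[keep, , drop = FALSE]
  survival_dataset(df[covariates], df[[time_col]], df[[event_col]],
                   covariate_names = covariates)
}

CHECKPOINT_VERSION <- 1L

#' Save a fitted model checkpoint
#'
#' Serialises the full model (configuration, every parameter array, the
#' time scale, covariate standardisation statistics and training history)
#' so that a reload reproduces predictions bit-exactly.
#'
#' @param model A `"survmix"` model.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "survmix"))
  obj <- list(format_version = CHECKPOINT_VERSION, model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' Refuses checkpoints written by a newer format version and turns corrupt
#' or truncated files into a clean error rather than a partial model.
#'
#' @param path Checkpoint file written by [save_checkpoint()].
#' @return The `"survmix"` model.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  obj <- tryCatch(suppressWarnings(readRDS(path)), error = function(e)
    stop(sprintf("corrupt or unreadable checkpoint: %s", conditionMessage(e)),
         call. = FALSE))
  if (!is.list(obj) || is.null(obj$format_version) ||
      !inherits(obj$model, "survmix"))
    stop("not a model checkpoint", call. = FALSE)
  if (obj$format_version > CHECKPOINT_VERSION)
    stop(sprintf(
      "checkpoint format version %d is newer than supported version %d",
      obj$format_version, CHECKPOINT_VERSION), call. = FALSE)
  obj$model
}
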