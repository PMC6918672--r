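# Lasso decoding under repeated stratified k-fold cross-validation.
# The penalty weight is tuned by inner cross-validation on the training
# folds only; held-out rows are never seen during standardization or tuning.

#' Cross-validation configuration
#'
#' @param n_folds Outer folds (default 4).
#' @param n_repetitions Repetitions of the full CV (default 100).
#' @param task `"binary"` or `"continuous"`.
#' @param lambda_rule `"inner_cv_min"` (penalty minimizing inner-CV deviance,
#'   default) or `"inner_cv_1se"` (largest penalty within one SE of the
#'   minimum).
#' @param inner_folds Inner folds for penalty tuning (default 3).
#' @param standardize Standardize features on the training data (default TRUE).
#' @param seed Integer seed; together with the repetition index it fully
#'   determines every fold assignment.
#' @return An object of class `lfp_cv_config`.
#' @export
cv_config <- function(n_folds = 4, n_repetitions = 100,
                      task = c("binary", "continuous"),
                      lambda_rule = c("inner_cv_min", "inner_cv_1se"),
                      inner_folds = 3, standardize = TRUE, seed = 1L) {
  task <- match.arg(task)
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(n_folds >= 2, n_repetitions >= 1, inner_folds >= 2)
  structure(
    list(n_folds = as.integer(n_folds),
         n_repetitions = as.integer(n_repetitions),
         task = task, lambda_rule = lambda_rule,
         inner_folds = as.integer(inner_folds),
         standardize = isTRUE(standardize), seed = as.integer(seed)),
    class = "lfp_cv_config"
  )
}

# Deterministic sub-seed derived from (seed, stream); kept within 32-bit range.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + as.double(stream) * 16807) %% 2147483629
}

#' Assign rows to cross-validation folds
#'
#' Partitions rows into near-equal folds; for binary tasks, folds are
#' stratified by label so class counts per fold differ by at most one.
#' Assignment is a pure function of `(seed, repetition)`. Rows from the same
#' rat may share folds: the cross-validation is sample-level, mirroring a
#' design that treats multiple recordings of one animal as separate samples
#' (the group-permutation null quantifies the consequence).
#'
#' @param n Number of rows.
#' @param labels Optional factor/vector of binary labels for stratification.
#' @param n_folds Number of folds.
#' @param seed Base seed.
#' @param repetition Repetition index (>= 1).
#' @return Integer vector of fold ids in `1..n_folds`.
#' @export
make_cv_folds <- function(n, labels = NULL, n_folds = 4, seed = 1L,
                          repetition = 1L) {
  if (n < n_folds)
    stop("need at least as many rows as folds", call. = FALSE)
  with_seed(derive_seed(seed, repetition), {
    fold <- integer(n)
    if (is.null(labels)) {
      fold <- rep_len(sample.int(n_folds), n)[sample.int(n)]
    } else {
      labels <- as.factor(labels)
      offset <- 0L
      for (lv in levels(labels)) {
        idx <- which(labels == lv)
        idx <- idx[sample.int(length(idx))]
        # rotate fold start per stratum so fold sizes stay balanced
        fold[idx] <- ((seq_along(idx) - 1L + offset) %% n_folds) + 1L
        offset <- offset + length(idx)
      }
    }
    fold
  })
}

#' Fit a cross-validated lasso model
#'
#' For each repetition, rows are split into `n_folds` outer folds (stratified
#' for binary tasks). Within each outer fold's training portion the penalty
#' weight is chosen by inner cross-validation; the refit model predicts the
#' held-out rows. The repetition's metric pools all held-out predictions:
#' percent correctly classified at probability 0.5 for binary tasks, mean
#' squared error (g/kg)^2 for continuous tasks. Metrics are aggregated over
#' repetitions into a mean, SEM, SD, and percentile 95% CI, alongside each
#' feature's mean coefficient and selection frequency across all fitted
#' models.
#'
#' @param x Numeric matrix of features (rows = sessions) or a feature-matrix
#'   data frame (the 60 canonical columns are used).
#' @param y Outcome: 2-level factor (or coercible) for binary tasks, numeric
#'   for continuous tasks.
#' @param config An [cv_config()].
#' @return An object of class `lfp_model_result`.
#' @export
fit_lasso_cv <- function(x, y, config = cv_config()) {
  stopifnot(inherits(config, "lfp_cv_config"))
  if (is.data.frame(x)) x <- feature_columns(x)
  if (anyNA(x)) stop("`x` contains missing values", call. = FALSE)
  n <- nrow(x)
  if (n < 2 * config$n_folds)
    stop("need at least 2 rows per fold (", 2 * config$n_folds,
         " total); got ", n, ". Reduce `n_folds` or add sessions.",
         call. = FALSE)
  binary <- config$task == "binary"
  if (binary) {
    y <- as.factor(y)
    if (nlevels(y) != 2L)
      stop("binary task requires exactly 2 classes; got ", nlevels(y),
           call. = FALSE)
    if (min(table(y)) < config$n_folds)
      stop("each class needs at least `n_folds` rows for stratified folds",
           call. = FALSE)
  } else {
    y <- as.numeric(y)
    if (stats::var(y) == 0)
      stop("constant outcome cannot be modeled", call. = FALSE)
  }
  family <- if (binary) "binomial" else "gaussian"
  p <- ncol(x)
  per_rep <- numeric(config$n_repetitions)
  coef_sum <- numeric(p)
  coef_nonzero <- numeric(p)
  n_models <- 0L
  for (rep_i in seq_len(config$n_repetitions)) {
    fold <- make_cv_folds(n, if (binary) y else NULL, config$n_folds,
                          config$seed, rep_i)
    pred <- numeric(n)
    for (k in seq_len(config$n_folds)) {
      tr <- fold != k
      inner_id <- make_cv_folds(sum(tr), if (binary) y[tr] else NULL,
                                config$inner_folds, config$seed,
                                rep_i * config$n_folds + k)
      cvfit <- glmnet::cv.glmnet(
        x[tr, , drop = FALSE],
        if (binary) y[tr] else y[tr],
        family = family, foldid = inner_id, nlambda = 50,
        standardize = config$standardize)
      s <- if (config$lambda_rule == "inner_cv_min") "lambda.min" else
        "lambda.1se"
      pred[!tr] <- as.numeric(
        stats::predict(cvfit, x[!tr, , drop = FALSE], s = s,
                       type = "response"))
      cf <- as.numeric(stats::coef(cvfit, s = s))[-1L]
      coef_sum <- coef_sum + cf
      coef_nonzero <- coef_nonzero + (cf != 0)
      n_models <- n_models + 1L
    }
    per_rep[rep_i] <- if (binary) {
      100 * mean((pred >= 0.5) == (y == levels(y)[2L]))
    } else {
      mean((pred - y)^2)
    }
  }
  metric_sd <- if (config$n_repetitions > 1) stats::sd(per_rep) else 0
  structure(
    list(task = config$task,
         per_rep_metric = per_rep,
         mean_metric = mean(per_rep),
         sd_metric = metric_sd,
         sem_metric = metric_sd / sqrt(config$n_repetitions),
         ci95 = unname(stats::quantile(per_rep, c(0.025, 0.975))),
         coefficient_summary = data.frame(
           feature = colnames(x) %||% paste0("x", seq_len(p)),
           mean_coefficient = coef_sum / n_models,
           selection_frequency = coef_nonzero / n_models,
           stringsAsFactors = FALSE),
         n_obs = n, config = config,
         classes = if (binary) levels(y) else NULL),
    class = "lfp_model_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize a cross-validated model
#'
#' @param result An `lfp_model_result` from [fit_lasso_cv()].
#' @return A list with `mean`, `sem`, `sd`, `ci95`, `n_repetitions`, `task`,
#'   and a preformatted `label` of the form `"mu = X +/- SEM"`.
#' @export
summarize_model <- function(result) {
  stopifnot(inherits(result, "lfp_model_result"))
  unit <- if (result$task == "binary") "%" else ""
  list(mean = result$mean_metric,
       sem = result$sem_metric,
       sd = result$sd_metric,
       ci95 = result$ci95,
       n_repetitions = length(result$per_rep_metric),
       task = result$task,
       label = sprintf("mu = %.2f +/- %.2g%s", result$mean_metric,
                       result$sem_metric, unit))
}

#' @export
print.lfp_model_result <- function(x, ...) {
  metric <- if (x$task == "binary") "accuracy (%)" else "MSE"
  cat(sprintf(
    "<lfp_model_result> %s lasso, %d reps x %d folds on %d rows\n  %s: %s [95%% CI %.3f, %.3f]\n",
    x$task, length(x$per_rep_metric), x$config$n_folds, x$n_obs, metric,
    summarize_model(x)$label, x$ci95[1], x$ci95[2]))
  invisible(x)
}
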