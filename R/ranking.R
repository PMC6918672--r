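# Exhaustive single-feature models: per-feature cross-validated AUC for
# binary outcomes and in-sample R^2 / slope for continuous outcomes.

#' Single-feature classification ranking
#'
#' For every feature, a one-predictor logistic regression is evaluated under
#' the same repeated stratified k-fold scheme as the lasso; the metric is the
#' mean area under the ROC curve across repetitions, computed on each
#' repetition's pooled held-out predicted probabilities. The direction
#' records which group has the higher raw feature mean (threshold-free, e.g.
#' "male > female"). Constant features get AUC 0.5 and a flag.
#'
#' @param x Feature matrix (matrix or feature data frame).
#' @param y Binary outcome (2 levels).
#' @param config An [cv_config()] (its task is ignored; classification is
#'   implied).
#' @return A data frame of class `lfp_ranking`, one row per feature, sorted
#'   by `mean_auc` descending (ties broken by canonical feature order), with
#'   columns `feature`, `mean_auc`, `direction`, `constant`.
#' @export
single_feature_classification <- function(x, y, config = cv_config()) {
  if (is.data.frame(x)) x <- feature_columns(x)
  y <- as.factor(y)
  if (nlevels(y) != 2L) stop("need exactly 2 classes", call. = FALSE)
  n <- nrow(x)
  lv <- levels(y)
  pos <- y == lv[2L]
  aucs <- numeric(ncol(x))
  direction <- character(ncol(x))
  constant <- logical(ncol(x))
  folds <- lapply(seq_len(config$n_repetitions), function(r)
    make_cv_folds(n, y, config$n_folds, config$seed, r))
  for (j in seq_len(ncol(x))) {
    f <- x[, j]
    m1 <- mean(f[y == lv[1L]])
    m2 <- mean(f[y == lv[2L]])
    if (stats::var(f) == 0) {
      aucs[j] <- 0.5
      direction[j] <- NA_character_
      constant[j] <- TRUE
      next
    }
    direction[j] <- if (m1 > m2) paste(lv[1L], ">", lv[2L]) else
      paste(lv[2L], ">", lv[1L])
    rep_auc <- numeric(config$n_repetitions)
    for (r in seq_len(config$n_repetitions)) {
      fold <- folds[[r]]
      pred <- numeric(n)
      for (k in seq_len(config$n_folds)) {
        tr <- fold != k
        fit <- suppressWarnings(
          stats::glm.fit(cbind(1, f[tr]), pos[tr],
                         family = stats::binomial()))
        eta <- cbind(1, f[!tr]) %*% fit$coefficients
        pred[!tr] <- 1 / (1 + exp(-eta))
      }
      rep_auc[r] <- as.numeric(pROC::auc(
        pROC::roc(response = as.integer(pos), predictor = pred,
                  quiet = TRUE, direction = "<", levels = c(0L, 1L))))
    }
    aucs[j] <- mean(rep_auc)
  }
  out <- data.frame(feature = colnames(x) %||% paste0("x", seq_len(ncol(x))),
                    mean_auc = aucs, direction = direction,
                    constant = constant, stringsAsFactors = FALSE)
  out <- out[order(-out$mean_auc, seq_len(nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("lfp_ranking", "data.frame")
  attr(out, "task") <- "binary"
  out
}

#' Single-feature regression ranking
#'
#' For every feature, an ordinary one-predictor linear fit of the continuous
#' outcome on all rows; the metric is the in-sample R^2 and the slope is the
#' fitted coefficient in outcome units per feature unit. Constant features
#' get R^2 = 0, slope 0, and a flag.
#'
#' @param x Feature matrix (matrix or feature data frame).
#' @param y Continuous outcome (variance > 0).
#' @return A data frame of class `lfp_ranking`, one row per feature, sorted
#'   by `r_squared` descending (ties broken by canonical feature order), with
#'   columns `feature`, `r_squared`, `slope`, `constant`.
#' @export
single_feature_regression <- function(x, y) {
  if (is.data.frame(x)) x <- feature_columns(x)
  y <- as.numeric(y)
  if (stats::var(y) == 0)
    stop("constant outcome cannot be ranked against", call. = FALSE)
  res <- vapply(seq_len(ncol(x)), function(j) {
    f <- x[, j]
    if (stats::var(f) == 0) return(c(0, 0, 1))
    fit <- stats::lm.fit(cbind(1, f), y)
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    c(r2, fit$coefficients[2L], 0)
  }, numeric(3))
  out <- data.frame(feature = colnames(x) %||% paste0("x", seq_len(ncol(x))),
                    r_squared = res[1, ], slope = res[2, ],
                    constant = res[3, ] > 0, stringsAsFactors = FALSE)
  out <- out[order(-out$r_squared, seq_len(nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("lfp_ranking", "data.frame")
  attr(out, "task") <- "continuous"
  out
}

#' Truncate a ranking table
#'
#' @param table An `lfp_ranking`.
#' @param k Number of top entries to keep (1 to nrow).
#' @return The first `k` rows of the sorted ranking.
#' @export
top_features <- function(table, k = 5) {
  stopifnot(inherits(table, "lfp_ranking"), k >= 1, k <= nrow(table))
  out <- table[seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  out
}
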