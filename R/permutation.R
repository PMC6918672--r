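# Null distributions for cross-validated model performance:
# - random permutation: outcomes shuffled across all rows (chance level);
# - group permutation: whole rats reassigned to balanced pseudo-groups,
#   keeping each rat's recordings together (information about arbitrary
#   animal groupings, quantifying the repeated-measures confound).

#' Permutation-testing configuration
#'
#' @param n_random_perms Number of random label permutations (default 100).
#' @param group_enumeration_cap Maximum number of group-permutation
#'   candidates; all candidates are enumerated when their count is at or
#'   below the cap, otherwise candidates are sampled uniformly without
#'   replacement (default 500).
#' @param null_repetitions CV repetitions used for each null model fit
#'   (default 10). Each null point is itself an average, so fewer repetitions
#'   than the real model's are required.
#' @param seed Integer seed for permutation draws and null fits.
#' @return An object of class `lfp_perm_config`.
#' @export
permutation_config <- function(n_random_perms = 100,
                               group_enumeration_cap = 500,
                               null_repetitions = 10, seed = 1L) {
  stopifnot(n_random_perms >= 1, group_enumeration_cap >= 1,
            null_repetitions >= 1)
  structure(
    list(n_random_perms = as.integer(n_random_perms),
         group_enumeration_cap = as.integer(group_enumeration_cap),
         null_repetitions = as.integer(null_repetitions),
         seed = as.integer(seed)),
    class = "lfp_perm_config"
  )
}

null_cv_config <- function(cv_config, perm_config, stream) {
  cv_config$n_repetitions <- perm_config$null_repetitions
  cv_config$seed <- as.integer(derive_seed(perm_config$seed, stream))
  cv_config
}

summarize_null <- function(metrics, kind, mode = "sampled") {
  n <- length(metrics)
  sdv <- if (n > 1) stats::sd(metrics) else 0
  structure(
    list(null_kind = kind, null_metrics = metrics,
         null_mean = mean(metrics), null_sd = sdv,
         null_sem = sdv / sqrt(n),
         null_ci95 = unname(stats::quantile(metrics, c(0.025, 0.975))),
         candidate_mode = mode,
         z_score = NA_real_, empirical_p = NA_real_, real_mean = NA_real_),
    class = "lfp_perm_null"
  )
}

#' Random-permutation null distribution
#'
#' For each permutation the outcome values are shuffled across all rows —
#' breaking every link between features, rats, and outcome — and the full
#' cross-validated lasso is refit. The resulting distribution of mean metrics
#' estimates chance performance.
#'
#' @param x Feature matrix (matrix or feature data frame).
#' @param y Outcome vector (binary or continuous, per `cv_config$task`).
#' @param cv_config An [cv_config()]; `null_repetitions` from `perm_config`
#'   overrides its repetition count for the null fits.
#' @param perm_config An [permutation_config()].
#' @return An `lfp_perm_null` holding the per-permutation metrics and their
#'   mean, SD, SEM and percentile 95% CI. Complete it with
#'   [compare_to_null()].
#' @export
random_permutation_null <- function(x, y, cv_config,
                                    perm_config = permutation_config()) {
  perms <- with_seed(perm_config$seed,
                     lapply(seq_len(perm_config$n_random_perms),
                            function(i) sample.int(length(y))))
  metrics <- vapply(seq_along(perms), function(i) {
    fit <- fit_lasso_cv(x, y[perms[[i]]],
                        null_cv_config(cv_config, perm_config, i))
    fit$mean_metric
  }, numeric(1))
  summarize_null(metrics, "random")
}

#' Enumerate balanced rat-level group assignments
#'
#' Candidate relabelings assign whole rats to labeled pseudo-groups of the
#' original group sizes, with the balance covariate (e.g. biological sex)
#' equally represented in each pseudo-group. The true assignment is excluded.
#' All candidates are enumerated when their count is at or below `cap`;
#' otherwise `cap` candidates are sampled uniformly without replacement.
#'
#' @param rat_ids Character vector of rat identifiers (one entry per rat).
#' @param groups True group of each rat (2 levels).
#' @param balance Balance covariate per rat (e.g. sex), or `NULL` to balance
#'   on nothing.
#' @param cap Maximum number of candidates returned.
#' @param seed Seed used when sampling is required.
#' @return List with `assignments` (list of factor vectors over rats, levels
#'   as in `groups`), `mode` (`"enumerated"` or `"sampled"`), and
#'   `n_possible` (count of labeled candidates including the truth).
#' @export
enumerate_group_assignments <- function(rat_ids, groups, balance = NULL,
                                        cap = 500, seed = 1L) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    stop("group permutation requires exactly 2 groups", call. = FALSE)
  n_rat <- length(rat_ids)
  if (anyDuplicated(rat_ids))
    stop("`rat_ids` must be one entry per rat", call. = FALSE)
  n1 <- sum(groups == levels(groups)[1L])
  if (is.null(balance)) balance <- rep("all", n_rat)
  balance <- as.factor(balance)
  strata <- split(seq_len(n_rat), balance)
  take <- vapply(strata, function(idx) {
    k <- length(idx) * n1 / n_rat
    if (abs(k - round(k)) > 1e-9)
      stop("balancing infeasible: stratum of ", length(idx),
           " rats cannot contribute equally to pseudo-groups of ", n1,
           " and ", n_rat - n1, " (", length(idx), " * ", n1, " / ", n_rat,
           " is not an integer)", call. = FALSE)
    as.integer(round(k))
  }, integer(1))
  n_possible <- prod(vapply(seq_along(strata), function(i)
    choose(length(strata[[i]]), take[i]), numeric(1)))
  true_in_1 <- which(groups == levels(groups)[1L])
  make_assign <- function(sel) {
    g <- factor(rep(levels(groups)[2L], n_rat), levels = levels(groups))
    g[sel] <- levels(groups)[1L]
    g
  }
  if (n_possible <= cap) {
    combos_per_stratum <- lapply(seq_along(strata), function(i) {
      m <- utils::combn(strata[[i]], take[i], simplify = FALSE)
      m
    })
    grid <- combos_per_stratum[[1L]]
    if (length(combos_per_stratum) > 1L) {
      for (i in 2L:length(combos_per_stratum)) {
        grid <- unlist(lapply(grid, function(a)
          lapply(combos_per_stratum[[i]], function(b) c(a, b))),
          recursive = FALSE)
      }
    }
    assignments <- lapply(grid, make_assign)
    keep <- !vapply(grid, function(sel)
      setequal(sel, true_in_1), logical(1))
    list(assignments = assignments[keep], mode = "enumerated",
         n_possible = n_possible)
  } else {
    sels <- with_seed(seed, {
      seen <- list(sort(true_in_1))
      out <- list()
      while (length(out) < cap) {
        sel <- sort(unlist(lapply(seq_along(strata), function(i)
          sample(strata[[i]], take[i]))))
        key <- paste(sel, collapse = ",")
        if (!key %in% vapply(seen, paste, character(1), collapse = ",")) {
          seen[[length(seen) + 1L]] <- sel
          out[[length(out) + 1L]] <- sel
        }
      }
      out
    })
    list(assignments = lapply(sels, make_assign), mode = "sampled",
         n_possible = n_possible)
  }
}

#' Group-permutation null distribution
#'
#' Each candidate relabeling (see [enumerate_group_assignments()]) reassigns
#' whole rats — with all their recordings — to balanced pseudo-groups, and
#' the full cross-validated lasso is refit on the pseudo-labels. Because real
#' between-rat differences survive this shuffling, the distribution measures
#' how much information the features carry about arbitrary (balanced) animal
#' groupings, not about the outcome itself.
#'
#' @param x Feature matrix (matrix or feature data frame).
#' @param y Binary outcome per row (each rat's rows must share one label).
#' @param rat_ids Rat identifier per row.
#' @param balance Balance covariate per row (e.g. sex), or `NULL`.
#' @param cv_config An [cv_config()] with `task = "binary"`.
#' @param perm_config An [permutation_config()].
#' @return An `lfp_perm_null`; complete it with [compare_to_null()].
#' @export
group_permutation_null <- function(x, y, rat_ids, balance = NULL,
                                   cv_config = cv_config(task = "binary"),
                                   perm_config = permutation_config()) {
  if (cv_config$task != "binary")
    stop("group permutation is defined for binary tasks", call. = FALSE)
  y <- as.factor(y)
  rat_ids <- as.character(rat_ids)
  per_rat <- tapply(as.character(y), rat_ids, unique)
  if (any(lengths(per_rat) != 1L))
    stop("each rat's recordings must share one true group", call. = FALSE)
  rats <- names(per_rat)
  rat_group <- factor(unlist(per_rat), levels = levels(y))
  rat_balance <- NULL
  if (!is.null(balance)) {
    pb <- tapply(as.character(balance), rat_ids, unique)
    if (any(lengths(pb) != 1L))
      stop("balance covariate must be constant within rat", call. = FALSE)
    rat_balance <- unlist(pb)[rats]
  }
  cand <- enumerate_group_assignments(rats, rat_group, rat_balance,
                                      perm_config$group_enumeration_cap,
                                      perm_config$seed)
  metrics <- vapply(seq_along(cand$assignments), function(i) {
    g <- cand$assignments[[i]]
    y_perm <- g[match(rat_ids, rats)]
    fit <- fit_lasso_cv(x, y_perm, null_cv_config(cv_config, perm_config, i))
    fit$mean_metric
  }, numeric(1))
  out <- summarize_null(metrics, "group", cand$mode)
  out$n_possible <- cand$n_possible
  out
}

#' Compare a real model to a null distribution
#'
#' Completes a permutation comparison with a z-score and an empirical
#' p-value. The z-score is signed so that better-than-null is positive:
#' `z = (real - null_mean) / null_sd` when higher metrics are better
#' (accuracy) and `z = (null_mean - real) / null_sd` when lower is better
#' (error). The empirical p follows the add-one rule
#' `p = (1 + #\{null at least as good as real\}) / (1 + n_perms)`.
#'
#' @param real An `lfp_model_result` from [fit_lasso_cv()].
#' @param null An `lfp_perm_null`.
#' @param better `"higher"` (accuracy) or `"lower"` (error). Defaults to
#'   `"higher"` for binary tasks and `"lower"` for continuous tasks.
#' @return The `lfp_perm_null` completed with `real_mean`, `z_score` and
#'   `empirical_p` (class `lfp_perm_comparison`).
#' @export
compare_to_null <- function(real, null, better = NULL) {
  stopifnot(inherits(real, "lfp_model_result"),
            inherits(null, "lfp_perm_null"))
  if (is.null(better))
    better <- if (real$task == "binary") "higher" else "lower"
  better <- match.arg(better, c("higher", "lower"))
  rm_ <- real$mean_metric
  nm <- null$null_metrics
  null$real_mean <- rm_
  null$better <- better
  if (null$null_sd > 0) {
    null$z_score <- if (better == "higher")
      (rm_ - null$null_mean) / null$null_sd
    else
      (null$null_mean - rm_) / null$null_sd
  } else {
    null$z_score <- NA_real_
  }
  as_good <- if (better == "higher") sum(nm >= rm_) else sum(nm <= rm_)
  null$empirical_p <- (1 + as_good) / (1 + length(nm))
  class(null) <- c("lfp_perm_comparison", class(null))
  null
}

#' @export
print.lfp_perm_null <- function(x, ...) {
  mode <- if (x$null_kind == "group")
    paste0(" (", x$candidate_mode, ")") else ""
  cat(sprintf(
    "<%s permutation null> %d permutations%s: mean %.3f, SD %.3f [95%% CI %.3f, %.3f]\n",
    x$null_kind, length(x$null_metrics), mode,
    x$null_mean, x$null_sd, x$null_ci95[1], x$null_ci95[2]))
  if (!is.na(x$empirical_p))
    cat(sprintf("  real mean %.3f, z = %.2f, empirical p = %.4f\n",
                x$real_mean, x$z_score, x$empirical_p))
  invisible(x)
}
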