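fake_result <- function(mean_metric, task = "binary") {
  structure(list(task = task, mean_metric = mean_metric,
                 per_rep_metric = mean_metric),
            class = "lfp_model_result")
}

fake_null <- function(metrics) {
  structure(list(null_kind = "random", null_metrics = metrics,
                 null_mean = mean(metrics), null_sd = sd(metrics),
                 null_sem = sd(metrics) / sqrt(length(metrics)),
                 null_ci95 = unname(quantile(metrics, c(0.025, 0.975))),
                 candidate_mode = "sampled",
                 z_score = NA_real_, empirical_p = NA_real_,
                 real_mean = NA_real_),
            class = "lfp_perm_null")
}

test_that("z-score and empirical p follow the stated formulas", {
  set.seed(1)
  nulls <- rnorm(100, 50, 5)
  nulls <- 50 + 5 * (nulls - mean(nulls)) / sd(nulls)  # exact mean/sd
  cmp <- compare_to_null(fake_result(60), fake_null(nulls), "higher")
  expect_equal(cmp$z_score, 2)
  # centering: real equal to null mean gives z = 0
  cmp0 <- compare_to_null(fake_result(50), fake_null(nulls), "higher")
  expect_equal(cmp0$z_score, 0)
  # real better than every null: add-one rule
  cmp_best <- compare_to_null(fake_result(max(nulls) + 1), fake_null(nulls),
                              "higher")
  expect_equal(cmp_best$empirical_p, 1 / 101)
  # for errors, lower is better and the sign convention flips
  cmp_err <- compare_to_null(fake_result(40, "continuous"), fake_null(nulls),
                             "lower")
  expect_equal(cmp_err$z_score, 2)
  cmp_err_best <- compare_to_null(fake_result(min(nulls) - 1, "continuous"),
                                  fake_null(nulls), "lower")
  expect_equal(cmp_err_best$empirical_p, 1 / 101)
})

test_that("random-permutation null estimates chance for balanced labels", {
  set.seed(2)
  n <- 16
  x <- matrix(rnorm(n * 20), n, 20)
  y <- rep(c("a", "b"), each = 8)
  cvc <- cv_config(n_repetitions = 3, task = "binary", seed = 3)
  pc <- permutation_config(n_random_perms = 30, null_repetitions = 3,
                           seed = 5)
  null <- null_quiet(x, y, cvc, pc)
  expect_length(null$null_metrics, 30)
  expect_gt(null$null_mean, 40)
  expect_lt(null$null_mean, 60)
  # fully reproducible from the seeds
  null2 <- null_quiet(x, y, cvc, pc)
  expect_identical(null$null_metrics, null2$null_metrics)
})

test_that("balanced rat-level assignments are enumerated exactly", {
  rats <- sprintf("r%d", 1:8)
  groups <- rep(c("g1", "g2"), each = 4)
  sex <- rep(c("m", "f"), 4)
  enum <- enumerate_group_assignments(rats, groups, sex, cap = 500)
  # C(4,2) * C(4,2) = 36 labeled assignments, 35 after dropping the truth
  expect_identical(enum$n_possible, 36)
  expect_identical(enum$mode, "enumerated")
  expect_length(enum$assignments, 35)
  for (g in enum$assignments) {
    expect_identical(as.vector(table(g)), c(4L, 4L))
    # the balance covariate is equally represented in each pseudo-group
    expect_true(all(table(g, sex) == 2))
  }
  # no candidate equals the true assignment
  expect_false(any(vapply(enum$assignments, identical,
                          logical(1), factor(groups))))
})

test_that("enumeration falls back to uniform sampling above the cap", {
  rats <- sprintf("r%d", 1:12)
  groups <- rep(c("g1", "g2"), each = 6)
  sex <- rep(c("m", "f"), 6)
  enum <- enumerate_group_assignments(rats, groups, sex, cap = 50, seed = 2)
  expect_identical(enum$mode, "sampled")
  expect_identical(enum$n_possible, choose(6, 3)^2)
  expect_length(enum$assignments, 50)
  keys <- vapply(enum$assignments, paste, character(1), collapse = "")
  expect_false(anyDuplicated(keys) > 0)
  expect_false(any(vapply(enum$assignments, identical,
                          logical(1), factor(groups))))
})

test_that("infeasible balancing is rejected with the arithmetic explained", {
  rats <- sprintf("r%d", 1:8)
  groups <- rep(c("g1", "g2"), each = 4)
  sex <- c(rep("m", 3), rep("f", 5))
  expect_error(enumerate_group_assignments(rats, groups, sex),
               "infeasible")
})

test_that("group permutations keep each rat's recordings together", {
  set.seed(6)
  n_rat <- 8
  rat_ids <- rep(sprintf("r%d", 1:n_rat), each = 2)
  y <- rep(rep(c("a", "b"), each = 4), each = 2)
  sex <- rep(rep(c("m", "f"), 4), each = 2)
  x <- matrix(rnorm(16 * 10), 16, 10)
  cvc <- cv_config(n_repetitions = 2, task = "binary", seed = 1)
  pc <- permutation_config(group_enumeration_cap = 8, null_repetitions = 2,
                           seed = 9)
  null <- gnull_quiet(x, y, rat_ids, sex, cvc, pc)
  expect_identical(null$null_kind, "group")
  expect_length(null$null_metrics, 8)
  expect_error(
    gnull_quiet(x, rep(c("a", "b"), 8), rat_ids, sex, cvc, pc),
    "share one true group")
})
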