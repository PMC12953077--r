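test_that("exact signed-rank statistics match hand enumeration", {
  # all five folds improve: W = 15, p = 1/32
  r <- wilcoxon_one_sided(c(1, 2, 3, 4, 5), rep(0, 5))
  expect_equal(r$W, 15)
  expect_equal(r$p_value, 1 / 32)
  expect_true(r$significant)

  # mixed signs: W = 9, p = 13/32
  r2 <- wilcoxon_one_sided(c(1, -2, 3, -4, 5), rep(0, 5))
  expect_equal(r2$W, 9)
  expect_equal(r2$p_value, 13 / 32)
  expect_false(r2$significant)

  # identical arms degenerate to p = 1
  r3 <- wilcoxon_one_sided(c(0.7, 0.8), c(0.7, 0.8))
  expect_true(r3$degenerate)
  expect_equal(r3$p_value, 1)

  # direction = "less": improvement means smaller values
  r4 <- wilcoxon_one_sided(c(1, 1, 1, 1, 1), c(2, 2, 2, 2, 2),
                           direction = "less")
  expect_equal(r4$W, 15)
  expect_equal(r4$p_value, 1 / 32)
})

test_that("exact p-values match full 2^n sign enumeration with ties", {
  set.seed(7)
  for (rep in 1:12) {
    n <- sample(3:10, 1)
    d <- round(stats::rnorm(n), 1)  # rounding induces ties
    d <- d[d != 0]
    if (length(d) < 2) next
    mine <- wilcoxon_one_sided(d, rep(0, length(d)))
    oracle <- oracle_wilcoxon(d)
    expect_equal(mine$W, oracle$W, info = paste("rep", rep))
    expect_equal(mine$p_value, oracle$p, tolerance = 1e-12,
                 info = paste("rep", rep))
  }
})

test_that("large-n normal approximation tracks the exact tail", {
  set.seed(8)
  d <- stats::rnorm(20) + 0.5
  approx_p <- wilcoxon_one_sided(d, rep(0, 20))$p_value
  exact_p <- suppressWarnings(
    stats::wilcox.test(d, alternative = "greater",
                       exact = TRUE)$p.value)
  expect_equal(approx_p, exact_p, tolerance = 0.02)
})

test_that("type-I error stays near nominal under a simulated null", {
  set.seed(11)
  hits <- 0
  n_rep <- 1000
  for (i in seq_len(n_rep)) {
    x <- stats::rnorm(5, 0.7, 0.05)
    y <- stats::rnorm(5, 0.7, 0.05)
    if (wilcoxon_one_sided(x, y)$significant) hits <- hits + 1
  }
  expect_lte(hits / n_rep, 0.07)
})

fake_ablation <- function(metrics_by_run) {
  rows <- purrr::imap(metrics_by_run, function(runs, task) {
    kind <- if (task == "LCDP") "regression" else "classification"
    purrr::imap(runs, function(v, fs) {
      met <- if (kind == "classification")
        tibble::tibble(fold = 1:5, BACC = v)
      else tibble::tibble(fold = 1:5, MAE = v)
      tibble::tibble(task = task, feature_set = fs, kind = kind,
                     metric_name = if (kind == "classification") "BACC"
                     else "MAE",
                     ensemble_metric_mean = mean(v),
                     ensemble_metric_sd = stats::sd(v),
                     holdout_metric = mean(v),
                     ensemble = list(list(fold_metrics = met)))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  class(rows) <- c("admira_ablation", class(rows))
  rows
}

test_that("the a-priori plan yields two comparisons per task", {
  base <- c(0.7, 0.72, 0.68, 0.71, 0.69)
  runs <- list("MO" = base, "MO+MS" = base + 0.01,
               "MO+MS+GT" = base - 0.01)
  abl <- fake_ablation(list("CN-ADD" = runs, "CN-MCI" = runs,
                            "MCI-ADD" = runs, "LCDP" = runs))
  cmp <- compare_feature_sets(abl)
  expect_equal(nrow(cmp), 8)
  expect_setequal(unique(cmp$comparison),
                  c("MO vs. MO+MS", "MO+MS vs. MO+MS+GT"))
  expect_equal(cmp$metric[cmp$task == "LCDP"], rep("MAE", 2))

  # identical arms everywhere -> all degenerate
  same <- list("MO" = base, "MO+MS" = base, "MO+MS+GT" = base)
  cmp2 <- compare_feature_sets(fake_ablation(list("CN-ADD" = same)))
  expect_true(all(cmp2$degenerate))

  # a uniform 0.1 improvement on every fold is significant at n = 5
  dom <- list("MO" = base, "MO+MS" = base + 0.1,
              "MO+MS+GT" = base + 0.1)
  cmp3 <- compare_feature_sets(fake_ablation(list("CN-ADD" = dom)))
  row <- cmp3[cmp3$comparison == "MO vs. MO+MS", ]
  expect_equal(row$p_value, 0.03125)
  expect_true(row$significant)

  # LCDP: lower MAE on every fold is an improvement
  dom_r <- list("MO" = base + 0.1, "MO+MS" = base,
                "MO+MS+GT" = base)
  cmp4 <- compare_feature_sets(fake_ablation(list("LCDP" = dom_r)))
  expect_true(cmp4$significant[cmp4$comparison == "MO vs. MO+MS"])

  expect_error(compare_feature_sets(
    fake_ablation(list("CN-ADD" = list("MO" = base)))), "missing")
})

test_that("bootstrap CIs are percentile, seeded, and degenerate-safe", {
  oof <- tibble::tibble(truth = rep(c(0, 1), each = 25),
                        pred = rep(c(0.1, 0.9), each = 25))
  acc <- function(y, p) mean((p >= 0.5) == y)
  ci <- bootstrap_ci(oof, acc, B = 1000, seed = 3, classification = TRUE)
  expect_equal(ci$B, 1000)
  expect_equal(ci$estimate, 1)
  expect_equal(ci$lower, 1)
  expect_equal(ci$upper, 1)

  ci2 <- bootstrap_ci(oof, acc, B = 50, seed = 4, classification = TRUE)
  ci3 <- bootstrap_ci(oof, acc, B = 50, seed = 4, classification = TRUE)
  expect_identical(ci2$replicates, ci3$replicates)
  expect_true(ci2$lower <= ci2$estimate && ci2$estimate <= ci2$upper)
})

test_that("bootstrap CI width shrinks with sample size", {
  make_oof <- function(n, seed) {
    set.seed(seed)
    tibble::tibble(truth = stats::rnorm(n), pred = 0)
  }
  mfn <- function(y, p) mean(y)
  w_small <- with(bootstrap_ci(make_oof(30, 1), mfn, B = 400, seed = 5),
                  upper - lower)
  w_big <- with(bootstrap_ci(make_oof(500, 1), mfn, B = 400, seed = 5),
                upper - lower)
  expect_lt(w_big, w_small)
})

test_that("bootstrap coverage of a known mean is near nominal", {
  covered <- 0
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    set.seed(1000 + i)
    oof <- tibble::tibble(truth = stats::rnorm(40), pred = 0)
    ci <- bootstrap_ci(oof, function(y, p) mean(y), B = 200,
                       seed = 2000 + i)
    if (ci$lower <= 0 && 0 <= ci$upper) covered <- covered + 1
  }
  expect_gt(covered / n_rep, 0.85)
  expect_lte(covered / n_rep, 1)
})

test_that("ROC curves and bands behave at the extremes", {
  oof_perf <- tibble::tibble(truth = rep(c(0, 1), each = 20),
                             pred = c(stats::runif(20, 0, 0.4),
                                      stats::runif(20, 0.6, 1)))
  roc <- roc_with_bands(oof_perf, B = 100, seed = 2)
  expect_equal(roc$auc, 1)
  expect_true(any(roc$curve$fpr == 0 & roc$curve$tpr == 1))

  # the band contains the point curve at the grid
  curve_at <- stats::approx(roc$curve$fpr, roc$curve$tpr,
                            xout = roc$band$fpr, method = "constant",
                            ties = max, rule = 2)$y
  expect_true(all(curve_at >= roc$band$lo - 1e-9))
  expect_true(all(curve_at <= roc$band$hi + 1e-9))

  set.seed(3)
  oof_rand <- tibble::tibble(truth = rbinom(100, 1, 0.5),
                             pred = stats::runif(100))
  roc_r <- roc_with_bands(oof_rand, B = 100, seed = 3)
  expect_lt(abs(roc_r$auc - 0.5), 1.96 * sqrt(1 / 12) *
              sqrt(1 / 50 + 1 / 50))
  expect_error(roc_with_bands(tibble::tibble(truth = c(1, 1),
                                             pred = c(0.5, 0.6))),
               "both classes")
})

test_that("permutation importance isolates the predictive feature", {
  set.seed(9)
  n <- 150
  x <- cbind(signal = stats::rnorm(n), junk = stats::rnorm(n))
  y <- as.integer(x[, "signal"] > 0)
  predict_fn <- function(m) as.integer(m[, "signal"] > 0)
  metric_fn <- function(y, p) mean(y == p)
  imp <- permutation_importance(predict_fn, x, y, metric_fn,
                                repeats = 5, seed = 4)
  expect_equal(imp$feature[1], "signal")
  expect_lt(abs(imp$importance[imp$feature == "junk"]), 0.05)

  imp2 <- permutation_importance(predict_fn, x, y, metric_fn,
                                 repeats = 5, seed = 4)
  expect_identical(imp, imp2)
  expect_error(permutation_importance(predict_fn, x, y, metric_fn,
                                      repeats = 0), "repeats")
})

test_that("report bundles are complete and byte-stable", {
  base <- c(0.7, 0.75, 0.65, 0.72, 0.68)
  runs <- list("MO" = base, "MO+MS" = base + 0.02,
               "MO+MS+GT" = base + 0.01)
  abl <- fake_ablation(list("CN-ADD" = runs, "LCDP" = runs))
  # attach minimal OOF/importance payloads expected by the renderer
  for (i in seq_len(nrow(abl))) {
    set.seed(i)
    abl$ensemble[[i]]$importance <- tibble::tibble(
      feature = paste0("f", 1:30), importance = rep(1 / 30, 30),
      rank = 1:30)
    abl$ensemble[[i]]$oof <- tibble::tibble(
      truth = rep(c(0, 1), each = 20),
      pred = stats::runif(40))
  }
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  render_report(abl, compare_feature_sets(abl), d1)
  render_report(abl, compare_feature_sets(abl), d2)
  files <- sort(list.files(d1))
  expect_true("best_per_task.csv" %in% files)
  expect_true("comparisons.csv" %in% files)
  expect_true(any(grepl("^importance_top20_", files)))
  expect_true(any(grepl("^roc_", files)))
  expect_identical(files, sort(list.files(d2)))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  best <- readr::read_csv(file.path(d1, "best_per_task.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(best), 2)  # one row per task
  cmp <- readr::read_csv(file.path(d1, "comparisons.csv"),
                         show_col_types = FALSE)
  expect_true(all(c("W", "p_value") %in% names(cmp)))
  expect_error(render_report(abl[0, ], NULL, d1), "empty")
})
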