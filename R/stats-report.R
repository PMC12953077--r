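#' Paired one-sided Wilcoxon signed-rank test across folds
#'
#' Differences are oriented toward improvement before testing: with
#' `direction = "greater"` the alternative is that `x` exceeds `y`
#' (higher-is-better metrics such as balanced accuracy); with
#' `direction = "less"` the differences are negated first
#' (lower-is-better metrics such as MAE). Zero differences are dropped and
#' tied absolute differences receive average ranks. The statistic is the
#' sum of ranks of positive oriented differences; the one-sided p-value is
#' exact — computed from the full distribution over all 2^n sign
#' assignments — for n <= 12 usable differences, with a
#' continuity-corrected normal approximation (tie-adjusted variance)
#' above. With 5 folds the smallest attainable exact p is 1/32 = 0.03125.
#'
#' @param x,y equal-length fold-wise metric vectors
#' @param direction `"greater"` (x better when larger) or `"less"`
#' @param alpha significance level recorded on the result
#' @return object of class `admira_comparison`: `W`, `p_value`, `n_used`,
#'   `degenerate`, `significant`
#' @export
wilcoxon_one_sided <- function(x, y, direction = c("greater", "less"),
                               alpha = 0.05) {
  direction <- match.arg(direction)
  stopifnot(length(x) == length(y))
  d <- x - y
  if (direction == "less") d <- -d
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(structure(list(W = 0, p_value = 1, n_used = 0L,
                          degenerate = TRUE, significant = FALSE,
                          direction = direction, alpha = alpha),
                     class = "admira_comparison"))
  }
  r <- rank(abs(d))
  w_stat <- sum(r[d > 0])
  if (n <= 12) {
    # exact: distribution of the positive-rank sum over all 2^n sign
    # assignments, via the rank generating function (ranks doubled to
    # keep tied half-ranks on an integer lattice)
    r2 <- as.integer(round(2 * r))
    dp <- c(1, rep(0, sum(r2)))
    for (ri in r2) {
      shifted <- c(rep(0, ri), dp[seq_len(length(dp) - ri)])
      dp <- dp + shifted
    }
    w2 <- as.integer(round(2 * w_stat))
    p <- sum(dp[(w2 + 1):length(dp)]) / 2^n
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    p <- stats::pnorm((w_stat - 0.5 - mu) / sqrt(sigma2),
                      lower.tail = FALSE)
  }
  structure(list(W = w_stat, p_value = p, n_used = n, degenerate = FALSE,
                 significant = p < alpha, direction = direction,
                 alpha = alpha),
            class = "admira_comparison")
}

#' @export
tidy.admira_comparison <- function(x, ...) {
  tibble::tibble(W = x$W, p_value = x$p_value, n_used = x$n_used,
                 degenerate = x$degenerate, significant = x$significant)
}

#' A-priori feature-set comparisons on fold-wise ensemble metrics
#'
#' Evaluates the planned incremental comparisons per task — does adding MS
#' to MO help (MO vs. MO+MS), and does adding GT to MO+MS help (MO+MS vs.
#' MO+MS+GT)? Classification arms are compared on balanced accuracy
#' (higher better), the regression task on MAE (lower better); the second
#' arm of each pair is tested as the improvement.
#'
#' @param ablation an `admira_ablation` result (needs the `ensemble`
#'   list-column with fold metrics)
#' @param plan list of comparisons as character pairs; default the two
#'   incremental pairs
#' @param alpha significance level
#' @return tibble: task, comparison, W, p_value, significant
#' @export
compare_feature_sets <- function(ablation,
                                 plan = list(c("MO", "MO+MS"),
                                             c("MO+MS", "MO+MS+GT")),
                                 alpha = 0.05) {
  rows <- list()
  for (task_id in unique(ablation$task)) {
    sub <- ablation[ablation$task == task_id, ]
    kind <- sub$kind[1]
    metric <- if (kind == "classification") "BACC" else "MAE"
    direction <- if (kind == "classification") "greater" else "less"
    for (pair in plan) {
      a <- sub[sub$feature_set == pair[1], ]
      b <- sub[sub$feature_set == pair[2], ]
      if (nrow(a) == 0 || nrow(b) == 0)
        stop("missing comparison arm for task ", task_id, ": ",
             paste(pair, collapse = " vs. "), call. = FALSE)
      xa <- a$ensemble[[1]]$fold_metrics[[metric]]
      xb <- b$ensemble[[1]]$fold_metrics[[metric]]
      # tests whether the richer set (second arm) improves on the first
      cmp <- wilcoxon_one_sided(xb, xa, direction = direction,
                                alpha = alpha)
      rows[[length(rows) + 1]] <- tibble::tibble(
        task = task_id, comparison = paste(pair[1], "vs.", pair[2]),
        metric = metric, W = cmp$W, p_value = cmp$p_value,
        degenerate = cmp$degenerate, significant = cmp$significant)
    }
  }
  dplyr::bind_rows(rows)
}

#' Bootstrap confidence interval on an out-of-fold metric
#'
#' Percentile 95% interval over subject-level resamples with replacement
#' of the pooled OOF predictions. Classification resamples that lose a
#' class are redrawn (up to 100 retries each).
#'
#' @param oof tibble with `truth` and `pred` columns
#' @param metric_fn function `(truth, pred) -> scalar`
#' @param B bootstrap iterations
#' @param seed integer seed
#' @param level confidence level
#' @param classification require both classes in each resample
#' @return object of class `admira_bootstrap`: `estimate`, `lower`,
#'   `upper`, `B`
#' @export
bootstrap_ci <- function(oof, metric_fn, B = 1000, seed = 1L,
                         level = 0.95, classification = FALSE) {
  if (nrow(oof) < 2) stop("need >= 2 subjects", call. = FALSE)
  estimate <- metric_fn(oof$truth, oof$pred)
  stats_boot <- .with_substream(seed, 600000L, {
    vapply(seq_len(B), function(b) {
      for (tries in seq_len(100)) {
        idx <- sample.int(nrow(oof), replace = TRUE)
        if (!classification || length(unique(oof$truth[idx])) > 1)
          return(metric_fn(oof$truth[idx], oof$pred[idx]))
      }
      NA_real_
    }, numeric(1))
  })
  if (all(is.na(stats_boot)))
    stop("metric undefined on all bootstrap resamples", call. = FALSE)
  q <- stats::quantile(stats_boot, c((1 - level) / 2, (1 + level) / 2),
                       na.rm = TRUE, names = FALSE)
  structure(list(estimate = estimate, lower = q[1], upper = q[2], B = B,
                 level = level, replicates = stats_boot),
            class = "admira_bootstrap")
}

#' @export
tidy.admira_bootstrap <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, lower = x$lower, upper = x$upper,
                 B = x$B, level = x$level)
}

#' ROC curve with bootstrap confidence band
#'
#' Computes the ROC curve at all prediction thresholds plus a pointwise
#' percentile band over subject-level bootstrap resamples, interpolated on
#' a fixed false-positive-rate grid.
#'
#' @param oof tibble with 0/1 `truth` and `pred` columns
#' @param B bootstrap iterations
#' @param seed integer seed
#' @param fpr_grid grid on which the band is interpolated
#' @return object of class `admira_roc`: `curve` (fpr, tpr), `band`
#'   (fpr, lo, hi), `auc`
#' @export
roc_with_bands <- function(oof, B = 1000, seed = 1L,
                           fpr_grid = seq(0, 1, by = 0.02)) {
  if (length(unique(oof$truth)) < 2)
    stop("both classes must be present", call. = FALSE)
  curve <- .roc_points(oof$truth, oof$pred)
  bands <- .with_substream(seed, 700000L, {
    vapply(seq_len(B), function(b) {
      repeat {
        idx <- sample.int(nrow(oof), replace = TRUE)
        if (length(unique(oof$truth[idx])) > 1) break
      }
      pts <- .roc_points(oof$truth[idx], oof$pred[idx])
      stats::approx(pts$fpr, pts$tpr, xout = fpr_grid, method = "constant",
                    ties = max, rule = 2)$y
    }, numeric(length(fpr_grid)))
  })
  lo <- apply(bands, 1, stats::quantile, probs = 0.025)
  hi <- apply(bands, 1, stats::quantile, probs = 0.975)
  structure(list(curve = curve,
                 band = tibble::tibble(fpr = fpr_grid, lo = lo, hi = hi),
                 auc = auc_rank(oof$truth, oof$pred)),
            class = "admira_roc")
}

.roc_points <- function(truth, pred) {
  thresholds <- c(Inf, sort(unique(pred), decreasing = TRUE))
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  pts <- vapply(thresholds, function(t) {
    c(fpr = sum(pred >= t & truth == 0) / n0,
      tpr = sum(pred >= t & truth == 1) / n1)
  }, numeric(2))
  tibble::tibble(fpr = pts["fpr", ], tpr = pts["tpr", ])
}

#' Permutation feature importance
#'
#' Model-agnostic importance: the mean drop in a metric when a feature
#' column is shuffled, over a configured number of repeats. Ranked
#' descending; deterministic per seed.
#'
#' @param predict_fn function `(x) -> predictions` for the fitted model
#' @param x feature matrix (named columns)
#' @param y targets
#' @param metric_fn function `(y, pred) -> scalar`, higher better
#' @param repeats shuffles per feature (>= 1)
#' @param seed integer seed
#' @return tibble `feature`, `importance`, `rank`
#' @export
permutation_importance <- function(predict_fn, x, y, metric_fn,
                                   repeats = 5, seed = 1L) {
  if (repeats < 1) stop("repeats must be >= 1", call. = FALSE)
  baseline <- metric_fn(y, predict_fn(x))
  drops <- .with_substream(seed, 800000L, {
    vapply(colnames(x), function(f) {
      mean(vapply(seq_len(repeats), function(r) {
        xp <- x
        xp[, f] <- sample(xp[, f])
        baseline - metric_fn(y, predict_fn(xp))
      }, numeric(1)))
    }, numeric(1))
  })
  tibble::tibble(feature = colnames(x), importance = unname(drops)) |>
    dplyr::arrange(dplyr::desc(.data$importance)) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Render the report bundle
#'
#' Writes the study-shaped outputs of a completed ablation to a
#' directory: the best-per-task summary (mean +/- sd over outer folds),
#' the a-priori comparison table (W, p), top-20 propagated importance
#' tables per run, and ROC curve data for classification runs. Reruns
#' with the same inputs are byte-identical. The exact five-fold Wilcoxon
#' test cannot reach p below 1/32; the comparison table footer records
#' this floor.
#'
#' @param ablation an `admira_ablation` result
#' @param comparisons tibble from [compare_feature_sets()]
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
render_report <- function(ablation, comparisons, dir) {
  if (nrow(ablation) == 0) stop("empty results", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  best <- ablation |>
    dplyr::group_by(.data$task) |>
    dplyr::slice(if (.data$kind[1] == "classification")
      which.max(.data$ensemble_metric_mean)
      else which.min(.data$ensemble_metric_mean)) |>
    dplyr::ungroup() |>
    dplyr::select("task", "feature_set", "metric_name",
                  "ensemble_metric_mean", "ensemble_metric_sd",
                  "holdout_metric")
  paths <- character(0)
  p <- file.path(dir, "best_per_task.csv")
  readr::write_csv(best, p)
  paths <- c(paths, p)
  p <- file.path(dir, "comparisons.csv")
  readr::write_csv(comparisons, p)
  paths <- c(paths, p)
  writeLines(c("# Note: with 5 outer folds the exact one-sided Wilcoxon",
               "# test cannot attain p < 1/32 = 0.03125."),
             file.path(dir, "comparisons_footer.txt"))
  paths <- c(paths, file.path(dir, "comparisons_footer.txt"))
  for (i in seq_len(nrow(ablation))) {
    ens <- ablation$ensemble[[i]]
    tag <- paste0(ablation$task[i], "_",
                  gsub("\\+", "-", ablation$feature_set[i]))
    p <- file.path(dir, paste0("importance_top20_", tag, ".csv"))
    readr::write_csv(utils::head(ens$importance, 20), p)
    paths <- c(paths, p)
    if (ablation$kind[i] == "classification") {
      roc <- roc_with_bands(ens$oof, B = 200, seed = 1L)
      p <- file.path(dir, paste0("roc_", tag, ".csv"))
      readr::write_csv(
        dplyr::left_join(roc$band,
                         tibble::tibble(fpr = roc$curve$fpr,
                                        tpr = roc$curve$tpr) |>
                           dplyr::group_by(.data$fpr) |>
                           dplyr::summarise(tpr = max(.data$tpr)),
                         by = "fpr"), p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
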