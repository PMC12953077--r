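#' Pearson correlation between two models' out-of-fold predictions
#'
#' Degenerate (constant) prediction vectors are treated as maximally
#' redundant (correlation 1, with a warning) so they are pruned first.
#'
#' @param oof_a,oof_b numeric prediction vectors with identical subject
#'   alignment
#' @return correlation in \[-1, 1\]
#' @export
prediction_correlation <- function(oof_a, oof_b) {
  if (length(oof_a) != length(oof_b))
    stop("prediction vectors must share subject alignment", call. = FALSE)
  if (stats::sd(oof_a) == 0 || stats::sd(oof_b) == 0) {
    warning("constant OOF prediction vector: treated as maximally ",
            "redundant (rho = 1)", call. = FALSE)
    return(1)
  }
  stats::cor(oof_a, oof_b)
}

#' Correlation-based model pruning
#'
#' Greedy diversity pruning of a base-model pool: pairs of models are
#' processed in descending order of OOF-prediction correlation; while any
#' retained pair exceeds the threshold, the member with inferior
#' cross-validated performance is discarded (performance ties broken by
#' lexicographic learner id). At least one model is always retained, and
#' the surviving pool has no pair above the threshold.
#'
#' @param oof_matrix subjects x models matrix of OOF predictions (named
#'   columns)
#' @param performance named vector of cross-validated performance (higher
#'   is better; negate MAE for regression)
#' @param tau correlation threshold
#' @return list of class `admira_diversity`: `retained`, `pruned` (tibble
#'   with the discarded model, its retained partner and both
#'   performances), `rho` (the full correlation matrix), `tau`
#' @export
prune_models <- function(oof_matrix, performance, tau = 0.85) {
  ids <- colnames(oof_matrix)
  stopifnot(!is.null(ids), all(ids %in% names(performance)))
  k <- length(ids)
  rho <- diag(1, k)
  dimnames(rho) <- list(ids, ids)
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
      r <- suppressWarnings(prediction_correlation(oof_matrix[, i],
                                                   oof_matrix[, j]))
      rho[i, j] <- rho[j, i] <- r
    }
  }
  retained <- ids
  pruned <- list()
  repeat {
    if (length(retained) <= 1) break
    sub <- rho[retained, retained, drop = FALSE]
    ut <- which(upper.tri(sub) & sub > tau, arr.ind = TRUE)
    if (nrow(ut) == 0) break
    vals <- sub[ut]
    top <- ut[which.max(vals), ]
    a <- retained[top[1]]
    b <- retained[top[2]]
    worse <- if (performance[[a]] < performance[[b]]) a
             else if (performance[[b]] < performance[[a]]) b
             else max(a, b)  # tie: lexicographically later id discarded
    keep <- setdiff(c(a, b), worse)
    pruned[[length(pruned) + 1]] <- tibble::tibble(
      pruned = worse, retained_partner = keep, rho = sub[top[1], top[2]],
      pruned_perf = performance[[worse]],
      retained_perf = performance[[keep]])
    retained <- setdiff(retained, worse)
  }
  structure(list(retained = retained, pruned = dplyr::bind_rows(pruned),
                 rho = rho, tau = tau), class = "admira_diversity")
}

#' Build the stacking meta-feature matrix
#'
#' One column per retained base model holding its out-of-fold prediction
#' (class-1 probability for classification, predicted value for
#' regression); rows aligned to training subjects. Strictly OOF — no
#' in-fold refits enter the matrix.
#'
#' @param oof long tibble with `subject_id`, `learner`, `pred` (as
#'   produced by [nested_cv_run()])
#' @param retained character vector of retained learner ids
#' @return matrix subjects x retained models, rownames = subject ids
#' @export
build_meta_features <- function(oof, retained) {
  wide <- oof |>
    dplyr::filter(.data$learner %in% retained) |>
    dplyr::select("subject_id", "learner", "pred") |>
    tidyr::pivot_wider(names_from = "learner", values_from = "pred")
  if (anyNA(wide))
    stop("misaligned subjects across retained models", call. = FALSE)
  m <- as.matrix(wide[, retained, drop = FALSE])
  rownames(m) <- wide$subject_id
  m
}

#' Fit the stacking meta-model
#'
#' Logistic meta-classifier (classification) or ridge meta-regressor
#' (regression) trained exclusively on pooled out-of-fold predictions.
#' Ridge-style regularization with default strength 1 keeps the meta-fit
#' stable when base predictions are collinear.
#'
#' @param meta meta-feature matrix from [build_meta_features()]
#' @param targets outcome vector aligned to the meta rows
#' @param kind `"classification"` or `"regression"`
#' @param strength regularization strength (sklearn-style C for the
#'   logistic meta-model; lambda scale for ridge)
#' @return list with elements `fit`, `w` (named meta-weights, intercept
#'   excluded), `kind`
#' @export
fit_stacking <- function(meta, targets, kind, strength = 1) {
  stopifnot(nrow(meta) == length(targets))
  n <- nrow(meta)
  if (kind == "classification" && length(unique(targets)) < 2)
    stop("single-class targets: cannot fit meta-classifier",
         call. = FALSE)
  if (all(apply(meta, 2, stats::sd) == 0)) {
    # all base models constant: intercept-only meta-model (majority
    # class probability / mean target)
    return(list(fit = NULL, intercept = mean(targets),
                w = stats::setNames(rep(0, ncol(meta)), colnames(meta)),
                kind = kind))
  }
  if (kind == "classification") {
    fit <- suppressWarnings(
      glmnet::glmnet(.meta_design(meta), factor(targets,
                                                levels = c(0, 1)),
                     family = "binomial", alpha = 0,
                     lambda = 1 / (n * strength)))
  } else {
    fit <- glmnet::glmnet(.meta_design(meta), targets, alpha = 0,
                          lambda = strength / n)
  }
  w <- as.matrix(stats::coef(fit))[, 1]
  list(fit = fit, w = w[-1][colnames(meta)], kind = kind)
}

# glmnet needs >= 2 columns; pad a constant (zero-variance) column when a
# single base model survives pruning
.meta_design <- function(meta) {
  if (ncol(meta) >= 2) return(meta)
  cbind(meta, .const = 0)
}

#' Fit the full diversity-aware stacking ensemble from a nested-CV result
#'
#' Prunes the base pool by OOF-prediction correlation, fits the stacking
#' meta-model on pooled OOF predictions, computes ensemble predictions
#' and fold-wise metrics under the same outer folds as the base models,
#' and propagates feature importance through the stacking weights.
#'
#' @param cv an `admira_cv` result from [nested_cv_run()]
#' @param tau correlation-pruning threshold
#' @param strength meta-model regularization strength
#' @return object of class `admira_ensemble`
#' @export
fit_ensemble <- function(cv, tau = 0.85, strength = 1) {
  oof_all <- build_meta_features(cv$oof, unique(cv$oof$learner))
  diversity <- prune_models(oof_all, cv$performance, tau = tau)
  meta <- build_meta_features(cv$oof, diversity$retained)

  truth_tbl <- cv$oof |>
    dplyr::distinct(.data$subject_id, .data$fold, .data$truth)
  truth_tbl <- truth_tbl[match(rownames(meta), truth_tbl$subject_id), ]

  stack <- fit_stacking(meta, truth_tbl$truth, cv$kind,
                        strength = strength)
  ens_pred <- .predict_meta(stack, meta)

  fold_metrics <- purrr::map(sort(unique(truth_tbl$fold)), function(f) {
    idx <- truth_tbl$fold == f
    met <- if (cv$kind == "classification")
      classification_metrics(truth_tbl$truth[idx], ens_pred[idx])
    else regression_metrics(truth_tbl$truth[idx], ens_pred[idx])
    dplyr::bind_cols(tibble::tibble(fold = f), met)
  }) |> dplyr::bind_rows()

  importance <- propagate_importance(stack$w, cv$attributions)

  structure(list(
    retained = diversity$retained, diversity = diversity, w = stack$w,
    meta = stack, kind = cv$kind,
    oof = tibble::tibble(subject_id = rownames(meta),
                         fold = truth_tbl$fold, pred = ens_pred,
                         truth = truth_tbl$truth),
    fold_metrics = fold_metrics, importance = importance
  ), class = "admira_ensemble")
}

.predict_meta <- function(stack, base_pred) {
  if (is.null(stack$fit))
    return(rep(stack$intercept, nrow(base_pred)))
  x <- .meta_design(base_pred)
  type <- if (stack$kind == "classification") "response" else "link"
  as.numeric(stats::predict(stack$fit, x, type = type))
}

#' Predict from a fitted ensemble given base-model predictions
#'
#' @param ensemble an `admira_ensemble`
#' @param base_pred matrix with one named column per retained base model
#' @return ensemble predictions (class-1 probability or value)
#' @export
predict_ensemble <- function(ensemble, base_pred) {
  stopifnot(all(ensemble$retained %in% colnames(base_pred)))
  .predict_meta(ensemble$meta,
                base_pred[, ensemble$retained, drop = FALSE])
}

#' Propagate feature importance through the stacking weights
#'
#' For each original feature j, importance is the sum over retained base
#' models of |meta-weight| x |base attribution|, then normalized to sum
#' to one and ranked. Models that supply no attribution (e.g. the
#' Gaussian process regressor) are excluded with a warning.
#'
#' @param w named meta-weight vector (one entry per retained model)
#' @param attributions named list: learner id -> named vector of absolute
#'   per-feature attributions
#' @return tibble `feature`, `importance`, `rank`, sorted descending
#' @export
propagate_importance <- function(w, attributions) {
  use <- names(w)
  lacking <- use[vapply(use, function(m) is.null(attributions[[m]]),
                        logical(1))]
  if (length(lacking) > 0) {
    warning("model(s) lacking attributions excluded from importance ",
            "propagation: ", paste(lacking, collapse = ", "),
            call. = FALSE)
    use <- setdiff(use, lacking)
  }
  if (length(use) == 0)
    return(tibble::tibble(feature = character(), importance = numeric(),
                          rank = integer()))
  features <- names(attributions[[use[1]]])
  imp <- stats::setNames(rep(0, length(features)), features)
  for (m in use) imp <- imp + abs(w[[m]]) * abs(attributions[[m]][features])
  if (sum(imp) > 0) imp <- imp / sum(imp)
  tibble::tibble(feature = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance)) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' @export
tidy.admira_ensemble <- function(x, ...) {
  tibble::tibble(learner = names(x$w), meta_weight = unname(x$w))
}

#' @export
glance.admira_ensemble <- function(x, ...) {
  sel <- if (x$kind == "classification") "BACC" else "MAE"
  tibble::tibble(
    n_retained = length(x$retained), kind = x$kind,
    metric = sel, metric_mean = mean(x$fold_metrics[[sel]]),
    metric_sd = stats::sd(x$fold_metrics[[sel]])
  )
}

#' @export
tidy.admira_diversity <- function(x, ...) x$pruned
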