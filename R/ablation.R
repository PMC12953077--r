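#' Cross-validation fold plan
#'
#' @param holdout_fraction fraction of subjects held out for final
#'   evaluation (stratified by diagnosis)
#' @param outer_folds number of outer CV folds
#' @param inner_folds number of inner (grid-search) folds
#' @param seed integer seed controlling the hold-out split and fold
#'   assignment
#' @return object of class `fold_plan`
#' @export
fold_plan <- function(holdout_fraction = 0.2, outer_folds = 5L,
                      inner_folds = 3L, seed = 1L) {
  stopifnot(holdout_fraction > 0, holdout_fraction < 1,
            outer_folds >= 2, inner_folds >= 2)
  structure(list(holdout_fraction = holdout_fraction,
                 outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' Task specifications
#'
#' The four study tasks: three binary stage classifications (the impaired
#' class is positive) and the longitudinal cognitive decline regression on
#' annualized MMSE change.
#'
#' @param task_id one of `"CN-ADD"`, `"CN-MCI"`, `"MCI-ADD"`, `"LCDP"`
#' @return list with `task_id`, `kind`, and for classification `classes`
#'   and `positive`
#' @export
task_spec <- function(task_id = c("CN-ADD", "CN-MCI", "MCI-ADD", "LCDP")) {
  task_id <- match.arg(task_id)
  if (task_id == "LCDP")
    return(list(task_id = "LCDP", kind = "regression"))
  classes <- strsplit(task_id, "-")[[1]]
  list(task_id = task_id, kind = "classification", classes = classes,
       positive = classes[2])
}

#' The seven feature-set combinations
#' @return character vector of valid combinations
#' @export
feature_set_combinations <- function() {
  c("MO", "MS", "GT", "MO+MS", "MO+GT", "MS+GT", "MO+MS+GT")
}

# round-half-up
.round_half_up <- function(x) floor(x + 0.5)

#' Stratified hold-out split
#'
#' Splits subjects into train/test stratified by class, with per-class
#' test counts `round(fraction * class size)` to the nearest integer
#' (ties rounded up). Deterministic per seed.
#'
#' @param cohort tibble with `subject_id` and the stratification column
#' @param fraction test fraction
#' @param seed integer seed
#' @param strata name of the stratification column
#' @return list with character vectors `train` and `test`
#' @export
holdout_split <- function(cohort, fraction = 0.2, seed = 1L,
                          strata = "diagnosis") {
  groups <- split(cohort$subject_id, droplevels(factor(cohort[[strata]])))
  if (any(vapply(groups, length, 1L) < 2))
    stop("every class needs at least 2 subjects to stratify",
         call. = FALSE)
  test <- .with_substream(seed, 400000L, {
    unlist(purrr::imap(groups, function(ids, g) {
      k <- .round_half_up(fraction * length(ids))
      sample(ids, k)
    }), use.names = FALSE)
  })
  list(train = setdiff(cohort$subject_id, test), test = test)
}

#' Assemble a feature-set combination
#'
#' Column-concatenates the requested feature tables (subject ids must
#' match exactly) and always appends the amyloid-status column, which
#' rides along every combination. Column order is frozen: MO, MS, GT
#' blocks in that order, amyloid last.
#'
#' @param tables named list with (a subset of) tibbles `MO`, `MS`, `GT`,
#'   each `subject_id` + feature columns
#' @param combination one of [feature_set_combinations()]
#' @param abeta tibble with `subject_id` and `abeta_status`
#' @return tibble `subject_id` + the combined feature columns
#' @export
assemble_feature_set <- function(tables, combination, abeta) {
  if (!combination %in% feature_set_combinations())
    stop("invalid feature-set combination: ", combination, call. = FALSE)
  parts <- strsplit(combination, "+", fixed = TRUE)[[1]]
  missing <- setdiff(parts, names(tables))
  if (length(missing) > 0)
    stop("missing component table(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  ids <- tables[[parts[1]]]$subject_id
  out <- tables[[parts[1]]]
  for (p in parts[-1]) {
    if (!identical(sort(tables[[p]]$subject_id), sort(ids)))
      stop("subject ids do not match across component tables",
           call. = FALSE)
    out <- dplyr::inner_join(out, tables[[p]], by = "subject_id")
  }
  if (!all(ids %in% abeta$subject_id))
    stop("subject ids do not match the amyloid table", call. = FALSE)
  dplyr::inner_join(out, abeta[, c("subject_id", "abeta_status")],
                    by = "subject_id")
}

# fold assignment: stratified round-robin after a seeded shuffle
.make_folds <- function(y, k, seed, stratified = TRUE) {
  n <- length(y)
  fold <- integer(n)
  .with_substream(seed, 500000L, {
    if (stratified) {
      for (lev in unique(y)) {
        idx <- sample(which(y == lev))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      fold[sample.int(n)] <- rep_len(seq_len(k), n)
    }
  })
  fold
}

.selection_metric <- function(kind, y, pred) {
  if (kind == "classification")
    classification_metrics(y, pred)$BACC
  else -mean(abs(y - pred))
}

#' Nested cross-validation over a learner pool
#'
#' Runs the leakage-safe outer/inner cross-validation for one task and one
#' assembled feature table. Within each outer fold the age/sex
#' residualizer and standardizer are fitted on the outer training fold
#' only and applied to its test fold; the inner folds grid-search each
#' learner's hyperparameters (selection metric: balanced accuracy for
#' classification, negative MAE for regression); the winning configuration
#' is refit on the outer training fold and predictions are recorded on the
#' outer test fold. Every subject therefore receives exactly one
#' out-of-fold prediction per learner.
#'
#' @param features tibble `subject_id` + feature columns (amyloid status
#'   passes through adjustment untouched)
#' @param target vector aligned with `features` rows: 0/1 for
#'   classification (1 = impaired), numeric for regression
#' @param demographics tibble with `subject_id`, `age`, `sex`
#' @param kind `"classification"` or `"regression"`
#' @param learners a [learner_registry()] pool
#' @param plan a [fold_plan()]
#' @return object of class `admira_cv`: `oof` (subject, fold, learner,
#'   prediction, truth), `fold_metrics`, `best_params`, `performance`
#'   (per-learner mean selection metric), `attributions` (per-learner
#'   normalized feature attribution vectors)
#' @export
nested_cv_run <- function(features, target, demographics, kind, learners,
                          plan = fold_plan()) {
  stopifnot(nrow(features) == length(target))
  feat_cols <- .feature_cols(features)
  folds <- .make_folds(if (kind == "classification") target else
                         rep(1, length(target)),
                       plan$outer_folds, plan$seed,
                       stratified = kind == "classification")

  sanitize <- stats::setNames(paste0("f", seq_along(feat_cols)), feat_cols)
  desanitize <- stats::setNames(names(sanitize), sanitize)

  oof <- list()
  fold_metrics <- list()
  best_params <- list()
  attributions <- stats::setNames(
    replicate(length(learners), list(), simplify = FALSE), names(learners))

  for (f in seq_len(plan$outer_folds)) {
    tr <- folds != f
    te <- !tr
    adj <- fit_adjustment(features[tr, ], demographics, fold_id = f)
    ztr <- apply_adjustment(adj, features[tr, ], demographics)
    zte <- apply_adjustment(adj, features[te, ], demographics)
    xtr <- as.matrix(ztr[, feat_cols])
    xte <- as.matrix(zte[, feat_cols])
    colnames(xtr) <- colnames(xte) <- unname(sanitize[feat_cols])
    ytr <- target[tr]
    yte <- target[te]

    inner <- .make_folds(if (kind == "classification") ytr else
                           rep(1, length(ytr)),
                         plan$inner_folds, plan$seed + f,
                         stratified = kind == "classification")
    if (kind == "classification" &&
        any(vapply(seq_len(plan$inner_folds),
                   function(j) length(unique(ytr[inner == j])) < 2 ||
                     length(unique(ytr[inner != j])) < 2, logical(1))))
      stop("single-class inner fold: increase group sizes", call. = FALSE)

    for (lid in names(learners)) {
      lrn <- learners[[lid]]
      grid <- expand.grid(lrn$grid, stringsAsFactors = FALSE)
      scores <- vapply(seq_len(nrow(grid)), function(gi) {
        params <- as.list(grid[gi, , drop = FALSE])
        mean(vapply(seq_len(plan$inner_folds), function(j) {
          fit <- lrn$fit(xtr[inner != j, , drop = FALSE], ytr[inner != j],
                         params, seed = plan$seed + 100 * f + j)
          pred <- lrn$predict(fit, xtr[inner == j, , drop = FALSE])
          .selection_metric(kind, ytr[inner == j], pred)
        }, numeric(1)))
      }, numeric(1))
      best <- as.list(grid[which.max(scores), , drop = FALSE])

      fit <- lrn$fit(xtr, ytr, best, seed = plan$seed + f)
      pred <- lrn$predict(fit, xte)

      oof[[length(oof) + 1]] <- tibble::tibble(
        subject_id = features$subject_id[te], fold = f, learner = lid,
        pred = pred, truth = yte)
      met <- if (kind == "classification")
        classification_metrics(yte, pred) else
          regression_metrics(yte, pred)
      fold_metrics[[length(fold_metrics) + 1]] <-
        dplyr::bind_cols(tibble::tibble(learner = lid, fold = f), met)
      best_params[[length(best_params) + 1]] <- tibble::tibble(
        learner = lid, fold = f, params = list(best))

      imp <- lrn$importance(fit, colnames(xtr))
      if (!is.null(imp)) {
        names(imp) <- desanitize[names(imp)]
        s <- sum(imp)
        attributions[[lid]][[f]] <- if (s > 0) imp / s else imp
      }
    }
  }

  attributions <- purrr::map(attributions, function(lst) {
    lst <- purrr::compact(lst)
    if (length(lst) == 0) return(NULL)
    Reduce(`+`, lst) / length(lst)
  })

  fold_metrics <- dplyr::bind_rows(fold_metrics)
  sel <- if (kind == "classification") "BACC" else "MAE"
  performance <- fold_metrics |>
    dplyr::group_by(.data$learner) |>
    dplyr::summarise(metric = mean(.data[[sel]]), .groups = "drop") |>
    dplyr::mutate(metric = if (kind == "classification") .data$metric
                  else -.data$metric)

  structure(list(
    oof = dplyr::bind_rows(oof), fold_metrics = fold_metrics,
    best_params = dplyr::bind_rows(best_params),
    performance = stats::setNames(performance$metric,
                                  performance$learner),
    attributions = attributions, folds = folds, kind = kind,
    feature_names = feat_cols
  ), class = "admira_cv")
}

# modal hyperparameters across outer folds for one learner
.modal_params <- function(cv, lid) {
  plist <- cv$best_params$params[cv$best_params$learner == lid]
  keys <- vapply(plist, function(p) paste(unlist(p), collapse = "|"),
                 character(1))
  plist[[which.max(table(keys)[keys])]]
}

#' Run the full feature-set ablation
#'
#' For every requested task and feature-set combination: stratified 80/20
#' hold-out, nested cross-validation of the learner pool on the training
#' portion, diversity-aware stacking ensemble on the pooled out-of-fold
#' predictions, and (optionally) hold-out evaluation of the refit ensemble.
#' The default grid (4 tasks x 7 feature sets) yields 28 runs.
#'
#' @param cohort cohort tibble; must carry `mmse_visits` if `"LCDP"` is
#'   among the tasks
#' @param tables named list of feature tibbles `MO`, `MS`, `GT`
#' @param tasks character vector of task ids
#' @param feature_sets character vector of combinations
#' @param plan a [fold_plan()]
#' @param learners optional learner-id subset (applied to both rosters)
#' @param grids optional per-learner grid overrides
#' @param tau correlation-pruning threshold for the ensemble
#' @param holdout evaluate the refit ensemble on the hold-out portion
#' @return tibble of class `admira_ablation`: one row per (task x feature
#'   set) with summary metrics and list-columns `cv` and `ensemble`
#' @export
run_ablation <- function(cohort, tables,
                         tasks = c("CN-ADD", "CN-MCI", "MCI-ADD", "LCDP"),
                         feature_sets = feature_set_combinations(),
                         plan = fold_plan(), learners = NULL,
                         grids = NULL, tau = 0.85, holdout = TRUE) {
  abeta <- cohort[, c("subject_id", "abeta_status")]
  demog <- cohort[, c("subject_id", "age", "sex")]

  rows <- list()
  for (task_id in tasks) {
    tsk <- task_spec(task_id)
    if (tsk$kind == "classification") {
      sub <- cohort[cohort$diagnosis %in% tsk$classes, ]
      target_tbl <- tibble::tibble(
        subject_id = sub$subject_id,
        y = as.integer(sub$diagnosis == tsk$positive))
    } else {
      dm <- delta_mmse(cohort)
      sub <- cohort[cohort$subject_id %in% dm$subject_id, ]
      target_tbl <- tibble::tibble(
        subject_id = sub$subject_id,
        y = dm$delta_mmse[match(sub$subject_id, dm$subject_id)])
    }
    split <- holdout_split(sub, fraction = plan$holdout_fraction,
                           seed = plan$seed)
    lrn_sub <- if (is.list(learners)) learners[[tsk$kind]] else learners
    if (!is.null(lrn_sub)) {
      lrn_sub <- intersect(lrn_sub, names(learner_registry(tsk$kind)))
      if (length(lrn_sub) == 0)
        stop("no requested learner applies to ", tsk$kind, call. = FALSE)
    }
    grids_sub <- if (!is.null(grids))
      grids[intersect(names(grids), lrn_sub %||%
                        names(learner_registry(tsk$kind)))] else NULL
    pool <- learner_registry(tsk$kind, learners = lrn_sub,
                             grids = grids_sub)

    for (fs in feature_sets) {
      feats <- assemble_feature_set(tables, fs, abeta)
      feats <- feats[match(sub$subject_id, feats$subject_id), ]
      tr_idx <- feats$subject_id %in% split$train
      y <- target_tbl$y[match(feats$subject_id, target_tbl$subject_id)]

      cv <- nested_cv_run(feats[tr_idx, ], y[tr_idx], demog, tsk$kind,
                          pool, plan)
      ens <- fit_ensemble(cv, tau = tau)

      hold <- NULL
      if (holdout) {
        hold <- .holdout_eval(ens, cv, pool, feats, y, tr_idx, demog,
                              tsk$kind, plan)
      }
      em <- ens$fold_metrics
      sel <- if (tsk$kind == "classification") "BACC" else "MAE"
      best_base <- names(which.max(cv$performance))
      rows[[length(rows) + 1]] <- tibble::tibble(
        task = task_id, feature_set = fs, kind = tsk$kind,
        n_train = sum(tr_idx), n_test = sum(!tr_idx),
        n_features = length(cv$feature_names),
        ensemble_metric_mean = mean(em[[sel]]),
        ensemble_metric_sd = stats::sd(em[[sel]]),
        metric_name = sel,
        best_base = best_base,
        best_base_metric = if (tsk$kind == "classification")
          max(cv$performance) else -max(cv$performance),
        holdout_metric = if (is.null(hold)) NA_real_ else hold[[sel]],
        cv = list(cv), ensemble = list(ens))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("admira_ablation", class(out))
  out
}

# refit retained base models on the full training portion (modal
# hyperparameters), apply the pooled-OOF meta-model to their hold-out
# predictions
.holdout_eval <- function(ens, cv, pool, feats, y, tr_idx, demog, kind,
                          plan) {
  adj <- fit_adjustment(feats[tr_idx, ], demog, fold_id = "holdout")
  ztr <- apply_adjustment(adj, feats[tr_idx, ], demog)
  zte <- apply_adjustment(adj, feats[!tr_idx, ], demog)
  feat_cols <- cv$feature_names
  sanitize <- stats::setNames(paste0("f", seq_along(feat_cols)), feat_cols)
  xtr <- as.matrix(ztr[, feat_cols])
  xte <- as.matrix(zte[, feat_cols])
  colnames(xtr) <- colnames(xte) <- unname(sanitize[feat_cols])
  base_pred <- vapply(ens$retained, function(lid) {
    fit <- pool[[lid]]$fit(xtr, y[tr_idx], .modal_params(cv, lid),
                           seed = plan$seed)
    pool[[lid]]$predict(fit, xte)
  }, numeric(sum(!tr_idx)))
  base_pred <- matrix(base_pred, ncol = length(ens$retained),
                      dimnames = list(NULL, ens$retained))
  pred <- predict_ensemble(ens, base_pred)
  if (kind == "classification") classification_metrics(y[!tr_idx], pred)
  else regression_metrics(y[!tr_idx], pred)
}
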