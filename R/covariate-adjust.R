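#' Annualized MMSE change
#'
#' The longitudinal target: the difference between a follow-up and an
#' earlier MMSE score, normalized by the elapsed time in years,
#' `(mmse_followup - mmse_visit) / (months_elapsed / 12)`, in points/year.
#'
#' @param visit,followup one-row data frames (or lists) with
#'   `months_from_baseline` and `mmse`; the follow-up must be strictly
#'   later
#' @return annualized change, points per year
#' @export
annualized_mmse_change <- function(visit, followup) {
  months <- followup$months_from_baseline - visit$months_from_baseline
  if (length(months) != 1 || !is.finite(months) || months <= 0)
    stop("follow-up must be strictly later than the visit", call. = FALSE)
  (followup$mmse - visit$mmse) / (months / 12)
}

#' Select the visit pair for the longitudinal target
#'
#' Uses the (first, last) rule: the baseline visit and the last available
#' follow-up, maximizing elapsed time. Subjects with fewer than two visits
#' are excluded (error of class `admira_exclusion`).
#'
#' @param visits tibble with `months_from_baseline`, `mmse`
#' @return list with one-row tibbles `visit` and `followup`
#' @export
select_visit_pair <- function(visits) {
  if (nrow(visits) < 2)
    stop(structure(class = c("admira_exclusion", "error", "condition"),
                   list(message = "subject has fewer than 2 visits",
                        call = NULL)))
  v <- dplyr::arrange(visits, .data$months_from_baseline)
  list(visit = v[1, ], followup = v[nrow(v), ])
}

#' Per-subject annualized MMSE change for a cohort
#'
#' @param cohort cohort tibble with an `mmse_visits` list-column
#' @return tibble `subject_id`, `months_elapsed`, `delta_mmse`; subjects
#'   with fewer than two visits are dropped
#' @export
delta_mmse <- function(cohort) {
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    visits <- cohort$mmse_visits[[i]]
    if (is.null(visits) || nrow(visits) < 2) return(NULL)
    pair <- select_visit_pair(visits)
    tibble::tibble(
      subject_id = cohort$subject_id[i],
      months_elapsed = pair$followup$months_from_baseline -
        pair$visit$months_from_baseline,
      delta_mmse = annualized_mmse_change(pair$visit, pair$followup)
    )
  })
  dplyr::bind_rows(rows)
}

#' Normalize volumetric features by intracranial volume
#'
#' Divides each subcortical/ventricular/callosal volume column (and, by
#' default, brain parenchymal volume) by the subject's estimated total
#' intracranial volume. Cortical thickness and all MS/GT columns are left
#' untouched. This is a per-subject transform, so it may run before any
#' train/test split without leakage.
#'
#' @param features tibble with `subject_id` and feature columns
#' @param cohort tibble with `subject_id` and `etiv`
#' @param normalize_bpv treat BPV as a volume and normalize it too
#' @return the feature tibble with volume columns rescaled
#' @export
etiv_normalize <- function(features, cohort, normalize_bpv = TRUE) {
  if (!all(features$subject_id %in% cohort$subject_id))
    stop("missing eTIV for some subjects", call. = FALSE)
  etiv <- cohort$etiv[match(features$subject_id, cohort$subject_id)]
  if (any(is.na(etiv) | etiv <= 0))
    stop("every subject must have etiv > 0", call. = FALSE)
  vol_cols <- intersect(names(features), sv_feature_names())
  if (normalize_bpv) vol_cols <- c(vol_cols, intersect(names(features), "BPV"))
  for (col in vol_cols) features[[col]] <- features[[col]] / etiv
  features
}

.feature_cols <- function(features) setdiff(names(features), "subject_id")

.design_matrix <- function(demographics, sex_coding = c(M = 0, F = 1)) {
  sex <- sex_coding[as.character(demographics$sex)]
  cbind(intercept = 1, age = demographics$age, sex = unname(sex))
}

#' Fit an age/sex residualizer on training data
#'
#' Per feature, an ordinary least-squares fit
#' `x = b0 + b1 * Age + b2 * Sex + e` on the training subjects only
#' (sex coded M = 0, F = 1). Rank-deficient designs (constant age,
#' single-sex folds) fall back to the pseudoinverse with a warning.
#'
#' @param features training feature tibble (`subject_id` + features)
#' @param demographics tibble with `subject_id`, `age`, `sex` covering the
#'   training subjects
#' @param fold_id optional identifier recorded with the model
#' @return object of class `admira_residualizer`
#' @export
fit_residualizer <- function(features, demographics, fold_id = NA) {
  if (nrow(features) < 3)
    stop("need at least 3 training subjects", call. = FALSE)
  demographics <- demographics[match(features$subject_id,
                                     demographics$subject_id), ]
  x_mat <- as.matrix(features[, .feature_cols(features)])
  design <- .design_matrix(demographics)
  qr_d <- qr(design)
  coef <- if (qr_d$rank < ncol(design)) {
    warning("rank-deficient covariate design; using pseudoinverse",
            call. = FALSE)
    MASS::ginv(design) %*% x_mat
  } else {
    qr.coef(qr_d, x_mat)
  }
  rownames(coef) <- c("intercept", "age", "sex")
  structure(list(coefficients = coef,
                 features = .feature_cols(features),
                 fold_id = fold_id),
            class = "admira_residualizer")
}

#' Apply a fitted residualizer
#'
#' Subtracts the age/sex prediction using the coefficients estimated on
#' the training fold; never refits, so applying to held-out data carries
#' the training fold's parameters.
#'
#' @param model an `admira_residualizer`
#' @param features feature tibble to transform
#' @param demographics tibble with `subject_id`, `age`, `sex`
#' @return feature tibble of residuals
#' @export
apply_residualizer <- function(model, features, demographics) {
  if (!inherits(model, "admira_residualizer"))
    stop("residualizer has not been fitted", call. = FALSE)
  if (!setequal(.feature_cols(features), model$features))
    stop("feature names do not match the fitted residualizer",
         call. = FALSE)
  demographics <- demographics[match(features$subject_id,
                                     demographics$subject_id), ]
  x_mat <- as.matrix(features[, model$features])
  pred <- .design_matrix(demographics) %*% model$coefficients[, model$features,
                                                              drop = FALSE]
  out <- tibble::as_tibble(x_mat - pred)
  dplyr::bind_cols(features["subject_id"], out)
}

#' Fit / apply fold-wise feature standardization
#'
#' `fit_standardizer()` stores the per-feature training mean and standard
#' deviation (population, divide-by-n, convention by default; toggleable);
#' `apply_standardizer()` computes `z = (x - mu_train) / sigma_train` with
#' the stored parameters. Constant training features emit 0 with a
#' warning.
#'
#' @param features training feature tibble
#' @param sd_convention `"population"` (divide by n) or `"sample"`
#' @param fold_id optional identifier recorded with the model
#' @return `fit_standardizer()`: object of class `admira_standardizer`
#' @export
fit_standardizer <- function(features, sd_convention = c("population",
                                                         "sample"),
                             fold_id = NA) {
  sd_convention <- match.arg(sd_convention)
  x_mat <- as.matrix(features[, .feature_cols(features)])
  n <- nrow(x_mat)
  mu <- colMeans(x_mat)
  sigma <- apply(x_mat, 2, stats::sd)
  if (sd_convention == "population") sigma <- sigma * sqrt((n - 1) / n)
  if (any(sigma == 0))
    warning("constant training feature(s) will standardize to 0: ",
            paste(utils::head(names(mu)[sigma == 0], 5), collapse = ", "),
            if (sum(sigma == 0) > 5) ", ..." else "", call. = FALSE)
  structure(list(mu = mu, sigma = sigma, constant = sigma == 0,
                 sd_convention = sd_convention, fold_id = fold_id),
            class = "admira_standardizer")
}

#' @rdname fit_standardizer
#' @param model a fitted `admira_standardizer`
#' @export
apply_standardizer <- function(model, features) {
  if (!inherits(model, "admira_standardizer"))
    stop("standardizer has not been fitted", call. = FALSE)
  cols <- names(model$mu)
  if (!all(cols %in% names(features)))
    stop("feature names do not match the fitted standardizer",
         call. = FALSE)
  x_mat <- as.matrix(features[, cols])
  sigma <- ifelse(model$constant, 1, model$sigma)
  z <- sweep(sweep(x_mat, 2, model$mu), 2, sigma, "/")
  z[, model$constant] <- 0
  dplyr::bind_cols(features["subject_id"], tibble::as_tibble(z))
}

#' Fit and apply the full leakage-safe adjustment pipeline
#'
#' Convenience wrappers chaining residualization and standardization with
#' the strict fit-on-train / apply-on-test contract. eTIV normalization is
#' per-subject and is expected to have been applied upstream. Non-imaging
#' columns listed in `passthrough` (amyloid status by default) bypass both
#' transforms and are re-appended raw.
#'
#' @param features training feature tibble
#' @param demographics tibble with `subject_id`, `age`, `sex`
#' @param passthrough columns excluded from adjustment
#' @param sd_convention forwarded to [fit_standardizer()]
#' @param fold_id optional fold identifier
#' @return `fit_adjustment()`: list with the fitted residualizer and
#'   standardizer (class `admira_adjustment`)
#' @export
fit_adjustment <- function(features, demographics,
                           passthrough = "abeta_status",
                           sd_convention = "population", fold_id = NA) {
  keep <- setdiff(names(features), passthrough)
  imaging <- features[, keep]
  res <- fit_residualizer(imaging, demographics, fold_id = fold_id)
  resid_train <- apply_residualizer(res, imaging, demographics)
  std <- fit_standardizer(resid_train, sd_convention = sd_convention,
                          fold_id = fold_id)
  structure(list(residualizer = res, standardizer = std,
                 passthrough = intersect(passthrough, names(features))),
            class = "admira_adjustment")
}

#' @rdname fit_adjustment
#' @param model a fitted `admira_adjustment`
#' @export
apply_adjustment <- function(model, features, demographics) {
  if (!inherits(model, "admira_adjustment"))
    stop("adjustment pipeline has not been fitted", call. = FALSE)
  keep <- setdiff(names(features), model$passthrough)
  imaging <- features[, keep]
  z <- apply_standardizer(model$standardizer,
                          apply_residualizer(model$residualizer, imaging,
                                             demographics))
  if (length(model$passthrough) > 0)
    z <- dplyr::bind_cols(z, features[, model$passthrough, drop = FALSE])
  z
}

#' @export
tidy.admira_residualizer <- function(x, ...) {
  coef <- x$coefficients
  tibble::tibble(
    feature = rep(colnames(coef), each = nrow(coef)),
    term = rep(rownames(coef), times = ncol(coef)),
    estimate = as.vector(coef)
  )
}
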