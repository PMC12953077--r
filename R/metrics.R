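#' Classification metric suite
#'
#' Computes accuracy, balanced accuracy, sensitivity, specificity and
#' rocAUC from predicted positive-class probabilities. Sensitivity is the
#' recall of the impaired (positive) class, specificity of the negative
#' class; BACC is their mean; rocAUC is the Mann-Whitney rank statistic
#' over the probabilities (average ranks for ties), so a constant scorer
#' gets 0.5.
#'
#' @param y_true 0/1 vector (1 = positive / impaired class)
#' @param p_pred predicted positive-class probabilities
#' @param threshold decision threshold on the probability
#' @return one-row tibble with `ACC`, `BACC`, `SEN`, `SPE`, `rocAUC`
#' @export
classification_metrics <- function(y_true, p_pred, threshold = 0.5) {
  y_true <- as.integer(y_true)
  if (length(unique(y_true)) < 2)
    stop("both classes must be present in y_true", call. = FALSE)
  y_hat <- as.integer(p_pred >= threshold)
  tp <- sum(y_hat == 1 & y_true == 1)
  fn <- sum(y_hat == 0 & y_true == 1)
  tn <- sum(y_hat == 0 & y_true == 0)
  fp <- sum(y_hat == 1 & y_true == 0)
  sen <- tp / (tp + fn)
  spe <- tn / (tn + fp)
  tibble::tibble(
    ACC = (tp + tn) / length(y_true),
    BACC = (sen + spe) / 2,
    SEN = sen, SPE = spe,
    rocAUC = auc_rank(y_true, p_pred)
  )
}

#' Rank-statistic ROC AUC
#'
#' @param y_true 0/1 vector
#' @param p_pred scores
#' @return area under the ROC curve via the Mann-Whitney U statistic
#' @export
auc_rank <- function(y_true, p_pred) {
  y_true <- as.integer(y_true)
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present", call. = FALSE)
  r <- rank(p_pred)
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Regression metric suite
#'
#' @param y_true observed targets (variance > 0 required for R^2)
#' @param y_pred predictions
#' @return one-row tibble with `MAE`, `MSE`, `RMSE`, `R2`
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) < 2 || stats::var(y_true) == 0)
    stop("R^2 undefined: y_true needs >= 2 observations with variance > 0",
         call. = FALSE)
  err <- y_true - y_pred
  mse <- mean(err^2)
  tibble::tibble(
    MAE = mean(abs(err)), MSE = mse, RMSE = sqrt(mse),
    R2 = 1 - sum(err^2) / sum((y_true - mean(y_true))^2)
  )
}
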