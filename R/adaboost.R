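#' Adaptive boosting on decision stumps
#'
#' Discrete AdaBoost (SAMME, binary) for classification and the AdaBoost.R2
#' scheme for regression, built on weighted `rpart` trees. Both are
#' deterministic for a fixed seed. The classifier predicts the weighted
#' vote fraction for class 1 (a score in \[0, 1\]); the regressor predicts
#' the weighted median of its rounds' predictions.
#'
#' @param x numeric feature matrix
#' @param y 0/1 labels (`ada_fit`) or numeric targets (`ada_r2_fit`)
#' @param n_rounds maximum boosting rounds
#' @param maxdepth depth of each weak tree
#' @param seed RNG seed (AdaBoost.R2 resamples by weight)
#' @return fitted boosting model (list of trees, round weights)
#' @keywords internal
#' @export
ada_fit <- function(x, y, n_rounds = 50, maxdepth = 1, seed = 1L) {
  set.seed(seed)
  n <- nrow(x)
  df <- data.frame(x, check.names = FALSE)
  df$.y <- factor(y, levels = c(0, 1))
  w <- rep(1 / n, n)
  trees <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    tree <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                         control = rpart::rpart.control(
                           maxdepth = maxdepth, cp = -1, minsplit = 2,
                           xval = 0))
    pred <- as.integer(as.character(
      stats::predict(tree, df, type = "class")))
    err <- sum(w * (pred != y))
    if (err <= 1e-12) {
      trees[[length(trees) + 1]] <- tree
      alphas <- c(alphas, 10)
      break
    }
    if (err >= 0.5) break
    alpha <- 0.5 * log((1 - err) / err)
    trees[[length(trees) + 1]] <- tree
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
  }
  if (length(trees) == 0) {
    # degenerate: fall back to a single stump
    tree <- rpart::rpart(.y ~ ., data = df, method = "class",
                         control = rpart::rpart.control(
                           maxdepth = maxdepth, cp = -1, minsplit = 2,
                           xval = 0))
    trees <- list(tree)
    alphas <- 1
  }
  structure(list(trees = trees, alphas = alphas, kind = "classification"),
            class = "admira_ada")
}

#' @rdname ada_fit
#' @param fit a fitted `admira_ada` model
#' @export
ada_predict <- function(fit, x) {
  df <- data.frame(x, check.names = FALSE)
  votes <- vapply(fit$trees, function(tree) {
    as.numeric(as.character(stats::predict(tree, df, type = "class")))
  }, numeric(nrow(df)))
  votes <- matrix(votes, nrow = nrow(df))
  as.numeric(votes %*% fit$alphas / sum(fit$alphas))
}

#' @rdname ada_fit
#' @export
ada_r2_fit <- function(x, y, n_rounds = 50, maxdepth = 3, seed = 1L) {
  set.seed(seed)
  n <- nrow(x)
  df <- data.frame(x, check.names = FALSE)
  df$.y <- y
  w <- rep(1 / n, n)
  trees <- list()
  betas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    idx <- sample.int(n, n, replace = TRUE, prob = w)
    tree <- rpart::rpart(.y ~ ., data = df[idx, ], method = "anova",
                         control = rpart::rpart.control(
                           maxdepth = maxdepth, cp = 0.001, xval = 0))
    pred <- stats::predict(tree, df)
    abs_err <- abs(pred - y)
    emax <- max(abs_err)
    if (emax <= 1e-12) {
      trees[[length(trees) + 1]] <- tree
      betas <- c(betas, 1e-6)
      break
    }
    loss <- abs_err / emax
    ebar <- sum(w * loss)
    if (ebar >= 0.5) break
    beta <- ebar / (1 - ebar)
    trees[[length(trees) + 1]] <- tree
    betas <- c(betas, beta)
    w <- w * beta^(1 - loss)
    w <- w / sum(w)
  }
  if (length(trees) == 0) {
    tree <- rpart::rpart(.y ~ ., data = df, method = "anova",
                         control = rpart::rpart.control(
                           maxdepth = maxdepth, cp = 0.001, xval = 0))
    trees <- list(tree)
    betas <- 0.5
  }
  structure(list(trees = trees, alphas = log(1 / betas),
                 kind = "regression"), class = "admira_ada")
}

#' @rdname ada_fit
#' @export
ada_r2_predict <- function(fit, x) {
  df <- data.frame(x, check.names = FALSE)
  preds <- vapply(fit$trees, function(tree) stats::predict(tree, df),
                  numeric(nrow(df)))
  preds <- matrix(preds, nrow = nrow(df))
  a <- pmax(fit$alphas, 1e-9)
  apply(preds, 1, function(p) {
    o <- order(p)
    cw <- cumsum(a[o]) / sum(a)
    p[o][which(cw >= 0.5)[1]]
  })
}

#' @rdname ada_fit
#' @export
ada_importance <- function(fit) {
  out <- numeric(0)
  a <- pmax(fit$alphas, 1e-9)
  for (m in seq_along(fit$trees)) {
    vi <- fit$trees[[m]]$variable.importance
    if (is.null(vi)) next
    for (f in names(vi)) out[f] <- (if (f %in% names(out)) out[f] else 0) +
        a[m] * vi[f]
  }
  out
}
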