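#' Learner registry
#'
#' The heterogeneous base-learner rosters behind the ablation engine:
#' seven classifiers (LogR, LDA, DT, RF, AdaBoost, XGB, SVM) and seven
#' regressors (Ridge, DT, RF, AdaBoost, XGB, GPR, SVR). Each learner is a
#' small adapter around an established estimator implementation exposing a
#' uniform `fit(x, y, params, seed)` / `predict(fit, x)` /
#' `importance(fit, features)` surface plus a default hyperparameter grid;
#' the registry, not the individual learners, is the package's contract,
#' and grids are overridable per learner. Classification learners consume
#' a 0/1 outcome (1 = impaired class) and predict the class-1 probability;
#' importance vectors are absolute coefficient or native impurity/gain
#' magnitudes on the original feature names (the Gaussian process
#' regressor exposes none).
#'
#' @param kind `"classification"` or `"regression"`
#' @param learners optional character subset of learner ids
#' @param grids optional named list of grid overrides, e.g.
#'   `list(RF = list(mtry_mult = 1))`
#' @return named list of learner definitions
#' @export
learner_registry <- function(kind = c("classification", "regression"),
                             learners = NULL, grids = NULL) {
  kind <- match.arg(kind)
  reg <- if (kind == "classification") .classifier_registry()
         else .regressor_registry()
  if (!is.null(learners)) {
    missing <- setdiff(learners, names(reg))
    if (length(missing) > 0)
      stop("unknown learner id(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    reg <- reg[learners]
  }
  if (!is.null(grids)) {
    for (id in names(grids)) {
      if (!id %in% names(reg))
        stop("grid override for unknown learner: ", id, call. = FALSE)
      if (length(grids[[id]]) == 0)
        stop("hyperparameter grid must be non-empty", call. = FALSE)
      reg[[id]]$grid <- grids[[id]]
    }
  }
  for (l in reg) if (length(l$grid) == 0)
    stop("hyperparameter grid must be non-empty for ", l$id, call. = FALSE)
  reg
}

.named_importance <- function(values, features) {
  out <- stats::setNames(rep(0, length(features)), features)
  common <- intersect(names(values), features)
  out[common] <- abs(values[common])
  out
}

.classifier_registry <- function() {
  list(
    LogR = list(
      id = "LogR", grid = list(lambda = c(0.001, 0.01, 0.1)),
      fit = function(x, y, params, seed) {
        # glmnet warns about small class counts on desk-scale folds
        suppressWarnings(
          glmnet::glmnet(x, factor(y, levels = c(0, 1)),
                         family = "binomial", alpha = 0,
                         lambda = params$lambda))
      },
      predict = function(fit, x)
        as.numeric(stats::predict(fit, x, type = "response")),
      importance = function(fit, features) {
        b <- as.matrix(stats::coef(fit))[, 1]
        .named_importance(b[-1], features)
      }
    ),
    LDA = list(
      id = "LDA", grid = list(tol = 1e-8),
      fit = function(x, y, params, seed) {
        suppressWarnings(MASS::lda(x, grouping = factor(y,
                                                        levels = c(0, 1)),
                                   tol = params$tol))
      },
      predict = function(fit, x)
        as.numeric(stats::predict(fit, x)$posterior[, "1"]),
      importance = function(fit, features) {
        b <- fit$scaling[, 1]
        .named_importance(b, features)
      }
    ),
    DT = list(
      id = "DT", grid = list(maxdepth = c(3, 5, 10)),
      fit = function(x, y, params, seed) {
        df <- data.frame(x, check.names = FALSE)
        df$.y <- factor(y, levels = c(0, 1))
        rpart::rpart(.y ~ ., data = df, method = "class",
                     control = rpart::rpart.control(
                       maxdepth = params$maxdepth, cp = 0.001,
                       xval = 0))
      },
      predict = function(fit, x)
        as.numeric(stats::predict(fit, data.frame(x, check.names = FALSE),
                                  type = "prob")[, "1"]),
      importance = function(fit, features)
        .named_importance(fit$variable.importance, features)
    ),
    RF = list(
      id = "RF", grid = list(mtry_mult = c(0.5, 1, 2)),
      fit = function(x, y, params, seed) {
        mtry <- max(1L, min(ncol(x),
                            round(params$mtry_mult * sqrt(ncol(x)))))
        ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                       probability = TRUE, num.trees = 200, mtry = mtry,
                       importance = "impurity", seed = seed,
                       num.threads = 1)
      },
      predict = function(fit, x)
        as.numeric(stats::predict(fit, data = x,
                                  num.threads = 1)$predictions[, "1"]),
      importance = function(fit, features)
        .named_importance(fit$variable.importance, features)
    ),
    AdaBoost = list(
      id = "AdaBoost", grid = list(n_rounds = c(50, 100)),
      fit = function(x, y, params, seed)
        ada_fit(x, y, n_rounds = params$n_rounds, maxdepth = 1,
                seed = seed),
      predict = function(fit, x) ada_predict(fit, x),
      importance = function(fit, features)
        .named_importance(ada_importance(fit), features)
    ),
    XGB = list(
      id = "XGB", grid = list(nrounds = c(50, 100), max_depth = 3),
      fit = function(x, y, params, seed) {
        set.seed(seed)
        xgboost::xgboost(x, factor(y, levels = c(0, 1)),
                         nrounds = params$nrounds,
                         max_depth = params$max_depth,
                         learning_rate = 0.1, nthreads = 1,
                         verbosity = 0)
      },
      predict = function(fit, x)
        as.numeric(stats::predict(fit, x, type = "response")),
      importance = function(fit, features) {
        imp <- xgboost::xgb.importance(model = fit)
        .named_importance(stats::setNames(imp$Gain, imp$Feature), features)
      }
    ),
    SVM = list(
      id = "SVM", grid = list(cost = c(0.1, 1, 10)),
      fit = function(fit_x, y, params, seed) {
        set.seed(seed)
        e1071::svm(fit_x, factor(y, levels = c(0, 1)), kernel = "radial",
                   cost = params$cost, probability = TRUE, scale = FALSE)
      },
      predict = function(fit, x) {
        p <- stats::predict(fit, x, probability = TRUE)
        as.numeric(attr(p, "probabilities")[, "1"])
      },
      importance = function(fit, features) {
        w <- abs(as.vector(t(fit$coefs) %*% fit$SV))
        .named_importance(stats::setNames(w, colnames(fit$SV)), features)
      }
    )
  )
}

.regressor_registry <- function() {
  list(
    Ridge = list(
      id = "Ridge", grid = list(lambda = c(0.01, 0.1, 1, 10, 100)),
      fit = function(x, y, params, seed)
        glmnet::glmnet(x, y, alpha = 0, lambda = params$lambda),
      predict = function(fit, x) as.numeric(stats::predict(fit, x)),
      importance = function(fit, features) {
        b <- as.matrix(stats::coef(fit))[, 1]
        .named_importance(b[-1], features)
      }
    ),
    DT = list(
      id = "DT", grid = list(maxdepth = c(3, 5, 10)),
      fit = function(x, y, params, seed) {
        df <- data.frame(x, check.names = FALSE)
        df$.y <- y
        rpart::rpart(.y ~ ., data = df, method = "anova",
                     control = rpart::rpart.control(
                       maxdepth = params$maxdepth, cp = 0.001, xval = 0))
      },
      predict = function(fit, x)
        as.numeric(stats::predict(fit, data.frame(x, check.names = FALSE))),
      importance = function(fit, features)
        .named_importance(fit$variable.importance, features)
    ),
    RF = list(
      id = "RF", grid = list(mtry_mult = c(0.5, 1, 2)),
      fit = function(x, y, params, seed) {
        mtry <- max(1L, min(ncol(x),
                            round(params$mtry_mult * ncol(x) / 3)))
        ranger::ranger(x = x, y = y, num.trees = 200, mtry = mtry,
                       importance = "impurity", seed = seed,
                       num.threads = 1)
      },
      predict = function(fit, x)
        as.numeric(stats::predict(fit, data = x,
                                  num.threads = 1)$predictions),
      importance = function(fit, features)
        .named_importance(fit$variable.importance, features)
    ),
    AdaBoost = list(
      id = "AdaBoost", grid = list(n_rounds = c(25, 50)),
      fit = function(x, y, params, seed)
        ada_r2_fit(x, y, n_rounds = params$n_rounds, maxdepth = 3,
                   seed = seed),
      predict = function(fit, x) ada_r2_predict(fit, x),
      importance = function(fit, features)
        .named_importance(ada_importance(fit), features)
    ),
    XGB = list(
      id = "XGB", grid = list(nrounds = c(50, 100), max_depth = 3),
      fit = function(x, y, params, seed) {
        set.seed(seed)
        xgboost::xgboost(x, y, nrounds = params$nrounds,
                         max_depth = params$max_depth,
                         learning_rate = 0.1, nthreads = 1,
                         verbosity = 0)
      },
      predict = function(fit, x) as.numeric(stats::predict(fit, x)),
      importance = function(fit, features) {
        imp <- xgboost::xgb.importance(model = fit)
        .named_importance(stats::setNames(imp$Gain, imp$Feature), features)
      }
    ),
    GPR = list(
      id = "GPR", grid = list(sigma_mult = c(0.5, 1)),
      fit = function(x, y, params, seed) {
        sigma <- params$sigma_mult / ncol(x)
        kernlab::gausspr(x, y, type = "regression",
                         kernel = "rbfdot", kpar = list(sigma = sigma),
                         var = 0.1)
      },
      predict = function(fit, x) as.numeric(kernlab::predict(fit, x)),
      importance = function(fit, features) NULL
    ),
    SVR = list(
      id = "SVR", grid = list(cost = c(0.1, 1, 10)),
      fit = function(x, y, params, seed) {
        set.seed(seed)
        e1071::svm(x, y, kernel = "radial", cost = params$cost,
                   scale = FALSE)
      },
      predict = function(fit, x) as.numeric(stats::predict(fit, x)),
      importance = function(fit, features) {
        w <- abs(as.vector(t(fit$coefs) %*% fit$SV))
        .named_importance(stats::setNames(w, colnames(fit$SV)), features)
      }
    )
  )
}
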