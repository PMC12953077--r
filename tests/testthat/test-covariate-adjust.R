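visit_at <- function(months, mmse) {
  tibble::tibble(months_from_baseline = months, mmse = mmse)
}

test_that("annualized MMSE change follows the points-per-year formula", {
  expect_equal(annualized_mmse_change(visit_at(0, 30), visit_at(36, 30)), 0)
  expect_equal(annualized_mmse_change(visit_at(0, 28), visit_at(24, 22)),
               -3)
  expect_equal(annualized_mmse_change(visit_at(0, 27), visit_at(12, 25)),
               -2)
  expect_error(annualized_mmse_change(visit_at(12, 27), visit_at(12, 25)),
               "strictly later")
  expect_error(annualized_mmse_change(visit_at(12, 27), visit_at(0, 25)),
               "strictly later")
})

test_that("visit-pair selection takes the baseline and last follow-up", {
  v <- visit_at(c(0, 12, 80), c(30, 29, 25))
  pair <- select_visit_pair(v)
  expect_equal(pair$visit$months_from_baseline, 0)
  expect_equal(pair$followup$months_from_baseline, 80)

  two <- visit_at(c(6, 18), c(28, 27))
  pair2 <- select_visit_pair(two)
  expect_equal(pair2$visit$months_from_baseline, 6)
  expect_error(select_visit_pair(visit_at(0, 30)),
               class = "admira_exclusion")
})

test_that("eTIV normalization divides volume columns only", {
  coh <- tibble::tibble(subject_id = c("a", "b"), etiv = c(1.6e6, 4000))
  feats <- tibble::tibble(
    subject_id = c("a", "b"),
    `Left-Hippocampus` = c(4000, 4000),
    `ctx-lh-bankssts` = c(2.5, 2.5),
    `wholebrain-FA` = c(0.4, 0.4))
  out <- etiv_normalize(feats, coh)
  expect_equal(out$`Left-Hippocampus`, c(2.5e-3, 1))
  expect_equal(out$`ctx-lh-bankssts`, c(2.5, 2.5))
  expect_equal(out$`wholebrain-FA`, c(0.4, 0.4))
  expect_error(etiv_normalize(feats, coh[1, ]), "missing eTIV")
})

test_that("BPV normalization is toggleable", {
  coh <- tibble::tibble(subject_id = "a", etiv = 2)
  feats <- tibble::tibble(subject_id = "a", BPV = 1.5)
  expect_equal(etiv_normalize(feats, coh)$BPV, 0.75)
  expect_equal(etiv_normalize(feats, coh, normalize_bpv = FALSE)$BPV, 1.5)
})

make_adjust_fixture <- function(n = 200, seed = 1) {
  set.seed(seed)
  demog <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    age = stats::runif(n, 60, 90),
    sex = factor(sample(c("M", "F"), n, replace = TRUE),
                 levels = c("M", "F")))
  feats <- tibble::tibble(
    subject_id = demog$subject_id,
    double_age = 2 * demog$age,
    confounded = 5 + 0.3 * demog$age + 2 * (demog$sex == "F") +
      stats::rnorm(n),
    independent = stats::rnorm(n))
  list(demog = demog, feats = feats)
}

test_that("residualizer recovers exact and null coefficients", {
  fx <- make_adjust_fixture()
  mod <- fit_residualizer(fx$feats, fx$demog)
  expect_equal(mod$coefficients["age", "double_age"], 2, tolerance = 1e-8)
  resid <- apply_residualizer(mod, fx$feats, fx$demog)
  expect_equal(max(abs(resid$double_age)), 0, tolerance = 1e-8)

  # feature independent of age/sex: coefficients near zero
  lm_fit <- stats::lm(independent ~ age + sex, data = cbind(fx$demog,
    independent = fx$feats$independent))
  se <- summary(lm_fit)$coefficients[-1, "Std. Error"]
  expect_lt(abs(mod$coefficients["age", "independent"]), 3 * se[1])
  expect_lt(abs(mod$coefficients["sex", "independent"]), 3 * se[2])

  # OLS orthogonality on the training fold
  expect_lt(abs(stats::cor(resid$confounded, fx$demog$age)), 1e-10)
  expect_lt(abs(stats::cor(resid$confounded,
                           as.integer(fx$demog$sex == "F"))), 1e-10)
})

test_that("residualizer matches lm residuals and hand arithmetic", {
  fx <- make_adjust_fixture(n = 50, seed = 2)
  mod <- fit_residualizer(fx$feats, fx$demog)
  resid <- apply_residualizer(mod, fx$feats, fx$demog)
  lm_fit <- stats::lm(confounded ~ age + sex,
                      data = cbind(fx$demog,
                                   confounded = fx$feats$confounded))
  expect_equal(resid$confounded, unname(stats::residuals(lm_fit)),
               tolerance = 1e-9)

  # hand-computed application on a new subject
  new_demog <- tibble::tibble(subject_id = "new", age = 70,
                              sex = factor("F", levels = c("M", "F")))
  new_feats <- tibble::tibble(subject_id = "new", double_age = 150,
                              confounded = 30, independent = 1)
  out <- apply_residualizer(mod, new_feats, new_demog)
  b <- mod$coefficients[, "confounded"]
  expect_equal(out$confounded, 30 - (b[1] + b[2] * 70 + b[3] * 1),
               ignore_attr = TRUE)
})

test_that("held-out residual means are not re-centred (no refit leak)", {
  fx <- make_adjust_fixture(n = 100, seed = 3)
  mod <- fit_residualizer(fx$feats, fx$demog)
  shifted <- fx$feats
  shifted$confounded <- shifted$confounded + 10
  out <- apply_residualizer(mod, shifted, fx$demog)
  expect_gt(abs(mean(out$confounded)), 5)
})

test_that("rank-deficient designs warn and fall back to pseudoinverse", {
  fx <- make_adjust_fixture(n = 20, seed = 4)
  fx$demog$sex <- factor("F", levels = c("M", "F"))
  expect_warning(fit_residualizer(fx$feats, fx$demog), "rank-deficient")
})

test_that("standardizer reproduces hand-computed z-scores", {
  train <- tibble::tibble(subject_id = c("a", "b", "c"), x = c(1, 2, 3))
  std <- fit_standardizer(train)
  expect_equal(std$mu[["x"]], 2)
  expect_equal(std$sigma[["x"]], sqrt(2 / 3), tolerance = 1e-12)
  test <- tibble::tibble(subject_id = "d", x = 4)
  z <- apply_standardizer(std, test)
  expect_equal(z$x, 2 / sqrt(2 / 3), tolerance = 1e-4)
  expect_equal(z$x, 2.449, tolerance = 1e-3)

  # centering: a test value at the train mean maps to 0
  expect_equal(apply_standardizer(
    std, tibble::tibble(subject_id = "e", x = 2))$x, 0)

  # sample-sd convention toggle
  std_s <- fit_standardizer(train, sd_convention = "sample")
  expect_equal(std_s$sigma[["x"]], 1)
})

test_that("standardized training folds have mean 0 and unit variance", {
  fx <- make_adjust_fixture(n = 60, seed = 5)
  std <- fit_standardizer(fx$feats)
  z <- apply_standardizer(std, fx$feats)
  for (col in c("double_age", "confounded", "independent")) {
    expect_lt(abs(mean(z[[col]])), 1e-10)
    n <- nrow(z)
    expect_equal(stats::sd(z[[col]]) * sqrt((n - 1) / n), 1,
                 tolerance = 1e-10)
  }
})

test_that("constant features are flagged at fit and standardize to zero", {
  train <- tibble::tibble(subject_id = c("a", "b"), x = c(1, 1))
  expect_warning(std <- fit_standardizer(train), "constant")
  z <- apply_standardizer(std, train)
  expect_equal(z$x, c(0, 0))
})

test_that("unfitted transforms refuse to apply", {
  feats <- tibble::tibble(subject_id = "a", x = 1)
  expect_error(apply_residualizer(list(), feats, NULL), "not been fitted")
  expect_error(apply_standardizer(list(), feats), "not been fitted")
  expect_error(apply_adjustment(list(), feats, NULL), "not been fitted")
})

test_that("full pipeline removes age/sex correlation on the training fold", {
  fx <- make_adjust_fixture(n = 150, seed = 6)
  # double_age is perfectly explained by age, hence constant after
  # residualization
  adj <- suppressWarnings(
    fit_adjustment(fx$feats, fx$demog, passthrough = character(0)))
  z <- apply_adjustment(adj, fx$feats, fx$demog)
  for (col in c("confounded", "independent")) {
    expect_lt(abs(stats::cor(z[[col]], fx$demog$age)), 1e-10)
    expect_lt(abs(stats::cor(z[[col]],
                             as.integer(fx$demog$sex == "F"))), 1e-10)
    n <- nrow(z)
    expect_equal(stats::sd(z[[col]]) * sqrt((n - 1) / n), 1,
                 tolerance = 1e-10)
  }
})

test_that("fitted parameters depend only on the training fold", {
  fx <- make_adjust_fixture(n = 80, seed = 7)
  train <- fx$feats[1:60, ]
  adj1 <- fit_adjustment(train, fx$demog, passthrough = character(0))
  # perturb held-out subjects wildly; refitted parameters identical
  fx$feats[61:80, -1] <- fx$feats[61:80, -1] * 1000
  adj2 <- fit_adjustment(fx$feats[1:60, ], fx$demog,
                         passthrough = character(0))
  expect_identical(adj1$residualizer$coefficients,
                   adj2$residualizer$coefficients)
  expect_identical(adj1$standardizer$mu, adj2$standardizer$mu)
  expect_identical(adj1$standardizer$sigma, adj2$standardizer$sigma)
})

test_that("residualized features reduce age leakage into decision scores", {
  cfg <- cohort_config(
    n_per_group = c(CN = 110, MCI = 0, ADD = 110), seed = 13,
    effect_config = list("Left-Hippocampus" = c(MCI = 0, ADD = -0.8)),
    confound_config = list(".all" = c(age = -0.08, sex = 0)))
  coh <- generate_cohort(cfg)
  feats <- etiv_normalize(generate_mo_ms_features(coh, cfg), coh)
  feats <- feats[, c("subject_id", mo_feature_names())]
  y <- as.integer(coh$diagnosis == "ADD")
  demog <- coh[, c("subject_id", "age", "sex")]

  score_cor <- function(tbl) {
    x <- as.matrix(tbl[, -1])
    colnames(x) <- paste0("f", seq_len(ncol(x)))
    fit <- glmnet::glmnet(x, factor(y), family = "binomial", alpha = 0,
                          lambda = 0.05)
    s <- as.numeric(stats::predict(fit, x, type = "link"))
    abs(stats::cor(s, coh$age))
  }
  raw_cor <- score_cor(feats)
  adj <- fit_adjustment(feats, demog, passthrough = character(0))
  resid_cor <- score_cor(apply_adjustment(adj, feats, demog))
  expect_lt(resid_cor, raw_cor)
})

test_that("tidy() exposes residualizer coefficients in long form", {
  fx <- make_adjust_fixture(n = 30, seed = 8)
  td <- tidy(fit_residualizer(fx$feats, fx$demog))
  expect_equal(nrow(td), 3 * 3)
  expect_setequal(unique(td$term), c("intercept", "age", "sex"))
})
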