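# shared fixture builders: small, fast synthetic inputs

quiet_config <- function(n_cn = 10, n_mci = 0, n_add = 10, seed = 1L, ...) {
  cohort_config(n_per_group = c(CN = n_cn, MCI = n_mci, ADD = n_add),
                seed = seed, ...)
}

# configuration with every stochastic element switched off: all subjects
# in a group are copies of the group template
frozen_config <- function(n_cn = 3, n_mci = 3, n_add = 3, seed = 1L) {
  dem <- default_demographics()
  dem$age_sd <- 0
  dem$edu_sd <- 0
  dem$mmse_sd <- 0
  dem$p_male <- 1
  cohort_config(
    n_per_group = c(CN = n_cn, MCI = n_mci, ADD = n_add), seed = seed,
    demographics = dem, etiv_sd = 0,
    abeta_prev = c(CN = 0, MCI = 0, ADD = 0),
    effect_config = list(), confound_config = list(),
    noise_sd = 0,
    connectome = list(noise_sdlog = 0, atten = c(CN = 1, MCI = 1, ADD = 1)),
    mmse = list(noise_sd = 0, followup_sd_months = 0)
  )
}

# a small labeled symmetric test matrix
toy_matrix <- function(n = 5, seed = 1, density = 0.7) {
  set.seed(seed)
  m <- matrix(0, n, n)
  w <- stats::runif(n * (n - 1) / 2)
  w[stats::runif(length(w)) > density] <- 0
  m[upper.tri(m)] <- w
  m <- m + t(m)
  dimnames(m) <- list(paste0("R", seq_len(n)), paste0("R", seq_len(n)))
  m
}

# assembled task data for nested-CV tests: MO features only, CN vs ADD
toy_task_data <- function(n_per_class = 20, seed = 3L, effects = NULL) {
  cfg <- cohort_config(
    n_per_group = c(CN = n_per_class, MCI = 0, ADD = n_per_class),
    seed = seed,
    effect_config = effects %||% default_effect_config())
  coh <- generate_cohort(cfg)
  feats <- etiv_normalize(generate_mo_ms_features(coh, cfg), coh)
  list(cohort = coh,
       features = feats[, c("subject_id", mo_feature_names())],
       target = as.integer(coh$diagnosis == "ADD"),
       demographics = coh[, c("subject_id", "age", "sex")])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
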