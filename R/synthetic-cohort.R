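#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the synthetic Alzheimer's cohort: group sizes,
#' per-group demographic sampling distributions, amyloid prevalence,
#' planted group effects on imaging features, linear age/sex confound
#' loadings, connectome template parameters, and MMSE trajectory dynamics.
#' Defaults emulate the demographic and clinical structure of a
#' 394-subject ADNI-style staging cohort (228 CN, 120 MCI, 46 ADD):
#' group-wise age means/sds, male proportions, education, baseline MMSE,
#' and amyloid-positive prevalences track the published cohort table;
#' disease effects are standardized mean shifts (medial-temporal atrophy,
#' ventricular enlargement, raised diffusivity in ADD, intermediate in
#' MCI).
#'
#' @param n_per_group named integer vector `c(CN=, MCI=, ADD=)`
#' @param seed integer master seed; every subject draws from a substream
#'   keyed by `(seed, subject index)` so adding subjects never perturbs
#'   existing draws
#' @param demographics tibble with one row per group (columns `diagnosis`,
#'   `age_mean`, `age_sd`, `age_min`, `age_max`, `p_male`, `edu_mean`,
#'   `edu_sd`, `mmse_mean`, `mmse_sd`)
#' @param etiv_mean,etiv_sd estimated total intracranial volume sampling
#'   parameters, mm^3
#' @param abeta_prev named vector of amyloid-positive prevalence per group
#' @param effect_config named list: feature name -> `c(MCI=, ADD=)`
#'   standardized mean shifts relative to CN
#' @param confound_config named list: feature name (or `".all"` default) ->
#'   `c(age=, sex=)` loadings in feature-sd units (age centered at 74 y,
#'   per year; sex is the female shift)
#' @param noise_sd residual noise, in feature-sd units
#' @param connectome list of connectome template parameters: `density`,
#'   `decay`, `base_scale`, `atten` (named multiplicative attenuation per
#'   group on targeted edges), `target_regions`, `noise_sdlog`
#' @param mmse list of trajectory parameters: `rates` (points/year per
#'   group), `noise_sd`, `followup_mean_months`, `followup_sd_months`,
#'   `min_months`, `n_visits`
#' @return object of class `cohort_config`
#' @export
cohort_config <- function(n_per_group = c(CN = 228L, MCI = 120L, ADD = 46L),
                          seed = 1L,
                          demographics = default_demographics(),
                          etiv_mean = 1.55e6, etiv_sd = 1.5e5,
                          abeta_prev = c(CN = 138 / 228, MCI = 60 / 120,
                                         ADD = 37 / 46),
                          effect_config = default_effect_config(),
                          confound_config = list(".all" = c(age = -0.02,
                                                            sex = 0.1)),
                          noise_sd = 1,
                          connectome = list(),
                          mmse = list()) {
  stopifnot(all(c("CN", "MCI", "ADD") %in% names(n_per_group)))
  n_per_group <- as.integer(n_per_group[c("CN", "MCI", "ADD")])
  names(n_per_group) <- c("CN", "MCI", "ADD")
  if (any(n_per_group < 0)) stop("group counts must be >= 0", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("noise_sd must be >= 0", call. = FALSE)
  if (any(abeta_prev < 0 | abeta_prev > 1))
    stop("abeta prevalences must lie in [0, 1]", call. = FALSE)
  if (any(demographics$age_sd < 0) || any(demographics$edu_sd < 0) ||
      any(demographics$mmse_sd < 0) || etiv_sd < 0)
    stop("sampling sds must be >= 0", call. = FALSE)

  conn <- utils::modifyList(list(
    density = 0.3, decay = 0.4, base_scale = 50,
    atten = c(CN = 1, MCI = 0.85, ADD = 0.7),
    target_regions = default_target_regions(),
    noise_sdlog = 0.25
  ), connectome)
  mm <- utils::modifyList(list(
    rates = c(CN = -0.1, MCI = -0.9, ADD = -2.8),
    noise_sd = 0.8,
    followup_mean_months = 79.2, followup_sd_months = 18,
    min_months = 12, n_visits = 3L
  ), mmse)

  structure(list(
    n_per_group = n_per_group, seed = as.integer(seed),
    demographics = demographics, etiv_mean = etiv_mean, etiv_sd = etiv_sd,
    abeta_prev = abeta_prev, effect_config = effect_config,
    confound_config = confound_config, noise_sd = noise_sd,
    connectome = conn, mmse = mm
  ), class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_demographics <- function() {
  tibble::tribble(
    ~diagnosis, ~age_mean, ~age_sd, ~age_min, ~age_max, ~p_male,
    ~edu_mean, ~edu_sd, ~mmse_mean, ~mmse_sd,
    "CN",  73.48, 7.51, 55, 96, 129 / 228, 16.71, 2.23, 28.89, 1.35,
    "MCI", 74.65, 8.57, 55, 96,  55 / 120, 16.13, 2.65, 27.69, 2.11,
    "ADD", 75.48, 9.30, 55, 96,  22 / 46,  15.35, 2.51, 21.39, 4.27
  )
}

#' @rdname cohort_config
#' @export
default_effect_config <- function() {
  add <- c(
    "Left-Hippocampus" = -1.2, "Right-Hippocampus" = -1.2,
    "Left-Amygdala" = -0.9, "Right-Amygdala" = -0.9,
    "Left-Accumbens-area" = -0.6, "Right-Accumbens-area" = -0.6,
    "Left-Thalamus" = -0.5, "Right-Thalamus" = -0.5,
    "Left-Putamen" = -0.5, "Right-Putamen" = -0.5,
    "Left-Lateral-Ventricle" = 0.9, "Right-Lateral-Ventricle" = 0.9,
    "BPV" = -0.6,
    "ctx-lh-entorhinal" = -1.0, "ctx-rh-entorhinal" = -1.0,
    "ctx-lh-inferiortemporal" = -0.7, "ctx-rh-inferiortemporal" = -0.7,
    "ctx-lh-middletemporal" = -0.7, "ctx-rh-middletemporal" = -0.7,
    "ctx-lh-fusiform" = -0.5, "ctx-rh-fusiform" = -0.5,
    "wholebrain-MD" = 1.0, "wholebrain-FA" = -0.7,
    "Left-Hippocampus-MD" = 1.1, "Right-Hippocampus-MD" = 1.1,
    "skeleton-FA" = -0.8
  )
  lapply(stats::setNames(names(add), names(add)),
         function(f) c(MCI = unname(add[f]) / 2, ADD = unname(add[f])))
}

#' @rdname cohort_config
#' @export
default_target_regions <- function() {
  c("Left-Hippocampus", "Right-Hippocampus",
    "ctx-lh-entorhinal", "ctx-rh-entorhinal",
    "ctx-lh-middletemporal", "ctx-rh-middletemporal",
    "ctx-lh-inferiortemporal", "ctx-rh-inferiortemporal",
    "ctx-lh-temporalpole", "ctx-rh-temporalpole")
}

# substream seed for subject idx (idx = 0 reserved for the template),
# kept well below 2^31
.subject_seed <- function(seed, idx) {
  (((seed %% 100003L) + 7L) * 10007L + idx) %% 2147483647L
}

.with_substream <- function(seed, idx, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.subject_seed(seed, idx))
  force(code)
}

.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  k <- 0L
  while (length(bad) > 0 && k < 1000L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
    k <- k + 1L
  }
  pmin(pmax(x, lo), hi)
}

#' Generate a synthetic cohort
#'
#' Draws one subject record per row: diagnosis, age, sex, education, eTIV,
#' amyloid status and baseline MMSE, each from the configured per-group
#' distribution. Deterministic for a fixed seed; each subject has its own
#' RNG substream.
#'
#' @param config a [cohort_config()]
#' @return tibble with columns `subject_id`, `diagnosis`, `age`, `sex`,
#'   `education`, `etiv`, `abeta_status`, `mmse_baseline`
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_per_group
  if (sum(n) == 0) stop("all group counts are zero: empty cohort",
                        call. = FALSE)
  groups <- rep(c("CN", "MCI", "ADD"), times = n)
  dem <- config$demographics
  rows <- purrr::map(seq_along(groups), function(i) {
    g <- groups[i]
    d <- dem[dem$diagnosis == g, ]
    .with_substream(config$seed, i, {
      age <- .rtrunc_norm(1, d$age_mean, d$age_sd, d$age_min, d$age_max)
      sex <- if (stats::runif(1) < d$p_male) "M" else "F"
      edu <- round(.rtrunc_norm(1, d$edu_mean, d$edu_sd, 6, 20))
      etiv <- .rtrunc_norm(1, config$etiv_mean, config$etiv_sd,
                           0.5 * config$etiv_mean, 1.5 * config$etiv_mean)
      ab <- as.integer(stats::runif(1) < config$abeta_prev[[g]])
      mmse <- min(30, max(0, round(stats::rnorm(1, d$mmse_mean, d$mmse_sd))))
      tibble::tibble(
        subject_id = sprintf("S%04d", i), diagnosis = g, age = age,
        sex = sex, education = edu, etiv = etiv, abeta_status = ab,
        mmse_baseline = mmse
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  out$diagnosis <- factor(out$diagnosis, levels = c("CN", "MCI", "ADD"))
  out$sex <- factor(out$sex, levels = c("M", "F"))
  out
}

# baseline templates: volumes as fraction of eTIV (so eTIV normalization is
# meaningful), cortical thickness in mm, diffusion summaries on their
# physical scales; `sd` is the between-subject sd on the same scale
.feature_templates <- function() {
  sv_frac <- c(
    "Thalamus" = 0.0045, "Caudate" = 0.0022, "Putamen" = 0.0030,
    "Pallidum" = 0.0011, "Hippocampus" = 0.0024, "Amygdala" = 0.0010,
    "Accumbens-area" = 0.00035
  )
  sv <- tibble::tibble(
    feature = sv_feature_names(),
    mean = c(rep(unname(sv_frac), 2), 0.008, 0.008, 0.0012,
             rep(6e-4, 5)),
    sd = c(rep(unname(sv_frac) * 0.08, 2), 0.008 * 0.3, 0.008 * 0.3,
           0.0012 * 0.3, rep(6e-4 * 0.15, 5)),
    kind = "volume_fraction"
  )
  ct <- tibble::tibble(
    feature = ct_feature_names(), mean = 2.5, sd = 0.12, kind = "thickness"
  )
  bpv <- tibble::tibble(feature = "BPV", mean = 0.75, sd = 0.03,
                        kind = "volume_fraction")
  ms <- tibble::tibble(
    feature = ms_feature_names(),
    mean = c(0.38, 7.8e-4, 9.5e-4, 9.5e-4, 0.45),
    sd = c(0.02, 0.4e-4, 0.6e-4, 0.6e-4, 0.025),
    kind = "diffusion"
  )
  dplyr::bind_rows(sv, ct, bpv, ms)
}

.resolve_loading <- function(confound_config, feature) {
  if (!is.null(confound_config[[feature]])) return(confound_config[[feature]])
  if (!is.null(confound_config[[".all"]])) return(confound_config[[".all"]])
  c(age = 0, sex = 0)
}

#' Generate morphometric and microstructural features
#'
#' Produces the 96 imaging feature columns per subject: 22 subcortical/
#' ventricular/callosal volumes (mm^3, generated as fraction-of-eTIV times
#' the subject's eTIV), 68 cortical thicknesses (mm, eTIV-independent),
#' brain parenchymal volume, and the 5 diffusion summaries. Each feature is
#' baseline + planted group effect + linear age/sex confound + Gaussian
#' noise, all expressed in feature-sd units before mapping back to the
#' physical scale.
#'
#' @param cohort tibble from [generate_cohort()]
#' @param config the same [cohort_config()]
#' @return tibble: `subject_id` plus 96 feature columns (91 MO then 5 MS)
#' @export
generate_mo_ms_features <- function(cohort, config = cohort_config()) {
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  tpl <- .feature_templates()
  known <- tpl$feature
  bad <- setdiff(names(config$effect_config), known)
  if (length(bad) > 0)
    stop("unknown feature name(s) in effect_config: ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(setdiff(names(config$confound_config), ".all"), known)
  if (length(bad) > 0)
    stop("unknown feature name(s) in confound_config: ",
         paste(bad, collapse = ", "), call. = FALSE)

  p <- nrow(tpl)
  eff_mci <- eff_add <- stats::setNames(numeric(p), tpl$feature)
  for (f in names(config$effect_config)) {
    eff_mci[f] <- config$effect_config[[f]][["MCI"]]
    eff_add[f] <- config$effect_config[[f]][["ADD"]]
  }
  loads <- t(vapply(tpl$feature,
                    function(f) .resolve_loading(config$confound_config, f),
                    numeric(2)))

  vals <- matrix(NA_real_, nrow(cohort), p,
                 dimnames = list(NULL, tpl$feature))
  for (i in seq_len(nrow(cohort))) {
    g <- as.character(cohort$diagnosis[i])
    eff <- switch(g, CN = numeric(p), MCI = eff_mci, ADD = eff_add)
    conf <- loads[, "age"] * (cohort$age[i] - 74) +
      loads[, "sex"] * (cohort$sex[i] == "F")
    z <- .with_substream(config$seed, 100000L + i,
                         stats::rnorm(p, 0, config$noise_sd))
    x <- tpl$mean + tpl$sd * (eff + conf + z)
    vol <- tpl$kind == "volume_fraction"
    x[vol] <- pmax(x[vol], 1e-8) * cohort$etiv[i]
    x[!vol] <- pmax(x[!vol], 1e-8)
    vals[i, ] <- x
  }
  dplyr::bind_cols(tibble::tibble(subject_id = cohort$subject_id),
                   tibble::as_tibble(vals))
}

#' Generate structural connectomes
#'
#' Builds a shared distance-penalized random-geometric template (82 nodes
#' on the unit cube, edge weight decaying with distance, thresholded at the
#' configured density), then derives one symmetric non-negative matrix per
#' subject: multiplicative group attenuation on edges incident to the
#' configured target regions, plus log-normal subject noise (unit mean).
#'
#' @inheritParams generate_mo_ms_features
#' @param labels node labels (default the 82-region roster)
#' @return named list of 82x82 symmetric matrices, one per subject
#' @export
generate_connectomes <- function(cohort, config = cohort_config(),
                                 labels = connectome_labels()) {
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  cc <- config$connectome
  n <- length(labels)
  tmpl <- .with_substream(config$seed, 0L, {
    xyz <- matrix(stats::runif(3 * n), n, 3)
    d <- as.matrix(stats::dist(xyz))
    w <- exp(-d / cc$decay)
    diag(w) <- 0
    thr <- stats::quantile(w[upper.tri(w)], probs = 1 - cc$density)
    w[w < thr] <- 0
    w * cc$base_scale
  })
  dimnames(tmpl) <- list(labels, labels)
  if (!isTRUE(all.equal(tmpl, t(tmpl))))
    stop("connectome template is not symmetric", call. = FALSE)

  target <- intersect(cc$target_regions, labels)
  is_target_edge <- outer(labels %in% target, labels %in% target, `|`)

  out <- purrr::map(seq_len(nrow(cohort)), function(i) {
    g <- as.character(cohort$diagnosis[i])
    att <- cc$atten[[g]]
    m <- tmpl
    m[is_target_edge] <- m[is_target_edge] * att
    if (cc$noise_sdlog > 0) {
      noise <- .with_substream(config$seed, 300000L + i, {
        e <- matrix(stats::rnorm(n * n, -cc$noise_sdlog^2 / 2,
                                 cc$noise_sdlog), n, n)
        e[lower.tri(e)] <- t(e)[lower.tri(e)]
        exp(e)
      })
      m <- m * noise
    }
    m <- (m + t(m)) / 2
    diag(m) <- 0
    m
  })
  stats::setNames(out, cohort$subject_id)
}

#' Generate longitudinal MMSE trajectories
#'
#' Adds a nested `mmse_visits` list-column to the cohort: per subject,
#' `n_visits` visits at months 0 .. final follow-up, where the final
#' follow-up is drawn around the configured mean (default 79.2 months, i.e.
#' a 6.6-year mean follow-up). MMSE follows
#' baseline + rate x years + noise, clipped to \[0, 30\].
#'
#' @inheritParams generate_mo_ms_features
#' @return cohort tibble with an added `mmse_visits` list-column (each
#'   element a tibble `months_from_baseline`, `mmse`, sorted by time)
#' @export
generate_mmse_trajectories <- function(cohort, config = cohort_config()) {
  mm <- config$mmse
  if (any(is.na(mm$rates[c("CN", "MCI", "ADD")])))
    stop("per-group decline rates must be configured", call. = FALSE)
  if (mm$min_months < 0 || mm$followup_mean_months < 0)
    stop("visit spacing must be non-negative", call. = FALSE)
  visits <- purrr::map(seq_len(nrow(cohort)), function(i) {
    g <- as.character(cohort$diagnosis[i])
    .with_substream(config$seed, 200000L + i, {
      final <- max(mm$min_months,
                   stats::rnorm(1, mm$followup_mean_months,
                                mm$followup_sd_months))
      months <- seq(0, final, length.out = max(2L, mm$n_visits))
      noise <- c(0, stats::rnorm(length(months) - 1, 0, mm$noise_sd))
      mmse <- cohort$mmse_baseline[i] + mm$rates[[g]] * months / 12 + noise
      tibble::tibble(months_from_baseline = months,
                     mmse = pmin(30, pmax(0, mmse)))
    })
  })
  out <- cohort
  out$mmse_visits <- visits
  out
}

#' Flatten nested MMSE visits to long format
#'
#' @param cohort cohort with an `mmse_visits` list-column
#' @return long tibble `subject_id`, `months_from_baseline`, `mmse`
#' @export
mmse_long <- function(cohort) {
  stopifnot("mmse_visits" %in% names(cohort))
  cohort |>
    dplyr::select("subject_id", "mmse_visits") |>
    tidyr::unnest("mmse_visits")
}

#' Read and write connectome TSV files
#'
#' Connectomes are exchanged as TSV with the region labels as header row
#' and first column.
#'
#' @param mat symmetric non-negative matrix with label dimnames
#' @param path file path
#' @return `read_connectome_tsv()` returns the labeled matrix.
#' @export
write_connectome_tsv <- function(mat, path) {
  df <- data.frame(region = rownames(mat), mat, check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_connectome_tsv
#' @export
read_connectome_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
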