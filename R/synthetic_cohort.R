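#' Configuration for the synthetic periampullary cohort generator
#'
#' Defines the study conditions the generator emulates: 117 patients (72
#' malignant, 45 benign), 28 panel metabolites with 16 planted group effects
#' (15 reduced in malignancy, Glutamic acid elevated), six neoadjuvant
#' patients and seven post-surgery sampling dates with benign-like profiles,
#' two measurement batches sharing nine bridge samples with per-metabolite
#' multiplicative batch factors, and Weibull proportional-hazards survival
#' with a protective Phenylalanine effect and a high target RFS-OS
#' correlation.
#'
#' @param n_total Total patient count.
#' @param n_malignant,n_benign Group sizes; must sum to `n_total`.
#' @param n_neoadjuvant Malignant patients treated with neoadjuvant
#'   chemotherapy before sampling; their metabolite profiles are drawn from
#'   the benign distribution.
#' @param n_post_surgery Samples with a post-surgery collection date; one of
#'   them coincides with a neoadjuvant patient.
#' @param metabolite_names Ordered metabolite panel (28 names by default).
#' @param effect_metabolites_down Metabolites shifted downwards in the
#'   malignant group (log2 scale).
#' @param effect_metabolites_up Metabolites shifted upwards in the malignant
#'   group (default Glutamic acid only).
#' @param effect_size Log2-scale mean shift applied to effect metabolites.
#' @param correlation_blocks List of `list(metabolites=, rho=)` entries
#'   inducing within-block correlation through a Gaussian copula on the log
#'   scale. Defaults to a BCAA block and a 3-carbon amino-acid block.
#' @param batch_factors Per-metabolite multiplicative factors applied to
#'   batch-2 measurements (all > 0).
#' @param n_bridge Number of bridge samples measured in both batches.
#' @param survival_params List of survival-generator parameters: Weibull
#'   `shape`, `scale_malignant` and `scale_benign` (months),
#'   `phe_loghr` (log-hazard per centered log2 unit of Phenylalanine,
#'   negative = protective), censoring windows `censor_min`/`censor_max`
#'   (malignant) and `benign_censor_min`/`benign_censor_max`,
#'   `target_rfs_os_cor`, and the relapse-to-death lag shape
#'   `lag_median`/`lag_sdlog` (months, log-normal).
#' @param missing_rates Completely-at-random missingness rates for `bmi`,
#'   `nutrition`, `handling` and `ca19_9`.
#' @param seed Integer seed; identical configurations yield bit-identical
#'   cohorts.
#'
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_total = 117L,
                             n_malignant = 72L,
                             n_benign = 45L,
                             n_neoadjuvant = 6L,
                             n_post_surgery = 7L,
                             metabolite_names = periamp_metabolites(),
                             effect_metabolites_down = periamp_effect_metabolites(),
                             effect_metabolites_up = "Glutamic acid",
                             effect_size = 1.0,
                             correlation_blocks = list(
                               list(metabolites = c("Valine", "Leucine", "Isoleucine"), rho = 0.7),
                               list(metabolites = c("Alanine", "Glycine", "Serine"), rho = 0.6)),
                             batch_factors = NULL,
                             n_bridge = 9L,
                             survival_params = list(),
                             missing_rates = list(bmi = 2 / 117, nutrition = 6 / 117,
                                                  handling = 8 / 117, ca19_9 = 32 / 117),
                             seed = 1L) {
  sp <- list(shape = 1.2, scale_malignant = 27, scale_benign = 130,
             phe_loghr = -1.0, censor_min = 40, censor_max = 110,
             benign_censor_min = 24, benign_censor_max = 135,
             target_rfs_os_cor = 0.94, lag_median = 6.9, lag_sdlog = 0.7)
  sp[names(survival_params)] <- survival_params
  if (is.null(batch_factors))
    batch_factors <- seq(0.7, 1.4, length.out = length(metabolite_names))
  if (length(batch_factors) != length(metabolite_names))
    stop("invalid config: batch_factors must have one entry per metabolite",
         call. = FALSE)
  if (is.null(names(batch_factors))) names(batch_factors) <- metabolite_names
  cfg <- structure(list(
    n_total = as.integer(n_total), n_malignant = as.integer(n_malignant),
    n_benign = as.integer(n_benign), n_neoadjuvant = as.integer(n_neoadjuvant),
    n_post_surgery = as.integer(n_post_surgery),
    metabolite_names = metabolite_names,
    effect_metabolites_down = effect_metabolites_down,
    effect_metabolites_up = effect_metabolites_up,
    effect_size = effect_size,
    correlation_blocks = correlation_blocks,
    batch_factors = batch_factors,
    n_bridge = as.integer(n_bridge),
    survival_params = sp,
    missing_rates = missing_rates,
    seed = as.integer(seed)), class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    if (n_malignant + n_benign != n_total)
      stop("invalid config: n_malignant + n_benign must equal n_total", call. = FALSE)
    if (n_neoadjuvant > n_malignant)
      stop("invalid config: n_neoadjuvant must not exceed n_malignant", call. = FALSE)
    if (n_bridge > n_total)
      stop("invalid config: n_bridge must not exceed n_total", call. = FALSE)
    if (length(intersect(effect_metabolites_down, effect_metabolites_up)) > 0)
      stop("invalid config: effect_metabolites_down and effect_metabolites_up must be disjoint",
           call. = FALSE)
    if (!all(effect_metabolites_down %in% metabolite_names) ||
        !all(effect_metabolites_up %in% metabolite_names))
      stop("invalid config: effect metabolites must be a subset of metabolite_names",
           call. = FALSE)
    if (any(batch_factors <= 0))
      stop("invalid config: all batch_factors must be > 0", call. = FALSE)
    for (b in correlation_blocks) {
      if (b$rho <= -1 || b$rho >= 1)
        stop("invalid config: correlation_blocks rho must lie in (-1, 1)", call. = FALSE)
      if (!all(b$metabolites %in% metabolite_names))
        stop("invalid config: correlation block names must be metabolites", call. = FALSE)
    }
    if (anyDuplicated(metabolite_names))
      stop("invalid config: metabolite_names must be unique", call. = FALSE)
  })
  invisible(cfg)
}

# derived sub-seeds for the generator's independent stages (kept < 2^31)
stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) + 104729 * stage) %% 2147483647)
}

block_correlation_matrix <- function(cfg) {
  p <- length(cfg$metabolite_names)
  sigma <- diag(p)
  dimnames(sigma) <- list(cfg$metabolite_names, cfg$metabolite_names)
  for (b in cfg$correlation_blocks) {
    idx <- match(b$metabolites, cfg$metabolite_names)
    sigma[idx, idx] <- b$rho
    diag(sigma)[idx] <- 1
  }
  sigma
}

#' Generate a synthetic cohort
#'
#' Draws per-patient true metabolite concentrations (log-normal per
#' metabolite, correlated within configured blocks through a Gaussian copula
#' on the log2 scale) and a clinical table. Malignant patients receive the
#' configured log2-scale shift on the effect metabolites, except neoadjuvant
#' and post-surgery patients whose profiles are drawn from the benign
#' distribution. Survival fields are filled by [generate_survival()] using
#' the patients' Phenylalanine levels.
#'
#' @param config A [synthetic_config()].
#' @return A list with `concentrations` (strictly positive `n_total` x 28
#'   matrix, rownames = sample ids) and `clinical` (data frame, one row per
#'   patient).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  n <- config$n_total
  mets <- config$metabolite_names
  set.seed(stage_seed(config$seed, 1L))

  ids <- sprintf("P%03d", seq_len(n))
  group <- factor(rep(c("malignant", "benign"), c(config$n_malignant, config$n_benign)),
                  levels = c("benign", "malignant"))
  mal_idx <- which(group == "malignant")
  ben_idx <- which(group == "benign")

  neoadjuvant <- rep(FALSE, n)
  neoadjuvant[sample(mal_idx, config$n_neoadjuvant)] <- TRUE

  # post-surgery draws: mostly malignant, one overlaps with neoadjuvant,
  # one benign patient
  post_surgery <- rep(FALSE, n)
  if (config$n_post_surgery > 0) {
    n_ps_mal <- max(config$n_post_surgery - 1L, 0L)
    ps_mal <- integer(0)
    if (n_ps_mal > 0) {
      overlap <- if (config$n_neoadjuvant > 0) sample(which(neoadjuvant), 1L) else integer(0)
      pool <- setdiff(mal_idx, which(neoadjuvant))
      ps_mal <- c(overlap, sample(pool, n_ps_mal - length(overlap)))
    }
    ps_ben <- sample(ben_idx, min(1L, config$n_post_surgery))
    post_surgery[c(ps_mal, ps_ben)] <- TRUE
  }

  # single metastatic-at-diagnosis and single non-standard-treatment patient,
  # untreated malignant cases
  plain_mal <- setdiff(mal_idx, which(neoadjuvant | post_surgery))
  special <- sample(plain_mal, min(2L, length(plain_mal)))
  metastatic <- rep(FALSE, n); metastatic[special[1]] <- TRUE
  nonstandard <- rep(FALSE, n); nonstandard[special[2]] <- TRUE

  # day-of-surgery (expected fasting) draws: 37 malignant / 27 benign
  day_of_surgery <- rep(FALSE, n)
  day_of_surgery[sample(mal_idx, min(37L, length(mal_idx)))] <- TRUE
  day_of_surgery[sample(ben_idx, min(27L, length(ben_idx)))] <- TRUE

  # metabolite profiles: benign-like = benign, neoadjuvant, or post-surgery
  sigma <- block_correlation_matrix(config)
  z <- matrix(rnorm(n * length(mets)), nrow = n) %*% chol(sigma)
  loc <- metabolite_log2_location(mets)
  scl <- metabolite_log2_scale(mets)
  log2conc <- sweep(sweep(z, 2, scl, `*`), 2, loc, `+`)
  dimnames(log2conc) <- list(ids, mets)

  shifted <- group == "malignant" & !neoadjuvant & !post_surgery
  down <- match(config$effect_metabolites_down, mets)
  up <- match(config$effect_metabolites_up, mets)
  log2conc[shifted, down] <- log2conc[shifted, down] - config$effect_size
  log2conc[shifted, up] <- log2conc[shifted, up] + config$effect_size
  conc <- 2^log2conc

  clinical <- data.frame(
    sample_id = ids,
    group = group,
    subtype = draw_subtype(group),
    neoadjuvant = neoadjuvant,
    post_surgery_sample = post_surgery,
    day_of_surgery_draw = day_of_surgery,
    handling = draw_with_na(sample(c("immediate", "overnight"), n, TRUE, c(0.35, 0.65)),
                            config$missing_rates$handling),
    age = round(pmin(pmax(rnorm(n, 66, 11), 31), 88), 1),
    sex = draw_sex(group),
    bmi = draw_with_na(round(pmin(pmax(rnorm(n, 24.5, 4), 14.5), 43), 1),
                       config$missing_rates$bmi),
    nutrition = draw_nutrition(group, config$missing_rates$nutrition),
    diabetes = runif(n) < ifelse(group == "malignant", 15 / 72, 11 / 45),
    blood_type = draw_blood_type(group),
    ca19_9 = draw_ca19_9(group, config$missing_rates$ca19_9),
    metastatic_at_diagnosis = metastatic,
    nonstandard_treatment = nonstandard,
    stringsAsFactors = FALSE)

  clinical <- generate_survival(clinical, config,
                                phenylalanine = log2conc[, "Phenylalanine"])
  list(concentrations = conc, clinical = clinical)
}

draw_with_na <- function(x, rate) {
  x[runif(length(x)) < rate] <- NA
  x
}

draw_subtype <- function(group) {
  out <- character(length(group))
  mal <- group == "malignant"
  out[mal] <- sample(c("PDAC", "Ampullary cancer", "Cholangiocarcinoma",
                       "Mucinous/IPMN-associated carcinoma", "Uncertain origin"),
                     sum(mal), TRUE, prob = c(59, 3, 5, 4, 1))
  out[!mal] <- sample(c("IPMN", "Pancreatitis", "Other benign"),
                      sum(!mal), TRUE, prob = c(15, 12, 18))
  out
}

draw_sex <- function(group) {
  # 64/117 male overall: 38 of 72 malignant, 26 of 45 benign
  out <- character(length(group))
  mal <- which(group == "malignant"); ben <- which(group != "malignant")
  out[mal] <- "female"; out[ben] <- "female"
  out[sample(mal, min(38L, length(mal)))] <- "male"
  out[sample(ben, min(26L, length(ben)))] <- "male"
  out
}

draw_nutrition <- function(group, rate) {
  out <- character(length(group))
  mal <- group == "malignant"
  out[mal] <- sample(c("none", "moderate", "severe"), sum(mal), TRUE, prob = c(27, 19, 23))
  out[!mal] <- sample(c("none", "moderate", "severe"), sum(!mal), TRUE, prob = c(36, 4, 2))
  draw_with_na(out, rate)
}

draw_blood_type <- function(group) {
  out <- character(length(group))
  mal <- group == "malignant"
  out[mal] <- sample(c("A", "B", "O", "AB"), sum(mal), TRUE, prob = c(42, 6, 23, 1))
  out[!mal] <- sample(c("A", "B", "O", "AB"), sum(!mal), TRUE, prob = c(24, 2, 15, 4))
  out
}

draw_ca19_9 <- function(group, rate) {
  out <- numeric(length(group))
  mal <- group == "malignant"
  out[mal] <- round(rlnorm(sum(mal), log(184.5), 1.6), 1)
  out[!mal] <- round(rlnorm(sum(!mal), log(15), 0.9), 1)
  draw_with_na(out, rate)
}

#' Generate survival outcomes for a synthetic cohort
#'
#' Fills OS and RFS fields. Malignant overall survival follows a Weibull
#' proportional-hazards model whose log hazard depends linearly on the
#' (centered) Phenylalanine level with the configured coefficient (negative
#' by default: higher Phenylalanine, longer survival), under independent
#' uniform censoring. RFS is OS minus a positive log-normal relapse-to-death
#' lag whose spread is scaled so the empirical RFS-OS Pearson correlation
#' among malignant event pairs tracks the configured target. Benign patients
#' have long survival and never relapse.
#'
#' @param clinical Clinical table from [generate_cohort()] (survival columns
#'   are overwritten).
#' @param config The [synthetic_config()] used.
#' @param phenylalanine Per-patient Phenylalanine values (log2 scale),
#'   aligned with `clinical` rows.
#' @return `clinical` with `os_months`, `os_event`, `rfs_months`,
#'   `rfs_event` columns filled.
#' @export
generate_survival <- function(clinical, config, phenylalanine) {
  if (length(phenylalanine) != nrow(clinical))
    stop("alignment error: phenylalanine values must match clinical rows", call. = FALSE)
  sp <- config$survival_params
  set.seed(stage_seed(config$seed, 2L))
  n <- nrow(clinical)
  mal <- clinical$group == "malignant"

  os <- numeric(n); ev <- logical(n)
  lp <- numeric(n)
  lp[mal] <- sp$phe_loghr * (phenylalanine[mal] - mean(phenylalanine[mal]))
  t_true <- numeric(n)
  u <- runif(n)
  t_true[mal] <- sp$scale_malignant * (-log(u[mal]) / exp(lp[mal]))^(1 / sp$shape)
  t_true[!mal] <- sp$scale_benign * (-log(u[!mal]))^(1 / sp$shape)
  cens <- numeric(n)
  cens[mal] <- runif(sum(mal), sp$censor_min, sp$censor_max)
  cens[!mal] <- runif(sum(!mal), sp$benign_censor_min, sp$benign_censor_max)
  os <- pmax(pmin(t_true, cens), 0.5)
  ev <- t_true <= cens

  # relapse-to-death lag, scaled to the target RFS-OS correlation under the
  # independence approximation sd_lag = sd_os * sqrt(1/r^2 - 1)
  rfs <- os; rev_ <- rep(FALSE, n)
  lag_raw <- rlnorm(n, log(sp$lag_median), sp$lag_sdlog)
  os_ev <- os[mal & ev]
  if (length(os_ev) >= 3 && sp$target_rfs_os_cor > 0 && sp$target_rfs_os_cor < 1) {
    sd_target <- sd(os_ev) * sqrt(1 / sp$target_rfs_os_cor^2 - 1)
    lag_raw <- lag_raw * sd_target / sd(lag_raw[mal & ev])
  }
  mal_ev <- mal & ev
  rfs[mal_ev] <- pmax(os[mal_ev] - lag_raw[mal_ev], 0.02 * os[mal_ev])
  rev_[mal_ev] <- TRUE

  clinical$os_months <- os
  clinical$os_event <- ev
  clinical$rfs_months <- rfs
  clinical$rfs_event <- rev_
  clinical
}

#' Split true concentrations into two bridged measurement batches
#'
#' Partitions the cohort into two LC-MS/MS batches. The bridge samples are
#' drawn from batch 1 and re-measured in batch 2, whose values (including the
#' bridge re-measurements) are multiplied per metabolite by the configured
#' batch factors. Total measurement rows = `n_total + n_bridge`.
#'
#' @param true_table Strictly positive concentration matrix from
#'   [generate_cohort()].
#' @param config The [synthetic_config()] used.
#' @return List with `batch1`, `batch2` (each a [metabolite_batch()]) and
#'   `bridge_ids`.
#' @export
split_batches <- function(true_table, config) {
  if (config$n_bridge > nrow(true_table))
    stop("invalid config: n_bridge must not exceed the number of samples", call. = FALSE)
  set.seed(stage_seed(config$seed, 3L))
  ids <- rownames(true_table)
  n1 <- ceiling(length(ids) / 2)
  ids1 <- sort(sample(ids, n1))
  ids2 <- setdiff(ids, ids1)
  bridge_ids <- sort(sample(ids1, config$n_bridge))

  fac <- config$batch_factors[colnames(true_table)]
  v1 <- true_table[ids1, , drop = FALSE]
  v2 <- sweep(true_table[c(ids2, bridge_ids), , drop = FALSE], 2, fac, `*`)
  list(
    batch1 = metabolite_batch("set1", v1, bridge_ids),
    batch2 = metabolite_batch("set2", v2, bridge_ids),
    bridge_ids = bridge_ids)
}

#' Write a synthetic cohort to disk
#'
#' Writes the two batch tables and the clinical table as CSV, the bridge IDs
#' as a plain-text list, and the configuration (including the seed) as JSON,
#' so a cohort can be re-ingested through [read_batch()].
#'
#' @param cohort Output of [generate_cohort()].
#' @param batches Output of [split_batches()].
#' @param config The [synthetic_config()] used (recorded, with its seed, in
#'   the output metadata).
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, batches, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("batch1.csv", "batch2.csv", "clinical.csv",
                            "bridge_ids.txt", "config.json"))
  for (i in 1:2) {
    b <- batches[[i]]
    df <- data.frame(sample_id = b$sample_ids, b$values, check.names = FALSE)
    write.csv(df, paths[i], row.names = FALSE)
  }
  write.csv(cohort$clinical, paths[3], row.names = FALSE)
  writeLines(batches$bridge_ids, paths[4])
  jsonlite::write_json(
    unclass(config)[c("n_total", "n_malignant", "n_benign", "n_neoadjuvant",
                      "n_post_surgery", "effect_size", "n_bridge", "seed")],
    paths[5], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
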