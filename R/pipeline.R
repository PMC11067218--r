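#' Principal component projection
#'
#' Projects the (already centered) analysis matrix onto its top
#' right-singular directions, with per-component explained-variance
#' fractions.
#'
#' @param values Centered samples-by-metabolites matrix.
#' @param n_components Number of components (at most `min(dim(values))`).
#' @return List with `scores` (samples x n_components), `explained`
#'   (fractions for the returned components, non-increasing) and
#'   `all_explained` (full spectrum, summing to 1).
#' @export
pca_project <- function(values, n_components = 2) {
  if (n_components > min(dim(values)))
    stop("n_components must not exceed min(samples, metabolites)", call. = FALSE)
  pc <- prcomp(values, center = FALSE, scale. = FALSE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained = frac[seq_len(n_components)],
       all_explained = frac)
}

#' Run the full cohort analysis pipeline
#'
#' Orchestrates every stage on either a synthetic cohort (generated from
#' `config`) or on ingested batch tables: bridge-sample normalization and
#' integration, per-metabolite benign-vs-malignant testing with FDR
#' control, group-wise Spearman correlations and their contrast, PCA,
#' resampled consensus clustering with CDF-based selection of k, the
#' cluster-centroid correlation classifier with ROC/AUC, and survival
#' analysis (exclusion filtering, RFS-OS correlation, Phenylalanine
#' mean-dichotomization with log-rank comparison, univariable Cox, and
#' backwards-elimination multivariable Cox). Fully deterministic given the
#' configuration seed.
#'
#' @param config A [synthetic_config()] (ignored when `input` is given must
#'   then be `NULL`).
#' @param input Optional list of ingested data: `batch1`, `batch2`
#'   ([metabolite_batch()] objects) and `clinical` (data frame). Exactly one
#'   of `config` / `input` must be active.
#' @param k_range,n_iterations,resample_fraction Consensus-clustering
#'   parameters (defaults 2:5, 1000, 0.8).
#' @param elbow_threshold Elbow cutoff for selecting k (default 0.1).
#' @param survival_covariates Covariate columns for the multivariable Cox
#'   model; `"phenylalanine"` refers to the centered log2 Phenylalanine
#'   level.
#' @param outdir Optional directory; when given, every stage table is
#'   written as CSV and the run report as JSON.
#' @return Object of class `run_report` (see Details) with per-stage
#'   results and summaries.
#' @export
run_pipeline <- function(config = synthetic_config(),
                         input = NULL,
                         k_range = 2:5,
                         n_iterations = 1000,
                         resample_fraction = 0.8,
                         elbow_threshold = 0.1,
                         survival_covariates = c("phenylalanine", "age", "sex", "diabetes"),
                         outdir = NULL) {
  if (!is.null(input) && !missing(config))
    stop("configuration error: supply either a synthetic config or input data, not both",
         call. = FALSE)

  if (is.null(input)) {
    cohort <- generate_cohort(config)
    batches <- split_batches(cohort$concentrations, config)
    clinical <- cohort$clinical
    b1 <- batches$batch1; b2 <- batches$batch2
    seed <- config$seed
  } else {
    b1 <- input$batch1; b2 <- input$batch2
    clinical <- input$clinical
    seed <- input$seed %||% 1L
  }

  # integration: reference-mean division, duplicate averaging, log2, centering
  b1n <- normalize_by_reference(b1, compute_bridge_reference(b1))
  b2n <- normalize_by_reference(b2, compute_bridge_reference(b2))
  merged <- merge_batches(b1n, b2n)
  mat <- log2_mean_center(merged)
  clinical <- clinical[match(rownames(mat), clinical$sample_id), ]
  groups <- factor(clinical$group, levels = c("benign", "malignant"))

  differential <- compare_groups(mat, groups)
  benign_cor <- correlation_matrix(mat, groups == "benign", "benign")
  malignant_cor <- correlation_matrix(mat, groups == "malignant", "malignant")
  delta <- delta_correlation(benign_cor, malignant_cor)
  pca <- pca_project(mat, 2)

  consensus <- consensus_run(mat, k_range = k_range, n_iterations = n_iterations,
                             resample_fraction = resample_fraction, seed = seed)
  selection <- cdf_and_select_k(consensus, elbow_threshold)
  clusters <- final_clusters(consensus, 2, groups)
  association <- cluster_disease_association(clusters, groups)

  model <- build_centroids(mat, groups, clusters)
  scores <- classify_samples(mat, model)
  roc <- roc_auc(scores$score, groups)

  survival_report <- pipeline_survival(mat, clinical, survival_covariates)

  report <- structure(list(
    seed = seed,
    n_samples = nrow(mat),
    n_benign = sum(groups == "benign"),
    n_malignant = sum(groups == "malignant"),
    matrix = mat,
    clinical = clinical,
    differential = differential,
    n_significant = sum(differential$q_value <= 0.05),
    correlations = list(benign = benign_cor, malignant = malignant_cor,
                        delta = delta),
    pca_explained = pca$explained,
    consensus = consensus,
    area = selection$area,
    delta_area = selection$delta_area,
    selected_k = selection$selected_k,
    clusters = clusters,
    cluster_table = association$table,
    cluster_fisher_p = association$p_value,
    centroids = model,
    scores = scores,
    auc = roc$auc,
    roc = roc,
    survival = survival_report), class = "run_report")
  if (!is.null(outdir)) write_run_report(report, outdir)
  report
}

pipeline_survival <- function(mat, clinical, survival_covariates) {
  included <- survival_exclusion_filter(clinical)
  phe <- mat[included$sample_id, "Phenylalanine"]
  ev <- included$os_event & included$rfs_event
  rfs_os_cor <- if (sum(ev) >= 3)
    pearson_correlation(included$os_months[ev], included$rfs_months[ev]) else NA_real_

  phe_group <- dichotomize_by_mean(phe)
  km <- lapply(split(seq_len(nrow(included)), phe_group), function(ix)
    km_estimate(included$os_months[ix], included$os_event[ix]))
  logrank <- survdiff(Surv(included$os_months, included$os_event) ~ phe_group)
  logrank_p <- pchisq(logrank$chisq, df = 1, lower.tail = FALSE)

  uni <- cox_fit(included$os_months, included$os_event,
                 data.frame(phenylalanine = phe))
  covs <- data.frame(phenylalanine = phe)
  for (v in setdiff(survival_covariates, "phenylalanine"))
    covs[[v]] <- included[[v]]
  keep <- stats::complete.cases(covs)
  trace <- cox_backwards_eliminate(included$os_months[keep],
                                   included$os_event[keep],
                                   covs[keep, , drop = FALSE])
  list(n_included = nrow(included),
       rfs_os_correlation = rfs_os_cor,
       phe_group = phe_group,
       km = km,
       logrank_p = logrank_p,
       univariable_phe = uni,
       elimination = trace)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Cohort analysis run report\n")
  cat(sprintf("  samples: %d (%d benign / %d malignant), seed %d\n",
              x$n_samples, x$n_benign, x$n_malignant, x$seed))
  cat(sprintf("  metabolites at FDR <= 0.05: %d of %d\n",
              x$n_significant, nrow(x$differential)))
  cat(sprintf("  PCA variance explained (PC1, PC2): %.1f%%, %.1f%%\n",
              100 * x$pca_explained[1], 100 * x$pca_explained[2]))
  cat(sprintf("  consensus clustering: selected k = %d\n", x$selected_k))
  print(x$cluster_table)
  cat(sprintf("  cluster-disease Fisher p = %.3g\n", x$cluster_fisher_p))
  cat(sprintf("  centroid classifier AUC = %.3f\n", x$auc))
  cat(sprintf("  survival: n = %d included, RFS-OS r = %.3f, log-rank p (Phe split) = %.3g\n",
              x$survival$n_included, x$survival$rfs_os_correlation,
              x$survival$logrank_p))
  hr <- x$survival$univariable_phe$coefficients
  cat(sprintf("  Phenylalanine univariable HR = %.2f (95%% CI %.2f-%.2f, p = %.3g)\n",
              hr$hazard_ratio, hr$ci_low, hr$ci_high, hr$p_value))
  cat(sprintf("  elimination retained: %s\n",
              paste(x$survival$elimination$final_variables, collapse = ", ")))
  invisible(x)
}

write_run_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) write.csv(x, file.path(outdir, f), row.names = TRUE)
  w(report$matrix, "metabolite_matrix.csv")
  write.csv(report$differential, file.path(outdir, "differential.csv"), row.names = FALSE)
  w(report$correlations$benign$rho, "rho_benign.csv")
  w(report$correlations$malignant$rho, "rho_malignant.csv")
  w(report$correlations$delta$delta, "rho_delta.csv")
  for (k in names(report$consensus$consensus))
    w(report$consensus$consensus[[k]], sprintf("consensus_k%s.csv", k))
  write.csv(data.frame(sample_id = names(report$clusters),
                       cluster = as.character(report$clusters)),
            file.path(outdir, "clusters.csv"), row.names = FALSE)
  write.csv(report$scores, file.path(outdir, "classifier_scores.csv"), row.names = FALSE)
  jsonlite::write_json(run_report_summary(report),
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

run_report_summary <- function(report) {
  elim <- report$survival$elimination
  list(seed = report$seed,
       n_samples = report$n_samples,
       n_benign = report$n_benign,
       n_malignant = report$n_malignant,
       n_significant = report$n_significant,
       pca_explained = report$pca_explained,
       selected_k = report$selected_k,
       delta_area = as.list(report$delta_area),
       cluster_table = as.vector(report$cluster_table),
       cluster_fisher_p = report$cluster_fisher_p,
       auc = report$auc,
       n_survival_included = report$survival$n_included,
       rfs_os_correlation = report$survival$rfs_os_correlation,
       logrank_p = report$survival$logrank_p,
       phenylalanine_hr = report$survival$univariable_phe$coefficients$hazard_ratio,
       eliminated = elim$trace$variable_removed,
       retained = elim$final_variables)
}
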