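#' Build cluster-restricted group centroids
#'
#' The benign centroid is the per-metabolite mean over the benign samples
#' inside the Benign cluster; the malignant centroid the mean over the
#' malignant samples inside the Malignant cluster.
#'
#' @param values Samples-by-metabolites matrix (centered log2 scale).
#' @param group_labels Per-sample disease status (benign/malignant).
#' @param cluster_labels Per-sample cluster assignment from
#'   [final_clusters()] at k = 2 (levels "Benign cluster" /
#'   "Malignant cluster").
#' @return Object of class `centroid_model`: list with `benign_centroid`,
#'   `malignant_centroid`, `metabolite_order`.
#' @export
build_centroids <- function(values, group_labels, cluster_labels) {
  ben <- group_labels == "benign" & cluster_labels == "Benign cluster"
  mal <- group_labels == "malignant" & cluster_labels == "Malignant cluster"
  if (!any(ben))
    stop("empty defining subset: no benign samples in the Benign cluster", call. = FALSE)
  if (!any(mal))
    stop("empty defining subset: no malignant samples in the Malignant cluster", call. = FALSE)
  structure(list(
    benign_centroid = colMeans(values[ben, , drop = FALSE]),
    malignant_centroid = colMeans(values[mal, , drop = FALSE]),
    metabolite_order = colnames(values)), class = "centroid_model")
}

#' Correlation-based sample classification
#'
#' Each sample's metabolite profile is correlated with the two centroids;
#' the score is r_malignant - r_benign and the call is "malignant-like" for
#' a positive score ("benign-like" at ties, logged). Resubstitution is the
#' intended use: the same samples that defined the centroids are scored.
#'
#' @param values Samples-by-metabolites matrix, metabolite order matching
#'   the model.
#' @param model A [build_centroids()] model.
#' @param method Correlation type: `"pearson"` (default) or `"spearman"`.
#' @return Data frame: sample_id, r_benign, r_malignant, score, call.
#'   Zero-variance profiles get `NA` correlations and call, with a warning.
#' @export
classify_samples <- function(values, model, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!identical(colnames(values), model$metabolite_order))
    stop("metabolite order must match the centroid model", call. = FALSE)
  rb <- suppressWarnings(
    apply(values, 1, cor, y = model$benign_centroid, method = method))
  rm_ <- suppressWarnings(
    apply(values, 1, cor, y = model$malignant_centroid, method = method))
  if (anyNA(rb) || anyNA(rm_))
    warning("zero-variance sample profile(s): correlations undefined, excluded from ROC",
            call. = FALSE)
  score <- rm_ - rb
  call <- ifelse(score > 0, "malignant-like", "benign-like")
  data.frame(sample_id = rownames(values) %||% as.character(seq_len(nrow(values))),
             r_benign = rb, r_malignant = rm_, score = score, call = call,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' ROC curve and AUC
#'
#' ROC over a continuous score with malignant as the positive class. The
#' AUC is the Mann-Whitney probability that a random positive scores higher
#' than a random negative, ties counted one half.
#'
#' @param scores Numeric scores (higher = more malignant-like); `NA` scores
#'   are dropped.
#' @param truth Logical or two-level factor, `TRUE`/"malignant" = positive.
#' @return Object of class `roc_result`: list with `thresholds`,
#'   `sensitivity`, `specificity`, `auc`.
#' @export
roc_auc <- function(scores, truth) {
  if (is.factor(truth) || is.character(truth)) truth <- truth == "malignant"
  keep <- !is.na(scores)
  scores <- scores[keep]; truth <- as.logical(truth)[keep]
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  sens <- vapply(thr, function(t) mean(scores[truth] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!truth] < t), numeric(1))
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.3f (%d thresholds)\n", x$auc,
              length(x$thresholds)))
  invisible(x)
}
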