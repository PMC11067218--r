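# Pearson correlation distance d(i,j) = 1 - cor(row_i, row_j); a
# zero-variance row has no defined correlation and gets distance 1 to every
# other row (warning).
pearson_distance <- function(x) {
  cc <- suppressWarnings(cor(t(x)))
  if (anyNA(cc)) {
    warning("zero-variance row: correlation distance set to 1", call. = FALSE)
    cc[is.na(cc)] <- 0
  }
  as.dist(1 - cc)
}

#' Inner clustering step
#'
#' Agglomerative clustering of the rows of a (sub)matrix with Pearson
#' correlation distance, cut at k clusters. Complete linkage (the default)
#' is the algorithm used for the final clustering of the consensus matrix;
#' the resampling loop instead uses average linkage by default (see
#' [consensus_run()]), because complete linkage's outermost split tends to
#' peel off single outlying samples, which destabilizes small-k partitions
#' under resampling.
#'
#' @param x Numeric matrix (rows = items).
#' @param k Number of clusters, at most `nrow(x)`.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return Integer vector of cluster labels.
#' @export
inner_cluster <- function(x, k, linkage = "complete") {
  if (k > nrow(x))
    stop("k must not exceed the number of rows", call. = FALSE)
  cutree(hclust(pearson_distance(x), method = linkage), k = k)
}

# counter-based per-iteration seed keyed by (seed, k, iteration) so the
# random stream is independent of execution order; all arithmetic exact in
# doubles, result < 2^31
iteration_seed <- function(seed, k, iteration) {
  as.integer((as.double(seed) + 2654435761 * (k * 1e5 + iteration)) %% 2147483647)
}

#' Resampled consensus clustering
#'
#' For each k in `k_range`, runs `n_iterations` clustering iterations; each
#' iteration resamples `resample_fraction` of the items and of the features
#' without replacement (floor counts), clusters the subsample with
#' [inner_cluster()], and accumulates co-clustering and co-sampling counts.
#' The consensus entry for a pair of items is its co-cluster count divided
#' by its co-sample count (0, with a warning, for pairs never co-sampled).
#' Item and feature draws are taken over the sorted identifiers, so results
#' do not depend on the row or column order of the input.
#'
#' @param values Samples-by-features matrix with rownames (>= 10 samples).
#' @param k_range Integer vector of cluster counts (default 2:5).
#' @param n_iterations Iterations per k (default 1000).
#' @param resample_fraction Fraction of items and of features drawn each
#'   iteration (default 0.8).
#' @param inner_linkage Linkage for the per-iteration clustering (default
#'   `"average"`; see [inner_cluster()]).
#' @param seed Integer seed for the counter-based iteration streams.
#' @return Object of class `consensus_result`: list with `k_range`,
#'   `consensus` (one symmetric samples-by-samples matrix in \[0, 1\] per k,
#'   unit diagonal), `n_iterations`, `resample_fraction`, `seed`.
#' @export
consensus_run <- function(values, k_range = 2:5, n_iterations = 1000,
                          resample_fraction = 0.8, inner_linkage = "average",
                          seed = 1L) {
  n <- nrow(values)
  if (n < 10)
    stop("at least 10 samples are required", call. = FALSE)
  if (resample_fraction <= 0 || resample_fraction > 1)
    stop("resample_fraction must lie in (0, 1]", call. = FALSE)
  ids <- rownames(values)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  item_order <- order(ids)
  feat_order <- order(colnames(values) %||% as.character(seq_len(ncol(values))))
  n_items <- floor(resample_fraction * n)
  n_feats <- max(1L, floor(resample_fraction * ncol(values)))

  consensus <- vector("list", length(k_range))
  names(consensus) <- as.character(k_range)
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    hits <- matrix(0, n, n)
    tries <- matrix(0, n, n)
    for (it in seq_len(n_iterations)) {
      set.seed(iteration_seed(seed, k, it))
      idx <- item_order[sample.int(n, n_items)]
      fidx <- feat_order[sample.int(ncol(values), n_feats)]
      lab <- inner_cluster(values[idx, fidx, drop = FALSE], k,
                           linkage = inner_linkage)
      tries[idx, idx] <- tries[idx, idx] + 1
      for (cl in unique(lab)) {
        jj <- idx[lab == cl]
        hits[jj, jj] <- hits[jj, jj] + 1
      }
    }
    if (any(tries[upper.tri(tries)] == 0))
      warning(sprintf("k = %d: some sample pairs were never co-sampled; their consensus is 0", k),
              call. = FALSE)
    cons <- ifelse(tries > 0, hits / pmax(tries, 1), 0)
    diag(cons) <- 1
    dimnames(cons) <- list(ids, ids)
    consensus[[ki]] <- cons
  }
  structure(list(k_range = k_range, consensus = consensus,
                 n_iterations = n_iterations,
                 resample_fraction = resample_fraction, seed = seed),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: %d samples, k = %s, %d iterations (%.0f%% resampling)\n",
              nrow(x$consensus[[1]]), paste(range(x$k_range), collapse = "-"),
              x$n_iterations, 100 * x$resample_fraction))
  invisible(x)
}

# exact area under the empirical CDF of the upper-triangle consensus values
# on [0, 1] (step integral)
consensus_cdf_area <- function(m) {
  v <- m[upper.tri(m)]
  f <- ecdf(v)
  knots <- sort(unique(c(0, v, 1)))
  list(cdf = data.frame(value = knots, cdf = f(knots)),
       area = sum(diff(knots) * f(knots[-length(knots)])))
}

#' CDF summaries and selection of the cluster count
#'
#' Computes, per k, the empirical CDF of the upper-triangle consensus values
#' and its area, and the relative change in area comparing k with k - 1
#' (for the smallest k there is no k - 1 and the total area itself is
#' reported). The full curve is always returned.
#'
#' The selected k minimizes the proportion of ambiguous clustering (PAC):
#' the share of sample pairs whose consensus lies strictly between 0.1 and
#' 0.9 (ties go to the smaller k). A stable partition cannot be improved by
#' adding clusters — splitting a stable cluster only moves pairs into the
#' ambiguous mid-range — and, unlike the delta-area elbow, PAC is not
#' inflated by that mid-range mass. The elbow reading of the delta-area
#' curve (last k before the relative change falls below `elbow_threshold`)
#' is also reported, as `elbow_k`.
#'
#' @param result A [consensus_run()] result.
#' @param elbow_threshold Relative-change cutoff for the reported elbow
#'   (default 0.1).
#' @return List with `cdf` (per-k step functions as data frames), `area`,
#'   `delta_area`, `pac` (all named by k), `selected_k` (PAC minimizer) and
#'   `elbow_k`.
#' @export
cdf_and_select_k <- function(result, elbow_threshold = 0.1) {
  ks <- result$k_range
  summaries <- lapply(result$consensus, consensus_cdf_area)
  area <- vapply(summaries, `[[`, numeric(1), "area")
  delta <- numeric(length(ks))
  names(delta) <- names(area)
  delta[1] <- area[1]
  for (i in seq_along(ks)[-1]) {
    prev <- area[i - 1]
    delta[i] <- if (prev > 0) (area[i] - prev) / prev else 0
  }
  pac <- vapply(result$consensus, function(m) {
    v <- m[upper.tri(m)]
    mean(v > 0.1 & v < 0.9)
  }, numeric(1))
  elbow_k <- ks[length(ks)]
  for (i in seq_along(ks)[-1]) {
    if (delta[i] < elbow_threshold) {
      elbow_k <- ks[i - 1]
      break
    }
  }
  list(cdf = lapply(summaries, `[[`, "cdf"), area = area,
       delta_area = delta, pac = pac,
       selected_k = ks[which.min(pac)], elbow_k = elbow_k)
}

#' Final clustering of the consensus matrix
#'
#' Rows of the consensus matrix are clustered with Pearson correlation
#' distance and complete linkage and the tree is cut at k. For k = 2 with
#' group labels supplied, the cluster holding the larger share of benign
#' samples is named "Benign cluster" and the other "Malignant cluster"
#' (ties fall back to naming the larger cluster "Benign cluster", with a
#' warning).
#'
#' @param result A [consensus_run()] result.
#' @param k Cluster count (must be in `result$k_range`).
#' @param groups Optional per-sample factor with levels benign/malignant,
#'   used only for cluster naming at k = 2.
#' @return Factor (named clusters at k = 2 with `groups`) or integer vector
#'   of labels, named by sample id.
#' @export
final_clusters <- function(result, k, groups = NULL) {
  key <- as.character(k)
  if (!key %in% names(result$consensus))
    stop(sprintf("no consensus matrix for k = %d", k), call. = FALSE)
  m <- result$consensus[[key]]
  labels <- cutree(hclust(pearson_distance(m), method = "complete"), k = k)
  names(labels) <- rownames(m)
  if (k == 2 && !is.null(groups)) {
    benign_share <- vapply(1:2, function(cl)
      mean(groups[labels == cl] == "benign"), numeric(1))
    if (benign_share[1] == benign_share[2]) {
      warning("tie in benign share: naming the larger cluster 'Benign cluster'",
              call. = FALSE)
      benign_cl <- which.max(tabulate(labels, 2))
    } else {
      benign_cl <- which.max(benign_share)
    }
    out <- factor(ifelse(labels == benign_cl, "Benign cluster", "Malignant cluster"),
                  levels = c("Benign cluster", "Malignant cluster"))
    names(out) <- names(labels)
    return(out)
  }
  labels
}

#' Cluster-disease association
#'
#' Builds the 2x2 disease-by-cluster contingency table and tests it with
#' Fisher's exact test.
#'
#' @param labels Two-level cluster assignment (from [final_clusters()] at
#'   k = 2).
#' @param groups Per-sample disease status with levels benign/malignant.
#' @return List with `table` (2x2: rows = disease, columns = cluster),
#'   `odds_ratio`, `p_value`.
#' @export
cluster_disease_association <- function(labels, groups) {
  labels <- droplevels(factor(labels))
  if (nlevels(labels) != 2)
    stop("association is defined for exactly two clusters", call. = FALSE)
  tab <- table(factor(groups, levels = c("benign", "malignant")), labels)
  ft <- fisher_exact_2x2(unclass(tab))
  list(table = tab, odds_ratio = ft$odds_ratio, p_value = ft$p_value)
}
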