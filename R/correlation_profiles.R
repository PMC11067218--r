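#' Spearman correlation of one metabolite pair
#'
#' Spearman's rho on mid-ranks with the two-sided p-value from the
#' t-approximation t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of
#' freedom; |rho| = 1 gives p = 0. A constant vector has no defined rank
#' correlation and yields a missing rho with a warning.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho` and `p_value`.
#' @export
spearman_pair <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined", call. = FALSE)
    return(list(rho = NA_real_, p_value = NA_real_))
  }
  rho <- cor(rank(x), rank(y))
  n <- length(x)
  if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p)
}

#' Group-wise Spearman correlation matrix
#'
#' All pairwise Spearman correlations of the panel metabolites over a subset
#' of samples (e.g. the benign or the malignant group), with two-sided
#' p-values per pair. The p-values are deliberately unadjusted; pairwise
#' significance is read at P < 0.05.
#'
#' @param values Samples-by-metabolites matrix.
#' @param rows Optional logical or index vector of samples to use (>= 3).
#' @param group_label Label stored with the result (e.g. "benign").
#' @return Object of class `correlation_set`: list with `group_label`,
#'   `rho` and `p` (symmetric metabolite-by-metabolite matrices; unit
#'   diagonal for `rho`, `NA` diagonal for `p`).
#' @export
correlation_matrix <- function(values, rows = NULL, group_label = NA_character_) {
  if (!is.null(rows)) values <- values[rows, , drop = FALSE]
  if (nrow(values) < 3)
    stop("at least 3 samples are required", call. = FALSE)
  mets <- colnames(values)
  p <- length(mets)
  ranks <- apply(values, 2, rank)
  rho <- cor(ranks)
  n <- nrow(values)
  pm <- matrix(NA_real_, p, p, dimnames = list(mets, mets))
  off <- abs(rho) < 1 - 1e-12
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-300))
  pm[] <- 2 * pt(-abs(tstat), df = n - 2)
  pm[!off] <- 0
  diag(rho) <- 1
  diag(pm) <- NA_real_
  structure(list(group_label = group_label, rho = rho, p = pm, n = n),
            class = "correlation_set")
}

#' @export
print.correlation_set <- function(x, ...) {
  cat(sprintf("correlation_set '%s': %d metabolites, n = %d samples\n",
              x$group_label, ncol(x$rho), x$n))
  invisible(x)
}

#' Differential correlation between two groups
#'
#' Elementwise change in Spearman correlation, malignant minus benign, with
#' a mask flagging pairs whose absolute change exceeds the threshold (the
#' contrast visualized at |delta| > 0.25).
#'
#' @param benign_set,malignant_set [correlation_matrix()] results over the
#'   same metabolites in the same order.
#' @param threshold Absolute-change threshold for the mask (default 0.25).
#' @return Object of class `delta_correlation`: list with `delta`, `mask`,
#'   `threshold`.
#' @export
delta_correlation <- function(benign_set, malignant_set, threshold = 0.25) {
  if (!identical(colnames(benign_set$rho), colnames(malignant_set$rho)))
    stop("metabolite sets must match between the two groups", call. = FALSE)
  delta <- malignant_set$rho - benign_set$rho
  structure(list(delta = delta, mask = abs(delta) > threshold,
                 threshold = threshold),
            class = "delta_correlation")
}

#' Long-format differential correlation table
#'
#' @param benign_set,malignant_set [correlation_matrix()] results.
#' @param delta A [delta_correlation()] result.
#' @return Tidy data frame: one row per unordered metabolite pair with both
#'   groups' rho, the change, and the mask flag.
#' @export
delta_correlation_table <- function(benign_set, malignant_set, delta) {
  mets <- colnames(delta$delta)
  pairs <- which(upper.tri(delta$delta), arr.ind = TRUE)
  data.frame(
    metabolite_1 = mets[pairs[, 1]],
    metabolite_2 = mets[pairs[, 2]],
    rho_benign = benign_set$rho[pairs],
    rho_malignant = malignant_set$rho[pairs],
    delta = delta$delta[pairs],
    masked = delta$mask[pairs],
    stringsAsFactors = FALSE)
}
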