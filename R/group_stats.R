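#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test with mid-ranks for ties. The exact path
#' enumerates the permutation distribution of the rank sum over all
#' assignments of the pooled (mid-)ranks to group 1, so ties are handled
#' exactly; the approximate path uses the tie-corrected normal approximation
#' with continuity correction.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param exact `"auto"` (exact when both groups have at most 8
#'   observations), `TRUE`, or `FALSE`.
#' @return List with `statistic` (Mann-Whitney U for `x`) and `p_value`
#'   (two-sided).
#' @export
wilcoxon_rank_sum <- function(x, y, exact = "auto") {
  if (length(x) == 0 || length(y) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  u <- w - n1 * (n1 + 1) / 2
  use_exact <- isTRUE(exact) || (identical(exact, "auto") && n1 <= 8 && n2 <= 8)
  if (use_exact) {
    idx <- combn(n, n1)
    ws <- colSums(matrix(r[idx], nrow = n1))
    mu <- n1 * (n + 1) / 2
    p <- mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
  } else {
    p <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  }
  list(statistic = u, p_value = min(1, p))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard BH step-up: in sorted order q(i) = min over j >= i of
#' p(j) * m / j, capped at 1, returned in the original order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values (FDR-adjusted p-values).
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p_values, method = "BH")
}

star_label <- function(q) {
  cut(q, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", ""), right = TRUE)
}

#' Per-metabolite two-group comparison
#'
#' Runs the Wilcoxon rank-sum test for every metabolite between the two
#' label levels, adjusts across the panel by Benjamini-Hochberg, and
#' attaches the direction of the median difference and the FDR star label
#' (`*` q <= 0.05 up to `****` q <= 0.0001).
#'
#' @param values Samples-by-metabolites matrix (centered log2 scale).
#' @param labels Factor (or coercible) with exactly two levels, aligned to
#'   the matrix rows.
#' @param strata Optional logical or index vector restricting the rows used.
#' @param exact Passed to [wilcoxon_rank_sum()].
#' @return Data frame: metabolite, statistic, p_value, q_value, direction
#'   (sign of median(level1) - median(level2)), stars.
#' @export
compare_groups <- function(values, labels, strata = NULL, exact = FALSE) {
  if (!is.null(strata)) {
    values <- values[strata, , drop = FALSE]
    labels <- labels[strata]
  }
  keep <- !is.na(labels)
  values <- values[keep, , drop = FALSE]
  labels <- labels[keep]
  labels <- droplevels(factor(labels))
  if (nlevels(labels) != 2)
    stop("labels must have exactly two levels", call. = FALSE)
  lv <- levels(labels)
  for (g in lv)
    if (sum(labels == g) < 2)
      stop(sprintf("group '%s' has fewer than 2 samples", g), call. = FALSE)
  res <- lapply(colnames(values), function(m) {
    a <- values[labels == lv[1], m]
    b <- values[labels == lv[2], m]
    t <- wilcoxon_rank_sum(a, b, exact = exact)
    data.frame(metabolite = m, statistic = t$statistic, p_value = t$p_value,
               direction = sign(median(a) - median(b)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_adjust(out$p_value)
  out$stars <- as.character(star_label(out$q_value))
  out[, c("metabolite", "statistic", "p_value", "q_value", "direction", "stars")]
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value as the sum of the probabilities of all tables with
#' fixed margins whose hypergeometric probability does not exceed that of
#' the observed table. The odds-ratio estimate is the sample odds ratio
#' ad/bc (infinite when bc = 0).
#'
#' @param tab 2x2 matrix of non-negative integer counts
#'   (rows = disease status, columns = cluster).
#' @return List with `odds_ratio` and `p_value`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)))
    stop("a 2x2 table is required", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(tab) == 0)
    stop("table total must be positive", call. = FALSE)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds_ratio = or, p_value = fisher.test(tab)$p.value)
}

round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Descriptive counts and percentages
#'
#' Per-level counts of a clinical field with percentages on one decimal
#' (half away from zero), missing values excluded from the denominator and
#' reported separately — the style of a clinical characteristics table.
#'
#' @param clinical Clinical data frame.
#' @param field Column name to summarize.
#' @param subset Optional logical or index vector of rows.
#' @return Data frame (level, n, pct) with attribute `n_missing`.
#' @export
proportion_summary <- function(clinical, field, subset = NULL) {
  if (!field %in% names(clinical))
    stop(sprintf("field '%s' not found", field), call. = FALSE)
  v <- clinical[[field]]
  if (!is.null(subset)) v <- v[subset]
  n_missing <- sum(is.na(v))
  v <- v[!is.na(v)]
  if (length(v) == 0)
    stop(sprintf("all values of '%s' are missing", field), call. = FALSE)
  counts <- table(v)
  out <- data.frame(level = names(counts),
                    n = as.integer(counts),
                    pct = round_half_up(100 * as.integer(counts) / length(v), 1),
                    stringsAsFactors = FALSE)
  attr(out, "n_missing") <- n_missing
  out
}
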