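#' Construct a metabolite batch
#'
#' A batch holds one LC-MS/MS measurement set: a strictly positive
#' samples-by-metabolites concentration matrix with unique sample IDs and a
#' per-sample bridge flag marking samples re-measured in the other batch.
#'
#' @param batch_id Label for the batch.
#' @param values Numeric matrix (rows = samples with rownames, columns =
#'   named metabolites), all entries > 0.
#' @param bridge_ids Sample IDs measured in both batches.
#' @return An object of class `metabolite_batch`.
#' @export
metabolite_batch <- function(batch_id, values, bridge_ids = character(0)) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("batch values need sample rownames and metabolite colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample_ids within a batch", call. = FALSE)
  bad <- which(!is.finite(values) | values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("ingestion error: non-positive or non-numeric concentration at sample '%s', metabolite '%s'",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]), call. = FALSE)
  structure(list(batch_id = batch_id,
                 sample_ids = rownames(values),
                 values = values,
                 bridge_flags = rownames(values) %in% bridge_ids),
            class = "metabolite_batch")
}

#' @export
print.metabolite_batch <- function(x, ...) {
  cat(sprintf("metabolite_batch '%s': %d samples x %d metabolites (%d bridge)\n",
              x$batch_id, nrow(x$values), ncol(x$values), sum(x$bridge_flags)))
  invisible(x)
}

#' Read a batch concentration table
#'
#' Reads a CSV/TSV file whose first column (or a column named `sample_id`)
#' holds sample IDs and whose remaining header names are metabolites.
#' Columns are reordered to the canonical panel order; unknown or missing
#' metabolite names are a schema error, and non-positive or non-numeric
#' concentrations are an ingestion error with coordinates. Bridge IDs absent
#' from the file are dropped with a warning.
#'
#' @param path CSV (`,`) or TSV (tab) file path; delimiter chosen by file
#'   extension.
#' @param bridge_ids Character vector of bridge sample IDs (may be empty).
#' @param batch_id Batch label; defaults to the file name.
#' @param metabolites Canonical metabolite order to enforce.
#' @return A [metabolite_batch()].
#' @export
read_batch <- function(path, bridge_ids = character(0),
                       batch_id = basename(path),
                       metabolites = periamp_metabolites()) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.delim(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
  id_col <- if ("sample_id" %in% names(df)) "sample_id" else names(df)[1]
  ids <- as.character(df[[id_col]])
  df <- df[, setdiff(names(df), id_col), drop = FALSE]
  unknown <- setdiff(names(df), metabolites)
  if (length(unknown) > 0)
    stop(sprintf("schema error: unknown metabolite name(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  missing <- setdiff(metabolites, names(df))
  if (length(missing) > 0)
    stop(sprintf("schema error: missing metabolite column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  values <- as.matrix(df[, metabolites, drop = FALSE])
  if (!is.numeric(values))
    stop("ingestion error: non-numeric concentration values", call. = FALSE)
  rownames(values) <- ids
  absent <- setdiff(bridge_ids, ids)
  if (length(absent) > 0) {
    warning(sprintf("bridge id(s) not present in '%s', ignored: %s",
                    batch_id, paste(absent, collapse = ", ")), call. = FALSE)
    bridge_ids <- setdiff(bridge_ids, absent)
  }
  metabolite_batch(batch_id, values, bridge_ids)
}

#' Per-metabolite bridge reference means
#'
#' The arithmetic mean of the raw concentrations of each metabolite over the
#' batch's bridge samples — the scaling reference that puts both batches on
#' a common level.
#'
#' @param batch A [metabolite_batch()] with at least one bridge sample.
#' @return Named numeric vector of per-metabolite reference means.
#' @export
compute_bridge_reference <- function(batch) {
  if (!any(batch$bridge_flags))
    stop("no bridge samples in batch", call. = FALSE)
  colMeans(batch$values[batch$bridge_flags, , drop = FALSE])
}

#' Divide a batch by its bridge reference
#'
#' Every concentration is divided elementwise by its metabolite's reference
#' mean, so the bridge-sample mean of the normalized batch equals 1 for
#' every metabolite and purely multiplicative batch effects cancel.
#'
#' @param batch A [metabolite_batch()].
#' @param reference Named per-metabolite reference means, strictly positive
#'   (from [compute_bridge_reference()]).
#' @return The normalized [metabolite_batch()].
#' @export
normalize_by_reference <- function(batch, reference) {
  reference <- reference[colnames(batch$values)]
  if (any(!is.finite(reference) | reference <= 0))
    stop("reference means must be strictly positive for every metabolite", call. = FALSE)
  out <- batch
  out$values <- sweep(batch$values, 2, reference, `/`)
  out
}

#' Merge two normalized batches
#'
#' Samples measured in only one batch pass through; samples shared between
#' the batches (the bridge samples) contribute the elementwise mean of their
#' two normalized rows as a single data point. Output has one row per unique
#' patient.
#'
#' @param b1,b2 Normalized [metabolite_batch()] objects with identical
#'   metabolite columns.
#' @return List with `values` (unique-patient matrix) and `provenance`
#'   (data frame: sample_id, batches, merged flag).
#' @export
merge_batches <- function(b1, b2) {
  if (!identical(colnames(b1$values), colnames(b2$values)))
    stop("metabolite columns must be identical (names and order) across batches",
         call. = FALSE)
  shared <- intersect(b1$sample_ids, b2$sample_ids)
  only1 <- setdiff(b1$sample_ids, shared)
  only2 <- setdiff(b2$sample_ids, shared)
  merged <- rbind(
    b1$values[only1, , drop = FALSE],
    b2$values[only2, , drop = FALSE],
    (b1$values[shared, , drop = FALSE] + b2$values[shared, , drop = FALSE]) / 2)
  ids <- c(only1, only2, shared)
  rownames(merged) <- ids
  ord <- order(ids)
  provenance <- data.frame(
    sample_id = ids,
    batches = c(rep(b1$batch_id, length(only1)), rep(b2$batch_id, length(only2)),
                rep(paste(b1$batch_id, b2$batch_id, sep = "+"), length(shared))),
    merged = c(rep(FALSE, length(only1) + length(only2)), rep(TRUE, length(shared))),
    stringsAsFactors = FALSE)[ord, ]
  rownames(provenance) <- NULL
  list(values = merged[ord, , drop = FALSE], provenance = provenance)
}

#' Log2-transform and mean-center an integrated table
#'
#' The integrated concentration table is log2-transformed and each
#' metabolite column is centered on its mean over all samples (benign and
#' malignant pooled), giving the analysis-scale matrix used by every
#' downstream stage.
#'
#' @param merged Either the list returned by [merge_batches()] or a strictly
#'   positive numeric matrix.
#' @return Numeric matrix of centered log2 values (column means 0 within
#'   1e-9), with the merge provenance attached as attribute `"provenance"`
#'   when available.
#' @export
log2_mean_center <- function(merged) {
  values <- if (is.list(merged)) merged$values else merged
  if (any(!is.finite(values) | values <= 0))
    stop("all values must be strictly positive for the log2 transform", call. = FALSE)
  lv <- log2(values)
  out <- sweep(lv, 2, colMeans(lv), `-`)
  if (is.list(merged)) attr(out, "provenance") <- merged$provenance
  out
}
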