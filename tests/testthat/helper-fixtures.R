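# Shared fixture builders. Cohorts are generated in code at test time; the
# default-condition cohort is cached per session since several files use it.

normalize_chain <- function(cohort, config) {
  batches <- split_batches(cohort$concentrations, config)
  b1 <- normalize_by_reference(batches$batch1, compute_bridge_reference(batches$batch1))
  b2 <- normalize_by_reference(batches$batch2, compute_bridge_reference(batches$batch2))
  mat <- log2_mean_center(merge_batches(b1, b2))
  clinical <- cohort$clinical[match(rownames(mat), cohort$clinical$sample_id), ]
  list(matrix = mat, clinical = clinical,
       groups = factor(clinical$group, levels = c("benign", "malignant")))
}

.fixture_cache <- new.env(parent = emptyenv())

default_fixture <- function(seed = 424243) {
  key <- as.character(seed)
  if (is.null(.fixture_cache[[key]])) {
    config <- synthetic_config(seed = seed)
    cohort <- generate_cohort(config)
    .fixture_cache[[key]] <- c(normalize_chain(cohort, config),
                               list(config = config, cohort = cohort))
  }
  .fixture_cache[[key]]
}

# tiny deterministic positive concentration matrix
toy_batch_values <- function(n = 3, seed = 7, mets = periamp_metabolites()) {
  set.seed(seed)
  v <- matrix(2^rnorm(n * length(mets), 5, 1), nrow = n,
              dimnames = list(sprintf("S%02d", seq_len(n)), mets))
  v
}
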