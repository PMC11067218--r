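test_that("config invariants are enforced with informative errors", {
  expect_error(synthetic_config(n_total = 100), "n_malignant \\+ n_benign")
  expect_error(synthetic_config(n_neoadjuvant = 80), "n_neoadjuvant")
  expect_error(synthetic_config(n_bridge = 200), "n_bridge")
  expect_error(synthetic_config(effect_metabolites_up = "Alanine"), "disjoint")
  expect_error(synthetic_config(effect_metabolites_up = "NotAMetabolite"), "subset")
  expect_error(synthetic_config(batch_factors = rep(-1, 28)), "batch_factors")
  expect_error(synthetic_config(correlation_blocks = list(
    list(metabolites = c("Valine", "Leucine"), rho = 1.2))), "rho")
})

test_that("default cohort has the configured group and flag counts", {
  fx <- default_fixture()
  cl <- fx$cohort$clinical
  expect_equal(nrow(cl), 117L)
  expect_equal(sum(cl$group == "malignant"), 72L)
  expect_equal(sum(cl$group == "benign"), 45L)
  expect_equal(sum(cl$neoadjuvant), 6L)
  expect_equal(sum(cl$post_surgery_sample), 7L)
  expect_equal(sum(cl$metastatic_at_diagnosis), 1L)
  expect_equal(sum(cl$nonstandard_treatment), 1L)
  expect_true(all(fx$cohort$concentrations > 0))
  expect_equal(dim(fx$cohort$concentrations), c(117L, 28L))
  # neoadjuvant only occurs in the malignant group
  expect_true(all(cl$group[cl$neoadjuvant] == "malignant"))
})

test_that("cohort generation is deterministic given the seed", {
  a <- generate_cohort(synthetic_config(seed = 11))
  b <- generate_cohort(synthetic_config(seed = 11))
  c <- generate_cohort(synthetic_config(seed = 12))
  expect_identical(a, b)
  expect_false(identical(a$concentrations, c$concentrations))
})

test_that("null configuration is calibrated: raw Wilcoxon rejections near 5%", {
  hits <- vapply(seq_len(200), function(s) {
    cfg <- synthetic_config(seed = 50000 + s, effect_size = 0)
    co <- generate_cohort(cfg)
    g <- co$clinical$group
    lg <- log2(co$concentrations)
    ps <- apply(lg, 2, function(v)
      wilcoxon_rank_sum(v[g == "benign"], v[g == "malignant"])$p_value)
    mean(ps < 0.05)
  }, numeric(1))
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.09)
})

test_that("survival fields respect the domain invariants", {
  cl <- default_fixture()$cohort$clinical
  expect_true(all(cl$os_months > 0))
  expect_true(all(cl$rfs_months > 0))
  both <- cl$os_event & cl$rfs_event
  expect_true(all(cl$rfs_months[both] <= cl$os_months[both]))
  expect_false(any(cl$rfs_event[cl$group == "benign"]))
})

test_that("RFS-OS correlation tracks the configured target over seeds", {
  rs <- vapply(seq_len(50), function(s) {
    cfg <- synthetic_config(seed = 60000 + s)
    co <- generate_cohort(cfg)
    inc <- survival_exclusion_filter(co$clinical)
    ev <- inc$os_event & inc$rfs_event
    cor(inc$os_months[ev], inc$rfs_months[ev])
  }, numeric(1))
  expect_gte(mean(rs), 0.89)
  expect_lte(mean(rs), 0.99)
})

test_that("a zero Phenylalanine coefficient gives a null-calibrated log-rank test", {
  ps <- vapply(seq_len(60), function(s) {
    cfg <- synthetic_config(seed = 70000 + s,
                            survival_params = list(phe_loghr = 0))
    co <- generate_cohort(cfg)
    inc <- survival_exclusion_filter(co$clinical)
    phe <- log2(co$concentrations[inc$sample_id, "Phenylalanine"])
    g <- dichotomize_by_mean(phe)
    sd <- survival::survdiff(survival::Surv(inc$os_months, inc$os_event) ~ g)
    stats::pchisq(sd$chisq, 1, lower.tail = FALSE)
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.17)
})

test_that("an all-censored configuration keeps the KM curve at 1", {
  cfg <- synthetic_config(seed = 5,
                          survival_params = list(scale_malignant = 1e6,
                                                 scale_benign = 1e6))
  co <- generate_cohort(cfg)
  expect_false(any(co$clinical$os_event))
  km <- km_estimate(co$clinical$os_months, co$clinical$os_event)
  expect_true(all(km$surv == 1))
})

test_that("split_batches yields 126 measurement rows over 117 unique patients", {
  fx <- default_fixture()
  batches <- split_batches(fx$cohort$concentrations, fx$config)
  n_rows <- nrow(batches$batch1$values) + nrow(batches$batch2$values)
  expect_equal(n_rows, 117L + 9L)
  expect_equal(length(unique(c(batches$batch1$sample_ids, batches$batch2$sample_ids))),
               117L)
  expect_length(batches$bridge_ids, 9L)
  expect_true(all(batches$bridge_ids %in% batches$batch1$sample_ids))
  expect_true(all(batches$bridge_ids %in% batches$batch2$sample_ids))
})

test_that("batch 2 equals the true table scaled by the batch factors", {
  fx <- default_fixture()
  cfg <- fx$config
  batches <- split_batches(fx$cohort$concentrations, cfg)
  ids2 <- batches$batch2$sample_ids
  expected <- sweep(fx$cohort$concentrations[ids2, ], 2,
                    cfg$batch_factors, `*`)
  expect_equal(batches$batch2$values, expected)
  # identity factors reproduce the true table exactly
  cfg1 <- synthetic_config(seed = fx$config$seed, batch_factors = rep(1, 28))
  b1 <- split_batches(fx$cohort$concentrations, cfg1)
  expect_identical(b1$batch1$values,
                   fx$cohort$concentrations[b1$batch1$sample_ids, ])
  expect_identical(b1$batch2$values,
                   fx$cohort$concentrations[b1$batch2$sample_ids, ])
})

test_that("written cohorts round-trip through read_batch", {
  fx <- default_fixture()
  batches <- split_batches(fx$cohort$concentrations, fx$config)
  dir <- withr::local_tempdir()
  write_cohort(fx$cohort, batches, fx$config, dir)
  b1 <- read_batch(file.path(dir, "batch1.csv"), batches$bridge_ids, "set1")
  expect_equal(b1$values, batches$batch1$values, tolerance = 1e-12)
  expect_equal(sum(b1$bridge_flags), 9L)
})
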