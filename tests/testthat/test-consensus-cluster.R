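test_that("inner clustering separates point masses and handles degenerate cuts", {
  set.seed(300)
  base <- matrix(rnorm(8), nrow = 2)
  x <- rbind(base[rep(1, 3), ], base[rep(2, 4), ]) +
    matrix(rnorm(28, sd = 1e-6), nrow = 7)
  lab <- inner_cluster(x, 2)
  expect_equal(length(unique(lab[1:3])), 1L)
  expect_equal(length(unique(lab[4:7])), 1L)
  expect_false(lab[1] == lab[7])

  expect_equal(sort(unique(inner_cluster(x, 7))), 1:7)
  expect_error(inner_cluster(x, 8), "must not exceed")
  xz <- x; xz[3, ] <- 5  # constant row
  expect_warning(inner_cluster(xz, 2), "zero-variance")
})

test_that("complete-linkage cut matches a brute-force agglomerative oracle", {
  set.seed(301)
  for (i in 1:10) {
    x <- matrix(rnorm(5 * 6), nrow = 5)
    d <- 1 - cor(t(x))
    for (k in 2:4) {
      ours <- inner_cluster(x, k)
      oracle <- oracle_complete_linkage(as.dist(d), k)
      olab <- integer(5)
      for (ci in seq_along(oracle)) olab[oracle[[ci]]] <- ci
      expect_true(same_partition(ours, olab),
                  info = sprintf("case %d k %d", i, k))
    }
  }
})

test_that("consensus matrices match a naive recount on a small instance", {
  set.seed(302)
  x <- matrix(rnorm(6 * 4), nrow = 6,
              dimnames = list(paste0("s", 1:6), paste0("f", 1:4)))
  # 10 samples (6 distinct profiles, 4 repeated) so the resampler has room
  ids <- make.unique(paste0("s", c(1:6, 1:4)))
  y <- x[c(1:6, 1:4), ]; rownames(y) <- ids
  res <- suppressWarnings(consensus_run(y, k_range = 2:3, n_iterations = 50, seed = 9))
  for (k in 2:3) {
    hits <- matrix(0, 10, 10, dimnames = list(ids, ids))
    tries <- hits
    io <- order(ids); fo <- order(colnames(y))
    for (it in 1:50) {
      set.seed(periamp:::iteration_seed(9, k, it))
      idx <- io[sample.int(10, 8)]
      fidx <- fo[sample.int(4, 3)]
      sub <- y[idx, fidx, drop = FALSE]
      lab <- cutree(hclust(as.dist(1 - cor(t(sub))), method = "average"), k)
      for (a in seq_along(idx)) for (b in seq_along(idx)) {
        tries[idx[a], idx[b]] <- tries[idx[a], idx[b]] + 1
        if (lab[a] == lab[b]) hits[idx[a], idx[b]] <- hits[idx[a], idx[b]] + 1
      }
    }
    expected <- ifelse(tries > 0, hits / pmax(tries, 1), 0)
    diag(expected) <- 1
    expect_identical(res$consensus[[as.character(k)]], expected)
  }
})

test_that("consensus entries are ratios in [0,1], symmetric, 1 for duplicates", {
  set.seed(303)
  x <- matrix(rnorm(12 * 6), nrow = 12,
              dimnames = list(sprintf("r%02d", 1:12), paste0("f", 1:6)))
  x[2, ] <- x[1, ]  # exact duplicate pair within heterogeneous data
  res <- consensus_run(x, k_range = 2, n_iterations = 100, seed = 4)
  m <- res$consensus[["2"]]
  expect_equal(m, t(m))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(unname(m["r01", "r02"]), 1)

  # a single iteration votes 0/1 only and warns about un-co-sampled pairs
  expect_warning(one <- consensus_run(x, k_range = 2, n_iterations = 1, seed = 4),
                 "never co-sampled")
  expect_true(all(one$consensus[["2"]] %in% c(0, 1)))
})

test_that("consensus is invariant to the row order of the input", {
  set.seed(304)
  x <- matrix(rnorm(14 * 6), nrow = 14,
              dimnames = list(sprintf("r%02d", 1:14), paste0("f", 1:6)))
  perm <- sample(14)
  a <- consensus_run(x, k_range = 2:3, n_iterations = 60, seed = 2)
  b <- consensus_run(x[perm, ], k_range = 2:3, n_iterations = 60, seed = 2)
  ids <- rownames(x)
  for (k in c("2", "3"))
    expect_equal(a$consensus[[k]][ids, ids], b$consensus[[k]][ids, ids])
})

test_that("CDF area is exact on a block-diagonal consensus and selection works", {
  # crisp two-block consensus: 40% of pairs at 1, 60% at 0
  m <- matrix(0, 10, 10)
  m[1:6, 1:6] <- 1; m[7:10, 7:10] <- 1
  v <- m[upper.tri(m)]
  frac0 <- mean(v == 0)
  res <- structure(list(k_range = 2:3, consensus = list("2" = m, "3" = m)),
                   class = "consensus_result")
  sel <- cdf_and_select_k(res)
  # CDF steps to frac0 at 0 and stays there until 1: area = frac0
  expect_equal(unname(sel$area[1]), frac0)
  expect_equal(unname(sel$delta_area[1]), frac0)
  expect_equal(unname(sel$delta_area[2]), 0)
  expect_equal(unname(sel$pac), c(0, 0))
  expect_equal(sel$selected_k, 2L)
  expect_true(all(diff(sel$cdf[["2"]]$cdf) >= 0))
  expect_equal(range(sel$cdf[["2"]]$cdf), c(frac0, 1))
})

test_that("two-group cohorts yield k = 2, crisp consensus and group recovery", {
  picks <- vapply(1:5, function(s) {
    cfg <- synthetic_config(seed = 30000 + s)
    fx <- normalize_chain(generate_cohort(cfg), cfg)
    res <- consensus_run(fx$matrix, k_range = 2:5, n_iterations = 300,
                         seed = cfg$seed)
    sel <- cdf_and_select_k(res)
    m <- res$consensus[["2"]]
    cl <- fx$clinical
    profile <- ifelse(cl$group == "benign" | cl$neoadjuvant | cl$post_surgery_sample,
                      "benign-like", "malignant-like")
    same <- outer(profile, profile, "==")
    ut <- upper.tri(m)
    labels <- final_clusters(res, 2, fx$groups)
    assoc <- cluster_disease_association(labels, fx$groups)
    c(sel$selected_k,
      mean(m[same & ut]),      # within planted profile groups
      mean(m[!same & ut]),     # between
      assoc$p_value)
  }, numeric(4))
  expect_true(all(picks[1, ] == 2))
  expect_true(all(picks[2, ] > 0.9))
  expect_true(all(picks[3, ] < 0.3))
  expect_true(all(picks[4, ] < 1e-6))
})

test_that("final clustering recovers blocks and names the benign cluster", {
  m <- matrix(0.02, 12, 12)
  m[1:7, 1:7] <- 0.97; m[8:12, 8:12] <- 0.97
  diag(m) <- 1
  dimnames(m) <- list(sprintf("s%02d", 1:12), sprintf("s%02d", 1:12))
  res <- structure(list(k_range = 2L, consensus = list("2" = m)),
                   class = "consensus_result")
  groups <- rep(c("benign", "malignant"), c(7, 5))
  lab <- final_clusters(res, 2, groups)
  expect_equal(as.character(lab[1:7]), rep("Benign cluster", 7))
  expect_equal(as.character(lab[8:12]), rep("Malignant cluster", 5))
  expect_error(final_clusters(res, 4), "no consensus matrix")

  assoc <- cluster_disease_association(lab, groups)
  expect_equal(unclass(assoc$table)[1:4], c(7L, 0L, 0L, 5L), ignore_attr = TRUE)
  expect_equal(assoc$p_value, fisher_exact_2x2(matrix(c(7, 0, 0, 5), 2))$p_value)
  expect_error(cluster_disease_association(rep("a", 12), groups), "two clusters")
})

test_that("permuted group labels give uniform association p-values", {
  fx <- default_fixture()
  res <- consensus_run(fx$matrix, k_range = 2, n_iterations = 150,
                       seed = fx$config$seed)
  lab <- final_clusters(res, 2, fx$groups)
  set.seed(305)
  ps <- vapply(1:40, function(i)
    cluster_disease_association(lab, sample(as.character(fx$groups)))$p_value,
    numeric(1))
  expect_gt(mean(ps > 0.05), 0.6)   # mostly non-significant under the null
})
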