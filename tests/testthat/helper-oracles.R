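# Independent brute-force oracles. Each recomputes its statistic by a
# different route than the package (pair counting, full enumeration,
# explicit product-limit), so agreement is a real check.

# Exact two-sided Wilcoxon p by enumerating every assignment of the pooled
# observations to group 1 and counting discordant/tied pairs directly.
oracle_wilcoxon_p <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x)
  pair_u <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "==") )
  u_obs <- pair_u(x, y)
  center <- n1 * length(y) / 2
  sets <- utils::combn(length(v), n1)
  us <- apply(sets, 2, function(ix) pair_u(v[ix], v[-ix]))
  mean(abs(us - center) >= abs(u_obs - center) - 1e-9)
}

# Two-sided Fisher p by summing hypergeometric probabilities of all tables
# with the observed margins that are no more probable than the observed one.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(xs, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# BH step-up written out longhand.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m == 1) break
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# AUC as the fraction of correctly ordered positive/negative pairs.
oracle_auc <- function(scores, truth) {
  sp <- scores[truth]; sn <- scores[!truth]
  (sum(outer(sp, sn, ">")) + 0.5 * sum(outer(sp, sn, "=="))) /
    (length(sp) * length(sn))
}

# Kaplan-Meier by the product-limit definition, evaluated at event times.
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    deaths <- sum(time == ts[i] & event)
    s <- s * (1 - deaths / at_risk)
    surv[i] <- s
  }
  data.frame(time = ts, surv = surv)
}

oracle_spearman_rho <- function(x, y) stats::cor(rank(x), rank(y))

# Naive agglomerative complete linkage over an explicit distance matrix:
# repeatedly merge the two clusters with the smallest maximum inter-point
# distance; returns the partition (list of index sets) with k clusters.
oracle_complete_linkage <- function(d, k) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  while (length(clusters) > k) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        cd <- max(d[clusters[[i]], clusters[[j]]])
        if (cd < best_d) {
          best_d <- cd
          best <- c(j, i)
        }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  clusters
}

# partition equality irrespective of labels
same_partition <- function(labels_a, labels_b) {
  identical(as.vector(table(labels_a, labels_b) > 0) |> sum(),
            length(unique(labels_a))) &&
    length(unique(labels_a)) == length(unique(labels_b))
}
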