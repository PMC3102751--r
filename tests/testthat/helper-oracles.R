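# Independent oracles used by the tests. Each is written from the defining
# formula or by brute force, deliberately not sharing code with the package.

# Exact HWE p-value by direct enumeration of the Levene-Haldane distribution
# (explicit closed-form probability of each heterozygote count, normalized).
hwe_oracle <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  nB <- 2 * n - nA
  hs <- seq(if (nA %% 2 == 0) 0 else 1, min(nA, nB), by = 2)
  probs <- sapply(hs, function(h) {
    aa <- (nA - h) / 2; bb <- (nB - h) / 2
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
          h * log(2) + lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n))
  })
  probs <- probs / sum(probs)            # guard rounding
  sum(probs[probs <= probs[hs == nAB] * (1 + 1e-12)])
}

# log10 Bayes factor by adaptive quadrature over sigma^2 (in log space, with
# the effect marginalized analytically), for a single prior scale.
bf_quadrature_oracle <- function(y, g, sigma_a) {
  n <- length(y)
  yc <- y - mean(y); gc <- g - mean(g)
  Syy <- sum(yc^2); Sgg <- sum(gc^2); Sgy <- sum(gc * yc)
  log_marginal <- function(rss, lextra) {
    h <- function(u) lextra - (n - 1) / 2 * (log(2 * pi) + u) -
      rss / (2 * exp(u))
    umax <- stats::optimize(h, c(-40, 40), maximum = TRUE)$maximum
    hm <- h(umax)
    v <- stats::integrate(function(u) exp(h(u) - hm), -40, 40,
                          rel.tol = 1e-12, subdivisions = 500L)$value
    hm + log(v)
  }
  l1 <- log_marginal(Syy - Sgy^2 / (Sgg + sigma_a^-2),
                     -0.5 * log1p(sigma_a^2 * Sgg))
  l0 <- log_marginal(Syy, 0)
  (l1 - l0) / log(10)
}

# Complete-linkage clustering by exhaustive merge (agglomerate the pair with
# the smallest maximum inter-cluster distance until every merge would exceed
# the cut height). Returns cluster labels.
complete_linkage_oracle <- function(dist_mat, cut_height) {
  k <- nrow(dist_mat)
  clusters <- as.list(seq_len(k))
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d <- max(dist_mat[clusters[[i]], clusters[[j]]])
      if (d < best_d) { best_d <- d; best <- c(i, j) }
    }
    if (best_d > cut_height) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  lab <- integer(k)
  for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
  lab
}

# Storey q-values straight from the defining formula, with explicit loops.
storey_oracle <- function(p, pi0) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(0)
    for (j in i:m) vals <- c(vals, pi0 * m * p[o[j]] / j)
    q[o[i]] <- min(vals, 1)
  }
  q
}

# Balanced one-way ANOVA method-of-moments variance components for a design
# grouped by preparation nested in haplotype (r replicates per prep).
balanced_anova_components <- function(y, hap, prep) {
  r <- length(y) / length(unique(prep))
  prep_means <- tapply(y, prep, mean)
  hap_of_prep <- tapply(as.character(hap), prep, `[`, 1)
  ms_within <- sum((y - prep_means[as.character(prep)])^2) /
    (length(y) - length(unique(prep)))
  hap_means <- tapply(prep_means, hap_of_prep, mean)
  df_prep <- length(unique(prep)) - length(unique(hap))
  ms_prep <- r * sum((prep_means - hap_means[hap_of_prep])^2) / df_prep
  c(prep = max((ms_prep - ms_within) / r, 0), residual = ms_within)
}

# Upper-tail hypergeometric by explicit enumeration over overlap counts.
hyper_oracle <- function(overlap, n_cat, n_universe, n_hits) {
  ks <- overlap:min(n_cat, n_hits)
  sum(sapply(ks, function(k)
    choose(n_cat, k) * choose(n_universe - n_cat, n_hits - k))) /
    choose(n_universe, n_hits)
}

# Small default simulation for pipeline-level tests.
tiny_config <- function(seed = 1, ...) {
  simulation_config(n_genes = 40, panel_sizes = c(80, 40, 90),
                    n_snps_per_gene = 6, seed = seed, ...)
}
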