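# Independent brute-force oracles, deliberately naive: explicit double
# loops and full enumerations, never sharing code with the package.

# geNorm stability M by an explicit pairwise double loop
oracle_genorm_M <- function(mat, candidates) {
  M <- numeric(length(candidates))
  names(M) <- candidates
  for (g in candidates) {
    sds <- c()
    for (k in candidates) {
      if (k == g) next
      ratios <- log2(mat[g, ] / mat[k, ])
      sds <- c(sds, sd(ratios))
    }
    M[g] <- mean(sds)
  }
  M
}

# per-entity Davies-Bouldin index by explicit loops over entity pairs
oracle_dbi <- function(points, labels) {
  ents <- sort(unique(labels))
  cent <- list(); S <- c()
  for (e in ents) {
    x <- points[, labels == e, drop = FALSE]
    cent[[e]] <- rowMeans(x)
    d <- c()
    for (j in seq_len(ncol(x))) d <- c(d, sqrt(sum((x[, j] - cent[[e]])^2)))
    S[e] <- mean(d)
  }
  D <- c()
  for (e in ents) {
    best <- -Inf
    for (f in ents) {
      if (f == e) next
      m <- sqrt(sum((cent[[e]] - cent[[f]])^2))
      best <- max(best, (S[e] + S[f]) / m)
    }
    D[e] <- best
  }
  D
}

# Benjamini-Hochberg by sort / scale / cumulative minimum
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  scaled <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# two-sided Fisher exact p by full enumeration of tables with fixed margins
oracle_fisher <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  prob <- function(x) dhyper(x, c1, n - c1, r1)
  p_obs <- prob(a)
  support <- max(0, r1 - (n - c1)):min(r1, c1)
  sum(vapply(support, function(x) {
    p <- prob(x)
    if (p <= p_obs * (1 + 1e-7)) p else 0
  }, 0))
}

# smallest qualifying purity cutoff by exhaustive scan
oracle_purity_cutoff <- function(prob, rho, target = 0.9) {
  for (c_ in sort(unique(rho))) {
    idx <- rho >= c_
    if (sum(prob[idx] > 0.5) / sum(idx) > target) return(c_)
  }
  NA_real_
}
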