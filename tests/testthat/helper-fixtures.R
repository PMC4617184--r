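# Shared fixtures built in code.

suppressMessages(library(SummarizedExperiment))

# Small F2 study configuration (fast to simulate).
tinyConfig <- function(seed = 1L, ...) {
  args <- list(n_f2 = 60L, n_chrom = 2L, chrom_length_bp = 5e7,
               n_snps_per_chrom = 100L, n_genes = 60L, n_causal_oi_snps = 10L,
               n_cis_eqtl = 5L, n_trans_eqtl = 1L, n_de_genes = 6L,
               n_modules = 1L, module_sizes = 12L, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simulationConfig, args)
}

# Gaussian expression matrix with planted correlated modules:
# within-module correlation = load^2 between any two member genes.
moduleMatrix <- function(seed, n = 36L, sizes = c(60L, 50L, 40L),
                         noise = 150L, load = sqrt(0.7), oi = NULL) {
  set.seed(seed)
  nm <- length(sizes)
  f <- matrix(stats::rnorm(nm * n), nm)
  if (!is.null(oi)) f[1, ] <- (oi - mean(oi)) / stats::sd(oi)
  G <- sum(sizes) + noise
  lab <- c(rep(seq_len(nm), times = sizes), rep(0L, noise))
  x <- matrix(stats::rnorm(G * n), G, n)
  for (m in seq_len(nm)) {
    idx <- lab == m
    x[idx, ] <- load * matrix(f[m, ], sum(idx), n, byrow = TRUE) +
      sqrt(1 - load^2) * x[idx, ]
  }
  rownames(x) <- sprintf("g%03d", seq_len(G))
  colnames(x) <- sprintf("s%02d", seq_len(n))
  list(x = x, labels = stats::setNames(lab, rownames(x)))
}

# Wrap a plain matrix as ProcessedExpression.
asProcessed <- function(y, weights = NULL) {
  sygnet:::.processedExpression(y, weights = weights,
                                provenance = "fixture")
}

# Independent Spearman oracle: explicit rank formula with tie correction
# via Pearson on average ranks.
spearmanOracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Independent HWE oracle: probabilities of all heterozygote counts from
# binomial coefficients (choose-based, distinct from the lgamma route).
hweOracle <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB; nB <- 2 * nBB + nAB
  nMin <- min(nA, nB)
  if (nMin == 0) return(1)
  hets <- seq(nMin %% 2, nMin, by = 2)
  pr <- vapply(hets, function(h) {
    aa <- (nMin - h) / 2; bb <- n - aa - h
    choose(n, aa) * choose(n - aa, h) * 2^h
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[match(nAB, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# Triple-loop TOM oracle.
tomOracle <- function(a) {
  n <- nrow(a); diag(a) <- 1
  out <- matrix(0, n, n)
  k <- rowSums(a) - 1
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    L <- 0
    for (u in seq_len(n)) if (u != i && u != j) L <- L + a[i, u] * a[u, j]
    out[i, j] <- (L + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# Step-up BH oracle.
bhOracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(ord)]
}
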