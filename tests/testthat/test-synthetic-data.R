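test_that("F2 genotypes segregate 1:2:1 with fixed divergent founders", {
  cfg <- tinyConfig(seed = 11, n_f2 = 2000L, n_chrom = 1L,
                    n_snps_per_chrom = 60L, n_genes = 10L,
                    n_cis_eqtl = 0L, n_trans_eqtl = 0L, n_de_genes = 0L,
                    n_modules = 0L, module_sizes = integer(0))
  set.seed(11)
  g <- simulateF2Genotypes(cfg)
  d <- dosage(g)
  expect_true(all(d %in% 0:2))
  pvals <- apply(d, 2L, function(col) {
    obs <- tabulate(col + 1L, nbins = 3L)
    stats::chisq.test(obs, p = c(0.25, 0.5, 0.25))$p.value
  })
  expect_gte(mean(pvals > 0.001), 0.99)
  # MAF close to 0.5 for nearly all SNPs at this population size
  maf <- pmin(colMeans(d) / 2, 1 - colMeans(d) / 2)
  expect_gte(mean(abs(maf - 0.5) < 0.05), 0.95)
})

test_that("recombination fraction between markers 1 cM apart matches Haldane", {
  # two equally spaced markers 1 Mb apart at 1 cM/Mb; r = (1-exp(-0.02))/2
  cfg <- tinyConfig(seed = 5, n_f2 = 5000L, n_chrom = 1L,
                    chrom_length_bp = 3e6, n_snps_per_chrom = 2L,
                    n_genes = 5L, n_cis_eqtl = 0L, n_trans_eqtl = 0L,
                    n_de_genes = 0L, n_modules = 0L,
                    module_sizes = integer(0))
  set.seed(5)
  g <- simulateF2Genotypes(cfg)
  d <- dosage(g)
  expect_equal(diff(snpMeta(g)$pos), 1e6)
  # dosage correlation estimates 1 - 2r over the 10,000 transmitted gametes
  rhat <- (1 - stats::cor(d[, 1], d[, 2])) / 2
  expect_lt(abs(rhat - 0.0099), 0.004)
})

test_that("genotype correlation decays with map distance", {
  cfg <- tinyConfig(seed = 9, n_f2 = 800L, n_chrom = 1L,
                    chrom_length_bp = 1e8, n_snps_per_chrom = 100L,
                    n_genes = 5L, n_cis_eqtl = 0L, n_trans_eqtl = 0L,
                    n_de_genes = 0L, n_modules = 0L,
                    module_sizes = integer(0))
  set.seed(9)
  d <- dosage(simulateF2Genotypes(cfg))
  co <- stats::cor(d)
  gap <- abs(outer(seq_len(100), seq_len(100), `-`))
  bands <- sapply(c(2, 10, 30, 60), function(k)
    mean(co[gap >= k - 2 & gap <= k + 2 & gap > 0]))
  expect_true(all(diff(bands) < 0))
})

test_that("obesity index heritability scaling is honored", {
  cfg <- tinyConfig(seed = 2, n_f2 = 400L)
  set.seed(2)
  g <- simulateF2Genotypes(cfg)
  causal <- data.frame(snp = snpIDs(g)[c(3, 50, 120)],
                       effect = c(0.5, -0.3, 0.8))
  # heritability 1: OI is exactly the centered genetic value
  oi1 <- simulateObesityIndex(g, causal, 1)
  gval <- dosage(g)[, causal$snp] %*% causal$effect
  expect_equal(unname(oi1), as.numeric(gval - mean(gval)), tolerance = 1e-12)
  expect_equal(mean(oi1), 0, tolerance = 1e-12)
  # heritability 0.5: mean realized variance ratio over replicates
  set.seed(7)
  ratios <- replicate(500, {
    oi <- simulateObesityIndex(g, causal, 0.5)
    stats::var(gval - mean(gval)) / stats::var(oi)
  })
  expect_lt(abs(mean(ratios) - 0.5), 0.05)
  expect_error(simulateObesityIndex(g, causal, 1.2), "heritability")
  empty <- data.frame(snp = character(), effect = numeric())
  expect_error(simulateObesityIndex(g, empty, 0.5), "causal")
  oi0 <- simulateObesityIndex(g, empty, 0.5, allowEmpty = TRUE)
  expect_length(oi0, nrow(dosage(g)))
})

test_that("profiling groups are selected deterministically by OI rank", {
  oi <- stats::setNames(as.numeric(1:36), sprintf("s%02d", 1:36))
  sel <- selectProfilingGroups(oi, 12L)
  expect_equal(nrow(sel), 36L)
  expect_equal(as.integer(table(sel$group)), c(12L, 12L, 12L))
  expect_setequal(sel$sample_id[sel$group == "lean"], sprintf("s%02d", 1:12))
  expect_setequal(sel$sample_id[sel$group == "intermediate"],
                  sprintf("s%02d", 13:24))
  expect_setequal(sel$sample_id[sel$group == "obese"],
                  sprintf("s%02d", 25:36))
  m <- tapply(sel$oi, sel$group, mean)
  expect_true(m["lean"] < m["intermediate"] &&
                m["intermediate"] < m["obese"])
  expect_error(selectProfilingGroups(oi[1:20], 12L), "too small")
})

test_that("expression counts carry no genotype association when nothing is planted", {
  cfg <- tinyConfig(seed = 21, n_f2 = 100L, n_genes = 500L, n_cis_eqtl = 0L,
                    n_trans_eqtl = 0L, n_de_genes = 0L, n_modules = 0L,
                    module_sizes = integer(0), sex_effect_sd = 0)
  st <- simulateStudy(cfg, profile = "all")
  m <- log2(assay(st@counts, "counts") + 1)
  d <- dosage(st@genotypes)
  set.seed(1)
  snps <- sample(ncol(d), nrow(m), replace = TRUE)
  cors <- vapply(seq_len(nrow(m)), function(g)
    stats::cor(m[g, ], d[, snps[g]]), numeric(1))
  expect_lt(abs(mean(cors)), 0.02)
})

test_that("planted cis effects are recoverable by per-gene regression", {
  hits <- 0L; reps <- 40L
  for (r in seq_len(reps)) {
    cfg <- tinyConfig(seed = 300 + r, n_f2 = 200L, n_snps_per_chrom = 50L,
                      n_genes = 300L, n_cis_eqtl = 1L, n_trans_eqtl = 0L,
                      n_de_genes = 0L, n_modules = 0L,
                      module_sizes = integer(0), cis_effect_sd = 0.8)
    st <- simulateStudy(cfg, profile = "all")
    pc <- st@truth$planted_cis
    cnt <- assay(st@counts, "counts")
    lib <- colSums(cnt)
    y <- log2((cnt[pc$gene, ] + 0.5) / (lib + 1) * 1e6)
    x <- dosage(st@genotypes)[colnames(cnt), pc$snp]
    fit <- summary(stats::lm(y ~ x))
    ci <- fit$coefficients["x", 1] +
      c(-1.96, 1.96) * fit$coefficients["x", 2]
    if (pc$effect >= ci[1] && pc$effect <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.9)
})

test_that("library size controls the expected total count", {
  base <- tinyConfig(seed = 33, n_genes = 500L, n_cis_eqtl = 0L,
                     n_trans_eqtl = 0L, n_de_genes = 0L, n_modules = 0L,
                     module_sizes = integer(0),
                     libsize_range = c(2e6, 2e6))
  st1 <- simulateStudy(base)
  tot1 <- colSums(assay(st1@counts, "counts"))
  expect_true(all(abs(tot1 / 2e6 - 1) < 0.1))
  dbl <- tinyConfig(seed = 33, n_genes = 500L, n_cis_eqtl = 0L,
                    n_trans_eqtl = 0L, n_de_genes = 0L, n_modules = 0L,
                    module_sizes = integer(0),
                    libsize_range = c(4e6, 4e6))
  st2 <- simulateStudy(dbl)
  expect_true(all(abs(colSums(assay(st2@counts, "counts")) / (2 * tot1) - 1)
                  < 0.1))
})

test_that("PPI edges are enriched within true modules", {
  genes <- sprintf("g%03d", 1:200)
  lab <- stats::setNames(c(rep(1:2, each = 40), rep(0L, 120)), genes)
  denser <- logical(20)
  for (s in 1:20) {
    set.seed(500 + s)
    ppi <- simulatePPI(genes, lab, pWithin = 0.3, pBackground = 0.01)
    la <- lab[ppi$protein_a]; lb <- lab[ppi$protein_b]
    within <- sum(la > 0 & la == lb)
    nWithinPairs <- 2 * choose(40, 2)
    nOtherPairs <- choose(200, 2) - nWithinPairs
    denser[s] <- within / nWithinPairs > (nrow(ppi) - within) / nOtherPairs
  }
  expect_true(all(denser))
  # degenerate cases
  set.seed(1)
  expect_equal(nrow(simulatePPI(genes, lab, 0, 0)), 0L)
  expect_equal(nrow(simulatePPI("g1", NULL)), 0L)
  # no self loops, no duplicates
  set.seed(2)
  ppi <- simulatePPI(genes, lab)
  expect_true(all(ppi$protein_a != ppi$protein_b))
  key <- paste(pmin(ppi$protein_a, ppi$protein_b),
               pmax(ppi$protein_a, ppi$protein_b))
  expect_false(any(duplicated(key)))
})

test_that("identical configuration gives a bit-identical study", {
  cfg <- tinyConfig(seed = 77)
  st1 <- simulateStudy(cfg)
  st2 <- simulateStudy(cfg)
  expect_identical(dosage(st1@genotypes), dosage(st2@genotypes))
  expect_identical(assay(st1@counts, "counts"), assay(st2@counts, "counts"))
  expect_identical(st1@truth$planted_cis, st2@truth$planted_cis)
  expect_identical(st1@ppi, st2@ppi)
})

test_that("planted truth has referential integrity and respects the cis window", {
  cfg <- tinyConfig(seed = 13)
  st <- simulateStudy(cfg)
  tr <- st@truth
  expect_true(all(tr$planted_cis$snp %in% snpIDs(st@genotypes)))
  expect_true(all(tr$planted_cis$gene %in% rownames(st@counts)))
  sm <- as.data.frame(snpMeta(st@genotypes))
  gm <- tr$gene_meta
  i <- match(tr$planted_cis$snp, rownames(sm))
  j <- match(tr$planted_cis$gene, gm$gene)
  expect_true(all(sm$chrom[i] == gm$chrom[j]))
  expect_true(all(abs(sm$pos[i] - gm$tss[j]) < cfg@cis_window_bp))
  expect_error(simulateF2Genotypes(tinyConfig(n_chrom = 0L)))
})
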