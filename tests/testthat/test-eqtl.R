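test_that("HWE exact test matches full enumeration and conventions", {
  expect_equal(hweExactTest(10, 0, 0), 1)   # monomorphic
  expect_equal(hweExactTest(0, 0, 7), 1)
  # worked configuration against the choose-based oracle
  expect_equal(hweExactTest(3, 5, 2), hweOracle(3, 5, 2),
               tolerance = 1e-12)
  # extreme heterozygote deficit fails the QC threshold
  expect_lt(hweExactTest(25, 0, 25), 1e-4)
  # random configurations against the oracle
  set.seed(14)
  for (r in 1:200) {
    n <- sample(50, 1)
    aa <- sample(0:n, 1); ab <- sample(0:(n - aa), 1); bb <- n - aa - ab
    expect_equal(hweExactTest(aa, ab, bb), hweOracle(aa, ab, bb),
                 tolerance = 1e-12)
  }
})

test_that("SNP QC removes boundary SNPs strictly", {
  # 20 samples; construct SNPs sitting exactly on each threshold
  d <- cbind(
    good  = rep(c(0L, 1L, 2L, 1L), 5),
    cr    = c(rep(c(0L, 1L, 2L, 1L), 5)[-1], NA),   # call rate 19/20 = 0.95
    lowmaf = c(1L, rep(0L, 18L), 1L),               # maf = 2/40 = 0.05
    hetdef = rep(c(0L, 2L), 10L)                    # extreme HWE failure
  )
  rownames(d) <- paste0("s", 1:20)
  g <- GenotypeMatrix(d, data.frame(chrom = "chr1", pos = 1:4 * 100,
                                    ref = "A", alt = "B"))
  qc <- snpQC(g)
  expect_equal(snpIDs(qc$genotypes), "good")
  rep <- qc$report
  expect_equal(rep$call_rate[rep$snp == "cr"], 0.95)
  expect_false(rep$passed[rep$snp == "cr"])       # strictly above required
  expect_equal(rep$maf[rep$snp == "lowmaf"], 0.05)
  expect_false(rep$passed[rep$snp == "lowmaf"])
  expect_match(rep$reasons[rep$snp == "hetdef"], "hwe")
  # hwe exactly at the threshold is removed too
  d2 <- cbind(a = rep(c(0L, 1L, 2L, 1L), 5),      # het-balanced: p = 1
              b = rep(c(0L, 0L, 2L, 1L), 5))      # het deficit: p < 1
  rownames(d2) <- paste0("s", 1:20)
  g2 <- GenotypeMatrix(d2, data.frame(chrom = "chr1", pos = c(1, 2),
                                      ref = "A", alt = "B"))
  qc2 <- snpQC(g2, hwePMin = hweExactTest(10, 5, 5))
  expect_true(qc2$report$passed[qc2$report$snp == "a"])
  expect_false(qc2$report$passed[qc2$report$snp == "b"])  # p == threshold
  expect_error(snpQC(g2, mafMin = 0.6), "no SNP")
})

test_that("cis/trans classification uses a strict 1-Mb window", {
  expect_equal(classifyPair("chr1", 2e6, "chr1", 1.1e6)$kind, "cis")
  expect_equal(classifyPair("chr1", 2e6, "chr1", 1.1e6)$distance, 9e5)
  exact <- classifyPair("chr1", 2e6, "chr1", 1e6)
  expect_equal(exact$kind, "trans")           # exactly 1 Mb is trans
  expect_equal(exact$distance, 1e6)
  expect_equal(classifyPair("chr2", 5, "chr1", 5)$kind, "trans")
  expect_true(is.na(classifyPair("chr2", 5, "chr1", 5)$distance))
})

test_that("rank association matches a Spearman oracle and handles ties", {
  x <- c(0, 1, 2, 2); y <- c(1, 2, 3, 4)
  r <- rankAssociation(x, y)
  expect_gt(r$rho, 0)
  expect_equal(r$rho, spearmanOracle(x, y), tolerance = 1e-12)
  expect_equal(r$n_used, 4L)
  # perfect anti-monotone, no ties
  y2 <- c(9, 7, 4, 1); x2 <- c(0, 1, 2, 3)
  expect_equal(rankAssociation(x2, y2)$rho, -1, tolerance = 1e-12)
  # degenerate and missing
  expect_null(rankAssociation(c(1, 1, 1, 1), y))
  expect_null(rankAssociation(c(0, 1, NA, NA, 2), c(1, 2, 3, 4, 5)))
  r2 <- rankAssociation(c(0, 1, 2, NA, 1), c(1, 2, 3, 4, 2))
  expect_equal(r2$n_used, 4L)
  # p value formula
  set.seed(2)
  x3 <- rnorm(30); y3 <- rnorm(30)
  r3 <- rankAssociation(x3, y3)
  tt <- r3$rho * sqrt((30 - 2) / (1 - r3$rho^2))
  expect_equal(r3$p, 2 * pt(-abs(tt), 28), tolerance = 1e-12)
})

test_that("mapEqtls enumerates exactly the allowed pairs", {
  d <- matrix(rep(c(0L, 1L, 2L, 1L, 0L, 2L), 2), ncol = 2,
              dimnames = list(paste0("s", 1:6), c("snpA", "snpB")))
  g <- GenotypeMatrix(d, data.frame(chrom = c("chr1", "chr2"),
                                    pos = c(5e5, 5e5), ref = "A",
                                    alt = "B"))
  set.seed(1)
  y <- matrix(rnorm(12), 2, dimnames = list(c("gene1", "gene2"),
                                            paste0("s", 1:6)))
  gm <- data.frame(gene = c("gene1", "gene2"),
                   chrom = c("chr1", "chr2"), tss = c(1.2e6, 5e6))
  pe <- asProcessed(y)
  cis <- mapEqtls(g, pe, geneMeta = gm, mode = "cis")
  expect_equal(nrow(cis), 1L)   # only snpA-gene1 is within 1 Mb same-chrom
  expect_equal(cis$snp, "snpA"); expect_equal(cis$gene, "gene1")
  expect_equal(cis$distance_bp, 5e5 - 1.2e6)
  both <- mapEqtls(g, pe, geneMeta = gm, mode = "both")
  expect_equal(nrow(both), 4L)
  expect_equal(sum(both$kind == "trans"), 3L)
  sub <- mapEqtls(g, pe, geneMeta = gm, mode = "both",
                  geneSubset = "gene2")
  expect_true(all(sub$gene == "gene2"))
  expect_error(mapEqtls(g, pe, geneMeta = gm, geneSubset = "nope"),
               "missing ids")
})

test_that("missing dosages are handled pairwise-complete", {
  cfg <- tinyConfig(seed = 61, n_f2 = 80L)
  st <- simulateStudy(cfg, groupSize = 20L, profile = "all")
  fc <- filterLowExpression(st@counts, mode = "any_sample")
  pe <- eqtlNormalize(fc)
  d <- dosage(st@genotypes)
  d[1:5, 3] <- NA_integer_
  g2 <- GenotypeMatrix(d, as.data.frame(snpMeta(st@genotypes)))
  rec <- mapEqtls(g2, pe, mode = "cis")
  touched <- rec[rec$snp == snpIDs(g2)[3], ]
  if (nrow(touched)) expect_true(all(touched$n_used == 75L))
  full <- rec[rec$snp != snpIDs(g2)[3], ]
  expect_true(all(full$n_used == 80L))
})

test_that("identical sample reordering leaves associations unchanged", {
  cfg <- tinyConfig(seed = 62, n_f2 = 50L)
  st <- simulateStudy(cfg, groupSize = 12L, profile = "all")
  pe <- eqtlNormalize(filterLowExpression(st@counts, mode = "any_sample"))
  rec1 <- mapEqtls(st@genotypes, pe, mode = "cis")
  perm <- sample(ncol(pe))
  pe2 <- asProcessed(exprValues(pe)[, perm])
  d2 <- dosage(st@genotypes)[colnames(exprValues(pe))[perm], ]
  g2 <- GenotypeMatrix(d2, as.data.frame(snpMeta(st@genotypes)))
  rec2 <- mapEqtls(g2, pe2, geneMeta = st@truth$gene_meta, mode = "cis")
  ord <- function(r) r[order(r$snp, r$gene), c("rho", "p_value")]
  expect_equal(ord(rec1), ord(rec2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("permutation FDR arithmetic, reproducibility and monotonicity", {
  cfg <- tinyConfig(seed = 63, n_f2 = 80L, n_cis_eqtl = 5L,
                    cis_effect_sd = 1.2)
  st <- simulateStudy(cfg, groupSize = 20L, profile = "all")
  pe <- eqtlNormalize(filterLowExpression(st@counts, mode = "any_sample"))
  rec <- mapEqtls(st@genotypes, pe, mode = "cis")
  out1 <- permutationFdr(st@genotypes, pe, rec, nPerm = 5L, seed = 9L)
  out2 <- permutationFdr(st@genotypes, pe, rec, nPerm = 5L, seed = 9L)
  expect_identical(out1$fdr, out2$fdr)
  # monotone non-decreasing in p within the cis scope
  ord <- order(out1$p_value)
  expect_true(all(diff(out1$fdr[ord]) >= -1e-12))
  expect_true(all(out1$fdr >= 0 & out1$fdr <= 1))
  # estimator arithmetic at the smallest p: mean permuted count / real count
  pp <- attr(out1, "perm_p")$p
  rp <- sort(out1$p_value)
  manual <- pmin(1, (findInterval(rp, sort(pp)) / 5) / seq_along(rp))
  manual <- rev(cummin(rev(manual)))
  expect_equal(sort(out1$fdr), sort(manual), tolerance = 1e-12)
  # planted strong effects should be called
  sig <- attr(out1, "significant")
  expect_gt(nrow(sig), 0)
  # empty records in, empty out
  e <- permutationFdr(st@genotypes, pe, rec[0, ], nPerm = 2L, seed = 1L)
  expect_equal(nrow(e), 0L)
})

test_that("top eQTL per gene keeps the strongest record with stated ties", {
  rec <- data.frame(
    snp = c("s1", "s2", "s3", "s4", "s5"),
    gene = c("g1", "g1", "g2", "g2", "g3"),
    kind = "cis",
    distance_bp = c(5e3, 5e5, 5e3, 5e5, 1e4),
    rho = 0.5,
    p_value = c(1e-6, 1e-4, 2e-5, 2e-5, 0.01),
    n_used = 36L)
  top <- topEqtlPerGene(rec)
  expect_equal(nrow(top), 3L)
  expect_equal(top$snp[top$gene == "g1"], "s1")   # smaller p
  expect_equal(top$snp[top$gene == "g2"], "s3")   # tie: smaller |distance|
  expect_equal(top$snp[top$gene == "g3"], "s5")   # single record
})

test_that("eQTL summaries tabulate distances and trans targets", {
  rec <- data.frame(
    snp = c("s1", "s1", "s2", "s2", "s2", "s3"),
    gene = paste0("g", 1:6),
    kind = c("cis", "cis", rep("trans", 4)),
    distance_bp = c(-5e4, 5e4, NA, NA, NA, 2e6),
    rho = 0.4, p_value = 1e-4, n_used = 36L)
  sm <- summarizeEqtls(rec, binWidth = 1e5)
  expect_equal(sum(sm$cis_distance_hist$count), 2L)
  expect_equal(sm$trans_targets$n_genes[sm$trans_targets$snp == "s2"], 3L)
  expect_equal(unname(sm$counts["cis"]), 2L)
  expect_equal(unname(sm$counts["trans_other_chrom"]), 3L)
  empty <- summarizeEqtls(rec[0, ])
  expect_equal(nrow(empty$cis_distance_hist), 0L)
  # all-cis at distance zero: one occupied bin
  rec0 <- rec[1:2, ]; rec0$distance_bp <- 0
  one <- summarizeEqtls(rec0, binWidth = 1e5)
  expect_equal(nrow(one$cis_distance_hist), 1L)
  expect_equal(one$cis_distance_hist$count, 2L)
})
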