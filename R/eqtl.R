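#' @include constructors.R
NULL

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the observed allele counts, the p value is
#' the sum of probabilities of all heterozygote counts (of the same parity)
#' that are no more probable than the observed one.  Monomorphic SNPs return
#' p = 1 by convention.
#'
#' @param nHomRef,nHet,nHomAlt genotype counts.
#' @return p value in (0, 1].
#' @examples
#' hweExactTest(3, 5, 2)
#' @export
hweExactTest <- function(nHomRef, nHet, nHomAlt) {
  stopifnot(nHomRef >= 0, nHet >= 0, nHomAlt >= 0)
  n <- nHomRef + nHet + nHomAlt
  if (n < 1L) stop("need at least one genotype")
  nA <- 2 * nHomRef + nHet          # minor-allele-agnostic: use rarer allele
  nB <- 2 * nHomAlt + nHet
  nMinor <- min(nA, nB)
  if (nMinor == 0L) return(1)
  # all possible het counts share the parity of nMinor
  hets <- seq(nMinor %% 2L, nMinor, by = 2L)
  # log P(het = h | allele counts) up to a shared constant:
  # P = n! / (nAA! nAB! nBB!) * 2^h / C(2n, nMinor)-type normalization
  logp <- vapply(hets, function(h) {
    aa <- (nMinor - h) / 2
    bb <- n - aa - h
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
      h * log(2)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(nHet, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' SNP quality control
#'
#' Retains a SNP iff call rate > \code{callRateMin}, minor allele frequency
#' > \code{mafMin}, and exact Hardy-Weinberg p > \code{hwePMin} (all strict,
#' so a SNP exactly at a boundary is removed).
#'
#' @param genotypes a \code{\link{GenotypeMatrix-class}}.
#' @param callRateMin,mafMin,hwePMin thresholds (defaults 0.95, 0.05, 1e-4).
#' @return list: \code{genotypes} (filtered) and \code{report}
#'   (\code{data.frame}: snp, call_rate, maf, hwe_p, passed, reasons).
#' @export
snpQC <- function(genotypes, callRateMin = 0.95, mafMin = 0.05,
                  hwePMin = 1e-4) {
  d <- dosage(genotypes)
  n <- nrow(d)
  callRate <- colMeans(!is.na(d))
  nAA <- colSums(d == 0L, na.rm = TRUE)
  nAB <- colSums(d == 1L, na.rm = TRUE)
  nBB <- colSums(d == 2L, na.rm = TRUE)
  fAlt <- (nAB + 2 * nBB) / (2 * pmax(1, nAA + nAB + nBB))
  maf <- pmin(fAlt, 1 - fAlt)
  hwe <- vapply(seq_len(ncol(d)), function(s) {
    if (nAA[s] + nAB[s] + nBB[s] == 0L) return(1)
    hweExactTest(nAA[s], nAB[s], nBB[s])
  }, numeric(1))
  passed <- callRate > callRateMin & maf > mafMin & hwe > hwePMin
  reasons <- character(ncol(d))
  reasons[callRate <= callRateMin] <- "call_rate"
  reasons[maf <= mafMin] <- paste0(reasons[maf <= mafMin], ";maf")
  reasons[hwe <= hwePMin] <- paste0(reasons[hwe <= hwePMin], ";hwe")
  reasons <- sub("^;", "", reasons)
  report <- data.frame(snp = colnames(d), call_rate = callRate, maf = maf,
                       hwe_p = hwe, passed = passed, reasons = reasons,
                       row.names = NULL)
  if (!any(passed)) stop("no SNP passed quality control")
  filt <- GenotypeMatrix(d[, passed, drop = FALSE],
                         as.data.frame(snpMeta(genotypes))[passed, ,
                                                           drop = FALSE])
  list(genotypes = filt, report = report)
}

#' Classify a SNP-gene pair as cis or trans
#'
#' cis iff the SNP and the gene's TSS share a chromosome and their distance
#' is strictly below the window (default 1 Mb, chosen for the long haplotype
#' blocks of an F2 intercross); trans otherwise.  The signed distance
#' (SNP position - TSS) is reported for same-chromosome pairs.
#'
#' @param snpChrom,snpPos SNP location.
#' @param geneChrom,geneTss gene TSS location.
#' @param windowBp cis window (default 1e6).
#' @return list: \code{kind} ("cis"/"trans"), \code{distance} (signed bp, NA
#'   across chromosomes).
#' @export
classifyPair <- function(snpChrom, snpPos, geneChrom, geneTss,
                         windowBp = 1e6) {
  stopifnot(snpPos > 0, geneTss > 0)
  same <- as.character(snpChrom) == as.character(geneChrom)
  dist <- ifelse(same, snpPos - geneTss, NA_real_)
  kind <- ifelse(same & abs(dist) < windowBp, "cis", "trans")
  list(kind = kind, distance = dist)
}

#' Rank-based association between dosage and expression
#'
#' Spearman correlation (average ranks for ties) over pairwise-complete
#' samples, with the t approximation
#' t = rho * sqrt((n-2)/(1-rho^2)) on n-2 df, two-sided.  The sign of rho is
#' oriented to the alternate-allele dosage.
#'
#' @param dosage per-sample 0/1/2 dosages (NA = missing).
#' @param expr per-sample continuous expression.
#' @return list: \code{rho}, \code{p}, \code{n_used}; \code{NULL} when the
#'   test is degenerate (< 4 complete pairs or constant input).
#' @export
rankAssociation <- function(dosage, expr) {
  ok <- !is.na(dosage) & !is.na(expr)
  n <- sum(ok)
  if (n < 4L) return(NULL)
  x <- dosage[ok]; y <- expr[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NULL)
  rho <- stats::cor(rank(x), rank(y))
  p <- .spearmanP(rho, n)
  list(rho = rho, p = p, n_used = n)
}

.spearmanP <- function(rho, n) {
  r2 <- pmin(rho^2, 1 - 1e-15)
  tt <- rho * sqrt((n - 2) / (1 - r2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

# Enumerate candidate SNP x gene pairs for a mapping mode.  Returns a
# data.frame with snp/gene indices, kind and signed distance.
.enumeratePairs <- function(sm, gm, windowBp, mode) {
  snpIdx <- seq_len(nrow(sm)); geneIdx <- seq_len(nrow(gm))
  out <- list()
  if (mode %in% c("cis", "both")) {
    cisParts <- list()
    for (ch in unique(as.character(gm$chrom))) {
      gi <- geneIdx[as.character(gm$chrom) == ch]
      si <- snpIdx[as.character(sm$chrom) == ch]
      if (!length(gi) || !length(si)) next
      spos <- sm$pos[si]
      ord <- order(spos)
      si <- si[ord]; spos <- spos[ord]
      lo <- findInterval(gm$tss[gi] - windowBp, spos) + 1L
      hi <- findInterval(gm$tss[gi] + windowBp - 1e-9, spos)
      keep <- hi >= lo
      if (!any(keep)) next
      gi <- gi[keep]; lo <- lo[keep]; hi <- hi[keep]
      reps <- hi - lo + 1L
      g <- rep(gi, reps)
      s <- si[sequence(reps, from = lo)]
      dist <- sm$pos[s] - gm$tss[g]
      inwin <- abs(dist) < windowBp
      cisParts[[ch]] <- data.frame(snp = s[inwin], gene = g[inwin],
                                   kind = "cis", distance = dist[inwin])
    }
    if (length(cisParts)) out$cis <- do.call(rbind, cisParts)
  }
  if (mode %in% c("trans", "both")) {
    # all pairs not cis (the caller restricts universes before this)
    g <- rep(geneIdx, each = length(snpIdx))
    s <- rep(snpIdx, times = length(geneIdx))
    same <- as.character(sm$chrom[s]) == as.character(gm$chrom[g])
    dist <- ifelse(same, sm$pos[s] - gm$tss[g], NA_real_)
    isTrans <- !same | abs(dist) >= windowBp
    out$trans <- data.frame(snp = s[isTrans], gene = g[isTrans],
                            kind = "trans", distance = dist[isTrans])
  }
  do.call(rbind, out)
}

#' Map cis/trans eQTLs by rank association
#'
#' Tests every SNP-gene pair allowed by the mode, the cis window and the
#' optional subsets.  cis mode enumerates only in-window pairs by position
#' indexing; trans mode tests all non-cis pairs over the supplied universes
#' (restrict via \code{geneSubset}/\code{snpSubset}: the all-pairs trans
#' scan is quadratic).  When the dosage matrix is complete the rank
#' correlations are computed by blocked matrix products; SNPs with missing
#' calls fall back to pairwise-complete per-pair tests.
#'
#' @param genotypes a (QC-filtered) \code{\link{GenotypeMatrix-class}}.
#' @param pe a \code{\link{ProcessedExpression-class}}; samples must match
#'   the genotype samples (matched by id).
#' @param geneMeta gene annotation (gene, chrom, tss); default: rowData(pe).
#' @param windowBp cis window (default 1e6).
#' @param geneSubset,snpSubset optional id vectors restricting the universe.
#' @param mode \code{"cis"}, \code{"trans"} or \code{"both"}.
#' @return \code{data.frame} of records: snp, gene, kind, distance_bp, rho,
#'   p_value, n_used.
#' @export
mapEqtls <- function(genotypes, pe, geneMeta = NULL, windowBp = 1e6,
                     geneSubset = NULL, snpSubset = NULL,
                     mode = c("cis", "trans", "both")) {
  mode <- match.arg(mode)
  y <- exprValues(pe)
  d <- dosage(genotypes)
  common <- intersect(colnames(y), rownames(d))
  if (!length(common)) stop("no shared samples between genotypes and expression")
  y <- y[, common, drop = FALSE]
  d <- d[common, , drop = FALSE]
  if (is.null(geneMeta)) {
    rd <- rowData(pe)
    geneMeta <- data.frame(gene = rownames(y), chrom = rd$chrom,
                           tss = rd$tss)
  }
  gm <- geneMeta[match(rownames(y), geneMeta$gene), , drop = FALSE]
  annotated <- !is.na(gm$chrom) & !is.na(gm$tss)
  if (any(!annotated))
    message(sum(!annotated), " unannotated gene(s) excluded from mapping")
  genes <- rownames(y)[annotated]
  if (!is.null(geneSubset)) {
    missing <- setdiff(geneSubset, rownames(y))
    genes <- intersect(genes, geneSubset)
    if (!length(genes))
      stop("empty gene subset after intersection; missing ids: ",
           paste(utils::head(missing, 10), collapse = ", "))
  }
  snps <- colnames(d)
  if (!is.null(snpSubset)) {
    missing <- setdiff(snpSubset, snps)
    snps <- intersect(snps, snpSubset)
    if (!length(snps))
      stop("empty SNP subset after intersection; missing ids: ",
           paste(utils::head(missing, 10), collapse = ", "))
  }
  y <- y[genes, , drop = FALSE]
  d <- d[, snps, drop = FALSE]
  sm <- as.data.frame(snpMeta(genotypes))[match(snps, snpIDs(genotypes)), ,
                                          drop = FALSE]
  gm <- gm[match(genes, gm$gene), , drop = FALSE]
  pairs <- .enumeratePairs(sm, gm, windowBp, mode)
  if (is.null(pairs) || !nrow(pairs))
    return(data.frame(snp = character(), gene = character(),
                      kind = character(), distance_bp = numeric(),
                      rho = numeric(), p_value = numeric(),
                      n_used = integer()))
  n <- nrow(d)
  snpComplete <- !colSums(is.na(d))
  # standardized ranks for the complete-data fast path
  zr <- function(m) {
    r <- apply(m, 2L, rank)
    r <- scale(r)
    r[, attr(r, "scaled:scale") == 0] <- NA
    r
  }
  zy <- zr(t(y))            # samples x genes
  rho <- p <- rep(NA_real_, nrow(pairs)); nUsed <- rep(n, nrow(pairs))
  fast <- snpComplete[pairs$snp]
  if (any(fast)) {
    zd <- zr(d[, unique(pairs$snp[fast]), drop = FALSE])
    colmap <- match(snps[pairs$snp[fast]], colnames(zd))
    # blocked crossproduct over the needed pairs
    rr <- crossprod(zd, zy) / (n - 1)
    rho[fast] <- rr[cbind(colmap, pairs$gene[fast])]
    p[fast] <- .spearmanP(rho[fast], n)
  }
  slow <- which(!fast)
  for (k in slow) {
    res <- rankAssociation(d[, pairs$snp[k]], y[pairs$gene[k], ])
    if (is.null(res)) next
    rho[k] <- res$rho; p[k] <- res$p; nUsed[k] <- res$n_used
  }
  ok <- !is.na(rho)
  data.frame(snp = snps[pairs$snp[ok]], gene = genes[pairs$gene[ok]],
             kind = pairs$kind[ok], distance_bp = pairs$distance[ok],
             rho = rho[ok], p_value = p[ok], n_used = nUsed[ok],
             row.names = NULL)
}

#' Permutation-based FDR for eQTL records
#'
#' Builds a null p-value distribution by permuting the sample labels of the
#' expression matrix (once per permutation, globally, preserving gene-gene
#' correlation) and re-running the identical mapping.  For a candidate
#' threshold t, FDR(t) = mean permuted count with p <= t divided by the real
#' count with p <= t; the curve is made monotone non-decreasing in p by
#' taking, at each real p, the minimum estimate over all thresholds at least
#' as large.  cis and trans records are treated as separate scopes by
#' default (their test counts differ vastly); \code{scope = "joint"} pools
#' them.
#'
#' @param genotypes,pe,geneMeta,windowBp,geneSubset,snpSubset,mode as in
#'   \code{\link{mapEqtls}} (must match the call that produced
#'   \code{records}).
#' @param records real mapping records from \code{\link{mapEqtls}}.
#' @param nPerm number of permutations (default 10).
#' @param fdrThreshold significance cut (default 0.05, strict).
#' @param scope \code{"separate"} (cis and trans independently) or
#'   \code{"joint"}.
#' @param seed integer seed for the permutations.
#' @return \code{records} with an \code{fdr} column and attributes
#'   \code{"significant"} (the subset with fdr < fdrThreshold) and
#'   \code{"perm_p"} (the pooled permutation p values, for calibration
#'   checks).
#' @export
permutationFdr <- function(genotypes, pe, records, nPerm = 10L,
                           fdrThreshold = 0.05,
                           scope = c("separate", "joint"), seed = 1L,
                           geneMeta = NULL, windowBp = 1e6,
                           geneSubset = NULL, snpSubset = NULL,
                           mode = c("cis", "trans", "both")) {
  scope <- match.arg(scope)
  mode <- match.arg(mode)
  stopifnot(nPerm >= 1L)
  if (!nrow(records)) {
    records$fdr <- numeric(0)
    attr(records, "significant") <- records
    return(records)
  }
  set.seed(seed)
  permP <- vector("list", nPerm)
  y <- exprValues(pe)
  for (b in seq_len(nPerm)) {
    perm <- sample(ncol(y))
    yp <- y[, perm, drop = FALSE]
    colnames(yp) <- colnames(y)
    pep <- .processedExpression(yp, template = pe,
                                provenance = c(provenance(pe),
                                               "permuted"))
    rec <- mapEqtls(genotypes, pep, geneMeta = geneMeta,
                    windowBp = windowBp, geneSubset = geneSubset,
                    snpSubset = snpSubset, mode = mode)
    permP[[b]] <- data.frame(kind = rec$kind, p = rec$p_value)
  }
  permP <- do.call(rbind, permP)
  attr(records, "perm_p") <- permP
  records$fdr <- NA_real_
  scopes <- if (scope == "separate") unique(records$kind) else "joint"
  for (sc in scopes) {
    idx <- if (sc == "joint") seq_len(nrow(records))
           else which(records$kind == sc)
    pp <- if (sc == "joint") permP$p else permP$p[permP$kind == sc]
    rp <- records$p_value[idx]
    ord <- order(rp)
    sorted <- rp[ord]
    nReal <- seq_along(sorted)                     # count with p <= t
    nPermLe <- findInterval(sorted, sort(pp))      # permuted count <= t
    fdr <- pmin(1, (nPermLe / nPerm) / nReal)
    fdr <- rev(cummin(rev(fdr)))                   # monotone in p
    records$fdr[idx[ord]] <- fdr
  }
  sig <- records[records$fdr < fdrThreshold, , drop = FALSE]
  attr(records, "significant") <- sig
  records
}

#' Keep the strongest eQTL per gene
#'
#' Per gene, the record with the smallest p value; exact ties broken by
#' smaller |distance| (cross-chromosome trans counts as infinite), then by
#' SNP id.
#'
#' @param records \code{data.frame} of eQTL records.
#' @return one record per gene.
#' @export
topEqtlPerGene <- function(records) {
  if (!nrow(records)) return(records)
  absd <- abs(records$distance_bp)
  absd[is.na(absd)] <- Inf
  ord <- order(records$gene, records$p_value, absd, records$snp)
  rec <- records[ord, , drop = FALSE]
  rec[!duplicated(rec$gene), , drop = FALSE]
}

#' Summarize eQTL records
#'
#' Returns the histogram of signed SNP-TSS distances for cis records, the
#' per-trans-SNP target-gene counts, and overall cis/trans tallies.
#'
#' @param records \code{data.frame} of eQTL records.
#' @param binWidth histogram bin width in bp (default 1e5).
#' @return list: \code{cis_distance_hist} (data.frame bin_mid/count),
#'   \code{trans_targets} (data.frame snp/n_genes), \code{counts} (named
#'   vector: cis, trans, trans_other_chrom).
#' @export
summarizeEqtls <- function(records, binWidth = 1e5) {
  cis <- records[records$kind == "cis", , drop = FALSE]
  trans <- records[records$kind == "trans", , drop = FALSE]
  hist <- data.frame(bin_mid = numeric(0), count = integer(0))
  if (nrow(cis)) {
    b <- floor(cis$distance_bp / binWidth)
    tb <- table(b)
    hist <- data.frame(bin_mid = (as.numeric(names(tb)) + 0.5) * binWidth,
                       count = as.integer(tb))
  }
  tt <- data.frame(snp = character(0), n_genes = integer(0))
  if (nrow(trans)) {
    tab <- table(trans$snp)
    tt <- data.frame(snp = names(tab), n_genes = as.integer(tab),
                     row.names = NULL)
    tt <- tt[order(-tt$n_genes, tt$snp), , drop = FALSE]
  }
  list(cis_distance_hist = hist, trans_targets = tt,
       counts = c(cis = nrow(cis), trans = nrow(trans),
                  trans_other_chrom = sum(is.na(trans$distance_bp))))
}

#' Run the full eQTL mapping stack
#'
#' SNP QC, eQTL normalization, principal-component removal, cis (and
#' optionally trans) rank-association mapping, and permutation FDR.
#'
#' @param genotypes raw \code{\link{GenotypeMatrix-class}}.
#' @param counts an \code{\link{ExpressionCounts-class}}.
#' @param nPCs principal components to remove: an integer (default 4), or
#'   \code{"scan"} to pick the eQTL-count-maximizing value over
#'   \code{scanCandidates} (the tuning rule the PC correction is meant to
#'   serve; see \code{\link{scanPCRemoval}}).
#' @param scanCandidates candidate PC counts for \code{nPCs = "scan"}.
#' @param windowBp cis window.
#' @param nPerm permutations (default 10).
#' @param fdrThreshold significance cut (default 0.05).
#' @param mode mapping mode.
#' @param geneSubset,snpSubset optional restriction universes.
#' @param seed permutation seed.
#' @return list: \code{records} (with fdr), \code{significant},
#'   \code{top_per_gene} (strongest significant record per gene),
#'   \code{qc_report}, \code{expr} (the normalized matrix).
#' @export
runEqtlMapping <- function(genotypes, counts, nPCs = 4L, windowBp = 1e6,
                           nPerm = 10L, fdrThreshold = 0.05, mode = "cis",
                           geneSubset = NULL, snpSubset = NULL, seed = 1L,
                           scanCandidates = 0:6) {
  qc <- snpQC(genotypes)
  fc <- filterLowExpression(counts, mode = "any_sample")
  pe <- eqtlNormalize(fc)
  scanTable <- NULL
  if (identical(nPCs, "scan")) {
    scanTable <- scanPCRemoval(pe, qc$genotypes,
                               candidates = scanCandidates, mode = mode,
                               windowBp = windowBp, geneSubset = geneSubset,
                               snpSubset = snpSubset)
    nPCs <- attr(scanTable, "best")
  }
  pe <- removePrincipalComponents(pe, nPCs)
  rec <- mapEqtls(qc$genotypes, pe, windowBp = windowBp, mode = mode,
                  geneSubset = geneSubset, snpSubset = snpSubset)
  rec <- permutationFdr(qc$genotypes, pe, rec, nPerm = nPerm,
                        fdrThreshold = fdrThreshold, seed = seed,
                        windowBp = windowBp, mode = mode,
                        geneSubset = geneSubset, snpSubset = snpSubset)
  sig <- attr(rec, "significant")
  list(records = rec, significant = sig,
       top_per_gene = topEqtlPerGene(sig), qc_report = qc$report,
       expr = pe, n_pcs = nPCs, pc_scan = scanTable)
}
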