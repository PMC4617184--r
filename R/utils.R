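#' @include constructors.R
NULL

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 = identical up to renaming, ~0 = random.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjustedRandIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sumIJ <- sum(comb2(tab))
  sumI <- sum(comb2(rowSums(tab)))
  sumJ <- sum(comb2(colSums(tab)))
  nC2 <- comb2(length(a))
  expected <- sumI * sumJ / nC2
  maxIdx <- (sumI + sumJ) / 2
  if (maxIdx == expected) return(ifelse(sumIJ == expected, 1, 0))
  (sumIJ - expected) / (maxIdx - expected)
}

#' Gene-level recovery of planted eQTL signals
#'
#' Compares significant eQTL records against the planted truth at the gene
#' level: a planted gene counts as recovered when it has at least one
#' significant record of the planted kind, and a significant gene not
#' planted counts as a false positive.  Pair-level identity is deliberately
#' not used: in an F2 intercross, linkage disequilibrium extends across the
#' whole cis window, so markers linked to the causal SNP are genuine
#' detections of the planted signal, not errors.
#'
#' @param significant \code{data.frame} of significant records (snp, gene,
#'   kind).
#' @param truthPairs \code{data.frame} of planted pairs (snp, gene).
#' @param kind restrict to records of this kind (default "cis").
#' @return list: \code{recall}, \code{fdr}, \code{n_true_positive},
#'   \code{n_false_positive}.
#' @export
evaluateEqtlRecovery <- function(significant, truthPairs, kind = "cis") {
  sig <- significant[significant$kind == kind, , drop = FALSE]
  sigGenes <- unique(sig$gene)
  trueGenes <- unique(truthPairs$gene)
  tp <- length(intersect(sigGenes, trueGenes))
  fp <- length(setdiff(sigGenes, trueGenes))
  list(recall = if (length(trueGenes)) tp / length(trueGenes) else NA_real_,
       fdr = if (length(sigGenes)) fp / length(sigGenes) else 0,
       n_true_positive = tp, n_false_positive = fp)
}

#' Recovery of planted differentially expressed genes
#'
#' @param called character vector of genes called DE.
#' @param planted character vector of planted OI-associated genes.
#' @return list: \code{recall}, \code{fdr}, counts.
#' @export
evaluateDeRecovery <- function(called, planted) {
  called <- unique(called); planted <- unique(planted)
  tp <- length(intersect(called, planted))
  fp <- length(setdiff(called, planted))
  list(recall = if (length(planted)) tp / length(planted) else NA_real_,
       fdr = if (length(called)) fp / length(called) else 0,
       n_true_positive = tp, n_false_positive = fp)
}
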