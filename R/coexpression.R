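#' @include constructors.R
NULL

#' Build the supervised network input set
#'
#' The supervised co-expression network is built on the union of the DE
#' genes and the cis-eQTL genes (deduplicated, order of first appearance in
#' the expression matrix).
#'
#' @param deGenes,cisEqtlGenes character vectors of gene ids.
#' @param pe a \code{\link{ProcessedExpression-class}}.
#' @return the subset matrix (genes x samples) with attribute \code{"size"}.
#' @export
buildInputSet <- function(deGenes, cisEqtlGenes, pe) {
  y <- exprValues(pe)
  ids <- union(deGenes, cisEqtlGenes)
  miss <- setdiff(ids, rownames(y))
  if (length(miss))
    stop("genes absent from expression: ",
         paste(utils::head(miss, 10), collapse = ", "))
  if (!length(ids)) stop("empty union of DE and eQTL genes")
  keep <- rownames(y)[rownames(y) %in% ids]
  out <- y[keep, , drop = FALSE]
  attr(out, "size") <- length(keep)
  out
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins the connectivities into \code{nBins} equal-width bins (empty bins
#' dropped) and returns the squared correlation of log10 p(k) against
#' log10 mean-k, signed negative when the log-log slope is positive (the
#' standard signed scale-free fit index).
#'
#' @param k per-gene connectivities.
#' @param nBins number of equal-width bins (default 10).
#' @return list: \code{r_squared}, \code{slope}, \code{table}.
#' @export
scaleFreeFit <- function(k, nBins = 10L) {
  k <- k[is.finite(k) & k > 0]
  if (length(unique(k)) < 3L)
    return(list(r_squared = NA_real_, slope = NA_real_,
                table = data.frame()))
  cut <- seq(min(k), max(k), length.out = nBins + 1L)
  bin <- findInterval(k, cut, rightmost.closed = TRUE)
  tab <- data.frame(
    mean_k = tapply(k, bin, mean),
    p_k = as.numeric(table(factor(bin, levels = sort(unique(bin))))) /
      length(k))
  tab <- tab[tab$p_k > 0 & tab$mean_k > 0, , drop = FALSE]
  if (nrow(tab) < 3L)
    return(list(r_squared = NA_real_, slope = NA_real_, table = tab))
  x <- log10(tab$mean_k); y <- log10(tab$p_k)
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2]
  r2 <- stats::cor(x, y)^2
  if (slope > 0) r2 <- -r2
  list(r_squared = unname(r2), slope = unname(slope), table = tab)
}

#' Choose the soft-thresholding power
#'
#' For each candidate power beta the adjacency is |Pearson cor|^beta and the
#' connectivity k_i the row sum minus one; the chosen beta is the smallest
#' whose signed scale-free fit R^2 reaches the target (default 0.90), or the
#' R^2-maximizing beta (with a warning) when none does.  Constant genes are
#' removed with a warning before correlation.
#'
#' @param exprSubset genes x samples matrix (e.g. \code{buildInputSet}).
#' @param candidateBetas candidate powers (default 1:20).
#' @param targetR2 target fit (default 0.90).
#' @param signed build a signed network (default FALSE: unsigned |cor|).
#' @param minMeanK sparsity floor on mean connectivity used only by the
#'   fallback rule when no power reaches the target fit.
#' @return list: \code{beta}, \code{fit_table} (beta, r_squared, slope,
#'   mean_k), \code{cor} (the correlation matrix, reused downstream).
#' @export
softThresholdScan <- function(exprSubset, candidateBetas = 1:20,
                              targetR2 = 0.90, signed = FALSE,
                              minMeanK = 1.5) {
  if (nrow(exprSubset) < 30L)
    warning("fewer than 30 genes: scale-free fit will be unstable")
  sds <- apply(exprSubset, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) removed")
    exprSubset <- exprSubset[sds > 0, , drop = FALSE]
  }
  cc <- stats::cor(t(exprSubset))
  base <- if (signed) (1 + cc) / 2 else abs(cc)
  rows <- lapply(candidateBetas, function(b) {
    a <- base^b
    k <- rowSums(a) - 1
    f <- scaleFreeFit(k)
    data.frame(beta = b, r_squared = f$r_squared, slope = f$slope,
               mean_k = mean(k))
  })
  tab <- do.call(rbind, rows)
  hit <- which(!is.na(tab$r_squared) & tab$r_squared >= targetR2)
  if (length(hit)) {
    beta <- tab$beta[hit[1]]
  } else {
    # fallback: maximize R^2 among powers that keep mean connectivity above
    # a sparsity floor (just above the percolation threshold of mean degree
    # 1); beyond it the network is near-empty and the fit index meaningless
    ok <- which(!is.na(tab$r_squared) & tab$mean_k >= minMeanK)
    if (!length(ok)) ok <- which(!is.na(tab$r_squared))
    beta <- tab$beta[ok[which.max(tab$r_squared[ok])]]
    warning("no candidate power reached R^2 >= ", targetR2,
            "; returning the constrained maximizer beta = ", beta)
  }
  list(beta = beta, fit_table = tab, cor = cc)
}

#' Adjacency matrix at a soft power
#'
#' @param cc gene-gene Pearson correlation matrix.
#' @param beta soft power.
#' @param signed signed network transform.
#' @return adjacency in [0,1], diagonal 1.
#' @export
adjacencyFromCor <- function(cc, beta, signed = FALSE) {
  a <- if (signed) ((1 + cc) / 2)^beta else abs(cc)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' tom_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij), where L_ij is the
#' shared-neighbor sum over u != i,j of a_iu a_uj and k_i the connectivity
#' excluding the diagonal; the diagonal is set to 1.  Computed by matrix
#' products.
#'
#' @param a adjacency matrix (symmetric, diagonal 1, entries in [0,1]).
#' @return the TOM, same shape.
#' @export
topologicalOverlap <- function(a) {
  stopifnot(isSymmetric(unname(a)), all(a >= 0), all(a <= 1 + 1e-12))
  diag(a) <- 1
  A2 <- a %*% a
  L <- A2 - 2 * a            # removes u = i and u = j terms (diag(a) = 1)
  k <- rowSums(a) - 1
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (L + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect modules from the TOM
#'
#' Average-linkage hierarchical clustering of the dissimilarity 1 - TOM with
#' a deterministic static cut at \code{cutQuantile} x the maximum merge
#' height; clusters of at least \code{minSize} genes become modules
#' (numbered by decreasing size), the rest are unassigned (label 0).  This
#' static-cut-plus-minimum-size rule is the package's deterministic stand-in
#' for adaptive dendrogram cutting.
#'
#' @param tom topological overlap matrix.
#' @param minSize minimum module size (default 25).
#' @param cutQuantile fraction of the maximum merge height (default 0.99).
#' @return named integer vector of labels (0 = unassigned) with attribute
#'   \code{"dendrogram"} (the hclust object).
#' @export
detectModules <- function(tom, minSize = 25L, cutQuantile = 0.99) {
  n <- nrow(tom)
  genes <- rownames(tom)
  if (is.null(genes)) genes <- paste0("g", seq_len(n))
  if (n < minSize) {
    warning("fewer genes than the minimum module size: all unassigned")
    out <- rep(0L, n); names(out) <- genes
    return(out)
  }
  h <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cut <- stats::cutree(h, h = cutQuantile * max(h$height))
  sizes <- table(cut)
  big <- names(sizes)[sizes >= minSize]
  # label by decreasing size, ties by first occurrence
  big <- big[order(-sizes[big], match(big, names(sizes)))]
  out <- rep(0L, n)
  for (i in seq_along(big)) out[cut == as.integer(big[i])] <- i
  names(out) <- genes
  attr(out, "dendrogram") <- h
  out
}

#' Module eigengenes
#'
#' Per module, genes are standardized and the first right singular vector
#' over samples (the module's first principal component) is scaled to unit
#' variance and sign-oriented so that the mean correlation with the module's
#' genes is positive.  Constant genes are dropped from the PCA.
#'
#' @param exprSubset genes x samples matrix.
#' @param labels named integer labels (0 = unassigned).
#' @return list: \code{eigengenes} (modules x samples), \code{var_explained}
#'   (per module).
#' @export
moduleEigengenes <- function(exprSubset, labels) {
  mods <- sort(unique(labels[labels > 0L]))
  if (!length(mods)) stop("no modules")
  samples <- colnames(exprSubset)
  eg <- matrix(NA_real_, nrow = length(mods), ncol = ncol(exprSubset),
               dimnames = list(paste0("ME", mods), samples))
  ve <- numeric(length(mods))
  for (i in seq_along(mods)) {
    genes <- names(labels)[labels == mods[i]]
    x <- exprSubset[genes, , drop = FALSE]
    sds <- apply(x, 1L, stats::sd)
    if (any(sds == 0)) {
      message(sum(sds == 0), " constant gene(s) dropped from module ",
              mods[i], " PCA")
      x <- x[sds > 0, , drop = FALSE]
    }
    if (nrow(x) < 2L) stop("module ", mods[i], " has fewer than 2 usable genes")
    xs <- t(scale(t(x)))
    sv <- svd(xs, nu = 0L, nv = 1L)
    e <- sv$v[, 1]
    e <- e / stats::sd(e)
    if (mean(stats::cor(e, t(xs))) < 0) e <- -e
    eg[i, ] <- e
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = eg, var_explained = ve)
}

#' Module-trait relationships
#'
#' Pearson correlation of each module eigengene with each numeric trait,
#' with a two-sided t-test p value; a module is selected for follow-up when
#' |MTR| is strictly above \code{selectThreshold} and p < \code{alpha}.
#'
#' @param eigengenes modules x samples matrix.
#' @param traits \code{data.frame} of per-sample numeric traits.
#' @param selectThreshold |correlation| threshold (default 0.5, strict).
#' @param alpha significance level (default 0.05).
#' @return \code{data.frame}: module, trait, cor, p_value, selected.
#' @export
moduleTraitRelationships <- function(eigengenes, traits,
                                     selectThreshold = 0.5, alpha = 0.05) {
  traits <- as.data.frame(traits)
  rows <- list()
  n <- ncol(eigengenes)
  for (m in rownames(eigengenes)) {
    for (tr in colnames(traits)) {
      x <- as.numeric(traits[[tr]])
      if (stats::sd(x) == 0 || anyNA(x)) {
        rows[[length(rows) + 1L]] <- data.frame(
          module = m, trait = tr, cor = NA_real_, p_value = NA_real_,
          selected = FALSE)
        next
      }
      r <- stats::cor(eigengenes[m, ], x)
      tt <- r * sqrt((n - 2) / max(1 - r^2, 1e-15))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, trait = tr, cor = r, p_value = p,
        selected = abs(r) > selectThreshold & p < alpha)
    }
  }
  do.call(rbind, rows)
}

#' Gene-eigengene module membership (kME)
#'
#' @param exprSubset genes x samples matrix.
#' @param eigengenes modules x samples matrix.
#' @return genes x modules correlation matrix.
#' @export
computeKME <- function(exprSubset, eigengenes) {
  stats::cor(t(exprSubset), t(eigengenes))
}

#' Filter module membership by kME
#'
#' A gene keeps its module label iff its correlation with its own module
#' eigengene is strictly above \code{ownMin} and its highest correlation
#' with any other module eigengene is strictly below \code{otherMax}
#' (default reading; the literal published phrasing "with other modules
#' >0.6" is available via \code{literalCrossModuleRule = TRUE}).  Dropped
#' genes become unassigned.
#'
#' @param labels named integer labels.
#' @param kme genes x modules kME matrix (columns "ME1", "ME2", ...).
#' @param ownMin own-module kME threshold (default 0.6).
#' @param otherMax cross-module kME ceiling (default 0.6).
#' @param literalCrossModuleRule require max other-module kME > otherMax
#'   instead (the published phrasing read literally).
#' @return filtered labels.
#' @export
filterModuleMembership <- function(labels, kme, ownMin = 0.6,
                                   otherMax = 0.6,
                                   literalCrossModuleRule = FALSE) {
  out <- labels
  for (g in names(labels)[labels > 0L]) {
    m <- labels[[g]]
    own <- kme[g, paste0("ME", m)]
    others <- kme[g, setdiff(colnames(kme), paste0("ME", m))]
    maxOther <- if (length(others)) max(abs(others)) else -Inf
    keep <- own > ownMin &&
      (if (literalCrossModuleRule) maxOther > otherMax
       else maxOther < otherMax)
    if (length(others) == 0L) keep <- own > ownMin
    if (!keep) out[[g]] <- 0L
  }
  out
}

#' Identify module hub genes
#'
#' Primary rule: the gene with the highest intramodular connectivity (sum of
#' adjacency to the other module genes), ties broken by gene id.
#' Alternative rule: any gene with own-module kME strictly above
#' \code{kmeMin} and |gene-trait correlation| strictly above \code{traitMin}
#' is hub-eligible.  Both outputs are returned.
#'
#' @param labels named integer labels.
#' @param adjacency gene adjacency matrix.
#' @param kme genes x modules kME matrix.
#' @param traitCor named per-gene correlation with the trait of interest.
#' @param kmeMin,traitMin alternative-rule thresholds (0.8, 0.6; strict).
#' @return \code{data.frame}: module, hub (max-connectivity gene),
#'   hub_connectivity, eligible (comma-separated kME/trait-eligible genes).
#' @export
identifyHubGenes <- function(labels, adjacency, kme, traitCor,
                             kmeMin = 0.8, traitMin = 0.6) {
  mods <- sort(unique(labels[labels > 0L]))
  rows <- lapply(mods, function(m) {
    genes <- names(labels)[labels == m]
    a <- adjacency[genes, genes, drop = FALSE]
    kIntra <- rowSums(a) - 1
    hub <- genes[order(-kIntra, genes)][1]
    elig <- genes[kme[genes, paste0("ME", m)] > kmeMin &
                    abs(traitCor[genes]) > traitMin]
    data.frame(module = m, hub = hub,
               hub_connectivity = max(kIntra),
               eligible = paste(sort(elig), collapse = ","))
  })
  do.call(rbind, rows)
}

#' Run the supervised co-expression stack
#'
#' Builds the input union, scans the soft power, computes adjacency and TOM,
#' detects modules, eigengenes, module-trait relationships, kME filtering
#' and hub genes.
#'
#' @param pe a \code{\link{ProcessedExpression-class}}.
#' @param deGenes,cisEqtlGenes input gene sets (union is used).
#' @param traits per-sample trait \code{data.frame} (first column is the
#'   trait of interest for hub calling).
#' @param minSize minimum module size (default 25).
#' @param targetR2 scale-free target (default 0.90).
#' @param cutQuantile static-cut fraction (default 0.99).
#' @return a \code{\link{ModuleSet-class}} plus network matrices in
#'   \code{attr(, "network")} (beta, cor, adjacency, tom).
#' @export
runCoexpression <- function(pe, deGenes, cisEqtlGenes, traits,
                            minSize = 25L, targetR2 = 0.90,
                            cutQuantile = 0.99) {
  x <- buildInputSet(deGenes, cisEqtlGenes, pe)
  scan <- softThresholdScan(x, targetR2 = targetR2)
  a <- adjacencyFromCor(scan$cor, scan$beta)
  tom <- topologicalOverlap(a)
  labels <- detectModules(tom, minSize = minSize, cutQuantile = cutQuantile)
  eg <- moduleEigengenes(x, labels)
  kme <- computeKME(x, eg$eigengenes)
  mtr <- moduleTraitRelationships(eg$eigengenes, traits)
  labels2 <- filterModuleMembership(labels, kme)
  traitCor <- stats::cor(t(x), as.numeric(traits[[1]]))[, 1]
  hubs <- identifyHubGenes(labels, a, kme, traitCor)
  ms <- new("ModuleSet", labels = labels2, eigengenes = eg$eigengenes,
            varExplained = eg$var_explained, kme = kme, mtr = mtr,
            hubs = hubs)
  attr(ms, "network") <- list(beta = scan$beta, fit_table = scan$fit_table,
                              cor = scan$cor, adjacency = a, tom = tom,
                              labels_unfiltered = labels)
  ms
}
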