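#' @include constructors.R
NULL

#' Filter lowly expressed genes
#'
#' Two readings of the low-count rule are supported as modes.
#' \code{"any_sample"} (the eQTL stack) removes a gene when any sample has
#' fewer than \code{threshold} counts (min over samples < threshold);
#' \code{"total"} (the DE stack) removes a gene whose expression is at or
#' below the threshold in every sample (max over samples <= threshold).
#' Surviving gene order is preserved.
#'
#' @param counts an \code{\link{ExpressionCounts-class}}.
#' @param threshold count threshold (default 5).
#' @param mode \code{"any_sample"} or \code{"total"}.
#' @return the filtered \code{ExpressionCounts}.
#' @export
filterLowExpression <- function(counts, threshold = 5L,
                                mode = c("any_sample", "total")) {
  mode <- match.arg(mode)
  stopifnot(threshold >= 0)
  m <- assay(counts, "counts")
  keep <- if (mode == "any_sample") {
    apply(m, 1L, min) >= threshold
  } else {
    apply(m, 1L, max) > threshold
  }
  if (!any(keep))
    stop("all genes removed by the low-expression filter; ",
         "lower the threshold")
  counts[keep, ]
}

#' Median-of-ratios size factors
#'
#' For each sample j the size factor is the median over genes of
#' count_gj / geometric-mean_g, where the geometric mean of each gene is
#' taken across samples; genes with a zero count in any sample are excluded
#' from the reference set.
#'
#' @param counts an \code{\link{ExpressionCounts-class}} or counts matrix.
#' @return positive numeric vector of per-sample size factors.
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' medianOfRatiosSizeFactors(m)  # 1/sqrt(2), sqrt(2)
#' @export
medianOfRatiosSizeFactors <- function(counts) {
  m <- if (is(counts, "SummarizedExperiment")) assay(counts, "counts")
       else as.matrix(counts)
  ref <- m[apply(m, 1L, function(x) all(x > 0)), , drop = FALSE]
  if (nrow(ref) == 0L)
    stop("no usable reference gene: every gene has a zero count")
  loggm <- rowMeans(log(ref))
  sf <- apply(ref, 2L, function(col) exp(stats::median(log(col) - loggm)))
  names(sf) <- colnames(m)
  sf
}

#' Variance-stabilizing log2-CPM transform (voom-style)
#'
#' Values are \code{log2((count + 0.5) / (effective library size + 1) * 1e6)}
#' with effective library size = column sum x size factor.  When weights are
#' requested, a lowess trend of sqrt(residual standard deviation) against
#' mean log2-CPM is fitted across genes and inverted into per-observation
#' precision weights (predicted^-4), the standard mean-variance modelling for
#' RNA-seq counts.
#'
#' @param counts an \code{\link{ExpressionCounts-class}}.
#' @param sizeFactors per-sample positive factors (default: median of
#'   ratios).
#' @param useWeights compute precision weights (default \code{TRUE}).
#' @return a \code{\link{ProcessedExpression-class}} with assays
#'   \code{values} and (optionally) \code{weights}.
#' @export
voomTransform <- function(counts, sizeFactors = NULL, useWeights = TRUE) {
  m <- assay(counts, "counts")
  if (is.null(sizeFactors)) sizeFactors <- medianOfRatiosSizeFactors(m)
  if (any(sizeFactors <= 0)) stop("size factors must be positive")
  lib <- colSums(m) * sizeFactors
  y <- t(log2(t(m + 0.5) / (lib + 1) * 1e6))
  w <- NULL
  prov <- c("size_factors", "voom_log2cpm")
  if (useWeights) {
    if (nrow(m) < 10L) {
      warning("fewer than 10 genes: falling back to unweighted transform")
    } else {
      amean <- rowMeans(y)
      sdres <- apply(y, 1L, stats::sd)
      lo <- stats::lowess(amean, sqrt(sdres), f = 0.5)
      f <- stats::approxfun(lo, rule = 2)
      # per-observation fitted log2-cpm: gene mean shifted by the sample's
      # relative (effective) library size
      shift <- log2((lib + 1) / exp(mean(log(lib + 1))))
      fitted <- outer(amean, shift, `+`)
      w <- f(fitted)^-4
      dim(w) <- dim(y); dimnames(w) <- dimnames(y)
      prov <- c(prov, "voom_weights")
    }
  }
  .processedExpression(y, weights = w, template = counts, provenance = prov)
}

#' Regress a covariate out of every gene
#'
#' Each gene is replaced by the residuals of its least-squares fit on
#' intercept + covariate, removing (for example) the sex effect before
#' network construction.  A constant covariate leaves the matrix unchanged
#' (with a warning).
#'
#' @param pe a \code{\link{ProcessedExpression-class}}.
#' @param covariate per-sample numeric vector or factor.
#' @return the residualized \code{ProcessedExpression}.
#' @export
regressOutCovariate <- function(pe, covariate) {
  y <- exprValues(pe)
  if (length(covariate) != ncol(y))
    stop("covariate length must equal the sample count")
  x <- if (is.factor(covariate) || is.character(covariate))
    as.numeric(factor(covariate)) else as.numeric(covariate)
  if (stats::sd(x) == 0) {
    warning("constant covariate: returning the matrix unchanged")
    return(.addProvenance(pe, "regress_covariate(identity)"))
  }
  X <- cbind(1, x)
  # residual maker applied to all genes at once
  res <- t(stats::lm.fit(X, t(y))$residuals)
  dimnames(res) <- dimnames(y)
  out <- .processedExpression(res, weights = exprWeights(pe), template = pe,
                              provenance = c(provenance(pe),
                                             "regress_covariate"),
                              removed_pcs = removedPCs(pe))
  out
}

#' eQTL normalization stack
#'
#' Applies, in order: quantile normalization across samples (each sample's
#' sorted values are replaced by the cross-sample mean of order statistics,
#' ties receiving the mean of their tied ranks), log2, per-gene
#' mean-centering, and a per-sample z-transform (each sample column to mean 0
#' and SD 1).  Input must already be filtered so that all counts are
#' positive (the any-sample filter guarantees this).
#'
#' @param counts an \code{\link{ExpressionCounts-class}} (filtered).
#' @return a \code{\link{ProcessedExpression-class}}.
#' @importFrom limma normalizeQuantiles
#' @export
eqtlNormalize <- function(counts) {
  m <- assay(counts, "counts")
  if (any(m <= 0))
    stop("eqtlNormalize requires strictly positive counts; ",
         "apply filterLowExpression(mode = 'any_sample') first")
  q <- limma::normalizeQuantiles(m, ties = TRUE)
  lg <- log2(q)
  lg <- lg - rowMeans(lg)
  mu <- colMeans(lg)
  sdc <- apply(lg, 2L, stats::sd)
  if (any(sdc == 0))
    stop("sample with zero variance after centering")
  z <- sweep(sweep(lg, 2L, mu), 2L, sdc, `/`)
  dimnames(z) <- dimnames(m)
  .processedExpression(z, template = counts,
                       provenance = c("quantile_normalize", "log2",
                                      "gene_center", "sample_ztransform"))
}

#' Remove top principal components from an expression matrix
#'
#' Projects out the top \code{nPCs} sample-space principal components
#' (right singular vectors of the gene-centered matrix), the usual guard
#' against technical and batch variation before eQTL mapping.  The operation
#' is a projection: applying it twice equals applying it once.
#'
#' @param pe a \code{\link{ProcessedExpression-class}}.
#' @param nPCs number of components to remove (0 = identity).
#' @return the deflated \code{ProcessedExpression}; \code{removedPCs()}
#'   records the count.
#' @export
removePrincipalComponents <- function(pe, nPCs) {
  y <- exprValues(pe)
  nPCs <- as.integer(nPCs)
  if (nPCs < 0L || nPCs >= min(dim(y)))
    stop("nPCs must satisfy 0 <= nPCs < min(genes, samples)")
  if (nPCs == 0L) return(pe)
  yc <- y - rowMeans(y)
  sv <- svd(yc, nu = 0L, nv = nPCs)
  v <- sv$v[, seq_len(nPCs), drop = FALSE]
  res <- yc - (yc %*% v) %*% t(v)
  dimnames(res) <- dimnames(y)
  .processedExpression(res, weights = exprWeights(pe), template = pe,
                       provenance = c(provenance(pe),
                                      sprintf("remove_pcs(%d)", nPCs)),
                       removed_pcs = removedPCs(pe) + nPCs)
}

#' Scan the number of removed PCs by detected eQTL count
#'
#' Re-runs cis (and optionally trans) eQTL mapping for each candidate number
#' of removed principal components and reports the count-maximizing choice,
#' mirroring the tuning criterion used for expression-PC correction.
#'
#' @param pe normalized \code{\link{ProcessedExpression-class}} (before PC
#'   removal).
#' @param genotypes a QC-filtered \code{\link{GenotypeMatrix-class}}.
#' @param candidates integer vector of candidate PC counts.
#' @param mode \code{"cis"}, \code{"trans"} or \code{"both"}.
#' @param pThreshold nominal p threshold used for counting.
#' @param ... passed to \code{\link{mapEqtls}}.
#' @return \code{data.frame} (n_pcs, n_cis, n_trans, n_total) with attribute
#'   \code{best} = count-maximizing n_pcs.
#' @export
scanPCRemoval <- function(pe, genotypes, candidates = 0:6, mode = "cis",
                          pThreshold = 1e-5, ...) {
  rows <- lapply(candidates, function(k) {
    rec <- mapEqtls(genotypes, removePrincipalComponents(pe, k),
                    mode = mode, ...)
    data.frame(n_pcs = k,
               n_cis = sum(rec$kind == "cis" & rec$p_value < pThreshold),
               n_trans = sum(rec$kind == "trans" & rec$p_value < pThreshold),
               n_total = sum(rec$p_value < pThreshold))
  })
  out <- do.call(rbind, rows)
  attr(out, "best") <- out$n_pcs[which.max(out$n_total)]
  out
}
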