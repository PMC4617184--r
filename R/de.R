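#' @include constructors.R
NULL

#' Fit per-gene linear models of expression on the Obesity Index
#'
#' For each gene, expression is regressed on an intercept, the continuous
#' Obesity Index and sex (0 = female, 1 = male) by exact (weighted) least
#' squares.  Although the headline model is written without an intercept,
#' one is always included: without it the OI slope of non-centered
#' expression is meaningless.  If only one sex is present the sex column is
#' dropped (with a message).
#'
#' @param pe a \code{\link{ProcessedExpression-class}} (weights used if
#'   present).
#' @param oi per-sample Obesity Index (default: \code{colData(pe)$oi}).
#' @param sex per-sample 0/1 sex (default: \code{colData(pe)$sex}).
#' @return \code{data.frame}, one row per gene: \code{gene}, \code{beta_oi},
#'   \code{beta_sex}, \code{se_beta_oi}, \code{sigma2} (residual variance),
#'   \code{df_residual}, \code{v_oi} (unscaled variance of the OI
#'   coefficient, so \code{se = sqrt(sigma2 * v_oi)}).
#' @export
fitGeneModels <- function(pe, oi = NULL, sex = NULL) {
  y <- exprValues(pe)
  w <- exprWeights(pe)
  if (is.null(oi)) oi <- colData(pe)$oi
  if (is.null(sex)) sex <- colData(pe)$sex
  n <- ncol(y)
  if (is.null(oi) || length(oi) != n || anyNA(oi))
    stop("OI must be available for all samples")
  if (n <= 3L) stop("need more than 3 samples to fit the model")
  if (stats::sd(oi) == 0) stop("OI is constant: no estimable slope")
  sex <- as.numeric(sex)
  dropSex <- is.null(sex) || length(sex) != n || stats::sd(sex) == 0
  X <- if (dropSex) cbind(intercept = 1, oi = oi)
       else cbind(intercept = 1, oi = oi, sex = sex)
  if (dropSex) message("sex constant or unavailable: dropped from design")
  p <- ncol(X); dfres <- n - p
  G <- nrow(y)
  beta_oi <- beta_sex <- sigma2 <- v_oi <- numeric(G)
  if (is.null(w)) {
    XtXi <- solve(crossprod(X))
    cf <- XtXi %*% crossprod(X, t(y))
    res <- t(y) - X %*% cf
    sigma2 <- colSums(res^2) / dfres
    beta_oi <- cf["oi", ]
    beta_sex <- if (dropSex) rep(NA_real_, G) else cf["sex", ]
    v_oi <- rep(XtXi["oi", "oi"], G)
  } else {
    for (g in seq_len(G)) {
      fit <- stats::lm.wfit(X, y[g, ], w[g, ])
      XtWXi <- solve(crossprod(X * sqrt(w[g, ])))
      beta_oi[g] <- fit$coefficients["oi"]
      beta_sex[g] <- if (dropSex) NA_real_ else fit$coefficients["sex"]
      sigma2[g] <- sum(w[g, ] * fit$residuals^2) / dfres
      v_oi[g] <- XtWXi["oi", "oi"]
    }
  }
  data.frame(gene = rownames(y), beta_oi = unname(beta_oi),
             beta_sex = unname(beta_sex),
             se_beta_oi = sqrt(pmax(sigma2, 0) * v_oi),
             sigma2 = unname(pmax(sigma2, 0)),
             df_residual = dfres, v_oi = unname(v_oi), row.names = NULL)
}

# Inverse of the trigamma function by Newton iteration (monotone decreasing).
.trigammaInverse <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v) || v <= 0) return(Inf)
    if (v > 1e7) return(1 / sqrt(v))
    if (v < 1e-6) return(1 / v)
    y <- 0.5 + 1 / v
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / v) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif) / y < 1e-10) break
    }
    y
  }, numeric(1))
}

#' Estimate the shared variance prior (d0, s0^2)
#'
#' Method of moments on the log sample variances: with s_g^2 ~
#' s0^2 * chi^2_{d0,g scaled}, log(s_g^2) has known digamma/trigamma
#' moments; matching the excess spread of log variances over its sampling
#' expectation gives d0 (via the inverse trigamma), and the mean gives s0^2.
#' When the observed spread is no larger than expected under equal true
#' variances, d0 is infinite (complete shrinkage).
#'
#' @param sigma2 per-gene residual variances (floored at 1e-12).
#' @param df per-gene residual degrees of freedom.
#' @return list with \code{d0} and \code{s0_sq}.
#' @export
estimateVariancePrior <- function(sigma2, df) {
  s2 <- pmax(sigma2, 1e-12)
  df <- rep_len(df, length(s2))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (!is.finite(evar) || evar <= 0) {
    warning("no excess variance dispersion: d0 = Inf (complete shrinkage)")
    return(list(d0 = Inf, s0_sq = exp(emean)))
  }
  d0 <- 2 * .trigammaInverse(evar)
  s0 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0)
}

#' Empirical-Bayes moderated statistics
#'
#' Shrinks per-gene residual variances toward the shared prior:
#' s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g); the moderated t is
#' beta_OI / (s~_g sqrt(v_g)) on d0 + d_g degrees of freedom, with a
#' two-sided p value.  A log-odds of differential expression (B statistic)
#' is reported using a fixed prior proportion of DE genes (default 0.01);
#' it is informational and never used for calling.
#'
#' @param fits output of \code{\link{fitGeneModels}}.
#' @param d0,s0_sq optional prior overrides (\code{d0 = 0} gives the
#'   ordinary t; \code{d0 = Inf} complete shrinkage to \code{s0_sq}).
#' @param proportion prior probability that a gene is DE (for the B
#'   statistic only).
#' @return \code{data.frame}: gene, beta_oi, t_moderated, p_value,
#'   p_adjusted (BH), log_odds, direction (up_in_obese/down_in_obese),
#'   plus the shared d0 and s0_sq as attributes \code{"d0"}, \code{"s0_sq"}.
#' @export
moderateStatistics <- function(fits, d0 = NULL, s0_sq = NULL,
                               proportion = 0.01) {
  if (nrow(fits) < 2L) stop("need at least 2 genes")
  prior <- estimateVariancePrior(fits$sigma2, fits$df_residual)
  if (is.null(d0)) d0 <- prior$d0
  if (is.null(s0_sq)) s0_sq <- prior$s0_sq
  dg <- fits$df_residual; s2 <- fits$sigma2
  post <- if (is.infinite(d0)) rep(s0_sq, length(s2))
          else (d0 * s0_sq + dg * s2) / (d0 + dg)
  tmod <- fits$beta_oi / sqrt(post * fits$v_oi)
  dft <- d0 + dg
  p <- 2 * stats::pt(-abs(tmod), df = dft)
  # B statistic: prior variance v0 of the coefficient estimated from the
  # most extreme |t| genes (method of moments), fallback 1/s0^2
  ntop <- max(1L, ceiling(proportion * length(tmod)))
  top <- order(-abs(tmod))[seq_len(ntop)]
  v0 <- mean(pmax(0, fits$v_oi[top] * (tmod[top]^2 - 1)))
  if (!is.finite(v0) || v0 <= 0) v0 <- 1 / s0_sq
  r <- (fits$v_oi + v0) / fits$v_oi
  dfb <- ifelse(is.finite(dft), dft, 1e6)
  kernel <- (dfb + 1) / 2 * log((tmod^2 + dfb) / (tmod^2 / r + dfb))
  B <- log(proportion / (1 - proportion)) - 0.5 * log(r) + kernel
  out <- data.frame(gene = fits$gene, beta_oi = fits$beta_oi,
                    t_moderated = tmod, p_value = p,
                    p_adjusted = benjaminiHochberg(p), log_odds = B,
                    direction = ifelse(fits$beta_oi > 0, "up_in_obese",
                                       "down_in_obese"),
                    row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper around \code{stats::p.adjust(method = "BH")}; input order is
#' preserved on return.
#'
#' @param p vector of p values in [0, 1].
#' @return adjusted p values, same order.
#' @export
benjaminiHochberg <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' A gene is DE when its BH-adjusted p value is strictly below \code{fdr};
#' a positive OI slope means up-regulated in obese animals.
#'
#' @param results output of \code{\link{moderateStatistics}}.
#' @param fdr FDR threshold (default 0.05, strict).
#' @return the DE subset of \code{results}, with attribute
#'   \code{"direction_counts"} (up_in_obese / down_in_obese).
#' @export
callDEGenes <- function(results, fdr = 0.05) {
  stopifnot(nrow(results) > 0L)
  de <- results[results$p_adjusted < fdr, , drop = FALSE]
  cnt <- c(up_in_obese = sum(de$direction == "up_in_obese"),
           down_in_obese = sum(de$direction == "down_in_obese"))
  attr(de, "direction_counts") <- cnt
  de
}

#' Run the full differential-expression stack
#'
#' Low-count filter (total mode), median-of-ratios size factors, voom-style
#' transform with precision weights, per-gene linear models on OI + sex,
#' empirical-Bayes moderation, BH adjustment and DE calling.
#'
#' @param counts an \code{\link{ExpressionCounts-class}} with \code{oi} and
#'   \code{sex} in \code{colData}.
#' @param fdr FDR threshold.
#' @param filterThreshold low-count threshold.
#' @param useWeights use voom precision weights in the fits.
#' @return list: \code{results} (all genes), \code{de} (called subset),
#'   \code{expr} (the processed matrix).
#' @export
runDifferentialExpression <- function(counts, fdr = 0.05,
                                      filterThreshold = 5L,
                                      useWeights = TRUE) {
  fc <- filterLowExpression(counts, filterThreshold, mode = "total")
  sf <- medianOfRatiosSizeFactors(fc)
  pe <- voomTransform(fc, sf, useWeights = useWeights)
  fits <- fitGeneModels(pe)
  res <- moderateStatistics(fits)
  list(results = res, de = callDEGenes(res, fdr), expr = pe)
}
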