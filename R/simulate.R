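#' @include constructors.R
NULL

# One meiotic gamete along one chromosome under the Haldane model:
# crossovers are a Poisson process (no interference), so map distance d (in
# Morgans) gives recombination fraction r = (1 - exp(-2d))/2.
# hapA/hapB are the parent's two haplotypes at the SNP positions `pos`.
.gamete <- function(hapA, hapB, pos, chrom_length_bp, morgans) {
  k <- stats::rpois(1L, morgans)
  start <- sample.int(2L, 1L)
  if (k == 0L) {
    idx <- rep(start, length(pos))
  } else {
    xov <- sort(stats::runif(k, 0, chrom_length_bp))
    idx <- (start - 1L + findInterval(pos, xov)) %% 2L + 1L
  }
  ifelse(idx == 1L, hapA, hapB)
}

#' Simulate F2 intercross genotypes
#'
#' Generates dosage genotypes for an F2 population descending from two
#' divergent founder lines (an obese minipig-like line and a lean production
#' line).  By default the founders are inbred lines fixed for alternate
#' alleles, so every F1 is heterozygous at every SNP and the F2 segregates
#' 1:2:1; a founder-frequency mode draws founder haplotypes from line-specific
#' allele frequencies instead.  Gametes recombine as a Poisson crossover
#' process along the chromosome (Haldane map function), with the expected
#' crossover count set by the genetic map density.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param founderMode \code{"fixed"} (default) or \code{"frequency"}.
#' @param founderFreqs length-2 alternate-allele frequencies of the two
#'   founder lines (frequency mode only).
#' @return a \code{\link{GenotypeMatrix-class}} with a \code{pedigree}
#'   attribute (\code{data.frame}: id, family).
#' @examples
#' cfg <- simulationConfig(n_f2 = 20, n_snps_per_chrom = 50, seed = 7)
#' g <- simulateF2Genotypes(cfg)
#' g
#' @export
simulateF2Genotypes <- function(config, founderMode = c("fixed", "frequency"),
                                founderFreqs = c(0.9, 0.1)) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  founderMode <- match.arg(founderMode)
  nC <- config@n_chrom; nS <- config@n_snps_per_chrom
  if (nC < 1L || nS < 1L)
    stop("configuration error: need at least one chromosome and one SNP")
  len <- config@chrom_length_bp
  # equally spaced marker grid
  step <- len / (nS + 1)
  pos1 <- round(seq(step, by = step, length.out = nS))
  chrom <- rep(paste0("chr", seq_len(nC)), each = nS)
  pos <- rep(pos1, nC)
  snp_ids <- sprintf("snp_%s_%05d", rep(seq_len(nC), each = nS),
                     rep(seq_len(nS), nC))
  morgans <- len / 1e6 * config@genetic_map_cm_per_mb / 100
  nF2 <- config@n_f2
  fam <- sort(rep_len(seq_len(max(1L, config@n_f1_pairs)), nF2))

  # founder haplotypes per chromosome (1 = alt allele)
  makeFounderHap <- function(freq) {
    function() stats::rbinom(nS, 1L, freq)
  }
  # F1 parents: one haplotype from each line.  In fixed mode every F1 is
  # identical (all line-A alt / line-B ref), so parents need not be tracked.
  nPairs <- max(1L, config@n_f1_pairs)
  f1hap <- vector("list", nC)
  for (cc in seq_len(nC)) {
    if (founderMode == "fixed") {
      hapA <- rep(1L, nS); hapB <- rep(0L, nS)
      f1hap[[cc]] <- list(
        sire = replicate(nPairs, list(A = hapA, B = hapB), simplify = FALSE),
        dam  = replicate(nPairs, list(A = hapA, B = hapB), simplify = FALSE))
    } else {
      drawParent <- function()
        list(A = stats::rbinom(nS, 1L, founderFreqs[1]),
             B = stats::rbinom(nS, 1L, founderFreqs[2]))
      f1hap[[cc]] <- list(
        sire = replicate(nPairs, drawParent(), simplify = FALSE),
        dam  = replicate(nPairs, drawParent(), simplify = FALSE))
    }
  }

  d <- matrix(0L, nrow = nF2, ncol = nC * nS)
  for (i in seq_len(nF2)) {
    p <- fam[i]
    for (cc in seq_len(nC)) {
      sire <- f1hap[[cc]]$sire[[p]]; dam <- f1hap[[cc]]$dam[[p]]
      g1 <- .gamete(sire$A, sire$B, pos1, len, morgans)
      g2 <- .gamete(dam$A, dam$B, pos1, len, morgans)
      d[i, (cc - 1L) * nS + seq_len(nS)] <- g1 + g2
    }
  }
  rownames(d) <- sprintf("F2_%04d", seq_len(nF2))
  colnames(d) <- snp_ids
  out <- GenotypeMatrix(d, data.frame(chrom = chrom, pos = pos,
                                      ref = "A", alt = "B"))
  attr(out, "pedigree") <- data.frame(id = rownames(d), family = fam)
  out
}

#' Simulate the aggregate Obesity Index
#'
#' The OI is an additive genetic value plus environmental noise: the genetic
#' value of animal i is the sum over causal SNPs of effect x dosage, and the
#' environmental variance is chosen so that var(g)/var(OI) matches the
#' requested heritability.  The returned OI is centered to mean zero.
#'
#' @param genotypes a \code{\link{GenotypeMatrix-class}}.
#' @param causal \code{data.frame} with columns \code{snp} and \code{effect}.
#' @param heritability fraction of OI variance that is genetic, in [0, 1].
#'   With heritability 1 the OI is the centered genetic value exactly; with
#'   heritability 0 it is pure standard-normal environment.
#' @param allowEmpty if \code{TRUE}, an empty causal set yields an all-zero
#'   genetic value instead of an error.
#' @return named numeric vector of OI values, one per sample, mean zero.
#' @export
simulateObesityIndex <- function(genotypes, causal, heritability,
                                 allowEmpty = FALSE) {
  stopifnot(is(genotypes, "GenotypeMatrix"))
  if (heritability < 0 || heritability > 1)
    stop("heritability must lie in [0, 1]")
  d <- dosage(genotypes)
  if (nrow(causal) == 0L) {
    if (!allowEmpty) stop("no causal SNPs supplied (set allowEmpty = TRUE ",
                          "for an all-zero genetic value)")
    g <- rep(0, nrow(d))
  } else {
    miss <- setdiff(causal$snp, colnames(d))
    if (length(miss))
      stop("causal SNPs absent from genotypes: ",
           paste(miss, collapse = ", "))
    dd <- d[, causal$snp, drop = FALSE]
    if (anyNA(dd)) { # mean-impute for the generative model only
      mu <- colMeans(dd, na.rm = TRUE)
      idx <- which(is.na(dd), arr.ind = TRUE)
      dd[idx] <- mu[idx[, 2]]
    }
    g <- as.numeric(dd %*% causal$effect)
  }
  vg <- stats::var(g)
  if (heritability == 0 || vg == 0) {
    oi <- if (heritability == 1) g else g + stats::rnorm(length(g))
    if (heritability == 1) oi <- g
  } else if (heritability == 1) {
    oi <- g
  } else {
    ve <- vg * (1 - heritability) / heritability
    oi <- g + stats::rnorm(length(g), 0, sqrt(ve))
  }
  oi <- oi - mean(oi)
  names(oi) <- rownames(d)
  oi
}

#' Select the lean / intermediate / obese profiling groups
#'
#' Selective expression profiling: from the full population, the
#' \code{groupSize} animals with the lowest OI are labelled \code{lean}, the
#' highest \code{obese}, and the \code{groupSize} animals nearest the
#' population median OI \code{intermediate}.  Ties are broken by sample id
#' order, making the selection deterministic.
#'
#' @param oi named numeric vector of Obesity Index values.
#' @param groupSize animals per group (default 12, the 12/12/12 design).
#' @return \code{data.frame} with columns \code{sample_id}, \code{oi},
#'   \code{group} (factor lean < intermediate < obese), ordered lean,
#'   intermediate, obese.
#' @examples
#' oi <- setNames(1:36, sprintf("s%02d", 1:36))
#' table(selectProfilingGroups(oi, 12)$group)
#' @export
selectProfilingGroups <- function(oi, groupSize = 12L) {
  if (is.null(names(oi))) stop("oi must be named by sample id")
  n <- length(oi)
  if (n < 3L * groupSize)
    stop("population too small: need at least ", 3L * groupSize,
         " animals, got ", n)
  ord <- order(oi, names(oi))
  lean <- names(oi)[ord[seq_len(groupSize)]]
  obese <- names(oi)[ord[seq(n - groupSize + 1L, n)]]
  rest <- setdiff(names(oi), c(lean, obese))
  med <- stats::median(oi)
  rest <- rest[order(abs(oi[rest] - med), rest)]
  inter <- rest[seq_len(groupSize)]
  sel <- c(lean, inter, obese)
  data.frame(
    sample_id = sel,
    oi = unname(oi[sel]),
    group = factor(rep(c("lean", "intermediate", "obese"),
                       each = groupSize),
                   levels = c("lean", "intermediate", "obese")),
    row.names = NULL)
}

#' Simulate adipose expression counts with planted signals
#'
#' Per gene g and sample i the log2 mean is
#' \code{baseline_g + sum(effect x dosage) + slope_g x zOI_i +
#' sexeff_g x sex_i + loading_g x f_m(i)}, where zOI is the OI standardized
#' over the profiled samples, f_m is the latent factor of gene g's module
#' (standard normal, or the scaled OI for OI-driven modules), and baselines
#' are log-normal.  Counts are negative binomial with shared dispersion and
#' per-sample library sizes: relative expression is scaled so each sample's
#' expected total equals its library size.
#'
#' @param genotypes \code{\link{GenotypeMatrix-class}} (profiled samples).
#' @param samples \code{data.frame} with \code{sample_id}, \code{sex}
#'   (0 = female, 1 = male) and \code{oi}.
#' @param truth list with \code{gene_meta} (gene, chrom, tss, strand),
#'   \code{planted_cis}, \code{planted_trans} (snp, gene, effect),
#'   \code{de_genes} (gene, slope), \code{module_labels} (named integer),
#'   \code{oi_driven_modules}, \code{sex_effects} (named numeric, optional).
#' @param config a \code{\link{simulationConfig}}.
#' @return an \code{\link{ExpressionCounts-class}} for the profiled samples.
#' @export
simulateExpression <- function(genotypes, samples, truth, config) {
  stopifnot(is(genotypes, "GenotypeMatrix"))
  d <- dosage(genotypes)
  sid <- samples$sample_id
  if (!all(sid %in% rownames(d)))
    stop("samples absent from genotypes")
  d <- d[sid, , drop = FALSE]
  gm <- truth$gene_meta
  genes <- gm$gene
  nG <- length(genes); nI <- length(sid)

  # planted cis pairs must lie within the generation window
  pc <- truth$planted_cis
  if (nrow(pc)) {
    sm <- snpMeta(genotypes)
    i <- match(pc$snp, rownames(sm)); j <- match(pc$gene, genes)
    if (anyNA(i) || anyNA(j)) stop("planted pair ids unknown")
    same <- as.character(sm$chrom[i]) == as.character(gm$chrom[j])
    within <- same & abs(sm$pos[i] - gm$tss[j]) < config@cis_window_bp
    if (!all(within))
      stop("generation error: planted cis pair outside the cis window: ",
           paste(pc$snp[!within], pc$gene[!within], collapse = "; "))
  }

  log2mu <- matrix(rep(truth$baselines %||% stats::rnorm(nG, 4, 1.5), nI),
                   nrow = nG)
  rownames(log2mu) <- genes; colnames(log2mu) <- sid

  addEffect <- function(tab) {
    for (k in seq_len(nrow(tab))) {
      g <- tab$gene[k]
      log2mu[g, ] <<- log2mu[g, ] + tab$effect[k] * d[, tab$snp[k]]
    }
  }
  if (nrow(pc)) addEffect(pc)
  if (nrow(truth$planted_trans)) addEffect(truth$planted_trans)

  oi <- samples$oi
  zoi <- if (stats::sd(oi) > 0) (oi - mean(oi)) / stats::sd(oi) else oi * 0
  de <- truth$de_genes
  if (nrow(de))
    log2mu[de$gene, ] <- log2mu[de$gene, , drop = FALSE] +
      outer(de$slope, zoi)

  sexeff <- truth$sex_effects
  if (is.null(sexeff)) sexeff <- stats::rnorm(nG, 0, config@sex_effect_sd)
  sex <- as.numeric(samples$sex)
  log2mu <- log2mu + outer(sexeff, sex)

  lab <- truth$module_labels[genes]
  lab[is.na(lab)] <- 0L
  mods <- sort(unique(lab[lab > 0L]))
  for (m in mods) {
    f <- if (m %in% truth$oi_driven_modules) zoi else stats::rnorm(nI)
    member <- which(lab == m)
    log2mu[member, ] <- log2mu[member, , drop = FALSE] +
      config@module_cor * matrix(f, nrow = length(member), ncol = nI,
                                 byrow = TRUE)
  }

  libsize <- stats::runif(nI, config@libsize_range[1], config@libsize_range[2])
  rel <- 2^log2mu
  mu <- sweep(rel, 2L, libsize / colSums(rel), `*`)
  cnt <- matrix(stats::rnbinom(nG * nI, mu = mu,
                               size = 1 / config@nb_dispersion),
                nrow = nG, dimnames = dimnames(mu))
  ExpressionCounts(cnt,
                   geneMeta = gm,
                   sampleData = samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate protein-protein interaction edges
#'
#' Undirected edges without self-loops or duplicates; gene pairs inside the
#' same true module interact with probability \code{pWithin}, all other pairs
#' with background probability \code{pBackground} (emulating a public PPI
#' resource that is enriched within functional modules).
#'
#' @param genes character vector of gene/protein ids.
#' @param moduleLabels named integer vector (0/NA = no module).
#' @param pWithin,pBackground edge probabilities.
#' @return \code{data.frame} with columns \code{protein_a}, \code{protein_b}.
#' @export
simulatePPI <- function(genes, moduleLabels = NULL, pWithin = 0.3,
                        pBackground = 0.01) {
  n <- length(genes)
  if (n < 2L)
    return(data.frame(protein_a = character(), protein_b = character()))
  lab <- rep(0L, n); names(lab) <- genes
  if (!is.null(moduleLabels)) {
    hit <- intersect(names(moduleLabels), genes)
    lab[hit] <- as.integer(moduleLabels[hit])
    lab[is.na(lab)] <- 0L
  }
  edges <- list()
  # within-module pairs: enumerate (modules are small)
  for (m in unique(lab[lab > 0L])) {
    member <- which(lab == m)
    if (length(member) < 2L) next
    pr <- utils::combn(member, 2L)
    keep <- stats::runif(ncol(pr)) < pWithin
    if (any(keep))
      edges[[length(edges) + 1L]] <- t(pr[, keep, drop = FALSE])
  }
  # background: binomial number of edges over all cross/background pairs,
  # sampled by linear pair index to avoid materializing all pairs
  npairs <- n * (n - 1) / 2
  nbg <- stats::rbinom(1L, npairs, pBackground)
  if (nbg > 0L) {
    k <- sample(npairs, nbg)
    # unordered pair (i < j) from linear index over the upper triangle:
    # row i contributes n - i pairs; locate the row by cumulative counts
    cum <- cumsum(n - seq_len(n - 1L))
    i <- findInterval(k - 0.5, c(0, cum)) # row index
    j <- i + (k - c(0, cum)[i])
    edges[[length(edges) + 1L]] <- cbind(as.integer(i), as.integer(j))
  }
  if (!length(edges))
    return(data.frame(protein_a = character(), protein_b = character()))
  e <- do.call(rbind, edges)
  a <- pmin(e[, 1], e[, 2]); b <- pmax(e[, 1], e[, 2])
  keep <- !duplicated(cbind(a, b)) & a != b
  data.frame(protein_a = genes[a[keep]], protein_b = genes[b[keep]],
             row.names = NULL)
}

#' Simulate a complete F2 obesity study
#'
#' End-to-end generator: F2 genotypes, causal-SNP-driven Obesity Index,
#' 12/12/12 (by default) lean/intermediate/obese selective profiling,
#' expression counts with planted cis/trans eQTLs, OI-associated genes, sex
#' effects and correlated modules, plus module-enriched PPI edges.  The
#' planted truth (pair lists, slopes, module labels) is returned alongside
#' the data so recovery can be measured.  Identical config gives a
#' bit-identical study.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param groupSize animals per profiling group (default 12).
#' @param profile \code{"groups"} (default): expression only for the
#'   selected 3 x groupSize animals, the selective-profiling design;
#'   \code{"all"}: expression for every F2 animal (used for eQTL power
#'   studies at full population size).
#' @param ppiWithin,ppiBackground PPI edge probabilities.
#' @return a \code{\link{SimulatedStudy-class}}.
#' @examples
#' cfg <- simulationConfig(n_f2 = 60, n_snps_per_chrom = 100, n_genes = 60,
#'                         n_cis_eqtl = 4, n_trans_eqtl = 1, n_de_genes = 6,
#'                         n_modules = 1, module_sizes = 12L, seed = 42,
#'                         n_causal_oi_snps = 10)
#' study <- simulateStudy(cfg, groupSize = 6)
#' study
#' @export
simulateStudy <- function(config, groupSize = 12L,
                          profile = c("groups", "all"), ppiWithin = 0.3,
                          ppiBackground = 0.01) {
  profile <- match.arg(profile)
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  geno <- simulateF2Genotypes(config)
  sm <- snpMeta(geno)
  allSnps <- snpIDs(geno)

  causal <- data.frame(
    snp = sample(allSnps, min(config@n_causal_oi_snps, length(allSnps))),
    effect = stats::rnorm(min(config@n_causal_oi_snps, length(allSnps))))
  oi <- simulateObesityIndex(geno, causal, config@oi_heritability,
                             allowEmpty = TRUE)
  sex <- stats::rbinom(length(oi), 1L, 0.5)
  names(sex) <- names(oi)
  sel <- selectProfilingGroups(oi, groupSize)
  sel$sex <- sex[sel$sample_id]
  if (profile == "all") {
    prof <- data.frame(sample_id = names(oi), oi = unname(oi),
                       group = "none", sex = unname(sex),
                       row.names = NULL)
    prof$group[match(sel$sample_id, prof$sample_id)] <-
      as.character(sel$group)
    sel <- prof
  }

  # gene placement: cis genes get a TSS within the window of a random SNP
  nG <- config@n_genes
  genes <- sprintf("gene_%05d", seq_len(nG))
  gchrom <- sample(unique(as.character(sm$chrom)), nG, replace = TRUE)
  gtss <- round(stats::runif(nG, 1, config@chrom_length_bp))
  gstrand <- sample(c("+", "-"), nG, replace = TRUE)

  cisGenes <- integer(0); cisSnps <- character(0)
  if (config@n_cis_eqtl > 0L) {
    cisGenes <- sample(nG, config@n_cis_eqtl)
    cisSnps <- sample(allSnps, config@n_cis_eqtl, replace = FALSE)
    off <- round(stats::runif(config@n_cis_eqtl,
                              -config@cis_window_bp * 0.45,
                              config@cis_window_bp * 0.45))
    gchrom[cisGenes] <- as.character(sm[cisSnps, "chrom"])
    gtss[cisGenes] <- pmax(1, pmin(config@chrom_length_bp,
                                   sm[cisSnps, "pos"] + off))
  }
  gene_meta <- data.frame(gene = genes, chrom = gchrom, tss = gtss,
                          strand = gstrand)

  sgn <- function(n) sample(c(-1, 1), n, replace = TRUE)
  planted_cis <- data.frame(
    snp = cisSnps, gene = genes[cisGenes],
    effect = sgn(config@n_cis_eqtl) * config@cis_effect_sd)

  transGenes <- integer(0); transSnps <- character(0)
  if (config@n_trans_eqtl > 0L && config@n_chrom > 1L) {
    pool <- setdiff(seq_len(nG), cisGenes)
    transGenes <- sample(pool, config@n_trans_eqtl)
    transSnps <- vapply(transGenes, function(g) {
      sample(allSnps[as.character(sm$chrom) != gchrom[g]], 1L)
    }, character(1))
  }
  planted_trans <- data.frame(
    snp = transSnps, gene = genes[transGenes],
    effect = if (length(transGenes))
      sgn(length(transGenes)) * config@cis_effect_sd else numeric(0))

  dePool <- setdiff(seq_len(nG), c(cisGenes, transGenes))
  deGenes <- sample(dePool, min(config@n_de_genes, length(dePool)))
  de_genes <- data.frame(
    gene = genes[deGenes],
    slope = sgn(length(deGenes)) *
      stats::runif(length(deGenes), config@de_effect_range[1],
                   config@de_effect_range[2]))

  module_labels <- rep(0L, nG); names(module_labels) <- genes
  modPool <- setdiff(seq_len(nG), c(cisGenes, transGenes, deGenes))
  if (config@n_modules > 0L && sum(config@module_sizes) <= length(modPool)) {
    pick <- sample(modPool, sum(config@module_sizes))
    module_labels[pick] <- rep(seq_len(config@n_modules),
                               times = config@module_sizes)
  } else if (config@n_modules > 0L) {
    pick <- sample(setdiff(seq_len(nG), c(cisGenes, transGenes)),
                   sum(config@module_sizes))
    module_labels[pick] <- rep(seq_len(config@n_modules),
                               times = config@module_sizes)
  }
  oi_driven <- seq_len(config@n_oi_modules)

  truth <- list(
    gene_meta = gene_meta,
    planted_cis = planted_cis,
    planted_trans = planted_trans,
    oi_causal_snps = causal,
    de_genes = de_genes,
    module_labels = module_labels,
    oi_driven_modules = oi_driven,
    baselines = stats::rnorm(nG, 4, 1.5),
    sex_effects = stats::rnorm(nG, 0, config@sex_effect_sd))

  counts <- simulateExpression(geno, sel, truth, config)
  ppi <- simulatePPI(genes, module_labels, ppiWithin, ppiBackground)

  samples <- data.frame(sample_id = names(oi), sex = unname(sex),
                        oi = unname(oi),
                        group = "none", row.names = NULL)
  samples$group[match(sel$sample_id, samples$sample_id)] <-
    as.character(sel$group)

  new("SimulatedStudy", genotypes = geno, counts = counts,
      samples = samples, ppi = ppi, truth = truth, config = config)
}
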