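#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData assayNames
NULL

#' Configuration of a synthetic F2 intercross study
#'
#' Holds every parameter of the study generator: the genome grid, the genetic
#' architecture of the Obesity Index (OI), the planted expression signals
#' (cis/trans eQTLs, OI-associated genes, sex effects, co-expression modules)
#' and the negative-binomial count model.  Defaults correspond to the
#' scaled-down study the package's own validation uses; see
#' \code{\link{simulationConfig}} for the meaning and units of each field.
#'
#' @slot n_f2 number of F2 animals.
#' @slot n_chrom number of chromosomes.
#' @slot chrom_length_bp chromosome length in bp (all chromosomes equal).
#' @slot n_snps_per_chrom SNPs per chromosome.
#' @slot genetic_map_cm_per_mb genetic map density, cM per Mb.
#' @slot n_genes number of genes.
#' @slot n_causal_oi_snps number of SNPs with additive effects on the OI.
#' @slot oi_heritability fraction of OI variance that is genetic, in [0,1].
#' @slot n_cis_eqtl number of planted cis-eQTL (SNP, gene) pairs.
#' @slot n_trans_eqtl number of planted trans-eQTL pairs.
#' @slot cis_effect_sd planted cis/trans allelic effect, log2 units per
#'   alternate allele (effects drawn with this magnitude, random sign).
#' @slot n_de_genes number of genes with a planted OI slope.
#' @slot de_effect_range length-2 numeric, |slope| range in log2 units per OI
#'   standard deviation.
#' @slot n_modules number of planted co-expression modules.
#' @slot module_sizes integer vector of module sizes (length n_modules).
#' @slot module_cor latent-factor loading in [0,1]; within-module expression
#'   correlation is approximately module_cor^2... see vignette.
#' @slot n_oi_modules number of modules whose latent factor is the scaled OI.
#' @slot nb_dispersion negative-binomial dispersion (1/size), shared.
#' @slot libsize_range length-2 numeric, range of per-sample library sizes.
#' @slot sex_effect_sd SD of per-gene sex effects, log2 units.
#' @slot cis_window_bp cis window used when placing planted cis pairs.
#' @slot n_f1_pairs number of F1 mating pairs F2s are drawn from.
#' @slot seed integer seed making the whole study reproducible.
#' @export
setClass("SimulationConfig", representation(
  n_f2 = "integer", n_chrom = "integer", chrom_length_bp = "numeric",
  n_snps_per_chrom = "integer", genetic_map_cm_per_mb = "numeric",
  n_genes = "integer", n_causal_oi_snps = "integer",
  oi_heritability = "numeric", n_cis_eqtl = "integer",
  n_trans_eqtl = "integer", cis_effect_sd = "numeric",
  n_de_genes = "integer", de_effect_range = "numeric",
  n_modules = "integer", module_sizes = "integer", module_cor = "numeric",
  n_oi_modules = "integer", nb_dispersion = "numeric",
  libsize_range = "numeric", sex_effect_sd = "numeric",
  cis_window_bp = "numeric", n_f1_pairs = "integer", seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  pos <- c(n_f2 = object@n_f2, n_chrom = object@n_chrom,
           chrom_length_bp = object@chrom_length_bp,
           n_snps_per_chrom = object@n_snps_per_chrom,
           n_genes = object@n_genes, nb_dispersion = object@nb_dispersion)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad))
    msg <- c(msg, paste0("fields must be positive: ",
                         paste(bad, collapse = ", ")))
  if (object@oi_heritability < 0 || object@oi_heritability > 1)
    msg <- c(msg, "oi_heritability must lie in [0, 1]")
  if (sum(object@module_sizes) > object@n_genes)
    msg <- c(msg, "module_sizes must sum to at most n_genes")
  if (length(object@module_sizes) != object@n_modules)
    msg <- c(msg, "module_sizes must have length n_modules")
  if (object@n_cis_eqtl > object@n_genes)
    msg <- c(msg, "n_cis_eqtl must not exceed n_genes")
  if (object@n_oi_modules > object@n_modules)
    msg <- c(msg, "n_oi_modules must not exceed n_modules")
  if (length(object@de_effect_range) != 2L ||
      any(object@de_effect_range < 0) || diff(object@de_effect_range) < 0)
    msg <- c(msg, "de_effect_range must be an increasing non-negative pair")
  if (length(object@libsize_range) != 2L || any(object@libsize_range <= 0) ||
      diff(object@libsize_range) < 0)
    msg <- c(msg, "libsize_range must be an increasing positive pair")
  if (object@module_cor < 0 || object@module_cor > 1)
    msg <- c(msg, "module_cor must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Genotype dosage matrix for a SNP panel
#'
#' Samples-by-SNPs alternate-allele dosages (0/1/2, \code{NA} = missing call)
#' plus per-SNP metadata (chromosome, 1-based position, ref/alt alleles).
#'
#' @slot dosage integer matrix, samples x SNPs, entries in \{0,1,2,NA\}.
#' @slot snpMeta \code{DataFrame} with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, one row per SNP.
#' @export
setClass("GenotypeMatrix", representation(
  dosage = "matrix", snpMeta = "DataFrame"
))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  d <- object@dosage
  if (!all(d[!is.na(d)] %in% 0:2))
    msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  if (nrow(object@snpMeta) != ncol(d))
    msg <- c(msg, "snpMeta must have one row per SNP column")
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% colnames(object@snpMeta)))
    msg <- c(msg, paste0("snpMeta must have columns ",
                         paste(need, collapse = ", ")))
  else if (any(object@snpMeta$pos <= 0))
    msg <- c(msg, "SNP positions must be positive (1-based)")
  if (is.null(rownames(d)) || is.null(colnames(d)))
    msg <- c(msg, "dosage must carry sample (row) and SNP (column) names")
  if (length(msg)) msg else TRUE
})

#' Raw gene-level expression counts with gene coordinates
#'
#' A \code{SummarizedExperiment} whose single \code{counts} assay is a
#' genes-by-samples non-negative integer matrix; \code{rowData} carries the
#' gene annotation (\code{chrom}, \code{tss}, \code{strand}; \code{NA} where a
#' gene could not be annotated) and \code{colData} the sample table (sex, OI,
#' profiling group, phenotypes).
#'
#' @export
setClass("ExpressionCounts", contains = "SummarizedExperiment")

setValidity("ExpressionCounts", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "an assay named 'counts' is required")
  else {
    m <- assay(object, "counts")
    if (any(!is.finite(m)) || any(m < 0) || any(m != round(m)))
      msg <- c(msg, "counts must be finite non-negative integers")
  }
  if (!all(c("chrom", "tss") %in% colnames(rowData(object))))
    msg <- c(msg, "rowData must have columns chrom and tss")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Processed continuous expression matrix
#'
#' A \code{SummarizedExperiment} holding the continuous genes-by-samples
#' matrix produced by a normalization stack (\code{values} assay), optional
#' precision weights (\code{weights} assay), and provenance: the ordered list
#' of applied transforms and the number of removed principal components, kept
#' in \code{metadata()}.
#'
#' @export
setClass("ProcessedExpression", contains = "SummarizedExperiment")

setValidity("ProcessedExpression", function(object) {
  msg <- character()
  if (!"values" %in% assayNames(object))
    msg <- c(msg, "an assay named 'values' is required")
  else if (any(!is.finite(assay(object, "values"))))
    msg <- c(msg, "values must be finite")
  if ("weights" %in% assayNames(object) &&
      any(assay(object, "weights") <= 0))
    msg <- c(msg, "weights must be positive")
  if (length(msg)) msg else TRUE
})

#' A complete simulated F2 study
#'
#' Bundles the generated genotypes, expression counts (with the sample table
#' in \code{colData}), protein-protein interaction edges, and the planted
#' truth used by recovery tests.
#'
#' @slot genotypes \code{\link{GenotypeMatrix}} over all F2 animals.
#' @slot counts \code{\link{ExpressionCounts}} over the profiled subset.
#' @slot samples \code{data.frame}: sample_id, sex, oi, group for all animals.
#' @slot ppi \code{data.frame} of undirected PPI edges (protein_a, protein_b).
#' @slot truth named \code{list}: planted_cis, planted_trans, oi_causal_snps,
#'   de_genes, module_labels, oi_driven_modules.
#' @slot config the \code{\link{SimulationConfig}} that generated the study.
#' @export
setClass("SimulatedStudy", representation(
  genotypes = "GenotypeMatrix", counts = "ExpressionCounts",
  samples = "data.frame", ppi = "data.frame", truth = "list",
  config = "SimulationConfig"
))

setValidity("SimulatedStudy", function(object) {
  msg <- character()
  if (!all(colnames(object@counts) %in% rownames(object@genotypes@dosage)))
    msg <- c(msg, "profiled sample ids must exist in the genotype matrix")
  tr <- object@truth
  need <- c("planted_cis", "planted_trans", "oi_causal_snps", "de_genes",
            "module_labels", "oi_driven_modules")
  if (!all(need %in% names(tr)))
    msg <- c(msg, paste0("truth must contain: ", paste(need, collapse = ", ")))
  else {
    ids <- colnames(object@genotypes@dosage)
    genes <- rownames(object@counts)
    if (nrow(tr$planted_cis) &&
        (!all(tr$planted_cis$snp %in% ids) ||
         !all(tr$planted_cis$gene %in% genes)))
      msg <- c(msg, "planted_cis refers to unknown snp or gene ids")
    if (nrow(tr$planted_trans) &&
        (!all(tr$planted_trans$snp %in% ids) ||
         !all(tr$planted_trans$gene %in% genes)))
      msg <- c(msg, "planted_trans refers to unknown snp or gene ids")
  }
  if (length(msg)) msg else TRUE
})

#' Co-expression module set
#'
#' Result container of the supervised WGCNA stage: module labels, eigengenes,
#' module membership (kME), module-trait relationships and hub genes.
#'
#' @slot labels named integer vector, gene -> module id (0 = unassigned).
#' @slot eigengenes modules x samples matrix of unit-variance eigengenes.
#' @slot varExplained per-module fraction of variance explained.
#' @slot kme genes x modules matrix of gene-eigengene correlations.
#' @slot mtr \code{data.frame} of module-trait correlations and p values.
#' @slot hubs \code{data.frame} of hub calls per module.
#' @export
setClass("ModuleSet", representation(
  labels = "integer", eigengenes = "matrix", varExplained = "numeric",
  kme = "matrix", mtr = "data.frame", hubs = "data.frame"
))

setValidity("ModuleSet", function(object) {
  msg <- character()
  if (is.null(names(object@labels)))
    msg <- c(msg, "labels must be named by gene id")
  if (length(object@kme) && max(abs(object@kme), na.rm = TRUE) > 1 + 1e-8)
    msg <- c(msg, "|kME| must not exceed 1")
  if (length(msg)) msg else TRUE
})
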