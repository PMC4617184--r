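#' @include AllClasses.R
NULL

#' Construct a SimulationConfig
#'
#' Defaults describe the scaled-down F2 study used throughout the package's
#' validation: 279 F2 animals from a divergent two-breed intercross genotyped
#' on a 2-chromosome, 2,000-SNP panel, a heritable aggregate Obesity Index
#' driven by 50 causal SNPs, and 1,000 adipose genes carrying 40 planted
#' cis-eQTLs (0.8 log2 units per alternate allele), 5 trans-eQTLs, 100
#' OI-associated genes (slopes of 0.5-1 log2 units per OI standard
#' deviation), sex effects, and 3 correlated modules (one driven by the OI).
#'
#' @param n_f2 number of F2 animals.
#' @param n_chrom,chrom_length_bp,n_snps_per_chrom genome grid: chromosome
#'   count, length (bp) and SNPs per chromosome (equally spaced).
#' @param genetic_map_cm_per_mb genetic map density in cM/Mb.
#' @param n_genes number of genes.
#' @param n_causal_oi_snps,oi_heritability genetic architecture of the OI.
#' @param n_cis_eqtl,n_trans_eqtl,cis_effect_sd planted eQTL pairs and their
#'   allelic effect magnitude (log2 units per alternate allele; random sign).
#' @param n_de_genes,de_effect_range planted OI-associated genes; absolute
#'   slope range in log2 units per OI standard deviation.
#' @param n_modules,module_sizes,module_cor,n_oi_modules planted
#'   co-expression modules: count, sizes, latent-factor loading, and how many
#'   modules use the scaled OI as their latent factor.
#' @param nb_dispersion shared negative-binomial dispersion (1/size).
#' @param libsize_range per-sample library-size range (uniform draw).
#' @param sex_effect_sd SD of per-gene additive sex effects (log2 units).
#' @param cis_window_bp window within which planted cis pairs are placed.
#' @param n_f1_pairs number of F1 mating pairs the F2s descend from.
#' @param seed integer seed; the whole study is reproducible given the config.
#' @return a validated \code{\link{SimulationConfig-class}} object.
#' @examples
#' cfg <- simulationConfig(n_f2 = 50, n_snps_per_chrom = 100, n_genes = 50,
#'                         n_cis_eqtl = 5, n_de_genes = 5,
#'                         n_modules = 1, module_sizes = 10)
#' cfg
#' @export
simulationConfig <- function(n_f2 = 279L, n_chrom = 2L,
                             chrom_length_bp = 1e8, n_snps_per_chrom = 1000L,
                             genetic_map_cm_per_mb = 1,
                             n_genes = 1000L, n_causal_oi_snps = 50L,
                             oi_heritability = 0.7,
                             n_cis_eqtl = 40L, n_trans_eqtl = 5L,
                             cis_effect_sd = 0.8,
                             n_de_genes = 100L, de_effect_range = c(0.5, 1),
                             n_modules = 3L, module_sizes = c(60L, 50L, 40L),
                             module_cor = 0.8,
                             n_oi_modules = min(1L, n_modules),
                             nb_dispersion = 0.1,
                             libsize_range = c(1e6, 2e6),
                             sex_effect_sd = 0.2, cis_window_bp = 1e6,
                             n_f1_pairs = 40L, seed = 1L) {
  new("SimulationConfig",
      n_f2 = as.integer(n_f2), n_chrom = as.integer(n_chrom),
      chrom_length_bp = as.numeric(chrom_length_bp),
      n_snps_per_chrom = as.integer(n_snps_per_chrom),
      genetic_map_cm_per_mb = as.numeric(genetic_map_cm_per_mb),
      n_genes = as.integer(n_genes),
      n_causal_oi_snps = as.integer(n_causal_oi_snps),
      oi_heritability = as.numeric(oi_heritability),
      n_cis_eqtl = as.integer(n_cis_eqtl),
      n_trans_eqtl = as.integer(n_trans_eqtl),
      cis_effect_sd = as.numeric(cis_effect_sd),
      n_de_genes = as.integer(n_de_genes),
      de_effect_range = as.numeric(de_effect_range),
      n_modules = as.integer(n_modules),
      module_sizes = as.integer(module_sizes),
      module_cor = as.numeric(module_cor),
      n_oi_modules = as.integer(n_oi_modules),
      nb_dispersion = as.numeric(nb_dispersion),
      libsize_range = as.numeric(libsize_range),
      sex_effect_sd = as.numeric(sex_effect_sd),
      cis_window_bp = as.numeric(cis_window_bp),
      n_f1_pairs = as.integer(n_f1_pairs), seed = as.integer(seed))
}

#' Construct a GenotypeMatrix
#'
#' @param dosage samples x SNPs matrix of alternate-allele dosages (0/1/2,
#'   \code{NA} missing), with row and column names.
#' @param snpMeta per-SNP annotation with columns \code{chrom}, \code{pos}
#'   (1-based), \code{ref}, \code{alt}.
#' @return a validated \code{\link{GenotypeMatrix-class}}.
#' @export
GenotypeMatrix <- function(dosage, snpMeta) {
  storage.mode(dosage) <- "integer"
  meta <- as(as.data.frame(snpMeta), "DataFrame")
  rownames(meta) <- colnames(dosage)
  new("GenotypeMatrix", dosage = dosage, snpMeta = meta)
}

#' Construct an ExpressionCounts object
#'
#' @param counts genes x samples non-negative integer matrix with dimnames.
#' @param geneMeta per-gene annotation (\code{chrom}, \code{tss},
#'   \code{strand}); genes absent from it are retained with \code{NA}
#'   coordinates and flagged un-annotatable (excluded from cis/trans
#'   classification, used everywhere else).  Must carry gene ids either as
#'   row names or in a \code{gene} column.
#' @param sampleData per-sample table (sex, oi, group, phenotypes), matched
#'   to \code{colnames(counts)} by row names or a \code{sample_id} column.
#' @return a validated \code{\link{ExpressionCounts-class}}.
#' @export
ExpressionCounts <- function(counts, geneMeta = NULL, sampleData = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene (row) and sample (column) names")
  storage.mode(counts) <- "integer"
  rd <- DataFrame(chrom = rep(NA_character_, nrow(counts)),
                  tss = rep(NA_real_, nrow(counts)),
                  strand = rep(NA_character_, nrow(counts)),
                  row.names = rownames(counts))
  if (!is.null(geneMeta)) {
    gm <- as.data.frame(geneMeta)
    if ("gene" %in% colnames(gm) && anyDuplicated(gm$gene))
      stop("duplicate gene ids in annotation")
    ids <- if ("gene" %in% colnames(gm)) gm$gene else rownames(gm)
    hit <- match(rownames(counts), ids)
    for (col in intersect(c("chrom", "tss", "strand"), colnames(gm)))
      rd[[col]][!is.na(hit)] <- gm[[col]][hit[!is.na(hit)]]
  }
  rd$annotated <- !is.na(rd$chrom) & !is.na(rd$tss)
  cd <- DataFrame(row.names = colnames(counts))
  if (!is.null(sampleData)) {
    sd <- as.data.frame(sampleData)
    ids <- if ("sample_id" %in% colnames(sd)) sd$sample_id else rownames(sd)
    hit <- match(colnames(counts), ids)
    if (anyNA(hit))
      stop("sampleData is missing samples: ",
           paste(colnames(counts)[is.na(hit)], collapse = ", "))
    sd <- sd[hit, setdiff(colnames(sd), "sample_id"), drop = FALSE]
    rownames(sd) <- colnames(counts)
    cd <- as(sd, "DataFrame")
  }
  new("ExpressionCounts",
      SummarizedExperiment(assays = list(counts = counts),
                           rowData = rd, colData = cd))
}

# Internal: wrap a continuous matrix as ProcessedExpression, carrying over
# rowData/colData from a template SummarizedExperiment when supplied.
.processedExpression <- function(values, weights = NULL, template = NULL,
                                 provenance = character(),
                                 removed_pcs = 0L) {
  assays <- list(values = values)
  if (!is.null(weights)) assays$weights <- weights
  if (!is.null(template)) {
    se <- SummarizedExperiment(
      assays = assays,
      rowData = rowData(template)[match(rownames(values), rownames(template)), ,
                                  drop = FALSE],
      colData = colData(template)[colnames(values), , drop = FALSE])
  } else {
    se <- SummarizedExperiment(assays = assays)
  }
  out <- new("ProcessedExpression", se)
  metadata(out)$provenance <- provenance
  metadata(out)$removed_pcs <- as.integer(removed_pcs)
  out
}

# Internal: append a provenance entry.
.addProvenance <- function(pe, entry) {
  metadata(pe)$provenance <- c(metadata(pe)$provenance, entry)
  pe
}
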