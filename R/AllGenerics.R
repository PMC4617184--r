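#' @include AllClasses.R
NULL

#' Accessors for sygnet data classes
#'
#' \code{dosage} returns the samples-by-SNPs dosage matrix; \code{snpMeta}
#' the per-SNP annotation; \code{snpIDs}/\code{sampleIDs} the identifier
#' vectors; \code{counts} the raw count assay; \code{exprValues} the
#' processed continuous matrix; \code{exprWeights} the precision weights (or
#' \code{NULL}); \code{provenance} the ordered transform log;
#' \code{removedPCs} the number of principal components projected out;
#' \code{moduleLabels}, \code{moduleEigengeneMatrix}, \code{moduleKME},
#' \code{moduleTraitTable} and \code{moduleHubs} the \code{ModuleSet} slots.
#'
#' @param object a sygnet S4 object.
#' @return the slot value described above.
#' @name accessors
#' @aliases dosage snpMeta snpIDs sampleIDs exprValues exprWeights provenance
#'   removedPCs moduleLabels moduleEigengeneMatrix moduleKME moduleTraitTable
#'   moduleHubs
NULL

#' @rdname accessors
#' @export
setGeneric("dosage", function(object) standardGeneric("dosage"))
#' @rdname accessors
#' @export
setGeneric("snpMeta", function(object) standardGeneric("snpMeta"))
#' @rdname accessors
#' @export
setGeneric("snpIDs", function(object) standardGeneric("snpIDs"))
#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(object) standardGeneric("sampleIDs"))
#' @rdname accessors
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("exprWeights", function(object) standardGeneric("exprWeights"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("removedPCs", function(object) standardGeneric("removedPCs"))
#' @rdname accessors
#' @export
setGeneric("moduleLabels", function(object) standardGeneric("moduleLabels"))
#' @rdname accessors
#' @export
setGeneric("moduleEigengeneMatrix",
           function(object) standardGeneric("moduleEigengeneMatrix"))
#' @rdname accessors
#' @export
setGeneric("moduleKME", function(object) standardGeneric("moduleKME"))
#' @rdname accessors
#' @export
setGeneric("moduleTraitTable",
           function(object) standardGeneric("moduleTraitTable"))
#' @rdname accessors
#' @export
setGeneric("moduleHubs", function(object) standardGeneric("moduleHubs"))

setMethod("dosage", "GenotypeMatrix", function(object) object@dosage)
setMethod("snpMeta", "GenotypeMatrix", function(object) object@snpMeta)
setMethod("snpIDs", "GenotypeMatrix",
          function(object) colnames(object@dosage))
setMethod("sampleIDs", "GenotypeMatrix",
          function(object) rownames(object@dosage))
setMethod("sampleIDs", "SummarizedExperiment",
          function(object) colnames(object))

#' @importFrom SummarizedExperiment assay assayNames
setMethod("exprValues", "ProcessedExpression",
          function(object) assay(object, "values"))
setMethod("exprWeights", "ProcessedExpression", function(object) {
  if ("weights" %in% assayNames(object)) assay(object, "weights") else NULL
})
setMethod("provenance", "ProcessedExpression",
          function(object) metadata(object)$provenance)
setMethod("removedPCs", "ProcessedExpression", function(object) {
  n <- metadata(object)$removed_pcs
  if (is.null(n)) 0L else n
})

setMethod("moduleLabels", "ModuleSet", function(object) object@labels)
setMethod("moduleEigengeneMatrix", "ModuleSet",
          function(object) object@eigengenes)
setMethod("moduleKME", "ModuleSet", function(object) object@kme)
setMethod("moduleTraitTable", "ModuleSet", function(object) object@mtr)
setMethod("moduleHubs", "ModuleSet", function(object) object@hubs)

setMethod("show", "GenotypeMatrix", function(object) {
  d <- object@dosage
  cat("GenotypeMatrix:", nrow(d), "samples x", ncol(d), "SNPs\n")
  cat("  chromosomes:",
      paste(unique(as.character(object@snpMeta$chrom)), collapse = ", "),
      "\n")
  miss <- mean(is.na(d))
  cat(sprintf("  missing rate: %.3f\n", miss))
})

setMethod("show", "SimulatedStudy", function(object) {
  cat("SimulatedStudy\n")
  cat("  genotypes:", nrow(object@genotypes@dosage), "F2 animals x",
      ncol(object@genotypes@dosage), "SNPs\n")
  cat("  expression:", nrow(object@counts), "genes x",
      ncol(object@counts), "profiled samples\n")
  tr <- object@truth
  cat("  planted: ", nrow(tr$planted_cis), " cis, ",
      nrow(tr$planted_trans), " trans, ", nrow(tr$de_genes),
      " OI-associated genes, ",
      length(unique(tr$module_labels[tr$module_labels > 0])),
      " modules\n", sep = "")
  cat("  PPI edges:", nrow(object@ppi), "\n")
})

setMethod("show", "ModuleSet", function(object) {
  sizes <- table(object@labels[object@labels > 0])
  cat("ModuleSet:", length(sizes), "modules over",
      length(object@labels), "genes\n")
  if (length(sizes))
    cat("  sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  cat("  unassigned:", sum(object@labels == 0), "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: ", object@n_f2, " F2 animals, ", object@n_chrom,
      " chrom x ", object@n_snps_per_chrom, " SNPs, ", object@n_genes,
      " genes\n", sep = "")
  cat("  planted: ", object@n_cis_eqtl, " cis / ", object@n_trans_eqtl,
      " trans eQTLs, ", object@n_de_genes, " OI genes, ",
      object@n_modules, " modules\n", sep = "")
  cat("  OI: ", object@n_causal_oi_snps, " causal SNPs, h2 = ",
      object@oi_heritability, "; seed ", object@seed, "\n", sep = "")
})
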