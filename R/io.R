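#' @include constructors.R
NULL

#' Read a genotype matrix from PLINK PED/MAP or VCF
#'
#' Dosage is the count of the alternate allele; missing genotypes are kept as
#' \code{NA}; SNPs appear in file order.  For PED/MAP, the alternate allele
#' is taken from the \code{alleles} table when given, otherwise the
#' lexicographically later of the two observed alleles (monomorphic SNPs get
#' dosage 0 relative to their single observed allele).  Non-biallelic VCF
#' records are skipped with a warning.
#'
#' @param path for \code{"pedmap"}: path without extension, or the .ped file
#'   (the .map is found next to it); for \code{"vcf"}: the VCF file.
#' @param format \code{"pedmap"} or \code{"vcf"} (default: guessed from the
#'   extension).
#' @param alleles optional \code{data.frame} (snp, ref, alt) fixing the
#'   allele coding for PED input; alleles matching neither are a parse error.
#' @return a \code{\link{GenotypeMatrix-class}}.
#' @export
readGenotypes <- function(path, format = c("auto", "pedmap", "vcf"),
                          alleles = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "pedmap"
  if (format == "vcf") .readVcfGenotypes(path)
  else .readPedMap(path, alleles)
}

.readPedMap <- function(path, alleles = NULL) {
  base <- sub("\\.ped$", "", path)
  ped <- paste0(base, ".ped"); map <- paste0(base, ".map")
  if (!file.exists(ped) || !file.exists(map))
    stop("PED/MAP pair not found at ", base)
  mp <- utils::read.table(map, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(mp) < 4L) stop("parse error in MAP file: expected 4 columns")
  colnames(mp)[1:4] <- c("chrom", "snp", "cm", "pos")
  lines <- readLines(ped)
  lines <- lines[nzchar(lines)]
  nS <- nrow(mp)
  ids <- character(length(lines))
  d <- matrix(NA_integer_, nrow = length(lines), ncol = nS)
  refalt <- matrix(NA_character_, nrow = nS, ncol = 2)
  if (!is.null(alleles)) {
    hit <- match(mp$snp, alleles$snp)
    refalt[, 1] <- alleles$ref[hit]; refalt[, 2] <- alleles$alt[hit]
  }
  allmat <- matrix(NA_character_, nrow = length(lines), ncol = 2L * nS)
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * nS)
      stop("parse error in PED line ", i, ": expected ", 6L + 2L * nS,
           " fields, got ", length(f))
    ids[i] <- f[2]
    allmat[i, ] <- f[-(1:6)]
  }
  for (s in seq_len(nS)) {
    a1 <- allmat[, 2L * s - 1L]; a2 <- allmat[, 2L * s]
    miss <- a1 == "0" | a2 == "0"
    obs <- unique(c(a1[!miss], a2[!miss]))
    if (is.na(refalt[s, 1])) {
      obs <- sort(obs)
      if (length(obs) > 2L)
        stop("parse error: SNP ", mp$snp[s], " has more than two alleles")
      refalt[s, ] <- c(obs[1], if (length(obs) == 2L) obs[2] else NA)
    } else {
      bad <- !miss & !(a1 %in% refalt[s, ] & a2 %in% refalt[s, ])
      if (any(bad))
        stop("parse error in PED line ", which(bad)[1], ": allele at SNP ",
             mp$snp[s], " matches neither REF nor ALT")
    }
    alt <- refalt[s, 2]
    ds <- (a1 == alt) + (a2 == alt)
    if (is.na(alt)) ds <- rep(0L, length(a1))
    ds[miss] <- NA_integer_
    d[, s] <- as.integer(ds)
  }
  rownames(d) <- ids
  colnames(d) <- mp$snp
  GenotypeMatrix(d, data.frame(chrom = as.character(mp$chrom), pos = mp$pos,
                               ref = refalt[, 1],
                               alt = ifelse(is.na(refalt[, 2]), "N",
                                            refalt[, 2])))
}

#' @importFrom vcfR read.vcfR extract.gt getFIX
.readVcfGenotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  bi <- !grepl(",", fix$ALT) & nchar(fix$REF) >= 1
  if (any(!bi))
    warning(sum(!bi), " non-biallelic VCF record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[bi, , drop = FALSE]
  fix <- fix[bi, , drop = FALSE]
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  gtclean <- gsub("\\|", "/", gt)
  d <- matrix(unname(code[gtclean]), nrow = nrow(gt), dimnames = dimnames(gt))
  d <- t(d)  # samples x SNPs; unrecognized/missing calls become NA
  storage.mode(d) <- "integer"
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[
    is.na(ids) | ids == "."]
  colnames(d) <- ids
  GenotypeMatrix(d, data.frame(chrom = fix$CHROM,
                               pos = as.numeric(fix$POS),
                               ref = fix$REF, alt = fix$ALT))
}

#' Read a count matrix and BED-like gene annotation
#'
#' The counts TSV must have gene ids in the first column and one column per
#' sample; the annotation is BED-like (chrom, start, end, gene, score,
#' strand; 0-based half-open).  The TSS is \code{start + 1} on the + strand
#' and \code{end} on the - strand (converted to 1-based).  Genes present in
#' the counts but absent from the annotation are retained but flagged
#' un-annotatable.
#'
#' @param countsPath TSV of integer counts.
#' @param annotPath BED-like annotation (or \code{NULL} for none).
#' @param sampleData optional per-sample table (see
#'   \code{\link{ExpressionCounts}}).
#' @return an \code{\link{ExpressionCounts-class}}.
#' @export
readCountsAndAnnotation <- function(countsPath, annotPath = NULL,
                                    sampleData = NULL) {
  tab <- utils::read.table(countsPath, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop("duplicate gene ids in counts")
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (any(m < 0)) stop("negative counts")
  if (any(m != round(m))) stop("counts must be integers")
  rownames(m) <- ids
  gm <- NULL
  if (!is.null(annotPath)) gm <- readBedAnnotation(annotPath)
  ExpressionCounts(m, geneMeta = gm, sampleData = sampleData)
}

#' Read BED-like gene annotation into a gene-meta table
#'
#' @param path BED file: chrom, start, end, gene, score, strand (tab
#'   separated, 0-based half-open intervals).
#' @return \code{data.frame} with gene, chrom, tss (1-based), strand.
#' @export
readBedAnnotation <- function(path) {
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) stop("BED annotation needs at least 4 columns")
  strand <- if (ncol(bed) >= 6L) bed[[6]] else "+"
  tss <- ifelse(strand == "-", bed[[3]], bed[[2]] + 1L)
  data.frame(gene = bed[[4]], chrom = bed[[1]], tss = tss, strand = strand)
}

#' Write a simulated study to disk in standard formats
#'
#' Genotypes go to PLINK PED/MAP (and optionally VCF v4.2), counts to a TSV
#' matrix, gene annotation to BED (0-based half-open, 1-bp TSS feature on the
#' annotated strand), samples and PPI edges to TSV, and the planted truth to
#' a set of TSV files under \code{truth_*}.
#'
#' @param study a \code{\link{SimulatedStudy-class}}.
#' @param dir output directory (created if needed).
#' @param vcf also write genotypes as VCF v4.2.
#' @return invisibly, the vector of written file paths.
#' @export
writeStudy <- function(study, dir, vcf = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  g <- study@genotypes
  paths <- c(paths, writePedMap(g, file.path(dir, "genotypes")))
  if (vcf) paths <- c(paths, writeVcf(g, file.path(dir, "genotypes.vcf")))
  cm <- assay(study@counts, "counts")
  p <- file.path(dir, "counts.tsv")
  utils::write.table(data.frame(gene = rownames(cm), cm, check.names = FALSE),
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  gm <- study@truth$gene_meta
  p <- file.path(dir, "genes.bed")
  bed <- data.frame(chrom = gm$chrom,
                    start = ifelse(gm$strand == "-", gm$tss - 1L, gm$tss - 1L),
                    end = ifelse(gm$strand == "-", gm$tss, gm$tss),
                    gene = gm$gene, score = 0L, strand = gm$strand)
  utils::write.table(bed, p, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "samples.tsv")
  utils::write.table(study@samples, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "ppi.tsv")
  utils::write.table(study@ppi, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  tr <- study@truth
  for (nm in c("planted_cis", "planted_trans", "oi_causal_snps",
               "de_genes")) {
    p <- file.path(dir, paste0("truth_", nm, ".tsv"))
    utils::write.table(tr[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "truth_module_labels.tsv")
  utils::write.table(data.frame(gene = names(tr$module_labels),
                                module = unname(tr$module_labels)),
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}

#' Write genotypes as PLINK PED/MAP
#'
#' @param genotypes a \code{\link{GenotypeMatrix-class}}.
#' @param base output path without extension.
#' @return invisibly, the two file paths.
#' @export
writePedMap <- function(genotypes, base) {
  sm <- snpMeta(genotypes)
  d <- dosage(genotypes)
  mp <- data.frame(chrom = sm$chrom, snp = colnames(d), cm = 0,
                   pos = as.integer(sm$pos))
  utils::write.table(mp, paste0(base, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ref <- as.character(sm$ref); alt <- as.character(sm$alt)
  n <- nrow(d)
  con <- file(paste0(base, ".ped"), "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    ds <- d[i, ]
    a1 <- ifelse(is.na(ds), "0", ifelse(ds >= 1, alt, ref))
    a2 <- ifelse(is.na(ds), "0", ifelse(ds == 2, alt, ref))
    writeLines(paste(c("FAM1", rownames(d)[i], "0", "0", "0", "-9",
                       as.vector(rbind(a1, a2))), collapse = " "), con)
  }
  invisible(c(paste0(base, ".ped"), paste0(base, ".map")))
}

#' Write genotypes as VCF v4.2
#'
#' @param genotypes a \code{\link{GenotypeMatrix-class}}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeVcf <- function(genotypes, path) {
  sm <- snpMeta(genotypes)
  d <- dosage(genotypes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(d)), collapse = "\t")), con)
  gtcode <- c("0/0", "0/1", "1/1")
  for (s in seq_len(ncol(d))) {
    ds <- d[, s]
    gt <- ifelse(is.na(ds), "./.", gtcode[ds + 1L])
    writeLines(paste(c(as.character(sm$chrom[s]), as.integer(sm$pos[s]),
                       colnames(d)[s], as.character(sm$ref[s]),
                       as.character(sm$alt[s]), ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a result table as a TSV with stable ordering
#'
#' Rows are sorted by p value (if a \code{p_value} column exists) and then by
#' the remaining columns left to right, so reruns on identical input give
#' byte-identical files.
#'
#' @param records a \code{data.frame}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeResultsTSV <- function(records, path) {
  df <- as.data.frame(records)
  if (nrow(df)) {
    keys <- df[intersect(c("p_value", names(df)), names(df))]
    df <- df[do.call(order, unname(keys)), , drop = FALSE]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a graph as GraphML and as an edge-list TSV
#'
#' @param graph an \code{igraph} object.
#' @param base output path without extension; writes \code{<base>.graphml}
#'   and \code{<base>_edges.tsv}.
#' @return invisibly, the two paths.
#' @importFrom igraph write_graph as_data_frame
#' @export
writeGraphFiles <- function(graph, base) {
  gml <- paste0(base, ".graphml")
  igraph::write_graph(graph, gml, format = "graphml")
  el <- igraph::as_data_frame(graph, what = "edges")
  tsv <- paste0(base, "_edges.tsv")
  utils::write.table(el, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(gml, tsv))
}
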