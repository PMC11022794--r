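#' Read gene models from a GFF3 file
#'
#' Imports the file and keeps features of type `gene`, returning their
#' 1-based inclusive coordinates and strand.
#'
#' @param path GFF3 file.
#' @return data.frame: `gene` (id), `chrom`, `start`, `end`, `strand`.
#' @export
readGff <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   stop("failed to parse GFF3 '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  gr <- gr[gr$type == "gene"]
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$Name
  if (is.null(ids)) ids <- paste0("gene", seq_along(gr))
  data.frame(gene = as.character(ids),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Map SNPs to genes with flanking regions
#'
#' A site hits a gene when
#' `gene.start - flank <= pos <= gene.end + flank` (closed boundaries).
#' Hits inside the gene body are `within` (distance 0); flank hits are
#' `upstream-flank` or `downstream-flank` relative to the gene's strand,
#' with `distance` the base pairs from the nearest gene boundary. A SNP
#' may hit several overlapping genes; all hits are reported, sorted by
#' (chrom, pos).
#'
#' @param sites data.frame with `chrom` and `pos` columns (e.g.
#'   [siteInfo()] rows for selected SNPs); a `site` id column is carried
#'   through if present, otherwise built as chrom:pos.
#' @param genes data.frame from [readGff()].
#' @param flank flanking-region width in bp (default 1000).
#' @return data.frame: `site`, `chrom`, `pos`, `gene`, `relation`,
#'   `distance`.
#' @export
mapSnpsToGenes <- function(sites, genes, flank = 1000L) {
  if (is.null(sites$site)) sites$site <- siteIds(sites)
  if (nrow(sites) == 0 || nrow(genes) == 0)
    return(data.frame(site = character(0), chrom = character(0),
                      pos = integer(0), gene = character(0),
                      relation = character(0), distance = integer(0)))
  stopifnot(all(genes$start <= genes$end))
  snpGr <- GenomicRanges::GRanges(sites$chrom,
                                  IRanges::IRanges(sites$pos, sites$pos))
  geneGr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1L, genes$start - flank), genes$end + flank),
    strand = genes$strand)
  ov <- GenomicRanges::findOverlaps(snpGr, geneGr, ignore.strand = TRUE)
  si <- S4Vectors::queryHits(ov)
  gi <- S4Vectors::subjectHits(ov)
  pos <- sites$pos[si]
  gStart <- genes$start[gi]
  gEnd <- genes$end[gi]
  strand <- genes$strand[gi]
  within <- pos >= gStart & pos <= gEnd
  before <- pos < gStart
  # upstream = 5' of the gene: before start on '+', after end on '-'
  relation <- ifelse(within, "within",
               ifelse((before & strand != "-") | (!before & strand == "-"),
                      "upstream-flank", "downstream-flank"))
  distance <- ifelse(within, 0L,
                     ifelse(before, gStart - pos, pos - gEnd))
  out <- data.frame(site = sites$site[si], chrom = sites$chrom[si],
                    pos = pos, gene = genes$gene[gi], relation = relation,
                    distance = as.integer(distance),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos, out$gene), , drop = FALSE]
}

#' Candidate-gene table from SNP-gene hits
#'
#' One row per gene hit by at least one SNP: the number of hitting SNPs,
#' the best (largest) consensus model count among them, a summary of the
#' hit relations, and an optional functional-annotation passthrough.
#'
#' @param hits data.frame from [mapSnpsToGenes()].
#' @param consensus optional [ConsensusSet-class] supplying model counts.
#' @param annotation optional named character vector (gene id -> text).
#' @return data.frame: `gene`, `nSnps`, `bestModelCount`, `relations`,
#'   and `annotation` when provided.
#' @export
candidateTable <- function(hits, consensus = NULL, annotation = NULL) {
  if (!nrow(hits)) {
    out <- data.frame(gene = character(0), nSnps = integer(0),
                      bestModelCount = integer(0), relations = character(0))
    if (!is.null(annotation)) out$annotation <- character(0)
    return(out)
  }
  counts <- NULL
  if (!is.null(consensus))
    counts <- stats::setNames(consensus@selected$modelCount,
                              consensus@selected$site)
  byGene <- split(hits, hits$gene)
  out <- data.frame(
    gene = names(byGene),
    nSnps = vapply(byGene, function(h) length(unique(h$site)), integer(1)),
    bestModelCount = vapply(byGene, function(h) {
      if (is.null(counts)) return(NA_integer_)
      v <- counts[h$site]
      if (all(is.na(v))) NA_integer_ else as.integer(max(v, na.rm = TRUE))
    }, integer(1)),
    relations = vapply(byGene, function(h)
      paste(sort(unique(h$relation)), collapse = ";"), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(annotation))
    out$annotation <- unname(annotation[out$gene])
  out[order(out$gene), , drop = FALSE]
}
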