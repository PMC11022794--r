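#' Hard-filter thresholds for VCF site import
#'
#' Defaults follow common joint-genotyping practice for low-coverage
#' resequencing panels: mapping quality MQ > 30, estimated alternate allele
#' frequency MLEAF > 0.01, site total depth 300 < DP < 1500, FisherStrand
#' FS < 60, |MQRankSum| <= 12.5, |ReadPosRankSum| <= 8,
#' |BaseQRankSum| <= 12.5, biallelic SNPs only, and at most 10% missing
#' calls per site. A site is only tested against a criterion whose
#' annotation key is actually present in its INFO field; absent keys pass.
#'
#' @param mqMin,mleafMin,dpMin,dpMax,fsMax,mqRankSumAbsMax,readPosAbsMax,baseQAbsMax
#'   numeric thresholds as described above.
#' @param biallelicOnly drop multi-allelic and non-SNP records.
#' @param maxNocallFraction drop sites with a higher fraction of missing
#'   genotype calls.
#' @return A named list of class `vcfFilterConfig`.
#' @export
vcfFilterConfig <- function(mqMin = 30, mleafMin = 0.01,
                            dpMin = 300, dpMax = 1500, fsMax = 60,
                            mqRankSumAbsMax = 12.5, readPosAbsMax = 8,
                            baseQAbsMax = 12.5, biallelicOnly = TRUE,
                            maxNocallFraction = 0.1) {
  cfg <- list(mqMin = mqMin, mleafMin = mleafMin, dpMin = dpMin,
              dpMax = dpMax, fsMax = fsMax,
              mqRankSumAbsMax = mqRankSumAbsMax,
              readPosAbsMax = readPosAbsMax, baseQAbsMax = baseQAbsMax,
              biallelicOnly = biallelicOnly,
              maxNocallFraction = maxNocallFraction)
  stopifnot(all(vapply(cfg[1:8], is.finite, logical(1))),
            maxNocallFraction >= 0, maxNocallFraction <= 1)
  class(cfg) <- "vcfFilterConfig"
  cfg
}

#' Permissive filter configuration that retains every biallelic SNP
#'
#' @param biallelicOnly see [vcfFilterConfig()].
#' @return a `vcfFilterConfig` whose numeric thresholds never reject a site.
#' @export
passAllFilters <- function(biallelicOnly = TRUE) {
  cfg <- vcfFilterConfig()
  cfg$mqMin <- -Inf; cfg$mleafMin <- -Inf
  cfg$dpMin <- -Inf; cfg$dpMax <- Inf; cfg$fsMax <- Inf
  cfg$mqRankSumAbsMax <- Inf; cfg$readPosAbsMax <- Inf
  cfg$baseQAbsMax <- Inf
  cfg$biallelicOnly <- biallelicOnly
  cfg$maxNocallFraction <- 1
  cfg
}

# dosage code for one GT string; NA for any form of missing call.
# phased (|) and unphased (/) separators are equivalent.
.gtToCode <- function(gt) {
  gt <- sub(":.*", "", gt)
  out <- rep(NA_integer_, length(gt))
  gt2 <- gsub("|", "/", gt, fixed = TRUE)
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  hit <- match(gt2, names(known))
  out[!is.na(hit)] <- known[hit[!is.na(hit)]]
  out
}

#' Read a VCF into a filtered 0/1/2 genotype matrix
#'
#' Parses a VCF 4.x file (plain or bgzipped), keeps biallelic SNP records
#' passing the hard filters, and encodes diploid genotypes as
#' alternate-allele dosage: 0/0 -> 0, 0/1 or 1/0 -> 1, 1/1 -> 2, missing
#' (`./.` or `.`) -> `NA`. INFO annotations named by the filter config are
#' carried into `siteInfo()`.
#'
#' @param path VCF file.
#' @param filters a [vcfFilterConfig()]; use [passAllFilters()] to keep all
#'   biallelic SNPs, or `NULL` for the same.
#' @return A [GenotypeMatrix-class]; site order follows the file.
#' @export
readVcfGenotypes <- function(path, filters = vcfFilterConfig()) {
  if (is.null(filters)) filters <- passAllFilters()
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e)
                    stop("failed to parse VCF '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record files
  if (is.null(fix) || nrow(vcf@gt) == 0 || ncol(vcf@gt) < 2)
    stop("VCF '", path, "' contains no samples or no records")
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gt <- vcf@gt[, -1, drop = FALSE]  # drop FORMAT column
  nSamp <- ncol(gt)

  keep <- rep(TRUE, nrow(fix))
  if (filters$biallelicOnly) {
    keep <- keep & !grepl(",", fix$ALT, fixed = TRUE) &
      nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
      fix$ALT != "." & !is.na(fix$ALT)
  }

  info <- function(key) suppressWarnings(
    as.numeric(vcfR::extract.info(vcf, element = key)))
  passNum <- function(val, ok) ifelse(is.na(val), TRUE, ok(val))
  keep <- keep & passNum(info("MQ"), function(v) v > filters$mqMin)
  keep <- keep & passNum(info("MLEAF"), function(v) v > filters$mleafMin)
  keep <- keep & passNum(info("DP"),
                         function(v) v > filters$dpMin & v < filters$dpMax)
  keep <- keep & passNum(info("FS"), function(v) v < filters$fsMax)
  keep <- keep & passNum(info("MQRankSum"),
                         function(v) abs(v) <= filters$mqRankSumAbsMax)
  keep <- keep & passNum(info("ReadPosRankSum"),
                         function(v) abs(v) <= filters$readPosAbsMax)
  keep <- keep & passNum(info("BaseQRankSum"),
                         function(v) abs(v) <= filters$baseQAbsMax)

  codes <- matrix(NA_integer_, nrow = nSamp, ncol = nrow(fix))
  for (j in which(keep)) codes[, j] <- .gtToCode(gt[j, ])
  missFrac <- colMeans(is.na(codes))
  keep <- keep & missFrac <= filters$maxNocallFraction

  codes <- codes[, keep, drop = FALSE]
  rownames(codes) <- colnames(gt)
  sites <- data.frame(chrom = fix$CHROM[keep],
                      pos = as.integer(fix$POS[keep]),
                      ref = fix$REF[keep], alt = fix$ALT[keep],
                      stringsAsFactors = FALSE)
  genotypeMatrix(codes, sites)
}

#' Write a genotype matrix in the three-file 012 text dialect
#'
#' Produces `<prefix>.012` (one row per sample: 0-based row index then
#' tab-separated dosages, missing as -1), `<prefix>.012.indv` (sample ids,
#' one per line) and `<prefix>.012.pos` (chrom TAB pos per site, column
#' order), matching the layout emitted by vcftools' `--012` export.
#'
#' @param gm GenotypeMatrix.
#' @param prefix output path prefix.
#' @return Invisibly, the three file paths.
#' @export
write012 <- function(gm, prefix) {
  codes <- genoCodes(gm)
  codes[is.na(codes)] <- -1L
  rows <- vapply(seq_len(nrow(codes)), function(i)
    paste(c(i - 1L, codes[i, ]), collapse = "\t"), character(1))
  f012 <- paste0(prefix, ".012")
  writeLines(rows, f012)
  find <- paste0(prefix, ".012.indv")
  writeLines(sampleIds(gm), find)
  fpos <- paste0(prefix, ".012.pos")
  writeLines(paste(siteInfo(gm)$chrom, siteInfo(gm)$pos, sep = "\t"), fpos)
  invisible(c(f012, find, fpos))
}

#' Read a 012 three-file set back into a GenotypeMatrix
#'
#' Inverse of [write012()]; -1 maps back to `NA`. The three files must
#' agree on sample and site counts.
#'
#' @param prefix path prefix as given to [write012()].
#' @return A [GenotypeMatrix-class]. Ref/alt alleles are not represented in
#'   the 012 dialect and come back as the placeholder pair A/T.
#' @export
read012 <- function(prefix) {
  f012 <- paste0(prefix, ".012")
  indv <- readLines(paste0(prefix, ".012.indv"))
  posLines <- readLines(paste0(prefix, ".012.pos"))
  rows <- readLines(f012)
  if (length(rows) != length(indv))
    stop("012 consistency error: ", length(rows), " rows in .012 but ",
         length(indv), " sample ids in .012.indv")
  parts <- strsplit(rows, "\t", fixed = TRUE)
  ncodes <- unique(lengths(parts)) - 1L
  if (length(ncodes) > 1)
    stop("012 consistency error: ragged rows in .012")
  if (length(posLines) != max(ncodes, 0L) && length(rows) > 0)
    stop("012 consistency error: ", ncodes, " code columns but ",
         length(posLines), " sites in .012.pos")
  codes <- matrix(NA_integer_, nrow = length(rows), ncol = length(posLines))
  for (i in seq_along(parts)) {
    v <- suppressWarnings(as.integer(parts[[i]][-1]))
    if (anyNA(v))
      stop("012 domain error: non-integer code in .012 row ", i)
    if (any(v < -1L | v > 2L))
      stop("012 domain error: code outside {-1, 0, 1, 2} in .012 row ", i)
    v[v == -1L] <- NA_integer_
    codes[i, ] <- v
  }
  pp <- strsplit(posLines, "\t", fixed = TRUE)
  sites <- data.frame(chrom = vapply(pp, `[`, character(1), 1),
                      pos = as.integer(vapply(pp, `[`, character(1), 2)),
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
  genotypeMatrix(codes, sites, sampleIds = indv)
}

#' Filter sites by minor allele frequency
#'
#' The alternate-allele frequency of a site is `sum(codes) / (2 * nCalled)`
#' over non-missing codes; the minor allele frequency is
#' `min(f, 1 - f)`. Sites below `mafMin` are removed, as are sites with no
#' called genotypes at all (frequency undefined). Site order is preserved
#' and the operation is idempotent.
#'
#' @param gm GenotypeMatrix.
#' @param mafMin minimum minor allele frequency in \[0, 0.5\].
#' @return The filtered [GenotypeMatrix-class].
#' @export
mafFilter <- function(gm, mafMin) {
  stopifnot(mafMin >= 0, mafMin <= 0.5)
  codes <- genoCodes(gm)
  nCalled <- colSums(!is.na(codes))
  f <- colSums(codes, na.rm = TRUE) / (2 * nCalled)
  maf <- pmin(f, 1 - f)
  keep <- !is.na(maf) & nCalled > 0 & maf >= mafMin
  gm[, which(keep)]
}

#' Read a two-column phenotype table
#'
#' Expects tab-separated `sample_id<TAB>class_label` lines; lines starting
#' with `#` are comments. No header row is assumed.
#'
#' @param path file path.
#' @param classSet optional ordered class set; defaults to sorted unique
#'   labels in the file.
#' @return A [PhenotypeTable-class].
#' @export
readPhenotypes <- function(path, classSet = NULL) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = c("sample", "label"),
                          colClasses = "character")
  phenotypeTable(df$sample, df$label, classSet = classSet)
}

#' Write a phenotype table as two tab-separated columns
#'
#' @param phenos PhenotypeTable.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writePhenotypes <- function(phenos, path) {
  writeLines(paste(phenos@samples, as.character(phenos@labels), sep = "\t"),
             path)
  invisible(path)
}
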