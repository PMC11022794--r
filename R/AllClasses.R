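#' @import methods
NULL

#' GenotypeMatrix: samples x biallelic SNP sites coded 0/1/2/NA
#'
#' Holds the alternate-allele dosage matrix produced by VCF import,
#' 012 import or simulation. Rows are samples, columns are biallelic SNP
#' sites; entries are 0 (homozygous reference), 1 (heterozygous),
#' 2 (homozygous alternate) or `NA` (missing call). Site metadata
#' (chromosome, 1-based position, ref/alt alleles, optional caller
#' annotations) lives in a parallel data.frame.
#'
#' @slot codes integer matrix, samples x sites; values in {0L, 1L, 2L, NA}.
#'   Row names are sample ids, column names are site ids ("chrom:pos").
#' @slot sites data.frame with one row per site: `chrom`, `pos` (1-based),
#'   `ref`, `alt`, plus any annotation columns carried over from the VCF.
#'
#' @seealso [genotypeMatrix()], [readVcfGenotypes()], [read012()],
#'   [simulateGenotypes()]
#' @export
setClass("GenotypeMatrix",
  representation(codes = "matrix", sites = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  codes <- object@codes
  sites <- object@sites
  if (!is.integer(codes))
    msg <- c(msg, "codes must be an integer matrix")
  if (ncol(codes) != nrow(sites))
    msg <- c(msg, "number of code columns must equal number of site rows")
  if (is.null(rownames(codes)) && nrow(codes) > 0)
    msg <- c(msg, "codes must have sample ids as row names")
  if (anyDuplicated(rownames(codes)))
    msg <- c(msg, "sample ids must be unique")
  bad <- codes[!is.na(codes)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    msg <- c(msg, "codes must lie in {0, 1, 2, NA}")
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(sites))) {
    msg <- c(msg, "sites must have columns chrom, pos, ref, alt")
  } else if (nrow(sites)) {
    if (any(sites$pos < 1)) msg <- c(msg, "site positions must be >= 1")
    if (any(sites$ref == sites$alt)) msg <- c(msg, "ref must differ from alt")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param codes numeric or integer matrix of 0/1/2/NA dosages
#'   (samples x sites); coerced to integer storage.
#' @param sites data.frame of site metadata with columns `chrom`, `pos`,
#'   `ref`, `alt` (defaults are synthesised if omitted).
#' @param sampleIds character vector of sample identifiers; defaults to the
#'   row names of `codes` or `S1..Sn`.
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' gm <- genotypeMatrix(rbind(a = c(0, 1), b = c(2, NA)))
#' nSites(gm)
#' @export
genotypeMatrix <- function(codes, sites = NULL, sampleIds = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (is.null(sampleIds))
    sampleIds <- rownames(codes)
  if (is.null(sampleIds))
    sampleIds <- paste0("S", seq_len(nrow(codes)))
  rownames(codes) <- sampleIds
  if (is.null(sites)) {
    sites <- data.frame(
      chrom = rep("chr1", ncol(codes)),
      pos = seq_len(ncol(codes)),
      ref = rep("A", ncol(codes)),
      alt = rep("T", ncol(codes)),
      stringsAsFactors = FALSE)
  }
  rownames(sites) <- NULL
  colnames(codes) <- siteIds(sites)
  new("GenotypeMatrix", codes = codes, sites = sites)
}

siteIds <- function(sites) paste(sites$chrom, sites$pos, sep = ":")

#' @describeIn genotypeMatrix Number of samples.
#' @param x a `GenotypeMatrix`.
#' @export
nSamples <- function(x) nrow(x@codes)

#' @describeIn genotypeMatrix Number of sites.
#' @export
nSites <- function(x) ncol(x@codes)

#' @describeIn genotypeMatrix Sample identifiers.
#' @export
sampleIds <- function(x) {
  if (is(x, "GenotypeMatrix")) rownames(x@codes) else x@samples
}

#' @describeIn genotypeMatrix Site metadata data.frame.
#' @export
siteInfo <- function(x) x@sites

#' @describeIn genotypeMatrix The integer dosage matrix.
#' @export
genoCodes <- function(x) x@codes

setMethod("show", "GenotypeMatrix", function(object) {
  miss <- mean(is.na(object@codes))
  cat("GenotypeMatrix:", nSamples(object), "samples x", nSites(object),
      "sites\n")
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  if (nSites(object)) {
    ch <- unique(object@sites$chrom)
    cat("  contigs:", paste(utils::head(ch, 5), collapse = ", "),
        if (length(ch) > 5) "..." else "", "\n")
  }
})

#' Subset a GenotypeMatrix by samples (i) and/or sites (j)
#'
#' @param x GenotypeMatrix
#' @param i sample index/names
#' @param j site index/names
#' @param ... ignored
#' @param drop ignored; never drops dimensions
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  codes <- x@codes
  sites <- x@sites
  if (!missing(j)) {
    if (is.character(j)) j <- match(j, colnames(codes))
    codes <- codes[, j, drop = FALSE]
    sites <- sites[j, , drop = FALSE]
    rownames(sites) <- NULL
  }
  if (!missing(i)) codes <- codes[i, , drop = FALSE]
  new("GenotypeMatrix", codes = codes, sites = sites)
})

#' PhenotypeTable: sample to class-label assignment
#'
#' Maps each sample to one categorical phenotype class (e.g. a seed colour
#' group). The ordered set of allowed labels is kept as factor levels so
#' that downstream class ordering (tie-breaking, report rows) is stable.
#'
#' @slot samples character vector of unique sample ids.
#' @slot labels factor of class labels, parallel to `samples`; levels are
#'   the ordered class set.
#' @seealso [phenotypeTable()], [readPhenotypes()]
#' @export
setClass("PhenotypeTable",
  representation(samples = "character", labels = "factor"))

setValidity("PhenotypeTable", function(object) {
  msg <- character()
  if (length(object@samples) != length(object@labels))
    msg <- c(msg, "samples and labels must have equal length")
  if (anyDuplicated(object@samples))
    msg <- c(msg, "sample ids must be unique")
  if (anyNA(object@labels))
    msg <- c(msg, "every sample must have a label from the class set")
  if (length(msg)) msg else TRUE
})

#' Construct a PhenotypeTable
#'
#' @param samples character sample ids.
#' @param labels class labels (character or factor), parallel to `samples`.
#' @param classSet ordered vector of allowed labels; defaults to the sorted
#'   unique labels. Labels outside `classSet` are an error.
#' @return A [PhenotypeTable-class].
#' @examples
#' pt <- phenotypeTable(c("a", "b", "c"), c("white", "beige", "white"))
#' classCounts(pt)
#' @export
phenotypeTable <- function(samples, labels, classSet = NULL) {
  samples <- as.character(samples)
  if (is.null(classSet))
    classSet <- if (is.factor(labels)) levels(labels) else
      sort(unique(as.character(labels)))
  labels <- factor(as.character(labels), levels = classSet)
  new("PhenotypeTable", samples = samples, labels = labels)
}

#' @describeIn phenotypeTable Class labels as a factor named by sample id.
#' @param x a `PhenotypeTable`.
#' @export
classLabels <- function(x) stats::setNames(x@labels, x@samples)

#' @describeIn phenotypeTable The ordered class set.
#' @export
classSet <- function(x) levels(x@labels)

#' @describeIn phenotypeTable Per-class sample counts (in class-set order).
#' @export
classCounts <- function(x) table(x@labels)

setMethod("show", "PhenotypeTable", function(object) {
  cat("PhenotypeTable:", length(object@samples), "samples,",
      nlevels(object@labels), "classes\n")
  print(table(object@labels))
})

#' Align a PhenotypeTable to the samples of a GenotypeMatrix
#'
#' Restricts and reorders the table to the matrix's samples; errors if any
#' genotyped sample lacks a phenotype.
#' @param phenos PhenotypeTable
#' @param gm GenotypeMatrix
#' @return PhenotypeTable in `sampleIds(gm)` order.
#' @export
alignPhenotypes <- function(phenos, gm) {
  idx <- match(sampleIds(gm), phenos@samples)
  if (anyNA(idx))
    stop("samples without phenotype: ",
         paste(utils::head(sampleIds(gm)[is.na(idx)], 5), collapse = ", "))
  phenotypeTable(phenos@samples[idx], phenos@labels[idx],
                 classSet = levels(phenos@labels))
}

#' FitResult: one trained boosted classifier on one stratified split
#'
#' @slot trainIds,testIds character sample ids of the split.
#' @slot params list of hyperparameters used (including fitted `nrounds`).
#' @slot cvAuc numeric(1): mean cross-validated one-vs-rest AUC from tuning
#'   (NA when the model was fitted with fixed parameters).
#' @slot metrics list: `accuracy`, `perClass` (data.frame precision /
#'   recall / f1 / support), `macroF1`, `weightedF1`, `auc`.
#' @slot importance named numeric of per-site total gain (> 0 only),
#'   summed over every split on the site across all trees.
#' @export
setClass("FitResult",
  representation(trainIds = "character", testIds = "character",
                 params = "list", cvAuc = "numeric", metrics = "list",
                 importance = "numeric"))

setValidity("FitResult", function(object) {
  msg <- character()
  if (length(intersect(object@trainIds, object@testIds)))
    msg <- c(msg, "train and test ids must be disjoint")
  if (length(object@importance) && any(object@importance <= 0))
    msg <- c(msg, "importance gains must be strictly positive")
  m <- object@metrics
  for (nm in c("accuracy", "macroF1", "weightedF1", "auc")) {
    v <- m[[nm]]
    if (!is.null(v) && !is.na(v) && (v < 0 || v > 1))
      msg <- c(msg, paste(nm, "must lie in [0, 1]"))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "FitResult", function(object) {
  cat("FitResult:", length(object@trainIds), "train /",
      length(object@testIds), "test samples\n")
  cat(sprintf("  accuracy %.3f, weighted f1 %.3f, AUC %.3f; %d features used\n",
      object@metrics$accuracy, object@metrics$weightedF1,
      object@metrics$auc, length(object@importance)))
})

#' @describeIn trainEval Per-site gain importance of a fit (named numeric).
#' @param x a `FitResult`.
#' @export
importanceGains <- function(x) x@importance

#' @describeIn trainEval Test-set metrics list of a fit.
#' @export
testMetrics <- function(x) x@metrics

#' ConsensusSet: SNPs important in many replicate models, plus collinear additions
#'
#' @slot selected data.frame: `site`, `chrom`, `pos`, `modelCount` for sites
#'   with positive gain in at least `minModels` replicates.
#' @slot collinear data.frame: `site`, `chrom`, `pos`, `anchor`, `r` for
#'   non-selected sites correlated with a selected anchor at |r| >= rMin.
#' @slot combined character: union of selected and collinear site ids.
#' @slot minModels,nReplicates numeric scalars recording the thresholds.
#' @export
setClass("ConsensusSet",
  representation(selected = "data.frame", collinear = "data.frame",
                 combined = "character", minModels = "numeric",
                 nReplicates = "numeric"))

setValidity("ConsensusSet", function(object) {
  msg <- character()
  if (nrow(object@selected) &&
      isTRUE(any(object@selected$modelCount < object@minModels,
                 na.rm = TRUE)))
    msg <- c(msg, "selected sites must reach the minModels threshold")
  if (!setequal(object@combined,
                union(object@selected$site, object@collinear$site)))
    msg <- c(msg, "combined must be the union of selected and collinear sites")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ConsensusSet", function(object) {
  cat("ConsensusSet:", nrow(object@selected), "selected (>=",
      object@minModels, "of", object@nReplicates, "models) +",
      nrow(object@collinear), "collinear =", length(object@combined),
      "sites\n")
})

#' @describeIn consensusSelect Selected-site table of a ConsensusSet.
#' @param x a `ConsensusSet`.
#' @export
selectedSites <- function(x) x@selected

#' @describeIn consensusSelect Collinear-addition table of a ConsensusSet.
#' @export
collinearSites <- function(x) x@collinear

#' @describeIn consensusSelect Combined site-id vector of a ConsensusSet.
#' @export
combinedSites <- function(x) x@combined

#' SyntheticTruth: the planted signal behind a simulated dataset
#'
#' @slot causalIndices integer site indices carrying phenotype effects.
#' @slot effects numeric matrix (classes x causal SNPs) of liability
#'   effects per dosage unit.
#' @slot subpop integer subpopulation assignment per sample.
#' @export
setClass("SyntheticTruth",
  representation(causalIndices = "integer", effects = "matrix",
                 subpop = "integer"))

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  if (anyDuplicated(object@causalIndices))
    msg <- c(msg, "causal indices must be distinct")
  if (ncol(object@effects) != length(object@causalIndices))
    msg <- c(msg, "effects must have one column per causal SNP")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", length(object@causalIndices), "causal SNPs,",
      nrow(object@effects), "classes,", length(unique(object@subpop)),
      "subpopulations\n")
})

#' @describeIn simulateGenotypes Planted causal site indices of a truth object.
#' @param x a `SyntheticTruth`.
#' @export
causalIndices <- function(x) x@causalIndices
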