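#' Configuration for the replicate-model ensemble
#'
#' @param nReplicates number of replicate models, each on its own random
#'   stratified split (study default 100; the package demo uses 25).
#' @param minModels a site must carry positive gain importance in at least
#'   this many replicates to enter the consensus set (study default 9 of
#'   100; the demo uses 3 of 25).
#' @param nTest held-out test samples per replicate (count). `NULL` means
#'   one quarter of the panel, echoing the 71/24 split of a 95-sample
#'   design.
#' @param nTrialsPerReplicate hyperparameter-search budget per replicate;
#'   each replicate is tuned independently.
#' @param nFolds cross-validation folds inside the tuner.
#' @param maxRounds,earlyStoppingRounds boosting budget.
#' @param baseSeed integer; replicate r splits with seed `baseSeed + r`
#'   and tunes with seed `baseSeed + 100000 + r`.
#' @param aucAverage one-vs-rest AUC averaging (`"macro"` default).
#' @return list of class `ensembleConfig`.
#' @export
ensembleConfig <- function(nReplicates = 100L, minModels = 9L,
                           nTest = NULL, nTrialsPerReplicate = 250L,
                           nFolds = 4L, maxRounds = 500L,
                           earlyStoppingRounds = 35L, baseSeed = 1L,
                           aucAverage = "macro") {
  stopifnot(minModels >= 1, nReplicates >= 1)
  structure(list(nReplicates = as.integer(nReplicates),
                 minModels = as.integer(minModels),
                 nTest = if (is.null(nTest)) NULL else as.integer(nTest),
                 nTrialsPerReplicate = as.integer(nTrialsPerReplicate),
                 nFolds = as.integer(nFolds),
                 maxRounds = as.integer(maxRounds),
                 earlyStoppingRounds = as.integer(earlyStoppingRounds),
                 baseSeed = as.integer(baseSeed),
                 aucAverage = aucAverage),
            class = "ensembleConfig")
}

# one replicate: stratified split, independent tuning, final fit
.runReplicate <- function(X, phenos, config, r) {
  on.exit(gc(verbose = FALSE), add = TRUE)  # release native DMatrix memory
  nTest <- if (is.null(config$nTest)) round(nrow(X) / 4) else config$nTest
  split <- stratifiedSplit(phenos, nTest, seed = config$baseSeed + r)
  labs <- classLabels(phenos)[split$trainIds]
  hp <- tuneBoost(X[split$trainIds, , drop = FALSE], labs,
                  nTrials = config$nTrialsPerReplicate,
                  nFolds = config$nFolds,
                  seed = config$baseSeed + 100000L + r,
                  maxRounds = config$maxRounds,
                  earlyStoppingRounds = config$earlyStoppingRounds,
                  aucAverage = config$aucAverage)
  trainEval(X, phenos, split, hp, aucAverage = config$aucAverage)
}

.summariseEnsemble <- function(results) {
  acc <- vapply(results, function(f) f@metrics$accuracy, numeric(1))
  f1 <- vapply(results, function(f) f@metrics$weightedF1, numeric(1))
  auc <- vapply(results, function(f) f@metrics$auc, numeric(1))
  cv <- vapply(results, function(f) f@cvAuc, numeric(1))
  list(meanAccuracy = mean(acc), maxAccuracy = max(acc),
       meanF1 = mean(f1), meanAuc = mean(auc, na.rm = TRUE),
       meanCvAuc = mean(cv, na.rm = TRUE),
       accuracy = acc, f1 = f1, auc = auc)
}

#' Train the replicate-model ensemble
#'
#' Trains `nReplicates` boosted classifiers, each on an independent random
#' stratified train/test split (replicate r uses split seed
#' `baseSeed + r`) with its own hyperparameter search; the aggregated
#' per-replicate gain importances are the raw material for consensus
#' selection.
#'
#' @param x GenotypeMatrix or numeric feature matrix.
#' @param phenos PhenotypeTable.
#' @param config an [ensembleConfig()].
#' @return list of class `ensembleResult`: `results` (list of
#'   [FitResult-class]) and `summary` (mean/max accuracy, mean weighted
#'   f1, mean test AUC, mean CV AUC, and the per-replicate vectors).
#' @export
runEnsemble <- function(x, phenos, config = ensembleConfig()) {
  X <- .featureMatrix(x)
  phenos <- if (is(x, "GenotypeMatrix")) alignPhenotypes(phenos, x) else phenos
  results <- lapply(seq_len(config$nReplicates), function(r)
    .runReplicate(X, phenos, config, r))
  structure(list(results = results,
                 summary = .summariseEnsemble(results),
                 config = config),
            class = "ensembleResult")
}

#' Select consensus SNPs from replicate importances
#'
#' A site's model count is the number of replicates in whose importance
#' map it appears with strictly positive gain; sites with
#' `modelCount >= minModels` form the selected set.
#'
#' @param results list of [FitResult-class] (or an `ensembleResult`).
#' @param minModels the replicate-count threshold.
#' @param sites optional site metadata data.frame (as from [siteInfo()])
#'   used to attach chrom/pos to the selected sites.
#' @return A [ConsensusSet-class] with an empty collinear table (see
#'   [expandCollinear()]). If `minModels` exceeds the number of
#'   replicates, the set is empty and a warning is raised.
#' @export
consensusSelect <- function(results, minModels, sites = NULL) {
  if (inherits(results, "ensembleResult")) results <- results$results
  stopifnot(length(results) > 0)
  if (minModels > length(results))
    warning("minModels exceeds the number of replicate models; ",
            "consensus set is empty")
  counts <- table(unlist(lapply(results, function(f)
    names(importanceGains(f)))))
  sel <- counts[counts >= minModels]
  ord <- order(-as.integer(sel), names(sel))
  selected <- data.frame(site = names(sel)[ord],
                         modelCount = as.integer(sel)[ord],
                         stringsAsFactors = FALSE)
  selected <- .attachSiteMeta(selected, sites)
  new("ConsensusSet", selected = selected,
      collinear = .emptyCollinear(), combined = selected$site,
      minModels = as.numeric(minModels),
      nReplicates = as.numeric(length(results)))
}

.emptyCollinear <- function() {
  data.frame(site = character(0), chrom = character(0),
             pos = integer(0), anchor = character(0), r = numeric(0),
             stringsAsFactors = FALSE)
}

.attachSiteMeta <- function(df, sites) {
  if (!is.null(sites) && nrow(df)) {
    idx <- match(df$site, siteIds(sites))
    df$chrom <- sites$chrom[idx]
    df$pos <- sites$pos[idx]
  } else {
    df$chrom <- rep(NA_character_, nrow(df))
    df$pos <- rep(NA_integer_, nrow(df))
  }
  df[, c("site", "chrom", "pos",
         setdiff(names(df), c("site", "chrom", "pos")))]
}

#' Expand a consensus set with collinear SNPs
#'
#' Scans all non-selected sites for Pearson correlation (over pairwise
#' complete non-missing codes) with any selected anchor site. A site whose
#' strongest anchor correlation reaches `rMin` (in absolute value by
#' default, since allele coding makes the sign arbitrary) is added with
#' its anchor and r. Constant columns never match; anchor pairs sharing
#' fewer than `minShared` called samples are skipped. Additions are
#' matched against selected anchors only, never transitively, so
#' re-expanding the combined set adds nothing.
#'
#' @param gm GenotypeMatrix over the full site universe.
#' @param consensus a [ConsensusSet-class] (or character vector of selected
#'   site ids).
#' @param rMin correlation threshold (default 0.97).
#' @param signed if `TRUE`, only positive correlations >= rMin match.
#' @param minShared minimum pairwise-complete sample count.
#' @return The [ConsensusSet-class] with its `collinear` and `combined`
#'   slots filled.
#' @export
expandCollinear <- function(gm, consensus, rMin = 0.97, signed = FALSE,
                            minShared = 10L) {
  if (is.character(consensus)) {
    sel <- data.frame(site = consensus,
                      modelCount = rep(NA_integer_, length(consensus)),
                      stringsAsFactors = FALSE)
    sel <- .attachSiteMeta(sel, siteInfo(gm))
    consensus <- new("ConsensusSet", selected = sel,
                     collinear = .emptyCollinear(), combined = sel$site,
                     minModels = 0, nReplicates = 0)
  }
  selIds <- consensus@selected$site
  codes <- genoCodes(gm)
  hit <- selIds[selIds %in% colnames(codes)]
  if (!length(hit)) {
    consensus@collinear <- .emptyCollinear()
    consensus@combined <- selIds
    return(consensus)
  }
  anchors <- codes[, hit, drop = FALSE]
  others <- setdiff(colnames(codes), selIds)
  if (!length(others)) {
    consensus@collinear <- .emptyCollinear()
    consensus@combined <- selIds
    return(consensus)
  }
  storage.mode(anchors) <- "double"
  X <- codes[, others, drop = FALSE]
  storage.mode(X) <- "double"
  cors <- suppressWarnings(stats::cor(X, anchors,
                                      use = "pairwise.complete.obs"))
  shared <- crossprod(!is.na(X), !is.na(anchors))
  cors[shared < minShared] <- NA
  eff <- if (signed) cors else abs(cors)
  eff[is.na(eff)] <- -Inf
  best <- max.col(eff, ties.method = "first")
  bestVal <- eff[cbind(seq_len(nrow(eff)), best)]
  add <- which(bestVal >= rMin)
  collinear <- data.frame(
    site = others[add],
    anchor = hit[best[add]],
    r = cors[cbind(add, best[add])],
    stringsAsFactors = FALSE)
  collinear <- .attachSiteMeta(collinear, siteInfo(gm))
  ord <- order(collinear$chrom, collinear$pos, collinear$site)
  consensus@collinear <- collinear[ord, , drop = FALSE]
  consensus@combined <- union(selIds, collinear$site)
  validObject(consensus)
  consensus
}

#' Retrain the ensemble on a restricted site set
#'
#' Runs the identical ensemble procedure (same replicate seeds, same
#' tuning budget) on the matrix restricted to `sites`, so summaries are
#' directly comparable with the full-matrix ensemble — the retraining
#' check that quantifies how much predictive signal the selected SNPs
#' carry on their own.
#'
#' @param gm GenotypeMatrix.
#' @param sites character vector of site ids (e.g. `combinedSites()` of a
#'   consensus set).
#' @param phenos PhenotypeTable.
#' @param config the same [ensembleConfig()] used for the full run.
#' @return `ensembleResult`, as from [runEnsemble()].
#' @export
retrainSubset <- function(gm, sites, phenos, config = ensembleConfig()) {
  stopifnot(length(sites) > 0)
  runEnsemble(gm[, sites], phenos, config)
}

#' Write a consensus set as a tab-separated table
#'
#' Selected sites first (anchor and r empty), then collinear additions
#' (modelCount empty), mirroring the usual supplementary-table shape.
#'
#' @param consensus ConsensusSet.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeConsensus <- function(consensus, path) {
  sel <- consensus@selected
  sel$anchor <- rep(NA_character_, nrow(sel))
  sel$r <- rep(NA_real_, nrow(sel))
  col <- consensus@collinear
  col$modelCount <- rep(NA_integer_, nrow(col))
  cols <- c("site", "chrom", "pos", "modelCount", "anchor", "r")
  utils::write.table(rbind(sel[, cols], col[, cols]), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
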