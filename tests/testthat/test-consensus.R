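# build a FitResult carrying only an importance map
fitWithGains <- function(sites) {
  new("FitResult", trainIds = "t1", testIds = "t2", params = list(),
      cvAuc = NA_real_,
      metrics = list(accuracy = 0.5, perClass = data.frame(),
                     macroF1 = 0.5, weightedF1 = 0.5, auc = 0.5),
      importance = stats::setNames(rep(1, length(sites)), sites))
}

test_that("consensus selection counts models with positive gain per site", {
  results <- list(fitWithGains(c("A", "B")), fitWithGains(c("B", "C")),
                  fitWithGains("B"))
  cs <- consensusSelect(results, minModels = 2)
  expect_equal(selectedSites(cs)$site, "B")
  expect_equal(selectedSites(cs)$modelCount, 3L)
  # threshold floor: union of everything seen
  cs1 <- consensusSelect(results, minModels = 1)
  expect_setequal(selectedSites(cs1)$site, c("A", "B", "C"))
  # impossible threshold: empty with a warning, not an error
  expect_warning(cs4 <- consensusSelect(results, minModels = 4),
                 "exceeds")
  expect_equal(nrow(selectedSites(cs4)), 0)
})

test_that("consensus selection is monotone in the model-count threshold", {
  set.seed(5)
  pool <- paste0("site", 1:30)
  results <- lapply(1:12, function(i)
    fitWithGains(sample(pool, sample(3:10, 1))))
  prev <- NULL
  for (m in 1:6) {
    sel <- selectedSites(consensusSelect(results, m))$site
    if (!is.null(prev)) expect_true(all(sel %in% prev))
    prev <- sel
  }
})

test_that("collinear expansion matches a brute-force Pearson oracle", {
  set.seed(13)
  codes <- matrix(sample(c(0L, 1L, 2L, NA), 400, replace = TRUE,
                         prob = c(.35, .3, .25, .1)), 20, 20,
                  dimnames = list(paste0("s", 1:20), NULL))
  # plant a near-duplicate and an anti-correlated copy of column 1
  codes[, 2] <- codes[, 1]
  codes[, 3] <- 2L - codes[, 1]
  gm <- gmFromCodes(codes)
  ids <- colnames(genoCodes(gm))
  sel <- ids[1]
  cs <- expandCollinear(gm, sel, rMin = 0.97, minShared = 5)
  # oracle: loop over all non-selected sites, pairwise-complete Pearson
  expected <- character(0)
  for (j in 2:20) {
    ok <- !is.na(codes[, 1]) & !is.na(codes[, j])
    if (sum(ok) < 5 || stats::sd(codes[ok, j]) == 0 ||
        stats::sd(codes[ok, 1]) == 0) next
    r <- stats::cor(codes[ok, 1], codes[ok, j])
    if (abs(r) >= 0.97) expected <- c(expected, ids[j])
  }
  expect_setequal(collinearSites(cs)$site, expected)
  expect_true(all(abs(collinearSites(cs)$r) >= 0.97))
  # anti-correlated copy is present under the absolute-value convention
  expect_true(ids[3] %in% collinearSites(cs)$site)
  expect_lt(cs@collinear$r[cs@collinear$site == ids[3]], 0)
})

test_that("perfect copies and anti-copies get |r| = 1; constants never match", {
  codes <- cbind(c(0L, 1L, 2L, 0L), c(0L, 1L, 2L, 0L),
                 c(2L, 1L, 0L, 2L), c(1L, 1L, 1L, 1L))
  rownames(codes) <- paste0("s", 1:4)
  gm <- gmFromCodes(codes)
  ids <- colnames(genoCodes(gm))
  cs <- expandCollinear(gm, ids[1], rMin = 0.97, minShared = 2)
  col <- collinearSites(cs)
  expect_setequal(col$site, ids[2:3])
  expect_equal(col$r[col$site == ids[2]], 1)
  expect_equal(col$r[col$site == ids[3]], -1)  # cor((0,1,2,0),(2,1,0,2))
  expect_false(ids[4] %in% col$site)           # zero variance
})

test_that("expansion is a superset operation and closed under re-expansion", {
  set.seed(29)
  codes <- matrix(sample(0:2, 30 * 40, replace = TRUE), 30, 40,
                  dimnames = list(paste0("s", 1:30), NULL))
  codes[, 11] <- codes[, 5]
  gm <- gmFromCodes(codes)
  ids <- colnames(genoCodes(gm))
  sel <- ids[c(5, 20)]
  cs <- expandCollinear(gm, sel, rMin = 0.97)
  expect_true(all(sel %in% combinedSites(cs)))
  # re-expanding the combined set against the same anchors adds nothing
  cs2 <- expandCollinear(gm, combinedSites(cs), rMin = 0.97)
  expect_setequal(combinedSites(cs2), combinedSites(cs))
})

test_that("ensemble runs are reproducible and summaries are means of replicates", {
  pan <- cached("panel120", smallPanel())
  cfg <- ensembleConfig(nReplicates = 3, minModels = 2, nTest = 24,
                        nTrialsPerReplicate = 2, nFolds = 3,
                        maxRounds = 40, baseSeed = 77)
  ens1 <- cached("ens3", runEnsemble(pan$gm, pan$phenos, cfg))
  ens2 <- runEnsemble(pan$gm, pan$phenos, cfg)
  expect_equal(ens1$summary, ens2$summary)
  acc <- ens1$summary$accuracy
  expect_gte(ens1$summary$meanAccuracy, min(acc))
  expect_lte(ens1$summary$meanAccuracy, max(acc))
  expect_equal(ens1$summary$maxAccuracy, max(acc))
})

test_that("a single-replicate ensemble equals one tuned train/eval run", {
  pan <- cached("panel120", smallPanel())
  cfg <- ensembleConfig(nReplicates = 1, minModels = 1, nTest = 24,
                        nTrialsPerReplicate = 2, nFolds = 3,
                        maxRounds = 40, baseSeed = 123)
  ens <- runEnsemble(pan$gm, pan$phenos, cfg)
  sp <- stratifiedSplit(pan$phenos, 24, seed = 124)  # baseSeed + 1
  hp <- tuneBoost(pan$gm[sp$trainIds, ],
                  classLabels(pan$phenos)[sp$trainIds],
                  nTrials = 2, nFolds = 3, seed = 100124, maxRounds = 40)
  fit <- trainEval(pan$gm, pan$phenos, sp, hp)
  expect_equal(ens$results[[1]]@metrics$accuracy, fit@metrics$accuracy)
  expect_equal(importanceGains(ens$results[[1]]), importanceGains(fit))
})

test_that("retraining on all sites reproduces the full-matrix ensemble", {
  pan <- cached("panel120", smallPanel())
  cfg <- ensembleConfig(nReplicates = 2, minModels = 1, nTest = 24,
                        nTrialsPerReplicate = 1, nFolds = 3,
                        maxRounds = 30, baseSeed = 55)
  full <- runEnsemble(pan$gm, pan$phenos, cfg)
  sub <- retrainSubset(pan$gm, colnames(genoCodes(pan$gm)), pan$phenos, cfg)
  expect_equal(full$summary, sub$summary)
})

test_that("consensus tables serialize with model counts, anchors and r", {
  results <- list(fitWithGains(c("chr1:10", "chr1:20")),
                  fitWithGains("chr1:10"))
  sites <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L), ref = "A",
                      alt = "T")
  cs <- consensusSelect(results, 2, sites = sites)
  path <- tempfile()
  writeConsensus(cs, path)
  tab <- read.delim(path)
  expect_equal(tab$site, "chr1:10")
  expect_equal(tab$modelCount, 2L)
  expect_equal(tab$chrom, "chr1")
})
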