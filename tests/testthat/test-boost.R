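test_that("largest-remainder stratified split reproduces the 95-sample design", {
  # class counts (45, 27, 23), 24 held out -> test (11, 7, 6), train (34, 20, 17)
  labs <- rep(c("white", "beige", "orange"), times = c(45, 27, 23))
  pt <- phenotypeTable(sprintf("a%03d", 1:95), labs,
                       classSet = c("white", "beige", "orange"))
  sp <- stratifiedSplit(pt, 24, seed = 47)
  testLabs <- classLabels(pt)[sp$testIds]
  trainLabs <- classLabels(pt)[sp$trainIds]
  expect_equal(as.integer(table(testLabs)), c(11L, 7L, 6L))
  expect_equal(as.integer(table(trainLabs)), c(34L, 20L, 17L))
  expect_setequal(c(sp$trainIds, sp$testIds), sprintf("a%03d", 1:95))
})

test_that("stratified split handles exact proportions and the empty test set", {
  pt <- phenotypeTable(paste0("s", 1:20), rep(c("A", "B"), each = 10))
  sp <- stratifiedSplit(pt, 4, seed = 1)
  expect_equal(as.integer(table(classLabels(pt)[sp$testIds])), c(2L, 2L))
  sp0 <- stratifiedSplit(pt, 0, seed = 1)
  expect_length(sp0$testIds, 0)
  expect_length(sp0$trainIds, 20)
})

test_that("balanced class weights equalize total weight per class", {
  labs <- factor(c("A", "B", "B", "B"))
  w <- classWeights(labs)
  expect_equal(unname(w), c(2, 2 / 3), tolerance = 1e-12)
  # the weighted sample count is the same for every class
  perClass <- tapply(as.numeric(w[as.character(labs)]), labs, sum)
  expect_equal(unname(diff(range(perClass))), 0, tolerance = 1e-12)
  labsEq <- factor(rep(c("A", "B", "C"), each = 4))
  expect_equal(unname(classWeights(labsEq)), rep(1, 3))
})

test_that("class metrics reproduce hand-computed confusion summaries", {
  cm <- consensusSNP:::.classMetrics
  classes <- c("beige", "orange", "white")
  # majority predictor on test supports (7, 6, 11): accuracy 11/24
  labs <- factor(rep(classes, times = c(7, 6, 11)), levels = classes)
  probsMaj <- matrix(rep(c(0, 0, 1), each = 24), 24)
  m <- cm(probsMaj, labs)
  expect_equal(m$accuracy, 11 / 24)
  # beige row of a confusion where 4/7 beige are right and nothing else
  # is predicted beige: precision 1, recall 4/7, f1 0.73
  pred <- c(rep("beige", 4), rep("white", 3), rep("orange", 6),
            rep("white", 11))
  probs <- t(vapply(pred, function(p) as.numeric(classes == p),
                    numeric(3)))
  m2 <- cm(probs, labs)
  beige <- m2$perClass[m2$perClass$class == "beige", ]
  expect_equal(beige$precision, 1)
  expect_equal(round(beige$recall, 2), 0.57)
  expect_equal(round(beige$f1, 2), 0.73)
  # weighted f1 is the support-weighted mean of per-class f1
  expect_equal(m2$weightedF1,
               sum(m2$perClass$f1 * m2$perClass$support) / 24)
  # accuracy always equals trace(confusion) / sum(confusion)
  expect_equal(m2$accuracy, sum(diag(m2$confusion)) / sum(m2$confusion))
})

test_that("perfect predictions give unit accuracy, f1 and AUC", {
  cm <- consensusSNP:::.classMetrics
  labs <- factor(rep(c("A", "B", "C"), times = c(5, 3, 2)))
  probs <- t(vapply(as.character(labs),
                    function(p) as.numeric(levels(labs) == p), numeric(3)))
  m <- cm(probs, labs)
  expect_equal(m$accuracy, 1)
  expect_equal(m$perClass$f1, rep(1, 3))
  expect_equal(m$auc, 1)
})

test_that("metric report has per-class, accuracy, macro and weighted rows", {
  pan <- cached("panel120", smallPanel())
  sp <- stratifiedSplit(pan$phenos, 24, seed = 3)
  fit <- cached("fit120", trainEval(pan$gm, pan$phenos, sp,
                                    hyperParams(nrounds = 30)))
  rep <- metricReport(fit)
  k <- length(classSet(pan$phenos))
  expect_equal(nrow(rep), k + 3)
  expect_equal(rep["accuracy", "support"], 24)
  expect_equal(sum(rep[1:k, "support"]), 24)
  expect_true(all(rep$f1 >= 0 & rep$f1 <= 1))
})

test_that("gain importances are strictly positive and mapped to site ids", {
  pan <- cached("panel120", smallPanel())
  sp <- stratifiedSplit(pan$phenos, 24, seed = 3)
  fit <- cached("fit120", trainEval(pan$gm, pan$phenos, sp,
                                    hyperParams(nrounds = 30)))
  gains <- importanceGains(fit)
  expect_gt(length(gains), 0)
  expect_true(all(gains > 0))
  expect_true(all(names(gains) %in% colnames(genoCodes(pan$gm))))
})

test_that("fit results serialize to JSON with metrics, params and importance", {
  pan <- cached("panel120", smallPanel())
  sp <- stratifiedSplit(pan$phenos, 24, seed = 3)
  fit <- cached("fit120", trainEval(pan$gm, pan$phenos, sp,
                                    hyperParams(nrounds = 30)))
  path <- tempfile(fileext = ".json")
  writeFitResult(fit, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$metrics$accuracy, fit@metrics$accuracy)
  expect_equal(length(back$importance), length(importanceGains(fit)))
  expect_equal(back$params$nrounds, 30)
})

test_that("tuning is reproducible and degenerates to its single trial", {
  pan <- cached("panel120", smallPanel())
  sp <- stratifiedSplit(pan$phenos, 30, seed = 5)
  labs <- classLabels(pan$phenos)[sp$trainIds]
  X <- pan$gm[sp$trainIds, ]
  hp1 <- tuneBoost(X, labs, nTrials = 1, nFolds = 3, seed = 11,
                   maxRounds = 40)
  hp2 <- tuneBoost(X, labs, nTrials = 1, nFolds = 3, seed = 11,
                   maxRounds = 40)
  expect_identical(hp1[], hp2[])
  expect_equal(attr(hp1, "cvAuc"), attr(hp2, "cvAuc"))
  expect_equal(nrow(attr(hp1, "trials")), 1)
  hp3 <- tuneBoost(X, labs, nTrials = 3, nFolds = 3, seed = 12,
                   maxRounds = 40)
  trials <- attr(hp3, "trials")
  expect_equal(attr(hp3, "cvAuc"), max(trials$cvAuc))
})

test_that("training fails when a class is absent from the training set", {
  pan <- cached("panel120", smallPanel())
  labs <- classLabels(pan$phenos)
  small <- names(labs)[labs == classSet(pan$phenos)[3]]
  sp <- list(trainIds = setdiff(sampleIds(pan$gm), small),
             testIds = small, seed = 1L)
  class(sp) <- "splitSpec"
  expect_error(trainEval(pan$gm, pan$phenos, sp, hyperParams(nrounds = 5)),
               "absent")
})
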