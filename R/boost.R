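#' Stratified train/test split with largest-remainder allocation
#'
#' Allocates `nTest` held-out samples across classes proportionally to
#' class size by the largest-remainder (Hamilton) method: each class gets
#' the floor of its exact quota, remaining units go to the classes with
#' the largest fractional parts, ties broken by class-set order. Within a
#' class, membership is drawn uniformly at random from the seed.
#'
#' For class counts (45, 27, 23) and 24 held out this yields test supports
#' (11, 7, 6) and train counts (34, 20, 17).
#'
#' @param phenos PhenotypeTable.
#' @param nTest number of test samples (a count, not a fraction).
#' @param seed integer seed.
#' @return list of class `splitSpec` with `trainIds`, `testIds`, `seed`.
#' @export
stratifiedSplit <- function(phenos, nTest, seed = 1L) {
  counts <- as.integer(classCounts(phenos))
  n <- sum(counts)
  stopifnot(nTest < n, all(counts > 0))
  quota <- nTest * counts / n
  alloc <- floor(quota)
  rem <- nTest - sum(alloc)
  if (rem > 0) {
    frac <- quota - alloc
    # order by descending fraction, ties by class order
    extra <- order(-frac, seq_along(frac))[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1L
  }
  if (any(alloc > counts))
    stop("a class was allocated more test samples than it has members")
  labs <- classLabels(phenos)
  set.seed(seed)
  testIds <- character(0)
  for (ci in seq_along(levels(labs))) {
    ids <- names(labs)[as.integer(labs) == ci]
    if (alloc[ci] > 0)
      testIds <- c(testIds, sample(ids, alloc[ci]))
  }
  structure(list(trainIds = setdiff(names(labs), testIds),
                 testIds = testIds, seed = as.integer(seed)),
            class = "splitSpec")
}

#' Balanced class weights
#'
#' `weight_c = n / (k * n_c)` over the supplied (training) labels, so the
#' total weight carried by each class is equal.
#'
#' @param labels factor of class labels (training set).
#' @return named numeric vector of per-class weights.
#' @export
classWeights <- function(labels) {
  labels <- droplevels(as.factor(labels))
  tab <- table(labels)
  if (any(tab == 0)) stop("empty class in training labels")
  w <- length(labels) / (nlevels(labels) * as.numeric(tab))
  stats::setNames(w, names(tab))
}

#' Hyperparameter container for the boosted classifier
#'
#' @param maxDepth,minChildWeight,gamma,colsampleBytree,subsample,learningRate
#'   the six tuned tree-booster parameters.
#' @param maxRounds maximum boosting rounds.
#' @param earlyStoppingRounds patience for early stopping during
#'   cross-validation.
#' @param nrounds rounds to use for a final fit (set by [tuneBoost()] to
#'   the mean early-stopped best iteration; defaults to `maxRounds`).
#' @return list of class `hyperParams`.
#' @export
hyperParams <- function(maxDepth = 4L, minChildWeight = 1, gamma = 0,
                        colsampleBytree = 0.8, subsample = 0.8,
                        learningRate = 0.1, maxRounds = 500L,
                        earlyStoppingRounds = 35L, nrounds = NULL) {
  stopifnot(maxDepth >= 1, minChildWeight >= 0, gamma >= 0,
            colsampleBytree > 0, colsampleBytree <= 1,
            subsample > 0, subsample <= 1,
            learningRate > 0, learningRate <= 1)
  structure(list(maxDepth = as.integer(maxDepth),
                 minChildWeight = minChildWeight, gamma = gamma,
                 colsampleBytree = colsampleBytree, subsample = subsample,
                 learningRate = learningRate,
                 maxRounds = as.integer(maxRounds),
                 earlyStoppingRounds = as.integer(earlyStoppingRounds),
                 nrounds = if (is.null(nrounds)) as.integer(maxRounds)
                           else as.integer(nrounds)),
            class = "hyperParams")
}

#' Search-space bounds for hyperparameter tuning
#'
#' Conventional ranges for the six tuned parameters: max_depth 2-10,
#' min_child_weight 0-10, gamma 0-5, colsample_bytree 0.3-1,
#' subsample 0.5-1, learning_rate 0.01-0.3.
#'
#' @param maxDepth,minChildWeight,gamma,colsampleBytree,subsample,learningRate
#'   length-2 numeric ranges `c(lo, hi)`.
#' @return list of ranges.
#' @export
searchSpace <- function(maxDepth = c(2, 10), minChildWeight = c(0, 10),
                        gamma = c(0, 5), colsampleBytree = c(0.3, 1),
                        subsample = c(0.5, 1), learningRate = c(0.01, 0.3)) {
  list(maxDepth = maxDepth, minChildWeight = minChildWeight, gamma = gamma,
       colsampleBytree = colsampleBytree, subsample = subsample,
       learningRate = learningRate)
}

# feature matrix from a GenotypeMatrix or a plain numeric matrix
.featureMatrix <- function(x) {
  if (is(x, "GenotypeMatrix")) {
    m <- genoCodes(x)
    storage.mode(m) <- "double"
    m
  } else {
    stopifnot(is.matrix(x), !is.null(rownames(x)))
    x
  }
}

# binary AUC of score for positives vs negatives (one-vs-rest component)
.binaryAuc <- function(score, positive) {
  if (all(positive) || !any(positive)) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = positive, predictor = score,
                                 quiet = TRUE, direction = "<",
                                 levels = c(FALSE, TRUE))))
}

#' One-vs-rest multi-class AUC from predicted class probabilities
#'
#' Per class, the binary AUC of that class's predicted probability against
#' the class-membership indicator; averaged either unweighted over classes
#' (`macro`) or weighted by class support (`weighted`). Classes absent
#' from `labels` are skipped.
#'
#' @param probs matrix (samples x classes) of predicted probabilities;
#'   columns in class-set order.
#' @param labels factor of true labels (levels = class set).
#' @param average `"macro"` or `"weighted"`.
#' @return numeric AUC in \[0, 1\].
#' @export
aucOvr <- function(probs, labels, average = c("macro", "weighted")) {
  average <- match.arg(average)
  labels <- as.factor(labels)
  aucs <- supp <- numeric(0)
  for (ci in seq_len(nlevels(labels))) {
    pos <- as.integer(labels) == ci
    a <- .binaryAuc(probs[, ci], pos)
    if (!is.na(a)) {
      aucs <- c(aucs, a)
      supp <- c(supp, sum(pos))
    }
  }
  if (!length(aucs)) return(NA_real_)
  if (average == "macro") mean(aucs) else sum(aucs * supp) / sum(supp)
}

# stratified fold assignment: within each class, shuffled round-robin
.stratifiedFolds <- function(labels, nFolds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (ci in seq_len(nlevels(labels))) {
    idx <- which(as.integer(labels) == ci)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep(seq_len(nFolds), length.out = length(idx))
  }
  fold
}

# total gain per feature, summed over every split of every tree, parsed
# from the model's text dump (avoids per-feature-name booster queries)
.gainImportance <- function(bst) {
  dump <- xgboost::xgb.dump(bst, with_stats = TRUE)
  splits <- grep("gain=", dump, value = TRUE, fixed = TRUE)
  if (!length(splits)) return(stats::setNames(numeric(0), character(0)))
  feat <- sub("^[^\\[]*\\[([^<]+)<.*$", "\\1", splits, perl = TRUE)
  gain <- as.numeric(sub("^.*gain=([-0-9.eE+]+).*$", "\\1", splits,
                         perl = TRUE))
  tot <- tapply(gain, feat, sum)
  stats::setNames(as.numeric(tot), names(tot))
}

.xgbParams <- function(hp, nClass, seed) {
  list(objective = "multi:softprob", num_class = nClass,
       eval_metric = "mlogloss",
       max_depth = hp$maxDepth, min_child_weight = hp$minChildWeight,
       gamma = hp$gamma, colsample_bytree = hp$colsampleBytree,
       subsample = hp$subsample, eta = hp$learningRate,
       tree_method = "hist", max_bin = 16, nthread = 1,
       seed = as.integer(seed %% .Machine$integer.max))
}

# fit on a prebuilt fold (train DMatrix with weights, eval DMatrix) with
# early stopping; returns the held-out AUC and the best iteration
.cvFoldFit <- function(fold, nClass, hp, seed, aucAverage) {
  bst <- xgboost::xgb.train(.xgbParams(hp, nClass, seed), fold$dtr,
                            nrounds = hp$maxRounds,
                            evals = list(val = fold$dva),
                            early_stopping_rounds = hp$earlyStoppingRounds,
                            verbose = 0)
  best <- xgboost::xgb.attr(bst, "best_iteration")
  best <- if (is.null(best) || is.na(best)) hp$maxRounds else as.integer(best)
  probs <- predict(bst, fold$dva)
  list(auc = aucOvr(probs, fold$yva, aucAverage), bestIter = max(best, 1L))
}

#' Tune hyperparameters by seeded random search with stratified k-fold CV
#'
#' Evaluates `nTrials` parameter configurations sampled uniformly from
#' `space`. Each trial is scored by the mean one-vs-rest AUC over
#' `nFolds` stratified cross-validation folds, with balanced class
#' weights on each fold's training part and early stopping (default 35
#' rounds) inside each fold. The best-scoring configuration is returned
#' with `nrounds` set to its mean early-stopped best iteration, ready for
#' a deterministic final fit. Fully reproducible from `seed`.
#'
#' @param x GenotypeMatrix or numeric feature matrix (training samples).
#' @param labels factor of training labels.
#' @param nTrials number of sampled configurations (>= 1).
#' @param nFolds cross-validation folds.
#' @param seed integer seed for fold assignment, parameter sampling and
#'   the booster's internal randomness.
#' @param space parameter ranges from [searchSpace()].
#' @param maxRounds,earlyStoppingRounds boosting-round budget and patience.
#' @param aucAverage `"macro"` or `"weighted"` one-vs-rest averaging.
#' @return A `hyperParams` list with attributes `cvAuc` (best mean CV AUC)
#'   and `trials` (per-trial summary data.frame).
#' @export
tuneBoost <- function(x, labels, nTrials = 250L, nFolds = 4L, seed = 1L,
                      space = searchSpace(), maxRounds = 500L,
                      earlyStoppingRounds = 35L,
                      aucAverage = c("macro", "weighted")) {
  stopifnot(nTrials >= 1)
  aucAverage <- match.arg(aucAverage)
  X <- .featureMatrix(x)
  labels <- droplevels(as.factor(labels))
  if (min(table(labels)) < nFolds)
    stop("need at least nFolds samples per class to stratify CV folds")
  set.seed(seed)
  rint <- function(r) sample(seq(r[1], r[2]), nTrials, replace = TRUE)
  runi <- function(r) stats::runif(nTrials, r[1], r[2])
  trials <- data.frame(maxDepth = rint(space$maxDepth),
                       minChildWeight = runi(space$minChildWeight),
                       gamma = runi(space$gamma),
                       colsampleBytree = runi(space$colsampleBytree),
                       subsample = runi(space$subsample),
                       learningRate = runi(space$learningRate))
  fold <- .stratifiedFolds(labels, nFolds, seed)
  # fold DMatrices (with balanced weights from each fold's training part)
  # do not depend on the trial, so build them once
  folds <- lapply(seq_len(nFolds), function(f) {
    va <- fold == f
    ytr <- labels[!va]
    wts <- classWeights(ytr)
    list(dtr = xgboost::xgb.DMatrix(
           X[!va, , drop = FALSE], label = as.integer(ytr) - 1L,
           weight = as.numeric(wts[as.character(ytr)])),
         dva = xgboost::xgb.DMatrix(
           X[va, , drop = FALSE], label = as.integer(labels[va]) - 1L),
         yva = labels[va])
  })
  scores <- iters <- numeric(nTrials)
  for (t in seq_len(nTrials)) {
    hp <- hyperParams(trials$maxDepth[t], trials$minChildWeight[t],
                      trials$gamma[t], trials$colsampleBytree[t],
                      trials$subsample[t], trials$learningRate[t],
                      maxRounds = maxRounds,
                      earlyStoppingRounds = earlyStoppingRounds)
    aucs <- bests <- numeric(nFolds)
    for (f in seq_len(nFolds)) {
      fit <- .cvFoldFit(folds[[f]], nlevels(labels), hp,
                        seed + 131L * t + f, aucAverage)
      aucs[f] <- fit$auc
      bests[f] <- fit$bestIter
    }
    scores[t] <- mean(aucs, na.rm = TRUE)
    iters[t] <- mean(bests)
  }
  best <- which.max(scores)
  hp <- hyperParams(trials$maxDepth[best], trials$minChildWeight[best],
                    trials$gamma[best], trials$colsampleBytree[best],
                    trials$subsample[best], trials$learningRate[best],
                    maxRounds = maxRounds,
                    earlyStoppingRounds = earlyStoppingRounds,
                    nrounds = max(1L, round(iters[best])))
  attr(hp, "cvAuc") <- scores[best]
  attr(hp, "trials") <- cbind(trials, cvAuc = scores)
  hp
}

# metrics from predicted probabilities and true labels
.classMetrics <- function(probs, labels, aucAverage = "macro") {
  k <- nlevels(labels)
  pred <- factor(levels(labels)[max.col(probs, ties.method = "first")],
                 levels = levels(labels))
  conf <- table(true = labels, pred = pred)
  tp <- diag(conf)
  prec <- ifelse(colSums(conf) > 0, tp / colSums(conf), 0)
  rec <- ifelse(rowSums(conf) > 0, tp / rowSums(conf), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  supp <- as.numeric(rowSums(conf))
  list(accuracy = sum(tp) / sum(conf),
       perClass = data.frame(class = levels(labels), precision = prec,
                             recall = rec, f1 = f1, support = supp,
                             row.names = NULL),
       macroF1 = mean(f1),
       weightedF1 = sum(f1 * supp) / sum(supp),
       macroPrecision = mean(prec), macroRecall = mean(rec),
       weightedPrecision = sum(prec * supp) / sum(supp),
       weightedRecall = sum(rec * supp) / sum(supp),
       auc = aucOvr(probs, labels, aucAverage),
       confusion = conf)
}

#' Train a boosted classifier on a split and evaluate on its test set
#'
#' Fits a multi-class gradient-boosted tree model on the training samples
#' with balanced per-sample class weights and `params$nrounds` boosting
#' rounds (deterministic; set by [tuneBoost()]), then computes test-set
#' accuracy, per-class precision/recall/f1, macro and support-weighted
#' averages, one-vs-rest AUC, and per-site gain importances. Missing
#' genotype codes are passed to the tree learner as missing values and
#' handled by its default-direction mechanism.
#'
#' @param x GenotypeMatrix or numeric feature matrix over all samples.
#' @param phenos PhenotypeTable covering all samples of `x`.
#' @param split a `splitSpec` from [stratifiedSplit()].
#' @param params a `hyperParams` list.
#' @param aucAverage one-vs-rest averaging mode.
#' @param modelPath optional path; when given, the fitted booster is saved
#'   there in the boosting library's native format.
#' @return A [FitResult-class].
#' @export
trainEval <- function(x, phenos, split, params = hyperParams(),
                      aucAverage = c("macro", "weighted"),
                      modelPath = NULL) {
  aucAverage <- match.arg(aucAverage)
  X <- .featureMatrix(x)
  labs <- classLabels(phenos)[rownames(X)]
  ytr <- labs[split$trainIds]
  if (nlevels(droplevels(ytr)) < nlevels(ytr))
    stop("class absent from training set")
  yte <- labs[split$testIds]
  wts <- classWeights(ytr)
  dtr <- xgboost::xgb.DMatrix(X[split$trainIds, , drop = FALSE],
                              label = as.integer(ytr) - 1L,
                              weight = as.numeric(wts[as.character(ytr)]))
  bst <- xgboost::xgb.train(.xgbParams(params, nlevels(ytr), split$seed),
                            dtr, nrounds = params$nrounds, verbose = 0)
  if (!is.null(modelPath)) xgboost::xgb.save(bst, modelPath)
  probs <- predict(bst, xgboost::xgb.DMatrix(
    X[split$testIds, , drop = FALSE]))
  metrics <- .classMetrics(probs, yte, aucAverage)
  gains <- .gainImportance(bst)
  gains <- gains[gains > 0]
  cvAuc <- attr(params, "cvAuc")
  new("FitResult", trainIds = split$trainIds, testIds = split$testIds,
      params = unclass(params),
      cvAuc = if (is.null(cvAuc)) NA_real_ else cvAuc,
      metrics = metrics, importance = gains)
}

#' Serialize a FitResult (metrics, params, importance) as JSON
#'
#' @param fit a [FitResult-class].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeFitResult <- function(fit, path) {
  out <- list(
    trainIds = fit@trainIds, testIds = fit@testIds,
    params = fit@params, cvAuc = fit@cvAuc,
    metrics = fit@metrics[c("accuracy", "macroF1", "weightedF1", "auc")],
    perClass = fit@metrics$perClass,
    importance = as.list(fit@importance))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Classification report table for a fit
#'
#' One row per class (precision, recall, f1, support) followed by
#' `accuracy`, `macro avg` and `weighted avg` rows, in the layout of the
#' usual machine-learning classification report.
#'
#' @param fit a [FitResult-class] (or its `metrics` list).
#' @return data.frame with columns precision, recall, f1, support.
#' @export
metricReport <- function(fit) {
  m <- if (is(fit, "FitResult")) fit@metrics else fit
  pc <- m$perClass
  n <- sum(pc$support)
  rep <- rbind(
    data.frame(row.names = pc$class, precision = pc$precision,
               recall = pc$recall, f1 = pc$f1, support = pc$support),
    accuracy = data.frame(precision = NA, recall = NA, f1 = m$accuracy,
                          support = n),
    `macro avg` = data.frame(precision = m$macroPrecision,
                             recall = m$macroRecall, f1 = m$macroF1,
                             support = n),
    `weighted avg` = data.frame(precision = m$weightedPrecision,
                                recall = m$weightedRecall,
                                f1 = m$weightedF1, support = n))
  rep
}
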