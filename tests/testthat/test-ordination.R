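test_that("PCA reproduces the hand eigen-decomposition of a 1-D cloud", {
  gm <- gmFromCodes(rbind(a = c(0L, 0L), b = c(1L, 1L), c = c(2L, 2L)))
  proj <- pcaProject(gm, k = 2)
  expect_equal(proj$explainedVar[1], 1)
  expect_equal(unname(proj$coordinates[, 1]),
               c(-sqrt(2), 0, sqrt(2)), tolerance = 1e-10)
  expect_equal(unname(proj$coordinates[, 2]), rep(0, 3), tolerance = 1e-10)
})

test_that("PCA of identical samples is the zero projection", {
  gm <- gmFromCodes(matrix(1L, 4, 3, dimnames = list(paste0("s", 1:4), NULL)))
  proj <- pcaProject(gm, k = 2)
  expect_equal(unname(proj$coordinates), matrix(0, 4, 2))
  expect_equal(proj$explainedVar, c(0, 0))
})

test_that("full-rank PCA reconstructs the centered data", {
  set.seed(3)
  X <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(paste0("s", 1:8), NULL))
  proj <- pcaProject(X, k = 5)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  recon <- proj$coordinates %*% t(proj$loadings)
  expect_equal(unname(recon), unname(Xc)[, ], tolerance = 1e-8)
  expect_lte(sum(proj$explainedVar), 1 + 1e-12)
  expect_true(all(diff(proj$explainedVar) <= 1e-12))
})

test_that("duplicating every sample leaves principal directions unchanged", {
  set.seed(4)
  X <- matrix(sample(0:2, 30, TRUE), 6, 5, dimnames = list(paste0("s", 1:6), NULL))
  X2 <- rbind(X, X)
  rownames(X2) <- paste0("r", 1:12)
  p1 <- pcaProject(X, k = 2)
  p2 <- pcaProject(X2, k = 2)
  expect_equal(abs(p1$loadings), abs(p2$loadings), tolerance = 1e-8)
})

test_that("LDA is capped at classes minus one and separates separable classes", {
  gm <- gmFromCodes(rbind(a = c(0L, 0L, 0L), b = c(0L, 0L, 1L),
                          c = c(2L, 2L, 2L), d = c(2L, 2L, 1L)))
  pt <- phenotypeTable(letters[1:4], c("A", "A", "B", "B"))
  proj <- ldaProject(gm, pt, k = 2)
  expect_equal(ncol(proj$coordinates), 1L)  # k forced to classes - 1
  mA <- mean(proj$coordinates[1:2, 1])
  mB <- mean(proj$coordinates[3:4, 1])
  expect_gt(abs(mA - mB), 1e-6)
  expect_gt(separationScore(proj, pt), 0.8)
})

test_that("duplicated distinct points give perfect within-class collapse", {
  codes <- rbind(a = c(0L, 0L), b = c(0L, 0L), c = c(2L, 1L), d = c(2L, 1L))
  gm <- gmFromCodes(codes)
  pt <- phenotypeTable(letters[1:4], c("A", "A", "B", "B"))
  proj <- ldaProject(gm, pt)
  expect_lt(stats::sd(proj$coordinates[1:2, 1]), 1e-6)
  expect_lt(stats::sd(proj$coordinates[3:4, 1]), 1e-6)
})

test_that("permuting class labels destroys LDA separation", {
  pan <- cached("panel120", smallPanel())
  sub <- pan$gm[, seq_len(25)]
  real <- separationScore(ldaProject(sub, pan$phenos), pan$phenos)
  set.seed(99)
  perm <- phenotypeTable(sampleIds(pan$gm),
                         sample(as.character(classLabels(pan$phenos))),
                         classSet = classSet(pan$phenos))
  shuffled <- separationScore(ldaProject(sub, perm), perm)
  expect_lt(shuffled, 0.2)
})

test_that("silhouette agrees with the brute-force formula on four points", {
  coords <- rbind(p1 = c(0, 0), p2 = c(0, 1), p3 = c(4, 0), p4 = c(4, 1))
  pt <- phenotypeTable(rownames(coords), c("A", "A", "B", "B"))
  proj <- structure(list(coordinates = coords), class = "projection")
  # brute force: s(i) = (b - a) / max(a, b)
  d <- as.matrix(dist(coords))
  sil <- vapply(1:4, function(i) {
    own <- c(1:2, 3:4)[if (i <= 2) 1:2 else 3:4]
    a <- mean(d[i, setdiff(own, i)])
    b <- mean(d[i, setdiff(1:4, own)])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_equal(separationScore(proj, pt), mean(sil), tolerance = 1e-12)
})

test_that("degenerate identical coordinates score zero separation", {
  coords <- matrix(0, 4, 2, dimnames = list(paste0("s", 1:4), NULL))
  pt <- phenotypeTable(paste0("s", 1:4), c("A", "A", "B", "B"))
  proj <- structure(list(coordinates = coords), class = "projection")
  expect_equal(separationScore(proj, pt), 0)
})

test_that("average-linkage clustering reproduces hand-computed merge heights", {
  # 1-D codes 0, 1, 2: merge (0,1) at height 1, then 2 joins the pair at
  # the average distance (|0-2| + |1-2|) / 2 = 1.5
  codes <- matrix(c(0L, 1L, 2L), ncol = 1,
                  dimnames = list(c("a", "b", "c"), NULL))
  hm <- clusterHeatmap(gmFromCodes(codes))
  expect_equal(hm$sampleTree$height, c(1, 1.5))
  # identical rows merge first at height zero
  codes2 <- rbind(a = c(0L, 1L), b = c(0L, 1L), c = c(2L, 2L))
  hm2 <- clusterHeatmap(gmFromCodes(codes2))
  expect_equal(hm2$sampleTree$height[1], 0)
  expect_setequal(hm2$sampleOrder, 1:3)
})

test_that("cluster heatmap keeps missing codes visible but imputes distances", {
  codes <- rbind(a = c(0L, NA), b = c(0L, 2L), c = c(2L, 2L))
  hm <- clusterHeatmap(gmFromCodes(codes))
  expect_true(is.na(hm$matrix["a", 2]))
  expect_s3_class(hm$sampleTree, "hclust")
  expect_setequal(hm$siteOrder, 1:2)
})

test_that("structure check flags structure-driven phenotypes as confounded", {
  cfg <- simulationConfig(nSamples = 90, nSites = 200, nSubpops = 3,
                          fst = 0.3, nCausal = 0, missingRate = 0,
                          effects = matrix(0, 3, 0), seed = 41)
  sim <- simulateGenotypes(cfg)
  # phenotype = subpopulation identity, the textbook confounded design
  ph <- phenotypeTable(sampleIds(sim$genotypes),
                       c("white", "beige", "orange")[sim$truth@subpop])
  ec <- ensembleConfig(nReplicates = 4, minModels = 2, nTest = 18,
                       nTrialsPerReplicate = 1, nFolds = 3,
                       maxRounds = 30, baseSeed = 7)
  chk <- structureCheck(sim$genotypes, ph, ec, nPcs = 5)
  expect_equal(chk$flag, "confounded")
})

test_that("structure check with zero PCs reduces to the plain ensemble", {
  pan <- cached("panel120", smallPanel())
  ec <- ensembleConfig(nReplicates = 2, minModels = 1, nTest = 24,
                       nTrialsPerReplicate = 1, nFolds = 3,
                       maxRounds = 30, baseSeed = 19)
  chk <- structureCheck(pan$gm, pan$phenos, ec, nPcs = 0)
  plain <- runEnsemble(pan$gm, pan$phenos, ec)
  expect_equal(chk$flag, "clean")
  expect_equal(chk$ensemble$summary, plain$summary)
})
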