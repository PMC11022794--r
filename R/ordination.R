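#' @importFrom stats cor dist hclust prcomp pchisq sd predict
NULL

# impute missing codes by per-site mean of called codes; drop nothing
.imputeSiteMean <- function(codes) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "double"
  if (anyNA(codes)) {
    mu <- colMeans(codes, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(codes), arr.ind = TRUE)
    codes[idx] <- mu[idx[, 2]]
  }
  codes
}

#' Principal component projection of a genotype matrix
#'
#' Missing codes are imputed by the per-site mean of called codes, columns
#' are centered, and samples are projected onto the top `k` principal
#' axes. The sign of each axis is fixed by making its largest-magnitude
#' loading positive, so coordinates are fully deterministic. When the
#' matrix has more than `maxSites` sites, a seeded random subset of sites
#' is used (recorded in the result).
#'
#' @param x GenotypeMatrix or numeric matrix (samples x sites).
#' @param k number of components (default 2).
#' @param maxSites site cap for very wide matrices (default 200000).
#' @param seed seed for the site subsample when the cap binds.
#' @return list of class `projection`: `coordinates` (samples x k),
#'   `axisLabels`, `explainedVar` (fractions, nonincreasing), `method`,
#'   `loadings`, and `sitesUsed`.
#' @export
pcaProject <- function(x, k = 2L, maxSites = 200000L, seed = 1L) {
  X <- if (is(x, "GenotypeMatrix")) genoCodes(x) else as.matrix(x)
  sitesUsed <- ncol(X)
  if (ncol(X) > maxSites) {
    set.seed(seed)
    X <- X[, sort(sample.int(ncol(X), maxSites)), drop = FALSE]
    sitesUsed <- maxSites
  }
  if (k > min(nrow(X) - 1L, ncol(X)))
    stop("k exceeds min(n_samples - 1, n_sites)")
  Xc <- scale(.imputeSiteMean(X), center = TRUE, scale = FALSE)
  sv <- svd(Xc, nu = k, nv = k)
  d2 <- sv$d^2
  tot <- sum(d2)
  coords <- sv$u %*% diag(sv$d[seq_len(k)], nrow = k)
  loadings <- sv$v
  # sign convention: largest |loading| positive per axis
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      coords[, j] <- -coords[, j]
    }
  }
  rownames(coords) <- rownames(X)
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(coordinates = coords,
                 axisLabels = colnames(coords),
                 explainedVar = if (tot > 0) d2[seq_len(k)] / tot
                                else rep(0, k),
                 method = "PCA", loadings = loadings,
                 sitesUsed = sitesUsed),
            class = "projection")
}

#' Linear discriminant projection of a genotype matrix
#'
#' Fisher LDA on the imputed, centered codes: finds directions maximizing
#' between-class over within-class scatter. Because genotype panels have
#' far more sites than samples, the data are first reduced to the PCA
#' subspace of rank at most `n - classes` whenever sites exceed samples,
#' and the within-class scatter receives a small ridge
#' (`ridge * trace(Sw)/dim`) so it is always invertible. At most
#' `classes - 1` discriminants exist; `k` is truncated to that bound.
#'
#' @param x GenotypeMatrix or numeric matrix.
#' @param phenos PhenotypeTable covering the samples.
#' @param k requested discriminants (default 2; truncated to classes - 1).
#' @param ridge within-class scatter regularization factor (default 1e-6).
#' @return list of class `projection` with `coordinates` (samples x k'),
#'   `axisLabels`, `method = "LDA"`.
#' @export
ldaProject <- function(x, phenos, k = 2L, ridge = 1e-6) {
  X <- if (is(x, "GenotypeMatrix")) genoCodes(x) else as.matrix(x)
  labs <- classLabels(phenos)[rownames(X)]
  labs <- droplevels(labs)
  kMax <- nlevels(labs) - 1L
  if (kMax < 1) stop("LDA needs at least 2 classes")
  k <- min(k, kMax)
  Xi <- .imputeSiteMean(X)
  Xc <- scale(Xi, center = TRUE, scale = FALSE)
  # reduce to PCA subspace when p > n (scatter otherwise singular beyond ridge)
  V <- NULL
  if (ncol(Xc) > nrow(Xc)) {
    r <- min(nrow(Xc) - 1L, ncol(Xc))
    sv <- svd(Xc, nu = 0, nv = r)
    pos <- sv$d[seq_len(r)] > max(sv$d) * 1e-10
    V <- sv$v[, pos, drop = FALSE]
    Xc <- Xc %*% V
  }
  p <- ncol(Xc)
  Sw <- matrix(0, p, p)
  Sb <- matrix(0, p, p)
  mu <- colMeans(Xc)
  for (ci in levels(labs)) {
    rows <- which(labs == ci)
    Xk <- Xc[rows, , drop = FALSE]
    muk <- colMeans(Xk)
    Sw <- Sw + crossprod(sweep(Xk, 2, muk))
    Sb <- Sb + length(rows) * tcrossprod(muk - mu)
  }
  Sw <- Sw + diag(ridge * sum(diag(Sw)) / p + 1e-12, p)
  eig <- eigen(solve(Sw, Sb))
  W <- Re(eig$vectors[, seq_len(k), drop = FALSE])
  coords <- Xc %*% W
  for (j in seq_len(k)) {
    full <- if (is.null(V)) W[, j] else V %*% W[, j]
    i <- which.max(abs(full))
    if (full[i] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(X)
  colnames(coords) <- paste0("LD", seq_len(k))
  structure(list(coordinates = coords, axisLabels = colnames(coords),
                 explainedVar = NULL, method = "LDA"),
            class = "projection")
}

#' Mean silhouette of phenotype classes in a projection
#'
#' Euclidean-distance silhouette width averaged over samples; singleton
#' classes contribute 0 by convention, as do degenerate configurations
#' where distances vanish.
#'
#' @param projection a `projection` (or a coordinate matrix).
#' @param phenos PhenotypeTable.
#' @return numeric in \[-1, 1\].
#' @export
separationScore <- function(projection, phenos) {
  coords <- if (inherits(projection, "projection"))
    projection$coordinates else as.matrix(projection)
  labs <- droplevels(classLabels(phenos)[rownames(coords)])
  if (nlevels(labs) < 2) stop("separation score needs >= 2 classes")
  sil <- cluster::silhouette(as.integer(labs), dist(coords))
  widths <- sil[, "sil_width"]
  widths[is.nan(widths) | is.na(widths)] <- 0
  mean(widths)
}

#' Population-structure confounding check via principal-component features
#'
#' Appends the top `nPcs` principal-component coordinates of the genotype
#' matrix as extra feature columns, reruns the replicate ensemble, and
#' reports whether any PC pseudo-feature reaches the consensus threshold.
#' If the phenotype is driven by population structure rather than by
#' individual sites, the PC features — which summarize structure — will be
#' selected; the run is then flagged as confounded.
#'
#' @param gm GenotypeMatrix.
#' @param phenos PhenotypeTable.
#' @param config [ensembleConfig()].
#' @param nPcs number of PC features to append (default 10; 0 reduces to
#'   a plain ensemble run).
#' @return list: `flag` (`"confounded"` or `"clean"`), `pcCounts` (model
#'   count per PC feature), `consensus`, `ensemble`.
#' @export
structureCheck <- function(gm, phenos, config = ensembleConfig(),
                           nPcs = 10L) {
  X <- genoCodes(gm)
  storage.mode(X) <- "double"
  if (nPcs > 0) {
    proj <- pcaProject(gm, k = min(nPcs, nSamples(gm) - 1L, nSites(gm)))
    pcs <- proj$coordinates
    colnames(pcs) <- paste0("PCFEAT", seq_len(ncol(pcs)))
    X <- cbind(X, pcs)
  }
  ens <- runEnsemble(X, alignPhenotypes(phenos, gm), config)
  cons <- consensusSelect(ens$results, config$minModels,
                          sites = siteInfo(gm))
  pcSel <- grep("^PCFEAT", cons@selected$site, value = TRUE)
  counts <- table(unlist(lapply(ens$results,
                                function(f) names(importanceGains(f)))))
  pcCounts <- counts[grep("^PCFEAT", names(counts))]
  list(flag = if (length(pcSel)) "confounded" else "clean",
       pcCounts = pcCounts, consensus = cons, ensemble = ens)
}

#' Hierarchical clustering of samples and sites for a genotype heatmap
#'
#' Agglomerative clustering (average linkage, Euclidean distance) of both
#' samples and sites of a genotype subset, as used for genotype-pattern
#' heatmaps. Distances are computed on site-mean-imputed codes; the
#' returned `matrix` keeps missing codes as `NA` so a renderer can show
#' them as their own category.
#'
#' @param gm GenotypeMatrix (typically restricted to a consensus set).
#' @param phenos optional PhenotypeTable for row annotation.
#' @return list of class `clusterHeatmap`: `sampleTree`, `siteTree`
#'   (`hclust` objects or NULL when fewer than 2 rows/columns),
#'   `sampleOrder`, `siteOrder`, `matrix`, `classLabels`.
#' @export
clusterHeatmap <- function(gm, phenos = NULL) {
  stopifnot(nSites(gm) > 0)
  codes <- genoCodes(gm)
  Xi <- .imputeSiteMean(codes)
  sampleTree <- if (nrow(Xi) > 1) hclust(dist(Xi), method = "average")
  siteTree <- if (ncol(Xi) > 1) hclust(dist(t(Xi)), method = "average")
  structure(list(
    sampleTree = sampleTree, siteTree = siteTree,
    sampleOrder = if (is.null(sampleTree)) seq_len(nrow(Xi))
                  else sampleTree$order,
    siteOrder = if (is.null(siteTree)) seq_len(ncol(Xi))
                else siteTree$order,
    matrix = codes,
    classLabels = if (is.null(phenos)) NULL
                  else classLabels(phenos)[rownames(codes)]),
    class = "clusterHeatmap")
}

#' Write projection coordinates with class labels
#'
#' @param projection a `projection`.
#' @param phenos PhenotypeTable.
#' @param path output TSV.
#' @return Invisibly, `path`.
#' @export
writeProjection <- function(projection, phenos, path) {
  df <- data.frame(sample = rownames(projection$coordinates),
                   projection$coordinates,
                   class = as.character(
                     classLabels(phenos)[rownames(projection$coordinates)]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
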