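#' Centered relatedness (kinship) matrix
#'
#' `K = (1/p) * sum_j c_j c_j^T` where `c_j` is site j's dosage column
#' minus its mean (missing codes imputed by the site mean first) and `p`
#' the number of sites. Rows and columns sum to zero by construction and
#' K is positive semi-definite.
#'
#' @param gm GenotypeMatrix (or numeric samples x sites matrix).
#' @return symmetric n x n matrix with sample ids as dimnames.
#' @export
centeredRelatedness <- function(gm) {
  X <- if (is(gm, "GenotypeMatrix")) genoCodes(gm) else as.matrix(gm)
  stopifnot(nrow(X) >= 2, ncol(X) >= 1)
  Xc <- scale(.imputeSiteMean(X), center = TRUE, scale = FALSE)
  K <- tcrossprod(Xc) / ncol(Xc)
  dimnames(K) <- list(rownames(X), rownames(X))
  K
}

# profiled (restricted) log-likelihood of delta = sigma_e^2 / sigma_g^2
# on the eigenbasis of K; returns the criterion and the GLS pieces
.deltaProfile <- function(delta, d, eta, Xt, reml = TRUE) {
  n <- length(eta)
  q <- ncol(Xt)
  w <- 1 / (d + delta)
  A <- crossprod(Xt, w * Xt)
  beta <- tryCatch(solve(A, crossprod(Xt, w * eta)),
                   error = function(e) NULL)
  if (is.null(beta)) return(list(ll = -Inf))
  r <- eta - Xt %*% beta
  rss <- sum(w * r^2)
  if (rss <= 0) rss <- .Machine$double.eps
  if (reml) {
    s2 <- rss / (n - q)
    ll <- -0.5 * ((n - q) * log(s2) + sum(log(d + delta)) +
                    determinant(A, logarithm = TRUE)$modulus + (n - q))
  } else {
    s2 <- rss / n
    ll <- -0.5 * (n * log(s2) + sum(log(d + delta)) + n)
  }
  list(ll = as.numeric(ll), beta = as.numeric(beta), s2 = s2, A = A)
}

# golden-section maximization of f over [lo, hi] (log10-delta scale)
.goldenMax <- function(f, lo, hi, tol = 1e-6, maxIter = 80) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  for (i in seq_len(maxIter)) {
    if (abs(b - a) < tol) break
    if (f1 < f2) {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    } else {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    }
  }
  (a + b) / 2
}

#' Per-SNP linear-mixed-model Wald tests
#'
#' Fits, for every site, `y = alpha + x beta + u + e` with
#' `cov(u) = sigma_g^2 K` and `cov(e) = sigma_e^2 I`. K is
#' eigendecomposed once; for each site the variance ratio
#' `delta = sigma_e^2 / sigma_g^2` is estimated by maximizing the
#' restricted likelihood (REML; ML optional) over a log-spaced grid with
#' golden-section refinement, followed by generalized-least-squares
#' estimates of (alpha, beta). The Wald statistic `(beta/se)^2` is
#' referred to a chi-square with 1 df. Missing dosages are imputed by the
#' site mean; sites with zero genotypic variance are skipped with a
#' recorded reason.
#'
#' @param gm GenotypeMatrix (or numeric matrix) for the tested samples.
#' @param y numeric response (e.g. 0/1 class indicator), in sample order.
#' @param K kinship matrix from [centeredRelatedness()]; must be
#'   symmetric.
#' @param reml use REML (default) or ML for the variance ratio.
#' @param deltaRange grid bounds for delta (default `c(1e-5, 1e5)`).
#' @param nGrid number of log-spaced grid points (default 60).
#' @return data.frame: site, chrom, pos, beta, se, waldStat, p, skipped,
#'   reason.
#' @export
lmmWald <- function(gm, y, K, reml = TRUE, deltaRange = c(1e-5, 1e5),
                    nGrid = 60L) {
  X <- if (is(gm, "GenotypeMatrix")) genoCodes(gm) else as.matrix(gm)
  sites <- if (is(gm, "GenotypeMatrix")) siteInfo(gm) else
    data.frame(chrom = NA_character_, pos = NA_integer_)[rep(1, ncol(X)), ]
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X))
  if (length(unique(y)) < 2) stop("response y is constant")
  if (max(abs(K - t(K))) > 1e-8) stop("K must be symmetric")
  Xi <- .imputeSiteMean(X)
  if (is.null(colnames(Xi)))
    colnames(Xi) <- paste0("x", seq_len(ncol(Xi)))
  ev <- eigen(K, symmetric = TRUE)
  d <- pmax(ev$values, 0)
  U <- ev$vectors
  eta <- as.numeric(crossprod(U, y))
  ones <- as.numeric(crossprod(U, rep(1, nrow(X))))
  lgrid <- seq(log10(deltaRange[1]), log10(deltaRange[2]),
               length.out = nGrid)
  n <- nrow(Xi)
  out <- data.frame(site = colnames(Xi), chrom = sites$chrom,
                    pos = sites$pos, beta = NA_real_, se = NA_real_,
                    waldStat = NA_real_, p = NA_real_, skipped = FALSE,
                    reason = NA_character_, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(Xi))) {
    xj <- Xi[, j]
    if (stats::var(xj) == 0) {
      out$skipped[j] <- TRUE
      out$reason[j] <- "zero genotypic variance"
      next
    }
    Xt <- cbind(ones, as.numeric(crossprod(U, xj)))
    ll <- vapply(lgrid, function(l)
      .deltaProfile(10^l, d, eta, Xt, reml)$ll, numeric(1))
    b <- which.max(ll)
    lo <- lgrid[max(1, b - 1)]
    hi <- lgrid[min(nGrid, b + 1)]
    lhat <- .goldenMax(function(l)
      .deltaProfile(10^l, d, eta, Xt, reml)$ll, lo, hi)
    fit <- .deltaProfile(10^lhat, d, eta, Xt, reml)
    covB <- fit$s2 * solve(fit$A)
    beta <- fit$beta[2]
    se <- sqrt(covB[2, 2])
    w <- (beta / se)^2
    out$beta[j] <- beta
    out$se[j] <- se
    out$waldStat[j] <- w
    out$p[j] <- pchisq(w, df = 1, lower.tail = FALSE)
  }
  out
}

#' Pairwise-contrast GWAS over phenotype class pairs
#'
#' Runs [lmmWald()] for every unordered pair of the named classes, coding
#' the response 0/1 by class-set order and (by default) recomputing the
#' kinship matrix on each pair's samples. Sites with `p <` the fixed
#' genome-wide threshold are significant; the union over pairs is
#' reported with per-pair provenance.
#'
#' @param gm GenotypeMatrix over all samples.
#' @param phenos PhenotypeTable.
#' @param classes classes to pair up (default: the full class set).
#' @param pThreshold fixed genome-wide significance threshold
#'   (default 1e-8).
#' @param recomputeK recompute kinship per pair (default) or reuse a
#'   kinship from all samples, subset to the pair.
#' @param reml REML (default) or ML variance-ratio estimation.
#' @return list of class `gwasResult`: `perPair` (named list of
#'   data.frames), `union` (data.frame site/chrom/pos/pairs/minP),
#'   `pThreshold`.
#' @export
pairwiseGwas <- function(gm, phenos, classes = NULL, pThreshold = 1e-8,
                         recomputeK = TRUE, reml = TRUE) {
  phenos <- alignPhenotypes(phenos, gm)
  if (is.null(classes)) classes <- classSet(phenos)
  if (!all(classes %in% classSet(phenos)))
    stop("unknown class name: ",
         paste(setdiff(classes, classSet(phenos)), collapse = ", "))
  labs <- classLabels(phenos)
  Kfull <- if (!recomputeK) centeredRelatedness(gm) else NULL
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  perPair <- list()
  for (pr in pairs) {
    sel <- names(labs)[as.character(labs) %in% pr]
    sub <- gm[sel, ]
    yv <- as.numeric(as.character(labs[sel]) == pr[2])
    K <- if (recomputeK) centeredRelatedness(sub) else Kfull[sel, sel]
    res <- lmmWald(sub, yv, K, reml = reml)
    res$contrast <- paste(pr, collapse = "-")
    res$significant <- !res$skipped & res$p < pThreshold
    perPair[[paste(pr, collapse = "-")]] <- res
  }
  sig <- do.call(rbind, lapply(perPair, function(r)
    r[r$significant, c("site", "chrom", "pos", "contrast", "p")]))
  union <- if (is.null(sig) || !nrow(sig)) {
    data.frame(site = character(0), chrom = character(0),
               pos = integer(0), pairs = character(0), minP = numeric(0))
  } else {
    agg <- split(sig, sig$site)
    data.frame(
      site = names(agg),
      chrom = vapply(agg, function(a) a$chrom[1], character(1)),
      pos = vapply(agg, function(a) a$pos[1], integer(1)),
      pairs = vapply(agg, function(a)
        paste(sort(unique(a$contrast)), collapse = ";"), character(1)),
      minP = vapply(agg, function(a) min(a$p), numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(perPair = perPair, union = union,
                 pThreshold = pThreshold),
            class = "gwasResult")
}

#' Compare GWAS-significant sites with the boosting consensus set
#'
#' @param gwasSites character site ids significant in the univariate GWAS
#'   (or a `gwasResult`, whose union is used).
#' @param consensusSites character combined consensus site ids (or a
#'   [ConsensusSet-class]).
#' @param gwasGenes,consensusGenes optional character vectors of gene ids
#'   hit by each selection (from [mapSnpsToGenes()]), enabling the
#'   gene-level overlap.
#' @return list: set sizes, `snpIntersection`, `sizeRatio`
#'   (GWAS / consensus), and when genes are given `geneIntersection` and
#'   gene counts.
#' @export
compareSelections <- function(gwasSites, consensusSites,
                              gwasGenes = NULL, consensusGenes = NULL) {
  if (inherits(gwasSites, "gwasResult")) gwasSites <- gwasSites$union$site
  if (is(consensusSites, "ConsensusSet"))
    consensusSites <- combinedSites(consensusSites)
  out <- list(nGwas = length(gwasSites),
              nConsensus = length(consensusSites),
              snpIntersection = intersect(gwasSites, consensusSites),
              sizeRatio = if (length(consensusSites))
                length(gwasSites) / length(consensusSites) else NA_real_)
  if (!is.null(gwasGenes) && !is.null(consensusGenes)) {
    out$nGwasGenes <- length(unique(gwasGenes))
    out$nConsensusGenes <- length(unique(consensusGenes))
    out$geneIntersection <- intersect(gwasGenes, consensusGenes)
  }
  out
}

#' Write association results as tab-separated tables
#'
#' One file per contrast (`<prefix>.<pair>.tsv`) plus `<prefix>.union.tsv`.
#'
#' @param gwas a `gwasResult`.
#' @param prefix output path prefix.
#' @return Invisibly, the written paths.
#' @export
writeGwas <- function(gwas, prefix) {
  paths <- character(0)
  for (nm in names(gwas$perPair)) {
    p <- paste0(prefix, ".", gsub("[^A-Za-z0-9_-]", "_", nm), ".tsv")
    utils::write.table(
      gwas$perPair[[nm]][, c("chrom", "pos", "contrast", "beta", "se",
                             "p", "significant")],
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- paste0(prefix, ".union.tsv")
  utils::write.table(gwas$union, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, p))
}
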