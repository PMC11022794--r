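# small in-code fixtures shared across test files

# write a minimal VCF with the given fixed fields and GT strings
# records: list of lists with chrom, pos, ref, alt, info, gts (character)
writeToyVcf <- function(records, samples, path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  recs <- vapply(records, function(r)
    paste(c(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS",
            if (is.null(r$info)) "." else r$info, "GT", r$gts),
          collapse = "\t"), character(1))
  writeLines(c(hdr, recs), path)
  path
}

# genotype matrix straight from a code matrix, sites on one contig
gmFromCodes <- function(codes, chrom = "chr1", pos = NULL) {
  codes <- as.matrix(codes)
  if (is.null(pos)) pos <- seq_len(ncol(codes)) * 10L
  sites <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
                      stringsAsFactors = FALSE)
  genotypeMatrix(codes, sites)
}

# small three-class simulated panel with planted signal
smallPanel <- function(nSamples = 120, nSites = 300, nCausal = 4,
                       seed = 7, ...) {
  cfg <- simulationConfig(nSamples = nSamples, nSites = nSites,
                          nCausal = nCausal, seed = seed, ...)
  sim <- simulateGenotypes(cfg)
  list(gm = sim$genotypes, truth = sim$truth,
       phenos = assignPhenotypes(sim$genotypes, sim$truth, cfg),
       config = cfg)
}

# brute-force REML/ML fit: maximize the full-covariance likelihood over
# (log sigma_g^2, log10 delta) with direct matrix inversion, delta
# restricted to the same [1e-5, 1e5] domain the estimator searches; the
# independent oracle for the spectral-trick mixed-model Wald test
bruteLmm <- function(y, x, K, reml = TRUE) {
  X <- cbind(1, x)
  n <- length(y)
  nll <- function(par) {
    sg2 <- exp(par[1])
    V <- sg2 * (K + 10^par[2] * diag(n))
    Vi <- tryCatch(solve(V), error = function(e) NULL)
    if (is.null(Vi)) return(1e10)
    A <- t(X) %*% Vi %*% X
    beta <- solve(A, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    ll <- -0.5 * (determinant(V, TRUE)$modulus + t(r) %*% Vi %*% r)
    if (reml) ll <- ll - 0.5 * determinant(A, TRUE)$modulus
    -as.numeric(ll)
  }
  best <- NULL
  for (s1 in c(-3, 0, 2)) for (s2 in c(-4, 0, 3)) {
    o <- stats::optim(c(s1, s2), nll, method = "L-BFGS-B",
                      lower = c(-30, -5), upper = c(30, 5),
                      control = list(maxit = 2000, factr = 10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  V <- exp(best$par[1]) * (K + 10^best$par[2] * diag(n))
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  beta <- solve(A, t(X) %*% Vi %*% y)
  covB <- solve(A)
  w <- (beta[2] / sqrt(covB[2, 2]))^2
  list(beta = beta[2], wald = w,
       p = stats::pchisq(w, 1, lower.tail = FALSE))
}

# cache for expensive shared computations within one test run
.fixtureCache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, force(expr), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}
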