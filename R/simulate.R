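#' Configuration for the genotype-phenotype simulator
#'
#' Describes a synthetic resequencing panel: samples drawn from a few
#' subpopulations differentiated at a given FST (Balding-Nichols
#' beta-binomial allele frequencies), linkage disequilibrium modelled as
#' intra-block template copying, random missingness, and a small set of
#' planted causal SNPs determining a categorical phenotype through a
#' multinomial-logit liability.
#'
#' The defaults describe a desk-scale three-colour crop panel: 300
#' accessions in three classes at roughly a 45:27:23 imbalance, 5000 sites
#' in LD blocks of 5, mild structure (FST 0.05 over 3 subpopulations), 2%
#' missing calls, and 8 causal SNPs with strong effects.
#'
#' @param nSamples,nSites panel dimensions.
#' @param nSubpops number of subpopulations (samples split evenly).
#' @param fst fixation index in \[0, 1) controlling differentiation.
#' @param freqLo,freqHi ancestral allele-frequency bounds in (0, 1).
#' @param ldBlockSize sites per LD block; within a block, sites 2..k copy
#'   the block's first (template) column.
#' @param ldFlipProb per-entry probability that a copied site keeps its own
#'   independent draw instead of the template value (0 = perfect copies).
#' @param missingRate fraction of entries set to missing.
#' @param nCausal number of causal SNPs (placed on distinct block
#'   templates so each causal site has collinear proxies).
#' @param classLabels ordered phenotype class labels.
#' @param intercepts per-class liability intercepts; the default is the
#'   log of the target class proportions 45:27:23 minus each class's
#'   expected causal score contribution, so realized class frequencies
#'   track that imbalance on average.
#' @param effects (classes x causal) liability effect matrix per dosage
#'   unit; defaults assign each causal SNP an effect of 2 towards one
#'   class, cycling through classes.
#' @param samplingMode `"softmax-draw"` (stochastic labels from the
#'   softmax of class scores) or `"argmax"` (deterministic).
#' @param seed integer seed; every random draw descends from it.
#' @return A named list of class `simulationConfig`.
#' @export
simulationConfig <- function(nSamples = 300, nSites = 5000, nSubpops = 3,
                             fst = 0.05, freqLo = 0.1, freqHi = 0.9,
                             ldBlockSize = 5, ldFlipProb = 0.1,
                             missingRate = 0.02, nCausal = 8,
                             classLabels = c("white", "beige", "orange"),
                             intercepts = NULL, effects = NULL,
                             samplingMode = c("softmax-draw", "argmax"),
                             seed = 1L) {
  samplingMode <- match.arg(samplingMode)
  k <- length(classLabels)
  if (is.null(effects)) {
    effects <- matrix(0, nrow = k, ncol = nCausal)
    if (nCausal > 0)
      for (j in seq_len(nCausal))
        effects[(j - 1L) %% k + 1L, j] <- 2
  }
  if (is.null(intercepts)) {
    prop <- c(45, 27, 23)
    prop <- if (k == 3) prop / sum(prop) else rep(1 / k, k)
    # center out the expected causal score contribution per class
    # (expected dosage = 2 * mean allele frequency = freqLo + freqHi)
    # so that class frequencies track the target proportions on average
    expScore <- if (nCausal > 0)
      as.numeric(effects %*% rep(freqLo + freqHi, nCausal)) else rep(0, k)
    intercepts <- log(prop) - expScore
  }
  cfg <- list(nSamples = nSamples, nSites = nSites, nSubpops = nSubpops,
              fst = fst, freqLo = freqLo, freqHi = freqHi,
              ldBlockSize = ldBlockSize, ldFlipProb = ldFlipProb,
              missingRate = missingRate, nCausal = nCausal,
              classLabels = classLabels, intercepts = intercepts,
              effects = effects, samplingMode = samplingMode,
              seed = as.integer(seed))
  stopifnot(nCausal <= nSites, fst >= 0, fst < 1,
            freqLo > 0, freqHi < 1, freqLo <= freqHi,
            ldFlipProb >= 0, ldFlipProb <= 0.5,
            missingRate >= 0, missingRate <= 1,
            nrow(effects) == k, ncol(effects) == nCausal,
            length(intercepts) == k)
  class(cfg) <- "simulationConfig"
  cfg
}

#' Simulate a structured genotype matrix with LD blocks and planted causal sites
#'
#' Ancestral frequencies are Uniform(freqLo, freqHi); each subpopulation's
#' site frequency follows the Balding-Nichols model
#' Beta(p(1-F)/F, (1-p)(1-F)/F) (equal to p when F = 0); genotypes are
#' Binomial(2, subpopulation frequency). Within each LD block of
#' `ldBlockSize` consecutive sites, sites after the first copy the
#' template column entry-wise, each entry independently keeping its own
#' draw with probability `ldFlipProb`. Missing entries are then planted at
#' `missingRate`. Causal sites are the templates of `nCausal` distinct
#' blocks (chosen at random from the seed), so each causal signal also has
#' collinear within-block proxies.
#'
#' @param config a [simulationConfig()].
#' @return list with elements `genotypes` ([GenotypeMatrix-class]) and
#'   `truth` ([SyntheticTruth-class]).
#' @export
simulateGenotypes <- function(config) {
  stopifnot(inherits(config, "simulationConfig"))
  set.seed(config$seed)
  n <- config$nSamples; p <- config$nSites
  subpop <- rep(seq_len(config$nSubpops), length.out = n)
  anc <- stats::runif(p, config$freqLo, config$freqHi)
  F <- config$fst
  # subpopulation x site allele frequencies
  freq <- matrix(0, nrow = config$nSubpops, ncol = p)
  for (s in seq_len(config$nSubpops)) {
    if (F > 0) {
      freq[s, ] <- stats::rbeta(p, anc * (1 - F) / F,
                                (1 - anc) * (1 - F) / F)
    } else freq[s, ] <- anc
  }
  codes <- matrix(stats::rbinom(n * p, 2L, freq[subpop, ]), nrow = n)
  # LD: template copying within consecutive blocks
  bs <- config$ldBlockSize
  if (bs > 1) {
    blockId <- (seq_len(p) - 1L) %/% bs
    for (b in unique(blockId)) {
      cols <- which(blockId == b)
      if (length(cols) < 2) next
      tmpl <- codes[, cols[1]]
      for (j in cols[-1]) {
        keepOwn <- stats::runif(n) < config$ldFlipProb
        codes[, j] <- ifelse(keepOwn, codes[, j], tmpl)
      }
    }
  }
  if (config$missingRate > 0) {
    miss <- stats::runif(n * p) < config$missingRate
    codes[miss] <- NA_integer_
  }
  # causal sites: templates of distinct blocks
  nBlocks <- ceiling(p / max(bs, 1))
  stopifnot(config$nCausal <= nBlocks)
  causalBlocks <- sort(sample.int(nBlocks, config$nCausal))
  causal <- (causalBlocks - 1L) * max(bs, 1L) + 1L
  sites <- data.frame(
    chrom = paste0("chr", ((seq_len(p) - 1L) %/% 1000L) + 1L),
    pos = ((seq_len(p) - 1L) %% 1000L) * 100L + 1L,
    ref = "A", alt = "T", stringsAsFactors = FALSE)
  gm <- genotypeMatrix(codes, sites,
                       sampleIds = sprintf("S%03d", seq_len(n)))
  truth <- new("SyntheticTruth", causalIndices = as.integer(causal),
               effects = config$effects, subpop = as.integer(subpop))
  list(genotypes = gm, truth = truth)
}

#' Assign phenotype classes from planted causal genotypes
#'
#' Class scores are `intercept_c + sum_j effects[c, j] * dosage(causal_j)`
#' with missing dosages counted as 0 (so missingness leaks no class
#' information). Labels are the argmax of the scores or a seeded softmax
#' draw, per `config$samplingMode`.
#'
#' @param gm GenotypeMatrix from [simulateGenotypes()].
#' @param truth matching [SyntheticTruth-class].
#' @param config the [simulationConfig()] used.
#' @return A [PhenotypeTable-class] over `sampleIds(gm)`.
#' @export
assignPhenotypes <- function(gm, truth, config) {
  stopifnot(inherits(config, "simulationConfig"))
  X <- genoCodes(gm)[, truth@causalIndices, drop = FALSE]
  X[is.na(X)] <- 0L
  scores <- matrix(rep(config$intercepts, each = nSamples(gm)),
                   nrow = nSamples(gm))
  if (ncol(X)) scores <- scores + X %*% t(truth@effects)
  if (config$samplingMode == "argmax") {
    lab <- apply(scores, 1, which.max)
  } else {
    set.seed(config$seed + 1L)
    pr <- exp(scores - apply(scores, 1, max))
    pr <- pr / rowSums(pr)
    lab <- vapply(seq_len(nrow(pr)), function(i)
      sample.int(ncol(pr), 1L, prob = pr[i, ]), integer(1))
  }
  phenotypeTable(sampleIds(gm), config$classLabels[lab],
                 classSet = config$classLabels)
}

#' Write a GenotypeMatrix as a minimal biallelic VCF
#'
#' One record per site with GT-only FORMAT; dosage 0 -> `0/0`, 1 -> `0/1`,
#' 2 -> `1/1`, missing -> `./.`. `readVcfGenotypes(emitVcf(gm), passAllFilters())`
#' recovers the matrix exactly.
#'
#' @param gm GenotypeMatrix.
#' @param path output VCF path (plain text).
#' @return Invisibly, `path`.
#' @export
emitVcf <- function(gm, path) {
  sites <- siteInfo(gm)
  codes <- genoCodes(gm)
  gtStr <- c("0/0", "0/1", "1/1")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=consensusSNP",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sampleIds(gm)), collapse = "\t"))
  recs <- vapply(seq_len(nSites(gm)), function(j) {
    g <- codes[, j]
    gt <- ifelse(is.na(g), "./.", gtStr[g + 1L])
    paste(c(sites$chrom[j], sites$pos[j], ".", sites$ref[j], sites$alt[j],
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Write the planted-truth table of a simulation
#'
#' Tab-separated: site index, chrom, pos, then one effect column per class.
#'
#' @param truth SyntheticTruth.
#' @param gm the matching GenotypeMatrix.
#' @param path output file.
#' @param classLabels class labels naming the effect columns.
#' @return Invisibly, `path`.
#' @export
writeTruth <- function(truth, gm, path,
                       classLabels = paste0("class", seq_len(nrow(truth@effects)))) {
  sites <- siteInfo(gm)[truth@causalIndices, , drop = FALSE]
  df <- data.frame(index = truth@causalIndices,
                   chrom = sites$chrom, pos = sites$pos,
                   t(truth@effects))
  names(df)[-(1:3)] <- paste0("effect_", classLabels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
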