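test_that("VCF genotypes map to alt-allele dosage and missing calls", {
  path <- writeToyVcf(list(
    list(chrom = "chr1", pos = 100, ref = "A", alt = "G",
         gts = c("0/0", "0/1", "1/1", "1/0", "./.", "0|1"))),
    samples = paste0("s", 1:6))
  gm <- readVcfGenotypes(path, passAllFilters())
  expect_equal(as.integer(genoCodes(gm)[, 1]),
               c(0L, 1L, 2L, 1L, NA, 1L))
  expect_equal(sampleIds(gm), paste0("s", 1:6))
})

test_that("random GT fields always encode as their dosage", {
  gtPool <- c("0/0", "0/1", "1/0", "1/1", "./.", ".", "0|0", "0|1",
              "1|0", "1|1", ".|.")
  dosage <- c(0L, 1L, 1L, 2L, NA, NA, 0L, 1L, 1L, 2L, NA)
  set.seed(42)
  for (rep in 1:5) {
    idx <- sample(length(gtPool), 8, replace = TRUE)
    path <- writeToyVcf(list(
      list(chrom = "chr1", pos = 50, ref = "C", alt = "T",
           gts = gtPool[idx])), samples = paste0("s", 1:8))
    gm <- readVcfGenotypes(path, passAllFilters())
    expect_equal(as.integer(genoCodes(gm)[, 1]), dosage[idx])
  }
})

test_that("hard site filters drop low-MQ and multi-allelic records", {
  samples <- paste0("s", 1:4)
  path <- writeToyVcf(list(
    list(chrom = "chr1", pos = 10, ref = "A", alt = "G", info = "MQ=25",
         gts = c("0/0", "0/1", "1/1", "0/0")),
    list(chrom = "chr1", pos = 20, ref = "A", alt = "G", info = "MQ=31",
         gts = c("0/0", "0/1", "1/1", "0/0"))), samples)
  gm <- readVcfGenotypes(path, vcfFilterConfig())
  expect_equal(nSites(gm), 1L)
  expect_equal(siteInfo(gm)$pos, 20L)
})

test_that("toy VCF enumeration: triallelic and high-missingness sites drop", {
  samples <- paste0("s", 1:4)
  ok <- c("0/0", "0/1", "1/1", "0/0")
  path <- writeToyVcf(list(
    list(chrom = "chr1", pos = 10, ref = "A", alt = "G", gts = ok),
    list(chrom = "chr1", pos = 20, ref = "A", alt = "G,T", gts = ok),
    list(chrom = "chr1", pos = 30, ref = "A", alt = "G",
         gts = c("./.", "./.", "0/1", "1/1")),  # 2/4 uncalled
    list(chrom = "chr1", pos = 40, ref = "C", alt = "T", gts = ok),
    list(chrom = "chr2", pos = 10, ref = "G", alt = "C", gts = ok)),
    samples)
  gm <- readVcfGenotypes(path, vcfFilterConfig())  # maxNocallFraction 0.1
  expect_equal(nSites(gm), 3L)
  expect_equal(siteInfo(gm)$pos, c(10L, 40L, 10L))
})

test_that("absent annotation keys pass their criterion, present ones apply", {
  samples <- paste0("s", 1:2)
  path <- writeToyVcf(list(
    list(chrom = "chr1", pos = 10, ref = "A", alt = "G",
         info = "DP=500;FS=10", gts = c("0/1", "1/1")),
    list(chrom = "chr1", pos = 20, ref = "A", alt = "G",
         info = "DP=2000", gts = c("0/1", "1/1")),
    list(chrom = "chr1", pos = 30, ref = "A", alt = "G",
         info = "MQRankSum=-13.0", gts = c("0/1", "1/1"))), samples)
  gm <- readVcfGenotypes(path, vcfFilterConfig())
  expect_equal(siteInfo(gm)$pos, 10L)  # DP out of range and |RankSum| > 12.5 drop
})

test_that("012 dialect writes row index, -1 for missing, and site lines", {
  gm <- gmFromCodes(rbind(s1 = c(0L, NA, 2L)))
  prefix <- tempfile()
  write012(gm, prefix)
  expect_equal(readLines(paste0(prefix, ".012")), "0\t0\t-1\t2")
  expect_equal(readLines(paste0(prefix, ".012.indv")), "s1")
  expect_equal(length(readLines(paste0(prefix, ".012.pos"))), 3L)
})

test_that("012 round trip is the identity on codes, samples and positions", {
  set.seed(11)
  codes <- matrix(sample(c(0L, 1L, 2L, NA), 40, replace = TRUE), 5, 8,
                  dimnames = list(paste0("acc", 1:5), NULL))
  gm <- gmFromCodes(codes)
  prefix <- tempfile()
  write012(gm, prefix)
  back <- read012(prefix)
  expect_equal(genoCodes(back), genoCodes(gm))
  expect_equal(siteInfo(back)$chrom, siteInfo(gm)$chrom)
  expect_equal(siteInfo(back)$pos, siteInfo(gm)$pos)
})

test_that("inconsistent or out-of-domain 012 files are rejected", {
  gm <- gmFromCodes(rbind(a = c(0L, 1L), b = c(2L, 0L), c = c(1L, 1L)))
  prefix <- tempfile()
  write012(gm, prefix)
  # drop one matrix row -> sample-count mismatch
  rows <- readLines(paste0(prefix, ".012"))
  writeLines(rows[1:2], paste0(prefix, ".012"))
  expect_error(read012(prefix), "consistency")
  writeLines(rows, paste0(prefix, ".012"))
  # out-of-domain code
  writeLines(sub("\t1$", "\t3", rows), paste0(prefix, ".012"))
  expect_error(read012(prefix), "domain")
})

test_that("MAF filtering removes rare and monomorphic sites, idempotently", {
  codes <- rbind(c(0L, 0L, 0L, NA),
                 c(0L, 1L, 0L, NA),
                 c(0L, 1L, 0L, NA),
                 c(0L, 2L, 1L, NA))
  rownames(codes) <- paste0("s", 1:4)
  gm <- gmFromCodes(codes)
  # site1 monomorphic (f=0); site2 f=4/8=0.5; site3 f=1/8; site4 uncalled
  kept <- mafFilter(gm, 0.2)
  expect_equal(siteInfo(kept)$pos, 20L)
  keptAll <- mafFilter(gm, 0.01)
  expect_equal(siteInfo(keptAll)$pos, c(20L, 30L))
  # idempotent and order-preserving
  twice <- mafFilter(mafFilter(gm, 0.01), 0.01)
  expect_equal(genoCodes(twice), genoCodes(keptAll))
})

test_that("phenotype tables round-trip through the two-column text format", {
  pt <- phenotypeTable(c("a1", "a2", "a3"), c("white", "beige", "white"),
                       classSet = c("white", "beige", "orange"))
  path <- tempfile()
  writePhenotypes(pt, path)
  # comment lines are ignored on read
  writeLines(c("# sample\tcolour", readLines(path)), path)
  back <- readPhenotypes(path, classSet = c("white", "beige", "orange"))
  expect_equal(classLabels(back), classLabels(pt))
  expect_equal(classSet(back), classSet(pt))
})

test_that("genotype matrix validity rejects bad codes and mismatched sites", {
  expect_error(genotypeMatrix(rbind(a = c(0, 5))), "0, 1, 2")
  expect_error(new("GenotypeMatrix",
                   codes = matrix(0L, 2, 3,
                                  dimnames = list(c("a", "b"), NULL)),
                   sites = data.frame(chrom = "c", pos = 1, ref = "A",
                                      alt = "T")),
               "site")
})
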