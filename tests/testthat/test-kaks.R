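test_that("identical sequences give Ka = Ks = 0 and an undefined ratio", {
  k <- computeKaKs("ATGAAACCCGGGTTTACT", "ATGAAACCCGGGTTTACT")
  expect_equal(k$ka, 0)
  expect_equal(k$ks, 0)
  expect_true(is.na(k$ratio))
})

test_that("a single synonymous change matches the pathway oracle exactly", {
  ## 6 codons, one third-position synonymous difference (GGG -> GGA)
  s1 <- "ATGAAACCCGGGTTTACT"
  s2 <- "ATGAAACCCGGATTTACT"
  k <- computeKaKs(s1, s2)
  o <- oracleKaKs(s1, s2)
  expect_equal(k$ka, 0)
  expect_gt(k$ks, 0)
  expect_equal(k$ratio, 0)
  expect_equal(k$ks, o$ks, tolerance = 1e-9)
  expect_equal(k$synSites, o$S, tolerance = 1e-9)
  expect_equal(k$synSubs, o$sd, tolerance = 1e-9)
})

test_that("codon pairs with up to 2 differences match the brute-force oracle", {
  ## random subsample here; the full 61 x 61 sweep runs in the acceptance
  ## suite
  .ng <- SynBridge:::.ngTables()
  sense <- .ng$sense
  set.seed(41)
  pairs <- 0
  while (pairs < 120) {
    c1 <- sample(sense, 1); c2 <- sample(sense, 1)
    d <- sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (d == 0 || d > 2) next
    got <- SynBridge:::.countCodonPair(c1, c2)
    want <- oraclePathCounts(c1, c2)
    expect_equal(unname(got), unname(want), tolerance = 1e-9,
                 label = paste(c1, c2))
    pairs <- pairs + 1
  }
})

test_that("Ka/Ks is symmetric and conserves site counts", {
  sim <- simulateCdsPairs(12, 60, omegaValues = 0.5, branchLength = 0.1,
                          seed = 43)
  for (i in seq_len(6)) {
    a <- as.character(sim$ref[[i]]); b <- as.character(sim$derived[[i]])
    k1 <- computeKaKs(a, b); k2 <- computeKaKs(b, a)
    expect_equal(k1$ka, k2$ka, tolerance = 1e-12)
    expect_equal(k1$ks, k2$ks, tolerance = 1e-12)
    ## stop codon excluded: 60 counted codons
    expect_equal(k1$synSites + k1$nonsynSites, 3 * 60, tolerance = 1e-9)
  }
})

test_that("the CDS pair generator respects its degenerate limits", {
  s0 <- simulateCdsPairs(5, 30, omegaValues = 0.5, branchLength = 0,
                         seed = 47)
  expect_identical(as.character(s0$ref), as.character(s0$derived))
  sOmega0 <- simulateCdsPairs(10, 50, omegaValues = 0, branchLength = 0.3,
                              seed = 47)
  expect_true(all(sOmega0$pairs$nNonsynSub == 0))
  ## no stop codons ever appear inside the derived sequences
  gc <- Biostrings::GENETIC_CODE
  for (i in seq_len(10)) {
    s <- as.character(sOmega0$derived[[i]])
    n <- nchar(s) / 3
    codons <- substring(s, 3 * seq_len(n - 1) - 2, 3 * seq_len(n - 1))
    expect_false(any(gc[codons] == "*"))
  }
  expect_warning(simulateCdsPairs(2, 5, omegaValues = 0.5, seed = 1),
                 "unstable")
  expect_error(simulateCdsPairs(2, 50, omegaValues = -1), "omegaValues")
})

test_that("reconstruction substitutes only exonic SNPs", {
  cds <- "ATGAAATTTTAA"
  exons <- data.frame(gene = "g", scaffold = "s",
                      start = c(101, 120), end = c(106, 125), strand = "+")
  ## no SNPs: identity
  r0 <- reconstructOrtholog(cds, exons, data.frame(scaffold = character(),
                                                   bp = numeric(),
                                                   ref = character(),
                                                   alt = character()))
  expect_identical(r0$cds, cds)
  expect_identical(r0$nSub, 0L)
  ## one exonic SNP changes exactly one base
  snps <- data.frame(scaffold = "s", bp = 104, ref = "A", alt = "G")
  r1 <- reconstructOrtholog(cds, exons, snps)
  expect_identical(sum(strsplit(r1$cds, "")[[1]] !=
                         strsplit(cds, "")[[1]]), 1L)
  expect_identical(substr(r1$cds, 4, 4), "G")
  ## an intronic SNP leaves the CDS untouched
  r2 <- reconstructOrtholog(cds, exons,
                            data.frame(scaffold = "s", bp = 110,
                                       ref = "A", alt = "G"))
  expect_identical(r2$cds, cds)
  ## a substitution creating an internal stop is flagged
  r3 <- reconstructOrtholog(cds, exons,
                            data.frame(scaffold = "s", bp = 105,
                                       ref = "A", alt = "T"))
  ## codon 2 AAA -> ATA is fine; try codon 2 -> TAA via position 4
  r4 <- reconstructOrtholog(cds, exons,
                            data.frame(scaffold = "s", bp = 104,
                                       ref = "A", alt = "T"))
  expect_true(r4$prematureStop)
  expect_false(r0$prematureStop)
})

test_that("peak bins assign ratios with half-open boundaries", {
  kt <- data.frame(gene = paste0("g", 1:6),
                   ratio = c(0.2, 0.6, 0.95, NA, 0.35, 0.1))
  p <- partitionPeaks(kt)
  a <- setNames(p$assignment$bin, p$assignment$gene)
  expect_identical(unname(a["g1"]), "peak1")
  expect_identical(unname(a["g2"]), "peak3")   # 0.6 belongs to peak3
  expect_identical(unname(a["g3"]), "none")
  expect_identical(unname(a["g4"]), "none")    # undefined ratio
  expect_identical(unname(a["g5"]), "none")    # between bins
  expect_identical(unname(a["g6"]), "peak1")   # lower bound inclusive
  expect_error(partitionPeaks(kt[0, ]), "empty")
})

test_that("common-peak intersection behaves as set intersection", {
  ktA <- data.frame(gene = paste0("g", 1:40),
                    ratio = rep(c(0.2, 0.5, 0.8), times = c(10, 20, 10)))
  pA <- partitionPeaks(ktA, comparison = "A")
  ## identical partitions: common sets equal the bin sets
  cc <- intersectCommon(pA, pA)
  expect_identical(unname(cc$counts), c(10L, 20L, 10L))
  ## disjoint gene sets: all zero
  ktB <- ktA; ktB$gene <- paste0("h", 1:40)
  expect_identical(unname(intersectCommon(pA, partitionPeaks(ktB))$counts),
                   c(0L, 0L, 0L))
  ## planted overlap of 17 genes in peak2
  ktC <- data.frame(gene = c(paste0("g", 11:27), paste0("x", 1:5)),
                    ratio = 0.5)
  cc2 <- intersectCommon(pA, partitionPeaks(ktC))
  expect_identical(unname(cc2$counts[["peak2"]]), 17L)
  ## mismatched bins are rejected
  pAlt <- partitionPeaks(ktA, bins = list(p = c(0, 1)))
  expect_error(intersectCommon(pA, pAlt), "bin definitions")
})

test_that("ortholog groups are filtered by protein-length RSD", {
  f1 <- filterConservedOrthologs(matrix(c(300, 300, 300, 300), 1,
                                        dimnames = list("a", NULL)))
  expect_identical(f1$retained, "a")
  f2 <- filterConservedOrthologs(matrix(c(300, 303, 297), 1,
                                        dimnames = list("b", NULL)))
  expect_identical(length(f2$retained), 0L)
  expect_equal(unname(f2$rsd), sqrt(6) / 300, tolerance = 1e-12)
  f3 <- filterConservedOrthologs(matrix(c(300, 303, 297), 1), Inf)
  expect_identical(length(f3$retained), 1L)
  expect_error(filterConservedOrthologs(matrix(c(0, 300), 1)), "zero-length")
})

test_that("Ks-to-time conversion is exact linear arithmetic", {
  expect_equal(ksToTime(0.122, 6.1e-9), 10)
  expect_equal(ksToTime(0), 0)
  ## back-computation: 53.3 MYA at the default rate corresponds to
  ## Ks = 2 * rate * T
  ksWgd <- 2 * 6.1e-9 * 53.3e6
  expect_equal(ksToTime(ksWgd), 53.3, tolerance = 1e-12)
  expect_equal(round(ksWgd, 3), 0.650)
  expect_error(ksToTime(-0.1), "non-negative")
  expect_error(ksToTime(0.5, 0), "positive")
})

test_that("premature-stop pairs are excluded from the Ka/Ks table", {
  refs <- Biostrings::DNAStringSet(c(a = "ATGAAACCCTAA", b = "ATGAAACCCTAA"))
  alts <- Biostrings::DNAStringSet(c(a = "ATGTAACCCTAA",  # internal stop
                                     b = "ATGAAGCCCTAA"))
  kt <- kaksTable(refs, alts)
  expect_identical(kt$gene, "b")
  kt2 <- kaksTable(refs, alts, excludePrematureStops = FALSE)
  expect_identical(nrow(kt2), 2L)
  expect_identical(kt2$internalStops, c(1L, 0L))
})
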