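test_that("depth gating masks low-depth calls and drops monomorphic sites", {
  geno <- rbind(c("A", "B", "H", "A"),
                c("A", "A", "A", "B"),
                c("A", "A", "A", "A"))   # monomorphic: must be dropped
  depth <- rbind(c(9, 10, 30, 30),
                 c(30, 30, 30, 30),
                 c(30, 30, 30, 30))
  gs <- makeGenotypeSites(geno, depth = depth)
  out <- callSites(gs, minDepth = 10)
  expect_identical(nSites(out), 2L)
  expect_identical(siteGenotypes(out)[1, 1], "N")   # depth 9 -> N
  expect_identical(siteGenotypes(out)[2, ], c("A", "A", "A", "B"))
})

test_that("exactly the planted low-depth cells become N", {
  set.seed(5)
  geno <- matrix(sample(c("A", "B", "H"), 10 * 8, TRUE), 10, 8)
  depth <- matrix(30, 10, 8)
  planted <- cbind(c(1, 3, 5, 7, 9), c(2, 4, 6, 8, 1))
  depth[planted] <- 9
  gs <- makeGenotypeSites(geno, depth = depth)
  out <- callSites(gs, minDepth = 10)
  kept <- match(siteInfo(out)$site, siteInfo(gs)$site)
  for (k in seq_len(nSites(out))) {
    i <- kept[k]
    isN <- siteGenotypes(out)[k, ] == "N"
    shouldN <- depth[i, ] < 10
    expect_identical(isN, shouldN)
  }
})

test_that("co-segregation merging honours the 1 kb window", {
  geno <- rbind(c("A", "H", "B"), c("A", "H", "B"))
  gs <- makeGenotypeSites(geno, bp = c(1000, 1500))
  out <- mergeCosegregating(gs)
  expect_identical(nSites(out$sites), 1L)
  gs2 <- makeGenotypeSites(geno, bp = c(1000, 2500))  # 1.5 kb apart
  out2 <- mergeCosegregating(gs2)
  expect_identical(nSites(out2$sites), 2L)
  ## same spacing on different scaffolds never merges
  gs3 <- makeGenotypeSites(geno, scaffold = c("s1", "s2"), bp = c(1000, 1500))
  expect_identical(nSites(mergeCosegregating(gs3)$sites), 2L)
})

test_that("missing-tolerant consistency picks the lowest-N representative", {
  geno <- rbind(c("A", "H", "N"),
                c("A", "N", "B"),
                c("A", "H", "B"))
  gs <- makeGenotypeSites(geno, bp = c(100, 600, 1100))
  out <- mergeCosegregating(gs, mode = "tolerant")
  expect_identical(nSites(out$sites), 1L)
  expect_identical(siteInfo(out$sites)$site, "s3")   # zero N calls
  expect_identical(unique(out$members$representative), "s3")
  ## strict mode refuses the same merge
  out2 <- mergeCosegregating(gs, mode = "strict")
  expect_identical(nSites(out2$sites), 3L)
})

test_that("merging is idempotent on a simulated population", {
  ta <- simulateGenomes(nChromosomes = 2, genesPerChromosome = 40,
                        nScaffolds = 8, seed = 19)
  mt <- markerTruthFromAssembly(ta, markersPerScaffold = 3, clusterSize = 3,
                                seed = 19)
  pop <- simulateF4Population(mt, nLines = 100, missingRate = 0.02, seed = 19)
  gs <- callSites(asGenotypeSites(pop))
  once <- mergeCosegregating(gs)
  twice <- mergeCosegregating(once$sites)
  expect_identical(siteInfo(once$sites), siteInfo(twice$sites))
  expect_identical(siteGenotypes(once$sites), siteGenotypes(twice$sites))
  ## representatives absorb only members within the window on one scaffold
  mem <- merge(once$members, siteInfo(gs), by = "site")
  rep_info <- siteInfo(gs)[match(mem$representative, siteInfo(gs)$site), ]
  expect_true(all(mem$scaffold == rep_info$scaffold))
})

test_that("chi-square distortion filter matches direct computation", {
  mk <- function(nA, nH, nB, nN = 0) {
    c(rep("A", nA), rep("H", nH), rep("B", nB), rep("N", nN))
  }
  geno <- rbind(mk(70, 20, 70), mk(150, 5, 5), mk(0, 0, 0, 160))
  gs <- makeGenotypeSites(geno, bp = c(100, 5000, 9000))
  expect_warning(out <- filterDistorted(gs, alpha = 0.01), "untestable")
  rep <- out$report
  expect_identical(rep$status, c("retained", "removed", "untestable"))
  ## direct chi-square for the balanced site
  e <- 160 * c(7 / 16, 1 / 8, 7 / 16)
  chi1 <- sum((c(70, 20, 70) - e)^2 / e)
  expect_equal(rep$chisq[1], chi1)
  expect_equal(rep$p[1], pchisq(chi1, 2, lower.tail = FALSE))
  ## untestable sites are retained
  expect_identical(nSites(out$sites), 2L)
  ## output ordering preserved, subset of input
  expect_identical(siteInfo(out$sites)$site, c("s1", "s3"))
})

test_that("planted distorted markers are removed, clean markers survive", {
  removed_frac <- clean_removed <- numeric(0)
  for (seed in 1:3) {
    ta <- simulateGenomes(nChromosomes = 2, genesPerChromosome = 60,
                          nScaffolds = 10, seed = seed)
    mt <- markerTruthFromAssembly(ta, markersPerScaffold = 4, seed = seed)
    set.seed(seed)
    planted <- sample(mt$marker, round(0.1 * nrow(mt)))
    pop <- simulateF4Population(mt, nLines = 133, missingRate = 0.01,
                                distortedMarkers = planted, bias = 0.7,
                                seed = seed + 100)
    gs <- callSites(asGenotypeSites(pop))
    fd <- suppressWarnings(filterDistorted(gs))
    rem <- fd$report$site[fd$report$status == "removed"]
    removed_frac <- c(removed_frac, mean(planted %in% rem))
    clean <- setdiff(fd$report$site, planted)
    clean_removed <- c(clean_removed, mean(clean %in% rem))
  }
  expect_gte(mean(removed_frac), 0.9)
  expect_lte(mean(clean_removed), 0.02)
})

test_that("anchoring orders, orients and flags components correctly", {
  map <- data.frame(marker = c("a1", "a2", "b1", "c1", "c2", "d1", "d2"),
                    lg = c(1, 1, 1, 1, 1, 1, 2),
                    cm = c(5, 12, 20, 2, 7, 30, 40))
  pos <- data.frame(marker = map$marker,
                    scaffold = c("sA", "sA", "sB", "sC", "sC", "sD", "sD"),
                    bp = c(10e3, 900e3, 5e3, 800e3, 100e3, 1e3, 2e3))
  anch <- anchorToMap(map, pos)
  pl <- anch$placements
  rownames(pl) <- pl$component
  expect_identical(pl["sA", "orientation"], "+")   # bp rises with cM
  expect_identical(pl["sC", "orientation"], "-")   # bp falls with cM
  expect_identical(pl["sB", "orientation"], "?")   # single marker
  ## sD spans two linkage groups: conflict, unplaced by default
  expect_identical(anch$conflicts, "sD")
  expect_false("sD" %in% pl$component)
  ## order on lg 1 by median cM: sC (4.5), sA (8.5), sB (20)
  lg1 <- pl[pl$lg == 1, ]
  expect_identical(lg1$component[order(lg1$order)], c("sC", "sA", "sB"))
  ## majority mode places the conflicted component instead
  anch2 <- anchorToMap(map, pos, multiLg = "majority")
  expect_true("sD" %in% anch2$placements$component)
  ## unknown scaffolds are rejected
  expect_error(anchorToMap(map, pos[-1, ]), "unknown scaffold")
})

test_that("anchoring reproduces the simulated scaffold order", {
  ta <- simulateGenomes(nChromosomes = 2, genesPerChromosome = 60,
                        nScaffolds = 12, seed = 5)
  mt <- markerTruthFromAssembly(ta, markersPerScaffold = 2, seed = 5)
  pop <- simulateF4Population(mt, nLines = 133, missingRate = 0, seed = 5)
  gs <- callSites(asGenotypeSites(pop))
  mkPos <- siteInfo(gs)[, c("site", "scaffold", "bp")]
  names(mkPos)[1] <- "marker"
  anch <- anchorToMap(mt[mt$marker %in% mkPos$marker, c("marker", "lg", "cm")],
                      mkPos)
  for (ci in seq_along(unique(ta@scaffolds$chrom))) {
    chr <- unique(ta@scaffolds$chrom)[ci]
    sc <- ta@scaffolds[ta@scaffolds$chrom == chr, ]
    true_order <- sc$scaffold[order(sc$chromOrder)]
    pl <- anch$placements[anch$placements$lg == ci, ]
    expect_identical(pl$component[order(pl$order)], true_order)
  }
})

test_that("super-scaffold map consistency flags a planted misjoin", {
  map <- data.frame(marker = paste0("m", 1:6),
                    lg = c(1, 1, 1, 1, 1, 2),
                    cm = c(5, 8, 11, 20, 25, 3))
  pos <- data.frame(marker = map$marker,
                    scaffold = c("S1", "S2", "S3", "S4", "S5", "S6"),
                    bp = 1000)
  ch <- data.frame(
    superScaffold = c("ss1", "ss1", "ss1", "ss2", "ss2", "ss3", "ss3"),
    position = c(1, 2, 3, 1, 2, 1, 2),
    scaffold = c("S1", "S2", "S3", "S4", "S6", "S5", "S7"),
    orientation = "+", stringsAsFactors = FALSE)
  lens <- setNames(rep(2000, 7), paste0("S", 1:7))
  ss <- new("SuperScaffolds", chains = ch, singletons = character(0),
            fates = data.frame(), scaffoldLengths = lens, gapBp = 100)
  rep <- checkSuperScaffoldConsistency(ss, map, pos)
  rownames(rep) <- rep$superScaffold
  expect_identical(rep["ss1", "status"], "consistent")    # 5, 8, 11 cM
  expect_identical(rep["ss2", "status"], "inconsistent")  # jumps linkage group
  expect_identical(rep["ss3", "status"], "untestable")    # one markered member
  ## a descending chain is consistent after the global flip
  ch2 <- data.frame(superScaffold = "ss4", position = 1:3,
                    scaffold = c("S3", "S2", "S1"), orientation = "-",
                    stringsAsFactors = FALSE)
  ss2 <- new("SuperScaffolds", chains = ch2, singletons = character(0),
             fates = data.frame(), scaffoldLengths = lens, gapBp = 100)
  expect_identical(checkSuperScaffoldConsistency(ss2, map, pos)$status,
                   "consistent")
})
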