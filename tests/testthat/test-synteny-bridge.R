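test_that("parser resolves anchors, flags inverted blocks, skips bad ids", {
  d <- withr::local_tempdir()
  colf <- file.path(d, "x.col")
  writeLines(c(
    "## Alignment 1: score=100 e_value=0 N=3 sc1&chr1 plus",
    "  1-  0:\tt1\tr1\t0.10",
    "  1-  1:\tt2\tr2\t0.12",
    "  1-  2:\tt3\tr3\t0.11",
    "## Alignment 2: score=100 e_value=0 N=2 sc2&chr1 plus",
    "  2-  0:\tt4\tr4\t0.10",
    "  2-  1:\tt5\tr5\t0.10"), colf)
  tpos <- data.frame(chrom = c("sc1", "sc1", "sc1", "sc2", "sc2"),
                     gene = paste0("t", 1:5),
                     start = c(100, 200, 300, 100, 200),
                     end = c(150, 250, 350, 150, 250))
  ## reference positions of block 2 decrease while target increases
  rpos <- data.frame(chrom = "chr1", gene = paste0("r", 1:5),
                     start = c(1000, 2000, 3000, 9000, 8000),
                     end = c(1100, 2100, 3100, 9100, 8100))
  bl <- parseCollinearity(colf, tpos, rpos)
  b <- blockTable(bl)
  expect_identical(nrow(b), 2L)
  expect_identical(b$orientation[b$block == 1], "same")
  expect_identical(b$orientation[b$block == 2], "inverted")
  expect_identical(anchorTable(bl)$targetGene[1:3], c("t1", "t2", "t3"))

  ## one unresolvable gene id: anchor count drops by exactly one
  rpos2 <- rpos[rpos$gene != "r2", ]
  expect_warning(bl2 <- parseCollinearity(colf, tpos, rpos2),
                 "not in position table")
  expect_identical(nrow(anchorTable(bl2)), nrow(anchorTable(bl)) - 1L)

  ## a block reduced below 2 anchors is dropped entirely
  rpos3 <- rpos[rpos$gene != "r4", ]
  w <- capture_warnings(bl3 <- parseCollinearity(colf, tpos, rpos3))
  expect_true(any(grepl("fewer than 2 anchors", w)))
  expect_identical(nrow(blockTable(bl3)), 1L)
})

test_that("the recent Ks peak separates orthologous from ancient blocks", {
  set.seed(31)
  low <- rnorm(60, 0.1, 0.02)
  high <- rnorm(60, 0.65, 0.05)
  anchors <- do.call(rbind, lapply(seq_len(120), function(i) {
    ks <- c(low, high)[i]
    makeAnchors(i, paste0("s", i), c(100, 200), "chr1",
                c(1000 * i, 1000 * i + 100), ks = ks)
  }))
  bl <- makeSyntenyBlocks(anchors)
  sel <- selectRecentPeakBlocks(bl)
  expect_gt(sel$ksCutoff, 0.2)
  expect_lt(sel$ksCutoff, 0.5)
  kept <- blockTable(sel$blocks)$block
  expect_setequal(kept, 1:60)   # exactly the low-mode blocks survive
})

test_that("degenerate Ks distributions keep all blocks with a warning", {
  anchors <- do.call(rbind, lapply(1:12, function(i)
    makeAnchors(i, paste0("s", i), c(1, 2), "chr1", c(10 * i, 10 * i + 1),
                ks = 0.2)))
  bl <- makeSyntenyBlocks(anchors)
  expect_warning(sel <- selectRecentPeakBlocks(bl), "no WGD peak")
  expect_identical(nrow(blockTable(sel$blocks)), 12L)
})

test_that("links face the right scaffold ends and merge across references", {
  ## chr1 carries block->S1 (same) then block->S2 (same)
  a1 <- rbind(makeAnchors(1, "S1", c(100, 200), "chr1", c(1000, 2000)),
              makeAnchors(2, "S2", c(100, 200), "chr1", c(5000, 6000)))
  bs <- makeSyntenyBlocks(a1)
  links <- deriveLinks(list(refA = bs))
  expect_identical(nrow(links), 1L)
  expect_identical(links$endA[links$scaffoldA == "S1"], "tail")
  expect_identical(links$endB[links$scaffoldB == "S2"], "head")

  ## second block inverted: the link enters S2 through its tail
  a2 <- rbind(makeAnchors(1, "S1", c(100, 200), "chr1", c(1000, 2000)),
              makeAnchors(2, "S2", c(200, 100), "chr1", c(5000, 6000)))
  links2 <- deriveLinks(list(refA = makeSyntenyBlocks(a2)))
  expect_identical(links2$endB[links2$scaffoldB == "S2"], "tail")

  ## both references implying the same link merge with support 2
  links3 <- deriveLinks(list(refA = bs, refB = bs))
  expect_identical(nrow(links3), 1L)
  expect_identical(links3$support, 2L)
})

test_that("an inverted-block link reconstructs the implied gene order", {
  ## brute-force check: S1(+) joined to S2(-) means S2's genes read
  ## tail-to-head continue S1's order along the reference
  a <- rbind(makeAnchors(1, "S1", c(100, 200), "chr1", c(1000, 2000)),
             makeAnchors(2, "S2", c(900, 100), "chr1", c(3000, 4000)))
  links <- deriveLinks(list(refA = makeSyntenyBlocks(a), refB = makeSyntenyBlocks(a)))
  ss <- buildSuperScaffolds(links, c(S1 = 1000, S2 = 1000), minSupport = 2)
  ch <- chainTable(ss)
  ch <- ch[order(ch$position), ]
  ori <- setNames(ch$orientation, ch$scaffold)
  ## up to a global flip, S1 and S2 must have opposite orientations
  expect_true(ori[["S1"]] != ori[["S2"]])
})

test_that("chains form, conflicts drop, and N50 grows", {
  adj <- data.frame(
    scaffoldA = c("S1", "S2"), endA = c("tail", "tail"),
    scaffoldB = c("S2", "S3"), endB = c("head", "head"),
    support = c(2L, 2L), refs = "refA,refB", stringsAsFactors = FALSE)
  lens <- c(S1 = 1000, S2 = 2000, S3 = 1500)
  ss <- buildSuperScaffolds(adj, lens, minSupport = 2)
  ch <- chainTable(ss)
  expect_identical(nrow(ch), 3L)
  expect_identical(length(unique(ch$superScaffold)), 1L)
  expect_gt(assemblyN50(superScaffoldLengths(ss)), assemblyN50(lens))
  expect_identical(ch$scaffold[order(ch$position)] %in% c("S1", "S2", "S3"),
                   rep(TRUE, 3))

  ## equal-support fork at S1:tail: everything at that end is dropped
  adj2 <- data.frame(
    scaffoldA = c("S1", "S1"), endA = "tail",
    scaffoldB = c("S2", "S3"), endB = "head",
    support = 2L, refs = "refA,refB", stringsAsFactors = FALSE)
  ss2 <- buildSuperScaffolds(adj2, lens, minSupport = 2)
  expect_identical(nrow(chainTable(ss2)), 0L)
  expect_setequal(ss2@singletons, names(lens))
  expect_true(all(adjacencyFates(ss2)$fate == "conflict_dropped"))

  ## a strictly higher-support branch wins the fork
  adj3 <- adj2
  adj3$support <- c(3L, 2L)
  ss3 <- buildSuperScaffolds(adj3, lens, minSupport = 2)
  expect_identical(sort(unique(chainTable(ss3)$scaffold)), c("S1", "S2"))

  ## below-threshold support never joins
  adj4 <- adj
  adj4$support <- 1L
  ss4 <- buildSuperScaffolds(adj4, lens, minSupport = 2)
  expect_identical(nrow(chainTable(ss4)), 0L)
})

test_that("cycles are broken at the lowest-support link", {
  adj <- data.frame(
    scaffoldA = c("S1", "S2", "S3"), endA = "tail",
    scaffoldB = c("S2", "S3", "S1"), endB = "head",
    support = c(3L, 3L, 2L), refs = "r", stringsAsFactors = FALSE)
  ss <- buildSuperScaffolds(adj, c(S1 = 100, S2 = 100, S3 = 100),
                            minSupport = 2)
  f <- adjacencyFates(ss)
  expect_identical(f$fate[f$support == 2L], "cycle_broken")
  expect_identical(sum(f$fate == "used"), 2L)
  expect_identical(nrow(chainTable(ss)), 3L)  # one open chain of all three
})

test_that("every scaffold appears exactly once across chains and singletons", {
  ta <- simulateGenomes(nChromosomes = 2, genesPerChromosome = 60,
                        nScaffolds = 20, nRearrangements = 1, seed = 17)
  sets <- lapply(setNames(names(ta@collinearity), names(ta@collinearity)),
                 function(r) {
    d <- withr::local_tempdir()
    writeCollinearity(ta, r, file.path(d, "c"))
    writeGenePositions(ta, file.path(d, "t"), "target")
    writeGenePositions(ta, file.path(d, "r"), r)
    parseCollinearity(file.path(d, "c"), readGenePositions(file.path(d, "t")),
                      readGenePositions(file.path(d, "r")))
  })
  ss <- buildSuperScaffolds(deriveLinks(sets), scaffoldLengths(ta))
  all_members <- c(chainTable(ss)$scaffold, ss@singletons)
  expect_setequal(all_members, ta@scaffolds$scaffold)
  expect_identical(anyDuplicated(all_members), 0L)
  expect_gte(assemblyN50(superScaffoldLengths(ss)),
             assemblyN50(scaffoldLengths(ta)))
})

test_that("surviving links match a brute-force enumeration on small instances", {
  for (seed in c(2, 9, 23)) {
    ta <- simulateGenomes(nChromosomes = 2, genesPerChromosome = 24,
                          nScaffolds = 8, nRearrangements = 2, seed = seed)
    sets <- lapply(setNames(names(ta@collinearity), names(ta@collinearity)),
                   function(r) {
      d <- withr::local_tempdir()
      writeCollinearity(ta, r, file.path(d, "c"))
      writeGenePositions(ta, file.path(d, "t"), "target")
      writeGenePositions(ta, file.path(d, "r"), r)
      parseCollinearity(file.path(d, "c"),
                        readGenePositions(file.path(d, "t")),
                        readGenePositions(file.path(d, "r")))
    })
    links <- deriveLinks(sets)
    ss <- buildSuperScaffolds(links, scaffoldLengths(ta), minSupport = 2)
    got <- usedAdjacencyKeys(ss)
    want <- oracleAdjacencyKeys(sets, minSupport = 2)
    ## cycle breaking may remove one more edge than the oracle retains
    expect_true(all(got %in% want))
    expect_lte(length(want) - length(got),
               sum(adjacencyFates(ss)$fate == "cycle_broken"))
  }
})

test_that("AGP rows are arithmetically consistent and round-trip", {
  ch <- data.frame(superScaffold = "ss0001", position = 1:2,
                   scaffold = c("S1", "S2"), orientation = c("+", "-"),
                   stringsAsFactors = FALSE)
  ss <- new("SuperScaffolds", chains = ch, singletons = character(0),
            fates = data.frame(), scaffoldLengths = c(S1 = 1000, S2 = 1000),
            gapBp = 100)
  agp <- superScaffoldAgp(ss)
  expect_identical(nrow(agp), 3L)
  expect_equal(max(agp$object_end), 2100)
  expect_identical(agp$component_type, c("W", "N", "W"))
  expect_identical(agp$orientation[3], "-")
  f <- withr::local_tempfile(fileext = ".agp")
  writeAgp(agp, f)
  back <- readAgp(f)
  comp <- back[back$component_type == "W", ]
  expect_identical(comp$component_id, c("S1", "S2"))
  expect_identical(comp$orientation, c("+", "-"))
  ## unknown member length is rejected
  ss@scaffoldLengths <- c(S1 = 1000)
  expect_error(superScaffoldAgp(ss), "length")
})
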