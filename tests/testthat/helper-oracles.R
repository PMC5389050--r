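## Independent oracles used to validate the package's estimators.

## ---- Nei-Gojobori brute force -------------------------------------------
## Written against Biostrings::GENETIC_CODE directly; synonymous site
## fraction by explicit enumeration of all nine point changes per codon,
## substitution counts by explicit enumeration of substitution pathways
## (stop-containing pathways skipped; all-pathway fallback when blocked).

oracleSynSites <- function(codon) {
  GC <- Biostrings::GENETIC_CODE
  nt <- c("A", "C", "G", "T")
  s <- 0
  for (p in 1:3) {
    for (b in nt) {
      if (b == substr(codon, p, p)) next
      mut <- codon
      substr(mut, p, p) <- b
      if (GC[[mut]] != "*" && GC[[mut]] == GC[[codon]]) s <- s + 1 / 3
    }
  }
  s
}

.oraclePerms <- function(v) {
  if (length(v) <= 1) return(list(v))
  if (length(v) == 2) return(list(v, rev(v)))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .oraclePerms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

oraclePathCounts <- function(c1, c2) {
  GC <- Biostrings::GENETIC_CODE
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  pos <- which(a != b)
  if (!length(pos)) return(c(syn = 0, nonsyn = 0))
  ok <- list(); all <- list()
  for (ord in .oraclePerms(pos)) {
    cur <- a
    counts <- c(0, 0)
    blocked <- FALSE
    for (p in ord) {
      before <- paste(cur, collapse = "")
      cur[p] <- b[p]
      after <- paste(cur, collapse = "")
      if (GC[[after]] == "*" && after != c2) blocked <- TRUE
      if (GC[[before]] == GC[[after]]) counts[1] <- counts[1] + 1
      else counts[2] <- counts[2] + 1
    }
    all[[length(all) + 1]] <- counts
    if (!blocked) ok[[length(ok) + 1]] <- counts
  }
  use <- if (length(ok)) ok else all
  res <- Reduce(`+`, use) / length(use)
  c(syn = res[1], nonsyn = res[2])
}

## full NG86 on a pair of sequences, brute force end to end
oracleKaKs <- function(s1, s2) {
  GC <- Biostrings::GENETIC_CODE
  n <- nchar(s1) / 3
  st <- 3 * seq_len(n) - 2
  c1 <- substring(s1, st, st + 2)
  c2 <- substring(s2, st, st + 2)
  if (GC[[c1[n]]] == "*" && GC[[c2[n]]] == "*") {
    c1 <- c1[-n]; c2 <- c2[-n]
  }
  S <- mean(c(sum(vapply(c1, oracleSynSites, 0)),
              sum(vapply(c2, oracleSynSites, 0))))
  N <- 3 * length(c1) - S
  sd <- 0; nd <- 0
  for (i in seq_along(c1)) {
    cnt <- oraclePathCounts(c1[i], c2[i])
    sd <- sd + cnt[["syn"]]; nd <- nd + cnt[["nonsyn"]]
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, sd = sd, nd = nd, ks = jc(sd / S), ka = jc(nd / N))
}

## ---- two-locus selfing Markov chain -------------------------------------
## Closed-form genotype-pair distribution for an F(1+g) line at two loci
## with recombination fraction r, by iterating the selfing transition over
## the 16 ordered diplotype states.  Haplotypes coded 0..3 = 2*a1 + a2,
## alleles 0 (parent A) / 1 (parent B).

oracleSelfingDist <- function(r, generations = 3) {
  hapAlleles <- cbind(a1 = c(0, 0, 1, 1), a2 = c(0, 1, 0, 1))
  gameteDist <- function(h1, h2) {
    p <- numeric(4)
    for (g in 0:3) {
      x <- hapAlleles[g + 1, 1]; y <- hapAlleles[g + 1, 2]
      p[g + 1] <-
        0.5 * ((hapAlleles[h1 + 1, 1] == x) *
                 ((1 - r) * (hapAlleles[h1 + 1, 2] == y) +
                  r * (hapAlleles[h2 + 1, 2] == y)) +
               (hapAlleles[h2 + 1, 1] == x) *
                 ((1 - r) * (hapAlleles[h2 + 1, 2] == y) +
                  r * (hapAlleles[h1 + 1, 2] == y)))
    }
    p
  }
  ## state index for ordered pair (h1, h2): 4*h1 + h2 + 1
  dist <- numeric(16)
  dist[4 * 0 + 3 + 1] <- 1   # F1 = (AB, ab)
  for (g in seq_len(generations)) {
    nxt <- numeric(16)
    for (s in which(dist > 0)) {
      h1 <- (s - 1) %/% 4; h2 <- (s - 1) %% 4
      gp <- gameteDist(h1, h2)
      for (g1 in 0:3) for (g2 in 0:3)
        nxt[4 * g1 + g2 + 1] <- nxt[4 * g1 + g2 + 1] +
          dist[s] * gp[g1 + 1] * gp[g2 + 1]
    }
    dist <- nxt
  }
  ## collapse to joint genotype classes: (locus1, locus2), each in
  ## {0 = AA, 1 = het, 2 = BB}
  joint <- matrix(0, 3, 3)
  for (s in seq_len(16)) {
    h1 <- (s - 1) %/% 4; h2 <- (s - 1) %% 4
    g1 <- hapAlleles[h1 + 1, 1] + hapAlleles[h2 + 1, 1]
    g2 <- hapAlleles[h1 + 1, 2] + hapAlleles[h2 + 1, 2]
    joint[g1 + 1, g2 + 1] <- joint[g1 + 1, g2 + 1] + dist[s]
  }
  joint
}

## ---- whole-CDS translation oracle for variant effects --------------------
oracleEffect <- function(assembly, scaffold, bp, alt) {
  g <- assembly@genes
  hit <- g[g$scaffold == scaffold & bp >= g$start & bp <= g$end, ]
  if (!nrow(hit)) return("intergenic")
  gene <- hit$gene[1]
  seq <- strsplit(as.character(assembly@scaffoldSeqs[[scaffold]]), "")[[1]]
  before <- seq[hit$start:hit$end]
  after <- before
  after[bp - hit$start + 1] <- alt
  toProt <- function(v) {
    d <- Biostrings::DNAString(paste(v, collapse = ""))
    if (hit$strand == "-") d <- Biostrings::reverseComplement(d)
    as.character(Biostrings::translate(d))
  }
  if (toProt(before) == toProt(after)) "synonymous" else "nonsynonymous"
}

## ---- brute-force adjacency derivation for small instances ----------------
## Enumerates every reference-adjacent block pair, counts support per
## unordered end pair, applies the same threshold and strict-max conflict
## rule, and returns the surviving canonical keys.
oracleAdjacencyKeys <- function(blockSets, minSupport) {
  perRef <- list()
  for (r in names(blockSets)) {
    b <- blockTable(blockSets[[r]])
    keys <- character(0)
    for (chr in unique(b$refChrom)) {
      x <- b[b$refChrom == chr, ]
      x <- x[order(x$refStart, x$refEnd), ]
      if (nrow(x) < 2) next
      for (i in 1:(nrow(x) - 1)) {
        if (x$targetScaffold[i] == x$targetScaffold[i + 1]) next
        eA <- if (x$orientation[i] == "same") "tail" else "head"
        eB <- if (x$orientation[i + 1] == "same") "head" else "tail"
        e1 <- paste0(x$targetScaffold[i], ":", eA)
        e2 <- paste0(x$targetScaffold[i + 1], ":", eB)
        keys <- c(keys, paste(sort(c(e1, e2)), collapse = "|"))
      }
    }
    perRef[[r]] <- unique(keys)
  }
  support <- table(unlist(perRef))
  cand <- names(support)[support >= minSupport]
  ## conflict rule per endpoint
  eps <- unlist(strsplit(cand, "|", fixed = TRUE))
  surviving <- cand
  for (ep in unique(eps)) {
    touching <- cand[vapply(strsplit(cand, "|", fixed = TRUE),
                            function(p) ep %in% p, TRUE)]
    if (length(touching) <= 1) next
    s <- support[touching]
    if (sum(s == max(s)) == 1) drop <- touching[s != max(s)]
    else drop <- touching
    surviving <- setdiff(surviving, drop)
  }
  sort(surviving)
}

## canonical keys of the links that survived inside a SuperScaffolds object
usedAdjacencyKeys <- function(ss) {
  f <- adjacencyFates(ss)
  f <- f[f$fate == "used", , drop = FALSE]
  if (!nrow(f)) return(character(0))
  sort(unname(mapply(function(a, ea, b, eb) {
    paste(sort(c(paste0(a, ":", ea), paste0(b, ":", eb))), collapse = "|")
  }, f$scaffoldA, f$endA, f$scaffoldB, f$endB)))
}

## ---- small constructors ---------------------------------------------------
makeGenotypeSites <- function(geno, scaffold = "sc1", bp = NULL,
                              depth = NULL) {
  n <- nrow(geno)
  if (is.null(bp)) bp <- seq_len(n) * 100
  new("GenotypeSites",
      info = data.frame(site = paste0("s", seq_len(n)),
                        scaffold = rep_len(scaffold, n), bp = bp,
                        stringsAsFactors = FALSE),
      geno = geno, depth = depth)
}

makeSyntenyBlocks <- function(anchors, genomePair = c("target", "ref")) {
  blocks <- do.call(rbind, lapply(split(anchors, anchors$block), function(a) {
    data.frame(block = a$block[1], refChrom = a$refChrom[1],
               targetScaffold = a$targetScaffold[1], nAnchors = nrow(a),
               orientation = SynBridge:::.blockOrientation(a$targetBp, a$refBp),
               medianKs = median(a$ks), refStart = min(a$refBp),
               refEnd = max(a$refBp), targetStart = min(a$targetBp),
               targetEnd = max(a$targetBp), stringsAsFactors = FALSE)
  }))
  rownames(blocks) <- NULL
  new("SyntenyBlocks", blocks = blocks, anchors = anchors,
      genomePair = genomePair)
}

## two-block translation fixture: block 1 same-orientation
## (source 100-200 kb -> target 500-600 kb), block 2 inverted
## (source 300-400 kb -> target 600-500 kb)
qtlBlocks <- function() {
  a <- rbind(
    makeAnchors(1, "scX", c(500e3, 600e3), "chr1", c(100e3, 200e3)),
    makeAnchors(2, "scY", c(600e3, 500e3), "chr1", c(300e3, 400e3)))
  makeSyntenyBlocks(a, genomePair = c("target", "source"))
}

makeAnchors <- function(block, scaffold, targetBp, refChrom, refBp,
                        ks = 0.15) {
  data.frame(block = block,
             targetGene = paste0("tg", block, "_", seq_along(targetBp)),
             targetScaffold = scaffold, targetBp = targetBp,
             refGene = paste0("rg", block, "_", seq_along(refBp)),
             refChrom = refChrom, refBp = refBp, ks = ks,
             stringsAsFactors = FALSE)
}
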