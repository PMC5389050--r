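#' Simulate a fragmented target genome plus rearranged reference genomes
#'
#' Builds the ground truth for the synteny-bridge scaffolding stage: a
#' target genome of ordered genes on `nChromosomes` chromosomes, fragmented
#' into `nScaffolds` draft scaffolds of random orientation (recording the
#' true scaffold adjacencies), and `nReferences` related reference genomes
#' derived from the target gene order by whole-interval inversions and
#' translocations.  Orthologous collinearity anchor tables between the
#' target scaffolds and each reference are derived from the shared gene
#' order, with per-anchor Ks drawn around a recent (orthologous) mode;
#' optional decoy blocks emulate ancient duplicated segments at a high-Ks
#' mode and should be removed by [selectRecentPeakBlocks()].
#'
#' Rearrangements operate on whole gene-index intervals (synteny anchors
#' are gene-based, so no breakpoint falls inside a gene) and scaffold
#' breakpoints fall between genes, with at least `minGenesPerScaffold`
#' genes per scaffold so that orientation is always inferable.
#'
#' @param nChromosomes chromosomes in the target genome
#' @param genesPerChromosome genes per chromosome
#' @param nScaffolds total scaffolds (>= `nChromosomes`; the gene count
#'   must support `minGenesPerScaffold` genes per scaffold)
#' @param nRearrangements inversions/translocations applied per reference
#' @param nReferences number of reference genomes
#' @param nDecoyBlocks ancient-duplication decoy blocks per reference
#' @param minGenesPerScaffold minimum genes per scaffold
#' @param geneLength gene (CDS) length in bp; multiple of 3
#' @param intergenicBp intergenic spacing in bp
#' @param gapBp true gap between adjacent scaffolds (bp)
#' @param ksRecent mean and sd of the recent orthologous Ks mode
#' @param ksOld mean and sd of the ancient decoy Ks mode
#' @param seed integer seed
#' @return a [TruthAssembly-class]
#' @examples
#' ta <- simulateGenomes(nChromosomes = 2, genesPerChromosome = 50,
#'                       nScaffolds = 10, nRearrangements = 1, seed = 1)
#' ta
#' @export
simulateGenomes <- function(nChromosomes = 2, genesPerChromosome = 100,
                            nScaffolds = 20, nRearrangements = 2,
                            nReferences = 2, nDecoyBlocks = 0,
                            minGenesPerScaffold = 2, geneLength = 300,
                            intergenicBp = 700, gapBp = 100,
                            ksRecent = c(0.15, 0.03), ksOld = c(0.65, 0.05),
                            seed = 1) {
  if (nScaffolds < nChromosomes) stop("need at least one scaffold per chromosome")
  totalGenes <- nChromosomes * genesPerChromosome
  if (nScaffolds * minGenesPerScaffold > totalGenes)
    stop("more scaffolds than the gene count supports")
  if (geneLength %% 3 != 0) stop("geneLength must be a multiple of 3")
  set.seed(seed)
  spacing <- geneLength + intergenicBp
  offset <- intergenicBp %/% 2

  chroms <- sprintf("chr%02d", seq_len(nChromosomes))
  geneIds <- sprintf("g%05d", seq_len(totalGenes))
  targetChromosomes <- split(geneIds,
                             rep(chroms, each = genesPerChromosome))

  ## ---- allocate scaffolds to chromosomes, then sizes within ----
  alloc <- rep(1L, nChromosomes)
  capacity <- rep(genesPerChromosome %/% minGenesPerScaffold, nChromosomes)
  for (i in seq_len(nScaffolds - nChromosomes)) {
    open <- which(alloc < capacity)
    pick <- if (length(open) == 1) open else
      sample(open, 1, prob = genesPerChromosome - alloc[open] * minGenesPerScaffold + 1)
    alloc[pick] <- alloc[pick] + 1L
  }
  scafIds <- sprintf("sc%04d", sample.int(nScaffolds))  # ids carry no order info
  scafRows <- list(); geneRows <- list(); adjRows <- list()
  k <- 0L
  for (ci in seq_len(nChromosomes)) {
    genes_c <- targetChromosomes[[ci]]
    nsc <- alloc[ci]
    extra <- genesPerChromosome - nsc * minGenesPerScaffold
    add <- if (extra > 0) tabulate(sample.int(nsc, extra, replace = TRUE), nsc)
           else integer(nsc)
    sizes <- minGenesPerScaffold + add
    bnd <- cumsum(sizes)
    prev <- 0L
    for (si in seq_len(nsc)) {
      k <- k + 1L
      sid <- scafIds[k]
      sub <- genes_c[(prev + 1L):bnd[si]]
      prev <- bnd[si]
      ori <- sample(c("+", "-"), 1)
      scafGenes <- if (ori == "-") rev(sub) else sub
      strand <- sample(c("+", "-"), length(sub), replace = TRUE)
      n <- length(scafGenes)
      starts <- (seq_len(n) - 1L) * spacing + offset + 1L
      geneRows[[length(geneRows) + 1L]] <- data.frame(
        gene = scafGenes, chrom = chroms[ci],
        chromIndex = match(scafGenes, genes_c),
        scaffold = sid, scaffoldIndex = seq_len(n),
        start = starts, end = starts + geneLength - 1L,
        strand = strand, stringsAsFactors = FALSE)
      scafRows[[k]] <- data.frame(
        scaffold = sid, chrom = chroms[ci], length = n * spacing,
        orientation = ori, chromOrder = si, stringsAsFactors = FALSE)
      if (si > 1) {
        prevRow <- scafRows[[k - 1L]]
        adjRows[[length(adjRows) + 1L]] <- data.frame(
          scaffoldA = prevRow$scaffold,
          endA = if (prevRow$orientation == "+") "tail" else "head",
          scaffoldB = sid,
          endB = if (ori == "+") "head" else "tail",
          gap = gapBp, stringsAsFactors = FALSE)
      }
    }
  }
  genes <- do.call(rbind, geneRows)
  scaffolds <- do.call(rbind, scafRows)
  trueAdj <- if (length(adjRows)) do.call(rbind, adjRows) else
    data.frame(scaffoldA = character(), endA = character(),
               scaffoldB = character(), endB = character(), gap = numeric())

  ## ---- reference genomes by whole-interval rearrangements ----
  refIds <- paste0("ref", LETTERS[seq_len(nReferences)])
  refGeneRows <- list(); rearr <- list(); collinearity <- list()
  for (r in refIds) {
    orders <- targetChromosomes
    for (e in seq_len(nRearrangements)) {
      type <- sample(c("inversion", "translocation"), 1)
      src <- sample(seq_along(orders), 1)
      G <- length(orders[[src]])
      ij <- sort(sample.int(G, 2))
      if (type == "inversion") {
        orders[[src]][ij[1]:ij[2]] <- rev(orders[[src]][ij[1]:ij[2]])
        rearr[[length(rearr) + 1L]] <- data.frame(
          ref = r, type = type, chrom = chroms[src], from = ij[1], to = ij[2],
          destChrom = NA_character_, destPos = NA_integer_)
      } else {
        seg <- orders[[src]][ij[1]:ij[2]]
        if (length(seg) == G) next  # never empty a chromosome
        orders[[src]] <- orders[[src]][-(ij[1]:ij[2])]
        dst <- sample(seq_along(orders), 1)
        at <- sample.int(length(orders[[dst]]) + 1L, 1) - 1L
        orders[[dst]] <- append(orders[[dst]], seg, after = at)
        rearr[[length(rearr) + 1L]] <- data.frame(
          ref = r, type = type, chrom = chroms[src], from = ij[1], to = ij[2],
          destChrom = chroms[dst], destPos = at)
      }
    }
    for (ci in seq_along(orders)) {
      n <- length(orders[[ci]])
      starts <- (seq_len(n) - 1L) * spacing + offset + 1L
      refGeneRows[[length(refGeneRows) + 1L]] <- data.frame(
        ref = r, gene = orders[[ci]], chrom = chroms[ci],
        chromIndex = seq_len(n), start = starts,
        end = starts + geneLength - 1L, stringsAsFactors = FALSE)
    }
    collinearity[[r]] <- .deriveAnchors(orders, genes, chroms,
                                        nDecoyBlocks, ksRecent, ksOld)
  }
  referenceGenes <- do.call(rbind, refGeneRows)
  rearrangements <- if (length(rearr)) do.call(rbind, rearr) else
    data.frame(ref = character(), type = character(), chrom = character(),
               from = integer(), to = integer(), destChrom = character(),
               destPos = integer())

  ## ---- sequences ----
  .ngTables()
  sense <- .ng$sense
  cdsSeqs <- vapply(seq_len(totalGenes), function(i) {
    paste(c("ATG", sample(sense, geneLength / 3 - 2, replace = TRUE), "TAA"),
          collapse = "")
  }, "")
  names(cdsSeqs) <- geneIds
  scafSeqs <- character(nrow(scaffolds))
  names(scafSeqs) <- scaffolds$scaffold
  for (i in seq_len(nrow(scaffolds))) {
    sid <- scaffolds$scaffold[i]
    bases <- sample(c("A", "C", "G", "T"), scaffolds$length[i], replace = TRUE)
    gi <- genes[genes$scaffold == sid, , drop = FALSE]
    for (j in seq_len(nrow(gi))) {
      s <- cdsSeqs[[gi$gene[j]]]
      if (gi$strand[j] == "-")
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      bases[gi$start[j]:gi$end[j]] <- strsplit(s, "")[[1]]
    }
    scafSeqs[i] <- paste(bases, collapse = "")
  }

  new("TruthAssembly",
      targetChromosomes = targetChromosomes,
      genes = genes, scaffolds = scaffolds, trueAdjacencies = trueAdj,
      referenceGenes = referenceGenes, rearrangements = rearrangements,
      collinearity = collinearity,
      scaffoldSeqs = Biostrings::DNAStringSet(scafSeqs),
      cds = Biostrings::DNAStringSet(cdsSeqs),
      params = list(seed = seed, spacing = spacing, geneLength = geneLength,
                    intergenicBp = intergenicBp, gapBp = gapBp,
                    nRearrangements = nRearrangements))
}

## derive collinear anchor runs between a reference gene order and the
## target scaffolds; a run breaks on scaffold change, a jump in the
## scaffold gene index, or a direction flip
.deriveAnchors <- function(orders, genes, chroms, nDecoyBlocks,
                           ksRecent, ksOld) {
  idx <- match(unlist(orders, use.names = FALSE), genes$gene)
  rows <- list()
  blockId <- 0L
  for (ci in seq_along(orders)) {
    ord <- orders[[ci]]
    m <- genes[match(ord, genes$gene), , drop = FALSE]
    runStart <- 1L
    flush <- function(from, to) {
      if (to - from + 1L < 2L) return()
      blockId <<- blockId + 1L
      ks0 <- max(0.02, rnorm(1, ksRecent[1], ksRecent[2]))
      n <- to - from + 1L
      rows[[length(rows) + 1L]] <<- data.frame(
        block = blockId, targetGene = m$gene[from:to],
        refGene = m$gene[from:to], refChrom = chroms[ci],
        ks = pmax(0.005, rnorm(n, ks0, 0.01)), decoy = FALSE,
        stringsAsFactors = FALSE)
    }
    if (nrow(m) >= 2) {
      dirPrev <- NA_integer_
      for (i in 2:nrow(m)) {
        step <- m$scaffoldIndex[i] - m$scaffoldIndex[i - 1L]
        contiguous <- m$scaffold[i] == m$scaffold[i - 1L] && abs(step) == 1L
        if (!contiguous || (!is.na(dirPrev) && step != dirPrev)) {
          flush(runStart, i - 1L)
          runStart <- i
          dirPrev <- NA_integer_
        } else dirPrev <- step
      }
      flush(runStart, nrow(m))
    }
  }
  ## decoy blocks: ancient duplicated segments at the old Ks mode
  if (nDecoyBlocks > 0) {
    scafN <- table(genes$scaffold)
    for (d in seq_len(nDecoyBlocks)) {
      L <- sample(4:8, 1)
      cand <- names(scafN)[scafN >= L]
      if (!length(cand)) break
      sid <- sample(cand, 1)
      gi <- genes[genes$scaffold == sid, , drop = FALSE]
      gi <- gi[order(gi$scaffoldIndex), , drop = FALSE]
      s0 <- sample.int(nrow(gi) - L + 1L, 1)
      tGenes <- gi$gene[s0:(s0 + L - 1L)]
      ci <- sample(seq_along(orders), 1)
      ord <- orders[[ci]]
      if (length(ord) < L) next
      r0 <- sample.int(length(ord) - L + 1L, 1)
      rGenes <- ord[r0:(r0 + L - 1L)]
      if (sample(c(TRUE, FALSE), 1)) rGenes <- rev(rGenes)
      blockId <- blockId + 1L
      ks0 <- max(0.3, rnorm(1, ksOld[1], ksOld[2]))
      rows[[length(rows) + 1L]] <- data.frame(
        block = blockId, targetGene = tGenes, refGene = rGenes,
        refChrom = chroms[ci], ks = pmax(0.25, rnorm(L, ks0, 0.01)),
        decoy = TRUE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' True scaffold adjacencies of a TruthAssembly
#' @param assembly a [TruthAssembly-class]
#' @return data.frame: `scaffoldA`, `endA`, `scaffoldB`, `endB`, `gap`
#' @export
trueAdjacencies <- function(assembly) assembly@trueAdjacencies

#' Scaffold lengths of a TruthAssembly
#' @param assembly a [TruthAssembly-class]
#' @return named numeric vector (bp)
#' @export
scaffoldLengths <- function(assembly)
  setNames(as.numeric(assembly@scaffolds$length), assembly@scaffolds$scaffold)

#' Place truth-tagged genetic markers on the scaffolds of a TruthAssembly
#'
#' Samples marker sites on every scaffold and assigns each its true linkage
#' group (the chromosome) and cM position (proportional to the physical
#' position on the target chromosome at `cmPerMb`).  With `clusterSize > 1`
#' each sampled site becomes a cluster of co-segregating sites within
#' `clusterSpanBp`, sharing one cM position, to emulate the redundant SNP
#' sites that a co-segregation merge should collapse.
#'
#' @param assembly a [TruthAssembly-class]
#' @param markersPerScaffold sites sampled per scaffold
#' @param cmPerMb map expansion (cM per Mb of target sequence)
#' @param clusterSize co-segregating sites per sampled position
#' @param clusterSpanBp physical span of a cluster (bp)
#' @param seed integer seed
#' @return data.frame: `marker`, `lg`, `cm`, `scaffold`, `bp`, `cluster`
#'   (sorted by linkage group and cM)
#' @export
markerTruthFromAssembly <- function(assembly, markersPerScaffold = 3,
                                    cmPerMb = 400, clusterSize = 1,
                                    clusterSpanBp = 800, seed = 1) {
  stopifnot(markersPerScaffold >= 1, clusterSize >= 1)
  set.seed(seed)
  sc <- assembly@scaffolds
  gap <- assembly@params$gapBp
  rows <- list()
  for (ci in unique(sc$chrom)) {
    s <- sc[sc$chrom == ci, , drop = FALSE]
    s <- s[order(s$chromOrder), , drop = FALSE]
    offs <- cumsum(c(0, head(s$length + gap, -1)))
    for (i in seq_len(nrow(s))) {
      bp <- sort(sample.int(s$length[i], markersPerScaffold))
      targetPos <- if (s$orientation[i] == "+") offs[i] + bp
                   else offs[i] + s$length[i] - bp + 1
      for (j in seq_along(bp)) {
        jit <- unique(pmin(s$length[i], bp[j] +
                             c(0, sample.int(clusterSpanBp, clusterSize - 1L))))
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold = s$scaffold[i], bp = jit,
          lg = match(ci, unique(sc$chrom)),
          cm = targetPos[j] / 1e6 * cmPerMb,
          cluster = paste0(s$scaffold[i], "_", j),
          stringsAsFactors = FALSE)
      }
    }
  }
  mt <- do.call(rbind, rows)
  mt <- mt[order(mt$lg, mt$cm, mt$scaffold, mt$bp), , drop = FALSE]
  mt$marker <- sprintf("m%05d", seq_len(nrow(mt)))
  rownames(mt) <- NULL
  mt[, c("marker", "lg", "cm", "scaffold", "bp", "cluster")]
}
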