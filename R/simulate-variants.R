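#' Simulate wild-relative variant calls with truth-tagged filter fates
#'
#' Emits SNP and INDEL sites on the scaffolds of a [TruthAssembly-class]
#' together with per-site alignment statistics (depth, RMS mapping
#' quality, zero-MQ read count), planting a specified fraction of sites
#' that violate each post-genotyping filter rule.  Every site carries its
#' ground-truth filter fate (computed from the planted statistics) and its
#' true coding effect (synonymous / nonsynonymous / cds_indel /
#' intergenic, from direct codon-table lookup on the simulated CDS).
#'
#' @param assembly a [TruthAssembly-class]
#' @param nSnps,nIndels site counts to simulate
#' @param codingFraction fraction of sites placed inside coding sequence
#' @param statsModel list: `meanDepth` (the "sequence coverage"), and the
#'   fractions of sites violating each rule: `fracLowMq`, `fracDup`,
#'   `fracZeroMqCount`, `fracZeroMqFrac`
#' @param seed integer seed
#' @return list: `sites` (data.frame with columns `scaffold`, `bp`, `ref`,
#'   `alt`, `type`, `depth`, `mq`, `mq0`, `totalReads`, `gene`,
#'   `truthEffect`, `truthPass`, `truthReasons`), `coverage` (list with
#'   `meanDepth` and `mappedBp`)
#' @export
simulateVariants <- function(assembly, nSnps = 300, nIndels = 30,
                             codingFraction = 0.3,
                             statsModel = list(meanDepth = 30,
                                               fracLowMq = 0.05,
                                               fracDup = 0.05,
                                               fracZeroMqCount = 0.05,
                                               fracZeroMqFrac = 0.05),
                             seed = 1) {
  stopifnot(is(assembly, "TruthAssembly"))
  .checkFraction(codingFraction, "codingFraction", allowOne = TRUE)
  set.seed(seed)
  genes <- assembly@genes
  lens <- scaffoldLengths(assembly)
  geneLen <- assembly@params$geneLength
  nCoding <- round(nSnps * codingFraction)
  nInter <- nSnps - nCoding
  nCodingIndel <- round(nIndels * codingFraction)
  availCoding <- nrow(genes) * (geneLen - 6)   # inside-gene positions, ends spared
  if (nCoding + nCodingIndel > availCoding)
    stop("requested variants exceed available coding positions")
  if (nSnps + nIndels > sum(lens) / 2)
    stop("requested variants exceed available positions")
  gc <- Biostrings::GENETIC_CODE
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases <- names(comp)
  scafChars <- lapply(as.character(assembly@scaffoldSeqs), function(s)
    strsplit(s, "")[[1]])

  rows <- list()
  addSite <- function(scaf, bp, ref, alt, type, gene, effect) {
    rows[[length(rows) + 1L]] <<- data.frame(
      scaffold = scaf, bp = bp, ref = ref, alt = alt, type = type,
      gene = gene, truthEffect = effect, stringsAsFactors = FALSE)
  }

  ## ---- coding SNPs ----
  for (i in seq_len(nCoding)) {
    gi <- genes[sample.int(nrow(genes), 1), ]
    cdsPos <- sample(4:(geneLen - 3), 1)        # spare start and stop codons
    bp <- if (gi$strand == "+") gi$start + cdsPos - 1 else gi$end - cdsPos + 1
    ref <- scafChars[[gi$scaffold]][bp]
    alt <- sample(setdiff(bases, ref), 1)
    cds <- as.character(assembly@cds[[gi$gene]])
    altCoding <- if (gi$strand == "+") alt else comp[[alt]]
    ci <- (cdsPos - 1) %/% 3
    refCodon <- substr(cds, 3 * ci + 1, 3 * ci + 3)
    altCodon <- refCodon
    substr(altCodon, (cdsPos - 1) %% 3 + 1, (cdsPos - 1) %% 3 + 1) <- altCoding
    effect <- if (gc[[refCodon]] == gc[[altCodon]]) "synonymous" else "nonsynonymous"
    addSite(gi$scaffold, bp, ref, alt, "SNP", gi$gene, effect)
  }
  ## ---- intergenic SNPs ----
  .interPos <- function() {
    repeat {
      scaf <- sample(names(lens), 1, prob = lens)
      bp <- sample.int(lens[[scaf]], 1)
      g <- genes[genes$scaffold == scaf, , drop = FALSE]
      if (!any(bp >= g$start & bp <= g$end)) return(list(scaf = scaf, bp = bp))
    }
  }
  for (i in seq_len(nInter)) {
    p <- .interPos()
    ref <- scafChars[[p$scaf]][p$bp]
    addSite(p$scaf, p$bp, ref, sample(setdiff(bases, ref), 1), "SNP",
            NA_character_, "intergenic")
  }
  ## ---- INDELs ----
  for (i in seq_len(nIndels)) {
    coding <- i <= nCodingIndel
    if (coding) {
      gi <- genes[sample.int(nrow(genes), 1), ]
      bp <- sample((gi$start + 3):(gi$end - 4), 1)
      scaf <- gi$scaffold; gene <- gi$gene; effect <- "cds_indel"
    } else {
      p <- .interPos(); scaf <- p$scaf
      bp <- min(p$bp, lens[[scaf]] - 1)   # leave room for the anchor base
      gene <- NA_character_; effect <- "intergenic"
    }
    b1 <- scafChars[[scaf]][bp]; b2 <- scafChars[[scaf]][bp + 1]
    if (runif(1) < 0.5) addSite(scaf, bp, paste0(b1, b2), b1, "INDEL", gene, effect)
    else addSite(scaf, bp, b1, paste0(b1, sample(bases, 1)), "INDEL", gene, effect)
  }
  sites <- do.call(rbind, rows)
  sites <- sites[!duplicated(paste(sites$scaffold, sites$bp)), , drop = FALSE]
  n <- nrow(sites)

  ## ---- per-site alignment statistics with planted rule violations ----
  md <- statsModel$meanDepth
  frac <- vapply(c("fracLowMq", "fracDup", "fracZeroMqCount", "fracZeroMqFrac"),
                 function(k) if (is.null(statsModel[[k]])) 0 else statsModel[[k]],
                 0)
  if (sum(frac) > 1) stop("violation fractions sum above 1")
  counts <- round(frac * n)
  lab <- rep("clean", n)
  shuffled <- sample.int(n)
  at <- 0
  for (i in seq_along(counts)) {
    if (counts[i] > 0)
      lab[shuffled[(at + 1):(at + counts[i])]] <-
        c("low_mq", "dup", "mq0_count", "mq0_frac")[i]
    at <- at + counts[i]
  }
  depth <- pmin(2 * md, pmax(ceiling(md / 2),
                             round(rnorm(n, md, md / 8))))
  mq <- pmin(60, pmax(45, round(rnorm(n, 58, 3))))
  mq0 <- rbinom(n, 1, 0.2)
  depth[lab == "dup"] <- round(md * runif(sum(lab == "dup"), 2.05, 3))
  mq[lab == "low_mq"] <- round(runif(sum(lab == "low_mq"), 10, 29))
  sel <- lab == "mq0_count"   # >4 zero-MQ reads but fraction <= 10%
  depth[sel] <- round(md * 1.9)
  mq0[sel] <- 5L
  sel <- lab == "mq0_frac"    # fraction > 10% (count also trips when > 4)
  depth[sel] <- ceiling(md * 0.8)
  mq0[sel] <- ceiling(0.12 * depth[sel])
  sites$depth <- depth; sites$mq <- mq; sites$mq0 <- mq0
  sites$totalReads <- depth

  ## ground-truth fate from direct application of the four rules
  reasons <- mapply(function(d, q, z, tot) {
    r <- character(0)
    if (q < 30) r <- c(r, "mapping_quality")
    if (d > 2 * md) r <- c(r, "duplication")
    if (z > 4) r <- c(r, "zero_mq_count")
    if (z / tot > 0.10) r <- c(r, "zero_mq_fraction")
    paste(r, collapse = ";")
  }, depth, mq, mq0, sites$totalReads)
  sites$truthPass <- !nzchar(reasons)
  sites$truthReasons <- reasons
  rownames(sites) <- NULL
  list(sites = sites,
       coverage = list(meanDepth = md, mappedBp = sum(lens)))
}
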