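#' Write a gene position table (MCScanX-style)
#'
#' Four tab-separated columns: chromosome/scaffold, gene id, start, end.
#' Reference gene ids are prefixed with `"<ref>_"` so that target and
#' reference id spaces stay distinct.
#'
#' @param assembly a [TruthAssembly-class]
#' @param path output path
#' @param genome `"target"` (scaffold coordinates) or a reference id
#' @return invisibly, the path
#' @export
writeGenePositions <- function(assembly, path, genome = "target") {
  if (genome == "target") {
    g <- assembly@genes
    tab <- data.frame(chrom = g$scaffold, gene = g$gene,
                      start = g$start, end = g$end)
  } else {
    rg <- assembly@referenceGenes
    rg <- rg[rg$ref == genome, , drop = FALSE]
    if (!nrow(rg)) stop("unknown genome: ", genome)
    tab <- data.frame(chrom = rg$chrom, gene = paste0(genome, "_", rg$gene),
                      start = rg$start, end = rg$end)
  }
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene position table
#' @param path 4- or 5-column tab text: chrom, gene, start, end `[, strand]`
#' @return data.frame with columns `chrom`, `gene`, `start`, `end`
#' @export
readGenePositions <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("gene position table needs >= 4 columns")
  names(tab)[1:4] <- c("chrom", "gene", "start", "end")
  tab[, 1:4]
}

#' Write an MCScanX-style collinearity file from a TruthAssembly
#'
#' One `## Alignment` header per synteny block followed by its anchor
#' lines (`target gene`, `reference gene`, per-pair Ks).
#'
#' @param assembly a [TruthAssembly-class]
#' @param ref reference genome id (e.g. `"refA"`)
#' @param path output path
#' @return invisibly, the path
#' @export
writeCollinearity <- function(assembly, ref, path) {
  anc <- assembly@collinearity[[ref]]
  if (is.null(anc)) stop("unknown reference: ", ref)
  g <- assembly@genes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("############### Parameters ###############",
               "## produced from a simulated truth assembly"), con)
  for (b in unique(anc$block)) {
    a <- anc[anc$block == b, , drop = FALSE]
    scaf <- g$scaffold[match(a$targetGene[1], g$gene)]
    writeLines(sprintf("## Alignment %d: score=%.1f e_value=0 N=%d %s&%s plus",
                       b, 50 * nrow(a), nrow(a), scaf, a$refChrom[1]), con)
    writeLines(sprintf("%3d-%3d:\t%s\t%s_%s\t%.4f",
                       b, seq_len(nrow(a)) - 1L, a$targetGene,
                       ref, a$refGene, a$ks), con)
  }
  invisible(path)
}

#' Parse an MCScanX-style collinearity file
#'
#' Reads synteny blocks and resolves every anchor pair to coordinates on
#' both genomes through gene position tables.  Anchors whose gene id is
#' absent from a position table are skipped with a warning naming the line
#' number; blocks left with fewer than two anchors are dropped with a
#' warning (orientation would be undefined).  Block orientation is `"same"`
#' when reference positions increase with target positions, `"inverted"`
#' when they decrease.
#'
#' @param path collinearity file (MCScanX `.collinearity` layout; the last
#'   anchor column is read as the pair's Ks when numeric)
#' @param targetPositions,refPositions gene position data.frames
#'   (see [readGenePositions()]) for the target and reference genome
#' @param genomePair character(2) labels for the target and reference
#' @return a [SyntenyBlocks-class]
#' @export
parseCollinearity <- function(path, targetPositions, refPositions,
                              genomePair = c("target", "reference")) {
  lines <- readLines(path)
  hdr <- grepl("^## Alignment", lines)
  anchorRows <- list(); blockOf <- integer(0)
  cur <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (hdr[i]) {
      cur <- as.integer(sub("^## Alignment\\s+([0-9]+).*", "\\1", ln))
      next
    }
    if (is.na(cur) || grepl("^#", ln) || !nzchar(trimws(ln))) next
    body <- sub("^\\s*[-0-9]+-\\s*[0-9]+:\\s*", "", ln)
    f <- strsplit(body, "\t|\\s+")[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 2) {
      warning("malformed anchor line ", i, ": ", ln)
      next
    }
    tg <- f[1]; rg <- f[2]
    ks <- if (length(f) >= 3) suppressWarnings(as.numeric(f[3])) else NA_real_
    ti <- match(tg, targetPositions$gene)
    ri <- match(rg, refPositions$gene)
    if (is.na(ti) || is.na(ri)) {
      warning("line ", i, ": anchor gene not in position table (",
              if (is.na(ti)) tg else rg, "); anchor skipped")
      next
    }
    anchorRows[[length(anchorRows) + 1L]] <- data.frame(
      block = cur, targetGene = tg,
      targetScaffold = targetPositions$chrom[ti],
      targetBp = targetPositions$start[ti],
      refGene = rg, refChrom = refPositions$chrom[ri],
      refBp = refPositions$start[ri], ks = ks, stringsAsFactors = FALSE)
  }
  anchors <- if (length(anchorRows)) do.call(rbind, anchorRows) else
    data.frame(block = integer(), targetGene = character(),
               targetScaffold = character(), targetBp = numeric(),
               refGene = character(), refChrom = character(),
               refBp = numeric(), ks = numeric())
  ## drop blocks with < 2 resolvable anchors
  nA <- table(anchors$block)
  small <- as.integer(names(nA)[nA < 2])
  if (length(small)) {
    warning(length(small), " block(s) dropped with fewer than 2 anchors")
    anchors <- anchors[!(anchors$block %in% small), , drop = FALSE]
  }
  blocks <- do.call(rbind, lapply(split(anchors, anchors$block), function(a) {
    ori <- .blockOrientation(a$targetBp, a$refBp)
    data.frame(block = a$block[1], refChrom = a$refChrom[1],
               targetScaffold = a$targetScaffold[1], nAnchors = nrow(a),
               orientation = ori, medianKs = median(a$ks, na.rm = TRUE),
               refStart = min(a$refBp), refEnd = max(a$refBp),
               targetStart = min(a$targetBp), targetEnd = max(a$targetBp),
               stringsAsFactors = FALSE)
  }))
  if (is.null(blocks))
    blocks <- data.frame(block = integer(), refChrom = character(),
                         targetScaffold = character(), nAnchors = integer(),
                         orientation = character(), medianKs = numeric(),
                         refStart = numeric(), refEnd = numeric(),
                         targetStart = numeric(), targetEnd = numeric())
  rownames(blocks) <- rownames(anchors) <- NULL
  new("SyntenyBlocks", blocks = blocks, anchors = anchors,
      genomePair = genomePair)
}

## orientation of a block from anchor coordinates: rank concordance of
## reference vs target positions
.blockOrientation <- function(targetBp, refBp) {
  if (length(targetBp) < 2) return("same")
  tau <- suppressWarnings(cor(targetBp, refBp, method = "kendall"))
  if (is.na(tau) || tau >= 0) "same" else "inverted"
}

## subset a SyntenyBlocks by block ids
.subsetBlocks <- function(x, keep) {
  new("SyntenyBlocks",
      blocks = x@blocks[x@blocks$block %in% keep, , drop = FALSE],
      anchors = x@anchors[x@anchors$block %in% keep, , drop = FALSE],
      genomePair = x@genomePair)
}
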