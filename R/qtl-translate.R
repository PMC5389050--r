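#' Translate a marker position across genomes through synteny blocks
#'
#' Locates the synteny block whose reference (source-genome) span contains
#' the marker, finds the flanking anchor pair, and linearly interpolates
#' the marker's position between those anchors' target coordinates (the
#' axis is reversed inside inverted blocks).  Markers before the first or
#' after the last anchor of their block are clamped to that anchor's
#' target position.  Markers covered by no block are reported
#' `outside_blocks`; markers covered by two or more overlapping blocks are
#' `ambiguous`, with all candidate positions listed.
#'
#' @param chrom,bp source chromosome and position of the marker
#' @param blocks a [SyntenyBlocks-class] whose reference side is the
#'   source genome and whose target side is the destination genome
#' @param marker optional marker id carried through to the output
#' @return data.frame (one row per candidate placement): `marker`,
#'   `status` (`translated`/`outside_blocks`/`ambiguous`), `block`,
#'   `targetScaffold`, `targetBp`
#' @export
translatePosition <- function(chrom, bp, blocks, marker = NA_character_) {
  b <- blockTable(blocks)
  a <- anchorTable(blocks)
  usable <- b$nAnchors >= 2
  if (any(!usable)) {
    warning(sum(!usable), " block(s) with fewer than 2 anchors skipped")
    b <- b[usable, , drop = FALSE]
  }
  hit <- b[b$refChrom == chrom & bp >= b$refStart & bp <= b$refEnd, ,
           drop = FALSE]
  if (!nrow(hit))
    return(data.frame(marker = marker, status = "outside_blocks",
                      block = NA_integer_, targetScaffold = NA_character_,
                      targetBp = NA_real_, stringsAsFactors = FALSE))
  status <- if (nrow(hit) > 1) "ambiguous" else "translated"
  out <- lapply(seq_len(nrow(hit)), function(i) {
    blk <- hit$block[i]
    an <- a[a$block == blk, , drop = FALSE]
    an <- an[order(an$refBp), , drop = FALSE]
    tBp <- .interpolateAnchors(an$refBp, an$targetBp, bp)
    data.frame(marker = marker, status = status, block = blk,
               targetScaffold = an$targetScaffold[1], targetBp = tBp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## piecewise-linear interpolation between flanking anchors, clamped at the
## terminal anchors; target coordinates may decrease (inverted block)
.interpolateAnchors <- function(refBp, targetBp, x) {
  if (x <= refBp[1]) return(targetBp[1])
  n <- length(refBp)
  if (x >= refBp[n]) return(targetBp[n])
  j <- findInterval(x, refBp)
  if (refBp[j + 1] == refBp[j]) return(targetBp[j])
  f <- (x - refBp[j]) / (refBp[j + 1] - refBp[j])
  targetBp[j] + f * (targetBp[j + 1] - targetBp[j])
}

#' Translate a table of markers through synteny blocks
#'
#' @param markers data.frame: `marker`, `chrom`, `bp` (a `trait` column is
#'   carried through when present)
#' @param blocks a [SyntenyBlocks-class] (see [translatePosition()])
#' @return data.frame of candidate placements, one or more rows per marker
#' @export
translateMarkers <- function(markers, blocks) {
  rows <- lapply(seq_len(nrow(markers)), function(i)
    translatePosition(markers$chrom[i], markers$bp[i], blocks,
                      marker = markers$marker[i]))
  out <- do.call(rbind, rows)
  if ("trait" %in% names(markers))
    out$trait <- markers$trait[match(out$marker, markers$marker)]
  rownames(out) <- NULL
  out
}

#' Translate a QTL support interval through synteny blocks
#'
#' Both endpoints are translated independently; within each carrier block
#' the translated endpoints are reordered so start <= end (an inverted
#' block swaps them).  An interval spanning more than one block is split
#' into per-block pieces, each clipped to the block's reference span.  An
#' interval covered by no block is `untranslated`.
#'
#' @param chrom source chromosome
#' @param start,end source interval (start <= end)
#' @param blocks a [SyntenyBlocks-class]
#' @param marker optional id carried through
#' @return data.frame: `marker`, `status` (`translated`/`split`/
#'   `untranslated`), `block`, `targetScaffold`, `targetStart`,
#'   `targetEnd`
#' @export
translateInterval <- function(chrom, start, end, blocks,
                              marker = NA_character_) {
  if (start > end) stop("interval start must be <= end")
  b <- blockTable(blocks)
  b <- b[b$nAnchors >= 2, , drop = FALSE]
  hit <- b[b$refChrom == chrom & end >= b$refStart & start <= b$refEnd, ,
           drop = FALSE]
  if (!nrow(hit))
    return(data.frame(marker = marker, status = "untranslated",
                      block = NA_integer_, targetScaffold = NA_character_,
                      targetStart = NA_real_, targetEnd = NA_real_,
                      stringsAsFactors = FALSE))
  a <- anchorTable(blocks)
  status <- if (nrow(hit) > 1) "split" else "translated"
  out <- lapply(seq_len(nrow(hit)), function(i) {
    blk <- hit$block[i]
    an <- a[a$block == blk, , drop = FALSE]
    an <- an[order(an$refBp), , drop = FALSE]
    s <- max(start, hit$refStart[i])
    e <- min(end, hit$refEnd[i])
    p1 <- .interpolateAnchors(an$refBp, an$targetBp, s)
    p2 <- .interpolateAnchors(an$refBp, an$targetBp, e)
    data.frame(marker = marker, status = status, block = blk,
               targetScaffold = an$targetScaffold[1],
               targetStart = min(p1, p2), targetEnd = max(p1, p2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Swap the two genomes of a SyntenyBlocks object
#'
#' Returns blocks whose reference side is the former target and vice
#' versa, so that translations can be run in the opposite direction (the
#' round-trip through a block returns the original position to within
#' interpolation rounding).
#'
#' @param blocks a [SyntenyBlocks-class]
#' @return a [SyntenyBlocks-class] with the genome roles exchanged
#' @export
flipBlocks <- function(blocks) {
  a <- anchorTable(blocks)
  b <- blockTable(blocks)
  a2 <- data.frame(block = a$block, targetGene = a$refGene,
                   targetScaffold = a$refChrom, targetBp = a$refBp,
                   refGene = a$targetGene, refChrom = a$targetScaffold,
                   refBp = a$targetBp, ks = a$ks, stringsAsFactors = FALSE)
  b2 <- do.call(rbind, lapply(split(a2, a2$block), function(x) {
    data.frame(block = x$block[1], refChrom = x$refChrom[1],
               targetScaffold = x$targetScaffold[1], nAnchors = nrow(x),
               orientation = .blockOrientation(x$targetBp, x$refBp),
               medianKs = median(x$ks, na.rm = TRUE),
               refStart = min(x$refBp), refEnd = max(x$refBp),
               targetStart = min(x$targetBp), targetEnd = max(x$targetBp),
               stringsAsFactors = FALSE)
  }))
  rownames(b2) <- rownames(a2) <- NULL
  new("SyntenyBlocks", blocks = b2, anchors = a2,
      genomePair = rev(blocks@genomePair))
}
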