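#' Keep the synteny blocks under the most recent Ks peak
#'
#' Orthologous blocks from the most recent divergence form the lowest-Ks
#' mode of the block-median Ks distribution; older duplicated segments
#' (e.g. from an ancient whole-genome duplication) form higher modes.  A
#' kernel density estimate (Silverman's bandwidth, grid step
#' `gridStep`) is computed over the block median Ks values and blocks at or
#' below the first local minimum after the lowest mode are retained.  When
#' the density is unimodal no cutoff exists and all blocks are kept with a
#' warning.
#'
#' @param blocks a [SyntenyBlocks-class]
#' @param gridStep evaluation grid step for the density
#' @return list: `blocks` (filtered [SyntenyBlocks-class]), `ksCutoff`
#'   (numeric or `NA` when unimodal), `modes` (mode locations)
#' @export
selectRecentPeakBlocks <- function(blocks, gridStep = 0.005) {
  b <- blockTable(blocks)
  ks <- b$medianKs[is.finite(b$medianKs)]
  if (length(ks) < 10)
    warning("fewer than 10 blocks with finite Ks; density estimate is weak")
  if (length(unique(ks)) < 2) {
    warning("no WGD peak detected (degenerate Ks distribution); keeping all blocks")
    return(list(blocks = blocks, ksCutoff = NA_real_, modes = unique(ks)))
  }
  bw <- stats::bw.nrd0(ks)
  grid <- seq(max(0, min(ks) - 3 * bw), max(ks) + 3 * bw, by = gridStep)
  d <- stats::density(ks, bw = bw, from = min(grid), to = max(grid),
                      n = length(grid))
  y <- d$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  modes <- d$x[is_max]
  if (length(modes) < 2) {
    warning("no WGD peak detected; keeping all blocks")
    return(list(blocks = blocks, ksCutoff = NA_real_, modes = modes))
  }
  first_mode_i <- which(is_max)[1]
  is_min <- c(FALSE, y[2:(n - 1)] < y[1:(n - 2)] & y[2:(n - 1)] <= y[3:n], FALSE)
  min_i <- which(is_min & seq_len(n) > first_mode_i)[1]
  cutoff <- d$x[min_i]
  keep <- b$block[is.finite(b$medianKs) & b$medianKs <= cutoff]
  list(blocks = .subsetBlocks(blocks, keep), ksCutoff = cutoff, modes = modes)
}

#' Derive scaffold-end links from reference-adjacent synteny blocks
#'
#' For every pair of synteny blocks that are adjacent along a reference
#' chromosome but land on two different target scaffolds, the facing ends
#' of those scaffolds are linked: a block in `"same"` orientation points
#' out of the scaffold's tail (its high-coordinate end), an `"inverted"`
#' block out of its head.  Identical links implied by more than one
#' reference genome are merged with accumulated support.
#'
#' @param blockSets named list of [SyntenyBlocks-class], one per reference
#'   genome (names are the reference labels); blocks should already be
#'   peak-filtered (see [selectRecentPeakBlocks()])
#' @return data.frame of scaffold adjacencies: `scaffoldA`, `endA`,
#'   `scaffoldB`, `endB`, `support`, `refs`
#' @export
deriveLinks <- function(blockSets) {
  if (is.null(names(blockSets)) || any(!nzchar(names(blockSets))))
    names(blockSets) <- paste0("ref", seq_along(blockSets))
  rows <- list()
  for (r in names(blockSets)) {
    b <- blockTable(blockSets[[r]])
    if (!nrow(b)) next
    b <- b[order(b$refChrom, b$refStart, b$refEnd), , drop = FALSE]
    for (i in seq_len(nrow(b) - 1)) {
      b1 <- b[i, ]; b2 <- b[i + 1, ]
      if (b1$refChrom != b2$refChrom) next
      if (b1$targetScaffold == b2$targetScaffold) next
      endA <- if (b1$orientation == "same") "tail" else "head"
      endB <- if (b2$orientation == "same") "head" else "tail"
      rows[[length(rows) + 1L]] <- data.frame(
        scaffoldA = b1$targetScaffold, endA = endA,
        scaffoldB = b2$targetScaffold, endB = endB,
        ref = r, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(scaffoldA = character(), endA = character(),
                      scaffoldB = character(), endB = character(),
                      support = integer(), refs = character()))
  raw <- do.call(rbind, rows)
  key <- .adjKey(raw$scaffoldA, raw$endA, raw$scaffoldB, raw$endB)
  agg <- lapply(split(seq_len(nrow(raw)), key), function(idx) {
    x <- raw[idx[1], ]
    refs <- unique(raw$ref[idx])
    data.frame(scaffoldA = x$scaffoldA, endA = x$endA,
               scaffoldB = x$scaffoldB, endB = x$endB,
               support = length(refs), refs = paste(refs, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Build super-scaffolds from consensus scaffold-end links
#'
#' Links below `minSupport` are discarded.  At any scaffold end touched by
#' more than one surviving link, the strictly highest-support link is kept;
#' if the maximum is tied, all links at that end are dropped (the default
#' precision-first conflict policy).  The remaining graph, in which every
#' scaffold end has degree at most one, is decomposed into simple paths;
#' cycles are broken at their lowest-support link.  Each path becomes a
#' super-scaffold with member orientations propagated from its first
#' member.
#'
#' @param adjacencies data.frame from [deriveLinks()]
#' @param scaffoldLengths named numeric vector of all scaffold lengths (the
#'   scaffold universe; unlinked scaffolds are reported as singletons)
#' @param minSupport minimum number of supporting reference genomes
#'   (default 2: both external references must agree)
#' @param gapBp gap placed between joined members
#' @return a [SuperScaffolds-class]
#' @export
buildSuperScaffolds <- function(adjacencies, scaffoldLengths,
                                minSupport = 2, gapBp = 100) {
  stopifnot(minSupport >= 1)
  adj <- adjacencies
  adj$fate <- ifelse(adj$support >= minSupport, "candidate", "below_support")
  live <- which(adj$fate == "candidate")

  epA <- paste0(adj$scaffoldA, ":", adj$endA)
  epB <- paste0(adj$scaffoldB, ":", adj$endB)
  ## conflict resolution per endpoint
  keep <- rep(TRUE, nrow(adj))
  eps <- unique(c(epA[live], epB[live]))
  for (ep in eps) {
    at <- live[epA[live] == ep | epB[live] == ep]
    if (length(at) <= 1) next
    s <- adj$support[at]
    mx <- max(s)
    if (sum(s == mx) == 1) {
      drop <- at[s != mx]
    } else {
      drop <- at
    }
    keep[drop] <- FALSE
    adj$fate[drop] <- "conflict_dropped"
  }
  live <- live[keep[live]]

  ## break cycles: with endpoint degree <= 1, a component is a cycle iff
  ## every member scaffold has both ends used
  edge_list <- adj[live, , drop = FALSE]
  repeat {
    cyc <- .findCycle(edge_list)
    if (is.null(cyc)) break
    w <- cyc[which.min(edge_list$support[cyc])][1]
    row_id <- rownames(edge_list)[w]
    adj[row_id, "fate"] <- "cycle_broken"
    edge_list <- edge_list[-w, , drop = FALSE]
  }
  adj$fate[adj$fate == "candidate"] <- "used"
  used <- edge_list

  ## walk paths
  endEdge <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(used))) {
    assign(paste0(used$scaffoldA[i], ":", used$endA[i]), i, envir = endEdge)
    assign(paste0(used$scaffoldB[i], ":", used$endB[i]), i, envir = endEdge)
  }
  inChain <- character(0)
  chains <- list()
  members <- unique(c(used$scaffoldA, used$scaffoldB))
  for (s0 in members) {
    if (s0 %in% inChain) next
    freeEnds <- c("head", "tail")[vapply(c("head", "tail"), function(e)
      is.null(endEdge[[paste0(s0, ":", e)]]), TRUE)]
    if (!length(freeEnds)) next  # interior member; reached from an end
    startEnd <- freeEnds[1]                 # walk away from the free end
    leaveVia <- .otherEnd(startEnd)
    cur <- s0
    ori <- if (leaveVia == "tail") "+" else "-"
    chain <- data.frame(scaffold = cur, orientation = ori,
                        stringsAsFactors = FALSE)
    repeat {
      ei <- endEdge[[paste0(cur, ":", leaveVia)]]
      if (is.null(ei)) break
      e <- used[ei, ]
      if (e$scaffoldA == cur && e$endA == leaveVia) {
        nxt <- e$scaffoldB; entered <- e$endB
      } else {
        nxt <- e$scaffoldA; entered <- e$endA
      }
      ori <- if (entered == "head") "+" else "-"
      chain <- rbind(chain, data.frame(scaffold = nxt, orientation = ori,
                                       stringsAsFactors = FALSE))
      cur <- nxt
      leaveVia <- .otherEnd(entered)
    }
    inChain <- c(inChain, chain$scaffold)
    chains[[length(chains) + 1L]] <- chain
  }
  chainDf <- if (length(chains)) do.call(rbind, lapply(seq_along(chains),
    function(i) data.frame(superScaffold = sprintf("ss%04d", i),
                           position = seq_len(nrow(chains[[i]])),
                           chains[[i]], stringsAsFactors = FALSE)))
    else data.frame(superScaffold = character(), position = integer(),
                    scaffold = character(), orientation = character())
  singles <- setdiff(names(scaffoldLengths), chainDf$scaffold)
  new("SuperScaffolds", chains = chainDf, singletons = singles,
      fates = adj, scaffoldLengths = scaffoldLengths, gapBp = gapBp)
}

## detect one cycle in an edge list where every endpoint has degree <= 1;
## returns the row indices of a cycle, or NULL
.findCycle <- function(edges) {
  if (!nrow(edges)) return(NULL)
  scafs <- unique(c(edges$scaffoldA, edges$scaffoldB))
  ## union-find over scaffolds; an edge joining two already-connected
  ## scaffolds closes a cycle
  idx <- setNames(seq_along(scafs), scafs)
  parent <- seq_along(scafs)
  findi <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in seq_len(nrow(edges))) {
    a <- findi(idx[[edges$scaffoldA[e]]])
    b <- findi(idx[[edges$scaffoldB[e]]])
    if (a == b) {
      ## recover the cycle's edges: all edges in this component
      rootsA <- vapply(seq_len(nrow(edges)), function(j)
        findi(idx[[edges$scaffoldA[j]]]) == a, TRUE)
      return(which(rootsA))
    }
    parent[a] <- b
  }
  NULL
}

#' AGP v2.1 rows for super-scaffold chains
#'
#' Components alternate with explicit gap rows (`N`, gap type `scaffold`,
#' linkage `yes`, evidence `align_genus`).  Coordinates are 1-based
#' inclusive.
#'
#' @param superScaffolds a [SuperScaffolds-class]
#' @return data.frame of AGP rows
#' @export
superScaffoldAgp <- function(superScaffolds) {
  ch <- chainTable(superScaffolds)
  lens <- superScaffolds@scaffoldLengths
  if (nrow(ch) && any(!(ch$scaffold %in% names(lens))))
    stop("chain member without a known scaffold length")
  .agpFromChains(split(ch, ch$superScaffold), lens, superScaffolds@gapBp)
}

.agpFromChains <- function(chainList, lens, gapBp) {
  rows <- list()
  for (obj in names(chainList)) {
    ch <- chainList[[obj]]
    ch <- ch[order(ch$position), , drop = FALSE]
    pos <- 0; part <- 0L
    for (i in seq_len(nrow(ch))) {
      if (i > 1) {
        part <- part + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          object = obj, object_beg = pos + 1, object_end = pos + gapBp,
          part_number = part, component_type = "N",
          component_id = as.character(gapBp), component_beg = "scaffold",
          component_end = "yes", orientation = "align_genus",
          stringsAsFactors = FALSE)
        pos <- pos + gapBp
      }
      L <- lens[[ch$scaffold[i]]]
      part <- part + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        object = obj, object_beg = pos + 1, object_end = pos + L,
        part_number = part, component_type = "W",
        component_id = ch$scaffold[i], component_beg = "1",
        component_end = as.character(L), orientation = ch$orientation[i],
        stringsAsFactors = FALSE)
      pos <- pos + L
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(object = character(), object_beg = numeric(),
               object_end = numeric(), part_number = integer(),
               component_type = character(), component_id = character(),
               component_beg = character(), component_end = character(),
               orientation = character())
  rownames(out) <- NULL
  out
}

#' Write AGP rows to a file
#' @param agp data.frame of AGP rows (see [superScaffoldAgp()])
#' @param path output path
#' @return invisibly, the path
#' @export
writeAgp <- function(agp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  write.table(agp, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an AGP file back into component rows
#' @param path AGP file
#' @return data.frame with the 9 AGP columns (gap rows included,
#'   `component_type == "N"`)
#' @export
readAgp <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  names(tab) <- c("object", "object_beg", "object_end", "part_number",
                  "component_type", "component_id", "component_beg",
                  "component_end", "orientation")
  tab
}

#' Compare recovered scaffold adjacencies against the simulated truth
#'
#' @param superScaffolds a [SuperScaffolds-class]
#' @param truth data.frame of true adjacencies (see [trueAdjacencies()])
#' @return list: `recovered`, `nTrue`, `falseJoins`, `recoveryRate`
#' @export
adjacencyRecovery <- function(superScaffolds, truth) {
  ch <- chainTable(superScaffolds)
  usedKeys <- character(0)
  for (ssid in unique(ch$superScaffold)) {
    m <- ch[ch$superScaffold == ssid, ]
    m <- m[order(m$position), ]
    for (i in seq_len(nrow(m) - 1)) {
      eA <- if (m$orientation[i] == "+") "tail" else "head"
      eB <- if (m$orientation[i + 1] == "+") "head" else "tail"
      usedKeys <- c(usedKeys,
                    .adjKey(m$scaffold[i], eA, m$scaffold[i + 1], eB))
    }
  }
  trueKeys <- .adjKey(truth$scaffoldA, truth$endA, truth$scaffoldB, truth$endB)
  ## the unordered end-pair key of a junction is invariant under a global
  ## flip of the chain, so no flipped comparison is needed
  hit <- usedKeys %in% trueKeys
  list(recovered = sum(hit),
       nTrue = length(trueKeys),
       falseJoins = sum(!hit),
       recoveryRate = if (length(trueKeys))
         mean(trueKeys %in% usedKeys) else NA_real_)
}
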