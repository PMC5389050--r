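#' Depth-gate genotype calls and drop monomorphic sites
#'
#' Calls with read depth below `minDepth` are set to `N` ("over 10 read
#' depth" read as `>= 10` by default; the boundary is configurable through
#' `minDepth`).  Sites that are monomorphic after masking (fewer than two
#' distinct non-`N` genotype classes) are dropped.
#'
#' @param sites a [GenotypeSites-class] carrying a depth matrix
#' @param minDepth minimum per-call read depth (default 10)
#' @return a [GenotypeSites-class] of segregating, depth-gated sites; the
#'   `info` table gains an `nMasked` column
#' @export
callSites <- function(sites, minDepth = 10) {
  stopifnot(is(sites, "GenotypeSites"))
  geno <- sites@geno
  if (!is.null(sites@depth)) {
    low <- sites@depth < minDepth
    geno[low] <- "N"
    sites@info$nMasked <- rowSums(low & sites@geno != "N")
  } else {
    sites@info$nMasked <- 0L
  }
  sites@geno <- geno
  segregating <- apply(geno, 1, function(g) length(unique(g[g != "N"])) >= 2)
  .gsSubset(sites, which(segregating))
}

## two genotype arrays are consistent when they agree wherever both are
## called; "strict" additionally requires identical arrays
.arraysConsistent <- function(a, b, mode) {
  if (mode == "strict") return(all(a == b))
  both <- a != "N" & b != "N"
  all(a[both] == b[both])
}

#' Merge co-segregating sites within a physical window
#'
#' Scans sites along each scaffold and collapses maximal chains of
#' consecutive sites -- each within `windowBp` of the previous one and with
#' pairwise consistent genotype arrays -- into one representative site: the
#' member with the fewest `N` calls (ties resolved toward the smallest
#' position).
#'
#' @param sites a [GenotypeSites-class]
#' @param windowBp co-segregation window (default 1000 bp)
#' @param mode `"tolerant"` (arrays must agree wherever both calls are
#'   non-`N`; default) or `"strict"` (arrays must be identical)
#' @return list: `sites` (representative [GenotypeSites-class]),
#'   `members` (data.frame mapping every input site to its representative)
#' @export
mergeCosegregating <- function(sites, windowBp = 1000,
                               mode = c("tolerant", "strict")) {
  mode <- match.arg(mode)
  stopifnot(is(sites, "GenotypeSites"))
  ord <- order(sites@info$scaffold, sites@info$bp)
  info <- sites@info[ord, , drop = FALSE]
  geno <- sites@geno[ord, , drop = FALSE]
  n <- nrow(info)
  chain_id <- integer(n)
  cid <- 0L
  chainMembers <- integer(0)
  for (i in seq_len(n)) {
    newChain <- TRUE
    if (i > 1 && info$scaffold[i] == info$scaffold[i - 1] &&
        info$bp[i] - info$bp[i - 1] <= windowBp) {
      ok <- all(vapply(chainMembers, function(j)
        .arraysConsistent(geno[i, ], geno[j, ], mode), TRUE))
      if (ok) newChain <- FALSE
    }
    if (newChain) { cid <- cid + 1L; chainMembers <- i }
    else chainMembers <- c(chainMembers, i)
    chain_id[i] <- cid
  }
  nN <- rowSums(geno == "N")
  repIdx <- vapply(split(seq_len(n), chain_id), function(idx) {
    idx[order(nN[idx], info$bp[idx])][1]
  }, 0L)
  members <- data.frame(site = info$site,
                        representative = info$site[repIdx[chain_id]],
                        stringsAsFactors = FALSE)
  merged <- .gsSubset(sites, ord[sort(repIdx)])
  list(sites = merged, members = members)
}

#' Remove segregation-distorted sites by chi-square goodness of fit
#'
#' Observed `A`/`H`/`B` counts at each site are tested against the
#' expected F4 single-seed-descent ratios (7/16, 1/8, 7/16) with a
#' chi-square goodness-of-fit test (2 degrees of freedom, no multiplicity
#' correction).  Sites with `p < alpha` are removed; sites with fewer than
#' `minCalls` non-`N` calls are flagged untestable and retained with a
#' warning.
#'
#' @param sites a [GenotypeSites-class]
#' @param expected expected genotype proportions, in the order A, H, B
#' @param alpha significance level (default 0.01)
#' @param minCalls minimum non-`N` calls for a testable site
#' @return list: `sites` (retained [GenotypeSites-class]), `report`
#'   (data.frame: `site`, `nA`, `nH`, `nB`, `chisq`, `p`, `status`)
#' @export
filterDistorted <- function(sites, expected = c(7 / 16, 1 / 8, 7 / 16),
                            alpha = 0.01, minCalls = 20) {
  stopifnot(is(sites, "GenotypeSites"))
  if (abs(sum(expected) - 1) > 1e-8) stop("expected ratios must sum to 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  geno <- sites@geno
  nA <- rowSums(geno == "A"); nH <- rowSums(geno == "H")
  nB <- rowSums(geno == "B")
  nCalls <- nA + nH + nB
  E <- outer(nCalls, expected)
  O <- cbind(nA, nH, nB)
  chisq <- rowSums((O - E)^2 / E)
  p <- pchisq(chisq, df = 2, lower.tail = FALSE)
  status <- ifelse(nCalls < minCalls, "untestable",
                   ifelse(p < alpha, "removed", "retained"))
  if (any(status == "untestable"))
    warning(sum(status == "untestable"),
            " site(s) untestable (fewer than ", minCalls, " calls); retained")
  report <- data.frame(site = sites@info$site, nA = nA, nH = nH, nB = nB,
                       chisq = chisq, p = p, status = status,
                       stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(sites = .gsSubset(sites, which(status != "removed")), report = report)
}

#' Anchor scaffolds and super-scaffolds to a genetic map
#'
#' Each component (a scaffold, or a super-scaffold chain whose members are
#' resolved to component coordinates) is assigned to the linkage group of
#' its markers and ordered along the pseudo-chromosome by the median cM of
#' its markers.  Orientation is `"+"` when the component-internal physical
#' position increases with cM (Kendall concordance > 0), `"-"` when it
#' decreases, and `"?"` when only a single distinct marker position anchors
#' the component.  Components whose markers fall on more than one linkage
#' group are, by default, flagged as conflicts and left unplaced.
#'
#' @param map data.frame: `marker`, `lg`, `cm`
#' @param markerPositions data.frame: `marker`, `scaffold`, `bp`
#' @param superScaffolds optional [SuperScaffolds-class]; member scaffolds
#'   are anchored as part of their chain
#' @param scaffoldLengths named lengths, required when `superScaffolds`
#'   carries chains (member offsets need them); defaults to the lengths
#'   stored in the object
#' @param multiLg `"unplaced"` (default) or `"majority"`: how to handle
#'   components with markers on several linkage groups
#' @return list: `placements` (data.frame: `lg`, `order`, `component`,
#'   `orientation`, `nMarkers`, `medianCm`), `conflicts` (component ids),
#'   `markers` (per-marker placement detail)
#' @export
anchorToMap <- function(map, markerPositions, superScaffolds = NULL,
                        scaffoldLengths = NULL,
                        multiLg = c("unplaced", "majority")) {
  multiLg <- match.arg(multiLg)
  stopifnot(all(c("marker", "lg", "cm") %in% names(map)),
            all(c("marker", "scaffold", "bp") %in% names(markerPositions)))
  mk <- merge(map, markerPositions, by = "marker")
  if (nrow(mk) < nrow(map))
    stop("marker(s) reference unknown scaffolds: ",
         paste(setdiff(map$marker, mk$marker), collapse = ", "))
  ## map scaffolds to components (chains swallow their members)
  comp_of <- setNames(mk$scaffold, mk$scaffold)
  offset <- setNames(rep(0, length(unique(mk$scaffold))), unique(mk$scaffold))
  flip <- setNames(rep(FALSE, length(unique(mk$scaffold))), unique(mk$scaffold))
  lens <- scaffoldLengths
  if (!is.null(superScaffolds)) {
    if (is.null(lens)) lens <- superScaffolds@scaffoldLengths
    ch <- chainTable(superScaffolds)
    for (ssid in unique(ch$superScaffold)) {
      m <- ch[ch$superScaffold == ssid, ]
      m <- m[order(m$position), ]
      pos <- 0
      for (i in seq_len(nrow(m))) {
        s <- m$scaffold[i]
        comp_of[s] <- ssid
        offset[s] <- pos
        flip[s] <- m$orientation[i] == "-"
        pos <- pos + lens[[s]] + superScaffolds@gapBp
      }
    }
  }
  mk$component <- comp_of[mk$scaffold]
  mk$component[is.na(mk$component)] <- mk$scaffold[is.na(mk$component)]
  mk$compPos <- mk$bp
  known <- mk$scaffold %in% names(offset)
  fl <- known & flip[mk$scaffold]
  if (any(fl)) mk$compPos[fl] <- lens[mk$scaffold[fl]] - mk$bp[fl] + 1
  mk$compPos[known] <- mk$compPos[known] + offset[mk$scaffold[known]]

  placements <- list(); conflicts <- character(0)
  for (comp in unique(mk$component)) {
    x <- mk[mk$component == comp, , drop = FALSE]
    lgs <- table(x$lg)
    if (length(lgs) > 1) {
      conflicts <- c(conflicts, comp)
      if (multiLg == "unplaced") next
      lg <- names(lgs)[which.max(lgs)]
      x <- x[x$lg == lg, , drop = FALSE]
    }
    lg <- x$lg[1]
    ori <- if (length(unique(x$cm)) < 2 || length(unique(x$compPos)) < 2) {
      "?"   # a single distinct anchoring position cannot orient
    } else {
      tau <- suppressWarnings(cor(x$compPos, x$cm, method = "kendall"))
      if (is.na(tau) || tau >= 0) "+" else "-"
    }
    placements[[length(placements) + 1L]] <- data.frame(
      lg = lg, component = comp, orientation = ori, nMarkers = nrow(x),
      medianCm = median(x$cm), stringsAsFactors = FALSE)
  }
  pl <- if (length(placements)) do.call(rbind, placements) else
    data.frame(lg = character(), component = character(),
               orientation = character(), nMarkers = integer(),
               medianCm = numeric())
  pl <- pl[order(pl$lg, pl$medianCm, pl$component), , drop = FALSE]
  ord <- unlist(lapply(split(seq_len(nrow(pl)), pl$lg), seq_along))
  pl$order <- if (nrow(pl)) as.integer(ord) else integer(0)
  rownames(pl) <- NULL
  list(placements = pl[, c("lg", "order", "component", "orientation",
                           "nMarkers", "medianCm")],
       conflicts = conflicts, markers = mk)
}

#' AGP rows for anchored pseudo-chromosomes
#'
#' @param anchoring result of [anchorToMap()]
#' @param componentLengths named lengths of the anchored components
#'   (scaffolds and super-scaffold objects)
#' @param gapBp gap between consecutive components
#' @return data.frame of AGP rows (see [writeAgp()])
#' @export
pseudoChromosomeAgp <- function(anchoring, componentLengths, gapBp = 100) {
  pl <- anchoring$placements
  if (any(!(pl$component %in% names(componentLengths))))
    stop("anchored component without a known length")
  chainList <- lapply(split(pl, pl$lg), function(x) {
    x <- x[order(x$order), ]
    data.frame(position = x$order, scaffold = x$component,
               ## "?" components are written unoriented ("+" by AGP
               ## convention would overstate; use "?" column value)
               orientation = x$orientation, stringsAsFactors = FALSE)
  })
  names(chainList) <- paste0("pchr", names(chainList))
  .agpFromChains(chainList, componentLengths, gapBp)
}

#' Check super-scaffold chains against a genetic map
#'
#' A super-scaffold is consistent when all of its markered members lie on
#' one linkage group and their median cM values are monotone in chain order
#' (after choosing the better-fitting global flip of the chain; ties are
#' allowed).  Chains with fewer than two markered members are untestable.
#'
#' @param superScaffolds a [SuperScaffolds-class]
#' @param map data.frame: `marker`, `lg`, `cm`
#' @param markerPositions data.frame: `marker`, `scaffold`, `bp`
#' @return data.frame: `superScaffold`, `status`
#'   (`consistent`/`inconsistent`/`untestable`), `lg`, `nMarkedMembers`
#' @export
checkSuperScaffoldConsistency <- function(superScaffolds, map,
                                          markerPositions) {
  mk <- merge(map, markerPositions, by = "marker")
  ch <- chainTable(superScaffolds)
  out <- list()
  for (ssid in unique(ch$superScaffold)) {
    m <- ch[ch$superScaffold == ssid, ]
    m <- m[order(m$position), ]
    med <- vapply(m$scaffold, function(s) {
      v <- mk$cm[mk$scaffold == s]
      if (length(v)) median(v) else NA_real_
    }, 0)
    lgs <- unique(unlist(lapply(m$scaffold, function(s) mk$lg[mk$scaffold == s])))
    marked <- !is.na(med)
    if (sum(marked) < 2) {
      status <- "untestable"; lg <- if (length(lgs)) lgs[1] else NA
    } else if (length(lgs) > 1) {
      status <- "inconsistent"; lg <- NA
    } else {
      v <- med[marked]
      mono <- !is.unsorted(v) || !is.unsorted(rev(v))
      status <- if (mono) "consistent" else "inconsistent"
      lg <- lgs[1]
    }
    out[[length(out) + 1L]] <- data.frame(
      superScaffold = ssid, status = status, lg = as.character(lg),
      nMarkedMembers = sum(marked), stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(superScaffold = character(), status = character(),
               lg = character(), nMarkedMembers = integer())
  rownames(res) <- NULL
  res
}
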