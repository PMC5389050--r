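#' @import methods
#' @importFrom stats median rnorm rpois runif rbinom density cor pchisq setNames
#' @importFrom utils read.table write.table head tail
NULL

#' TruthAssembly: a synthetic draft assembly with known truth
#'
#' Container produced by [simulateGenomes()].  It holds a simulated target
#' genome (ordered genes on chromosomes), its fragmentation into draft
#' scaffolds with known true scaffold adjacencies, one or more related
#' reference genomes derived from the target gene order by whole-interval
#' rearrangements, per-reference anchor (collinearity) tables, and the
#' nucleotide sequences (scaffolds and per-gene CDS) needed by the variant
#' and selection stages.
#'
#' @slot targetChromosomes named list; per chromosome, the ordered gene ids.
#' @slot genes data.frame with one row per gene: `gene`, `chrom`,
#'   `chromIndex` (order along the target chromosome), `scaffold`,
#'   `scaffoldIndex` (order along the scaffold), `start`, `end` (1-based
#'   scaffold coordinates), `strand`.
#' @slot scaffolds data.frame: `scaffold`, `chrom`, `length`, `orientation`
#'   (orientation of the scaffold relative to the target chromosome),
#'   `chromOrder` (rank of the scaffold along its chromosome).
#' @slot trueAdjacencies data.frame: `scaffoldA`, `endA`, `scaffoldB`,
#'   `endB`, `gap` -- the junctions that reconstitute the target.
#' @slot referenceGenes data.frame: `ref`, `gene`, `chrom`, `chromIndex`,
#'   `start`, `end` -- gene positions in each rearranged reference genome.
#' @slot rearrangements data.frame log of applied inversions/translocations.
#' @slot collinearity named list (one per reference) of anchor tables:
#'   `block`, `targetGene`, `refGene`, `refChrom`, `ks`, `decoy`.
#' @slot scaffoldSeqs [Biostrings::DNAStringSet] of scaffold sequences.
#' @slot cds [Biostrings::DNAStringSet] of per-gene coding sequences
#'   (coding strand, terminal stop codon included).
#' @slot params list of the generator settings, including the seed.
#'
#' @seealso [simulateGenomes()], [writeCollinearity()], [trueAdjacencies()]
#' @export
setClass("TruthAssembly", representation(
  targetChromosomes = "list",
  genes = "data.frame",
  scaffolds = "data.frame",
  trueAdjacencies = "data.frame",
  referenceGenes = "data.frame",
  rearrangements = "data.frame",
  collinearity = "list",
  scaffoldSeqs = "ANY",
  cds = "ANY",
  params = "list"
))

setValidity("TruthAssembly", function(object) {
  msg <- character()
  g <- object@genes
  if (anyDuplicated(g$gene)) msg <- c(msg, "duplicated gene ids")
  ## concatenating scaffolds along true adjacencies must reproduce the target
  for (chr in names(object@targetChromosomes)) {
    sc <- object@scaffolds[object@scaffolds$chrom == chr, , drop = FALSE]
    sc <- sc[order(sc$chromOrder), , drop = FALSE]
    rebuilt <- unlist(lapply(seq_len(nrow(sc)), function(i) {
      gi <- g[g$scaffold == sc$scaffold[i], , drop = FALSE]
      gi <- gi[order(gi$scaffoldIndex), , drop = FALSE]
      if (sc$orientation[i] == "-") rev(gi$gene) else gi$gene
    }))
    if (!identical(rebuilt, object@targetChromosomes[[chr]]))
      msg <- c(msg, sprintf("scaffolds of %s do not reconstitute the target order", chr))
  }
  nAdjExpected <- nrow(object@scaffolds) - length(object@targetChromosomes)
  if (nrow(object@trueAdjacencies) != nAdjExpected)
    msg <- c(msg, "adjacency count != scaffolds - chromosomes")
  for (r in unique(object@referenceGenes$ref)) {
    rg <- object@referenceGenes[object@referenceGenes$ref == r, ]
    if (anyDuplicated(rg$gene) || !setequal(rg$gene, g$gene))
      msg <- c(msg, sprintf("reference %s is not a permutation of the target genes", r))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn TruthAssembly compact display
#' @param object a `TruthAssembly`
#' @export
setMethod("show", "TruthAssembly", function(object) {
  cat("TruthAssembly:",
      length(object@targetChromosomes), "chromosomes,",
      nrow(object@genes), "genes,",
      nrow(object@scaffolds), "scaffolds,",
      length(object@collinearity), "reference genomes\n")
  cat("  true adjacencies:", nrow(object@trueAdjacencies),
      " rearrangements applied:", nrow(object@rearrangements), "\n")
})

#' SyntenyBlocks: collinear ortholog anchor runs between two genomes
#'
#' Parsed representation of an MCScanX-style collinearity file: a block
#' table (one row per synteny block, with orientation and median Ks) and an
#' anchor table (one row per ortholog anchor pair, with coordinates resolved
#' on both genomes).
#'
#' @slot blocks data.frame: `block`, `refChrom`, `targetScaffold`,
#'   `nAnchors`, `orientation` (`"same"`/`"inverted"`), `medianKs`,
#'   `refStart`, `refEnd`, `targetStart`, `targetEnd`.
#' @slot anchors data.frame: `block`, `targetGene`, `targetScaffold`,
#'   `targetBp`, `refGene`, `refChrom`, `refBp`, `ks`.
#' @slot genomePair character(2): target and reference genome labels.
#' @seealso [parseCollinearity()], [selectRecentPeakBlocks()], [deriveLinks()]
#' @export
setClass("SyntenyBlocks", representation(
  blocks = "data.frame", anchors = "data.frame", genomePair = "character"
))

setValidity("SyntenyBlocks", function(object) {
  msg <- character()
  if (nrow(object@blocks) && any(object@blocks$nAnchors < 2))
    msg <- c(msg, "blocks with fewer than 2 anchors are not usable")
  if (!all(object@anchors$block %in% object@blocks$block))
    msg <- c(msg, "anchors referencing unknown blocks")
  if (length(msg)) msg else TRUE
})

#' @describeIn SyntenyBlocks compact display
#' @param object a `SyntenyBlocks`
#' @export
setMethod("show", "SyntenyBlocks", function(object) {
  cat("SyntenyBlocks (", paste(object@genomePair, collapse = " vs "), "): ",
      nrow(object@blocks), " blocks, ", nrow(object@anchors), " anchors\n", sep = "")
  if (nrow(object@blocks))
    cat("  median block Ks:", signif(median(object@blocks$medianKs), 3),
        " inverted:", sum(object@blocks$orientation == "inverted"), "\n")
})

#' @rdname SyntenyBlocks
#' @param x a `SyntenyBlocks`
#' @export
blockTable <- function(x) x@blocks

#' @rdname SyntenyBlocks
#' @export
anchorTable <- function(x) x@anchors

#' SuperScaffolds: oriented scaffold chains built from synteny links
#'
#' Result of [buildSuperScaffolds()]: ordered, oriented chains of scaffolds
#' plus the scaffolds left as singletons, and a per-adjacency fate table
#' recording why each candidate link was used or dropped.
#'
#' @slot chains data.frame: `superScaffold`, `position`, `scaffold`,
#'   `orientation` (`"+"`/`"-"`).
#' @slot singletons character: scaffolds not joined into any chain.
#' @slot fates data.frame: one row per input adjacency with a `fate` column
#'   (`used`, `below_support`, `conflict_dropped`, `cycle_broken`).
#' @slot scaffoldLengths named numeric: lengths (bp) of all scaffolds.
#' @slot gapBp numeric(1): gap inserted between joined members.
#' @seealso [buildSuperScaffolds()], [superScaffoldAgp()], [chainTable()]
#' @export
setClass("SuperScaffolds", representation(
  chains = "data.frame", singletons = "character", fates = "data.frame",
  scaffoldLengths = "numeric", gapBp = "numeric"
))

setValidity("SuperScaffolds", function(object) {
  msg <- character()
  all_members <- c(object@chains$scaffold, object@singletons)
  if (anyDuplicated(all_members))
    msg <- c(msg, "a scaffold appears in more than one chain/singleton")
  if (!all(object@chains$scaffold %in% names(object@scaffoldLengths)))
    msg <- c(msg, "chain member without a known length")
  if (length(msg)) msg else TRUE
})

#' @describeIn SuperScaffolds compact display
#' @param object a `SuperScaffolds`
#' @export
setMethod("show", "SuperScaffolds", function(object) {
  nc <- length(unique(object@chains$superScaffold))
  cat("SuperScaffolds:", nc, "chains covering",
      length(unique(object@chains$scaffold)), "scaffolds;",
      length(object@singletons), "singletons\n")
  lens <- superScaffoldLengths(object)
  cat("  output N50:", assemblyN50(lens), "bp (input N50:",
      assemblyN50(object@scaffoldLengths), "bp)\n")
})

#' @rdname SuperScaffolds
#' @param x a `SuperScaffolds`
#' @export
chainTable <- function(x) x@chains

#' @rdname SuperScaffolds
#' @export
adjacencyFates <- function(x) x@fates

#' Lengths of the output objects (chains plus singletons) of a
#' `SuperScaffolds` result, gaps included.
#' @param x a `SuperScaffolds`
#' @return named numeric vector of object lengths in bp
#' @export
superScaffoldLengths <- function(x) {
  lens <- x@scaffoldLengths
  out <- numeric(0)
  if (nrow(x@chains)) {
    sp <- split(x@chains$scaffold, x@chains$superScaffold)
    out <- vapply(sp, function(m) sum(lens[m]) + x@gapBp * (length(m) - 1L), 0)
  }
  c(out, lens[x@singletons])
}

#' F4Population: simulated single-seed-descent genotypes
#'
#' Result of [simulateF4Population()]: genotype calls for an F4 population
#' derived from a fully heterozygous F1 by three rounds of selfing, with
#' planted segregation distortion and missing data.
#'
#' @slot genotypes character matrix, lines x markers, symbols `A`, `B`,
#'   `H`, `N`.
#' @slot depth integer matrix, lines x markers, simulated read depths.
#' @slot markers data.frame marker truth: `marker`, `lg`, `cm`, `scaffold`,
#'   `bp`.
#' @slot distorted character: ids of markers with planted transmission bias.
#' @slot params list of generator settings.
#' @seealso [simulateF4Population()], [asGenotypeSites()]
#' @export
setClass("F4Population", representation(
  genotypes = "matrix", depth = "matrix", markers = "data.frame",
  distorted = "character", params = "list"
))

setValidity("F4Population", function(object) {
  msg <- character()
  if (!all(object@genotypes %in% c("A", "B", "H", "N")))
    msg <- c(msg, "genotype symbols outside {A,B,H,N}")
  if (ncol(object@genotypes) != nrow(object@markers))
    msg <- c(msg, "genotype columns != marker rows")
  cm_ok <- all(vapply(split(object@markers$cm, object@markers$lg),
                      function(v) all(v >= 0) && !is.unsorted(v), TRUE))
  if (!cm_ok) msg <- c(msg, "cM must be non-negative and non-decreasing per linkage group")
  if (length(msg)) msg else TRUE
})

#' @describeIn F4Population compact display
#' @param object an `F4Population`
#' @export
setMethod("show", "F4Population", function(object) {
  cat("F4Population:", nrow(object@genotypes), "lines x",
      ncol(object@genotypes), "markers in",
      length(unique(object@markers$lg)), "linkage groups\n")
  cat("  planted distorted markers:", length(object@distorted),
      " missing fraction:", signif(mean(object@genotypes == "N"), 3), "\n")
})

#' @rdname F4Population
#' @param x an `F4Population`
#' @export
genotypeMatrix <- function(x) x@genotypes

#' @rdname F4Population
#' @export
markerTruth <- function(x) x@markers

#' @rdname F4Population
#' @export
distortedMarkers <- function(x) x@distorted

#' GenotypeSites: per-site genotype calls over a mapping population
#'
#' The working unit of the map-anchoring stage: one row of `info` and one
#' row of the genotype matrix per segregating site.
#'
#' @slot info data.frame: `site`, `scaffold`, `bp` (plus bookkeeping columns
#'   added by the processing steps).
#' @slot geno character matrix, sites x lines, symbols `A`, `B`, `H`, `N`.
#' @slot depth optional numeric matrix (sites x lines) of read depths.
#' @seealso [callSites()], [mergeCosegregating()], [filterDistorted()]
#' @export
setClass("GenotypeSites", representation(
  info = "data.frame", geno = "matrix", depth = "ANY"
))

setValidity("GenotypeSites", function(object) {
  msg <- character()
  if (nrow(object@info) != nrow(object@geno))
    msg <- c(msg, "info rows != genotype rows")
  if (!all(object@geno %in% c("A", "B", "H", "N")))
    msg <- c(msg, "genotype symbols outside {A,B,H,N}")
  if (!is.null(object@depth) && !identical(dim(object@depth), dim(object@geno)))
    msg <- c(msg, "depth matrix dimensions differ from genotype matrix")
  if (length(msg)) msg else TRUE
})

#' @describeIn GenotypeSites compact display
#' @param object a `GenotypeSites`
#' @export
setMethod("show", "GenotypeSites", function(object) {
  cat("GenotypeSites:", nrow(object@geno), "sites x", ncol(object@geno),
      "lines on", length(unique(object@info$scaffold)), "scaffolds\n")
})

#' @rdname GenotypeSites
#' @param x a `GenotypeSites`
#' @export
siteInfo <- function(x) x@info

#' @rdname GenotypeSites
#' @export
siteGenotypes <- function(x) x@geno

#' Number of sites in a GenotypeSites object
#' @param x a `GenotypeSites`
#' @export
nSites <- function(x) nrow(x@info)

## internal subsetter keeping info/geno/depth aligned
.gsSubset <- function(x, idx) {
  new("GenotypeSites",
      info = x@info[idx, , drop = FALSE],
      geno = x@geno[idx, , drop = FALSE],
      depth = if (is.null(x@depth)) NULL else x@depth[idx, , drop = FALSE])
}

#' View an F4Population as GenotypeSites
#'
#' Transposes the line x marker genotype matrix of a simulated population
#' into the site-per-row layout consumed by the map-anchoring functions.
#'
#' @param pop an [F4Population-class]
#' @return a [GenotypeSites-class]
#' @export
asGenotypeSites <- function(pop) {
  stopifnot(is(pop, "F4Population"))
  m <- pop@markers
  new("GenotypeSites",
      info = data.frame(site = m$marker, scaffold = m$scaffold, bp = m$bp,
                        stringsAsFactors = FALSE),
      geno = t(pop@genotypes),
      depth = t(pop@depth))
}
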