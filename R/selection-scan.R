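#' Reconstruct a wild-relative ortholog CDS by SNP substitution
#'
#' Sample SNPs given in genomic coordinates are mapped through the gene's
#' exon structure and strand onto CDS positions and substituted into the
#' reference coding sequence (minus-strand genes receive the complemented
#' alternate base).  SNPs outside the gene's CDS are ignored; INDELs are
#' not applied.  A reconstruction that introduces an internal stop codon
#' is flagged.
#'
#' @param refCds reference CDS (character or [Biostrings::DNAString]),
#'   coding strand, terminal stop codon allowed
#' @param exons data.frame of the gene's exons: `scaffold`, `start`,
#'   `end`, `strand`
#' @param snps data.frame with `scaffold`, `bp`, `ref`, `alt` (and
#'   optionally `type`; non-SNP rows are skipped)
#' @return list: `cds` (derived sequence, character), `nSub` (substituted
#'   positions), `prematureStop` (logical)
#' @export
reconstructOrtholog <- function(refCds, exons, snps) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  seq <- strsplit(toupper(as.character(refCds)), "")[[1]]
  n <- 0L
  if (nrow(snps)) {
    if ("type" %in% names(snps)) snps <- snps[snps$type == "SNP", , drop = FALSE]
    snps <- snps[snps$scaffold %in% exons$scaffold, , drop = FALSE]
    for (i in seq_len(nrow(snps))) {
      cdsPos <- .genomicToCds(exons, snps$bp[i])
      if (is.na(cdsPos) || cdsPos > length(seq)) next
      alt <- if (exons$strand[1] == "+") snps$alt[i] else comp[[snps$alt[i]]]
      if (seq[cdsPos] != alt) { seq[cdsPos] <- alt; n <- n + 1L }
    }
  }
  out <- paste(seq, collapse = "")
  gc <- Biostrings::GENETIC_CODE
  nc <- length(seq) %/% 3
  starts <- 3 * seq_len(nc) - 2
  codons <- substring(out, starts, starts + 2)
  internal <- codons[-nc]
  premature <- any(gc[internal[internal %in% names(gc)]] == "*")
  list(cds = out, nSub = n, prematureStop = premature)
}

#' Partition genes into Ka/Ks peaks
#'
#' Genes are assigned to peak bins by their Ka/Ks ratio.  The default bins
#' follow the three observed selection-pressure modes (0.2, 0.5 and
#' 0.7~0.8): peak1 `[0.1, 0.3)`, peak2 `[0.4, 0.6)` and peak3
#' `[0.6, 0.9]` -- bins are half-open except the last, so a ratio of
#' exactly 0.6 belongs to peak3.  Genes with an undefined ratio (Ks = 0 or
#' saturated) fall into `none`, as do ratios outside every bin.  Mode
#' locations of a kernel density estimate over the ratios are reported
#' alongside.
#'
#' @param kaks data.frame with columns `gene` and `ratio`
#'   (see [kaksTable()])
#' @param bins named list of `c(lower, upper)` bin bounds
#' @param comparison label for this genome comparison
#' @return object of class `PeakPartition`: list with `comparison`,
#'   `bins`, `assignment` (data.frame `gene`, `ratio`, `bin`), `binSets`
#'   (genes per bin), `modes`
#' @export
partitionPeaks <- function(kaks,
                           bins = list(peak1 = c(0.1, 0.3),
                                       peak2 = c(0.4, 0.6),
                                       peak3 = c(0.6, 0.9)),
                           comparison = "comparison") {
  if (!nrow(kaks)) stop("empty Ka/Ks table")
  ratio <- kaks$ratio
  bin <- rep("none", length(ratio))
  nb <- length(bins)
  for (i in seq_len(nb)) {
    b <- bins[[i]]
    inBin <- !is.na(ratio) & ratio >= b[1] &
      (if (i == nb) ratio <= b[2] else ratio < b[2])
    bin[inBin] <- names(bins)[i]
  }
  ## half-open overlap resolution: later bins win their lower bound
  finite <- ratio[is.finite(ratio)]
  modes <- numeric(0)
  if (length(unique(finite)) >= 2) {
    d <- stats::density(finite)
    y <- d$y; n <- length(y)
    is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
    modes <- d$x[is_max]
  }
  assignment <- data.frame(gene = kaks$gene, ratio = ratio, bin = bin,
                           stringsAsFactors = FALSE)
  structure(list(comparison = comparison, bins = bins,
                 assignment = assignment,
                 binSets = lapply(stats::setNames(names(bins), names(bins)),
                                  function(b) assignment$gene[bin == b]),
                 modes = modes),
            class = "PeakPartition")
}

#' @export
print.PeakPartition <- function(x, ...) {
  cat("PeakPartition (", x$comparison, "):\n", sep = "")
  for (b in names(x$binSets))
    cat(sprintf("  %s [%g, %g%s: %d genes\n", b, x$bins[[b]][1],
                x$bins[[b]][2],
                if (b == tail(names(x$bins), 1)) "]" else ")",
                length(x$binSets[[b]])))
  cat("  none:", sum(x$assignment$bin == "none"), "genes\n")
  invisible(x)
}

#' Genes common to the same Ka/Ks peak across two comparisons
#'
#' @param partitionA,partitionB `PeakPartition` objects built with
#'   identical bin definitions
#' @return list: `common` (genes per bin), `counts` (named integer)
#' @export
intersectCommon <- function(partitionA, partitionB) {
  if (!identical(partitionA$bins, partitionB$bins))
    stop("peak bin definitions differ between the two partitions")
  common <- lapply(stats::setNames(names(partitionA$bins),
                                   names(partitionA$bins)), function(b)
    intersect(partitionA$binSets[[b]], partitionB$binSets[[b]]))
  list(common = common, counts = vapply(common, length, 0L))
}

#' Filter ortholog groups by relative standard deviation of protein length
#'
#' Retains groups whose protein lengths across species are nearly
#' identical: relative standard deviation (population standard deviation
#' divided by the mean) below `rsdCutoff` (default `1e-5`, i.e. only
#' essentially length-invariant orthologs survive).
#'
#' @param lengths matrix or data.frame of protein lengths, one row per
#'   ortholog group, one column per species
#' @param rsdCutoff RSD threshold
#' @return list: `retained` (row indices or names), `rsd` (per-group RSD)
#' @export
filterConservedOrthologs <- function(lengths, rsdCutoff = 1e-5) {
  m <- as.matrix(lengths)
  if (any(m <= 0)) stop("ortholog group with a zero-length protein")
  mu <- rowMeans(m)
  popSd <- sqrt(rowMeans((m - mu)^2))
  rsd <- popSd / mu
  keep <- which(rsd < rsdCutoff)
  list(retained = if (!is.null(rownames(m))) rownames(m)[keep] else keep,
       rsd = rsd)
}

#' Convert a synonymous-site divergence to time
#'
#' `T = Ks / (2 * rate)`, reported in millions of years (MYA); the factor
#' 2 accounts for divergence along both lineages.
#'
#' @param ks synonymous substitutions per synonymous site
#' @param rate substitution rate per site per year (default `6.1e-9`)
#' @return time in MYA
#' @examples
#' ksToTime(0.122) # 10 MYA
#' @export
ksToTime <- function(ks, rate = 6.1e-9) {
  if (any(ks < 0)) stop("Ks must be non-negative")
  if (rate <= 0) stop("rate must be positive")
  ks / (2 * rate) / 1e6
}
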