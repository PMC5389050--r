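#' Read a k-mer frequency histogram
#'
#' Reads the two-column whitespace-separated histogram emitted by standard
#' k-mer counters (`multiplicity  count`).
#'
#' @param path path to the histogram file
#' @return data.frame with columns `m` (multiplicity) and `count`
#' @export
readKmerHistogram <- function(path) {
  h <- read.table(path, header = FALSE, col.names = c("m", "count"))
  if (!nrow(h)) stop("empty histogram")
  h <- h[order(h$m), , drop = FALSE]
  if (anyDuplicated(h$m)) stop("duplicated multiplicities in histogram")
  if (any(h$count < 0)) stop("negative counts in histogram")
  rownames(h) <- NULL
  h
}

#' Locate the coverage peak of a k-mer histogram
#'
#' Sequencing-error k-mers dominate the lowest multiplicities, so the
#' histogram is scanned from `m = 1` to the first local minimum; the peak
#' multiplicity `M` is the position of the global maximum count after that
#' valley.  Ties are resolved toward the smaller multiplicity.
#'
#' @param histogram data.frame with columns `m` and `count`
#'   (see [readKmerHistogram()])
#' @return the peak multiplicity `M` (integer)
#' @examples
#' h <- data.frame(m = 1:7, count = c(1000, 50, 10, 80, 200, 80, 10))
#' findKmerPeak(h) # 5
#' @export
findKmerPeak <- function(histogram) {
  stopifnot(all(c("m", "count") %in% names(histogram)))
  cnt <- histogram$count
  if (length(cnt) < 2) stop("no coverage peak")
  ## first local minimum: first index where the count rises again
  rise <- which(diff(cnt) > 0)
  if (!length(rise)) stop("no coverage peak")
  valley <- rise[1]
  after <- seq(valley + 1L, length(cnt))
  peak_idx <- after[which.max(cnt[after])]  # which.max: first max = smallest m
  as.integer(histogram$m[peak_idx])
}

#' Estimate sequencing depth and genome size from a k-mer peak
#'
#' Depth is estimated as `N = M * L / (L - K + 1)` where `M` is the peak
#' k-mer multiplicity, `L` the read length and `K` the k-mer length; genome
#' size follows as `total_bases / N`.
#'
#' @param M peak k-mer multiplicity (see [findKmerPeak()])
#' @param L read length (bp)
#' @param K k-mer length (bp); must satisfy `L > K >= 1`
#' @param totalBases total bases sequenced; if `NULL` only the depth is
#'   returned
#' @return list with `depth` (`N`) and `genomeSize` (bp, `NA` when
#'   `totalBases` is `NULL`)
#' @examples
#' estimateDepthAndSize(M = 79, L = 100, K = 22, totalBases = 1e11)
#' # depth 100, genome size 1e9
#' @export
estimateDepthAndSize <- function(M, L, K, totalBases = NULL) {
  if (!is.numeric(M) || M <= 0) stop("M must be positive")
  if (K < 1 || L <= K) stop("require L > K >= 1")
  N <- M * L / (L - K + 1)
  list(depth = N,
       genomeSize = if (is.null(totalBases)) NA_real_ else totalBases / N)
}

#' Simulate a k-mer frequency histogram
#'
#' Generates the histogram a k-mer counter would produce for a genome of
#' the given size sequenced to the given read depth: a Poisson-shaped
#' signal component centred on the k-mer depth `N * (L - K + 1) / L`, plus
#' a geometric error component concentrated at low multiplicities.
#'
#' @param genomeSize genome size (bp)
#' @param depth read depth (x)
#' @param readLength read length `L` (bp)
#' @param k k-mer length
#' @param errorKmers number of distinct error k-mers
#' @param seed integer seed
#' @return data.frame with columns `m`, `count`
#' @export
simulateKmerHistogram <- function(genomeSize, depth, readLength = 100, k = 22,
                                  errorKmers = genomeSize / 2, seed = 1) {
  stopifnot(genomeSize > 0, depth > 0, readLength > k)
  set.seed(seed)
  kdepth <- depth * (readLength - k + 1) / readLength
  m <- seq_len(max(20, ceiling(3 * kdepth)))
  lambda <- genomeSize * stats::dpois(m, kdepth) +
    errorKmers * stats::dgeom(m - 1L, prob = 0.8)
  count <- rpois(length(m), pmin(lambda, .Machine$integer.max / 2))
  data.frame(m = m, count = count)
}

#' Write a k-mer histogram to a two-column text file
#' @param histogram data.frame with columns `m`, `count`
#' @param path output path
#' @return invisibly, the path
#' @export
writeKmerHistogram <- function(histogram, path) {
  write.table(histogram[, c("m", "count")], path, sep = " ",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
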