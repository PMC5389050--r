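#' Inverse mapping functions: cM distance to recombination fraction
#'
#' Kosambi: `r = tanh(2d)/2`; Haldane: `r = (1 - exp(-2d))/2`, with `d`
#' in Morgans.
#'
#' @param cm map distance in centiMorgans
#' @param mappingFunction `"kosambi"` or `"haldane"`
#' @return recombination fraction in `[0, 0.5)`
#' @export
recombinationFraction <- function(cm, mappingFunction = c("kosambi", "haldane")) {
  mappingFunction <- match.arg(mappingFunction)
  d <- cm / 100
  switch(mappingFunction,
         kosambi = tanh(2 * d) / 2,
         haldane = (1 - exp(-2 * d)) / 2)
}

#' Simulate an F4 single-seed-descent population genotyped at SNP markers
#'
#' Starting from a fully heterozygous F1, each line is propagated through
#' three rounds of selfing (single-seed descent) with per-interval
#' recombination fractions obtained from the marker cM distances through
#' the inverse mapping function (no interference beyond the mapping
#' function).  Segregation distortion is planted at the listed markers as a
#' biased transmission probability: heterozygous parents transmit the `A`
#' parent's allele with probability `bias` instead of 1/2.  Finally,
#' genotype calls are masked to `N` independently at `missingRate`, and a
#' read-depth matrix is simulated for the depth-gating step.
#'
#' @param markerTruth data.frame with columns `marker`, `lg`, `cm`,
#'   `scaffold`, `bp` (see [markerTruthFromAssembly()]); sorted internally
#'   by linkage group and cM
#' @param nLines number of F4 lines (the emulated design uses 133)
#' @param missingRate fraction of calls masked to `N`; in `[0, 1)`
#' @param distortedMarkers character vector of marker ids to distort
#' @param bias transmission probability of the `A` allele at distorted
#'   markers (default 0.7)
#' @param mappingFunction `"kosambi"` (default) or `"haldane"`
#' @param generations selfing generations after the F1 (3 gives an F4)
#' @param meanDepth mean of the simulated per-call read depth (Poisson)
#' @param seed integer seed
#' @return an [F4Population-class]
#' @examples
#' mt <- data.frame(marker = c("m1", "m2"), lg = 1, cm = c(0, 10),
#'                  scaffold = "sc1", bp = c(100, 200))
#' pop <- simulateF4Population(mt, nLines = 20, missingRate = 0, seed = 1)
#' table(genotypeMatrix(pop)[, "m1"])
#' @export
simulateF4Population <- function(markerTruth, nLines = 133, missingRate = 0.01,
                                 distortedMarkers = character(0), bias = 0.7,
                                 mappingFunction = c("kosambi", "haldane"),
                                 generations = 3, meanDepth = 25, seed = 1) {
  .checkFraction(missingRate, "missingRate")
  mappingFunction <- match.arg(mappingFunction)
  stopifnot(all(c("marker", "lg", "cm") %in% names(markerTruth)))
  if (bias < 0 || bias > 1) stop("bias must be in [0, 1]")
  set.seed(seed)
  mt <- markerTruth[order(markerTruth$lg, markerTruth$cm), , drop = FALSE]
  if (!"scaffold" %in% names(mt)) mt$scaffold <- NA_character_
  if (!"bp" %in% names(mt)) mt$bp <- NA_real_
  m <- nrow(mt)
  ## recombination fraction between adjacent markers; 0.5 across LG bounds
  r <- rep(0.5, m)
  if (m > 1) {
    d <- diff(mt$cm)
    sameLg <- mt$lg[-1] == mt$lg[-m]
    r[2:m] <- ifelse(sameLg, recombinationFraction(pmax(d, 0), mappingFunction), 0.5)
  }
  distCols <- which(mt$marker %in% distortedMarkers)
  pFlip <- max(0, 2 * bias - 1)   # bias the transmitted allele toward A (0)

  gamete <- function(hapA, hapB) {
    n <- nrow(hapA)
    sw <- matrix(rbinom(n * m, 1L, rep(r, each = n)), n, m)
    sw[, 1] <- rbinom(n, 1L, 0.5)
    state <- sw
    if (m > 1) for (j in 2:m) state[, j] <- state[, j - 1] + sw[, j]
    state <- state %% 2L
    gam <- ifelse(state == 0L, hapA, hapB)
    for (j in distCols) {
      het <- hapA[, j] != hapB[, j]
      flip <- het & gam[, j] == 1L & runif(n) < pFlip
      gam[flip, j] <- 0L
    }
    gam
  }

  hapA <- matrix(0L, nLines, m)   # F1: one chromosome from each parent
  hapB <- matrix(1L, nLines, m)
  for (g in seq_len(generations)) {
    g1 <- gamete(hapA, hapB)
    g2 <- gamete(hapA, hapB)
    hapA <- g1; hapB <- g2
  }
  geno <- matrix("H", nLines, m, dimnames = list(
    sprintf("line%04d", seq_len(nLines)), mt$marker))
  geno[hapA == 0L & hapB == 0L] <- "A"
  geno[hapA == 1L & hapB == 1L] <- "B"
  if (missingRate > 0)
    geno[matrix(runif(nLines * m) < missingRate, nLines, m)] <- "N"
  depth <- matrix(rpois(nLines * m, meanDepth), nLines, m,
                  dimnames = dimnames(geno))
  new("F4Population", genotypes = geno, depth = depth, markers = mt,
      distorted = mt$marker[distCols],
      params = list(seed = seed, nLines = nLines, missingRate = missingRate,
                    bias = bias, mappingFunction = mappingFunction,
                    generations = generations, meanDepth = meanDepth))
}
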