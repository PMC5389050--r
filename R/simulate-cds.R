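#' Simulate ortholog CDS pairs evolved at a known dN/dS
#'
#' Generates reference coding sequences of random sense codons (terminal
#' stop codon appended) and evolves a derived copy of each by proposing
#' point mutations at rate `branchLength` per nucleotide site and accepting
#' synonymous proposals always, nonsynonymous proposals with probability
#' `omega`, and stop-codon proposals never.  The realized substitution
#' count per gene is recorded as truth for the selection-scan estimators.
#'
#' `tsTvRatio` is the rate ratio of transitions to each transversion when a
#' proposal picks the mutant base; the default of 1 (no transition bias)
#' matches the mutational-opportunity assumptions of the Nei-Gojobori
#' counting method used downstream.
#'
#' @param nGenes number of ortholog pairs
#' @param codonsPerGene sense codons per gene (values below 10 trigger a
#'   warning: the Ka/Ks estimator is unstable on such short genes)
#' @param omegaValues dN/dS value(s); recycled across genes
#' @param tsTvRatio transition/transversion rate ratio (kappa)
#' @param branchLength expected proposed mutations per nucleotide site
#' @param seed integer seed
#' @return list with `pairs` (data.frame: `gene`, `trueOmega`, `nSub`,
#'   `nSynSub`, `nNonsynSub`), `ref` and `derived`
#'   ([Biostrings::DNAStringSet], terminal stop codon included)
#' @examples
#' sim <- simulateCdsPairs(5, 50, omegaValues = 0.2, seed = 1)
#' sim$pairs
#' @export
simulateCdsPairs <- function(nGenes, codonsPerGene, omegaValues,
                             tsTvRatio = 1, branchLength = 0.2, seed = 1) {
  if (any(omegaValues < 0)) stop("omegaValues must be > 0")
  if (branchLength < 0) stop("branchLength must be >= 0")
  if (codonsPerGene < 10)
    warning("fewer than 10 codons per gene: Ka/Ks estimates will be unstable")
  .ngTables()
  set.seed(seed)
  gc <- .ng$gc
  sense <- .ng$sense
  bases <- c("A", "C", "G", "T")
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  omegas <- rep_len(omegaValues, nGenes)
  genes <- sprintf("sim%04d", seq_len(nGenes))
  refs <- character(nGenes); ders <- character(nGenes)
  nSub <- integer(nGenes); nSyn <- integer(nGenes); nNon <- integer(nGenes)
  for (g in seq_len(nGenes)) {
    cod <- sample(sense, codonsPerGene, replace = TRUE)
    ref <- unlist(strsplit(cod, ""))
    der <- ref
    omega <- omegas[g]
    nEvents <- rpois(1, 3 * codonsPerGene * branchLength)
    if (nEvents > 0) {
      posns <- sample.int(3 * codonsPerGene, nEvents, replace = TRUE)
      us <- runif(nEvents); ua <- runif(nEvents)
      for (e in seq_len(nEvents)) {
        pos <- posns[e]
        ci <- (pos - 1L) %/% 3L
        old_codon <- paste(der[(3 * ci + 1):(3 * ci + 3)], collapse = "")
        cur <- der[pos]
        ## pick mutant base: transition weighted kappa, transversions 1 each
        p_ts <- tsTvRatio / (tsTvRatio + 2)
        if (us[e] < p_ts) {
          nb <- transition[[cur]]
        } else {
          tv <- setdiff(bases, c(cur, transition[[cur]]))
          nb <- tv[1 + (us[e] > (p_ts + (1 - p_ts) / 2))]
        }
        new <- der; new[pos] <- nb
        new_codon <- paste(new[(3 * ci + 1):(3 * ci + 3)], collapse = "")
        if (gc[[new_codon]] == "*") next            # never introduce a stop
        syn <- gc[[new_codon]] == gc[[old_codon]]
        if (!syn && ua[e] >= omega) next            # rejected by selection
        der[pos] <- nb
        nSub[g] <- nSub[g] + 1L
        if (syn) nSyn[g] <- nSyn[g] + 1L else nNon[g] <- nNon[g] + 1L
      }
    }
    refs[g] <- paste(c(ref, "TAA"), collapse = "")
    ders[g] <- paste(c(der, "TAA"), collapse = "")
  }
  list(pairs = data.frame(gene = genes, trueOmega = omegas, nSub = nSub,
                          nSynSub = nSyn, nNonsynSub = nNon,
                          stringsAsFactors = FALSE),
       ref = Biostrings::DNAStringSet(setNames(refs, genes)),
       derived = Biostrings::DNAStringSet(setNames(ders, genes)))
}
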