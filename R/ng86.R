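## Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction.
##
## Site counting: at each codon position the synonymous site fraction is the
## share of the three possible point changes that are synonymous; changes to
## stop codons count as nonsynonymous so that synonymous + nonsynonymous
## sites always sum to 3 per codon.  Substitutions between codons differing
## at d positions are averaged over the d! single-step pathways, skipping
## pathways that pass through a stop codon (falling back to all pathways
## when every one is blocked).

.ng <- new.env(parent = emptyenv())

.ngTables <- function() {
  if (!is.null(.ng$codons)) return(invisible(.ng))
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  bases <- c("A", "C", "G", "T")
  synFrac <- matrix(0, nrow = length(codons), ncol = 3,
                    dimnames = list(codons, NULL))
  for (c1 in codons) {
    s <- strsplit(c1, "")[[1]]
    for (p in 1:3) {
      syn <- 0L
      for (b in bases[bases != s[p]]) {
        s2 <- s; s2[p] <- b
        c2 <- paste(s2, collapse = "")
        if (gc[[c2]] != "*" && gc[[c2]] == gc[[c1]]) syn <- syn + 1L
      }
      synFrac[c1, p] <- syn / 3
    }
  }
  .ng$gc <- gc
  .ng$codons <- codons
  .ng$sense <- codons[gc != "*"]
  .ng$synFrac <- synFrac
  .ng$synSites <- rowSums(synFrac)
  .ng$pairCache <- new.env(parent = emptyenv())
  invisible(.ng)
}

## all orderings of a small index vector
.perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in .perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

## pathway-averaged (synonymous, nonsynonymous) substitution counts
## for one codon pair; cached
.countCodonPair <- function(c1, c2) {
  if (c1 == c2) return(c(0, 0))
  .ngTables()
  key <- paste0(c1, c2)
  hit <- .ng$pairCache[[key]]
  if (!is.null(hit)) return(hit)
  gc <- .ng$gc
  s1 <- strsplit(c1, "")[[1]]
  s2 <- strsplit(c2, "")[[1]]
  pos <- which(s1 != s2)
  acc_ok <- c(0, 0); n_ok <- 0L
  acc_all <- c(0, 0); n_all <- 0L
  for (ord in .perms(pos)) {
    cur <- s1
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in ord) {
      prev <- paste(cur, collapse = "")
      cur[p] <- s2[p]
      nxt <- paste(cur, collapse = "")
      if (gc[[nxt]] == "*" && nxt != c2) blocked <- TRUE
      if (gc[[prev]] == gc[[nxt]]) sd <- sd + 1 else nd <- nd + 1
    }
    acc_all <- acc_all + c(sd, nd); n_all <- n_all + 1L
    if (!blocked) { acc_ok <- acc_ok + c(sd, nd); n_ok <- n_ok + 1L }
  }
  res <- if (n_ok > 0) acc_ok / n_ok else acc_all / n_all
  assign(key, res, envir = .ng$pairCache)
  res
}

## Jukes-Cantor multiple-hit correction; NA when saturated (p >= 3/4)
.jcCorrect <- function(p) {
  ifelse(p >= 0.75, NA_real_,
         ifelse(p == 0, 0, -0.75 * log(1 - 4 * p / 3)))
}

#' Nei-Gojobori Ka/Ks for an aligned CDS pair
#'
#' Computes the number of nonsynonymous substitutions per nonsynonymous
#' site (Ka) and synonymous substitutions per synonymous site (Ks) between
#' two equal-length, codon-aligned coding sequences using the Nei-Gojobori
#' (1986) counting method: fractional site counts averaged over the two
#' sequences, substitution counts averaged over all single-step codon
#' pathways (stop-codon pathways excluded), and Jukes-Cantor correction
#' `d = -(3/4) ln(1 - (4/3) p)`.
#'
#' A shared terminal stop codon is excluded from the counted sites.  Codons
#' containing an internal stop or an ambiguous base in either sequence are
#' skipped and reported.  The Ka/Ks ratio is `NA` when `Ks` is 0 or either
#' proportion is saturated (`p >= 3/4`).
#'
#' @param refCds,altCds character or [Biostrings::DNAString]; equal-length
#'   sequences whose length is divisible by 3
#' @return list with elements `ka`, `ks`, `ratio`, `synSites` (S),
#'   `nonsynSites` (N), `synSubs` (Sd), `nonsynSubs` (Nd), `codonsUsed`,
#'   `saturated` (logical), `internalStops` (count of skipped codons)
#' @examples
#' computeKaKs("ATGAAACCCGGG", "ATGAAGCCCGGG") # one synonymous change
#' @export
computeKaKs <- function(refCds, altCds) {
  .ngTables()
  s1 <- toupper(as.character(refCds))
  s2 <- toupper(as.character(altCds))
  if (nchar(s1) != nchar(s2)) stop("sequences must be aligned to equal length")
  if (nchar(s1) %% 3 != 0) stop("length must be divisible by 3")
  n <- nchar(s1) / 3
  starts <- 3 * seq_len(n) - 2
  cod1 <- substring(s1, starts, starts + 2)
  cod2 <- substring(s2, starts, starts + 2)
  ## drop a shared terminal stop codon
  gc <- .ng$gc
  if (n > 0 && cod1[n] %in% names(gc) && cod2[n] %in% names(gc) &&
      gc[[cod1[n]]] == "*" && gc[[cod2[n]]] == "*") {
    cod1 <- cod1[-n]; cod2 <- cod2[-n]
  }
  known <- cod1 %in% names(gc) & cod2 %in% names(gc)
  is_stop <- known & (gc[cod1] == "*" | gc[cod2] == "*")
  use <- known & !is_stop
  internal_stops <- sum(is_stop, na.rm = TRUE)
  cod1 <- cod1[use]; cod2 <- cod2[use]
  if (!length(cod1)) stop("no usable codons")
  S <- (sum(.ng$synSites[cod1]) + sum(.ng$synSites[cod2])) / 2
  N <- 3 * length(cod1) - S
  diff_idx <- which(cod1 != cod2)
  sd <- 0; nd <- 0
  for (i in diff_idx) {
    cnt <- .countCodonPair(cod1[i], cod2[i])
    sd <- sd + cnt[1]; nd <- nd + cnt[2]
  }
  pS <- if (S > 0) sd / S else 0
  pN <- if (N > 0) nd / N else 0
  ks <- .jcCorrect(pS)
  ka <- .jcCorrect(pN)
  saturated <- is.na(ks) || is.na(ka)
  ratio <- if (saturated || ks == 0) NA_real_ else ka / ks
  list(ka = ka, ks = ks, ratio = ratio,
       synSites = S, nonsynSites = N, synSubs = sd, nonsynSubs = nd,
       codonsUsed = length(cod1), saturated = saturated,
       internalStops = internal_stops)
}

#' Ka/Ks table for a set of ortholog CDS pairs
#'
#' @param refSet,altSet [Biostrings::DNAStringSet] (or named character
#'   vectors) of aligned reference and derived CDS, matched by position
#' @param excludePrematureStops drop pairs whose derived sequence carries an
#'   internal stop codon (they are flagged in the output either way)
#' @return data.frame: `gene`, `ka`, `ks`, `ratio`, `saturated`,
#'   `internalStops`
#' @export
kaksTable <- function(refSet, altSet, excludePrematureStops = TRUE) {
  stopifnot(length(refSet) == length(altSet))
  genes <- names(refSet)
  if (is.null(genes)) genes <- paste0("gene", seq_along(refSet))
  rows <- lapply(seq_along(refSet), function(i) {
    k <- computeKaKs(refSet[[i]], altSet[[i]])
    data.frame(gene = genes[i], ka = k$ka, ks = k$ks, ratio = k$ratio,
               saturated = k$saturated, internalStops = k$internalStops,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (excludePrematureStops) out <- out[out$internalStops == 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}
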