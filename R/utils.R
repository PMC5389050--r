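#' Assembly N50
#'
#' Length such that pieces at least that long cover half of the total
#' assembly length.
#'
#' @param lengths numeric vector of piece lengths (bp)
#' @return the N50 length (bp)
#' @examples
#' assemblyN50(c(100, 200, 300, 400)) # 300
#' @export
assemblyN50 <- function(lengths) {
  lengths <- sort(as.numeric(lengths), decreasing = TRUE)
  if (!length(lengths) || any(lengths <= 0))
    stop("lengths must be positive")
  cum <- cumsum(lengths)
  lengths[which(cum >= sum(lengths) / 2)[1]]
}

## opposite scaffold end
.otherEnd <- function(end) ifelse(end == "head", "tail", "head")

## canonical key for an unordered pair of scaffold ends
.adjKey <- function(sA, eA, sB, eB) {
  a <- paste0(sA, ":", eA)
  b <- paste0(sB, ":", eB)
  ifelse(a < b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}

## stable integer sub-seed derivation (keeps results < 2^31)
.subSeed <- function(seed, offset) {
  (as.integer(seed) + 1000003L * as.integer(offset)) %% 2147483629L
}

.checkFraction <- function(x, name, allowOne = FALSE) {
  hi_ok <- if (allowOne) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || !hi_ok)
    stop(sprintf("%s must be in [0, 1%s", name, if (allowOne) "]" else ")"))
  invisible(x)
}
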