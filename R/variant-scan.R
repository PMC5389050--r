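#' Post-genotyping variant-site filters
#'
#' Applies the four site-level filter rules used after genotyping
#' wild-relative resequencing data against a draft reference.  A site
#' fails when
#' \itemize{
#'   \item its RMS mapping quality is below `mqCutoff` (default 30),
#'   \item its read depth exceeds `dupMultiplier` times the genome-wide
#'     mean ("sequence coverage"), marking a likely duplicated region,
#'   \item more than `zeroMqCount` reads with zero mapping quality cover
#'     it (strictly more than 4 by default), or
#'   \item the fraction of zero-MQ reads strictly exceeds `zeroMqFrac`
#'     (10 percent by default).
#' }
#' Reasons accumulate: a site may fail several rules.  Sites with missing
#' statistics are excluded as unevaluable with reason `"no_stats"`.
#'
#' @param sites data.frame with columns `scaffold`, `bp`, `ref`, `alt`,
#'   `type`, `depth`, `mq`, `mq0`, `totalReads`
#' @param coverage list with `meanDepth` (and optionally `mappedBp`), as
#'   returned in `simulateVariants()$coverage`, or a single number taken
#'   as the mean depth
#' @param mqCutoff,dupMultiplier,zeroMqCount,zeroMqFrac rule thresholds;
#'   all comparisons are strict, as documented
#' @return list: `pass`, `fail` (data.frames), and `sites` (all rows, with
#'   `pass` and `reasons` columns added)
#' @export
filterVariantSites <- function(sites, coverage, mqCutoff = 30,
                               dupMultiplier = 2, zeroMqCount = 4,
                               zeroMqFrac = 0.10) {
  md <- if (is.list(coverage)) coverage$meanDepth else coverage
  if (is.null(md) || !is.finite(md) || md <= 0)
    stop("coverage must provide a positive meanDepth")
  need <- c("depth", "mq", "mq0", "totalReads")
  stopifnot(all(need %in% names(sites)))
  noStats <- Reduce(`|`, lapply(sites[need], function(v) is.na(v)))
  reasons <- character(nrow(sites))
  add <- function(cond, tag) {
    cond <- !noStats & cond
    reasons[cond] <<- ifelse(nzchar(reasons[cond]),
                             paste(reasons[cond], tag, sep = ";"), tag)
  }
  add(sites$mq < mqCutoff, "mapping_quality")
  add(sites$depth > dupMultiplier * md, "duplication")
  add(sites$mq0 > zeroMqCount, "zero_mq_count")
  add(sites$mq0 / sites$totalReads > zeroMqFrac, "zero_mq_fraction")
  reasons[noStats] <- "no_stats"
  out <- sites
  out$pass <- !nzchar(reasons)
  out$reasons <- reasons
  list(pass = out[out$pass, , drop = FALSE],
       fail = out[!out$pass, , drop = FALSE],
       sites = out)
}

## map a genomic position to a CDS coordinate through a gene's exons
## exons: data.frame(gene, scaffold, start, end, strand); returns NA when
## the position is not exonic
.genomicToCds <- function(exons, bp) {
  strand <- exons$strand[1]
  ex <- exons[order(exons$start), , drop = FALSE]
  widths <- ex$end - ex$start + 1
  hit <- which(bp >= ex$start & bp <= ex$end)
  if (!length(hit)) return(NA_integer_)
  if (strand == "+") {
    sum(widths[seq_len(hit - 1)]) + (bp - ex$start[hit]) + 1L
  } else {
    after <- if (hit < nrow(ex)) sum(widths[(hit + 1):nrow(ex)]) else 0L
    after + (ex$end[hit] - bp) + 1L
  }
}

#' Annotate variant sites with their coding effect
#'
#' SNPs inside a coding sequence are translated in frame on the coding
#' strand (the alternate base is reverse-complemented for minus-strand
#' genes) and labelled `synonymous` or `nonsynonymous` by codon-table
#' comparison; INDELs inside a CDS are labelled `cds_indel`; positions
#' inside a gene span but outside its exons are `intronic`; everything
#' else is `intergenic`.  A SNP whose reference allele disagrees with the
#' supplied CDS base triggers a warning and is annotated from the supplied
#' reference.
#'
#' @param sites data.frame of variant sites (see [filterVariantSites()])
#' @param exons data.frame with columns `gene`, `scaffold`, `start`,
#'   `end`, `strand` (one row per exon)
#' @param cds [Biostrings::DNAStringSet] of coding sequences named by gene
#' @return `sites` with `annotation` and `annotGene` columns added
#' @export
annotateVariantEffects <- function(sites, exons, cds) {
  gc <- Biostrings::GENETIC_CODE
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  spans <- do.call(rbind, lapply(split(exons, exons$gene), function(e)
    data.frame(gene = e$gene[1], scaffold = e$scaffold[1],
               start = min(e$start), end = max(e$end),
               stringsAsFactors = FALSE)))
  ann <- character(nrow(sites)); annGene <- rep(NA_character_, nrow(sites))
  mismatches <- 0L
  for (i in seq_len(nrow(sites))) {
    sc <- sites$scaffold[i]; bp <- sites$bp[i]
    g <- spans[spans$scaffold == sc & bp >= spans$start & bp <= spans$end, ]
    if (!nrow(g)) { ann[i] <- "intergenic"; next }
    gene <- g$gene[1]
    ex <- exons[exons$gene == gene, , drop = FALSE]
    cdsPos <- .genomicToCds(ex, bp)
    if (is.na(cdsPos)) { ann[i] <- "intronic"; annGene[i] <- gene; next }
    annGene[i] <- gene
    if (sites$type[i] != "SNP") { ann[i] <- "cds_indel"; next }
    seq <- as.character(cds[[gene]])
    strand <- ex$strand[1]
    refCoding <- if (strand == "+") sites$ref[i] else comp[[sites$ref[i]]]
    altCoding <- if (strand == "+") sites$alt[i] else comp[[sites$alt[i]]]
    if (substr(seq, cdsPos, cdsPos) != refCoding) mismatches <- mismatches + 1L
    ci <- (cdsPos - 1) %/% 3
    refCodon <- substr(seq, 3 * ci + 1, 3 * ci + 3)
    altCodon <- refCodon
    substr(altCodon, (cdsPos - 1) %% 3 + 1, (cdsPos - 1) %% 3 + 1) <- altCoding
    ann[i] <- if (gc[[refCodon]] == gc[[altCodon]]) "synonymous"
              else "nonsynonymous"
  }
  if (mismatches > 0)
    warning(mismatches, " SNP(s) whose reference allele disagrees with the ",
            "supplied CDS; annotated from the supplied reference")
  sites$annotation <- ann
  sites$annotGene <- annGene
  sites
}

#' Divergence summary of a filtered variant set
#'
#' @param sites data.frame of passing variant sites (with `type` and,
#'   when annotated, `annotation`/`annotGene` columns)
#' @param mappedBp total mapped (callable) region in bp
#' @return list: `nSnp`, `nIndel`, `snpsPerKb`
#'   (`1000 * nSnp / mappedBp`), `byAnnotation` (table, when available),
#'   `genesWithNonsynonymous` (count, when available)
#' @export
divergenceSummary <- function(sites, mappedBp) {
  if (!is.numeric(mappedBp) || mappedBp <= 0)
    stop("mappedBp must be positive")
  nSnp <- sum(sites$type == "SNP")
  out <- list(nSnp = nSnp,
              nIndel = sum(sites$type == "INDEL"),
              snpsPerKb = 1000 * nSnp / mappedBp)
  if ("annotation" %in% names(sites)) {
    out$byAnnotation <- table(sites$annotation)
    out$genesWithNonsynonymous <-
      length(unique(sites$annotGene[sites$annotation == "nonsynonymous" &
                                      !is.na(sites$annotGene)]))
  }
  out
}

#' Write variant sites as a minimal VCF 4.2 file
#'
#' Site statistics are stored in INFO fields `DP`, `MQ`, `MQ0` and `TOT`.
#'
#' @param sites data.frame of variant sites
#' @param path output path
#' @return invisibly, the path
#' @export
writeVariantVcf <- function(sites, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Site depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=MQ0,Number=1,Type=Integer,Description=\"Zero-MQ reads\">",
    "##INFO=<ID=TOT,Number=1,Type=Integer,Description=\"Total mapped reads\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  filt <- if ("reasons" %in% names(sites))
    ifelse(nzchar(sites$reasons), gsub(";", ",", sites$reasons), "PASS")
  else rep(".", nrow(sites))
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\tDP=%d;MQ=%g;MQ0=%d;TOT=%d",
                     sites$scaffold, as.integer(sites$bp), sites$ref,
                     sites$alt, filt, as.integer(sites$depth), sites$mq,
                     as.integer(sites$mq0), as.integer(sites$totalReads)),
             con)
  invisible(path)
}

#' Read a VCF of variant sites with DP/MQ/MQ0/TOT site statistics
#'
#' Uses `vcfR` for parsing; multi-allelic records are decomposed into one
#' row per alternate allele before filtering.
#'
#' @param path VCF file
#' @return data.frame in the layout consumed by [filterVariantSites()]
#' @export
readVariantVcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("readVariantVcf() needs the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  getInfo <- function(key) {
    m <- regmatches(fix$INFO, regexpr(paste0("(^|;)", key, "=[^;]+"), fix$INFO))
    vals <- rep(NA_character_, nrow(fix))
    hit <- grepl(paste0("(^|;)", key, "="), fix$INFO)
    vals[hit] <- sub(paste0(".*", key, "="), "", m)
    as.numeric(vals)
  }
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",")[[1]]
    for (a in alts) {
      type <- if (nchar(fix$REF[i]) == 1 && nchar(a) == 1) "SNP" else "INDEL"
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = fix$CHROM[i], bp = as.numeric(fix$POS[i]),
        ref = fix$REF[i], alt = a, type = type, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  reps <- vapply(strsplit(fix$ALT, ","), length, 0L)
  out$depth <- rep(getInfo("DP"), reps)
  out$mq <- rep(getInfo("MQ"), reps)
  out$mq0 <- rep(getInfo("MQ0"), reps)
  out$totalReads <- rep(getInfo("TOT"), reps)
  rownames(out) <- NULL
  out
}
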