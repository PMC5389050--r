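#' Write the gene models of a TruthAssembly as GFF3
#'
#' One `gene` and one `CDS` feature per (single-exon) simulated gene, in
#' 1-based inclusive scaffold coordinates.
#'
#' @param assembly a [TruthAssembly-class]
#' @param path output path
#' @return invisibly, the path
#' @export
writeGeneGff3 <- function(assembly, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
      !requireNamespace("GenomicRanges", quietly = TRUE))
    stop("writeGeneGff3() needs rtracklayer and GenomicRanges")
  g <- assembly@genes
  feat <- rbind(
    data.frame(seqnames = g$scaffold, start = g$start, end = g$end,
               strand = g$strand, type = "gene", ID = g$gene,
               Parent = NA_character_, stringsAsFactors = FALSE),
    data.frame(seqnames = g$scaffold, start = g$start, end = g$end,
               strand = g$strand, type = "CDS", ID = paste0(g$gene, ".cds"),
               Parent = g$gene, stringsAsFactors = FALSE))
  gr <- GenomicRanges::GRanges(feat$seqnames,
                               IRanges::IRanges(feat$start, feat$end),
                               strand = feat$strand)
  gr$type <- feat$type
  gr$ID <- feat$ID
  gr$Parent <- feat$Parent
  gr$phase <- ifelse(feat$type == "CDS", 0L, NA_integer_)
  gr <- gr[order(feat$seqnames, feat$start, feat$type != "gene")]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models (CDS exons) from a GFF3 file
#'
#' @param path GFF3 file with `CDS` features carrying a `Parent` (or `ID`)
#'   attribute
#' @return data.frame of exons: `gene`, `scaffold`, `start`, `end`,
#'   `strand`
#' @export
readGeneModelsGff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("readGeneModelsGff3() needs rtracklayer")
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  parent <- as.character(unlist(cds$Parent))
  if (!length(parent) || all(is.na(parent)))
    parent <- sub("\\.cds$", "", as.character(cds$ID))
  data.frame(gene = parent,
             scaffold = as.character(GenomicRanges::seqnames(cds)),
             start = GenomicRanges::start(cds),
             end = GenomicRanges::end(cds),
             strand = as.character(GenomicRanges::strand(cds)),
             stringsAsFactors = FALSE)
}
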