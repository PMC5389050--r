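#' Default pipeline configuration
#'
#' All stage thresholds with their documented defaults.  The configuration
#' is a nested list; [validatePipelineConfig()] rejects unknown keys and
#' out-of-range values.
#'
#' @param seed master seed; per-stage sub-seeds are derived from it
#'   deterministically
#' @param outdir output directory for stage artifacts
#' @return nested configuration list
#' @export
defaultPipelineConfig <- function(seed = 1, outdir = "synbridge_run") {
  list(
    seed = seed,
    outdir = outdir,
    simulate = list(
      nChromosomes = 2, genesPerChromosome = 100, nScaffolds = 20,
      nRearrangements = 2, nReferences = 2, nDecoyBlocks = 4,
      markersPerScaffold = 3, clusterSize = 2,
      nLines = 133, missingRate = 0.01, distortedFraction = 0.1,
      distortionBias = 0.7, mappingFunction = "kosambi",
      nSnps = 300, nIndels = 30, codingFraction = 0.3, meanDepth = 30,
      nCdsGenes = 60, codonsPerGene = 300, omegas = c(0.2, 0.5, 0.8),
      genomeDepth = 50),
    kmersize = list(k = 22, readLength = 100),
    scaffold = list(minSupport = 2, gapBp = 100),
    anchor = list(windowBp = 1000, minDepth = 10, alpha = 0.01),
    variants = list(mqCutoff = 30, dupMultiplier = 2, zeroMqCount = 4,
                    zeroMqFrac = 0.10),
    kaks = list(bins = list(peak1 = c(0.1, 0.3), peak2 = c(0.4, 0.6),
                            peak3 = c(0.6, 0.9)),
                rate = 6.1e-9),
    translate = list(nMarkers = 40)
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys present in the file override the defaults; unknown keys are
#' rejected.
#'
#' @param path YAML file
#' @param seed optional master seed overriding the file/default
#' @return validated configuration list
#' @export
readPipelineConfig <- function(path, seed = NULL) {
  user <- yaml::read_yaml(path)
  cfg <- defaultPipelineConfig()
  merge2 <- function(base, upd, prefix = "") {
    for (k in names(upd)) {
      if (!k %in% names(base))
        stop("unknown configuration key: ", prefix, k)
      if (is.list(base[[k]]) && !is.null(names(base[[k]])))
        base[[k]] <- merge2(base[[k]], upd[[k]], paste0(prefix, k, "."))
      else base[[k]] <- upd[[k]]
    }
    base
  }
  cfg <- merge2(cfg, user)
  if (!is.null(seed)) cfg$seed <- seed
  validatePipelineConfig(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every threshold against its documented legal range and rejects
#' unknown keys.  Called before any stage runs.
#'
#' @param config configuration list (see [defaultPipelineConfig()])
#' @return invisibly, the config
#' @export
validatePipelineConfig <- function(config) {
  ref <- defaultPipelineConfig()
  chk <- function(base, x, prefix = "") {
    extra <- setdiff(names(x), names(base))
    if (length(extra))
      stop("unknown configuration key(s): ",
           paste0(prefix, extra, collapse = ", "))
    for (k in names(x))
      if (is.list(base[[k]]) && !is.null(names(base[[k]])) && k != "bins")
        chk(base[[k]], x[[k]], paste0(prefix, k, "."))
  }
  chk(ref, config)
  with(config, {
    if (!is.numeric(seed) || seed != round(seed)) stop("seed must be an integer")
    if (anchor$alpha <= 0 || anchor$alpha >= 1) stop("alpha must be in (0, 1)")
    if (simulate$missingRate < 0 || simulate$missingRate >= 1)
      stop("missingRate must be in [0, 1)")
    if (scaffold$minSupport < 1) stop("minSupport must be >= 1")
    if (anchor$minDepth < 0) stop("minDepth must be >= 0")
    if (variants$zeroMqFrac < 0 || variants$zeroMqFrac > 1)
      stop("zeroMqFrac must be in [0, 1]")
    if (variants$dupMultiplier <= 0) stop("dupMultiplier must be positive")
    if (kmersize$readLength <= kmersize$k) stop("readLength must exceed k")
    if (kaks$rate <= 0) stop("substitution rate must be positive")
  })
  invisible(config)
}

#' Run the full synthetic-demonstration pipeline
#'
#' Executes the stages in dependency order -- simulate, kmersize,
#' scaffold, anchor, variants, kaks, translate -- writing every stage's
#' artifacts under `config$outdir` and a JSON manifest recording the
#' package version, the seed and the MD5 checksum of every artifact.
#' Identical configuration and seed produce byte-identical artifacts and
#' manifest.
#'
#' @param config configuration list (see [defaultPipelineConfig()],
#'   [readPipelineConfig()])
#' @param quiet suppress progress messages
#' @return invisibly, the manifest list (also written to
#'   `manifest.json`)
#' @export
runPipeline <- function(config = defaultPipelineConfig(), quiet = FALSE) {
  validatePipelineConfig(config)
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[synbridge] ", ...)
  files <- character(0)
  reg <- function(...) files <<- c(files, ...)
  seed <- config$seed
  sim <- config$simulate

  ## ---- simulate ----
  say("stage simulate")
  ta <- simulateGenomes(
    nChromosomes = sim$nChromosomes,
    genesPerChromosome = sim$genesPerChromosome,
    nScaffolds = sim$nScaffolds, nRearrangements = sim$nRearrangements,
    nReferences = sim$nReferences, nDecoyBlocks = sim$nDecoyBlocks,
    seed = .subSeed(seed, 1))
  fa <- file.path(out, "scaffolds.fasta")
  Biostrings::writeXStringSet(ta@scaffoldSeqs, fa)
  gff <- file.path(out, "genes.gff3")
  writeGeneGff3(ta, gff)
  posT <- file.path(out, "genes.target.pos")
  writeGenePositions(ta, posT, "target")
  reg(fa, gff, posT)
  refs <- names(ta@collinearity)
  colFiles <- posFiles <- setNames(character(length(refs)), refs)
  for (r in refs) {
    colFiles[r] <- file.path(out, paste0(r, ".collinearity"))
    posFiles[r] <- file.path(out, paste0(r, ".pos"))
    writeCollinearity(ta, r, colFiles[r])
    writeGenePositions(ta, posFiles[r], r)
    reg(colFiles[r], posFiles[r])
  }
  mt <- markerTruthFromAssembly(ta, markersPerScaffold = sim$markersPerScaffold,
                                clusterSize = sim$clusterSize,
                                seed = .subSeed(seed, 2))
  nDist <- round(sim$distortedFraction * nrow(mt))
  set.seed(.subSeed(seed, 3))
  distorted <- sample(mt$marker, nDist)
  pop <- simulateF4Population(mt, nLines = sim$nLines,
                              missingRate = sim$missingRate,
                              distortedMarkers = distorted,
                              bias = sim$distortionBias,
                              mappingFunction = sim$mappingFunction,
                              seed = .subSeed(seed, 4))
  genoF <- file.path(out, "genotypes.tsv")
  write.table(genotypeMatrix(pop), genoF, sep = "\t", quote = FALSE)
  mapF <- file.path(out, "genetic_map.tsv")
  write.table(mt[, c("marker", "lg", "cm")], mapF, sep = "\t",
              quote = FALSE, row.names = FALSE)
  reg(genoF, mapF)
  vars <- simulateVariants(ta, nSnps = sim$nSnps, nIndels = sim$nIndels,
                           codingFraction = sim$codingFraction,
                           statsModel = list(meanDepth = sim$meanDepth,
                                             fracLowMq = 0.05, fracDup = 0.05,
                                             fracZeroMqCount = 0.05,
                                             fracZeroMqFrac = 0.05),
                           seed = .subSeed(seed, 5))
  vcfF <- file.path(out, "variants.vcf")
  writeVariantVcf(vars$sites, vcfF)
  reg(vcfF)
  cdsA <- simulateCdsPairs(sim$nCdsGenes, sim$codonsPerGene,
                           omegaValues = sim$omegas, seed = .subSeed(seed, 6))
  cdsB <- simulateCdsPairs(sim$nCdsGenes, sim$codonsPerGene,
                           omegaValues = sim$omegas, seed = .subSeed(seed, 7))
  genomeSize <- sum(scaffoldLengths(ta))
  kh <- simulateKmerHistogram(genomeSize, sim$genomeDepth,
                              readLength = config$kmersize$readLength,
                              k = config$kmersize$k,
                              seed = .subSeed(seed, 8))
  khF <- file.path(out, "kmer.histo")
  writeKmerHistogram(kh, khF)
  reg(khF)

  ## ---- kmersize ----
  say("stage kmersize")
  h <- readKmerHistogram(khF)
  M <- findKmerPeak(h)
  est <- estimateDepthAndSize(M, config$kmersize$readLength,
                              config$kmersize$k,
                              totalBases = sim$genomeDepth * genomeSize)
  kmerJson <- file.path(out, "kmersize.json")
  jsonlite::write_json(list(peakMultiplicity = M, depth = est$depth,
                            genomeSize = est$genomeSize,
                            trueGenomeSize = genomeSize),
                       kmerJson, auto_unbox = TRUE, digits = NA)
  reg(kmerJson)

  ## ---- scaffold ----
  say("stage scaffold")
  posTarget <- readGenePositions(posT)
  blockSets <- lapply(setNames(refs, refs), function(r) {
    bl <- parseCollinearity(colFiles[r], posTarget, readGenePositions(posFiles[r]),
                            genomePair = c("target", r))
    selectRecentPeakBlocks(bl)$blocks
  })
  links <- deriveLinks(blockSets)
  ss <- buildSuperScaffolds(links, scaffoldLengths(ta),
                            minSupport = config$scaffold$minSupport,
                            gapBp = config$scaffold$gapBp)
  agpF <- file.path(out, "superscaffolds.agp")
  writeAgp(superScaffoldAgp(ss), agpF)
  adjF <- file.path(out, "adjacencies.tsv")
  write.table(adjacencyFates(ss), adjF, sep = "\t", quote = FALSE,
              row.names = FALSE)
  reg(agpF, adjF)
  rec <- adjacencyRecovery(ss, trueAdjacencies(ta))

  ## ---- anchor ----
  say("stage anchor")
  gs <- callSites(asGenotypeSites(pop), minDepth = config$anchor$minDepth)
  mg <- mergeCosegregating(gs, windowBp = config$anchor$windowBp)
  fd <- suppressWarnings(filterDistorted(mg$sites, alpha = config$anchor$alpha))
  keptMap <- mt[mt$marker %in% fd$sites@info$site, c("marker", "lg", "cm")]
  mkPos <- fd$sites@info[, c("site", "scaffold", "bp")]
  names(mkPos)[1] <- "marker"
  anch <- anchorToMap(keptMap, mkPos, superScaffolds = ss)
  compLens <- c(superScaffoldLengths(ss))
  pagpF <- file.path(out, "pseudochromosomes.agp")
  writeAgp(pseudoChromosomeAgp(anch, compLens,
                               gapBp = config$scaffold$gapBp), pagpF)
  consF <- file.path(out, "map_consistency.tsv")
  cons <- checkSuperScaffoldConsistency(ss, keptMap, mkPos)
  write.table(cons, consF, sep = "\t", quote = FALSE, row.names = FALSE)
  reg(pagpF, consF)

  ## ---- variants ----
  say("stage variants")
  siteTab <- readVariantVcf(vcfF)
  flt <- filterVariantSites(siteTab, vars$coverage,
                            mqCutoff = config$variants$mqCutoff,
                            dupMultiplier = config$variants$dupMultiplier,
                            zeroMqCount = config$variants$zeroMqCount,
                            zeroMqFrac = config$variants$zeroMqFrac)
  exons <- readGeneModelsGff3(gff)
  annot <- annotateVariantEffects(flt$pass, exons, ta@cds)
  fvcfF <- file.path(out, "variants.filtered.vcf")
  writeVariantVcf(flt$sites, fvcfF)
  annF <- file.path(out, "variants.annotated.tsv")
  write.table(annot, annF, sep = "\t", quote = FALSE, row.names = FALSE)
  dsum <- divergenceSummary(annot, vars$coverage$mappedBp)
  dsumF <- file.path(out, "divergence.json")
  jsonlite::write_json(list(nSnp = dsum$nSnp, nIndel = dsum$nIndel,
                            snpsPerKb = dsum$snpsPerKb,
                            byAnnotation = as.list(dsum$byAnnotation),
                            genesWithNonsynonymous = dsum$genesWithNonsynonymous),
                       dsumF, auto_unbox = TRUE, digits = NA)
  reg(fvcfF, annF, dsumF)

  ## ---- kaks ----
  say("stage kaks")
  kA <- kaksTable(cdsA$ref, cdsA$derived)
  kB <- kaksTable(cdsB$ref, cdsB$derived)
  pA <- partitionPeaks(kA, bins = config$kaks$bins, comparison = "wildA")
  pB <- partitionPeaks(kB, bins = config$kaks$bins, comparison = "wildB")
  common <- intersectCommon(pA, pB)
  kaksF <- file.path(out, "kaks.tsv")
  write.table(merge(kA, cdsA$pairs[, c("gene", "trueOmega")], by = "gene"),
              kaksF, sep = "\t", quote = FALSE, row.names = FALSE)
  ## WGD timing from the ancient (decoy) block Ks mode, when present
  oldKs <- unlist(lapply(ta@collinearity, function(a) a$ks[a$decoy]))
  wgd <- if (length(oldKs)) ksToTime(median(oldKs), config$kaks$rate) else NA
  partF <- file.path(out, "peaks.json")
  jsonlite::write_json(list(
    binCounts = lapply(pA$binSets, length),
    commonCounts = as.list(common$counts),
    wgdTimeMya = wgd), partF, auto_unbox = TRUE, digits = NA)
  reg(kaksF, partF)

  ## ---- translate ----
  say("stage translate")
  set.seed(.subSeed(seed, 9))
  srcRef <- refs[1]
  rg <- ta@referenceGenes[ta@referenceGenes$ref == srcRef, ]
  pick <- rg[sample.int(nrow(rg), min(config$translate$nMarkers, nrow(rg))), ]
  qtlMarkers <- data.frame(marker = paste0("qtl_", pick$gene),
                           trait = "seed_weight", chrom = pick$chrom,
                           bp = pick$start + 17, stringsAsFactors = FALSE)
  trBlocks <- parseCollinearity(colFiles[srcRef], posTarget,
                                readGenePositions(posFiles[srcRef]),
                                genomePair = c("target", srcRef))
  ## the parsed blocks' reference side is the source genome, which is
  ## exactly the direction needed: source chromosome -> target scaffold
  tr <- translateMarkers(qtlMarkers, trBlocks)
  trF <- file.path(out, "qtl_translated.tsv")
  write.table(tr, trF, sep = "\t", quote = FALSE, row.names = FALSE)
  reg(trF)

  ## ---- manifest ----
  manifest <- list(
    package = "SynBridge",
    version = as.character(utils::packageVersion("SynBridge")),
    seed = seed,
    adjacencyRecovery = rec,
    superScaffoldConsistency = as.list(table(cons$status)),
    outputs = lapply(setNames(files, basename(files)), function(f)
      unname(tools::md5sum(f))))
  manF <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manF, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  say("done: ", manF)
  invisible(manifest)
}
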