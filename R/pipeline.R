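## Orchestration: a declarative, schema-validated configuration and a staged
## pipeline (simulate -> spectra -> features -> integrate -> diffpeaks ->
## dsb -> report) over the on-disk fixture bundle.  Every stage reads its
## inputs from the run directory through the package's format readers and
## writes its outputs there once; all randomness flows from the config seed,
## so a run is byte-reproducible.

PIPELINE_STAGES <- c("simulate", "spectra", "features", "integrate",
                     "diffpeaks", "dsb", "report")

#' Build a validated pipeline configuration
#'
#' Houses every numeric threshold of the analysis with its default: proximity
#' distance 1500 bp, cluster adjacency 1000 bp, G4Hunter threshold 1.2 with
#' scan window 25 and density bin 100 bp, GC-skew window 200 bp, SNV flank
#' 200 bp, FDR 0.05, fold change 1.5, top-25% base-mean filter (applied to
#' the SPI contrast only), same-strand merge within 1000 bp, NMF rank 2 with
#' 20 restarts.  Unknown keys are rejected.
#'
#' @param seed master seed (drives the synthetic config too).
#' @param synthetic named list of [syntheticConfig()] overrides.
#' @param dProximity,dCluster,clusterPerm,gcskewWindow,g4Window,g4Threshold,
#'   g4DensityBin,snvFlank,profileFlank,fdr,fc,topFraction,minRecurrence,
#'   mergeWithin,nmfRank,nmfRestarts,nRandomSites,rloopStrandMeans stage
#'   parameters; see Details in the package vignette.
#' @return A validated named list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(seed = 20260218L,
                           synthetic = list(),
                           dProximity = 1500L, dCluster = 1000L,
                           clusterPerm = 200L,
                           gcskewWindow = 200L, g4Window = 25L,
                           g4Threshold = 1.2, g4DensityBin = 100L,
                           snvFlank = 200L, profileFlank = 1000L,
                           fdr = 0.05, fc = 1.5, topFraction = 0.25,
                           minRecurrence = 2L, mergeWithin = 1000L,
                           nmfRank = 2L, nmfRestarts = 20L,
                           nRandomSites = 20000L,
                           rloopStrandMeans = "displaced") {
  cfg <- list(seed = as.integer(seed), synthetic = synthetic,
              dProximity = as.integer(dProximity),
              dCluster = as.integer(dCluster),
              clusterPerm = as.integer(clusterPerm),
              gcskewWindow = as.integer(gcskewWindow),
              g4Window = as.integer(g4Window),
              g4Threshold = g4Threshold,
              g4DensityBin = as.integer(g4DensityBin),
              snvFlank = as.integer(snvFlank),
              profileFlank = as.integer(profileFlank),
              fdr = fdr, fc = fc, topFraction = topFraction,
              minRecurrence = as.integer(minRecurrence),
              mergeWithin = as.integer(mergeWithin),
              nmfRank = as.integer(nmfRank),
              nmfRestarts = as.integer(nmfRestarts),
              nRandomSites = as.integer(nRandomSites),
              rloopStrandMeans = rloopStrandMeans)
  validatePipelineConfig(cfg)
  class(cfg) <- "pipelineConfig"
  cfg
}

validatePipelineConfig <- function(cfg) {
  allowed <- names(formals(pipelineConfig))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  missing <- setdiff(allowed, names(cfg))
  if (length(missing))
    stop("missing configuration keys: ", paste(missing, collapse = ", "))
  positive <- c("dCluster", "clusterPerm", "gcskewWindow", "g4Window",
                "g4DensityBin", "profileFlank", "minRecurrence",
                "nmfRank", "nmfRestarts", "nRandomSites")
  for (key in positive)
    if (cfg[[key]] < 1L) stop(key, " must be a positive integer")
  nonneg <- c("dProximity", "snvFlank", "mergeWithin")
  for (key in nonneg)
    if (cfg[[key]] < 0L) stop(key, " must be non-negative")
  if (cfg$fdr <= 0 || cfg$fdr > 1) stop("fdr must be in (0, 1]")
  if (cfg$fc < 1) stop("fc must be >= 1")
  if (!is.null(cfg$topFraction) &&
      (cfg$topFraction <= 0 || cfg$topFraction > 1))
    stop("topFraction must be in (0, 1]")
  if (!cfg$rloopStrandMeans %in% c("displaced", "hybrid"))
    stop("rloopStrandMeans must be 'displaced' or 'hybrid'")
  if (!is.list(cfg$synthetic))
    stop("synthetic must be a named list of syntheticConfig overrides")
  if (length(cfg$synthetic)) {
    synAllowed <- names(formals(syntheticConfig))
    bad <- setdiff(names(cfg$synthetic), synAllowed)
    if (length(bad))
      stop("unknown synthetic keys: ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' CLI-style override: values in \code{overrides} replace file values before
#' validation; unknown keys are rejected before any computation.
#'
#' @param path YAML file with \code{pipelineConfig} keys.
#' @param overrides named list of overriding values.
#' @return A validated \code{pipelineConfig}.
#' @export
readPipelineConfig <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  raw[names(overrides)] <- overrides
  unknown <- setdiff(names(raw), names(formals(pipelineConfig)))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, raw)
}

synConfigOf <- function(cfg) {
  args <- cfg$synthetic
  if (is.null(args$seed)) args$seed <- cfg$seed
  do.call(syntheticConfig, args)
}

writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order into \code{outDir}.
#' \code{simulate} writes the fixture bundle; every later stage reads its
#' inputs back from disk through the package readers, so the run exercises
#' the full I/O round trip.  The resolved configuration is persisted at the
#' start; the final report echoes parameters, records input/output MD5
#' checksums and warning counts, and contains no wall-clock state, so a rerun
#' with the same config is byte-identical.
#'
#' @param config a \code{pipelineConfig}.
#' @param outDir run directory (created; stage outputs are write-once).
#' @param stages subset of \code{c("simulate", "spectra", "features",
#'   "integrate", "diffpeaks", "dsb", "report")}; dependencies must already
#'   have run when a prefix is skipped.
#' @return The report list, invisibly.
#' @export
runPipeline <- function(config, outDir,
                        stages = PIPELINE_STAGES) {
  validatePipelineConfig(config)
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  writeJson(unclass(config), file.path(outDir, "resolved_config.json"))
  warningCounts <- list()
  runStage <- function(name, fun) {
    wc <- 0L
    withCallingHandlers(fun(),
      warning = function(w) {
        wc <<- wc + 1L
        invokeRestart("muffleWarning")
      })
    warningCounts[[name]] <<- wc
  }
  for (st in intersect(PIPELINE_STAGES, stages)) {
    fun <- switch(st,
      simulate = function() stageSimulate(config, outDir),
      spectra = function() stageSpectra(config, outDir),
      features = function() stageFeatures(config, outDir),
      integrate = function() stageIntegrate(config, outDir),
      diffpeaks = function() stageDiffpeaks(config, outDir),
      dsb = function() stageDsb(config, outDir),
      report = function() NULL)
    if (st != "report") runStage(st, fun)
  }
  report <- buildReport(config, outDir, warningCounts)
  if ("report" %in% stages)
    writeJson(report, file.path(outDir, "report.json"))
  invisible(report)
}

fixtureDir <- function(outDir) file.path(outDir, "fixtures")

loadFixtures <- function(config, outDir) {
  fd <- fixtureDir(outDir)
  syn <- synConfigOf(config)
  sl <- syn@contigs
  genome <- readGenomeFasta(file.path(fd, "genome.fa"))
  list(
    syn = syn, sl = sl, genome = genome,
    rloops = readBed(file.path(fd, "rloops.bed"), sl),
    muts = readMutationsVcf(file.path(fd, "mutations.vcf")),
    a3b = readBed(file.path(fd, "a3b_peaks.bed"), sl),
    dsb = readBed(file.path(fd, "dsb_peaks.bed"), sl),
    spi = readBed(file.path(fd, "spi_peaks.bed"), sl))
}

stageSimulate <- function(config, outDir) {
  synth <- buildSyntheticData(synConfigOf(config))
  writeFixtureBundle(synth, fixtureDir(outDir))
}

stageSpectra <- function(config, outDir) {
  fx <- loadFixtures(config, outDir)
  dir <- file.path(outDir, "spectra")
  if (!dir.exists(dir)) dir.create(dir)
  sp <- build96Spectrum(fx$muts, fx$genome)
  writeTsv(data.frame(channel = rownames(sp$spectrum), sp$spectrum,
                      check.names = FALSE),
           file.path(dir, "spectrum_96.tsv"))
  writeTsv(data.frame(class = rownames(sp$summary), sp$summary,
                      check.names = FALSE),
           file.path(dir, "class_summary.tsv"))
  imd <- intermutationDistance(fx$muts)
  writeTsv(data.frame(contig = as.character(seqnames(fx$muts)),
                      pos = start(fx$muts),
                      sample = mcols(fx$muts)$sample, imd = imd),
           file.path(dir, "imd.tsv"))
  callable <- GRanges(names(fx$sl), IRanges(1L, fx$sl),
                      seqlengths = fx$sl)
  cl <- detectClusters(fx$muts, callable, dMax = config$dCluster,
                       nPerm = config$clusterPerm,
                       seed = subSeed(config$seed, 21L))
  writeTsv(cl$clusters, file.path(dir, "clusters.tsv"))
  writeTsv(cl$perSample, file.path(dir, "clusters_per_sample.tsv"))
  rank <- min(config$nmfRank, ncol(sp$spectrum) - 1L)
  if (rank >= 1L && ncol(sp$spectrum) > 1L) {
    nmf <- extractSignaturesNMF(sp$spectrum, rank,
                                seed = subSeed(config$seed, 22L),
                                nRestarts = config$nmfRestarts)
    writeTsv(data.frame(channel = rownames(nmf$signatures), nmf$signatures,
                        check.names = FALSE),
             file.path(dir, "nmf_signatures.tsv"))
    writeTsv(data.frame(signature = rownames(nmf$exposures), nmf$exposures,
                        check.names = FALSE),
             file.path(dir, "nmf_exposures.tsv"))
  }
  invisible(dir)
}

stageFeatures <- function(config, outDir) {
  fx <- loadFixtures(config, outDir)
  dir <- file.path(outDir, "features")
  if (!dir.exists(dir)) dir.create(dir)
  skew <- gcSkewTrack(fx$genome, window = config$gcskewWindow)
  writeBedGraph(skew$plus, file.path(dir, "gc_skew_plus.bedGraph"))
  writeBedGraph(skew$minus, file.path(dir, "gc_skew_minus.bedGraph"))
  g4 <- g4HunterScan(fx$genome, window = config$g4Window,
                     threshold = config$g4Threshold,
                     densityBin = config$g4DensityBin)
  writeBed6(g4$intervals, file.path(dir, "g4_intervals.bed"))
  writeBedGraph(g4$density, file.path(dir, "g4_density.bedGraph"))
  flank <- config$profileFlank
  flank <- flank - flank %% config$gcskewWindow
  prof <- profileAround(fx$rloops, skew$plus, flank = flank,
                        strandAware = TRUE, signFlip = TRUE)
  writeTsv(prof, file.path(dir, "profile_skew_rloops.tsv"))
  cls <- classifySubstitution(fx$muts, fx$genome)
  tcw <- fx$muts[cls$is_TCW & cls$class == "C>T"]
  if (length(tcw)) {
    gf <- config$profileFlank - config$profileFlank %% config$g4DensityBin
    writeTsv(profileAround(tcw, g4$density, flank = gf,
                           strandAware = FALSE),
             file.path(dir, "profile_g4_tcw_sites.tsv"))
  }
  invisible(dir)
}

stageIntegrate <- function(config, outDir) {
  fx <- loadFixtures(config, outDir)
  fd <- fixtureDir(outDir)
  dir <- file.path(outDir, "integrate")
  if (!dir.exists(dir)) dir.create(dir)
  cls <- classifySubstitution(fx$muts, fx$genome)
  mcols(fx$muts)$pyr_strand <- cls$pyr_strand
  conc <- strandConcordance(fx$muts, fx$rloops,
                            rloopStrandMeans = config$rloopStrandMeans)
  writeJson(list(fraction = conc$fraction, ci = conc$ci, n = conc$n,
                 excluded = conc$excluded, chisq = conc$chisq, p = conc$p),
            file.path(dir, "strand_concordance.json"))
  prox <- classifyProximity(fx$a3b, fx$rloops, d = config$dProximity)
  writeJson(as.list(prox$fractions),
            file.path(dir, "a3b_rloop_proximity.json"))
  seg <- readBed(file.path(fd, "chromatin_states.bed"), fx$sl)
  writeTsv(stateEnrichment(fx$muts, seg, flank = config$snvFlank,
                           seqlengths = fx$sl),
           file.path(dir, "state_enrichment_snv.tsv"))
  writeTsv(stateEnrichment(fx$dsb, seg, flank = 0L, seqlengths = fx$sl),
           file.path(dir, "state_enrichment_dsb.tsv"))
  rt <- readBedGraphTrack(file.path(fd, "replication_timing.bedGraph"),
                          binWidth = fx$syn@rtBin, seqlengths = fx$sl)
  writeTsv(replicationQuartileRates(fx$muts, rt),
           file.path(dir, "replication_quartile_rates.tsv"))
  catalogue <- catalogueFromSegmentation(seg)
  rand <- randomSiteSample(fx$sl, config$nRandomSites,
                           seed = subSeed(config$seed, 23L))
  writeTsv(consequenceEnrichment(fx$muts, catalogue, rand),
           file.path(dir, "consequence_enrichment.tsv"))
  invisible(dir)
}

#' Derive a priority-ordered annotation catalogue from a state segmentation
#'
#' Maps the toy chromatin-state labels onto consequence-like categories
#' (coding from transcribed states, regulatory from promoter/enhancer
#' states, repressed from Polycomb/heterochromatin states) with coding
#' highest priority; everything else is intergenic.
#'
#' @param segmentation \code{GRanges} with state labels in \code{name}.
#' @return An [AnnotationCatalogue-class].
#' @export
catalogueFromSegmentation <- function(segmentation) {
  st <- mcols(segmentation)$name
  annotationCatalogue(list(
    coding = reduce(segmentation[st == "Tx"], ignore.strand = TRUE),
    regulatory = reduce(segmentation[st %in% c("Tss", "Enh")],
                        ignore.strand = TRUE),
    repressed = reduce(segmentation[st %in% c("ReprPC", "Het")],
                       ignore.strand = TRUE)))
}

stageDiffpeaks <- function(config, outDir) {
  fx <- loadFixtures(config, outDir)
  fd <- fixtureDir(outDir)
  dir <- file.path(outDir, "diffpeaks")
  if (!dir.exists(dir)) dir.create(dir)
  repFiles <- sort(list.files(fd, pattern = "^spi_rep[0-9]+\\.bed$",
                              full.names = TRUE))
  reps <- GRangesList(lapply(repFiles, readBed, seqlengths = fx$sl))
  cons <- consensusPeaks(reps, minRecurrence = config$minRecurrence,
                         mergeWithin = config$mergeWithin, stranded = FALSE)
  writeBed6(cons, file.path(dir, "consensus_peaks.bed"))
  counts <- readCountsTsv(file.path(fd, "spi_counts.tsv"))
  samples <- readTsv(file.path(fd, "spi_samples.tsv"))
  condition <- factor(samples$condition[match(colnames(counts),
                                              samples$sample)],
                      levels = c("control", "treated"))
  res <- testDifferential(counts, condition)
  res <- classifyInduced(res, fdr = config$fdr, fc = config$fc,
                         topFraction = config$topFraction)
  writeTsv(res, file.path(dir, "differential.tsv"))
  tss <- readBed(file.path(fd, "tss.bed"), fx$sl)
  hitPeaks <- fx$spi[match(res$feature[res$induced], mcols(fx$spi)$name)]
  assoc <- regionToGene(hitPeaks, tss)
  writeTsv(assoc, file.path(dir, "region_to_gene.tsv"))
  sets <- readTsv(file.path(fd, "gene_sets.tsv"))
  geneSets <- split(sets$gene, sets$set)
  hits <- unique(assoc$gene)
  writeTsv(geneSetOverlapTest(hits, geneSets, mcols(tss)$name),
           file.path(dir, "gene_set_overlap.tsv"))
  invisible(dir)
}

stageDsb <- function(config, outDir) {
  fx <- loadFixtures(config, outDir)
  fd <- fixtureDir(outDir)
  dir <- file.path(outDir, "dsb")
  if (!dir.exists(dir)) dir.create(dir)
  counts <- readCountsTsv(file.path(fd, "dsb_counts.tsv"))
  samples <- readTsv(file.path(fd, "dsb_samples.tsv"))
  samples <- samples[match(colnames(counts), samples$sample), ]
  e2 <- factor(samples$e2, levels = c("vehicle", "E2"))
  genotype <- factor(samples$genotype, levels = c("NT", "siA3B"))
  ## control-feature normalisation: features on A3B/R-loop overlaps are
  ## expected to respond to the knockdown and are excluded from size-factor
  ## estimation (context is fixed by genomic overlap, not by counts)
  cx <- dsbContext(fx$dsb, fx$a3b, fx$rloops, d = config$dProximity)
  ctrl <- cx$context != "both"
  if (!any(ctrl)) ctrl <- rep(TRUE, nrow(counts))
  sf <- normalizeMedianOfRatios(counts[ctrl, , drop = FALSE])
  ntSel <- genotype == "NT"
  e2Res <- classifyInduced(
    testDifferential(counts[, ntSel], e2[ntSel], sizeFactors = sf[ntSel]),
    fdr = config$fdr, fc = config$fc)
  e2Sel <- e2 == "E2"
  kdRes <- classifyInduced(
    testDifferential(counts[, e2Sel], genotype[e2Sel],
                     sizeFactors = sf[e2Sel]),
    fdr = config$fdr, fc = config$fc)
  cls <- classifyDsbs(e2Res, kdRes, fx$dsb, fx$a3b, fx$rloops,
                      d = config$dProximity)
  writeTsv(cls$table, file.path(dir, "dsb_classes.tsv"))
  dep <- dependenceRatioByClass(counts[, e2Sel], genotype[e2Sel],
                                cls$table, sizeFactors = sf[e2Sel])
  writeTsv(dep$perClass, file.path(dir, "dependence_by_class.tsv"))
  inter <- testInteraction(counts, e2, genotype, sizeFactors = sf)
  writeTsv(inter, file.path(dir, "interaction.tsv"))
  writeJson(list(
    overlap_e2 = cls$overlapE2, chisq = cls$chisq, p = cls$p,
    fractions = lapply(cls$fractions, as.list),
    excluded_zero_nt = dep$excluded),
    file.path(dir, "dsb_summary.json"))
  invisible(dir)
}

buildReport <- function(config, outDir, warningCounts) {
  files <- sort(list.files(outDir, recursive = TRUE))
  files <- files[files != "report.json"]
  sums <- tools::md5sum(file.path(outDir, files))
  list(
    package = "rloopedit",
    version = as.character(packageVersion("rloopedit")),
    config = unclass(config),
    warnings = warningCounts,
    outputs = setNames(as.list(unname(sums)), files))
}
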