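#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom BiocGenerics start end width strand strand<-
#' @importFrom GenomicRanges GRanges GRangesList seqnames findOverlaps
#'   countOverlaps distanceToNearest reduce granges
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqinfo Seqinfo
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement subseq
#'   writeXStringSet readDNAStringSet letterFrequency
#' @importFrom stats median pchisq phyper pnorm p.adjust rnbinom rnorm runif
#'   binom.test sd quantile setNames rpois var rexp t.test
#' @importFrom utils write.table read.table packageVersion head
NULL

## ---------------------------------------------------------------------------
## SyntheticConfig
## ---------------------------------------------------------------------------

#' Configuration of the synthetic multi-omic dataset
#'
#' A \code{SyntheticConfig} fixes every parameter of the synthetic-data
#' generator: the toy genome, the planted R-loops and their sequence features
#' (GC skew on the displaced strand, G-quadruplex motifs), the planted
#' mutations (TCW-motif editing with a set strand concordance, diffuse
#' background, omikli-like clusters), the replicate peak count model, and the
#' knockdown-dependence structure of double-strand-break (DSB) peaks.  A single
#' seed drives independent sub-seeds per artefact, so the whole bundle is
#' bitwise reproducible and individual artefacts can be regenerated in
#' isolation.
#'
#' @slot seed integer; master seed for all randomness.
#' @slot contigs named integer vector of contig lengths (bp).
#' @slot gcContent background genome GC fraction.
#' @slot nRloops,rloopLength number of planted R-loops and their length range
#'   (bp, min/max).
#' @slot skewStrength probability in \[0.5, 1\] that a strong (G/C) position
#'   inside an R-loop carries G on the displaced strand.  The expected
#'   displaced-strand GC skew is \code{2 * skewStrength - 1}.
#' @slot g4PlantRate probability that a G4 motif is inserted at an R-loop 5'
#'   end (on the displaced strand).
#' @slot nBackgroundMut,nRloopMut counts of diffuse background mutations and
#'   of TCW-motif C>T mutations planted inside R-loops.
#' @slot concordance fraction of R-loop mutations placed on the displaced
#'   strand.
#' @slot nClusters,clusterSize,clusterSpan planted mutation clusters: count,
#'   mutations per cluster, and the window (bp) containing each cluster.
#' @slot nPeaks,peakLength,fracInduced,inducedFc,nbDispersion,meanCount,
#'   meanSdlog,nReplicates replicate peak count model: number of peaks, their
#'   length range, the induced fraction and its fold change in the treated
#'   condition, the NB dispersion, the central per-peak mean count, the
#'   lognormal sd of per-peak baseline means, and replicates per condition.
#' @slot nA3bPeaks,a3bRloopFrac A3B binding peaks: count and the fraction
#'   placed overlapping R-loops.
#' @slot nDsb,dsbA3bRloopFrac,dsbE2Frac,dsbE2Fc,dsbDependenceRatio DSB peaks:
#'   count, fraction placed on A3B-and-R-loop overlaps, fraction and fold
#'   change of E2-induced DSBs, and the expected siA3B/NT count ratio for the
#'   A3B-and-R-loop class.
#' @slot rtBin,rtEffect replication-timing track bin width (bp) and the
#'   early/late mutation-rate ratio planted for background mutations (1 = no
#'   effect).
#' @slot nStates,stateMeanLength chromatin-state segmentation: number of
#'   states and mean segment length (bp).
#' @slot nGenes number of toy TSS annotations.
#'
#' @seealso [syntheticConfig()] for the user constructor with defaults.
#' @export
setClass("SyntheticConfig",
  representation(
    seed = "integer", contigs = "integer", gcContent = "numeric",
    nRloops = "integer", rloopLength = "integer", skewStrength = "numeric",
    g4PlantRate = "numeric",
    nBackgroundMut = "integer", nRloopMut = "integer", concordance = "numeric",
    nClusters = "integer", clusterSize = "integer", clusterSpan = "integer",
    nPeaks = "integer", peakLength = "integer", fracInduced = "numeric",
    inducedFc = "numeric", nbDispersion = "numeric", meanCount = "numeric",
    meanSdlog = "numeric", nReplicates = "integer",
    nA3bPeaks = "integer", a3bRloopFrac = "numeric",
    nDsb = "integer", dsbA3bRloopFrac = "numeric", dsbE2Frac = "numeric",
    dsbE2Fc = "numeric", dsbDependenceRatio = "numeric",
    rtBin = "integer", rtEffect = "numeric",
    nStates = "integer", stateMeanLength = "integer", nGenes = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  probs <- c(
    gcContent = object@gcContent, g4PlantRate = object@g4PlantRate,
    concordance = object@concordance, fracInduced = object@fracInduced,
    a3bRloopFrac = object@a3bRloopFrac,
    dsbA3bRloopFrac = object@dsbA3bRloopFrac, dsbE2Frac = object@dsbE2Frac
  )
  bad <- probs < 0 | probs > 1
  if (any(bad))
    msg <- c(msg, paste0("probabilities outside [0,1]: ",
                         paste(names(probs)[bad], collapse = ", ")))
  if (object@skewStrength < 0.5 || object@skewStrength > 1)
    msg <- c(msg, "skewStrength must be in [0.5, 1]")
  if (length(object@contigs) < 1L || any(object@contigs <= 0L) ||
      is.null(names(object@contigs)))
    msg <- c(msg, "contigs must be a named vector of positive lengths")
  if (length(object@rloopLength) != 2L || any(object@rloopLength <= 0L) ||
      object@rloopLength[1] > object@rloopLength[2])
    msg <- c(msg, "rloopLength must be (min, max) with 0 < min <= max")
  if (length(object@peakLength) != 2L || any(object@peakLength <= 0L) ||
      object@peakLength[1] > object@peakLength[2])
    msg <- c(msg, "peakLength must be (min, max) with 0 < min <= max")
  lens <- c(clusterSpan = object@clusterSpan, rtBin = object@rtBin,
            stateMeanLength = object@stateMeanLength)
  if (any(lens <= 0L))
    msg <- c(msg, "clusterSpan, rtBin and stateMeanLength must be positive")
  if (object@meanCount <= 0)
    msg <- c(msg, "meanCount must be positive")
  if (object@nbDispersion < 0)
    msg <- c(msg, "nbDispersion must be non-negative")
  if (object@inducedFc <= 0 || object@dsbE2Fc <= 0 ||
      object@dsbDependenceRatio <= 0)
    msg <- c(msg, "fold changes and dependence ratio must be positive")
  if (object@rtEffect <= 0)
    msg <- c(msg, "rtEffect must be positive")
  if (object@nReplicates < 2L)
    msg <- c(msg, "nReplicates must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Create a synthetic-data configuration
#'
#' Constructs a validated [SyntheticConfig-class] object.  The defaults define
#' the reference study conditions used throughout the package's tests and the
#' worked examples: a 2 Mb two-contig genome, 200 stranded R-loops with strong
#' displaced-strand GC skew (0.9, i.e. expected skew +0.8), 80% strand
#' concordance of planted TCW edits, 3-fold induction of 10% of 2000 peaks at
#' NB dispersion 0.1 in 3 vs 3 replicates, and a 0.4 knockdown dependence
#' ratio for DSBs sitting on A3B/R-loop overlaps.
#'
#' @param seed integer master seed.
#' @param contigs named integer vector of contig lengths in bp.
#' @param gcContent background GC fraction (default 0.41, human-like).
#' @param nRloops,rloopLength,skewStrength,g4PlantRate R-loop planting
#'   parameters; see [SyntheticConfig-class].
#' @param nBackgroundMut,nRloopMut,concordance,nClusters,clusterSize,
#'   clusterSpan mutation planting parameters.
#' @param nPeaks,peakLength,fracInduced,inducedFc,nbDispersion,meanCount,
#'   meanSdlog,nReplicates peak count model parameters.
#' @param nA3bPeaks,a3bRloopFrac,nDsb,dsbA3bRloopFrac,dsbE2Frac,dsbE2Fc,
#'   dsbDependenceRatio binding and DSB peak parameters.
#' @param rtBin,rtEffect,nStates,stateMeanLength,nGenes auxiliary track and
#'   annotation parameters.
#' @return A validated \code{SyntheticConfig}.
#' @examples
#' cfg <- syntheticConfig(seed = 1, contigs = c(chrT = 50000L), nRloops = 10L)
#' cfg
#' @export
syntheticConfig <- function(seed = 20260218L,
                            contigs = c(chrS1 = 1000000L, chrS2 = 1000000L),
                            gcContent = 0.41,
                            nRloops = 200L, rloopLength = c(800L, 2000L),
                            skewStrength = 0.9, g4PlantRate = 0.5,
                            nBackgroundMut = 300L, nRloopMut = 1000L,
                            concordance = 0.8,
                            nClusters = 20L, clusterSize = 3L,
                            clusterSpan = 900L,
                            nPeaks = 2000L, peakLength = c(300L, 800L),
                            fracInduced = 0.1, inducedFc = 3,
                            nbDispersion = 0.1, meanCount = 100,
                            meanSdlog = 0.4, nReplicates = 3L,
                            nA3bPeaks = 400L, a3bRloopFrac = 0.4,
                            nDsb = 600L, dsbA3bRloopFrac = 0.25,
                            dsbE2Frac = 0.2, dsbE2Fc = 3,
                            dsbDependenceRatio = 0.4,
                            rtBin = 1000L, rtEffect = 1,
                            nStates = 6L, stateMeanLength = 2000L,
                            nGenes = 200L) {
  contigs <- setNames(as.integer(contigs), names(contigs))
  new("SyntheticConfig",
      seed = as.integer(seed), contigs = contigs, gcContent = gcContent,
      nRloops = as.integer(nRloops), rloopLength = as.integer(rloopLength),
      skewStrength = skewStrength, g4PlantRate = g4PlantRate,
      nBackgroundMut = as.integer(nBackgroundMut),
      nRloopMut = as.integer(nRloopMut), concordance = concordance,
      nClusters = as.integer(nClusters), clusterSize = as.integer(clusterSize),
      clusterSpan = as.integer(clusterSpan),
      nPeaks = as.integer(nPeaks), peakLength = as.integer(peakLength),
      fracInduced = fracInduced, inducedFc = inducedFc,
      nbDispersion = nbDispersion, meanCount = meanCount,
      meanSdlog = meanSdlog, nReplicates = as.integer(nReplicates),
      nA3bPeaks = as.integer(nA3bPeaks), a3bRloopFrac = a3bRloopFrac,
      nDsb = as.integer(nDsb), dsbA3bRloopFrac = dsbA3bRloopFrac,
      dsbE2Frac = dsbE2Frac, dsbE2Fc = dsbE2Fc,
      dsbDependenceRatio = dsbDependenceRatio,
      rtBin = as.integer(rtBin), rtEffect = rtEffect,
      nStates = as.integer(nStates),
      stateMeanLength = as.integer(stateMeanLength),
      nGenes = as.integer(nGenes))
}

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig\n")
  cat("  seed:", object@seed, "\n")
  cat("  genome:", length(object@contigs), "contig(s),",
      sum(as.numeric(object@contigs)), "bp, GC", object@gcContent, "\n")
  cat("  R-loops:", object@nRloops, "x",
      paste(object@rloopLength, collapse = "-"), "bp; skew strength",
      object@skewStrength, "; G4 plant rate", object@g4PlantRate, "\n")
  cat("  mutations:", object@nRloopMut, "R-loop TCW (concordance",
      paste0(object@concordance, "),"), object@nBackgroundMut, "background,",
      object@nClusters, "clusters of", object@clusterSize, "\n")
  cat("  peaks:", object@nPeaks, "(induced", object@fracInduced, "x FC",
      paste0(object@inducedFc, "),"), "NB dispersion", object@nbDispersion,
      "\n")
  cat("  DSB:", object@nDsb, "peaks; dependence ratio",
      object@dsbDependenceRatio, "on A3B*R-loop overlaps\n")
})

## Derive a reproducible sub-seed from the master seed; keeps every stream
## independent and below .Machine$integer.max.
subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) + 7919 * k) %% 2147483647)
}

## ---------------------------------------------------------------------------
## BinnedTrack (SignalTrack)
## ---------------------------------------------------------------------------

#' Fixed-bin per-contig signal track
#'
#' A \code{BinnedTrack} stores one numeric value per fixed-width genomic bin
#' for each contig: GC skew, G4 density, replication timing, coverage.  Bins
#' are left-aligned and 0-based on disk (bedGraph); in memory, bin \code{i} of
#' a contig covers 1-based positions \code{((i-1)*binWidth + 1) : min(i *
#' binWidth, contigLength)} — the last partial bin is kept.  Missing values
#' are \code{NA} (e.g. GC-skew windows with no G or C).
#'
#' @slot values named list of numeric vectors, one per contig.
#' @slot binWidth integer bin width in bp.
#' @slot seqlengths named integer vector of contig lengths.
#' @export
setClass("BinnedTrack",
  representation(values = "list", binWidth = "integer",
                 seqlengths = "integer"))

setValidity("BinnedTrack", function(object) {
  msg <- character()
  if (object@binWidth < 1L) msg <- c(msg, "binWidth must be >= 1")
  if (!identical(names(object@values), names(object@seqlengths)))
    msg <- c(msg, "values and seqlengths must share contig names")
  expected <- ceiling(object@seqlengths / object@binWidth)
  actual <- lengths(object@values)
  if (!all(actual == expected))
    msg <- c(msg, "each value vector must have ceiling(length/binWidth) bins")
  if (length(msg)) msg else TRUE
})

#' Construct a BinnedTrack
#'
#' @param values named list of per-contig numeric vectors (one value per bin).
#' @param binWidth bin width in bp.
#' @param seqlengths named integer vector of contig lengths in bp.
#' @return A [BinnedTrack-class] object.
#' @export
binnedTrack <- function(values, binWidth, seqlengths) {
  new("BinnedTrack", values = values, binWidth = as.integer(binWidth),
      seqlengths = setNames(as.integer(seqlengths), names(seqlengths)))
}

#' @describeIn BinnedTrack-class bin width in bp.
#' @param x,object a \code{BinnedTrack}.
#' @export
binWidth <- function(x) x@binWidth

#' @describeIn BinnedTrack-class per-contig value list.
#' @export
trackValues <- function(x) x@values

setMethod("show", "BinnedTrack", function(object) {
  cat("BinnedTrack:", length(object@values), "contig(s), bin width",
      object@binWidth, "bp,", sum(lengths(object@values)), "bins (",
      sum(vapply(object@values, function(v) sum(is.na(v)), 0)),
      "missing)\n")
})

## ---------------------------------------------------------------------------
## AnnotationCatalogue
## ---------------------------------------------------------------------------

#' Priority-ordered functional annotation catalogue
#'
#' Holds one interval set per consequence category (e.g. coding, TF binding,
#' regulatory, UTR/exon/intron) together with a unique priority rank per
#' category.  A genomic site is annotated with its highest-priority (lowest
#' rank) overlapping category, and with \code{"intergenic"} when none
#' overlaps.  This is a deliberately simplified, transparent replacement for a
#' full variant-effect predictor.
#'
#' @slot regions a \code{GRangesList}, one element per category.
#' @slot priority integer ranks, parallel to \code{regions}; lower = higher
#'   priority; must be unique.
#' @export
setClass("AnnotationCatalogue",
  representation(regions = "GRangesList", priority = "integer"))

setValidity("AnnotationCatalogue", function(object) {
  msg <- character()
  if (length(object@regions) != length(object@priority))
    msg <- c(msg, "one priority per category required")
  if (anyDuplicated(object@priority))
    msg <- c(msg, "priorities must be unique")
  if (is.null(names(object@regions)) || anyDuplicated(names(object@regions)))
    msg <- c(msg, "categories must be uniquely named")
  if (length(msg)) msg else TRUE
})

#' Construct an annotation catalogue
#'
#' @param regions named list of \code{GRanges} (or a \code{GRangesList}), one
#'   per category.
#' @param priority integer ranks parallel to \code{regions}; lower rank wins
#'   when categories overlap.  Defaults to list order.
#' @return An [AnnotationCatalogue-class].
#' @export
annotationCatalogue <- function(regions, priority = seq_along(regions)) {
  if (!is(regions, "GRangesList")) regions <- GRangesList(regions)
  new("AnnotationCatalogue", regions = regions,
      priority = as.integer(priority))
}

setMethod("show", "AnnotationCatalogue", function(object) {
  ord <- order(object@priority)
  cat("AnnotationCatalogue:",
      paste(names(object@regions)[ord], collapse = " > "),
      "> intergenic\n")
})

## ---------------------------------------------------------------------------
## FixtureBundle
## ---------------------------------------------------------------------------

#' On-disk synthetic fixture bundle
#'
#' Records the paths of every file written by [writeFixtureBundle()]: the
#' genome FASTA, mutations VCF, stranded R-loop / A3B / DSB BEDs, replicate
#' peak BEDs, count TSVs, replication-timing bedGraph, chromatin-state BED,
#' TSS BED, gene sets TSV, and the truth tables of every planted element.
#'
#' @slot dir the bundle directory.
#' @slot paths named character vector of file paths (relative to \code{dir}).
#' @export
setClass("FixtureBundle",
  representation(dir = "character", paths = "character"))

setValidity("FixtureBundle", function(object) {
  missing <- !file.exists(file.path(object@dir, object@paths))
  if (any(missing))
    paste("missing bundle files:",
          paste(object@paths[missing], collapse = ", "))
  else TRUE
})

#' @describeIn FixtureBundle-class full path of a bundle component.
#' @param x a \code{FixtureBundle}.
#' @param name component name (e.g. \code{"genome"}, \code{"mutations"}).
#' @export
bundlePath <- function(x, name) {
  if (!name %in% names(x@paths))
    stop("no bundle component named '", name, "'")
  file.path(x@dir, x@paths[[name]])
}

setMethod("show", "FixtureBundle", function(object) {
  cat("FixtureBundle at", object@dir, "\n")
  for (nm in names(object@paths))
    cat(sprintf("  %-14s %s\n", nm, object@paths[[nm]]))
})
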