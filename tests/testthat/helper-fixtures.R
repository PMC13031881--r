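## Shared fixtures, built once per test run.  The default configuration is
## the package's reference study conditions; the small configuration keeps
## unit tests fast.

.fixtureCache <- new.env(parent = emptyenv())

defaultSynth <- function() {
  if (is.null(.fixtureCache$default))
    .fixtureCache$default <-
      suppressWarnings(buildSyntheticData(syntheticConfig()))
  .fixtureCache$default
}

smallSynthConfig <- function(seed = 7L, ...) {
  args <- list(seed = seed,
               contigs = c(chrA = 300000L, chrB = 200000L),
               nRloops = 50L, nRloopMut = 250L, nBackgroundMut = 80L,
               nClusters = 6L, nPeaks = 400L, nA3bPeaks = 120L,
               nDsb = 200L, nGenes = 60L)
  args <- utils::modifyList(args, list(...))
  do.call(syntheticConfig, args)
}

smallSynth <- function() {
  if (is.null(.fixtureCache$small))
    .fixtureCache$small <-
      suppressWarnings(buildSyntheticData(smallSynthConfig()))
  .fixtureCache$small
}

## a toy genome from explicit sequences
toyGenome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}

## width-1 mutation GRanges helper
mutGR <- function(contig, pos, ref, alt, sample = "s1",
                  seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos, width = 1L),
                               ref = ref, alt = alt, sample = sample)
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

## random stranded interval set on a toy genome
randomPeakCase <- function(seed, n, contigLen = 100000L) {
  set.seed(seed)
  starts <- sample.int(contigLen - 2000L, n, replace = TRUE)
  widths <- sample(50:1500, n, replace = TRUE)
  GenomicRanges::GRanges("chrT",
    IRanges::IRanges(starts, width = pmin(widths, contigLen - starts)),
    strand = sample(c("+", "-"), n, replace = TRUE),
    seqlengths = c(chrT = contigLen))
}
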