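## Sequence-derived signal tracks and strand-aware metaprofiles: GC skew
## (R-loop-favourable strand asymmetry), G4Hunter G-quadruplex propensity,
## and anchor-centred enrichment profiles with confidence bands.

#' GC-skew track pair
#'
#' Per non-overlapping window, skew = (G - C)/(G + C) counted on the plus
#' strand; the minus-strand track is its negation.  Windows without G or C
#' are missing (\code{NA}).  Positive skew on a strand means G-richness of
#' that strand, the configuration favouring R-loop formation when the
#' displaced strand is G-rich.
#'
#' @param genome named \code{DNAStringSet}.
#' @param window window (= bin) width in bp, default 200.
#' @return A list of two [BinnedTrack-class] objects, \code{plus} and
#'   \code{minus}.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "GGGGGCGCGC"))
#' trackValues(gcSkewTrack(g, window = 5)$plus)
#' @export
gcSkewTrack <- function(genome, window = 200L) {
  if (window < 1L) stop("window must be >= 1")
  sl <- genomeSeqlengths(genome)
  values <- lapply(names(genome), function(ctg) {
    len <- sl[[ctg]]
    n <- ceiling(len / window)
    starts <- (seq_len(n) - 1L) * window + 1L
    ends <- pmin(seq_len(n) * window, len)
    v <- Biostrings::Views(genome[[ctg]], start = starts, end = ends)
    freq <- Biostrings::letterFrequency(v, c("G", "C"))
    g <- as.numeric(freq[, "G"]); c <- as.numeric(freq[, "C"])
    unname(ifelse(g + c == 0, NA_real_, (g - c) / (g + c)))
  })
  names(values) <- names(genome)
  plus <- binnedTrack(values, window, sl)
  minus <- binnedTrack(lapply(values, function(v) -v), window, sl)
  list(plus = plus, minus = minus)
}

## Per-base G4Hunter run score: G runs score +min(L,4) per base, C runs
## -min(L,4) per base, everything else 0.
g4BaseScores <- function(chars) {
  r <- rle(chars)
  val <- ifelse(r$values == "G", pmin(r$lengths, 4L),
                ifelse(r$values == "C", -pmin(r$lengths, 4L), 0L))
  rep.int(val, r$lengths)
}

#' G4Hunter score of a sequence
#'
#' Each base is scored by its homopolymer run (G runs +min(L,4) per base, C
#' runs -min(L,4); other bases, including N, score 0); the sequence score is
#' the arithmetic mean over its length.  Scores are bounded in \[-4, 4\] and
#' antisymmetric under reverse complement.
#'
#' @param sequence a character string or \code{DNAString} over A,C,G,T,N.
#' @return The mean score.
#' @examples
#' g4HunterScore("GGGTTAGGGTTAGGGTTAGGG")  # 36/21
#' @export
g4HunterScore <- function(sequence) {
  s <- toupper(as.character(sequence))
  if (nchar(s) == 0L) stop("empty sequence")
  chars <- strsplit(s, "")[[1]]
  mean(g4BaseScores(chars))
}

#' Scan a genome for G4-forming sequence
#'
#' Slides a window of \code{window} bp one base at a time; windows whose mean
#' G4Hunter score has absolute value >= \code{threshold} qualify, with the
#' sign recorded as strand (+ for G-rich, - for C-rich).  Same-sign
#' qualifying windows closer than one window length are merged into maximal
#' intervals.  A density track counts, per \code{densityBin} bp bin, the G4
#' intervals overlapping that bin.
#'
#' @param genome named \code{DNAStringSet}.
#' @param window sliding-window width (default 25, the original algorithm's).
#' @param threshold absolute mean-score threshold (default 1.2).
#' @param densityBin density-track bin width in bp (default 100).
#' @return A list: \code{intervals} (stranded \code{GRanges}) and
#'   \code{density} (a [BinnedTrack-class]).
#' @export
g4HunterScan <- function(genome, window = 25L, threshold = 1.2,
                         densityBin = 100L) {
  if (window < 1L || densityBin < 1L)
    stop("window and densityBin must be >= 1")
  sl <- genomeSeqlengths(genome)
  pieces <- lapply(names(genome), function(ctg) {
    chars <- strsplit(as.character(genome[[ctg]]), "")[[1]]
    n <- length(chars)
    if (n < window) return(GRanges(seqlengths = sl))
    sc <- g4BaseScores(chars)
    cs <- c(0, cumsum(sc))
    means <- (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
    hit <- abs(means) >= threshold
    if (!any(hit)) return(GRanges(seqlengths = sl))
    starts <- which(hit)
    sign <- ifelse(means[starts] > 0, "+", "-")
    ## merge same-sign qualifying windows separated by < window bp
    out <- list()
    curS <- starts[1]; curE <- starts[1] + window - 1L; curSign <- sign[1]
    for (i in seq_along(starts)[-1]) {
      if (sign[i] == curSign && starts[i] <= curE + window) {
        curE <- starts[i] + window - 1L
      } else {
        out[[length(out) + 1L]] <- c(curS, curE, curSign == "+")
        curS <- starts[i]; curE <- starts[i] + window - 1L
        curSign <- sign[i]
      }
    }
    out[[length(out) + 1L]] <- c(curS, curE, curSign == "+")
    m <- do.call(rbind, out)
    GRanges(ctg, IRanges(as.integer(m[, 1]), as.integer(m[, 2])),
            strand = ifelse(m[, 3] == 1, "+", "-"), seqlengths = sl)
  })
  intervals <- sort(do.call(c, pieces))
  density <- lapply(names(sl), function(ctg) {
    nb <- ceiling(sl[[ctg]] / densityBin)
    bins <- GRanges(ctg, IRanges((seq_len(nb) - 1L) * densityBin + 1L,
                                 pmin(seq_len(nb) * densityBin, sl[[ctg]])),
                    seqlengths = sl)
    as.numeric(countOverlaps(bins, intervals, ignore.strand = TRUE))
  })
  names(density) <- names(sl)
  list(intervals = intervals,
       density = binnedTrack(density, densityBin, sl))
}

#' Strand-aware metaprofile of a track around anchors
#'
#' Extracts the track around each anchor midpoint on the bin grid, averages
#' across anchors and reports a 95% confidence band (1.96 x SEM).  When
#' \code{strandAware}, minus-strand anchors are reversed so that profiles are
#' oriented 5'->3' along the anchor; with \code{signFlip} their values are
#' additionally negated (for strand-antisymmetric tracks such as GC skew,
#' this reads the track on the anchor's own strand).  Positions hanging off
#' contig ends, and missing bins, contribute nothing to the mean (they are
#' not imputed as 0).
#'
#' @param anchors a \code{GRanges}; midpoints are used as anchor points.
#' @param track a [BinnedTrack-class].
#' @param flank half-width in bp; must be a multiple of the track bin width.
#' @param strandAware reverse minus-strand anchors? (default TRUE)
#' @param signFlip negate values of minus-strand anchors? (default FALSE)
#' @return A data.frame with columns \code{rel_pos} (bp, bin offsets from the
#'   anchor bin), \code{mean}, \code{ci95}, \code{n} (anchors contributing).
#' @export
profileAround <- function(anchors, track, flank, strandAware = TRUE,
                          signFlip = FALSE) {
  if (length(anchors) == 0L) stop("no usable anchors")
  bw <- track@binWidth
  if (flank %% bw != 0) stop("flank must be a multiple of the bin width")
  k <- flank %/% bw
  offsets <- -k:k
  mids <- (start(anchors) + end(anchors)) %/% 2L
  ctg <- as.character(seqnames(anchors))
  neg <- strandAware & as.character(strand(anchors)) == "-"
  mat <- matrix(NA_real_, length(anchors), length(offsets))
  for (i in seq_along(anchors)) {
    v <- track@values[[ctg[i]]]
    if (is.null(v)) next
    bin <- (mids[i] - 1L) %/% bw + 1L
    idx <- bin + offsets
    ok <- idx >= 1L & idx <= length(v)
    row <- rep(NA_real_, length(offsets))
    row[ok] <- v[idx[ok]]
    if (neg[i]) {
      row <- rev(row)
      if (signFlip) row <- -row
    }
    mat[i, ] <- row
  }
  n <- as.integer(colSums(!is.na(mat)))
  if (all(n == 0L)) stop("no usable anchors")
  mean <- colMeans(mat, na.rm = TRUE)
  sdv <- apply(mat, 2L, sd, na.rm = TRUE)
  ci <- ifelse(n >= 2L, 1.96 * sdv / sqrt(n), 0)
  data.frame(rel_pos = offsets * bw, mean = mean, ci95 = ci, n = n)
}
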