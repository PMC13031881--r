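## Synthetic multi-omic data generator.  Every statistical structure the
## downstream stages assume is planted here with known effect sizes, so the
## whole pipeline can be validated by parameter recovery: displaced-strand GC
## skew, G4 motifs at R-loop 5' ends, TCW-motif C>T editing with a set strand
## concordance, omikli-like mutation clusters, condition-induced peak subsets
## under an NB count model, and DSB peaks whose knockdown dependence is
## conditional on sitting at an A3B/R-loop overlap.

G4_MOTIF <- "GGGTTAGGGTTAGGGTTAGGG"

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

## Lightweight per-contig interval bookkeeping for rejection sampling:
## conflicts() and add() operate on plain integer vectors, avoiding GRanges
## construction inside hot placement loops.
intervalAccumulator <- function(seqlengths, avoid = NULL) {
  env <- new.env(parent = emptyenv())
  for (ctg in names(seqlengths)) {
    s <- integer(0); e <- integer(0)
    if (!is.null(avoid) && length(avoid)) {
      sel <- as.character(seqnames(avoid)) == ctg
      s <- start(avoid)[sel]; e <- end(avoid)[sel]
    }
    assign(ctg, list(s = s, e = e), envir = env)
  }
  list(
    conflicts = function(ctg, s, e) {
      v <- get(ctg, envir = env)
      any(s <= v$e & e >= v$s)
    },
    add = function(ctg, s, e) {
      v <- get(ctg, envir = env)
      assign(ctg, list(s = c(v$s, s), e = c(v$e, e)), envir = env)
    })
}

## Place n non-overlapping intervals uniformly on the genome, avoiding a
## forbidden region set; bounded rejection sampling (explicit error on an
## overcrowded configuration).
randomIntervals <- function(n, lengthRange, seqlengths, avoid = NULL,
                            margin = 2L, maxRetry = 1000L,
                            selfGap = 0L) {
  if (n == 0L)
    return(GRanges(seqlengths = seqlengths))
  acc <- intervalAccumulator(seqlengths, avoid = avoid)
  contigProb <- as.numeric(seqlengths) / sum(as.numeric(seqlengths))
  outCtg <- character(n); outS <- integer(n); outLen <- integer(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(maxRetry)) {
      ctg <- sample(names(seqlengths), 1L, prob = contigProb)
      len <- if (lengthRange[1] == lengthRange[2]) lengthRange[1] else
        sample(lengthRange[1]:lengthRange[2], 1L)
      maxStart <- seqlengths[[ctg]] - len - margin + 1L
      if (maxStart <= margin) next
      start <- sample(margin:maxStart, 1L)
      if (acc$conflicts(ctg, start - selfGap, start + len - 1L + selfGap))
        next
      acc$add(ctg, start - selfGap, start + len - 1L + selfGap)
      outCtg[i] <- ctg; outS[i] <- start; outLen[i] <- len
      ok <- TRUE
      break
    }
    if (!ok)
      stop("interval placement failed after ", maxRetry,
           " retries (placed ", i - 1L, " of ", n,
           "): configuration too crowded")
  }
  sort(GRanges(outCtg, IRanges(outS, width = outLen),
               seqlengths = seqlengths))
}

## Place n intervals uniformly and independently (overlap permitted).
independentIntervals <- function(n, lengthRange, seqlengths, margin = 2L) {
  contigProb <- as.numeric(seqlengths) / sum(as.numeric(seqlengths))
  ctg <- sample(names(seqlengths), n, replace = TRUE, prob = contigProb)
  len <- sample(lengthRange[1]:lengthRange[2], n, replace = TRUE)
  maxStart <- seqlengths[ctg] - len - margin + 1L
  start <- margin + floor(runif(n) * (maxStart - margin + 1L))
  sort(GRanges(ctg, IRanges(as.integer(start), width = len),
               seqlengths = seqlengths))
}

## Sample n positions uniformly from an allowed region set; exact
## cumulative-width sampling, no rejection.
samplePositions <- function(n, allowed, replace = FALSE) {
  allowed <- reduce(allowed, ignore.strand = TRUE)
  w <- as.numeric(width(allowed))
  total <- sum(w)
  if (total < 1 || (!replace && total < n))
    stop("allowed space too small to sample ", n, " positions")
  offs <- sort(sample.int(total, n, replace = replace))
  cw <- cumsum(w)
  idx <- findInterval(offs - 1, c(0, cw), rightmost.closed = FALSE)
  pos <- start(allowed)[idx] + (offs - 1) - c(0, cw)[idx]
  GRanges(seqnames(allowed)[idx], IRanges(pos, width = 1L),
          seqlengths = seqlengths(allowed))
}

## ---------------------------------------------------------------------------
## generateGenome
## ---------------------------------------------------------------------------

#' Generate a synthetic genome with planted stranded R-loops
#'
#' The background sequence is i.i.d. with the configured GC fraction.  Inside
#' each R-loop, every strong (G/C) position carries G on the displaced strand
#' with probability \code{skewStrength}, so the expected displaced-strand GC
#' skew is \code{2*skewStrength - 1}.  With probability \code{g4PlantRate}, a
#' G-quadruplex motif (four G3 runs) is inserted at the R-loop's 5' end on
#' the displaced strand.  The BED strand column of a planted R-loop names its
#' displaced ssDNA strand; strands are Bernoulli(0.5).  R-loops are
#' non-overlapping by construction (bounded rejection sampling).
#'
#' @param config a [SyntheticConfig-class].
#' @return A list with elements \code{genome} (named \code{DNAStringSet}) and
#'   \code{rloops} (stranded \code{GRanges} with \code{name} and
#'   \code{g4_planted} metadata columns).
#' @examples
#' gg <- generateGenome(syntheticConfig(seed = 1,
#'   contigs = c(chrT = 50000L), nRloops = 10L))
#' gg$rloops
#' @export
generateGenome <- function(config) {
  validObject(config)
  set.seed(subSeed(config@seed, 1L))
  sl <- config@contigs
  gc <- config@gcContent
  baseProb <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars <- lapply(sl, function(len)
    sample(names(baseProb), len, replace = TRUE, prob = baseProb))

  rloops <- randomIntervals(config@nRloops, config@rloopLength, sl)
  strand(rloops) <- sample(c("+", "-"), length(rloops), replace = TRUE)
  mcols(rloops)$name <- sprintf("rloop_%04d", seq_along(rloops))
  mcols(rloops)$score <- 0L

  g4 <- strsplit(G4_MOTIF, "")[[1]]
  g4rc <- rev(COMPLEMENT[g4])
  g4Planted <- runif(length(rloops)) < config@g4PlantRate
  p <- config@skewStrength

  for (i in seq_along(rloops)) {
    ctg <- as.character(seqnames(rloops)[i])
    idx <- start(rloops)[i]:end(rloops)[i]
    seg <- chars[[ctg]][idx]
    strong <- seg %in% c("G", "C")
    nStrong <- sum(strong)
    if (nStrong) {
      dispBase <- ifelse(runif(nStrong) < p, "G", "C")
      refBase <- if (as.character(strand(rloops)[i]) == "+") dispBase
                 else unname(COMPLEMENT[dispBase])
      seg[strong] <- refBase
    }
    if (g4Planted[i] && length(seg) > length(g4)) {
      if (as.character(strand(rloops)[i]) == "+")
        seg[seq_along(g4)] <- g4
      else
        seg[(length(seg) - length(g4) + 1L):length(seg)] <- g4rc
    }
    chars[[ctg]][idx] <- seg
  }
  mcols(rloops)$g4_planted <- g4Planted

  genome <- DNAStringSet(vapply(chars, paste, "", collapse = ""))
  names(genome) <- names(sl)
  list(genome = genome, rloops = rloops)
}

## ---------------------------------------------------------------------------
## plantMutations
## ---------------------------------------------------------------------------

## TCW-motif centre positions (the edited C) on both strands, genome-wide.
## On the + strand the reference pattern is T-C-W; on the - strand it is
## W-G-A on the reference (whose reverse complement reads T-C-W).
tcwSites <- function(genome) {
  sl <- genomeSeqlengths(genome)
  pieces <- lapply(names(genome), function(ctg) {
    s <- strsplit(as.character(genome[[ctg]]), "")[[1]]
    n <- length(s)
    if (n < 3L) return(GRanges(seqlengths = sl))
    i <- 2:(n - 1L)
    plus <- i[s[i - 1L] == "T" & s[i] == "C" & s[i + 1L] %in% c("A", "T")]
    minus <- i[s[i - 1L] %in% c("A", "T") & s[i] == "G" & s[i + 1L] == "A"]
    GRanges(ctg, IRanges(c(plus, minus), width = 1L),
            strand = rep(c("+", "-"), c(length(plus), length(minus))),
            seqlengths = sl)
  })
  do.call(c, pieces)
}

refAt <- function(genome, gr) {
  vapply(seq_along(gr), function(i)
    as.character(subseq(genome[[as.character(seqnames(gr)[i])]],
                        start(gr)[i], start(gr)[i])), "")
}

#' Plant point mutations with known strand concordance and clusters
#'
#' Three mutation populations are planted, each with truth labels: (i)
#' \code{nRloopMut} C>T substitutions at TCW motifs inside R-loops, a fraction
#' \code{concordance} of which sit on the displaced strand (the rest on the
#' opposite, hybridised strand); (ii) \code{nClusters} omikli-like clusters of
#' \code{clusterSize} mutations within \code{clusterSpan} bp, placed in
#' windows isolated by at least \code{dGuard} bp from R-loops, from each other
#' and from background mutations so that cluster recall is identifiable at any
#' seed; (iii) \code{nBackgroundMut} diffuse mutations uniform over the
#' remaining genome.  Every record carries the actual reference base.
#'
#' Mutations are spread over a small panel of synthetic colonies: R-loop and
#' cluster mutations over the APOBEC-active colonies (\code{A1..A3}),
#' background mutations over all colonies.
#'
#' @param genome,rloops output of [generateGenome()].
#' @param config the same [SyntheticConfig-class].
#' @param rtTrack optional replication-timing [BinnedTrack-class]; when
#'   \code{config@rtEffect != 1}, background mutations are enriched in
#'   early-replicating bins by that rate ratio (rejection sampling).
#' @param dGuard isolation distance in bp for planted clusters (default 1500).
#' @return A width-1 \code{GRanges} sorted by position with metadata columns
#'   \code{ref}, \code{alt}, \code{sample}, \code{origin} (\code{rloop},
#'   \code{cluster}, \code{background}), \code{cluster_id},
#'   \code{pyr_strand} (strand carrying the pyrimidine of the planted change)
#'   and \code{concordant} (R-loop mutations only).
#' @export
plantMutations <- function(genome, rloops, config, rtTrack = NULL,
                           dGuard = 1500L) {
  set.seed(subSeed(config@seed, 2L))
  sl <- genomeSeqlengths(genome)
  samples <- c("A1", "A2", "A3", "B1", "B2")
  apobecSamples <- c("A1", "A2", "A3")

  ## --- R-loop TCW mutations -----------------------------------------------
  sites <- tcwSites(genome)
  hits <- findOverlaps(sites, rloops, ignore.strand = TRUE)
  inR <- sites[S4Vectors::queryHits(hits)]
  rStrand <- strand(rloops)[S4Vectors::subjectHits(hits)]
  onDisp <- as.character(strand(inR)) == as.character(rStrand)
  concFlag <- runif(config@nRloopMut) < config@concordance
  nConc <- sum(concFlag)
  nDisc <- config@nRloopMut - nConc
  concPool <- which(onDisp)
  discPool <- which(!onDisp)
  if (length(concPool) < nConc)
    stop("insufficient displaced-strand TCW sites in R-loops: need ", nConc,
         ", have ", length(concPool))
  if (length(discPool) < nDisc)
    stop("insufficient hybrid-strand TCW sites in R-loops: need ", nDisc,
         ", have ", length(discPool))
  pick <- c(sample(concPool, nConc), sample(discPool, nDisc))
  rmut <- inR[pick]
  pyr <- as.character(strand(rmut))
  rmutRef <- ifelse(pyr == "+", "C", "G")
  rmutAlt <- ifelse(pyr == "+", "T", "A")
  rdf <- GRanges(seqnames(rmut), IRanges(start(rmut), width = 1L),
                 ref = rmutRef, alt = rmutAlt,
                 sample = sample(apobecSamples, length(rmut), replace = TRUE),
                 origin = "rloop", cluster_id = NA_character_,
                 pyr_strand = pyr,
                 concordant = c(rep(TRUE, nConc), rep(FALSE, nDisc)),
                 seqlengths = sl)

  ## --- clustered mutations -------------------------------------------------
  guard <- reduce(GenomicRanges::trim(rloops + dGuard), ignore.strand = TRUE)
  windows <- randomIntervals(config@nClusters,
                             rep(config@clusterSpan, 2L), sl,
                             avoid = guard, selfGap = 2L * dGuard)
  cpieces <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    offs <- sort(sample.int(config@clusterSpan, config@clusterSize)) - 1L
    pos <- start(windows)[i] + offs
    ctg <- as.character(seqnames(windows)[i])
    gr <- GRanges(ctg, IRanges(pos, width = 1L), seqlengths = sl)
    ref <- refAt(genome, gr)
    alt <- vapply(ref, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    mcols(gr) <- DataFrame(ref = ref, alt = unname(alt),
                           sample = sample(apobecSamples, 1L),
                           origin = "cluster",
                           cluster_id = sprintf("cluster_%03d", i),
                           pyr_strand = ifelse(ref %in% c("C", "T"),
                                               "+", "-"),
                           concordant = NA)
    cpieces[[i]] <- gr
  }
  cdf <- do.call(c, cpieces)

  ## --- background mutations -------------------------------------------------
  whole <- GRanges(names(sl), IRanges(2L, sl - 1L), seqlengths = sl)
  excl <- reduce(c(guard, GenomicRanges::trim(windows + dGuard)),
                 ignore.strand = TRUE)
  allowed <- GenomicRanges::setdiff(whole, excl, ignore.strand = TRUE)
  bg <- samplePositions(config@nBackgroundMut, allowed)
  if (config@rtEffect != 1 && !is.null(rtTrack)) {
    ## enrich early-replicating (high-signal) bins by rtEffect via rejection
    q <- replicationQuartileOf(bg, rtTrack)
    w <- ifelse(!is.na(q) & q == 4L, 1, 1 / config@rtEffect)
    keep <- runif(length(bg)) < w
    need <- sum(!keep)
    while (need > 0) {
      extra <- samplePositions(need, allowed, replace = TRUE)
      qe <- replicationQuartileOf(extra, rtTrack)
      we <- ifelse(!is.na(qe) & qe == 4L, 1, 1 / config@rtEffect)
      acc <- extra[runif(length(extra)) < we]
      bg <- c(bg[keep], acc)
      keep <- rep(TRUE, length(bg))
      need <- config@nBackgroundMut - length(bg)
    }
    bg <- sort(bg)
  }
  bgRef <- refAt(genome, bg)
  bgAlt <- vapply(bgRef, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  mcols(bg) <- DataFrame(ref = bgRef, alt = unname(bgAlt),
                         sample = sample(samples, length(bg), replace = TRUE),
                         origin = "background",
                         cluster_id = NA_character_,
                         pyr_strand = ifelse(bgRef %in% c("C", "T"),
                                             "+", "-"),
                         concordant = NA)

  muts <- sort(c(rdf, cdf, bg), ignore.strand = TRUE)
  dup <- duplicated(paste(seqnames(muts), start(muts)))
  muts <- muts[!dup]
  muts
}

## quartile (1 = latest/lowest signal ... 4 = earliest/highest) of positions
## under a timing track; used by the generator's optional timing effect.
replicationQuartileOf <- function(pos, track) {
  gr <- trackAsGRanges(track, dropMissing = TRUE)
  v <- mcols(gr)$score
  qs <- quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE)
  hit <- findOverlaps(pos, gr, select = "first")
  q <- rep(NA_integer_, length(pos))
  ok <- !is.na(hit)
  q[ok] <- findInterval(v[hit[ok]], qs) + 1L
  q
}

## ---------------------------------------------------------------------------
## simulatePeakCounts
## ---------------------------------------------------------------------------

#' Simulate replicate peak counts with a condition-induced subset
#'
#' Counts follow a negative-binomial model: each peak has a lognormal baseline
#' mean centred on \code{meanCount} (sdlog \code{meanSdlog}); each sample has
#' a lognormal true size factor; a random subset of \code{fracInduced} peaks
#' is multiplied by \code{inducedFc} in the treated condition.  Dispersion 0
#' degenerates to Poisson.
#'
#' @param peaks a \code{GRanges} of features (only its length and names are
#'   used by the count model).
#' @param config a [SyntheticConfig-class]; \code{meanCount} must be positive.
#' @param seedOffset sub-seed offset so independent assays can reuse the model.
#' @return A \code{SummarizedExperiment}: assay \code{counts}; colData
#'   \code{condition} (control/treated) and \code{replicate}; rowData
#'   \code{induced} (truth flag) and \code{true_base_mean}; true size factors
#'   in \code{metadata()$trueSizeFactors}.
#' @export
simulatePeakCounts <- function(peaks, config, seedOffset = 3L) {
  if (config@meanCount <= 0) stop("meanCount must be positive")
  if (length(peaks) == 0L) stop("peaks must be non-empty")
  set.seed(subSeed(config@seed, seedOffset))
  n <- length(peaks)
  nrep <- config@nReplicates
  m <- 2L * nrep
  condition <- factor(rep(c("control", "treated"), each = nrep),
                      levels = c("control", "treated"))
  sf <- exp(rnorm(m, 0, 0.15))
  base <- config@meanCount * exp(rnorm(n, 0, config@meanSdlog))
  nInduced <- round(config@fracInduced * n)
  induced <- rep(FALSE, n)
  if (nInduced > 0) induced[sample.int(n, nInduced)] <- TRUE
  mu <- outer(base, sf)
  mu[induced, condition == "treated"] <-
    mu[induced, condition == "treated"] * config@inducedFc
  counts <- drawNB(mu, config@nbDispersion)
  featNames <- if (!is.null(mcols(peaks)$name)) mcols(peaks)$name
               else sprintf("peak_%05d", seq_len(n))
  dimnames(counts) <- list(featNames,
                           paste0(rep(c("ctrl_", "treat_"), each = nrep),
                                  "rep", seq_len(nrep)))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(induced = induced, true_base_mean = base),
    colData = DataFrame(condition = condition,
                        replicate = rep(seq_len(nrep), 2L),
                        row.names = colnames(counts)),
    metadata = list(trueSizeFactors = setNames(sf, colnames(counts))))
}

drawNB <- function(mu, dispersion) {
  counts <- if (dispersion > 0)
    rnbinom(length(mu), mu = as.vector(mu), size = 1 / dispersion)
  else
    rpois(length(mu), as.vector(mu))
  matrix(as.integer(counts), nrow = nrow(mu))
}

## ---------------------------------------------------------------------------
## binding peaks / DSB peaks
## ---------------------------------------------------------------------------

#' Simulate A3B binding peaks with a set R-loop overlap fraction
#'
#' \code{a3bRloopFrac} of the peaks are placed so they overlap a random
#' R-loop by at least 1 bp; the remainder avoid R-loops entirely.  Peaks are
#' mutually non-overlapping.
#'
#' @param rloops stranded R-loop \code{GRanges} from [generateGenome()].
#' @param config a [SyntheticConfig-class].
#' @return An unstranded \code{GRanges} with \code{name} and
#'   \code{rloop_overlap_planted} metadata columns.
#' @export
simulateBindingPeaks <- function(rloops, config) {
  set.seed(subSeed(config@seed, 4L))
  sl <- seqlengths(rloops)
  nOv <- round(config@nA3bPeaks * config@a3bRloopFrac)
  acc <- intervalAccumulator(sl)
  outCtg <- character(nOv); outS <- integer(nOv); outLen <- integer(nOv)
  rCtg <- as.character(seqnames(rloops))
  for (i in seq_len(nOv)) {
    ok <- FALSE
    for (try in seq_len(1000L)) {
      j <- sample.int(length(rloops), 1L)
      len <- sample(config@peakLength[1]:config@peakLength[2], 1L)
      ctg <- rCtg[j]
      lo <- max(2L, start(rloops)[j] - len + 1L)
      hi <- min(end(rloops)[j], sl[[ctg]] - len - 1L)
      if (hi < lo) next
      s <- sample(lo:hi, 1L)
      if (acc$conflicts(ctg, s, s + len - 1L)) next
      acc$add(ctg, s, s + len - 1L)
      outCtg[i] <- ctg; outS[i] <- s; outLen[i] <- len
      ok <- TRUE
      break
    }
    if (!ok) stop("A3B peak placement failed: configuration too crowded")
  }
  placed <- GRanges(outCtg, IRanges(outS, width = outLen),
                    seqlengths = sl)
  nFree <- config@nA3bPeaks - nOv
  free <- if (nFree > 0)
    randomIntervals(nFree, config@peakLength, sl,
                    avoid = reduce(c(granges(rloops), placed),
                                   ignore.strand = TRUE))
  else GRanges(seqlengths = sl)
  peaks <- sort(c(placed, free))
  mcols(peaks)$name <- sprintf("a3b_%04d", seq_along(peaks))
  mcols(peaks)$score <- 0L
  mcols(peaks)$rloop_overlap_planted <-
    overlapsAny(peaks, rloops, ignore.strand = TRUE)
  peaks
}

#' Simulate DSB peaks with R-loop-conditional knockdown dependence
#'
#' A fraction \code{dsbA3bRloopFrac} of DSB peaks is placed on A3B/R-loop
#' overlap regions; the rest avoid those regions.  Per-condition counts are
#' then simulated over a 2x2 design (vehicle/E2 by NT/siA3B, each with
#' \code{nReplicates} replicates): an E2-induced subset gains
#' \code{dsbE2Fc}-fold signal under E2, and peaks on A3B/R-loop overlaps have
#' their siA3B+E2 mean multiplied by \code{dsbDependenceRatio}, so the
#' expected class mean of log2(siA3B/NT) under E2 is
#' \code{log2(dsbDependenceRatio)} for that class and 0 elsewhere.
#'
#' @param a3bPeaks,rloops feature sets from [simulateBindingPeaks()] and
#'   [generateGenome()].
#' @param config a [SyntheticConfig-class].
#' @return A list with \code{peaks} (a \code{GRanges} with truth flags) and
#'   \code{se} (a \code{SummarizedExperiment} with colData \code{e2},
#'   \code{genotype}, \code{replicate}).
#' @export
simulateDsbPeaks <- function(a3bPeaks, rloops, config) {
  set.seed(subSeed(config@seed, 5L))
  sl <- seqlengths(rloops)
  both <- GenomicRanges::intersect(
    reduce(granges(a3bPeaks), ignore.strand = TRUE),
    reduce(granges(rloops), ignore.strand = TRUE),
    ignore.strand = TRUE)
  nBoth <- round(config@nDsb * config@dsbA3bRloopFrac)
  if (length(both) == 0L) nBoth <- 0L
  acc <- intervalAccumulator(sl)
  outCtg <- character(nBoth); outS <- integer(nBoth); outLen <- integer(nBoth)
  bCtg <- as.character(seqnames(both))
  for (i in seq_len(nBoth)) {
    ok <- FALSE
    for (try in seq_len(1000L)) {
      j <- sample.int(length(both), 1L)
      len <- sample(config@peakLength[1]:config@peakLength[2], 1L)
      ctg <- bCtg[j]
      lo <- max(2L, start(both)[j] - len + 1L)
      hi <- min(end(both)[j], sl[[ctg]] - len - 1L)
      if (hi < lo) next
      s <- sample(lo:hi, 1L)
      if (acc$conflicts(ctg, s, s + len - 1L)) next
      acc$add(ctg, s, s + len - 1L)
      outCtg[i] <- ctg; outS[i] <- s; outLen[i] <- len
      ok <- TRUE
      break
    }
    if (!ok) stop("DSB peak placement failed: configuration too crowded")
  }
  placed <- GRanges(outCtg, IRanges(outS, width = outLen),
                    seqlengths = sl)
  nFree <- config@nDsb - nBoth
  free <- if (nFree > 0)
    randomIntervals(nFree, config@peakLength, sl,
                    avoid = reduce(c(both, placed), ignore.strand = TRUE))
  else GRanges(seqlengths = sl)
  peaks <- sort(c(placed, free))
  mcols(peaks)$name <- sprintf("dsb_%04d", seq_along(peaks))
  mcols(peaks)$score <- 0L
  mcols(peaks)$overlaps_a3b <- overlapsAny(peaks, a3bPeaks,
                                           ignore.strand = TRUE)
  mcols(peaks)$overlaps_rloop <- overlapsAny(peaks, rloops,
                                             ignore.strand = TRUE)
  dependent <- mcols(peaks)$overlaps_a3b & mcols(peaks)$overlaps_rloop

  n <- length(peaks)
  nrep <- config@nReplicates
  e2 <- factor(rep(rep(c("vehicle", "E2"), each = nrep), 2L),
               levels = c("vehicle", "E2"))
  genotype <- factor(rep(c("NT", "siA3B"), each = 2L * nrep),
                     levels = c("NT", "siA3B"))
  m <- length(e2)
  sf <- exp(rnorm(m, 0, 0.15))
  base <- config@meanCount * exp(rnorm(n, 0, config@meanSdlog))
  e2Induced <- runif(n) < config@dsbE2Frac
  mu <- outer(base, sf)
  mu[e2Induced, e2 == "E2"] <- mu[e2Induced, e2 == "E2"] * config@dsbE2Fc
  sel <- dependent
  cols <- e2 == "E2" & genotype == "siA3B"
  mu[sel, cols] <- mu[sel, cols] * config@dsbDependenceRatio
  counts <- drawNB(mu, config@nbDispersion)
  cn <- paste0(ifelse(genotype == "NT", "NT_", "si_"),
               ifelse(e2 == "E2", "E2_", "veh_"),
               "rep", rep(seq_len(nrep), 4L))
  dimnames(counts) <- list(mcols(peaks)$name, cn)
  mcols(peaks)$e2_induced_planted <- e2Induced
  mcols(peaks)$dependent_planted <- dependent
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(e2_induced = e2Induced, dependent = dependent,
                        overlaps_a3b = mcols(peaks)$overlaps_a3b,
                        overlaps_rloop = mcols(peaks)$overlaps_rloop),
    colData = DataFrame(e2 = e2, genotype = genotype,
                        replicate = rep(seq_len(nrep), 4L),
                        row.names = cn),
    metadata = list(trueSizeFactors = setNames(sf, cn)))
  list(peaks = peaks, se = se)
}

## ---------------------------------------------------------------------------
## auxiliary tracks and annotations
## ---------------------------------------------------------------------------

#' Simulate a smooth replication-timing track
#'
#' A sinusoid along each contig (period 300 kb) with Gaussian noise, binned at
#' \code{rtBin}; higher values mean earlier replication.
#'
#' @param config a [SyntheticConfig-class].
#' @return A [BinnedTrack-class].
#' @export
simulateTimingTrack <- function(config) {
  set.seed(subSeed(config@seed, 6L))
  sl <- config@contigs
  bw <- config@rtBin
  values <- lapply(sl, function(len) {
    n <- ceiling(len / bw)
    mid <- ((seq_len(n) - 0.5) * bw)
    sin(2 * pi * mid / 3e5) + rnorm(n, 0, 0.1)
  })
  binnedTrack(values, bw, sl)
}

#' Simulate a chromatin-state segmentation
#'
#' Partitions each contig into labelled segments with approximately
#' exponential lengths (mean \code{stateMeanLength}, floor 200 bp); states are
#' drawn uniformly from a fixed 6-label alphabet.
#'
#' @param config a [SyntheticConfig-class].
#' @return A \code{GRanges} partition with a \code{name} column holding the
#'   state label.
#' @export
simulateSegmentation <- function(config) {
  set.seed(subSeed(config@seed, 7L))
  sl <- config@contigs
  labels <- c("Tss", "Enh", "Tx", "ReprPC", "Het", "Quies")
  labels <- labels[seq_len(min(config@nStates, length(labels)))]
  pieces <- lapply(names(sl), function(ctg) {
    len <- sl[[ctg]]
    lens <- integer(0)
    total <- 0
    while (total < len) {
      l <- max(200L, as.integer(round(stats::rexp(1, 1 / config@stateMeanLength))))
      lens <- c(lens, l)
      total <- total + l
    }
    ends <- pmin(cumsum(lens), len)
    starts <- c(1L, head(ends, -1L) + 1L)
    keep <- starts <= ends
    GRanges(ctg, IRanges(starts[keep], ends[keep]),
            name = sample(labels, sum(keep), replace = TRUE),
            seqlengths = sl)
  })
  seg <- do.call(c, pieces)
  mcols(seg)$score <- 0L
  seg
}

#' Simulate a toy TSS annotation
#'
#' @param config a [SyntheticConfig-class].
#' @return A width-1 stranded \code{GRanges} with gene \code{name}s.
#' @export
simulateTss <- function(config) {
  set.seed(subSeed(config@seed, 8L))
  sl <- config@contigs
  whole <- GRanges(names(sl), IRanges(2L, sl - 1L), seqlengths = sl)
  tss <- sort(samplePositions(config@nGenes, whole))
  strand(tss) <- sample(c("+", "-"), length(tss), replace = TRUE)
  mcols(tss)$name <- sprintf("gene_%04d", seq_along(tss))
  mcols(tss)$score <- 0L
  tss
}

#' Simulate gene sets (one R-loop-linked set plus random sets)
#'
#' The \code{rloop_proximal} set contains every gene whose TSS lies within
#' 5 kb of an R-loop; three further sets are random draws.
#'
#' @param tss TSS annotation from [simulateTss()].
#' @param rloops R-loop peaks.
#' @param config a [SyntheticConfig-class].
#' @return A data.frame with columns \code{set} and \code{gene}.
#' @export
simulateGeneSets <- function(tss, rloops, config) {
  set.seed(subSeed(config@seed, 9L))
  near <- overlapsAny(tss, GenomicRanges::trim(rloops + 5000L),
                      ignore.strand = TRUE)
  sets <- list(rloop_proximal = mcols(tss)$name[near])
  for (k in 1:3)
    sets[[paste0("random_set_", k)]] <-
      sample(mcols(tss)$name, min(30L, length(tss)))
  data.frame(set = rep(names(sets), lengths(sets)),
             gene = unlist(sets, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Derive jittered replicate peak sets from a consensus truth
#'
#' Each replicate keeps each peak with probability \code{1 - dropout} and
#' jitters both ends uniformly by up to \code{jitter} bp; used to exercise
#' consensus-peak construction.
#'
#' @param peaks truth peaks.
#' @param config a [SyntheticConfig-class] (\code{nReplicates} sets the
#'   number of replicates).
#' @param dropout per-replicate peak dropout probability.
#' @param jitter maximal end jitter in bp.
#' @return A \code{GRangesList}, one element per replicate.
#' @export
simulateReplicatePeaks <- function(peaks, config, dropout = 0.1,
                                   jitter = 50L) {
  set.seed(subSeed(config@seed, 10L))
  sl <- seqlengths(peaks)
  reps <- lapply(seq_len(config@nReplicates), function(r) {
    keep <- runif(length(peaks)) >= dropout
    p <- peaks[keep]
    ds <- sample(-jitter:jitter, length(p), replace = TRUE)
    de <- sample(-jitter:jitter, length(p), replace = TRUE)
    ns <- pmax(1L, start(p) + ds)
    ne <- pmin(sl[as.character(seqnames(p))], end(p) + de)
    bad <- ns >= ne
    ns[bad] <- start(p)[bad]; ne[bad] <- end(p)[bad]
    GRanges(seqnames(p), IRanges(ns, ne), strand = strand(p),
            name = mcols(p)$name, score = 0L, seqlengths = sl)
  })
  names(reps) <- paste0("rep", seq_along(reps))
  GRangesList(reps)
}

## ---------------------------------------------------------------------------
## orchestration + bundle writing
## ---------------------------------------------------------------------------

#' Build the full synthetic dataset in memory
#'
#' Runs every generator stage in dependency order under the config's seed.
#'
#' @param config a [SyntheticConfig-class].
#' @return A named list with the genome, all planted feature sets, count
#'   experiments, auxiliary tracks and annotations.
#' @export
buildSyntheticData <- function(config) {
  gg <- generateGenome(config)
  rtTrack <- simulateTimingTrack(config)
  muts <- plantMutations(gg$genome, gg$rloops, config, rtTrack = rtTrack)
  ## SPI peaks are dense (a peak atlas); mutual overlap is permitted because
  ## their counts are simulated directly rather than counted from fragments
  set.seed(subSeed(config@seed, 11L))
  spiPeaks <- independentIntervals(config@nPeaks, config@peakLength,
                                   config@contigs)
  mcols(spiPeaks)$name <- sprintf("spi_%05d", seq_along(spiPeaks))
  mcols(spiPeaks)$score <- 0L
  spiCounts <- simulatePeakCounts(spiPeaks, config, seedOffset = 3L)
  spiReplicates <- simulateReplicatePeaks(spiPeaks, config)
  a3bPeaks <- simulateBindingPeaks(gg$rloops, config)
  dsb <- simulateDsbPeaks(a3bPeaks, gg$rloops, config)
  segmentation <- simulateSegmentation(config)
  tss <- simulateTss(config)
  geneSets <- simulateGeneSets(tss, gg$rloops, config)
  list(config = config, genome = gg$genome, rloops = gg$rloops,
       mutations = muts, spiPeaks = spiPeaks, spiCounts = spiCounts,
       spiReplicates = spiReplicates, a3bPeaks = a3bPeaks,
       dsbPeaks = dsb$peaks, dsbCounts = dsb$se, rtTrack = rtTrack,
       segmentation = segmentation, tss = tss, geneSets = geneSets)
}

#' Write a synthetic dataset to standard-format files
#'
#' Emits FASTA, VCF v4.2, BED6, bedGraph and TSV files plus truth tables for
#' every planted element; the bundle round-trips through the package's
#' readers without loss.
#'
#' @param synth output of [buildSyntheticData()].
#' @param dir output directory (created if needed).
#' @return A [FixtureBundle-class] recording every path.
#' @export
writeFixtureBundle <- function(synth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sl <- genomeSeqlengths(synth$genome)
  paths <- c(
    genome = "genome.fa", mutations = "mutations.vcf",
    rloops = "rloops.bed", a3b = "a3b_peaks.bed",
    dsb = "dsb_peaks.bed", spi = "spi_peaks.bed",
    spi_counts = "spi_counts.tsv", spi_samples = "spi_samples.tsv",
    dsb_counts = "dsb_counts.tsv", dsb_samples = "dsb_samples.tsv",
    timing = "replication_timing.bedGraph",
    states = "chromatin_states.bed", tss = "tss.bed",
    gene_sets = "gene_sets.tsv",
    truth_rloops = "truth_rloops.tsv",
    truth_mutations = "truth_mutations.tsv",
    truth_peaks = "truth_peaks.tsv",
    truth_dsb = "truth_dsb.tsv")
  reps <- paste0("spi_", names(synth$spiReplicates), ".bed")
  names(reps) <- paste0("spi_", names(synth$spiReplicates))
  paths <- c(paths, reps)
  fp <- function(nm) file.path(dir, paths[[nm]])

  writeGenomeFasta(synth$genome, fp("genome"))
  writeMutationsVcf(synth$mutations, fp("mutations"), sl)
  writeBed6(synth$rloops, fp("rloops"))
  writeBed6(synth$a3bPeaks, fp("a3b"))
  writeBed6(synth$dsbPeaks, fp("dsb"))
  writeBed6(synth$spiPeaks, fp("spi"))
  for (nm in names(synth$spiReplicates))
    writeBed6(synth$spiReplicates[[nm]],
              file.path(dir, paste0("spi_", nm, ".bed")))
  writeCountsTsv(SummarizedExperiment::assay(synth$spiCounts),
                 fp("spi_counts"))
  writeTsv(as.data.frame(SummarizedExperiment::colData(synth$spiCounts)) |>
             (\(d) cbind(sample = rownames(d), d))(),
           fp("spi_samples"))
  writeCountsTsv(SummarizedExperiment::assay(synth$dsbCounts),
                 fp("dsb_counts"))
  writeTsv(as.data.frame(SummarizedExperiment::colData(synth$dsbCounts)) |>
             (\(d) cbind(sample = rownames(d), d))(),
           fp("dsb_samples"))
  writeBedGraph(synth$rtTrack, fp("timing"))
  writeBed6(synth$segmentation, fp("states"))
  writeBed6(synth$tss, fp("tss"))
  writeTsv(synth$geneSets, fp("gene_sets"))

  writeTsv(data.frame(
    name = mcols(synth$rloops)$name,
    contig = as.character(seqnames(synth$rloops)),
    start0 = start(synth$rloops) - 1L, end = end(synth$rloops),
    displaced_strand = as.character(strand(synth$rloops)),
    g4_planted = mcols(synth$rloops)$g4_planted), fp("truth_rloops"))
  m <- synth$mutations
  writeTsv(data.frame(
    contig = as.character(seqnames(m)), pos = start(m),
    ref = mcols(m)$ref, alt = mcols(m)$alt, sample = mcols(m)$sample,
    origin = mcols(m)$origin, cluster_id = mcols(m)$cluster_id,
    pyr_strand = mcols(m)$pyr_strand,
    concordant = mcols(m)$concordant), fp("truth_mutations"))
  writeTsv(data.frame(
    feature = rownames(synth$spiCounts),
    induced = SummarizedExperiment::rowData(synth$spiCounts)$induced),
    fp("truth_peaks"))
  writeTsv(data.frame(
    feature = rownames(synth$dsbCounts),
    e2_induced = SummarizedExperiment::rowData(synth$dsbCounts)$e2_induced,
    dependent = SummarizedExperiment::rowData(synth$dsbCounts)$dependent,
    overlaps_a3b =
      SummarizedExperiment::rowData(synth$dsbCounts)$overlaps_a3b,
    overlaps_rloop =
      SummarizedExperiment::rowData(synth$dsbCounts)$overlaps_rloop),
    fp("truth_dsb"))

  new("FixtureBundle", dir = dir, paths = paths)
}
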