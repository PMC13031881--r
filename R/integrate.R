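## Strand-aware interval integration: proximity classification, displaced-
## strand concordance, enrichment against random genomic sites, chromatin-
## state fold enrichment, replication-timing quartile rates, GREAT-style
## region-to-gene assignment, and the chi-square scaffolding they share.

#' Two-sided chi-square test for a 2x2 table
#'
#' Closed form: \eqn{\chi^2 = n(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))}, with the
#' optional Yates continuity correction; the p-value is the upper tail of the
#' chi-square distribution with one degree of freedom.
#'
#' @param table 2x2 numeric matrix of counts.
#' @param yates apply the continuity correction? (default FALSE)
#' @return A list with \code{statistic} and \code{p}.
#' @examples
#' chiSquare2x2(matrix(c(10, 30, 20, 40), 2))
#' @export
chiSquare2x2 <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0)) stop("counts must be non-negative")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0))
    stop("zero margin: chi-square undefined, consider an exact test")
  num <- abs(a * d - b * c)
  if (yates) num <- max(0, num - n / 2)
  stat <- n * num^2 / prod(margins)
  list(statistic = stat, p = pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Classify query intervals by proximity to a reference set
#'
#' Each query is \code{overlapping} (>= 1 bp intersection), \code{proximal}
#' (end-to-end gap <= \code{d}) or \code{distal}.  In stranded mode the
#' reference is restricted to intervals on the query's strand.
#'
#' @param query,reference \code{GRanges} on the same genome.
#' @param d proximity distance in bp (default 1500, i.e. +/- 1.5 kb).
#' @param stranded restrict reference to matching strand? (default FALSE)
#' @return A list: \code{label} (factor per query), \code{fractions} (named
#'   numeric summary), \code{distance} (gap to nearest reference; 0 when
#'   overlapping, NA when no reference on the relevant strand).
#' @export
classifyProximity <- function(query, reference, d = 1500L,
                              stranded = FALSE) {
  if (d < 0) stop("d must be >= 0")
  lv <- c("overlapping", "proximal", "distal")
  if (length(reference) == 0L) {
    warning("empty reference set: all queries classified distal")
    lab <- factor(rep("distal", length(query)), levels = lv)
    return(list(label = lab,
                fractions = c(overlapping = 0, proximal = 0,
                              distal = as.numeric(length(query) > 0)),
                distance = rep(NA_real_, length(query))))
  }
  ignoreStrand <- !stranded
  dist <- rep(NA_real_, length(query))
  hits <- distanceToNearest(query, reference, ignore.strand = ignoreStrand)
  dist[S4Vectors::queryHits(hits)] <- mcols(hits)$distance
  lab <- ifelse(is.na(dist), "distal",
                ifelse(dist == 0 &
                         overlapsAny(query, reference,
                                     ignore.strand = ignoreStrand),
                       "overlapping",
                       ifelse(dist <= d, "proximal", "distal")))
  lab <- factor(lab, levels = lv)
  fr <- as.numeric(table(lab)) / max(1L, length(query))
  list(label = lab, fractions = setNames(fr, lv), distance = dist)
}

#' Strand concordance of mutations with R-loop displaced strands
#'
#' For mutations lying inside stranded R-loops, a mutation is concordant iff
#' its pyrimidine strand equals the R-loop's displaced strand (the BED strand
#' column; flip the interpretation upstream with
#' \code{rloopStrandMeans = "hybrid"} if your ssDRIP convention records the
#' hybridised strand).  Mutations inside two opposite-strand R-loops are
#' excluded and counted.  Also returns a 2x2 association table of
#' (inside/outside R-loop) x (pyrimidine strand equals strand of the nearest
#' R-loop), with its chi-square test.
#'
#' @param muts width-1 \code{GRanges} with a \code{pyr_strand} metadata
#'   column (from [classifySubstitution()]).
#' @param rloops stranded \code{GRanges}.
#' @param rloopStrandMeans \code{"displaced"} (default) or \code{"hybrid"}:
#'   what the R-loop strand column denotes; \code{"hybrid"} flips it.
#' @return A list: \code{fraction}, \code{ci} (exact binomial 95% CI),
#'   \code{n}, \code{excluded} (ambiguous overlaps), \code{table},
#'   \code{chisq}, \code{p}.  With no overlapping mutation, \code{fraction}
#'   is \code{NA} and \code{n} is 0.
#' @export
strandConcordance <- function(muts, rloops,
                              rloopStrandMeans = c("displaced", "hybrid")) {
  rloopStrandMeans <- match.arg(rloopStrandMeans)
  disp <- as.character(strand(rloops))
  if (rloopStrandMeans == "hybrid")
    disp <- chartr("+-", "-+", disp)
  pyr <- as.character(mcols(muts)$pyr_strand)
  if (is.null(pyr)) stop("muts must carry a pyr_strand column")
  hits <- findOverlaps(muts, rloops, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  hitStrand <- split(disp[S4Vectors::subjectHits(hits)], q)
  nStrand <- vapply(hitStrand, function(s) length(unique(s)), 0L)
  ambiguous <- as.integer(names(nStrand)[nStrand > 1L])
  inside <- setdiff(unique(q), ambiguous)
  if (length(inside) == 0L) {
    return(list(fraction = NA_real_, ci = c(NA_real_, NA_real_), n = 0L,
                excluded = length(ambiguous), table = NULL,
                chisq = NA_real_, p = NA_real_))
  }
  strandOf <- vapply(hitStrand, `[`, "", 1L)
  conc <- pyr[inside] == strandOf[as.character(inside)]
  bt <- binom.test(sum(conc), length(conc))
  outside <- setdiff(seq_along(muts), unique(q))
  tab <- NULL; chisq <- NA_real_; p <- NA_real_
  if (length(outside) && length(rloops)) {
    near <- distanceToNearest(muts[outside], rloops, ignore.strand = TRUE)
    oConc <- rep(NA, length(outside))
    oConc[S4Vectors::queryHits(near)] <-
      pyr[outside][S4Vectors::queryHits(near)] ==
        disp[S4Vectors::subjectHits(near)]
    oConc <- oConc[!is.na(oConc)]
    tab <- matrix(c(sum(conc), sum(!conc), sum(oConc), sum(!oConc)), 2L,
                  dimnames = list(c("concordant", "discordant"),
                                  c("inside", "outside")))
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      cs <- chiSquare2x2(t(tab))
      chisq <- cs$statistic; p <- cs$p
    }
  }
  list(fraction = mean(conc), ci = as.numeric(bt$conf.int),
       n = length(conc), excluded = length(ambiguous), table = tab,
       chisq = chisq, p = p)
}

#' Sample random genomic sites
#'
#' Positions are uniform over the genome minus an exclusion set, drawn by
#' exact cumulative-width sampling (with replacement), and fully seeded.
#'
#' @param seqlengths named integer contig lengths.
#' @param n number of sites (the reference analysis uses 1e6).
#' @param seed integer seed.
#' @param exclude optional \code{GRanges} to exclude.
#' @return A width-1 \code{GRanges} of \code{n} sites.
#' @export
randomSiteSample <- function(seqlengths, n, seed = 1L, exclude = NULL) {
  whole <- GRanges(names(seqlengths), IRanges(1L, seqlengths),
                   seqlengths = seqlengths)
  allowed <- if (is.null(exclude) || length(exclude) == 0L) whole
             else GenomicRanges::setdiff(whole, exclude,
                                         ignore.strand = TRUE)
  if (length(allowed) == 0L || sum(as.numeric(width(allowed))) == 0)
    stop("exclusion set covers the genome: no positions to sample")
  set.seed(seed)
  samplePositions(n, allowed, replace = TRUE)
}

#' Assign sites to their highest-priority annotation category
#'
#' @param sites a \code{GRanges}.
#' @param catalogue an [AnnotationCatalogue-class].
#' @return A factor with catalogue categories plus \code{"intergenic"}.
#' @export
assignCategory <- function(sites, catalogue) {
  ord <- order(catalogue@priority)
  cats <- names(catalogue@regions)[ord]
  lab <- rep("intergenic", length(sites))
  unassigned <- rep(TRUE, length(sites))
  for (cat in cats) {
    hit <- unassigned & overlapsAny(sites, catalogue@regions[[cat]],
                                    ignore.strand = TRUE)
    lab[hit] <- cat
    unassigned[hit] <- FALSE
  }
  factor(lab, levels = c(cats, "intergenic"))
}

#' Consequence-category enrichment of variants versus random sites
#'
#' Each variant and random site is assigned its highest-priority overlapping
#' category; per category, a 2x2 table (variant/random x in-category/not) is
#' tested by two-sided chi-square, with Benjamini-Hochberg adjustment across
#' categories (raw p-values are also reported).
#'
#' @param variants width-1 \code{GRanges}.
#' @param catalogue an [AnnotationCatalogue-class].
#' @param randomSites background sites from [randomSiteSample()].
#' @return A data.frame with per-category counts, fractions, fold enrichment,
#'   chi-square statistic, raw p and BH-adjusted fdr.
#' @export
consequenceEnrichment <- function(variants, catalogue, randomSites) {
  vCat <- assignCategory(variants, catalogue)
  rCat <- assignCategory(randomSites, catalogue)
  cats <- levels(vCat)
  nv <- length(variants); nr <- length(randomSites)
  rows <- lapply(cats, function(cat) {
    a <- sum(vCat == cat); b <- nv - a
    c <- sum(rCat == cat); d <- nr - c
    fv <- a / nv; fr <- c / nr
    tab <- matrix(c(a, c, b, d), 2L)
    ok <- all(rowSums(tab) > 0) && all(colSums(tab) > 0)
    cs <- if (ok) chiSquare2x2(tab) else list(statistic = NA_real_,
                                              p = NA_real_)
    data.frame(category = cat, n_variant = a, frac_variant = fv,
               n_random = c, frac_random = fr,
               fold = if (fr > 0) fv / fr else NA_real_,
               chisq = cs$statistic, p = cs$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, method = "BH")
  out
}

#' Chromatin-state fold enrichment of target regions
#'
#' Enrichment(state) = (target bases in state / total target bases) divided
#' by (state bases / genome bases).  Point targets (e.g. SNVs) are expanded
#' by \code{flank} bp on each side; with \code{flank = 0} the full-length
#' input intervals are used.  Target coverage is reduced before counting so
#' overlapping targets are not double-counted.
#'
#' @param targets a \code{GRanges}.
#' @param segmentation a \code{GRanges} partition with state labels in its
#'   \code{name} column.
#' @param flank bp added on each side of each target (default 0).
#' @param seqlengths named contig lengths (genome size); taken from
#'   \code{segmentation} when omitted.
#' @return A data.frame with per-state base counts and fold enrichment
#'   (\code{NA} for states with zero genomic bases).
#' @export
stateEnrichment <- function(targets, segmentation, flank = 0L,
                            seqlengths = NULL) {
  if (flank < 0) stop("flank must be >= 0")
  if (is.null(seqlengths)) seqlengths <- seqlengths(segmentation)
  if (any(is.na(seqlengths)))
    stop("segmentation must carry seqlengths (or pass them explicitly)")
  genomeBases <- sum(as.numeric(seqlengths))
  expanded <- if (flank > 0) {
    ctg <- as.character(seqnames(targets))
    GRanges(ctg,
            IRanges(pmax(1L, start(targets) - flank),
                    pmin(as.integer(seqlengths[ctg]),
                         end(targets) + flank)),
            seqlengths = seqlengths)
  } else granges(targets)
  cov <- reduce(expanded, ignore.strand = TRUE)
  totalTarget <- sum(as.numeric(width(cov)))
  states <- sort(unique(mcols(segmentation)$name))
  rows <- lapply(states, function(st) {
    sreg <- reduce(segmentation[mcols(segmentation)$name == st],
                   ignore.strand = TRUE)
    stateBases <- sum(as.numeric(width(sreg)))
    inState <- sum(as.numeric(width(
      GenomicRanges::intersect(cov, sreg, ignore.strand = TRUE))))
    enr <- if (stateBases == 0 || totalTarget == 0) NA_real_
           else (inState / totalTarget) / (stateBases / genomeBases)
    data.frame(state = st, target_bases = inState,
               state_bases = stateBases, enrichment = enr,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Relative mutation rates across replication-timing quartiles
#'
#' Covered genome bins are split into four equal-size quartiles by timing
#' value (Q1 = latest replicating = lowest signal, Q4 = earliest = highest;
#' ties broken by stable sort on (value, contig, bin index)).  The per-
#' quartile rate is mutations per covered Mb, normalised to the latest
#' quartile.
#'
#' @param muts width-1 \code{GRanges}.
#' @param track a replication-timing [BinnedTrack-class]; higher = earlier.
#' @return A data.frame with per-quartile mutation counts, covered Mb, rates
#'   and relative rates; the number of mutations on uncovered bins is in
#'   \code{attr(, "excluded")}.
#' @export
replicationQuartileRates <- function(muts, track) {
  bins <- trackAsGRanges(track, dropMissing = FALSE)
  v <- mcols(bins)$score
  covered <- which(!is.na(v))
  if (!length(covered)) stop("timing track has no covered bins")
  ord <- covered[order(v[covered], as.character(seqnames(bins))[covered],
                       covered, method = "radix")]
  nq <- 4L
  qsize <- floor(length(ord) / nq)
  qOfSorted <- rep(nq, length(ord))
  qOfSorted[seq_len(qsize * nq)] <- rep(seq_len(nq), each = qsize)
  quartile <- rep(NA_integer_, length(bins))
  quartile[ord] <- qOfSorted
  hit <- findOverlaps(muts, bins, select = "first")
  mq <- quartile[hit]
  excluded <- sum(is.na(mq))
  rows <- lapply(seq_len(nq), function(q) {
    nmut <- sum(mq == q, na.rm = TRUE)
    mb <- sum(as.numeric(width(bins)[which(quartile == q)])) / 1e6
    data.frame(quartile = paste0("Q", q),
               timing = c("latest", "late", "early", "earliest")[q],
               n_mut = nmut, mb = mb, rate = nmut / mb)
  })
  out <- do.call(rbind, rows)
  out$rel_rate <- out$rate / out$rate[1]
  attr(out, "excluded") <- excluded
  out
}

#' GREAT-style region-to-gene association (basal plus extension)
#'
#' Each gene gets a basal regulatory domain around its TSS (strand-aware,
#' default 5 kb upstream / 1 kb downstream), extended in both directions up
#' to the nearest neighbouring basal domain on the same contig, capped at
#' \code{extension} bp from the basal edge.  A region is associated with
#' every gene whose regulatory domain it intersects.  The downstream binomial
#' genomic-coverage test is out of scope; this implements the association
#' rule only.
#'
#' @param regions a \code{GRanges}.
#' @param tss width-1 stranded \code{GRanges} with gene \code{name}s.
#' @param basalUp,basalDown basal domain extent upstream/downstream of the
#'   TSS in bp (defaults 5000 / 1000).
#' @param extension maximal extension from the basal edge in bp (default
#'   1 Mb).
#' @return A data.frame with columns \code{region} (index into
#'   \code{regions}), \code{gene}; and the computed domains in
#'   \code{attr(, "domains")}.
#' @export
regionToGene <- function(regions, tss, basalUp = 5000L, basalDown = 1000L,
                         extension = 1000000L) {
  if (is.null(mcols(tss)$name)) stop("tss must carry gene names")
  plus <- as.character(strand(tss)) != "-"
  pos <- start(tss)
  basalStart <- ifelse(plus, pos - basalUp, pos - basalDown)
  basalEnd <- ifelse(plus, pos + basalDown, pos + basalUp)
  sl <- seqlengths(tss)
  ctg <- as.character(seqnames(tss))
  basalStart <- pmax(1L, basalStart)
  if (!any(is.na(sl))) basalEnd <- pmin(as.integer(sl[ctg]), basalEnd)
  domStart <- basalStart; domEnd <- basalEnd
  for (ct in unique(ctg)) {
    idx <- which(ctg == ct)
    ord <- idx[order(basalStart[idx], basalEnd[idx])]
    for (j in seq_along(ord)) {
      i <- ord[j]
      others <- setdiff(idx, i)
      leftEnds <- basalEnd[others][basalEnd[others] <= basalStart[i]]
      leftLimit <- if (length(leftEnds)) max(leftEnds) + 1L else 1L
      domStart[i] <- min(basalStart[i],
                         max(leftLimit, basalStart[i] - extension))
      rightStarts <- basalStart[others][basalStart[others] >= basalEnd[i]]
      ctgLen <- if (!any(is.na(sl))) as.integer(sl[ct]) else
        .Machine$integer.max %/% 2L
      rightLimit <- if (length(rightStarts)) min(rightStarts) - 1L
                    else ctgLen
      domEnd[i] <- max(basalEnd[i],
                       min(rightLimit, basalEnd[i] + extension))
    }
  }
  domains <- GRanges(ctg, IRanges(pmax(1L, domStart), domEnd),
                     strand = strand(tss), name = mcols(tss)$name)
  hits <- findOverlaps(regions, domains, ignore.strand = TRUE)
  out <- data.frame(region = S4Vectors::queryHits(hits),
                    gene = mcols(domains)$name[S4Vectors::subjectHits(hits)],
                    stringsAsFactors = FALSE)
  attr(out, "domains") <- domains
  out
}
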