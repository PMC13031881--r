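## Differential peak occupancy: consensus construction across replicates,
## fragment counting, median-of-ratios normalisation, a transparent NB/Wald
## test (single factor and two-factor interaction) and threshold-based
## classification of induced features.

#' Consensus peaks across replicates
#'
#' Overlapping peaks (>= 1 bp, chained across replicates) are grouped into
#' connected components; components supported by at least
#' \code{minRecurrence} distinct replicates are retained as their merged
#' extent.  Retained peaks on the same strand separated by at most
#' \code{mergeWithin} bp are then merged.  In unstranded mode strand is
#' ignored throughout and the result is unstranded.
#'
#' @param peakSets a \code{GRangesList} (or list of \code{GRanges}), one
#'   element per replicate.
#' @param minRecurrence minimal number of supporting replicates (default 2).
#' @param mergeWithin merge gap in bp (default 1000).
#' @param stranded respect strand? (default TRUE)
#' @return A \code{GRanges} with an \code{n_replicates} metadata column
#'   (support of each pre-merge component is recorded on the components in
#'   \code{attr(, "components")}).
#' @export
consensusPeaks <- function(peakSets, minRecurrence = 2L,
                           mergeWithin = 1000L, stranded = TRUE) {
  if (length(peakSets) < minRecurrence)
    stop("need at least minRecurrence replicate peak sets")
  if (!is(peakSets, "GRangesList")) peakSets <- GRangesList(peakSets)
  pooled <- unlist(peakSets, use.names = FALSE)
  repId <- rep(seq_along(peakSets), lengths(peakSets))
  if (length(pooled) == 0L) {
    warning("empty peak sets: empty consensus")
    return(GRanges())
  }
  ignoreStrand <- !stranded
  comps <- reduce(pooled, min.gapwidth = 0L, ignore.strand = ignoreStrand,
                  with.revmap = TRUE)
  support <- vapply(mcols(comps)$revmap, function(i)
    length(unique(repId[i])), 0L)
  kept <- comps[support >= minRecurrence]
  mcols(kept)$revmap <- NULL
  mcols(kept)$support <- support[support >= minRecurrence]
  merged <- reduce(kept, min.gapwidth = mergeWithin + 1L,
                   ignore.strand = ignoreStrand, with.revmap = TRUE)
  nrep <- vapply(mcols(merged)$revmap, function(i)
    max(mcols(kept)$support[i]), 0L)
  mcols(merged)$revmap <- NULL
  mcols(merged)$n_replicates <- nrep
  mcols(merged)$name <- sprintf("consensus_%05d", seq_along(merged))
  attr(merged, "components") <- kept
  merged
}

#' Count fragments in features by midpoint containment
#'
#' A fragment is assigned by its midpoint (integer division of its 0-based
#' half-open bounds, so a midpoint on the feature start boundary counts);
#' it contributes once to every feature containing the midpoint, which for
#' disjoint features prevents double counting across adjacent peaks.
#'
#' @param fragments a named list of \code{GRanges}, one element per sample.
#' @param features a \code{GRanges} of features (peaks).
#' @return An integer matrix, features x samples.
#' @export
countInFeatures <- function(fragments, features) {
  featNames <- if (!is.null(mcols(features)$name)) mcols(features)$name
               else sprintf("feature_%05d", seq_along(features))
  counts <- vapply(fragments, function(fr) {
    ## midpoint of 0-based half-open [s0, e0): floor((s0 + e0) / 2)
    m0 <- (start(fr) - 1L + end(fr)) %/% 2L
    mid <- GRanges(seqnames(fr), IRanges(m0 + 1L, width = 1L))
    countOverlaps(features, mid, ignore.strand = TRUE)
  }, integer(length(features)))
  counts <- matrix(as.integer(counts), nrow = length(features),
                   dimnames = list(featNames, names(fragments)))
  counts
}

#' Median-of-ratios size factors
#'
#' For every feature with all-positive counts, the ratio of each sample's
#' count to the feature's geometric mean across samples is formed; the
#' sample's size factor is the median of those ratios, rescaled so the
#' median size factor is 1.  When no feature qualifies, library-size ratios
#' are used instead and flagged.
#'
#' @param counts integer matrix, features x samples.
#' @return Numeric size factors (one per sample);
#'   \code{attr(, "fallback")} is TRUE when library sizes were used.
#' @export
normalizeMedianOfRatios <- function(counts) {
  counts <- as.matrix(counts)
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok)) {
    warning("no feature with all-positive counts: ",
            "falling back to library-size ratios")
    libs <- colSums(counts)
    sf <- libs / median(libs)
    attr(sf, "fallback") <- TRUE
    return(sf)
  }
  sub <- counts[ok, , drop = FALSE]
  logGeo <- rowMeans(log(sub))
  sf <- apply(sub, 2L, function(col) median(exp(log(col) - logGeo)))
  sf <- sf / median(sf)
  attr(sf, "fallback") <- FALSE
  sf
}

## Group means of normalised counts plus a dispersion estimate.  The
## method-of-moments estimate alpha = (s^2 - mu)/mu^2 is formed per feature
## (pooled over the groups) and, under the default "common" mode, averaged
## across features; the floor avoids degenerate Wald statistics.
nbGroupStats <- function(norm, groups, dispersionMode = c("common", "per-feature"),
                         dispersionFloor = 0.01) {
  dispersionMode <- match.arg(dispersionMode)
  lv <- levels(groups)
  mu <- vapply(lv, function(g)
    rowMeans(norm[, groups == g, drop = FALSE]), numeric(nrow(norm)))
  s2 <- vapply(lv, function(g)
    apply(norm[, groups == g, drop = FALSE], 1L, stats::var),
    numeric(nrow(norm)))
  mu <- matrix(mu, nrow = nrow(norm), dimnames = list(NULL, lv))
  s2 <- matrix(s2, nrow = nrow(norm), dimnames = list(NULL, lv))
  mom <- (s2 - mu) / mu^2
  mom[!is.finite(mom)] <- NA
  perFeature <- rowMeans(mom, na.rm = TRUE)
  perFeature[!is.finite(perFeature)] <- 0
  alpha <- switch(dispersionMode,
    common = rep(max(mean(perFeature, na.rm = TRUE), dispersionFloor),
                 nrow(norm)),
    `per-feature` = pmax(perFeature, dispersionFloor))
  list(mu = mu, alpha = alpha)
}

#' Differential occupancy test (NB/Wald)
#'
#' Counts are normalised by [normalizeMedianOfRatios()] size factors; per
#' feature, group means are compared on the log2 scale with a delta-method
#' Wald statistic: Var(log mean) is approximated by (1/n)(1/mu + alpha) per
#' group, with a method-of-moments dispersion alpha (floored at
#' \code{dispersionFloor}; by default a common value averaged across
#' features, matching a shared-dispersion count model and giving calibrated
#' p-values at small replicate numbers).  Two-sided normal p-values are
#' BH-adjusted.  Features with zero counts in both groups get p = 1 and
#' log2FC = 0, flagged in \code{all_zero}.
#'
#' @param counts integer matrix, features x samples.
#' @param condition factor of length ncol(counts) with exactly two levels;
#'   fold changes are level2 / level1.
#' @param sizeFactors optional precomputed size factors.
#' @param dispersionMode \code{"common"} (default) or \code{"per-feature"}.
#' @param dispersionFloor lower bound on the dispersion (default 0.01).
#' @return A data.frame with columns \code{feature}, \code{baseMean},
#'   \code{log2FC}, \code{SE}, \code{stat}, \code{p}, \code{fdr},
#'   \code{all_zero}.
#' @export
testDifferential <- function(counts, condition, sizeFactors = NULL,
                             dispersionMode = "common",
                             dispersionFloor = 0.01) {
  counts <- as.matrix(counts)
  condition <- droplevels(as.factor(condition))
  if (nlevels(condition) != 2L) stop("condition must have exactly 2 levels")
  if (any(table(condition) < 2L)) stop("need >= 2 replicates per level")
  if (is.null(sizeFactors)) sizeFactors <- normalizeMedianOfRatios(counts)
  norm <- sweep(counts, 2L, sizeFactors, "/")
  st <- nbGroupStats(norm, condition, dispersionMode, dispersionFloor)
  lv <- levels(condition)
  n1 <- sum(condition == lv[1]); n2 <- sum(condition == lv[2])
  mu1 <- st$mu[, lv[1]]; mu2 <- st$mu[, lv[2]]
  allZero <- mu1 == 0 & mu2 == 0
  ## pseudo-mean guard for one-sided zeros (keeps FC finite, variance defined)
  eps1 <- pmax(mu1, 0.5 / n1); eps2 <- pmax(mu2, 0.5 / n2)
  log2FC <- ifelse(allZero, 0, log2(eps2 / eps1))
  v1 <- (1 / n1) * (1 / eps1 + st$alpha)
  v2 <- (1 / n2) * (1 / eps2 + st$alpha)
  se <- sqrt(v1 + v2) / log(2)
  stat <- ifelse(allZero, 0, log2FC / se)
  p <- ifelse(allZero, 1, 2 * pnorm(-abs(stat)))
  data.frame(feature = rownames(counts), baseMean = rowMeans(norm),
             log2FC = log2FC, SE = se, stat = stat, p = p,
             fdr = p.adjust(p, method = "BH"), all_zero = allZero,
             stringsAsFactors = FALSE)
}

#' Two-factor interaction test (NB/Wald)
#'
#' Tests whether the effect of factor A differs between the levels of factor
#' B: interaction = (log2 mu11 - log2 mu10) - (log2 mu01 - log2 mu00), with
#' variance the sum of the four delta-method cell variances.  All four cells
#' need >= 2 replicates.
#'
#' @param counts integer matrix, features x samples.
#' @param factorA,factorB two-level factors over samples (e.g. treatment and
#'   knockdown).
#' @param sizeFactors optional precomputed size factors.
#' @param dispersionMode,dispersionFloor as in [testDifferential()].
#' @return A data.frame with \code{feature}, \code{baseMean},
#'   \code{interaction} (log2 units), \code{SE}, \code{stat}, \code{p},
#'   \code{fdr}.
#' @export
testInteraction <- function(counts, factorA, factorB, sizeFactors = NULL,
                            dispersionMode = "common",
                            dispersionFloor = 0.01) {
  counts <- as.matrix(counts)
  factorA <- droplevels(as.factor(factorA))
  factorB <- droplevels(as.factor(factorB))
  if (nlevels(factorA) != 2L || nlevels(factorB) != 2L)
    stop("both factors must have exactly 2 levels")
  cell <- interaction(factorA, factorB, drop = FALSE)
  if (any(table(cell) < 2L))
    stop("every A x B cell needs >= 2 replicates")
  if (is.null(sizeFactors)) sizeFactors <- normalizeMedianOfRatios(counts)
  norm <- sweep(counts, 2L, sizeFactors, "/")
  st <- nbGroupStats(norm, cell, dispersionMode, dispersionFloor)
  a <- levels(factorA); b <- levels(factorB)
  nm <- function(ai, bi) paste(a[ai], b[bi], sep = ".")
  nOf <- table(cell)
  getMu <- function(ai, bi) {
    mu <- st$mu[, nm(ai, bi)]
    pmax(mu, 0.5 / nOf[[nm(ai, bi)]])
  }
  mu00 <- getMu(1, 1); mu10 <- getMu(2, 1)
  mu01 <- getMu(1, 2); mu11 <- getMu(2, 2)
  est <- (log2(mu11) - log2(mu01)) - (log2(mu10) - log2(mu00))
  vcell <- function(mu, n) (1 / n) * (1 / mu + st$alpha)
  v <- vcell(mu00, nOf[[nm(1, 1)]]) + vcell(mu10, nOf[[nm(2, 1)]]) +
    vcell(mu01, nOf[[nm(1, 2)]]) + vcell(mu11, nOf[[nm(2, 2)]])
  se <- sqrt(v) / log(2)
  stat <- est / se
  p <- 2 * pnorm(-abs(stat))
  data.frame(feature = rownames(counts), baseMean = rowMeans(norm),
             interaction = est, SE = se, stat = stat, p = p,
             fdr = p.adjust(p, method = "BH"), stringsAsFactors = FALSE)
}

#' Classify induced features by FDR and fold-change thresholds
#'
#' Optionally keeps only the top \code{topFraction} of features by base mean
#' (abundance pre-filter; FDR is recomputed by BH within the kept set), then
#' flags a feature as induced iff FDR <= \code{fdr} and linear |fold change|
#' >= \code{fc}; thresholds are inclusive.  Direction records the sign.
#'
#' @param results a data.frame from [testDifferential()] (columns
#'   \code{feature}, \code{baseMean}, \code{log2FC}, \code{p}).
#' @param fdr FDR threshold (default 0.05).
#' @param fc linear fold-change threshold (default 1.5).
#' @param topFraction optional abundance filter quantile (e.g. 0.25 keeps
#'   the top 25% by base mean); \code{NULL} disables.
#' @return \code{results} with added columns \code{filtered},
#'   \code{fdr_used}, \code{induced}, \code{direction}.
#' @export
classifyInduced <- function(results, fdr = 0.05, fc = 1.5,
                            topFraction = NULL) {
  n <- nrow(results)
  keep <- rep(TRUE, n)
  if (!is.null(topFraction)) {
    nKeep <- ceiling(topFraction * n)
    keep <- rank(-results$baseMean, ties.method = "first") <= nKeep
  }
  fdrUsed <- rep(NA_real_, n)
  fdrUsed[keep] <- p.adjust(results$p[keep], method = "BH")
  thr <- log2(fc)
  induced <- keep & !is.na(fdrUsed) & fdrUsed <= fdr &
    abs(results$log2FC) >= thr - 1e-12
  results$filtered <- !keep
  results$fdr_used <- fdrUsed
  results$induced <- induced
  results$direction <- ifelse(induced, ifelse(results$log2FC >= 0,
                                              "up", "down"), NA)
  results
}

#' Hypergeometric gene-set overlap test
#'
#' Upper-tail hypergeometric probability of at least the observed overlap
#' between the hit genes and each gene set, within a common universe, with
#' BH adjustment across sets.
#'
#' @param hits character vector of hit genes (must be within the universe).
#' @param geneSets named list of character vectors (subsets of the universe).
#' @param universe character vector of all genes.
#' @return A data.frame with per-set overlap counts, p and fdr.
#' @export
geneSetOverlapTest <- function(hits, geneSets, universe) {
  if (length(universe) == 0L) stop("empty universe")
  hits <- unique(hits)
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  rows <- lapply(names(geneSets), function(nm) {
    set <- unique(intersect(geneSets[[nm]], universe))
    ov <- length(intersect(hits, set))
    p <- phyper(ov - 1L, length(set), length(universe) - length(set),
                length(hits), lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set), n_hits = length(hits),
               overlap = ov, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, method = "BH")
  out
}
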