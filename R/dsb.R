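## DSB taxonomy: E2-induced vs knockdown-modified classes, their overlap
## structure with A3B binding sites and R-loops, and per-class knockdown
## dependence ratios.

#' Overlap context of DSB peaks
#'
#' Labels each DSB by whether it overlaps an A3B binding site and whether it
#' overlaps or is proximal (gap <= \code{d}) to an R-loop; \code{d = 0}
#' restricts the R-loop association to pure overlap.
#'
#' @param dsbPeaks,a3bPeaks,rloops \code{GRanges} feature sets.
#' @param d proximity distance in bp (default 1500).
#' @return A list with logical vectors \code{overlaps_a3b},
#'   \code{overlaps_rloop} and the \code{context} factor (levels both,
#'   a3b_only, rloop_only, neither).
#' @export
dsbContext <- function(dsbPeaks, a3bPeaks, rloops, d = 1500L) {
  ovA3b <- overlapsAny(dsbPeaks, a3bPeaks, ignore.strand = TRUE)
  rl <- classifyProximity(dsbPeaks, rloops, d = d, stranded = FALSE)
  ovRloop <- as.logical(rl$label %in% c("overlapping", "proximal"))
  context <- factor(ifelse(ovA3b & ovRloop, "both",
                    ifelse(ovA3b, "a3b_only",
                    ifelse(ovRloop, "rloop_only", "neither"))),
                    levels = c("both", "a3b_only", "rloop_only", "neither"))
  list(overlaps_a3b = ovA3b, overlaps_rloop = ovRloop, context = context)
}

#' Classify DSB peaks by induction, knockdown response and overlap context
#'
#' A DSB is \emph{E2-induced} iff it passes [classifyInduced()] thresholds on
#' the E2 contrast with positive direction, and \emph{A3B-modified} iff it
#' passes them in either direction on the knockdown contrast (direction is
#' reported).  Each DSB is also labelled by its overlap context: A3B site
#' only, R-loop only, both, or neither, where the R-loop association uses
#' overlap-or-proximity (gap <= \code{d}) by default (set \code{d = 0} for
#' pure overlap).  A chi-square test asks whether being A3B-modified is
#' associated with sitting on an A3B-and-R-loop context.
#'
#' @param e2Results data.frame from [testDifferential()] +
#'   [classifyInduced()] on the E2 contrast (must carry \code{induced} and
#'   \code{direction}).
#' @param kdResults same for the knockdown contrast.
#' @param dsbPeaks \code{GRanges} of the consensus DSB peaks, parallel to the
#'   result rows (matched by \code{feature} name).
#' @param a3bPeaks,rloops context feature sets.
#' @param d proximity distance for the R-loop association (default 1500 bp).
#' @return A list: \code{table} (per-DSB data.frame with flags, context and
#'   class), \code{fractions} (context fractions within each class),
#'   \code{overlapE2} (fraction of A3B-modified DSBs that are also
#'   E2-induced), \code{chisq}, \code{p}.
#' @export
classifyDsbs <- function(e2Results, kdResults, dsbPeaks, a3bPeaks, rloops,
                         d = 1500L) {
  if (!identical(e2Results$feature, kdResults$feature))
    stop("E2 and knockdown results must cover the same features, in order")
  nm <- if (!is.null(mcols(dsbPeaks)$name)) mcols(dsbPeaks)$name
        else sprintf("feature_%05d", seq_along(dsbPeaks))
  if (!identical(sort(nm), sort(e2Results$feature)))
    stop("dsbPeaks do not match the tested feature set")
  dsb <- dsbPeaks[match(e2Results$feature, nm)]
  cx <- dsbContext(dsb, a3bPeaks, rloops, d = d)
  ovA3b <- cx$overlaps_a3b
  ovRloop <- cx$overlaps_rloop
  context <- cx$context
  e2Induced <- e2Results$induced & e2Results$direction %in% "up"
  a3bModified <- kdResults$induced
  class <- ifelse(e2Induced & a3bModified, "E2_induced|A3B_modified",
           ifelse(e2Induced, "E2_induced",
           ifelse(a3bModified, "A3B_modified", "unclassified")))
  tab <- data.frame(feature = e2Results$feature,
                    e2_induced = e2Induced,
                    a3b_modified = a3bModified,
                    kd_direction = kdResults$direction,
                    overlaps_a3b = ovA3b,
                    overlaps_rloop = as.logical(ovRloop),
                    context = context, class = class,
                    stringsAsFactors = FALSE)
  fractions <- lapply(split(context, class), function(cx) {
    if (!length(cx)) return(setNames(rep(NA_real_, 4), levels(context)))
    prop.table(table(cx))
  })
  overlapE2 <- if (any(a3bModified)) mean(e2Induced[a3bModified])
               else NA_real_
  assoc <- table(modified = a3bModified, both = context == "both")
  chisq <- NA_real_; p <- NA_real_
  if (all(dim(assoc) == c(2L, 2L)) && all(rowSums(assoc) > 0) &&
      all(colSums(assoc) > 0)) {
    cs <- chiSquare2x2(assoc)
    chisq <- cs$statistic; p <- cs$p
  }
  list(table = tab, fractions = fractions, overlapE2 = overlapE2,
       chisq = chisq, p = p)
}

#' Per-class knockdown dependence ratios of DSB signal
#'
#' For each DSB, the log2 ratio of mean normalised counts between the
#' knockdown (siA3B) and non-targeting samples is grouped by the DSB's
#' (A3B overlap x R-loop overlap) context; a planted dependence ratio r at
#' A3B-and-R-loop DSBs shows up as a class mean of log2(r) with other
#' classes near 0.  The context dependence of the knockdown effect is also
#' tested feature-wise with the two-factor interaction machinery when
#' vehicle samples are available, and summarised by a Welch t-test of the
#' "both" class against the "neither" class.
#'
#' @param counts integer matrix of DSB counts (features x samples).
#' @param genotype factor (\code{NT} first level, knockdown second) over
#'   samples.
#' @param classTable per-DSB table from [classifyDsbs()] (\code{context}
#'   column, rows matching \code{rownames(counts)}).
#' @param sizeFactors optional precomputed size factors.  By default they
#'   are estimated by median-of-ratios over the \emph{control features} —
#'   those outside the A3B-and-R-loop context — because the class under test
#'   is expected to change with genotype and would otherwise contaminate the
#'   normalisation (the context is fixed by genomic overlap, not by counts,
#'   so this selection is outcome-independent).
#' @return A list: \code{perClass} (data.frame with class mean/sd/n of the
#'   log2 ratios), \code{ratios} (per-feature log2 ratios; NA where the NT
#'   mean is 0 — those features are excluded and counted), \code{excluded},
#'   \code{welch} (t-test both vs neither; NULL when a class is empty).
#' @export
dependenceRatioByClass <- function(counts, genotype, classTable,
                                   sizeFactors = NULL) {
  counts <- as.matrix(counts)
  genotype <- droplevels(as.factor(genotype))
  if (nlevels(genotype) != 2L) stop("genotype must have exactly 2 levels")
  if (!identical(rownames(counts), classTable$feature))
    stop("counts and class table must cover the same features, in order")
  if (is.null(sizeFactors)) {
    control <- classTable$context != "both"
    if (!any(control)) control <- rep(TRUE, nrow(counts))
    sizeFactors <- normalizeMedianOfRatios(counts[control, , drop = FALSE])
  }
  norm <- sweep(counts, 2L, sizeFactors, "/")
  lv <- levels(genotype)
  muNT <- rowMeans(norm[, genotype == lv[1], drop = FALSE])
  muKD <- rowMeans(norm[, genotype == lv[2], drop = FALSE])
  ratio <- ifelse(muNT > 0, log2(pmax(muKD, .Machine$double.eps) / muNT),
                  NA_real_)
  excluded <- sum(muNT == 0)
  ctx <- factor(classTable$context,
                levels = c("both", "a3b_only", "rloop_only", "neither"))
  perClass <- do.call(rbind, lapply(levels(ctx), function(cl) {
    r <- ratio[ctx == cl & !is.na(ratio)]
    data.frame(context = cl, n = length(r),
               mean_log2_ratio = if (length(r)) mean(r) else NA_real_,
               sd = if (length(r) > 1) sd(r) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rBoth <- ratio[ctx == "both" & !is.na(ratio)]
  rNeither <- ratio[ctx == "neither" & !is.na(ratio)]
  welch <- if (length(rBoth) > 1 && length(rNeither) > 1)
    stats::t.test(rBoth, rNeither) else NULL
  list(perClass = perClass, ratios = ratio, excluded = excluded,
       welch = welch)
}
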