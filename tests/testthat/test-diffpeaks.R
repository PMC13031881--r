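test_that("consensus peaks follow the recurrence and merge rules", {
  sl <- c(chrT = 100000L)
  gr <- function(s, e, st = "+") GenomicRanges::GRanges("chrT",
    IRanges::IRanges(s, e), strand = st, seqlengths = sl)
  reps <- GenomicRanges::GRangesList(
    rep1 = c(gr(1000L, 1500L), gr(10000L, 10400L)),
    rep2 = c(gr(1200L, 1700L), gr(50000L, 50300L)),
    rep3 = gr(30000L, 30200L))
  cons <- consensusPeaks(reps, minRecurrence = 2L, mergeWithin = 1000L)
  ## only the peak seen in 2 of 3 replicates survives
  expect_length(cons, 1L)
  expect_identical(GenomicRanges::start(cons), 1000L)
  expect_identical(GenomicRanges::end(cons), 1700L)
  expect_identical(S4Vectors::mcols(cons)$n_replicates, 2L)
  ## same-strand peaks 900 bp apart merge; opposite strands stay apart
  reps2 <- GenomicRanges::GRangesList(
    rep1 = c(gr(1000L, 1500L), gr(2400L, 2900L), gr(6000L, 6500L, "-")),
    rep2 = c(gr(1000L, 1500L), gr(2400L, 2900L), gr(6000L, 6500L, "-")))
  cons2 <- consensusPeaks(reps2, minRecurrence = 2L, mergeWithin = 1000L)
  plus <- cons2[BiocGenerics::strand(cons2) == "+"]
  expect_length(plus, 1L)   # 1501..2399 gap = 900 <= 1000
  expect_identical(GenomicRanges::end(plus), 2900L)
  expect_length(cons2[BiocGenerics::strand(cons2) == "-"], 1L)
  expect_error(consensusPeaks(reps[1], minRecurrence = 2L), "at least")
})

test_that("consensus construction equals the brute-force oracle", {
  for (s in 1:30) {
    set.seed(s + 300)
    nrep <- sample(2:4, 1)
    reps <- GenomicRanges::GRangesList(lapply(seq_len(nrep), function(r)
      randomPeakCase(s * 100L + r, sample(3:40, 1))))
    stranded <- s %% 2 == 0
    got <- consensusPeaks(reps, minRecurrence = 2L, mergeWithin = 1000L,
                          stranded = stranded)
    pooled <- unlist(reps, use.names = FALSE)
    want <- oracleConsensus(GenomicRanges::start(pooled),
                            GenomicRanges::end(pooled),
                            as.character(BiocGenerics::strand(pooled)),
                            rep(seq_len(nrep), lengths(reps)),
                            2L, 1000L, stranded)
    if (is.null(want)) {
      expect_length(got, 0L)
    } else {
      ord <- order(GenomicRanges::start(got), GenomicRanges::end(got),
                   as.character(BiocGenerics::strand(got)))
      expect_identical(GenomicRanges::start(got)[ord],
                       as.integer(want$start), info = paste(s))
      expect_identical(GenomicRanges::end(got)[ord],
                       as.integer(want$end), info = paste(s))
    }
  }
})

test_that("fragment counting uses half-open midpoint containment", {
  sl <- c(chrT = 10000L)
  features <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(c(101L, 201L), c(200L, 300L)),
    name = c("f1", "f2"), seqlengths = sl)
  ## fragment [91, 110]: 0-based midpoint floor((90 + 110)/2) = 100 -> f1
  ## (position 101 1-based, the start boundary of f1)
  frag <- function(s, e) GenomicRanges::GRanges("chrT",
    IRanges::IRanges(s, e), seqlengths = sl)
  cts <- countInFeatures(list(s1 = frag(91L, 110L)), features)
  expect_identical(cts["f1", "s1"], 1L)
  expect_identical(cts["f2", "s1"], 0L)
  ## midpoint at the feature end boundary belongs to the next feature
  cts2 <- countInFeatures(list(s1 = frag(191L, 210L)), features)
  ## 0-based midpoint floor((190+210)/2) = 200 -> 1-based 201 -> f2
  expect_identical(unname(cts2[, "s1"]), c(0L, 1L))
  ## conservation: disjoint features never count a fragment twice
  set.seed(8)
  s <- sample.int(9000L, 200L, TRUE)
  frags <- frag(s, s + sample(10:100, 200L, TRUE))
  cts3 <- countInFeatures(list(s1 = frags), features)
  expect_lte(sum(cts3), length(frags))
})

test_that("median-of-ratios size factors have their closed-form values", {
  m <- matrix(rpois(500 * 4, 50), 500, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  same <- cbind(m[, 1], m[, 1], m[, 1])
  expect_equal(as.numeric(normalizeMedianOfRatios(same)), rep(1, 3),
               tolerance = 1e-12)
  doubled <- cbind(m[, 1], m[, 1], 2L * m[, 1])
  sf <- normalizeMedianOfRatios(doubled)
  expect_equal(as.numeric(sf), c(1, 1, 2), tolerance = 1e-12)
  ## invariance to feature order
  sh <- sample(nrow(m))
  expect_equal(as.numeric(normalizeMedianOfRatios(m[sh, ])),
               as.numeric(normalizeMedianOfRatios(m)), tolerance = 1e-12)
  ## fallback to library sizes when no feature is all-positive
  z <- m; z[cbind(seq_len(nrow(z)), (seq_len(nrow(z)) %% 4) + 1L)] <- 0L
  expect_warning(sfz <- normalizeMedianOfRatios(z), "library-size")
  expect_true(attr(sfz, "fallback"))
  ## agreement with DESeq2's estimator up to a common rescaling
  skip_if_not_installed("DESeq2")
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  mine <- normalizeMedianOfRatios(m)
  ## same estimator up to a common rescaling; tiny numeric differences come
  ## from interpolated medians being taken before vs after exponentiation
  expect_equal(as.numeric(mine / mine[1]), unname(ref / ref[1]),
               tolerance = 1e-3)
})

test_that("the NB/Wald differential test behaves under symmetry and zeros", {
  synth <- smallSynth()
  cts <- SummarizedExperiment::assay(synth$spiCounts)
  cond <- SummarizedExperiment::colData(synth$spiCounts)$condition
  res <- testDifferential(cts, cond)
  swapped <- factor(cond, levels = rev(levels(cond)))
  res2 <- testDifferential(cts, swapped)
  expect_equal(res2$log2FC, -res$log2FC, tolerance = 1e-12)
  expect_equal(res2$p, res$p, tolerance = 1e-12)
  ## scaling one sample leaves fold changes unchanged
  cts3 <- cts; cts3[, 1] <- cts3[, 1] * 3L
  res3 <- testDifferential(cts3, cond)
  expect_equal(res3$log2FC, res$log2FC, tolerance = 1e-9)
  ## all-zero features are flagged with p = 1, FC = 0
  ctsZ <- rbind(cts, zero = rep(0L, ncol(cts)))
  resZ <- testDifferential(ctsZ, cond)
  z <- resZ[resZ$feature == "zero", ]
  expect_true(z$all_zero)
  expect_equal(z$p, 1)
  expect_equal(z$log2FC, 0)
  expect_error(testDifferential(cts[, 1:3],
                                factor(c("a", "a", "b"))), "replicates")
})

test_that("planted fold changes are recovered with high sensitivity", {
  synth <- smallSynth()
  se <- synth$spiCounts
  res <- classifyInduced(testDifferential(
    SummarizedExperiment::assay(se),
    SummarizedExperiment::colData(se)$condition))
  truth <- SummarizedExperiment::rowData(se)$induced
  expect_gte(mean(res$induced[truth]), 0.8)
  expect_lte(mean(truth[res$induced] == FALSE), 0.15)
})

test_that("the interaction estimate is symmetric and recovers plants", {
  synth <- smallSynth()
  se <- synth$dsbCounts
  cts <- SummarizedExperiment::assay(se)
  cd <- SummarizedExperiment::colData(se)
  cx <- dsbContext(synth$dsbPeaks, synth$a3bPeaks, synth$rloops, d = 0L)
  ctrl <- cx$context != "both"
  sf <- normalizeMedianOfRatios(cts[ctrl, ])
  ir <- testInteraction(cts, cd$e2, cd$genotype, sizeFactors = sf)
  ## relabelling both factors leaves the estimate invariant
  ir2 <- testInteraction(cts,
                         factor(cd$e2, levels = rev(levels(cd$e2))),
                         factor(cd$genotype,
                                levels = rev(levels(cd$genotype))),
                         sizeFactors = sf)
  expect_equal(ir2$interaction, ir$interaction, tolerance = 1e-12)
  ## the planted dependence appears as a negative interaction
  dep <- SummarizedExperiment::rowData(se)$dependent
  expect_lt(abs(mean(ir$interaction[dep]) - log2(0.4)), 0.25)
  expect_lt(abs(mean(ir$interaction[!dep])), 0.1)
  expect_error(testInteraction(cts[, 1:9], cd$e2[1:9], cd$genotype[1:9]),
               "cell")
})

test_that("induced classification applies inclusive thresholds and filters", {
  mk <- function(p, fc, bm = 100) data.frame(
    feature = sprintf("f%03d", seq_along(p)), baseMean = bm,
    log2FC = log2(fc), SE = 1, stat = 0, p = p,
    fdr = p.adjust(p, "BH"), all_zero = FALSE)
  ## exactly at both thresholds: induced (inclusive)
  r <- classifyInduced(mk(0.05, 1.5))
  expect_true(r$induced)
  expect_identical(r$direction, "up")
  expect_false(classifyInduced(mk(0.051, 1.5))$induced)
  expect_false(classifyInduced(mk(0.05, 1.49))$induced)
  expect_true(classifyInduced(mk(0.05, 1 / 1.5))$induced)  # |FC| rule
  ## top-25% filter keeps exactly 25 of 100 and flags the rest
  set.seed(2)
  r100 <- classifyInduced(mk(runif(100), 1, bm = sample(1:1000, 100)),
                          topFraction = 0.25)
  expect_identical(sum(!r100$filtered), 25L)
  expect_identical(sum(r100$filtered), 75L)
  expect_true(all(is.na(r100$fdr_used[r100$filtered])))
})

test_that("hypergeometric overlap matches exact enumeration", {
  ## all 10 hits inside a 10-gene set from a universe of 100
  universe <- sprintf("g%03d", 1:100)
  res <- geneSetOverlapTest(universe[1:10], list(s = universe[1:10]),
                            universe)
  expect_equal(res$p, 1 / choose(100, 10), tolerance = 1e-12)
  ## zero overlap with a tiny set is uninformative
  res0 <- geneSetOverlapTest(universe[1:10], list(s = universe[99:100]),
                             universe)
  expect_gt(res0$p, 0.9)
  ## exact enumeration for small universes
  set.seed(14)
  for (i in 1:15) {
    N <- sample(10:30, 1)
    uni <- sprintf("u%02d", seq_len(N))
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    hits <- sample(uni, n)
    set <- sample(uni, K)
    ov <- length(intersect(hits, set))
    got <- geneSetOverlapTest(hits, list(x = set), uni)$p
    expect_equal(got, oracleHyper(ov, K, N, n), tolerance = 1e-9,
                 info = paste(i))
  }
  expect_error(geneSetOverlapTest("a", list(), character(0)), "universe")
})

test_that("reported FDR values are monotone and dominate Bonferroni", {
  synth <- smallSynth()
  res <- testDifferential(SummarizedExperiment::assay(synth$spiCounts),
                          SummarizedExperiment::colData(synth$spiCounts)$condition)
  ord <- order(res$p)
  expect_true(all(diff(res$fdr[ord]) >= -1e-12))
  bonf <- pmin(res$p * nrow(res), 1)
  expect_true(all(which(bonf <= 0.05) %in% which(res$fdr <= 0.05)))
})
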