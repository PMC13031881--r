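test_that("chi-square 2x2 matches its closed form and stats::chisq.test", {
  tab <- matrix(c(10, 30, 20, 40), 2)
  got <- chiSquare2x2(tab)
  n <- sum(tab)
  closed <- n * (10 * 40 - 20 * 30)^2 /
    (30 * 70 * 40 * 60)
  expect_equal(got$statistic, closed, tolerance = 1e-12)
  expect_equal(got$statistic, 100 * 200^2 / (30 * 70 * 40 * 60),
               tolerance = 1e-12)
  ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  ## proportional rows are independent
  ind <- chiSquare2x2(matrix(c(10, 20, 20, 40), 2))
  expect_equal(ind$statistic, 0)
  expect_equal(ind$p, 1)
  ## transposition invariance
  expect_equal(chiSquare2x2(t(tab))$statistic, got$statistic)
  ## Yates correction agrees with stats::chisq.test default
  refY <- stats::chisq.test(tab, correct = TRUE)
  expect_equal(chiSquare2x2(tab, yates = TRUE)$statistic,
               unname(refY$statistic), tolerance = 1e-9)
  expect_error(chiSquare2x2(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("proximity classification follows the gap rule", {
  sl <- c(chrT = 100000L)
  q <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1001L, 2000L),
                              seqlengths = sl)
  ref <- function(s, e) GenomicRanges::GRanges("chrT",
    IRanges::IRanges(s, e), seqlengths = sl)
  expect_identical(
    as.character(classifyProximity(q, ref(1501L, 1600L))$label),
    "overlapping")
  expect_identical(
    as.character(classifyProximity(q, ref(2501L, 2600L))$label),
    "proximal")  # gap 500
  expect_identical(
    as.character(classifyProximity(q, ref(3502L, 3600L))$label),
    "distal")    # gap 1501, strict
  expect_identical(
    as.character(classifyProximity(q, ref(3501L, 3600L))$label),
    "proximal")  # gap 1500 inclusive
  ## stranded mode only sees same-strand references
  qs <- q; GenomicRanges::strand(qs) <- "+"
  rs <- ref(1500L, 1600L); GenomicRanges::strand(rs) <- "-"
  expect_identical(
    as.character(classifyProximity(qs, rs, stranded = TRUE)$label),
    "distal")
  expect_warning(out <- classifyProximity(q, ref(1L, 10L)[0]), "empty")
  expect_identical(as.character(out$label), "distal")
})

test_that("proximity labels match the brute-force oracle on random genomes", {
  for (s in 1:40) {
    q <- randomPeakCase(s, sample(3:25, 1))
    r <- randomPeakCase(s + 1000L, sample(1:20, 1))
    got <- classifyProximity(q, r, d = 1500L)$label
    want <- vapply(seq_along(q), function(i)
      oracleProximity(GenomicRanges::start(q)[i], GenomicRanges::end(q)[i],
                      GenomicRanges::start(r), GenomicRanges::end(r),
                      1500L), "")
    expect_identical(as.character(got), want, info = paste("case", s))
  }
})

test_that("strand concordance handles degenerate and ambiguous input", {
  sl <- c(chrT = 100000L)
  rl <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(c(1000L, 1500L, 5000L), c(2000L, 2500L, 6000L)),
    strand = c("+", "-", "+"), seqlengths = sl)
  ## a mutation inside two opposite-strand R-loops is excluded and counted
  m <- mutGR("chrT", c(1700L, 5500L, 9000L), "C", "T", seqlengths = sl)
  S4Vectors::mcols(m)$pyr_strand <- c("+", "+", "+")
  sc <- strandConcordance(m, rl)
  expect_identical(sc$excluded, 1L)
  expect_identical(sc$n, 1L)
  expect_equal(sc$fraction, 1)
  ## hybrid interpretation flips the answer
  scH <- strandConcordance(m, rl, rloopStrandMeans = "hybrid")
  expect_equal(scH$fraction, 0)
  ## no overlapping mutations: explicit empty result
  far <- mutGR("chrT", 90000L, "C", "T", seqlengths = sl)
  S4Vectors::mcols(far)$pyr_strand <- "+"
  empty <- strandConcordance(far, rl)
  expect_true(is.na(empty$fraction))
  expect_identical(empty$n, 0L)
})

test_that("random site sampling is seeded, uniform and respects exclusions", {
  sl <- c(chrA = 1000L, chrB = 500L)
  s1 <- randomSiteSample(sl, 200L, seed = 5L)
  s2 <- randomSiteSample(sl, 200L, seed = 5L)
  expect_identical(GenomicRanges::start(s1), GenomicRanges::start(s2))
  expect_true(all(GenomicRanges::start(s1) >= 1L))
  excl <- GenomicRanges::GRanges("chrA", IRanges::IRanges(1L, 500L))
  s3 <- randomSiteSample(sl, 300L, seed = 5L, exclude = excl)
  onA <- as.character(GenomicRanges::seqnames(s3)) == "chrA"
  expect_true(all(GenomicRanges::start(s3)[onA] >= 501L))
  full <- GenomicRanges::GRanges(c("chrA", "chrB"),
                                 IRanges::IRanges(1L, c(1000L, 500L)))
  expect_error(randomSiteSample(sl, 10L, exclude = full), "covers")
})

test_that("consequence enrichment applies priorities and the chi-square", {
  sl <- c(chrT = 100000L)
  cat <- annotationCatalogue(list(
    coding = GenomicRanges::GRanges("chrT", IRanges::IRanges(1000L, 5000L)),
    regulatory = GenomicRanges::GRanges("chrT",
      IRanges::IRanges(c(4000L, 20000L), c(9000L, 30000L)))))
  ## priority: a site in coding AND regulatory counts once, as coding
  sites <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(c(4500L, 25000L, 50000L), width = 1L),
    seqlengths = sl)
  lab <- assignCategory(sites, cat)
  expect_identical(as.character(lab),
                   c("coding", "regulatory", "intergenic"))
  ## planted regulatory-only variants versus uniform random
  vars <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(sample(20000:30000, 200, replace = TRUE), width = 1L),
    seqlengths = sl)
  rand <- randomSiteSample(sl, 2000L, seed = 9L)
  enr <- consequenceEnrichment(vars, cat, rand)
  reg <- enr[enr$category == "regulatory", ]
  expect_equal(reg$frac_variant, 1)
  a <- reg$n_variant; b <- 200 - a; c <- reg$n_random; d <- 2000 - c
  n <- a + b + c + d
  closed <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(reg$chisq, closed, tolerance = 1e-9)
  expect_lt(reg$p, 1e-4)
  expect_true(all(enr$fdr >= enr$p - 1e-12 | is.na(enr$fdr)))
})

test_that("state enrichment matches the coverage formula", {
  sl <- c(chrT = 100000L)
  seg <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(c(1L, 10001L), c(10000L, 100000L)),
    name = c("stateA", "stateB"), seqlengths = sl)
  ## all targets inside a state covering 10% of the genome -> 10.0
  targets <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(c(100L, 5000L), c(200L, 5100L)), seqlengths = sl)
  enr <- stateEnrichment(targets, seg)
  expect_equal(enr$enrichment[enr$state == "stateA"], 10, tolerance = 1e-9)
  expect_equal(enr$enrichment[enr$state == "stateB"], 0)
  ## a target set tiling the genome has enrichment 1 everywhere
  tiles <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1L, 100000L),
                                  seqlengths = sl)
  enrT <- stateEnrichment(tiles, seg)
  expect_equal(enrT$enrichment, c(1, 1), tolerance = 1e-12)
  ## uniform random points are near 1
  rand <- randomSiteSample(sl, 5000L, seed = 3L)
  enrR <- stateEnrichment(rand, seg, flank = 50L)
  expect_true(all(abs(enrR$enrichment - 1) < 0.2))
})

test_that("replication-timing quartile rates are flat for uniform mutations", {
  synth <- smallSynth()
  sl <- stats::setNames(Biostrings::width(synth$genome),
                        names(synth$genome))
  muts <- randomSiteSample(sl, 4000L, seed = 12L)
  rates <- replicationQuartileRates(muts, synth$rtTrack)
  expect_equal(rates$rel_rate[1], 1)
  expect_true(all(abs(rates$rel_rate - 1) < 0.25))
  ## constant track: documented tie rule gives equal-size quartiles
  const <- binnedTrack(list(chrA = rep(1, 300), chrB = rep(1, 200)),
                       1000L, c(chrA = 300000L, chrB = 200000L))
  ratesC <- replicationQuartileRates(muts, const)
  expect_true(all(abs(ratesC$mb - 125 / 1000) < 0.003))
  expect_true(all(abs(ratesC$rel_rate - 1) < 0.3))
})

test_that("a planted early-replication excess is recovered as a rate ratio", {
  cfg <- smallSynthConfig(seed = 31L, rtEffect = 2,
                          nBackgroundMut = 2000L, nRloopMut = 50L,
                          nClusters = 0L)
  synth <- suppressWarnings(buildSyntheticData(cfg))
  m <- synth$mutations[S4Vectors::mcols(synth$mutations)$origin ==
                         "background"]
  rates <- replicationQuartileRates(m, synth$rtTrack)
  ratio <- rates$rate[4] / rates$rate[1]
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.7)
})

test_that("GREAT-style region-to-gene association follows the domain rules", {
  sl <- c(chrT = 10000000L)
  mkTss <- function(pos, strand, name) {
    GenomicRanges::GRanges("chrT", IRanges::IRanges(pos, width = 1L),
                           strand = strand, name = name, seqlengths = sl)
  }
  ## isolated TSS: a region 3 kb upstream is associated (basal 5 kb up)
  tss <- mkTss(1000000L, "+", "geneA")
  region <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(996900L, 997100L), seqlengths = sl)
  expect_identical(regionToGene(region, tss)$gene, "geneA")
  ## a region 2 Mb away is beyond the 1 Mb extension cap
  farRegion <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(3000000L, 3000100L), seqlengths = sl)
  expect_identical(nrow(regionToGene(farRegion, tss)), 0L)
  ## two genes 10 kb apart: their domains abut, the region between hits both
  two <- c(mkTss(1000000L, "+", "geneA"), mkTss(1010000L, "+", "geneB"))
  between <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(1003000L, 1003200L), seqlengths = sl)
  expect_setequal(regionToGene(between, two)$gene, c("geneA", "geneB"))
  ## minus-strand basal domain is mirrored
  tssM <- mkTss(1000000L, "-", "geneM")
  up <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(1003900L, 1004100L), seqlengths = sl)
  expect_identical(regionToGene(up, tssM)$gene, "geneM")
})

test_that("interval statistics are invariant to input ordering", {
  q <- randomPeakCase(5, 15)
  r <- randomPeakCase(6, 10)
  shuf <- sample(seq_along(q))
  a <- classifyProximity(q, r)$fractions
  b <- classifyProximity(q[shuf], r)$fractions
  expect_equal(a, b)
})
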