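test_that("substitutions are classified in pyrimidine-normalised context", {
  g <- toyGenome(chr1 = "ATCAGTGACACGAT")
  ## C>T at + context TCA (positions 2-4)
  r1 <- classifySubstitution(mutGR("chr1", 3L, "C", "T"), g)
  expect_identical(r1$class, "C>T")
  expect_identical(r1$channel, "T[C>T]A")
  expect_true(r1$is_TCW); expect_false(r1$is_CpG)
  expect_identical(r1$pyr_strand, "+")
  ## G>A with + context TGA (positions 6-8) normalises to T[C>T]A
  r2 <- classifySubstitution(mutGR("chr1", 7L, "G", "A"), g)
  expect_identical(r2$channel, "T[C>T]A")
  expect_true(r2$is_TCW)
  expect_identical(r2$pyr_strand, "-")
  ## C>T at context ACG (positions 10-12): CpG, not TCW
  r3 <- classifySubstitution(mutGR("chr1", 11L, "C", "T"), g)
  expect_true(r3$is_CpG); expect_false(r3$is_TCW)
  ## errors: reference mismatch and contig-edge positions
  expect_error(classifySubstitution(mutGR("chr1", 3L, "G", "A"), g),
               "mismatch")
  expect_error(classifySubstitution(mutGR("chr1", 1L, "A", "T"), g),
               "edge")
  expect_error(classifySubstitution(mutGR("chr1", 14L, "T", "C"), g),
               "edge")
})

test_that("96-channel spectra conserve counts and are strand symmetric", {
  synth <- smallSynth()
  m <- synth$mutations
  sp <- build96Spectrum(m, synth$genome)
  expect_identical(sum(sp$spectrum), length(m))
  expect_identical(sum(sp$summary), length(m))
  expect_identical(rownames(sp$spectrum), spectrumChannels())
  ## strand flip: reverse-complement the genome, mirror the coordinates
  g2 <- Biostrings::reverseComplement(synth$genome)
  sl <- stats::setNames(Biostrings::width(synth$genome),
                        names(synth$genome))
  newPos <- sl[as.character(GenomicRanges::seqnames(m))] -
    GenomicRanges::start(m) + 1L
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m2 <- mutGR(as.character(GenomicRanges::seqnames(m)), as.integer(newPos),
              unname(comp[S4Vectors::mcols(m)$ref]),
              unname(comp[S4Vectors::mcols(m)$alt]),
              S4Vectors::mcols(m)$sample, seqlengths = sl)
  sp2 <- build96Spectrum(m2, g2)
  expect_identical(sp$spectrum, sp2$spectrum)
  ## single planted mutation occupies exactly one channel
  g <- toyGenome(chr1 = "ATCAGT")
  one <- build96Spectrum(mutGR("chr1", 3L, "C", "T"), g)
  expect_identical(one$spectrum["T[C>T]A", "s1"], 1L)
  expect_identical(sum(one$spectrum), 1L)
  ## generator TCW plants are all TCW C>T on the pyrimidine strand
  cls <- classifySubstitution(m, synth$genome)
  rsel <- S4Vectors::mcols(m)$origin == "rloop"
  expect_true(all(cls$is_TCW[rsel]))
  expect_true(all(cls$class[rsel] == "C>T"))
  expect_identical(cls$pyr_strand[rsel],
                   S4Vectors::mcols(m)$pyr_strand[rsel])
})

test_that("cosine similarity has its closed-form values and guards", {
  expect_equal(cosineSimilarity(c(1, 1, 0), c(1, 0, 0)), 1 / sqrt(2),
               tolerance = 1e-12)
  expect_equal(cosineSimilarity(1:5, 1:5), 1, tolerance = 1e-12)
  expect_equal(cosineSimilarity(c(1, 0), c(0, 2)), 0, tolerance = 1e-12)
  expect_equal(cosineSimilarity(c(2, 2, 0), c(1, 1, 0)), 1,
               tolerance = 1e-12)  # scale invariance
  expect_error(cosineSimilarity(c(0, 0), c(1, 1)), "zero")
  expect_error(cosineSimilarity(1:3, 1:4), "length")
})

test_that("KL-NMF factorises exactly solvable matrices and is monotone", {
  set.seed(42)
  w <- runif(20, 0.1, 1); h <- runif(6, 1, 50)
  V <- outer(w, h)
  fit <- extractSignaturesNMF(V, 1L, seed = 5L, nRestarts = 5L,
                              maxIter = 500L, tol = 0)
  expect_lt(fit$divergence, 1e-6)
  expect_gt(cosineSimilarity(fit$signatures[, 1], w), 0.999)
  expect_true(all(diff(fit$objective) <= 1e-8))
  expect_true(all(fit$signatures >= 0))
  expect_true(all(fit$exposures >= 0))
  expect_equal(unname(colSums(fit$signatures)), 1, tolerance = 1e-9)
  ## reconstruction scale is preserved by the column renormalisation
  expect_equal(sum(fit$signatures %*% fit$exposures), sum(V),
               tolerance = 1e-3)
  expect_error(extractSignaturesNMF(matrix(0, 4, 3), 1L), "zero")
  expect_error(extractSignaturesNMF(V, 6L), "rank")
})

test_that("two planted signatures are recovered from Poisson mixtures", {
  set.seed(11)
  ch <- spectrumChannels()
  s1 <- rep(0.001, 96)
  s1[grepl("T\\[C>T\\][AT]", ch)] <- 0.24
  s1 <- s1 / sum(s1)
  s2 <- rexp(96); s2 <- s2 / sum(s2)
  H <- matrix(rexp(2 * 20, 1 / 200), 2, 20)
  V <- matrix(rpois(96 * 20, cbind(s1, s2) %*% H), 96, 20)
  fit <- extractSignaturesNMF(V, 2L, seed = 3L)
  ## best of the two possible pairings, scored by their weaker member
  cos <- outer(1:2, 1:2, Vectorize(function(i, j)
    cosineSimilarity(fit$signatures[, i], cbind(s1, s2)[, j])))
  best <- max(min(cos[1, 1], cos[2, 2]), min(cos[1, 2], cos[2, 1]))
  expect_gte(best, 0.95)
})

test_that("intermutation distances are per-sample and per-contig", {
  sl <- c(chr1 = 10000L, chr2 = 10000L)
  m <- mutGR(c("chr1", "chr1", "chr2"), c(10L, 25L, 30L),
             c("A", "A", "A"), c("T", "T", "T"), seqlengths = sl)
  expect_identical(intermutationDistance(m), c(NA_integer_, 15L, NA_integer_))
  ## two samples interleaved on one contig never share an IMD
  m2 <- mutGR("chr1", c(100L, 150L, 200L), "A", "T",
              sample = c("a", "b", "a"), seqlengths = sl)
  expect_identical(intermutationDistance(m2),
                   c(NA_integer_, NA_integer_, 100L))
  expect_identical(intermutationDistance(m[0]), integer(0))
})

test_that("cluster detection matches its definitions and the O(n^2) oracle", {
  sl <- c(chr1 = 100000L)
  callable <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1L, 100000L))
  mk <- function(pos) mutGR("chr1", pos, "A", "T", seqlengths = sl)
  ## 100, 400, 900, 5000 -> one omikli of {100,400,900}
  r <- detectClusters(mk(c(100L, 400L, 900L, 5000L)), callable,
                      nPerm = 20L, seed = 1L)
  expect_identical(nrow(r$clusters), 1L)
  expect_identical(r$clusters$class, "omikli")
  expect_identical(r$clusters$members, "100,400,900")
  ## six mutations 500 bp apart -> one kataegis of size 6
  r6 <- detectClusters(mk(seq(1000L, by = 500L, length.out = 6L)), callable,
                       nPerm = 20L, seed = 1L)
  expect_identical(r6$clusters$class, "kataegis")
  expect_identical(r6$clusters$size, 6L)
  ## strict threshold: 1001 bp apart is not clustered
  r0 <- detectClusters(mk(c(100L, 1101L)), callable, nPerm = 20L, seed = 1L)
  expect_identical(nrow(r0$clusters), 0L)
  ## adjacency exactly at 1000 bp clusters
  r1 <- detectClusters(mk(c(100L, 1100L)), callable, nPerm = 20L, seed = 1L)
  expect_identical(nrow(r1$clusters), 1L)
  ## oracle equivalence on random cases
  for (s in 1:25) {
    set.seed(s)
    n <- sample(2:50, 1L)
    pos <- sort(sample.int(50000L, n))
    got <- detectClusters(mk(pos), callable, nPerm = 5L, seed = 1L)
    want <- oracleClusters(pos, 1000L)
    gotMembers <- lapply(got$clusters$members, function(x)
      as.integer(strsplit(x, ",")[[1]]))
    expect_identical(length(gotMembers), length(want), info = paste(s))
    want <- want[order(vapply(want, min, 0))]
    for (k in seq_along(want))
      expect_identical(gotMembers[[k]], want[[k]])
  }
  ## unsorted input is auto-sorted with a warning
  expect_warning(detectClusters(mk(c(900L, 100L, 400L)), callable,
                                nPerm = 5L, seed = 1L), "sort")
  ## empty input gives an empty result
  none <- mutGR(character(0), integer(0), character(0), character(0),
                sample = character(0), seqlengths = sl)
  empty <- detectClusters(none, callable, nPerm = 5L, seed = 1L)
  expect_identical(nrow(empty$clusters), 0L)
})

test_that("permutation p-values are valid and conservative under the null", {
  sl <- c(chr1 = 1000000L)
  callable <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1L, 1000000L))
  ps <- vapply(1:30, function(s) {
    set.seed(s + 500)
    pos <- sort(sample.int(1000000L, 40L))
    r <- detectClusters(mutGR("chr1", pos, "A", "T", seqlengths = sl),
                        callable, nPerm = 99L, seed = s)
    r$perSample$p
  }, 0)
  expect_true(all(ps > 0 & ps <= 1))
  ## under a uniform null the p-value distribution is not anti-conservative
  expect_lte(mean(ps <= 0.05), 0.15)
})
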