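---
title: "Strand-aware analysis of cytosine deamination at R-loops: models and methods"
author: "rloopedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-aware analysis of cytosine deamination at R-loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Co-transcriptional R-loops expose a displaced single DNA strand, and the
nuclear cytosine deaminase APOBEC3B (A3B) edits single-stranded DNA
preferentially at 5'-TCW motifs (W = A or T).  If A3B edits the displaced
strand of R-loops at hormone-responsive enhancers, several genomic
footprints should co-occur: C>T changes concentrated at TCW motifs whose
pyrimidine strand coincides with the displaced strand; small clustered
hypermutation events (omikli); GC-skewed, G-quadruplex-prone sequence around
the edited sites; quantitative induction of single-stranded-DNA binding
peaks under oestrogen; and double-strand breaks (DSBs) whose signal depends
on A3B specifically where A3B binding and R-loops coincide.  `rloopedit`
implements the full chain of analyses needed to test each of these
footprints, together with a synthetic-data generator that plants all of them
with known effect sizes, so every stage can be validated by parameter
recovery rather than by visual inspection.

# Coordinate and strand conventions

In memory, all intervals are Bioconductor `GRanges` (1-based, closed).  On
disk the field's conventions hold: BED and bedGraph are 0-based half-open
(written and read through `rtracklayer`), VCF positions are 1-based.  The
conversion lives only in the I/O layer and is covered by an explicit
convention test (a planted mutation is checked at both conventions).

The strand column of a stranded R-loop record is interpreted as naming the
**displaced** single-stranded DNA strand.  Whether a strand-specific DRIP
experiment's "(+) R-loop" file denotes the hybridised or the displaced
strand is a convention of the upstream pipeline, not a fact this package can
infer; `strandConcordance(..., rloopStrandMeans = "hybrid")` flips the
interpretation without touching the data.

# The analysis stages

## Mutation spectra and clusters

Substitutions are normalised to the pyrimidine-centre convention:
purine-centred records are reverse-complemented, giving six substitution
classes and 96 trinucleotide channels in the COSMIC ordering.  A mutation is
TCW-motif iff its normalised context is `T[C>N]A` or `T[C>N]T`; the CpG flag
(normalised centre C followed by G) supports the CpG / non-CpG C>T split
used in class summaries, because spontaneous deamination at methyl-CpG is a
confounder of APOBEC attribution.

De novo signatures are extracted by non-negative matrix factorisation with
the generalised Kullback–Leibler objective — the natural choice for count
matrices — using multiplicative updates (200 iterations, relative-change
tolerance 1e-6), 20 random restarts with the best final divergence retained
(ties broken by the lowest restart index), and signature columns normalised
to sum 1 with exposures rescaled accordingly.  The objective is provably
non-increasing under these updates, and the test suite asserts the
monotonicity on the recorded trace.  NMF is only identifiable when the
cohort shows exposure contrast; the planted-recovery simulations therefore
include nearly pure anchor samples (the separability condition).  Real
cohorts usually satisfy this — e.g. APOBEC-high versus APOBEC-low tumours —
but a cohort in which two signatures always co-occur in fixed proportion
cannot be resolved by any NMF, and this limitation carries over to real
data.

Clustered hypermutation is detected by a transparent adjacency rule:
maximal runs of consecutive same-sample mutations on one contig with all
adjacent intermutation distances (IMD) at most `dMax` (default 1000 bp,
matching the conventional IMD threshold).  Runs of size 2–4 are classed
*omikli*, runs of 5 or more *kataegis*; the 2–4 boundary is a documented
approximation of the "a few mutations in fog-like clusters" description.
Significance per sample is an empirical permutation p-value: mutation
positions are re-drawn uniformly within the callable regions, and
`p = (1 + #{permutations with >= observed cluster count}) / (1 + nPerm)`,
which is never zero and conservative by construction.  Heavier model-based
cluster callers are deliberately not reproduced; analyses that depend on
their exact output are out of scope.

## Sequence features

GC skew is `(G - C)/(G + C)` in non-overlapping 200 bp windows on the plus
strand, with the minus-strand track its negation; windows without G or C are
missing, and missing bins are excluded from profile means rather than
imputed as zero.  G-quadruplex propensity follows the G4Hunter scheme: each
base scores by its homopolymer run (G runs `+min(L, 4)` per base, C runs
`-min(L, 4)`, others 0, computed once over the whole sequence), a 25 bp
window slides one base at a time, and windows with `|mean| >= 1.2` qualify,
the sign giving the strand.  Same-sign qualifying windows closer than one
window length are merged into maximal intervals; a density track counts
overlapping G4 intervals per 100 bp bin (the alternative — base coverage per
bin — is a plausible reading of "G4 frequency"; interval counts were chosen
and are stated here so profiles are interpretable).

Metaprofiles extract a binned track around anchor midpoints, reverse
minus-strand anchors so profiles read 5'→3' along the anchor, and optionally
negate their values (`signFlip`) for strand-antisymmetric tracks such as GC
skew, which turns the plus-strand track into "the track on the anchor's own
strand".  The band is 1.96 standard errors of the per-position anchor mean
— an honest finite-sample CI, so roughly 5% of true values fall outside it
by construction.

## Interval integration

Proximity uses the end-to-end gap with a strict threshold (default
1500 bp, i.e. ±1.5 kb); overlap requires at least one shared base.  Strand
concordance restricts to mutations inside stranded R-loops, calls a mutation
concordant iff its pyrimidine strand equals the displaced strand, reports an
exact binomial 95% CI, and excludes (with a count) mutations covered by two
R-loops of opposite strand, for which the question is ill-posed.

Enrichment against the genome uses seeded uniform random sites drawn by
exact cumulative-width sampling over the allowed space, a priority-ordered
annotation catalogue (each site annotated with its highest-priority
overlapping category, intergenic otherwise — a transparent, minimal
stand-in for a full variant-effect predictor), per-category 2×2 chi-square
tests in closed form, and Benjamini–Hochberg adjustment across categories
(raw p-values are also emitted, since single-category reports conventionally
quote them).  Chromatin-state enrichment is the coverage ratio
`(target bases in state / target bases) / (state bases / genome bases)`
with SNVs expanded by ±200 bp by default (any other flank, e.g. ±50 bp, is
a parameter) and full-length intervals used when `flank = 0`.  Replication-timing quartiles split covered bins into four
equal-size groups by timing value with a stable (value, contig, bin)
tie-break — Q1 is the latest-replicating quartile and rates are expressed
relative to it, as mutation loads conventionally rise toward late
replication.

Region–gene assignment is the basal-plus-extension rule: each gene's basal
domain (5 kb upstream, 1 kb downstream of the TSS, strand-aware) extends in
both directions to the nearest neighbouring basal domain, capped at 1 Mb; a
region is associated with every gene whose domain it intersects.  The
binomial genomic-coverage test layered on this rule by GREAT-style tools is
out of scope; gene-set enrichment of the associated genes uses the exact
upper-tail hypergeometric probability with BH adjustment across sets.

## Differential peak occupancy

Consensus peaks chain any-overlap components across replicate peak sets,
keep components supported by at least `minRecurrence` replicates (default
2), and merge retained peaks on the same strand within 1000 bp — a
transparent recurrence rule standing in for p-value-combining reproducibility
machinery.  Fragments are counted into features by midpoint containment
(half-open midpoint, so a midpoint on the start boundary counts), which
cannot double-count a fragment across adjacent disjoint peaks.

Normalisation is median-of-ratios: for features with all-positive counts,
the median over features of `count / geometric mean across samples`,
rescaled so the median size factor is 1 (this rescaling makes the
doubled-column example come out as factors (1, 1, 2) and changes nothing
downstream).  Median-of-ratios assumes a majority of unchanged features per
sample; where a feature class is expected to respond (the A3B∩R-loop DSBs
under knockdown), size factors are estimated on the complementary control
features — a selection fixed by genomic overlap, not by the counts, so it
cannot bias the test.

The differential test is a deliberately transparent NB/Wald scheme rather
than an emulation of any specific package: normalised group means are
compared on the log2 scale with the delta-method variance
`Var(log mean) ≈ (1/n)(1/μ + α)` per group, two-sided normal p-values and
BH adjustment.  The dispersion α is estimated by method of moments
`(s² − μ)/μ²` per feature (pooled over groups), then — by default —
averaged across features into a common value, floored at 0.01.  With 2–3
replicates the per-feature moment estimate is extremely noisy and produces
heavy-tailed Wald statistics; the common-dispersion default matches the
shared-dispersion count model and gives calibrated null p-values
(Kolmogorov–Smirnov against uniform passes at n = 2000 in the acceptance
suite); `dispersionMode = "per-feature"` retains the noisier classical
estimate.  The two-factor interaction statistic is
`(log2 μ₁₁ − log2 μ₁₀) − (log2 μ₀₁ − log2 μ₀₀)` with the four
delta-method variances summed; it is insensitive to systematic size-factor
error that is shared within a condition, which is why it is the primary
instrument for knockdown-by-treatment synergy.  Induced features are those
with `FDR ≤ 0.05` and linear `|fold change| ≥ 1.5`, both thresholds
inclusive; an optional abundance pre-filter keeps the top 25% of features by
base mean (the convention for the ssDNA-binding assay) and recomputes BH
within the kept set.

## DSB classification

DSB peaks are classed *E2-induced* (induced, positive direction, on the
oestrogen contrast) and *A3B-modified* (significant in either direction on
the knockdown contrast — the direction is reported, since depletion is the
expected sign).  Each DSB's context is its overlap with A3B binding sites
crossed with its overlap-or-proximity (±1.5 kb; pure overlap via `d = 0`)
to R-loops.  Class-by-context fractions, the fraction of A3B-modified DSBs
that are also E2-induced, and a chi-square association between being
A3B-modified and sitting on an A3B∩R-loop context summarise the taxonomy.
Knockdown dependence is the per-DSB `log2(siA3B / NT)` ratio of mean
normalised counts under oestrogen, grouped by context; a planted dependence
ratio r appears as a class mean of `log2 r`.

# The synthetic-data generator

The generator plants every structure the analyses assume, under one master
seed that drives independent sub-seeds per artefact (so artefacts can be
regenerated in isolation and the whole bundle is byte-reproducible).
Defaults define the package's reference study conditions:

* **Genome**: two 1 Mb contigs, i.i.d. background at GC 0.41 (human-like).
* **R-loops**: 200 non-overlapping intervals of 800–2000 bp, strands
  Bernoulli(0.5).  Inside each, every strong (G/C) position carries G on
  the displaced strand with probability 0.9, so the expected
  displaced-strand GC skew is (0.9 − 0.1)/(0.9 + 0.1) = +0.8; the minimum
  length of 800 bp guarantees the midpoint-containing 200 bp skew window
  lies entirely within the R-loop, keeping the profile estimand undiluted.
  A (G₃N₁)₄-type G4 motif is written at the displaced-strand 5' end with
  probability 0.5.
* **Mutations**: 1000 C>T changes at TCW motifs inside R-loops, 80% on the
  displaced strand (each mutation's strand an independent Bernoulli draw);
  20 clusters of 3 mutations within 900 bp; 300 diffuse background
  mutations.  Clusters are isolated by ≥1.5 kb guard zones from R-loops,
  from each other and from background mutations, so that planted-cluster
  recall is exactly measurable at any seed; background mutations are
  uniform outside R-loops and guard zones.  Mutations are spread over five
  synthetic colonies (three APOBEC-active carrying the R-loop and cluster
  mutations, two carrying background only), which gives the per-sample
  cluster statistics and the NMF stage realistic cohort structure.
* **Peak counts**: negative binomial with dispersion 0.1, per-feature
  lognormal baseline means around 100 (sdlog 0.4, giving the top-25%
  base-mean filter real content), per-sample lognormal size factors; 10% of
  2000 peaks are 3-fold induced in the treated condition, 3 vs 3
  replicates.
* **DSBs**: 600 peaks; 25% placed on A3B∩R-loop overlaps; a 2×2
  vehicle/E2 × NT/siA3B design in which 20% of DSBs gain 3-fold signal
  under E2 and the A3B∩R-loop subset has its siA3B+E2 mean multiplied by
  0.4 (so the planted class dependence is log2 0.4 ≈ −1.32 and the planted
  interaction equals the same value).  The E2-induced and dependent
  fractions are deliberately kept below one half so that a majority of
  features is unchanged in every sample — the identifiability assumption of
  median-of-ratios (and of every library-composition normalisation); a
  generator that violated it would bias any normaliser, not just this one.
* **Auxiliary tracks**: a sinusoidal replication-timing track (1 kb bins,
  period 300 kb) with an optional planted early-vs-late mutation-rate ratio;
  a random six-state chromatin segmentation (mean segment 2 kb); 200 toy
  TSSs; gene sets including one truth-linked set (genes within 5 kb of an
  R-loop).

What the generator does **not** emulate: sequencing reads and their
artefacts (mapping bias, duplicates, library preparation), transcript
structure, correlated mutation processes beyond the planted classes, and
realistic chromatin-state dependence of any signal.  Tests passing on this
generator therefore demonstrate that the statistical machinery recovers
planted truth under its stated model — not that the model captures every
property of real sequencing data.

# Numerical choices and degenerate inputs

* Chi-square tests use the closed 2×2 form with df = 1 upper-tail p-values;
  zero margins raise an error suggesting an exact test.  The Yates
  correction is available but off by default (large-count genomic tables).
* NMF guards denominators and the divergence at 1e-10; all-zero matrices
  are rejected.
* The Wald scheme floors the dispersion at 0.01 and replaces zero group
  means by 0.5/n when the other group is non-zero (both-zero features are
  reported flagged with p = 1, FC = 0).
* Track bins are left-aligned with the last partial bin kept; bedGraph
  output omits missing bins.
* Nearest-distance and quartile ties are broken deterministically (leftmost
  reference; stable sort by value, contig, bin index).
* Interval placement in the generator uses bounded rejection sampling
  (1000 retries) and fails with an explicit "too crowded" error rather than
  degrading; random site sampling is exact over the allowed space and can
  only fail when the exclusion covers the genome.
* Unknown or invalid configuration keys are rejected before any
  computation; every run persists its resolved configuration, and reports
  contain no wall-clock state, so reruns are byte-identical.

# Problem sizes

The reference conditions (2 Mb genome, 1360 mutations, 2000 SPI peaks, 600
DSBs, 12-sample DSB design) were chosen so that a full pipeline run
completes in about a minute on a single CPU while every recovered parameter
(concordance, skew, sensitivity, dependence ratio) has a tight sampling
distribution around its planted value.  The calibration analyses use 2000
null features; oracle-equivalence checks run on hundreds of randomized
small genomes of up to 100 kb.

# Known limitations

* The cluster caller is an adjacency rule, not a rate-model caller; its
  counts are not comparable to model-based callers' absolute numbers.
* The consequence annotator is a priority rule over user-supplied interval
  catalogues, not a transcript-aware effect predictor.
* The NB/Wald test uses a common dispersion by default; strongly
  feature-dependent dispersion (e.g. copy-number-variable regions) would
  call for trended or shrunken estimates, which are out of scope.
* Absolute peak counts from the motivating experimental system (tens of
  thousands of peaks from raw sequencing) require the deposited raw data
  and upstream peak calling, and are not reproduced here; the package's
  claims are about the statistical machinery, validated by planted-truth
  recovery.

# Using the pipeline

```{r example}
library(rloopedit)
cfg <- pipelineConfig(seed = 1)
report <- runPipeline(cfg, "run1")
## stage outputs under run1/: fixtures/, spectra/, features/, integrate/,
## diffpeaks/, dsb/, plus resolved_config.json and report.json
```

Each stage can be rerun in isolation (`stages = "dsb"`), reading its inputs
from the run directory through the same readers the tests exercise.
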