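# rloopedit

Strand-aware analysis of APOBEC3B cytosine deamination at R-loops, and of
its downstream consequences, as an R/Bioconductor-style package.

## The problem

R-loops are three-stranded structures formed during transcription: a
DNA:RNA hybrid plus a displaced single DNA strand.  The nuclear deaminase
APOBEC3B (A3B) converts C→U in single-stranded DNA, preferentially at
5'-TCW motifs (W = A/T), and base-excision repair of the resulting lesions
can be processed into double-strand breaks (DSBs).  Testing whether A3B
edits the *displaced* strand of R-loops — for example at oestrogen-receptor
enhancers — requires a chain of strand-aware genomic analyses:

* **Mutation spectra** — pyrimidine-normalised 96-channel trinucleotide
  spectra (6 substitution classes × 16 flank pairs), the TCW/CpG flags, de
  novo signature extraction by NMF minimising the generalised KL divergence
  D(V‖WH), cosine similarity to reference signatures, and detection of
  clustered hypermutation (omikli: runs of 2–4 mutations with
  intermutation distance ≤ 10³ bp; kataegis: runs ≥ 5) with permutation
  p-values.
* **Sequence features** — GC skew (G − C)/(G + C) in 200 bp windows and
  G4Hunter G-quadruplex propensity (run scores ±min(L, 4) per base, 25 bp
  sliding windows, |score| ≥ 1.2), aggregated into strand-aware
  metaprofiles with 95% confidence bands.
* **Interval integration** — overlap/proximity classification (±1.5 kb),
  strand concordance of mutations with the displaced strand (exact binomial
  CI), enrichment versus uniform random genomic sites (closed-form 2×2 χ²),
  chromatin-state fold enrichment, replication-timing quartile mutation
  rates, and GREAT-style basal-plus-extension region→gene assignment with
  hypergeometric gene-set tests.
* **Differential peaks** — ≥k-of-n consensus across replicates with 1 kb
  same-strand merging, midpoint fragment counting, median-of-ratios size
  factors, a transparent negative-binomial Wald test (log2 fold change with
  delta-method variance (1/n)(1/μ + α) per group), a two-factor interaction
  test (log2 μ₁₁ − log2 μ₁₀) − (log2 μ₀₁ − log2 μ₀₀), and induced-feature
  classification at FDR ≤ 0.05 and |FC| ≥ 1.5 with an optional top-25%
  base-mean filter.
* **DSB classification** — E2-induced vs A3B-modified DSB classes, their
  overlap context with A3B binding sites and R-loops, and per-class
  knockdown dependence log2(siA3B/NT).

Because the motivating quantities depend on planted truth being recoverable,
the package ships a fully seeded **synthetic-data generator** that writes a
standard-format bundle (FASTA, VCF, BED6, bedGraph, TSV) carrying every
structure above with known effect sizes — displaced-strand skew, strand
concordance, cluster positions, induced fold changes, DSB dependence ratios
— plus truth tables.  The vignette
(`vignettes/rloopedit-methods.Rmd`) documents every model, default and
limitation.

## Worked example

```r
library(rloopedit)
cfg   <- syntheticConfig(seed = 1)   # reference study conditions
synth <- buildSyntheticData(cfg)

## Are TCW edits on the displaced strand?
m <- synth$mutations
S4Vectors::mcols(m)$pyr_strand <-
  classifySubstitution(m, synth$genome)$pyr_strand
sc <- strandConcordance(m, synth$rloops)

## Is the displaced strand G-rich where R-loops form?
skew <- gcSkewTrack(synth$genome, window = 200)
prof <- profileAround(synth$rloops, skew$plus, flank = 600,
                      strandAware = TRUE, signFlip = TRUE)

## Are the 3-fold induced peaks recovered?
res <- classifyInduced(testDifferential(
  SummarizedExperiment::assay(synth$spiCounts),
  SummarizedExperiment::colData(synth$spiCounts)$condition))

## Does DSB signal at A3B/R-loop overlaps depend on A3B?
cts <- SummarizedExperiment::assay(synth$dsbCounts)
cd  <- SummarizedExperiment::colData(synth$dsbCounts)
cx  <- dsbContext(synth$dsbPeaks, synth$a3bPeaks, synth$rloops, d = 0)
dep <- dependenceRatioByClass(cts[, cd$e2 == "E2"],
                              droplevels(cd$genotype[cd$e2 == "E2"]),
                              data.frame(feature = rownames(cts),
                                         context = cx$context))
```

Output at seed 1:

```
Displaced-strand concordance: 0.777 (95% CI 0.750-0.802, n = 1000)
GC skew at R-loop midpoints: 0.794 +/- 0.009
Induced peaks recovered: 168/200 (84% sensitivity)
    context   n mean_log2_ratio        sd
       both 151    -1.324270918 0.3747478
   a3b_only  57    -0.009343263 0.3980603
 rloop_only  50     0.085113439 0.4350174
    neither 342     0.010521954 0.3889383
```

Reading: the generator planted 80% concordance (the estimate's binomial CI
covers 0.8), a displaced-strand skew of +0.8 = (0.9 − 0.1)/(0.9 + 0.1), a
3-fold induced peak subset (84% recovered at FDR ≤ 0.05, FC ≥ 1.5), and a
knockdown dependence ratio of 0.4 confined to DSBs on A3B∩R-loop overlaps —
recovered as a class mean of −1.32 ≈ log2 0.4 with all other classes near
0.

The staged pipeline runs everything end to end and is byte-reproducible
under a fixed seed:

```r
report <- runPipeline(pipelineConfig(seed = 1), "run1")
```

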