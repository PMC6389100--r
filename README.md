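# promarch — promoter architecture analysis from CAGE TSS data

`promarch` analyses promoter architecture across developmental stages from
CAGE (cap analysis of gene expression) transcription start site data. It
is aimed at regulatory genomicists working on organisms where TSS
selection changes through the life cycle — in particular compact genomes
with operons and spliced-leader (SL) trans-splicing — and implements the
whole path from per-position CTSS count tables to promoter classes,
expression clusters, shift calls, core-promoter motif statistics and
chromatin metagene profiles.

## What it computes

* **Tag clusters.** CTSSes (per-base tag counts) are tpm-normalized and
  clustered per stage: positions < 1 tpm dropped, neighbours within 20 bp
  merged, singleton clusters < 5 tpm dropped. Each cluster carries its
  dominant CTSS and the interquantile width — the distance between the
  first positions at which the 5'→3' cumulative signal reaches q₀.₁ and
  q₀.₉ of the cluster total — a robust sharp-vs-broad statistic. Pooled
  width quartiles define *sharp* (≤ Q1), *broad* (≥ Q3) and intermediate
  classes; CpG frequency in a 200 bp window defines LCG/HCG classes.
* **Consensus promoters and expression classes.** Clusters > 5 tpm merge
  across stages within 100 bp into consensus promoter regions (a
  `RangedSummarizedExperiment`); relative expression profiles are
  clustered on a 5×5 self-organizing map into 25 units labelled `0_0` …
  `4_4`.
* **Shifting promoters.** For a stage pair, the shifting score is the
  maximal difference of the two cumulative initiation distributions in a
  region — the fraction of the lower-expressed sample's initiation lying
  up- or downstream of the other sample's — with a two-sample
  Kolmogorov–Smirnov test at effective size `n_A·n_B/(n_A+n_B)` (raw tag
  counts) and Benjamini–Hochberg FDR; a shift is score > 0.6 and
  FDR < 0.01.
* **Position-specific motifs.** Exhaustive k-mer (k = 1–6) positional
  enrichment around dominant TSSs against a per-sequence composition
  null; IUPAC consensus searches in fixed upstream windows (e.g. TATAW at
  22–37 bp, TCTAGA at 22–52 bp); dinucleotide profiles; PWM scans at
  relative score ≥ 0.85 over the 101 bp upstream region; motif × SOM-class
  association tables with chi-square tests.
* **Operons and trans-splicing.** Assignment of clusters to gene bodies
  plus 500 bp upstream; SL trans-spliced gene classification (site in
  window, > 1 tag, AG acceptor immediately upstream in the reference);
  operon-internal promoter detection; and detection of trans-splice
  acceptor *exclusion* — a TCTAGA element whose internal AG is itself the
  acceptor, with the TSS downstream, so transcripts escape trans-splicing.
* **Tiling arrays.** log₂(Cy5/Cy3) normalization by subtracting the Tukey
  biweight mean, 150 bp running-median smoothing (≥ 3 non-zero probes),
  and metagene profiles around dominant TSSs with 95% bootstrap CIs from
  resampling promoters.
* **Synthetic data with planted truth.** `simulateStudy()` generates a
  multi-chromosome genome, operon-aware gene models, promoter archetypes
  (sharp with motifs at fixed offsets — TCTAGA at 44 bp, TATAA at 30 bp,
  ACCATAA at 56 bp — and broad with dispersed initiation), six-stage CAGE
  tables, SL sites and nucleosome-phased array probes, with every planted
  quantity recorded for validation.

## Worked example

```r
library(promarch)

sim  <- simulateStudy(seed = 1, nGenes = 120, nPerArchetype = 10)
ctss <- lapply(sim$ctss, normalizeTPM)
tcs  <- classifyShape(lapply(ctss, clusterCTSS))
pooled <- do.call(c, unname(tcs))
length(pooled)                      # 290 tag clusters across 6 stages
table(pooled$shape_class)           # broad 83 / intermediate 97 / sharp 110
median(pooled$iq_width[pooled$shape_side == "sharp"])   # 3 bp
median(pooled$iq_width[pooled$shape_side == "broad"])   # 22 bp

se <- assignSOM(buildConsensus(tcs), seed = 1)   # 60 consensus promoters

pr  <- sim$truth$promoters
tss <- GenomicRanges::GRanges(pr$chrom, IRanges::IRanges(pr$tss, width = 1),
                              strand = pr$strand, promoter_id = pr$promoter_id)
win <- promoterWindows(sim$genome, tss)
tct <- searchFixedWindow(win, "TCTAGA", 52, 22)
nrow(tct$hits)                      # 11 promoters with a TCTAGA hit
median(tct$hits$offset)             # 44 bp upstream of the dominant TSS

ev <- detectSLExclusion(tct$hits, tss, sim$slSites)
nrow(ev)                            # 5 acceptor-exclusion events (all planted)
```

The sharp-side promoters sit at a median width of 3 bp against 22 bp for
the broad side — the focused vs dispersed initiation contrast the width
statistic is designed to expose — and every planted TCTAGA element is
recovered at its 44 bp offset, including the five whose AGA coincides
with a trans-splice acceptor.

## Documentation

The methods vignette (`vignettes/promoter-architecture.Rmd`) describes the
models, conventions (coordinates, quantile and offset definitions, window
inclusivity), the synthetic generator's assumptions and the package's
numerical choices in detail. Every exported function carries roxygen
documentation.
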