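---
title: "Promoter architecture analysis from CAGE TSS data: models and methods"
author: "promarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter architecture analysis from CAGE TSS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promarch)
```

# Scope and model

CAGE (cap analysis of gene expression) sequences the capped 5' ends of
mRNAs, so each uniquely mapped tag marks one transcription initiation event
at single-base resolution. Summing tags per genomic position gives CTSSes
(CAGE transcription start sites); how CTSSes are distributed within a
promoter region — focused at one base ("sharp") or dispersed over tens of
bases ("broad") — reflects the mechanism of TSS selection: sharp promoters
are positioned by core sequence motifs at fixed upstream distances (the
TATA-box at ~30 bp; in the larvacean system this package targets, a
spermatogenesis-specific TCTAGA element at ~44 bp), broad promoters by
ordered nucleosomes.

`promarch` implements the full analysis path from per-stage CTSS count
tables to: tag clusters and interquantile widths; sharp/broad and CpG
classes; cross-stage consensus promoter regions; SOM expression classes;
promoter-shift detection; position-specific motif statistics;
trans-splicing and operon-aware annotation; and tiling-array metagene
profiles. A synthetic-data generator with planted ground truth
(`simulateStudy()`) makes every stage testable end to end.

# Tag clustering and promoter width

CTSS counts are normalized to tags per million (`normalizeTPM()`; library
size defaults to the table total but accepts the externally known
mapped-read count). Clustering (`clusterCTSS()`) follows the standard CAGE
recipe: positions under 1 tpm are discarded, neighbours within 20 bp
(inclusive) on the same chromosome and strand merge into one tag cluster,
and single-CTSS clusters under 5 tpm are discarded. All thresholds are
arguments.

The promoter width statistic is the interquantile width: walking 5' to 3'
along the cluster, `q_low` is the first position at which cumulative tpm
reaches 10% of the cluster total and `q_up` the first position reaching
90%; the width is `|q_up - q_low| + 1` bp. The "first position reaching
the quantile" convention is chosen because it is deterministic on discrete
signal and exactly strand-mirror symmetric; the tests verify both
properties against a naive cumulative-sum oracle. Dominant-CTSS ties are
broken to the 5'-most position (frequency of ties is observable via
`dominantCTSS()$tie`).

Shape classes come from quartiles of the pooled width distribution
(`classifyShape()`): width at or below Q1 is sharp, at or above Q3 broad,
otherwise intermediate. The pooled mean additionally divides widths into a
sharp side and a broad side (`shape_side`), reproducing the four width
strata that quartiles-plus-mean define. This matters for validation: with
a bimodal planted mixture of equal parts sharp and broad promoters, Q1
falls near the median of the sharp mode and Q3 near the median of the
broad mode, so by construction about half of each mode lands in
"intermediate". Recovery of planted architecture is therefore scored on
`shape_side` (and on the absence of strict sharp/broad confusions), not on
the three-level label. If all widths are identical the quartiles coincide
and everything is classed intermediate (with a message).

CpG classes (`classifyCpG()`) count CG dinucleotides in a 200 bp window
centred on the dominant CTSS, dividing by window − 1; pooled quartiles
define LCG / mid / HCG.

# Consensus promoters and SOM expression classes

Tag clusters with more than 5 tpm, represented by their interquantile
intervals, merge across stages when within 100 bp on the same strand
(`buildConsensus()`); the result is a `RangedSummarizedExperiment` whose
`tpm` assay conserves member-cluster tpm exactly (tested) and whose
`dominant_pos`/`iq_width` assays carry each stage's strongest member.

Expression profiles (rows scaled to 0–1 relative expression by their
maximum; z-scaling available behind `scale = "zscore"`) are clustered on a
5×5 self-organizing map (`somCluster()`), 25 units labelled `"row_col"`
(`"0_0"` … `"4_4"`). No SOM implementation suited to this pipeline is
among the package's dependencies, so the classic online algorithm is
implemented directly: codebooks initialized from sampled rows, Gaussian
neighbourhood, neighbourhood radius decaying linearly from half the grid
to 0.5 and learning rate from 0.05 to 0.01 over 100 epochs, deterministic
under a fixed seed. These hyperparameters are a design choice validated by
recovery, not by equivalence to any particular external run: with four
planted profile archetypes (maternal-decay, zygotic-peak, flat,
male-only) at noise sd 0.1, majority-mapped units reach adjusted Rand
index ≥ 0.8 (in practice ≈ 1.0). CTSS-level and consensus-level SOMs are
independent runs (`ctssExpressionMatrix()` builds the CTSS-level input).

# Shifting promoters

For two samples within one consensus region, both per-position tpm signals
are reduced to 5'→3' cumulative fractions `F_L` (the sample with the lower
raw tag count in the region) and `F_H`. The shifting score is the maximal
absolute difference of the two curves — the largest fraction of the lower
sample's initiation lying upstream (when `F_L` leads) or downstream (when
`F_H` leads) of the other sample's initiation. Identical usage scores 0,
disjoint usage 1; a constructed 60/40 split scores exactly 0.6. The score
is invariant to uniform scaling of either signal and strand-mirror
symmetric (property tests).

Significance uses the two-sample Kolmogorov–Smirnov statistic on the same
cumulative curves with the asymptotic p-value at effective size
`nA·nB/(nA+nB)`, where `nA`, `nB` are raw (un-normalized) tag counts in
the region — the natural effective sample sizes; they are reported and the
result is flagged when either count is below 10, where the asymptotic
approximation is poor. The statistic and p-value are validated against a
reference two-sample KS test applied to tag-expanded samples.
`detectShifts()` applies Benjamini–Hochberg FDR across tested regions and
calls a shift at score > 0.6 and FDR < 0.01 (both strict). A
`tc_overlap` column reports the fractional overlap of the two stages'
interquantile intervals (intersection over the shorter interval), so that
"< 40% overlap" filters can be applied downstream without re-deriving
positions. `shiftCountMatrix()` tabulates calls over all stage pairs.

# Position-specific motif analysis

All motif statistics use strand-oriented windows centred on dominant
CTSSes (`promoterWindows()`, default 200 bp, TSS at index 101). Offsets
are measured from the motif's 5'-most base to the TSS, positive =
upstream; planting a motif at offset *d* recovers median offset *d*
exactly (audited in tests for several *d*).

* `scanKmers()` counts every k-mer (k = 1–6) at every offset and ranks
  k-mers by peak positional enrichment. The expected count under the null
  uses each sequence's own mononucleotide composition, which controls
  GC/AT skew without assuming a genome-wide background.
* `searchFixedWindow()` matches IUPAC consensi inside closed offset
  windows. Phrases like "37–22 bp upstream" are read as closed offset
  interval [22, 37] for the motif's 5' base; endpoint inclusivity is a
  documented convention since interval phrasing alone does not determine
  it.
* `pwmScan()` scores log-odds PWMs with the relative score
  `(S − Smin)/(Smax − Smin)` and a default threshold of 0.85 over the
  101 bp upstream region; zero probabilities are floored at a
  machine-small value so that a pseudocount-0 consensus PWM still scores
  exactly 1.0 on its own consensus. PWMs can be read from MEME minimal
  files (`readMemeMotif()`).
* `dinucleotideProfile()` and `positionalDensity()` produce the plot-ready
  per-position frequency and heatmap matrices.
* `motifExpressionAssociation()` reports, per motif, the percentage of
  promoters in each SOM class containing it and the class distribution of
  motif-containing promoters, with a chi-square association test — by
  default without Yates continuity correction, matching the conventional
  reporting of such tables; correction is available behind a flag.

# Trans-splicing, operons and acceptor exclusion

Gene assignment (`assignToGenes()`) is strand-aware overlap of the
dominant CTSS with the gene body plus 500 bp upstream. Overlaps with
several gene windows resolve to the gene with the nearest annotated start
(then 5'-most); this tie rule is explicit plumbing — annotation formats do
not dictate one — and its frequency is reported. A gene is SL
trans-spliced (`classifySL()`) when an SL site in its window has more than
one supporting tag and the AG acceptor dinucleotide immediately upstream
on its strand in the reference; the three conditions are tested
exhaustively. Operon-internal promoters are clusters assigned to operon
genes at position ≥ 2 (`findInternalPromoters()`).

Acceptor exclusion (`detectSLExclusion()`) formalizes the configuration in
which a TCTAGA-type element overlaps a trans-splice acceptor: the motif's
internal AG (positions 4–5 of T-C-T-A-G-A — its only AG) coincides with
the acceptor's AG, the implied acceptor position is motif position 6, and
the dominant TSS lies 3' of it, so transcripts initiated there cannot
contain the acceptor and escape trans-splicing. Planted exclusion sites
are recovered exactly, with zero false events, in the acceptance tests.
`intersectPromoterMarks()` covers the companion chromatin check: any
overlap of an enriched region with the −500/+100 bp window around an
annotated start.

# Tiling-array metagene profiles

`normalizeProbes()` forms `log2(Cy5/Cy3)` and subtracts the sample-wide
Tukey biweight mean. The biweight uses the standard tuning constant
c = 4.685 with MAD scaling, iterated from the median to tolerance 1e-6 —
the iteration scheme is a documented default (configurable), chosen for
its standard 95% Gaussian efficiency. An injected multiplicative dye bias
is removed to |mean| < 0.01 on the synthetic arrays.

`smoothTrack()` is a running median over ±75 bp of genomic distance
(rather than probe index, which would behave badly over coverage gaps),
missing wherever fewer than 3 non-zero probes support the window.
`metagene()` maps probes to strand-aware offsets around dominant TSSs in a
±500 bp window, excludes promoters whose windows overlap another's (their
probes would enter twice), bins offsets at probe resolution without
interpolation, and reports the mean per offset with a 95% percentile
bootstrap CI obtained by resampling promoters (not probes) — the CI is on
the mean across promoters, which is what a metagene curve displays. A
single promoter degenerates to ci_low = mean = ci_high. On noise-free
planted nucleosome-phased cosines the mean recovers the curve to < 0.01;
with Gaussian probe noise, CI coverage of the true per-offset means is
95% ± 3% (pooled over replicates).

# The synthetic generator: what it emulates, and what it does not

`generateGenome()` builds random-composition chromosomes with
non-overlapping gene models on both strands, a configurable fraction
(default 0.278) grouped into operons of 2–4 same-strand genes.
`plantPromoters()` anchors promoter archetypes at gene starts (or at
internal operon genes), editing the reference so each motif sits exactly
at its archetype's upstream offset; intergenic spacing guarantees each
promoter an exclusive ±300 bp territory so every emitted tag is
attributable to exactly one promoter. `simulateCAGE()` allocates a fixed
per-stage depth among promoters with gamma-perturbed weights (dispersion
0.2, a typical CAGE-like overdispersion; a Dirichlet-multinomial, so the
per-stage total is conserved exactly while per-promoter counts are
overdispersed), and scatters tag positions as a discretized normal with
the archetype's spread (sharp ≤ 1 bp, broad ≥ 5 bp). `simulateSLSites()`
writes AG acceptors into gene bodies and can place acceptors exactly on a
planted TCTAGA's AGA; `simulateArray()` plants a period-175 bp cosine
(trough at the TSS) around broad promoters with Gaussian noise and a
global dye bias.

Default study conditions: six stages (oocyte, tailbud, tadpole, day-2,
day-6 female, day-6 male), six archetypes — broad maternal/zygotic/
ubiquitous without motifs, and sharp ubiquitous (ACCATAA at 56 bp), adult
TATA (TATAA at 30 bp) and male (TCTAGA at 44 bp) — with stage profiles
shaped accordingly. Default problem sizes used in the validation suite
(2 chromosomes of 150–300 kb, 60–220 genes, 10–20k tags per stage,
500 promoters for shift detection, 200 per archetype for SOM recovery,
1000 promoters for bootstrap coverage) were chosen as the smallest sets on
which the planted effects are comfortably identifiable.

What the generator does not emulate — and hence what passing tests do not
show about real data: mapping artefacts and multi-mapping tags, sequence
composition biases beyond uniform GC, overlapping or bidirectional
promoters, partially penetrant motifs, pooled-tissue mixtures, and
alternative TSSs within one gene outside the planted set. Recovery rates
on synthetic data are upper bounds for real data.

# Numerical and degenerate-input choices

One-based fully closed coordinates throughout. Gap rules are inclusive
(20 bp merges; consensus merge gap ≤ 100 bp). Duplicate CTSS keys on
reading are summed with a warning; malformed rows fail with line numbers.
Zero-signal regions are skipped (logged) by shift detection rather than
scored. All-zero SOM rows are excluded; fewer rows than units is an error
suggesting a smaller grid. Probes with non-positive intensities are
dropped before log-ratios. All simulation and training functions take
explicit seeds and are reproducible byte-for-byte.

# A worked mini-run

```{r example, eval = FALSE}
sim <- simulateStudy(seed = 1, nGenes = 120, nPerArchetype = 10)
ctss <- lapply(sim$ctss, normalizeTPM)
tcs <- classifyShape(lapply(ctss, clusterCTSS))
se <- assignSOM(buildConsensus(tcs), seed = 1)
sh <- detectShifts(se, ctss, "tailbud", "male_d6")
head(sh[sh$tested, ])
```

# Known limitations

The SOM is an online implementation with fixed decay schedules; unit
*identities* (which corner holds which profile) vary with the seed even
though the partition is stable. KS p-values are asymptotic only
(permutation tests are out of scope; small-count regions are flagged).
The k-mer null controls mononucleotide composition only, not dinucleotide
structure. Metagene binning at probe resolution attenuates sub-spacing
features when TSSs are not aligned to the probe grid.
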