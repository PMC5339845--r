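---
title: "Models and methods behind nomeseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nomeseqr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement model

NOMe-seq exposes nuclei to the M.CviPI GpC methyltransferase before
bisulfite conversion. The enzyme methylates cytosines in GpC dinucleotides
wherever chromatin is accessible; bisulfite sequencing then reads both this
artificial mark and the endogenous CpG methylome. Because the two marks
live in different trinucleotide contexts they can be separated on the same
molecules:

* **WCG** (ACG/TCG, W = A/T): endogenous CpG methylation. The GpC enzyme
  cannot touch these cytosines.
* **GCH** (GCA/GCT/GCC, H = A/T/C): accessibility. These cytosines are not
  CpG, so all methylation here is enzymatic.
* **GCG** is excluded — its methylation is an indistinguishable mixture of
  endogenous CpG and enzymatic GpC signal — and **CCG** is excluded because
  it captures slight enzyme off-target activity. The package drops both at
  read time and they never reach any estimator.

Contexts are strand-local: the package classifies every C on the plus
strand and every G on the plus strand (a minus-strand C, with its
trinucleotide read 5'→3' on the minus strand), reports minus-strand sites
at the G's plus-strand coordinate, and never collapses strands — GpC on one
strand is generally not GpC on the other. Whether the original analyses
pooled the two strands per dyad is not documented anywhere we could find;
keeping strands separate is the assumption-free choice and pooled
consumers (region levels, windows) are indifferent to it. Trinucleotides
containing N, and cytosines at sequence edges, classify as OTHER and are
excluded from both channels but retained for conversion QC.

Coordinates are 0-based and half-open everywhere inside the package; the
readers and writers of 1-based text formats convert at the boundary.

# Methylation levels

Every regional summary is a *pooled-count* level: methylated and
unmethylated read counts of qualifying sites are summed and the level is
`meth / (meth + unmeth)`. We standardize on pooling (rather than the mean
of per-site levels) for all summaries — windows, promoters, elements,
metaprofile bins — because the windowed test is defined on summed counts
and a single definition keeps every consumer mutually consistent; pooling
also weights deep sites more, which is the right behaviour for a
read-count statistic. A level with no qualifying site is undefined (`NA`),
never 0.

The only depth filter in the analysis is a minimum per-site depth of 3
reads, applied everywhere a level is computed (configurable `min_depth`).
The spike-in estimators default to `min_depth = 1` instead: the lambda
contig is fully unmethylated by construction, so every observation is
informative and no per-site stability is needed.

# Spike-in QC

The lambda phage spike-in carries no endogenous methylation, so

* M.CviPI efficiency = pooled GCH level over lambda,
* bisulfite conversion rate = 1 − pooled level over all *non-GCH* lambda
  cytosines (WCG and OTHER pooled together, maximizing observations
  without bias).

The retention rule is boundary-literal: efficiency ≥ 0.90 passes at
exactly 0.90 ("no less than"), conversion must be strictly greater than
0.98 (exactly 0.98 fails). Published spike fractions are internally
inconsistent between the wet-lab description (0.1%) and the analysis
description (5%); the generator therefore exposes `spike_fraction` as a
parameter (default 0.05) rather than asserting either value, and it only
scales spike-in coverage.

# Segmentation

Only GCH sites are used. Per chromosome the genome is tiled into sliding
windows (NDRs: 100 bp width, 20 bp step; nucleosomes: 40 bp, 20 bp), the
counts of sites with depth ≥ 3 inside each window are pooled, and each
covered window is tested with a 2×2 Pearson chi-squared (1 df, no
continuity correction) against the genome background — the pooled counts
over *all* qualifying GCH sites. Windows with −log10 p strictly above the
cutoff (5 for NDRs, 3 for nucleosomes) and the right direction are merged
when overlapping or book-ended, and merged segments shorter than the
minimum (140 bp NDR, 60 bp nucleosome) are discarded. The segment score is
the maximum per-window −log10 p.

Numerical and design choices:

* **Direction.** M.CviPI methylates accessible GpCs, so open chromatin is
  *methylated*-GCH enriched. The published description words the NDR test
  as enrichment of *un*methylated GCH (and the nucleosome test the other
  way round), which inverts the chemistry and is incompatible with every
  figure-level observation (open promoters of expressed genes, accessible
  CGIs). We implement the chemistry-consistent orientation — NDR =
  methylated-enriched, nucleosome = unmethylated-enriched — and provide
  `invert_directions` to restore the literal reading.
* **Background.** The background uses the full covered genome including
  the tested window; a window is at most a few hundred reads against
  millions, so the induced dependence is negligible and the totals stay
  fixed across windows (one background per sample). The lambda contig is
  excluded.
* **Degenerate windows.** Windows with zero qualifying sites are
  *undetected*: no p-value, never significant. A window whose proportion
  equals the background, or any empty table margin, gives statistic 0 and
  p = 1. p-values are floored at 1e-300 to keep −log10 finite.
* **No multiple-testing correction** — the cutoffs are raw −log10 p, as in
  the original analysis.
* **Merging** uses gap 0 (overlap or book-ended); the original merging gap
  is undocumented, so it is exposed as `merge_gap`.
* Because consecutive windows overlap (step < width), merged segments of
  *opposite* direction can share up to `window − step` bp at their edges;
  no single window is ever significant in both directions.

NDR proximity uses the integer midpoint of the segment and the nearest
TSS: distance < 2000 bp is proximal; the exact 2,000 bp tie is distal
("at least 2 kb away" read literally).

# Profiles, expression, specific NDRs

Metaprofiles pool counts per bin across anchors over `[-flank, +flank)`,
mirroring offsets at minus-strand anchors (half-open mirror
`offset → −offset − 1`). Empty bins are missing, not zero.

The promoter window is TSS ± 1 kb. The original promoter window is
undocumented; we chose a symmetric window on the same scale as the 2 kb
proximal rule, and it is configurable everywhere it appears.

Expression groups are boundary-literal RPKM classes (> 10 high, (1, 10]
intermediate, (0.1, 1] low, ≤ 0.1 silenced). Correlations between
expression and promoter state are Spearman with mid-ranked ties and the
asymptotic t p-value; genes with undefined levels are dropped pairwise,
and `expression_sliding_mean()` provides the 100-gene rolling-mean
presentation that accompanies the two scalar correlations.

Cell-type-specific proximal NDRs: the original description names three
pairwise correlations (methylome, accessibility, expression) but states a
single retention threshold. We gate on the accessibility–expression
correlation — the pair the downstream heatmaps display — at r > 0.6 and
raw p < 0.1, and report the methylation–expression correlation as an
annotation column. Group assignment (no published rule) is the argmax of
group-mean accessibility among the labelled groups. NDRs with fewer than
5 paired samples or constant accessibility are skipped. Sample–sample
distances are 1 − Spearman computed per pair over the rows where both
samples have a defined level (ranks within the shared rows); this is the
stated pairwise-complete contract, and differs slightly from rank-first
column-wise implementations when missingness is informative.

# Elements and repeats

"Relative enrichment" of a class is defined here as
`log2(pooled class GCH level / genome GCH level)` — the original statistic
is not specified beyond its name, and a log ratio of pooled levels is the
minimal scale-free choice. Overlapping annotations count in every class
they belong to (no precedence hierarchy), and a site inside two intervals
of one class contributes to both, which keeps class levels additive over
intervals.

Promoter CpG classes follow the observed/expected convention on a fixed
TSS ± 500 bp window: `o/e = n_CG · L / (n_C · n_G)`, GC fraction
`(n_C + n_G)/L`; HCP iff o/e ≥ 0.75 and GC ≥ 0.55, LCP iff o/e < 0.48,
ICP otherwise; windows without any C or G are LCP. The thresholds are the
standard high/low CpG-density convention and are configurable.

# The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which every recovery claim is made. `sim_config()` defaults encode
those conditions — they are not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `genome_length`, `gc_fraction` | 1 Mb, 0.40 | i.i.d. random chromosome |
| `n_ndr`, `ndr_length` | 200, 300 bp | standalone planted NDRs |
| `open_prob_ndr` / `open_prob_bg` | 0.85 / 0.15 | open probability inside/outside |
| `nucleosome_length`/`linker_length`/`protection` | 147/53 bp, 0.90 | phased arrays downstream of TSSs |
| `efficiency`, `conversion_failure` | 0.93, 0.013 | enzyme and conversion regime |
| `wcg_levels` | soma 0.65, fgc 0.07, heart 0.729, epiblast 0.777 | endogenous regimes |
| `mean_depth`, `depth_dispersion` | 20, 8 | negative-binomial coverage |
| `lambda_length` | 48,502 bp | spike-in contig |
| `expr_*` | −2, +4, −2, 0.3 | log10-RPKM coupling to promoter state |

Reads are modelled per site: depth is negative-binomial (no published
coverage model; NB is the standard overdispersed choice and zero-depth
sites are simply uncovered), and methylated counts are binomial at

* GCH: `open · efficiency + (1 − open · efficiency) · conversion_failure`
* WCG: `wcg + (1 − wcg) · conversion_failure`

so raw levels carry the conversion-failure floor exactly as real bisulfite
data do; recovery tests compare estimates to these read-level
expectations, not to the pre-conversion parameters. Promoter methylation
per gene is `wcg_bg · clip(1 − open + ε)` with per-gene jitter ε, giving
the anticorrelated open/hypomethylated promoters seen in real data.
Expression is `log10 RPKM = −2 + 4·open − 2·wcg + noise`, which populates
all four RPKM groups when promoter openness is drawn from its default
uniform range.

Features are laid out on equal slots of a single chromosome with random
jitter, which guarantees exact feature counts, no overlap, and recoverable
centers; infeasible requests (too many features for the length) error.
Cohorts plant `n_specific_per_group` genes per group whose promoter is
open (0.85) only in samples of that group and closed (0.15) elsewhere,
with expression coupled through the same per-sample openness.

**Power-driven design choice.** Nucleosome (protection) calls test windows
for *lower* accessibility than the genome background, so they are only
detectable where the surrounding background is substantially more open
than the protected cores. At the default 0.15 background a fully protected
40 bp window at depth 20 sits ~1.5 standard errors below background —
undetectable at −log10 p > 3 — while embedding the arrays in transcribed,
open chromatin (background 0.6, linkers 0.85, protection 0.9) puts the
same window ~5 standard errors below. The phased-array recovery simulation
therefore uses `open_prob_bg = 0.6`; this mirrors the biology (phased
arrays flank NDRs in otherwise accessible regions) and was fixed by this
power analysis before any recovery was measured.

**What the generator does not emulate:** sequencing and mapping error,
PCR duplicates, fragment-length effects, CpG islands or any non-stationary
base composition, chromosome-scale methylation domains, partial
methylation at the read level (counts are site-binomial), and strand- or
GC-dependent coverage bias. Recovery on this generator therefore
demonstrates correctness of the estimators and the calling logic under the
declared model — not robustness to alignment artefacts or genome
composition, which require real data.

# Problem sizes

The test suite and the acceptance script run at deliberately desk-scale
sizes chosen once: 1 Mb genomes for segmentation recovery (200 NDRs; 120
genes for arrays), 0.5 Mb for methylation regimes and repeats, 6 Mb /
2,000 genes for the expression coupling, and 9 samples (3 groups × 3) for
the cohort. The headline counts of the original study (&gt; 10^5 NDRs per
species) arise from full sequencing data and are out of desk-scale reach;
all claims here are therefore recovery properties of planted truth, and
the acceptance script reports the recomputed quantities with their problem
sizes.

# Known limitations

* Segmentation is threshold-and-merge; no HMM or kernel smoothing, and no
  between-sample differential NDR test.
* The generator writes one chromosome per genome (plus the lambda contig);
  multi-chromosome inputs are fully supported on the analysis side.
* Read-level co-methylation output (per-molecule methylation strings) is
  not produced; all simulation output is site counts.
* Hierarchical clustering, PCA/MDS and motif enrichment are deliberately
  out of scope: the package emits the distance matrix and BED/TSV products
  that standard tools consume.
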