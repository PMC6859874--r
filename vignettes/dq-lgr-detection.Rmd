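---
title: "Detecting large genomic rearrangements from amplicon read depth"
author: "dqcnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting large genomic rearrangements from amplicon read depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dqcnv)
```

## The problem

Hereditary breast/ovarian cancer testing must detect not only point
mutations but also large genomic rearrangements (LGRs): deletions or
duplications of one or more whole exons of *BRCA1*/*BRCA2*.  Amplicon-based
NGS panels sequence each exon through a fixed set of PCR amplicons, and the
read depth of each amplicon is — after normalization — proportional to the
number of template copies.  A heterozygous exon deletion therefore halves
the normalized coverage of the amplicons inside it.  The wet-lab gold
standard for exon dosage is MLPA; the point of a read-depth screen is to
decide *which* samples still need that assay, so the screen's negative
predictive value is the metric that matters most.

## The dosage quotient

For sample $s$ and amplicon $a$, let $f_{sa}$ be the read count divided by
the sample's total count over a normalization scope.  The dosage quotient
is

$$ DQ_{sa} = \frac{f_{sa}}{\bar f_a}, $$

where $\bar f_a$ is a reference average of the same quantity.  $DQ \approx
1$ for two copies, $\approx 0.5$ for a heterozygous deletion, $\approx 1.5$
for a heterozygous duplication.  Three variants differ only in the
reference and scope:

* **DQA** — intra-chip: $\bar f_a$ is the mean over all samples
  co-sequenced on the same chip (including the sample under test; at least
  `min_chip_samples = 8` samples are required, below which the cross-sample
  mean is too noisy and only the baseline modes are offered).  DQA tracks
  reagent-batch and run-day variability.
* **DQB1** — panel-wide normalization against an external baseline of
  LGR-negative samples (per-amplicon mean and SD of $f_{sa}$).
* **DQB2** — as DQB1, but each primer pool is normalized on its own total.
  A per-sample pool amplification shift multiplies every fraction in the
  pool by a common factor that cancels exactly, so DQB2 is invariant to
  pool batch effects; DQB1 and DQA are not.

Per amplicon, the deletion/duplication thresholds are the classic mean
$\pm$ 2 SD band of the reference DQ distribution, expressed on the DQ
scale (`lo = 1 - 2*sd/mean`, `hi = 1 + 2*sd/mean` for the baseline modes).
The threshold axis is per amplicon — each amplicon has its own band —
because amplicon-specific amplification efficiency makes per-amplicon
variability heterogeneous.  Values exactly on a threshold are *not*
flagged (strict inequalities).

Two evidence tiers are produced by `call_cnvs()`:

* **hard** calls: maximal same-direction runs of amplicons beyond the 2 SD
  band, down to run length 1 — single-amplicon exons are precisely the case
  where segmentation smoothing fails, so single-amplicon events must be
  callable;
* **soft** calls: runs of at least `soft_min_run = 3` consecutive amplicons
  beyond the gentler 1 SD band (`soft_sd_multiplier = 1`) in the same
  direction.  This formalizes the rescue of consistent multi-amplicon
  dosage drops in noisy profiles that never cross the hard band: three
  independent same-direction 1-SD excursions are unlikely by chance but are
  exactly what a real deletion looks like in degraded DNA.  A run that is
  entirely hard-flagged is reported once, as hard.

`sample_qc()` flags a sample as *degraded* when more than
`degraded_threshold = 10%` of its amplicons fall outside the hard band —
the many-peaks-out-of-threshold profile of poor-quality DNA, where hard
calls lose meaning and the soft tier is the more trustworthy signal.

Numerical choices: reference SDs are n−1 sample SDs, floored at 1% of the
amplicon mean so degenerate reference sets cannot create zero-width bands;
a zero count yields $DQ = 0$ and a hard deletion flag; an amplicon with
zero mean across references is an error at baseline build; the DQA
denominator includes the tested sample (with $n \ge 8$ the self-bias is
below 7% even for a full-dose event and is the conventional chip average).

## The HMM comparator

Commercial amplicon pipelines ship a copy-number HMM whose internals are
proprietary.  `hmm_fit()` implements an open surrogate with the same
documented behaviour: Gaussian emissions on $\log_2 DQ$ with state means
$\log_2(c/2)$ for copy numbers $c \in \{1, 2, 3\}$, a homogeneous
transition matrix with per-step switch probability `switch_prob = 1e-3`
split equally among the other states, emission SD `emission_sigma = 0.2`,
Viterbi decoding with ties broken toward copy number 2 (then the lower copy
number), and — crucially — segments shorter than `min_amplicons = 2`
suppressed from reporting.  That last rule reproduces the documented
limitation that such callers cannot report a CNV covered by a single
amplicon, which is the entire motivation for keeping the DQ screen primary.
Segment scores are defined openly here (log10 likelihood ratio vs copy
number 2, and the mean best-vs-second-best emission margin); they are not
intended to be numerically comparable to any vendor's scores.

The pipeline feeds the HMM per-pool-normalized DQ values built from a
dedicated 20-sample baseline.  Per-pool input was chosen after observing
that with panel-wide input a carrier's pool batch shift (log-scale SD 0.1)
occasionally drags a 2-amplicon deletion's DQ from 0.5 toward ~0.58, where
the smoothing prior wins and the segment is lost; per-pool normalization
removes that failure mode at no cost.

## Triage and validation metrics

`triage()` encodes the operative decision rule for selecting samples for
MLPA: DQ-negative samples are reported negative; samples positive by both
callers with calls overlapping in at least one amplicon can go directly to
a confirmation assay or breakpoint characterization; every other
DQ-positive sample requires MLPA.  HMM-positive/DQ-negative samples are
reported negative with a review flag (region match is deliberately "≥ 1
shared amplicon", not exact exon equality — real concordant calls are
rather precise but imperfect in their exon bounds).

`compute_metrics()` reports accuracy, sensitivity, specificity and NPV
from sample-level confusion counts, each with a 95% Wilson score interval
on its own numerator/denominator.  Metrics with zero denominators are
omitted rather than reported as 0.  Display rounding is half-up to one
decimal percent, computed from unrounded fractions.

## Breakpoint arithmetic

`parse_genomic_deletion()` handles `ref:g.<start>_<end>del[<n>]`
descriptors (1-based inclusive; a `del<n>` suffix must equal
$end - start + 1$).  Transcript-style descriptors with `?` bounds are
rejected rather than guessed.  `find_junction_homology()` locates the
perfectly repeated stretch shared by the two breakpoint junctions — the
footprint of Alu-mediated non-allelic homologous recombination — using the
right-slide convention: the homology length is the largest $h$ with
`ref[start .. start+h-1] == ref[end+1 .. end+h]`, and the deletion can be
slid $h$ positions without changing the rejoined product (matching the
HGVS 3' normalization direction; some literature conventions report the
repeat upstream instead).  Panel coordinates elsewhere in the package are 0-based
half-open (BED convention); the two conventions are never mixed
implicitly.

## The simulator and what it does (not) show

`simulate_cohort()` draws counts negative-binomially with mean
$L_s\, e_a\, g_{s,p(a)}\, c_{sa}/2$, renormalized so a sample's expected
total equals its library size $L_s$: log-normal library sizes (mean 5e5
reads, sdlog 0.25), log-normal amplicon efficiencies (sdlog 0.5 — a
realistic several-fold spread), log-normal per-sample-per-pool batch
factors (sdlog 0.1), and injected events that multiply the copy-number
term over contiguous amplicon runs.

DNA quality is modelled as a two-component mixture: standard samples use
NB size 300 (≈ 6% coverage CV on top of Poisson) and an independent 20% of
samples use NB size 15 (≈ 26% CV).  This heterogeneity is not decoration —
it is what makes a mean ± 2 SD screen behave the way it does on real
cohorts.  If every sample had the same noise level, each amplicon would
fall outside its own 2 SD band with probability ≈ 4.6% regardless of the
noise magnitude, and with 167 amplicons essentially every negative sample
would be flagged somewhere: specificity would be near zero for any
homogeneous noise model.  Observed specificities around 60% instead imply
that outliers concentrate in a noisy minority of samples while typical
samples sit well inside bands that the minority has widened.  The mixture
weights were chosen (by this reasoning, plus the requirement that the
baseline SD be stable when estimated from 127 references) to reproduce
that qualitative behaviour; the resulting simulated specificity (~0.4-0.6
across seeds) brackets nothing more precise than "well below 1, well above
0.3", and no claim is made that it estimates any real cohort's
false-positive rate.  Explicitly degraded samples use NB size
`dispersion/25` (≈ 29% CV, ~40% of amplicons out of band), the profile the
QC flag is designed to catch.

`validation_scenario()` fixes the cohort layout used throughout the tests:
127 reference samples for the DQ baseline (the first 20 double as the HMM
baseline) and 85 test samples with exactly three deletion carriers — a
7-amplicon two-exon deletion, a 2-amplicon single-exon deletion and a
single-amplicon deletion of an exon covered by one amplicon — plus one
heavily degraded negative.  The three carriers are drawn from the
standard-quality component (carriers with unusable DNA are a sample-prep
failure, not a caller benchmark), while references and the remaining test
samples keep the full quality mixture.

What passing the synthetic checks shows: the DQ arithmetic, thresholds and
run rules recover half-dose events of 1-7 amplicons at realistic noise,
and the minimum-two-amplicon HMM structurally misses the single-amplicon
event while catching the others.  What it does not show: performance under
real-world artefacts the generator omits — GC- and temperature-driven
efficiency drift correlated across samples, cross-sample contamination,
mosaicism, pseudogene mis-mapping — nor any quantitative false-positive
rate for a particular laboratory.

## Problem sizes and runtime choices

The bundled tests run the full scenario (212 × 167 counts, three DQ fits,
one HMM fit) over 50 seeds for the sensitivity contrast, 500 random cases
per oracle-equivalence check (Viterbi vs exhaustive enumeration capped at
10 amplicons, run merging vs brute-force scanning at up to 30, junction
homology vs all-lengths scanning), and 100-200 replicates for the
Monte-Carlo properties.  These sizes keep the whole suite in the
single-digit minutes while leaving the binomial noise floor of each check
well below its assertion margin.

## Limitations

* The screen is a triage tool: with specificity far below 1, every
  positive still needs orthogonal confirmation, and the design goal is
  NPV ≈ 1, not accuracy.
* Thresholds assume a baseline whose reference samples were processed like
  the test samples; a panel, chemistry or pool-layout change invalidates
  the baseline.
* The HMM surrogate reproduces vendor behaviour, not vendor numbers;
  its confidence/precision scores are package-defined.
* Copy-number estimation is limited to the configured state set
  (heterozygous loss/gain); homozygous deletions, subclonal fractions and
  GC correction are out of scope (amplicon efficiency is absorbed by the
  baseline instead).
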