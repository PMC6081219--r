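---
title: "Detecting germline CNVs from amplicon read depths: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting germline CNVs from amplicon read depths: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amplicnv)
library(dplyr)
```

## The measurement model

Multiplex-PCR targeted sequencing assigns every read to the amplicon whose
primers produced it, so coverage is naturally summarized as an integer
matrix of depths, amplicons × barcoded samples. Three nuisance factors
dominate that matrix:

* **per-amplicon amplification efficiency** — a stable property of each
  primer pair (GC content, product length, local sequence), spanning an
  order of magnitude across a panel but highly reproducible across samples;
* **library size** — total reads per barcode;
* **primer-pool mixing** — panels are amplified as two (or more) separate
  multiplex reactions that are pooled before sequencing, and the pooling
  ratio varies per library. A scatter of one sample's depths against
  another's therefore shows one trend per pool, not one trend overall.

The copy-number signal of interest is a small multiplicative factor (0, ½,
1, 1½, 2 × the diploid level) on top of these. The pipeline removes the
nuisance factors with two ratios:

1. relative depth within a sample and pool, $r_i = x_i / \bar{x}$ where
   $\bar{x}$ is the pool's mean depth in that sample — removes library size
   and pool mixing;
2. normalized relative depth against the batch,
   $t_{iq} = 2\, r_{iq} / \bar{r}_i$ where $\bar{r}_i$ is the mean of
   $r_i$ over all $p$ samples of the batch — removes amplicon efficiency
   and lands diploid dosage at exactly 2 (the batch mean of $t_i$ is 2 by
   construction).

The key assumptions are (a) efficiency rank-stability across samples, which
is what makes the batch reference meaningful, and (b) a batch in which most
samples are diploid at any given amplicon, since the reference is the plain
mean including any carriers. Both ratios are scale-free: multiplying one
sample's depths by any constant, or one pool's depths in all samples by any
constant, provably changes nothing downstream (these are tested invariants).

### Known biases of the literal equations

Because the reference includes the carrier, a CNV deflates or inflates its
own baseline: a heterozygous deletion carrier in a batch of $p$ reads
$t \approx 2dp/(2(p-1)+d)$ rather than $d$ — about +1% at $p = 45$, +9% at
$p = 5$. The package keeps the literal equations as the default and offers
`leave_one_out = TRUE` to exclude each sample from its own reference. A
second, subtler effect: an event also shifts the carrier's *pool mean*
(Eq. 1), moving every other value of that sample slightly in the opposite
direction. Both effects are exercised by tests rather than hidden.

The same arithmetic produces the chrX sex signature. With chrX amplicons
referenced against a mixed-sex batch (≈1.5 copies on average when sexes are
balanced), males read ≈ 2 × (1/1.5) = 1.3 and females ≈ 2 × (2/1.5) = 2.7.
The exact noiseless value under the literal equations is not 4/3: a male's
halved chrX depths also lower his own pool mean, giving $4/(3-f)$ where $f$
is the chrX fraction of the pool — 1.3404 for a realistic panel with
$f \approx 1.6\%$, which still prints as 1.3 at one decimal. On panels where
chrX is a large fraction of a pool the printed value drifts upward; the test
suite asserts the exact closed form, not the rounded folklore value.
`sex_aware = TRUE` normalizes within sex groups instead, restoring chrX to
the diploid scale (and forfeiting the sex readout).

## Tunable parameters

| parameter | default | units | why this value |
|---|---|---|---|
| `outlier_threshold` | 0.1 | batch-mean relative depth | ratios below a tenth of the pool average are dominated by counting noise; the mask is a ≤ rule, so exactly 0.1 is removed |
| `window` (smoothing, t-test) | 5 | amplicons | small enough to resolve single-gene events (typical genes carry 10–30 amplicons), large enough to average ~√5 of the per-amplicon noise |
| `min_run` | 3 | amplicons | a callable event must out-span the smoothing artifacts a single outlier can create |
| `sd multiplier` | 1 | sample SDs | the candidate screen is deliberately permissive — it feeds review, not reporting |
| `qc_threshold` | 0.5 | scaled MAD of normalized depth | a clean library at ~15% depth CV has MAD ≈ 0.3; 0.5 separates that regime cleanly from pool-starved libraries |
| `merge_gap` | 3 | amplicons | bridges the short holes that depth noise punches in long true events while leaving well-separated events distinct |
| `copy-state bands` | n ± 0.5 | dosage | midpoint rounding on the dosage scale; diploid band [1.5, 2.5] is closed, loss bands are [0, 0.5) and [0.5, 1.5), gain bands (2.5, 3.5] and (3.5, ∞) |

The low-coverage rule is stated as a strict `<` in places and `≤` in the
defining formula; the package implements ≤ (the formula) and exposes the
threshold, so either convention is reachable.

## Detection design

**Smoothing** is a centered moving mean in genomic order, restricted to one
(chromosome, gene) group — targeted panels have megabase gaps between genes
that a window must not straddle. At group edges the window is *truncated* to
the gene's extent rather than shrunk symmetrically, so an edge value still
averages at least `(window+1)/2` amplicons; with symmetric shrinking the
first and last amplicon of every gene would be returned unsmoothed, which
measurably destabilizes calls that span gene boundaries (whole-chromosome
trisomies). Smoothing of a constant profile returns the constant, and the
smoothed value never leaves the range of its window — both are tested
properties.

**The ±1 SD screen** computes each sample's mean and standard deviation over
retained amplicons and flags values farther than one SD from the mean. The
SD uses the population formula (divide by *N*): the batch's amplicons are
the entire population being screened, not a sample from it. The choice is
parameterizable (`sd_type = "sample"`) and immaterial at panel sizes in the
hundreds. With σ = 0 nothing is flagged.

**The windowed t-test** compares each run of 5 contiguous retained amplicons
(within a chromosome) against the sample's remaining retained amplicons,
two-sided. Welch's unequal-variance form is the default because the window
and background have genuinely different variances when the window covers an
event. The window is excluded from the background by default so that a large
event cannot contaminate its own null; an include-all mode and a one-sample
mode (window mean against the sample mean) are provided. Zero variance in
both groups is resolved by the limit convention p = 1 for equal means, else
p = 0. P-values aid inspection and are attached to calls; no multiplicity
correction is applied by default (`bh = TRUE` enables Benjamini–Hochberg per
sample), since the screen's purpose is review, not hypothesis testing. The
vectorized implementation is tested against `stats::t.test` to 1e-10.

**Segment calling** replaces by-eye curation with an explicit, reproducible
rule. Seeds are maximal runs of ≥ `min_run` contiguous retained amplicons
whose smoothed value falls in one non-diploid band. Each seed is then
extended over adjacent amplicons whose unsmoothed value stays on the event
side of the band edge nearest diploid (for gains the far edge is ignored —
counting noise scales with dosage, so a true 3-copy amplicon overshoots 3.5
as easily as a diploid one drifts past 2.5); nearby same-state runs are
merged across holes of up to `merge_gap` amplicons; each boundary is then
refined by a local weighted least-squares changepoint fit in which the flank
is modelled at dosage 2 and the segment at its own empirical level (clamped
to its band), each side's spread scaling with its mean; finally, overlapping
claims are arbitrated by model cost and short ambiguous gaps between
same-state segments are bridged when one merged segment explains the data
better than two segments plus the implied extra changepoints (a BIC-style
penalty of 2 log n per changepoint). Before any banding, each sample's
profile is recentered by a two-pass autosomal median, because a large event
(or the chrX sex block) shifts the carrier's own pool mean and would
otherwise drag every band decision.

With default (mixed-sex) normalization, chrX produces state-1 calls for
males and state-3 calls for females on panels with a sizable chrX fraction;
this is the sex readout of the dosage scale, not an error, and disappears
under `sex_aware = TRUE`.

**Batch QC** reports, per sample, the scaled MAD of retained normalized
depths and the raw pool-1/pool-2 mean-depth ratio. The failure mode this
catches is mechanistic: a badly imbalanced library starves one pool of
absolute depth, and the counting noise of the starved pool scatters the
whole normalized profile. Pool imbalance by itself is invisible after the
within-pool ratio (a tested invariance) — it is the induced noise that
fails QC.

Hidden-Markov-model copy-number estimation is intentionally out of scope;
the caller here is a transparent surrogate for visual curation, not a
maximum-likelihood segmenter.

## The simulator

`simulate_batch()` draws the expected depth of amplicon $a$ in sample $s$ as

$$\mu_{as} = \text{mean\_depth}_s \cdot \text{eff}_a \cdot
\text{poolfac}_{s,\text{pool}(a)} \cdot \text{dosage}_{as}/2$$

with log-normal efficiencies (σ_log = 0.5 by default, matching the
order-of-magnitude spread seen across real panels), a per-sample
multiplicative factor on pools ≥ 2, dosage 2 for autosomal diploid, the
event's copy number inside injected CNVs, and 1/2 on chrX for males/females.
Observed counts are negative-binomial with size 50 by default — a
coefficient of variation of ≈ 15% at 500× depth, the scatter regime of a
well-behaved amplicon run — with Poisson and noise-free modes for sharper
tests. The default batch is 45 samples (one sequencer run) on a 20-gene ×
15-amplicon two-pool panel with two genes on a trisomy-candidate chromosome
and two on chrX; sexes alternate so batches are near-balanced. In noise-free
mode the simulator returns the exact expected depths (real-valued, not
rounded), so closed-form identities hold to machine precision.

What the simulator does **not** emulate: GC- or length-dependent efficiency
*structure* (efficiencies are exchangeable draws, so any method exploiting
genomic covariates would not be rewarded here), cross-sample contamination,
segmental-duplication mismapping (the STRC problem — depth from a
pseudogene collapses onto the gene), mosaicism, or batch-to-batch reference
drift. Passing tests on simulated batches therefore demonstrates the
arithmetic and the detector under honest counting noise; they do not
demonstrate robustness to mapping artifacts in duplicated regions, which
real panels must confirm orthogonally.

## Numerical and degenerate-input conventions

* Undefined values (zero pool mean, zero reference) propagate as `NA`,
  never as silent zeros — an observed 0 depth is a meaningful homozygous
  deletion signal, an undefined ratio is not.
* An all-zero pool flags the sample as unanalyzable for that pool and its
  relative depths are `NA`; amplicons undefined in all samples lose their
  reference and are masked.
* Band ties: values exactly on 0.5 band edges follow the half-open
  intervals above (e.g. exactly 2.5 is diploid, exactly 1.5 diploid,
  exactly 0.5 state 1).
* Chromosome ordering is natural (chr1…chr22, chrX, chrY, others
  lexicographic); within a chromosome, by start then amplicon id — a total,
  deterministic order.
* Coordinates are 0-based half-open on disk (BED convention) and 1-based
  inclusive in reported calls (clinical convention).
* Reported floats are written with 6 decimals; the normalized matrix
  round-trips to 1e-6.

## Problem sizes used by the test suite

Unit tests run on 2–10-sample batches of the 300-amplicon default panel;
the recovery experiment runs 100 replicates of a 45-sample batch with one
event of each type (heterozygous 10-amplicon loss, homozygous loss, 1-copy
gain, whole-chromosome trisomy) at default noise; the sex-dosage check uses
a noiseless 44-sample balanced batch on a 63-gene, ~1,000-amplicon panel
with one chrX gene. The full suite completes in under two minutes on one
core.

## Limits of boundary recovery at default noise

At a 15% depth CV, a diploid amplicon's normalized value has σ ≈ 0.30 and a
3-copy amplicon σ ≈ 0.44 — against a fixed band half-width of 0.5. Boundary
placement at an event edge is then decided by one or two amplicons'
likelihoods, and no estimator can beat that information. A Monte-Carlo of
the ideal observer (maximum-likelihood changepoint with the true means and
variances, 200,000 draws) puts the probability of missing a gain boundary
by ≥ 2 amplicons at ≈ 4.0% per side, i.e. a ceiling of ~92% for recovering
both boundaries of an interior 1-copy gain within ±1. The implemented
caller measures 91% on that event type — at its ceiling — while losses
(σ ≈ 0.15 at dosage 1) recover at 99–100% and whole-chromosome trisomies
(boundaries pinned at chromosome ends) at ~96%. Gains are intrinsically the
hard case on this noise budget: the depth noise grows with the copy number
while the decision bands do not.

## Known limitations

* The batch reference is only as diploid as the batch: a CNV shared by many
  samples in one run (or a polymorphic locus like STRC) biases the
  reference toward itself and shrinks everyone's signal.
* Breakpoints are resolved at amplicon granularity; nothing below the
  amplicon spacing is estimable.
* Copy states above 4 are reported as state 4 ("4 or more"); the dosage
  scale itself is continuous and kept in `mean_norm_depth`.
* Calls are screening output. In clinical use every call requires
  orthogonal confirmation (e.g. aCGH) and segregation analysis; the package
  deliberately stops at the evidence-gathering stage.
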