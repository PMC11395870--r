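---
title: "Screening maternal-plasma cfDNA for fetal microdeletions and aneuploidy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening maternal-plasma cfDNA for fetal microdeletions and aneuploidy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nipscnv)
```

## The problem

Cell-free DNA in the plasma of a pregnant woman is a mixture: mostly
maternal, with a fraction *ff* (the fetal fraction, typically 4–35%) of
placental origin. A fetus carrying a heterozygous microdeletion — such as
the ~1.5–1.8 Mb 7q11.23 deletion that causes Williams–Beuren syndrome —
contributes one copy instead of two over the deleted interval, so the
sequencing coverage of that interval in maternal plasma drops by a factor
of only `ff/2`. At screening-grade depth (~10 M uniquely mapped reads
genome-wide) and `ff = 0.15`, that is a ~7.5% dip spread over one or two
megabase-scale windows. Detecting it reliably, while keeping the
genome-wide false-positive rate near zero, is the entire game; wet-lab
enrichment of the short fetal fragments raises `ff` (roughly twofold in
the cohorts this package emulates) and is modelled here purely as a shift
in the fetal-fraction distribution.

`nipscnv` implements the full read-depth screening pipeline — windowing,
GC correction, same-lot Z-scores, hidden-Markov copy-number decoding,
syndrome matching, chrY fetal-fraction estimation and QC — together with a
synthetic-cohort generator that makes every stage testable at desk scale.

## Genome windows

The genome is cut into adjacent windows holding a constant expected number
of uniquely mappable positions, ~1 Mb long on average. Per chromosome, the
quota is `T = total unique positions / round(chromosome length / target)`,
accumulated over small fixed bins (10 kb by default), so windows never
cross chromosome boundaries and the last window absorbs the remainder.
Constant quota means constant expected read count per window: regions of
poor mappability yield longer windows, not noisier ones. Per-window GC is
the mappability-weighted mean of the bin GC. Coordinates are 0-based
half-open internally (BED convention) and converted to 1-based inclusive
only in reports, matching clinical ISCN strings.

Two choices here were genuinely open. The quota is computed per chromosome
rather than genome-wide (the only choice consistent with windows that
never span chromosomes), and mappability enters at fixed 10 kb bin
resolution rather than per-base, which keeps synthetic tracks trivial to
build; real mappability tracks are an accepted input, not something this
package computes. The default target of 1 Mb is configurable — windows of
~0.8–0.9 Mb are a better match for Williams-size (1.5–1.8 Mb) events, and
the packaged case studies use them.

## Read filtering and counting

"Unique reads" are alignments that survive the filters: mapped, not
duplicate-flagged, not secondary/supplementary, mapping quality at least
30 (the uniqueness proxy; multi-mappers carry MAPQ 0), and at most 2
mismatches for a 50 bp single-end read. A record without an `NM` tag
passes the mismatch filter (permissive). Each retained read is assigned to
the window containing its leftmost aligned base; a read starting exactly
on a boundary belongs to the right-hand window. Reads on contigs absent
from the window map still count toward the genome-wide total (and the chrY
tally), because fetal-fraction estimation and depth QC are genome-wide
quantities. SAM input is read through Rsamtools.

## GC correction

PCR under-represents GC-poor and GC-rich fragments, bending coverage
against window GC. Each sample gets its own correction (library-specific
bias): windows are grouped into GC bins of width 0.01, the per-bin
*median* raw count (robust to CNV-carrying windows) is fitted with a cubic
smoothing spline under generalized cross-validation (an interpolating
natural spline when fewer than 10 bins are populated), and corrected read
numbers are

```
CRN_w = raw_w * reference / m(clip(gc_w))
```

with `reference` the median usable-window count and the curve evaluated
only inside the sample's [1st, 99th] GC percentile range (clamping, never
extrapolating, at the extremes; the curve is floored at 5% of the
reference so corrections stay finite). Fits are refused with fewer than 50
usable windows or fewer than 5 populated GC bins. The correction rescales
rather than inflates — total signal is preserved to a few percent — and is
idempotent within tolerance, both of which the test suite checks.

## Same-lot Z-scores

For each window, the batch ("lot") supplies a reference level and spread:

```
Z_win = (CRN_win - CRN_mean) / SD_CRN
```

Three practical details matter:

* **Depth normalisation.** Library depth varies sample to sample; raw
  per-window SDs would be dominated by it. Every sample's CRN vector is
  rescaled so its total over commonly usable windows equals the batch
  median total before the statistics are taken.
* **Leave-one-out.** A sample's own mean and SD are recomputed excluding
  it, so a true CNV does not shrink the very signal being tested —
  important in lots of 30–50 samples.
* **Outlier masking.** After a first pass, cells (window × sample) with
  |z| > 3 are masked and the per-window statistics recomputed over the
  remaining samples. Leave-one-out protects a sample from itself, but not
  from a *second* carrier of the same syndrome in the lot: in a
  scaled-down 50-sample cohort holding two 7q11.23 carriers, each would
  otherwise inflate the other's reference SD at the shared windows and
  push both below the calling threshold. Windows retaining fewer than 60%
  of samples, with zero SD, or with SD beyond 5× the median window SD are
  flagged unusable. No small-sample consistency correction is applied to
  the masked SD; the residual bias is under 2% and hand-checkable examples
  stay exact.

Under the euploid null the resulting per-window z is standardised (mean
≈ 0, SD ≈ 1 across a lot of 50; slightly heavy-tailed, as a
t-statistic with lot-size degrees of freedom must be), which the test
suite verifies on simulated lots.

## Copy-number decoding

A three-state (loss / neutral / gain) hidden Markov model runs over each
chromosome's window z-scores, discretised into seven symbols at cuts
(−4, −3, −2, 2, 3, 4); a z exactly on a cut joins the bin farther from
zero. Neutral emissions are the standard-normal bin masses. Loss emissions
approximate the bin masses of a unit-variance Gaussian centred near
z = −4 (floored so no symbol is impossible), and gains mirror them. That
centre is not arbitrary: the expected per-window z of a heterozygous
deletion is `-(ff/2) * sqrt(lambda)` at Poisson window depth `lambda`, and
at the conditions this pipeline is designed for — fetal fraction ~15%,
~10 M unique reads, ~0.9 Mb constant-quota windows on a ~3.1 Gb genome
(`lambda ≈ 2800`) — that is z ≈ −4. Transitions keep the neutral state
sticky (self-transition 0.99, the screening prior that CNVs are rare) with
loss/gain persistence 0.85 and negligible direct loss↔gain crossing; ties
in the Viterbi decode break toward neutral, then loss, then gain — a
conservative posture. Decoding is restricted to autosomes by default: in a
mixed-fetal-sex lot the X/Y window SDs reflect fetal sex, not copy number.

An earlier parameterisation with five symbols (cuts ±2.5, ±4) and a
0.998-sticky neutral state was evaluated first and rejected by analysis:
for a two-window event at z ≈ −4 per window it cannot recover both
windows unless at least one lands beyond −4, dropping exact-boundary
recovery well below what the data support. The seven-symbol table with the
−2 inner cut places the per-window inclusion threshold near the
likelihood-ratio balance point between the null and a z ≈ −4 event, which
is as well as any window-level decision can do.

Maximal loss/gain runs become segments with window-aligned coordinates
(no sub-window breakpoint refinement — a stated non-goal). A segment is
kept when its Stouffer-type evidence score `|sum(z)/sqrt(n)|` reaches 3.5.
A fixed per-window mean threshold was considered and rejected: it
penalises longer segments, whereas the Stouffer score grows with total
evidence. The score threshold controls the genome-wide rate of spurious
1–2-window candidates; those that survive are almost always unmatched by
the syndrome catalog and are reported as such, not as high-risk findings.

Matched syndromes: a segment matches a catalog region when the states
agree and the overlap covers at least the region's `min_overlap` (default
0.5) of the region length; the largest overlap wins, and matched segments
are classified `pathogenic_match` and drive the "high risk" label. The
packaged catalog (Williams–Beuren 7q11.23, 22q11.2, 15q11.2–q13, 5p15,
1p36) carries approximate GRCh37 spans as plain-text configuration data.

### Operating characteristics, honestly stated

Exact window-aligned recovery of a two-window deletion requires two
independent ~4σ events each to clear a ~2σ inclusion threshold, plus the
segment filter. A calibration study over independent simulated lots (30
samples, case parameters: 1.76 Mb at ff 15%/9.95 M reads; 1.65 Mb at ff
17.7%/5.81 M reads) put exact-size recovery near 80% per lot, with the
errors split between a one-window extension (~8%) and a miss or one-window
truncation; detection of the event *at all* (syndrome match) sits higher,
and the two-carrier 50-sample cohort screen returns exactly the two true
positives with no false positive in the large majority of lots. These are
properties of the signal-to-noise at the stated study conditions, not of
the decoder; the acceptance tests therefore assert sizing as a
majority-of-lots outcome while the acceptance script reports single
seeded runs.

## Fetal fraction and QC

For a male fetus the chrY read proportion rises linearly in `ff` between
two calibration anchors: `b_female` (background mismapping at ff = 0,
default 1e-4 for the synthetic genome) and `b_male_adult` (a 100% male
genome, default 2.1e-3). The estimate is the linear interpolation, clamped
to [0, 1], reported only when the proportion clears a small male-fetus
decision margin above `b_female`; below it the fetus is presumed female
and the method is "unavailable" (the genome-wide regression needed for
female-fetus estimation is out of scope). QC fails a sample below 3.5%
fetal fraction (informed by the 1st percentile of the unenriched cohort,
3.53%) or 5 M unique reads; female-fetus samples skip the fetal-fraction
gate with a recorded caveat. Downstream calling refuses QC-failed samples
("no-call") unless forced.

## Aneuploidy

Each sample's per-chromosome representation is the fraction of its CRN on
that chromosome, over usable windows, with an *autosomal* denominator:
fetal sex shifts chrX dosage by ff/2, and including sex chromosomes in the
denominator would make every autosomal fraction fetal-sex-dependent and
inflate the lot SD. X and Y are still reported relative to the autosomal
total. The Z-test uses the same leave-one-out lot statistics; calls at
|z| ≥ 3 (the industry convention) on autosomes only, with sex-chromosome
z-scores reported without karyotype interpretation. Chromosomes with zero
lot SD are flagged untestable rather than called. Under the euploid null
the empirical type-I error at |z| ≥ 3 stays below 1% (verified over
~1,000 simulated samples); with only 4–6 macro-chromosomes in the
synthetic genome, a genuine whole-chromosome trisomy also depresses the
*other* chromosomes' fractions noticeably — a denominator artefact of the
collapsed genome that is far weaker with 22 real autosomes, and a known
limitation of representation-based tests.

## The simulator

`simulate_cohort()` draws, per sample: fetal fraction from a truncated
normal; fetal sex; total depth (normal, default 10 M ± 1 M, the
laboratory-scale average); then per-window counts
`Poisson(depth_rest * share_w * gcbias(gc_w) * dosage_w)` where `share_w`
is proportional to the window's mappable positions, the GC bias curve is a
smooth quadratic dip (peak 0.40, strength 8 — a 5–10% depression at the
synthetic genome's GC extremes), and dosage is `1 - ff/2` in heterozygous
deletions, `1 + ff/2` in duplications and trisomies (scaled by the
overlapped window fraction), and `1 - ff/2` on chrX for a male fetus. chrY
reads are binomial at `b_female + ff * (b_male_adult - b_female)` for male
fetuses and `b_female` otherwise, spread over the Y windows. Ground truth
goes into a truth table, one row per sample.

The fetal-fraction presets reproduce the cohort summaries of the study
this pipeline emulates: pre-enrichment mean 9.44%, SD 4.03%, truncated at
the printed 1st/99th percentiles (3.53%, 28.94%); post-enrichment 19.32%,
6.04%, (7.57%, 35.54%). The underlying normal parameters are
moment-matched numerically so that the *truncated* distribution has the
printed mean and SD — plugging the printed values in directly would bias
the truncated mean by ~+0.3 points post-enrichment, exactly the margin the
recovery checks care about. The two distributions are treated as
independent specifications; the historical cohorts behind them are not
modelled.

Deliberately not simulated: fragment-length physics (enrichment appears
only as the fetal-fraction shift), read sequences and base qualities,
maternal CNVs, sequencing error, batch effects beyond an optional
overdispersion multiplier (counts are Poisson by default — unique-read
counts at ~3,000 per window are near-Poisson). Passing tests on this
generator therefore demonstrate the pipeline's statistical behaviour under
its own model assumptions, not robustness to real-world artefacts such as
maternal CNV background or GC structure that varies within a window.

Synthetic genomes: `"macro"` collapses the autosomes into four
macro-chromosomes plus X and Y (~3.1 Gb of window mass, preserving
per-window depth at a given total read count); `"ws"` swaps in a
chromosome-7-like contig (158.4 Mb — divisible into both 0.88 Mb and
0.825 Mb windows, so each reported case size is window-aligned under one
tiling) with GRCh37-like 7q11.23 coordinates.

## Numerical choices and problem sizes

Degenerate inputs fail loudly: empty tracks, non-multiple bin sizes,
overlapping window files (named by offending line), zero-read samples,
fewer than 8 samples per lot (overridable with `force`), constant-GC
genomes, zero-SD windows (flagged unusable, z missing rather than
infinite). Determinism: cohort simulation is bitwise reproducible under a
fixed seed; screening itself is deterministic given inputs. The test suite
and worked examples run lots of 30–50 samples on ~3,500-window genomes,
200-case brute-force Viterbi cross-checks, 60-replicate sensitivity grids
with sequential binomial-thinning coupling (so each replicate's counts are
monotone in fetal fraction, making the sensitivity-monotonicity check
sharp at modest replicate counts), and ~1,000-sample type-I studies —
sizes chosen so the full suite completes in minutes on one CPU while
leaving the Monte-Carlo margins comfortably wider than the tolerances
asserted.

## Key tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `target_avg_len` | 1e6 (case studies: 8.8e5/8.25e5) | bp | megabase windows; finer suits 1.5–1.8 Mb events |
| `min_mapq` | 30 | MAPQ | uniqueness proxy |
| `max_mismatches` | 2 | mismatches/50 bp | quality filter |
| GC bin width | 0.01 | GC fraction | enough windows per bin for a stable median |
| `mask_z` | 3 | z | same-lot carrier guard |
| HMM cuts | ±2, ±3, ±4 | z | inner cut at the null/event likelihood balance |
| `min_seg_score` | 3.5 | Stouffer z | genome-wide candidate control |
| `z_threshold` (aneuploidy) | 3 | z | industry convention |
| `min_ff` | 0.035 | fraction | 1st percentile of unenriched cohort |
| `min_unique_reads` | 5e6 | reads | depth QC |
| `b_female`, `b_male_adult` | 1e-4, 2.1e-3 | proportion | synthetic-genome anchors; calibrate for real data |

## Limitations

Window-resolution breakpoints only; no maternal-vs-fetal origin
assignment; no female-fetus fetal fraction; no mosaicism modelling;
sex-chromosome aneuploidies reported as z-scores only; the packaged
catalog and cytoband subset are approximate configuration data to be
reviewed before any clinical use. Detection of 1.5–1.8 Mb events at fetal
fractions below ~10% and ~10 M reads is genuinely marginal — which is
precisely why the cohorts this package emulates enrich fetal fragments
first.
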