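---
title: "Methods: joint-motif PR analysis of mutually exclusive TFBS motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint-motif PR analysis of mutually exclusive TFBS motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointmotif)
```

## The model in one paragraph

Given a positive set of NF ChIP-seq peaks, a negative set of NB
background sequences and two motif models A and B, the package asks
whether the *joint* motif A&B — "recognized wherever at least one
single motif is recognized" — predicts peaks more accurately than both
singles.  Accuracy is the partial, baseline-subtracted area under a
corrected precision–recall curve (pAUPRC), and the decision statistic
is the area ratio RAUC = pAUPRC(A&B) / max(pAUPRC(A), pAUPRC(B)).
RAUC > 1 means the two motifs tend to occupy *different* peaks
(mutually exclusive occurrence); RAUC ≤ 1 is what co-occurring or
redundant motifs produce, because joining them roughly doubles false
positives without adding true positives.

## The common ERR scale

PWM scores and externally computed recognition scores live on
incommensurable scales, so thresholds are calibrated against one
reference sequence set (ideally the promoters of all genes of the
genome; any FASTA is accepted).  For a threshold t, the expected
recognition rate is

ERR(t) = (# scanned positions on both strands of the reference set with
score ≥ t) / (total scanned positions),

a monotone map from threshold to expected hit frequency.  Every
sequence in the positive and negative sets is then reduced to the ERR
of its best hit, and two heterogeneous models become directly
comparable: "best hit at ERR 10⁻³" means the same degree of surprise
for both.  This per-sequence best-ERR representation is also what makes
the joint motif trivial to form — its best-hit ERR is the elementwise
minimum of the single-motif values — and it sidesteps the site-overlap
bookkeeping that plagues site-level pooling of two models.

Assumptions worth keeping in mind: the reference set stands in for the
null genomic background (its composition sets what counts as
"expected"), best-hit reduction discards multiplicity (two hits in one
peak count once), and both strands are always scanned.

## Numerical and boundary conventions

These conventions are exact contracts; all are unit-tested.

* **Threshold grid.** PR-curve thresholds are the distinct observed
  best-ERR values of the two profiles involved (no binning, no
  interpolation), restricted by the *strict* criterion ERR < ERRMAX.
  Curves are therefore deterministic step summaries of the data.
* **Prediction rule.** A sequence is predicted at grid value t when its
  best-hit ERR ≤ t (non-strict at the grid point, which is itself an
  observed value), while the ERRMAX truncation is strict; ties at
  exactly ERRMAX are excluded.
* **Virtual origin.** The trapezoid sum needs PREC(0) at REC(0) = 0,
  which no finite threshold defines; the precision of the first real
  point is carried backwards, the standard PR convention.  With it, a
  perfect classifier integrates to exactly 1 and a no-skill model to
  exactly 0.
* **Thresholds with TP = FP = 0** carry no prediction and are dropped;
  an entirely empty curve integrates to 0 with a warning.
* **Negative pAUPRC** (selection toward the negative set) is reported
  as computed, never clamped.
* **N handling.** Characters outside A/C/G/T/N are masked to N on
  input; windows containing N are unscoreable and are excluded from
  both the numerator and denominator of ERR — counting them as misses
  would bias ERR by N content.  Sequences shorter than a motif, or
  all-N, stay in the set as never-recognized, so NF is stable across
  motifs of different lengths.
* **Above-ceiling sentinel.** Scores milder than the calibration-table
  ceiling map to `Inf`; the arithmetic (elementwise min, strict
  comparisons) then handles them with no special cases.
* **ERR-table lookup** is a step function: a score gets the ERR of the
  most stringent tabulated threshold it reaches.  Monotonicity is exact
  because thresholds are the distinct observed scores; a quantile-grid
  mode (`n_grid`, default off, 10,000 points recommended) bounds table
  size for very large calibration sets at the cost of exactness between
  grid points.
* **Degenerate calibration.** A model scoring every window identically
  yields a single entry at ERR 1.0, which the ceiling truncates away; a
  "no usable thresholds" warning results and every profile value
  becomes the sentinel.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `errmax` | 0.002 | expected hits per scanned position | Partial-area bound; the recommended working range is 0.001 (stringent, target-TF motifs) to 0.01 (one hit per 100 bp, very permissive). 0.002 admits the less conserved motifs of partner TFs. |
| `err_ceiling` | 0.02 | same | Calibration-table truncation; thresholds milder than this are useless for recognition and only inflate the table. |
| `per_peak` (NB/NF) | 5 | sequences | Negative:positive ratio; the corrected precision removes the ratio's effect on the baseline, so this mainly controls the variance of FPR estimates. |
| `pseudocount` | 1.0 | counts | Laplace-style regularization of count matrices, distributed over bases proportionally to the background. |
| `background` | calibration-set composition (fallback uniform) | probabilities | Scoring and calibration then share one null model. |
| similarity `score_threshold`, `overlap_frac` | 0.9, 0.75 | — | A pair is flagged redundant only when near-identical columns cover most of the shorter motif. |

The PWM uses natural logarithms; the base is irrelevant because
thresholds are calibrated on the same scale, but it is fixed for
reproducibility.  None of pseudocount, log base or background are
dictated by the method itself; they are this package's documented
choices, and all are arguments.

## Design choices where the design was open

* **Redundancy is a flag, not a filter.**  Similar motif pairs are
  still analyzed and reported with their similarity score side by side
  with RAUC; filtering would hide exactly the comparisons a reader
  needs to judge.
* **Similarity measure.**  Mean column-wise Pearson correlation of
  frequency vectors over the best placement (all relative offsets, both
  orientations, overlap ≥ min(4, shorter length)).  Zero-variance
  (flat) columns correlate 1 with an equal column and 0 otherwise —
  a deterministic convention that keeps the measure symmetric.
* **External models** (e.g. dinucleotide-feature models trained by
  other software) enter as precomputed score tables over a fixed
  sequence set; training such models is out of scope.  Positions absent
  from a table are treated exactly like N windows.
* **Calibration tables on disk** are plain TSV with a metadata comment
  line, chosen for bit-reproducible round trips and golden-file
  testing.
* **Negative:positive ratio.**  The ratio convention is read as
  "several negatives per peak", i.e. NB = 5·NF by default; every
  formula stays general in NF/NB.
* **Tie-breaking** in rankings is lexicographic by motif name after
  RAUC and joint pAUPRC, making collection-scale outputs
  deterministic.
* **Implant placement** in the generator overwrites the background at
  the chosen offset (rather than inserting), preserving peak length and
  hence the position count across regimes; when one peak receives both
  motifs, the second placement avoids overlapping the first.

## What the synthetic generator does and does not emulate

`gen_background()` draws i.i.d. bases at a target G/C;
`gen_negatives()` matches each peak's length exactly and its G/C within
±0.02, emulating genome-sampled background selection;
`implant()` places motif instances under three regimes — independent,
co-occurring (indicators coincide per peak), mutually exclusive (never
both) — at uniform offsets and random strands, recording a truth table;
`gen_gaussian_profiles()` reproduces a published illustrative score
model (negatives N(5, 2.5); positives an equal mixture of N(10, 1) and
N(5.5, 4)) for direct PR-curve exercise.

Real peaks are not i.i.d.: they have positional motif enrichment at
summits, repeats, dinucleotide structure, copy-number artifacts and
heterogeneous quality.  Passing the synthetic recovery tests therefore
shows that the statistic separates the regimes it defines under a clean
null — not that any particular biological pair is mutually exclusive.
Dinucleotide-preserving shuffles are deliberately not offered as
negatives; length/G-C-matched sampling is the emulated practice.

## Problem sizes used by the test suite

The default benchmark universe is 500 peaks × 300 bp with two distinct
8-mer consensi at rates 0.5/0.5, five negatives per peak and a
200 × 3 kb calibration stand-in; the regime-recovery check runs it over
20 seeds per regime and requires the expected RAUC verdict (RAUC > 1
exclusive, RAUC ≤ 1.02 co-occurring) in at least 18 of 20.  Oracle
equivalence (exact trapezoid and survival-table brute force) runs on
hundreds of randomized small fixtures.  These sizes keep a full
pipeline run in single-digit seconds while leaving Monte-Carlo margins
wide.

## Known limitations

* Best-hit reduction ignores within-sequence multiplicity; motifs
  whose biology is copy-number dependent are summarized conservatively.
* ERR calibration inherits any composition bias of the chosen reference
  set; comparing motifs calibrated on different references is not
  meaningful.
* The PR curve is a step function over observed ERRs; no
  Davis–Goadrich interpolation is applied between points.
* The similarity screen addresses matrix redundancy only; two
  genuinely different matrices can still recognize overlapping site
  populations.
* RAUC compares a pair's joint motif with its best single; it does not
  test significance.  Seed-replicated synthetic runs (as in the test
  suite) are the supported way to gauge stability.
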