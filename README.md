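# jointmotif

Joint-motif precision–recall analysis of transcription-factor
binding-site (TFBS) motif pairs in ChIP-seq peak sets.

## The problem

A ChIP-seq experiment maps the genomic loci (peaks) bound by a target
transcription factor, usually as part of a multi-protein complex.  A
single factor may bind several structurally distinct site motifs, and
partner factors in the complex contribute motifs of their own.  Two
enriched motifs A and B can therefore relate to the peak set in two
ways: they **co-occur** (both motifs sit in the same peaks) or they are
**mutually exclusive** (each peak carries one motif or the other).
Mutual exclusivity is the signature of interchangeable binding modes —
structural variants of one factor's site, or sites of two factors that
substitute for each other in the complex.

`jointmotif` detects mutual exclusivity through a recognition-accuracy
argument.  Define the *joint motif* A&B as recognized in a sequence
when **at least one** of the two single motifs is recognized there.  If
A and B segregate into different peaks, the joint motif recovers the
union of both peak subsets while its false-positive rate grows far
less, so its recognition accuracy beats both singles.  If A and B mark
the same peaks, joining them adds false positives without new true
positives, and accuracy does not improve.

## The statistic

Heterogeneous motif models (position weight matrices, externally
trained models) are made comparable by calibrating every raw score
threshold to the **expected recognition rate** ERR: the fraction of
scanned positions (both strands) in a reference promoter set scoring at
or above the threshold.  Each sequence is then summarized by the ERR of
its best hit, and analysis is restricted to stringent thresholds
ERR < ERRMAX (default 0.002; recommended range 0.001–0.01).

With NF peaks and NB background sequences (NB = 5·NF by default,
G/C- and length-matched), at each ERR threshold:

- Recall: `REC = TPR = TP / NF`
- Corrected precision: `PREC = TPR / (TPR + FPR)` where `FPR = FP / NB`
  — the NF/NB normalization pins a no-skill model at `PREC = 0.5`
  regardless of the set-size ratio.

The partial area under the corrected PR curve, baseline-subtracted and
normalized to a maximum of 1, is

```
pAUPRC = 2 * Σ_i { (PREC(i) + PREC(i−1))/2 − 0.5 } * { REC(i) − REC(i−1) }
```

over all thresholds with ERR < ERRMAX (a virtual origin at recall 0
carries the first point's precision).  The decision statistic for a
pair is the ratio of areas under curves,

```
RAUC = pAUPRC(A&B) / max{ pAUPRC(A), pAUPRC(B) }
```

`RAUC > 1` flags mutually exclusive occurrence.  A PWM similarity
screen (best-placement mean column correlation over all offsets and
both orientations) guards against trivially redundant pairs.

## Worked example

A fully synthetic benchmark: 500 peaks of 300 bp in which two distinct
8-bp motifs are implanted mutually exclusively (each peak gets exactly
one of the two, probability 0.5/0.5), 5 G/C-matched negatives per peak,
and a 200 × 3 kb background stand-in for threshold calibration.

```r
library(jointmotif)

consensus_pcm <- function(s) {
  L <- nchar(s)
  counts <- matrix(1, L, 4)
  idx <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  counts[cbind(seq_len(L), idx)] <- 97
  motif_matrix(counts, name = s)
}

regime <- implant_regime("exclusive", "ACGTACGT", "GGATCCAT",
                         rate_a = 0.5, rate_b = 0.5)
u <- gen_universe(regime, seed = 101)

A <- calibrate(consensus_pcm("ACGTACGT"), u$promoters)
B <- calibrate(consensus_pcm("GGATCCAT"), u$promoters)

fit <- pair_analysis(A, B, u$positive, u$negative, errmax = 0.002)
fit
```

```
Joint-motif PR analysis: ACGTACGT + GGATCCAT
  NF = 500, NB = 2500, ERRMAX = 0.002
  pAUPRC: A = 0.5768, B = 0.6411, joint = 0.9757
  RAUC = 1.522  (joint motif outperforms both singles)
  similarity = 0.3333 [distinct]
```

Each single motif only ever sees its own half of the peaks, so its
partial area tops out near the accuracy achievable on half the set; the
joint motif recovers essentially all peaks at little extra
false-positive cost, and RAUC = 1.52 far exceeds 1 — mutual exclusivity
recovered.  The per-pair recognized fractions under ERRMAX tell the
same story:

```r
round(fit$recognized, 3)
#>     A     B joint
#> 0.730 0.814 1.000
```

`plot(fit)` draws the three PR curves; `coef(fit)` returns the pAUPRC
triplet and RAUC; `write_pair_report(fit, path)` and
`write_pr_curves(fit, path)` emit the TSV reports.  Re-running with
`implant_regime("cooccur", ...)` (both motifs in the same peaks) drives
RAUC back to ~1.

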