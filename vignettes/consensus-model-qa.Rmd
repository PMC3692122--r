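---
title: "Consensus quality assessment of protein models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus quality assessment of protein models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ConsensusQA)
```

# The problem and the model

Predicted 3D protein models carry errors that, without the native
structure, can only be estimated. ConsensusQA estimates them by
clustering: every model of a target is compared against all other models
in a pool, and models (and residues) that agree with the consensus are
predicted to be close to the native structure. The assumption doing the
work is that the pool samples the native basin more densely than any
single wrong fold — true when models come from reasonable predictors,
false when the pool is dominated by one systematically wrong answer (see
*Limitations*).

All models of a target are indexed against the target sequence: residue
correspondence is by residue sequence number, never by structural
re-alignment. Models whose numbering disagrees with the target (numbers
outside 1..L, insertion codes, duplicate numbers without altLoc codes)
are rejected rather than reconciled; silent re-alignment would change
what the per-residue output means.

## Pairwise comparison

Two complementary similarity measures are computed for each of the
N(N−1)/2 unordered model pairs:

**TM-score.** The maximum over rigid motions of
$\frac{1}{L}\sum_i \frac{1}{1+(d_i/d_0(L))^2}$ with
$d_0(L)=1.24(L-15)^{1/3}-1.8$, floored at 0.5 Å. We normalize by the
*target length* L, the conventional choice when all models address one
target; it keeps the score comparable across models with different
coverage and penalizes incomplete models. The alternative
(common-residue count) is exposed through the `normLength` argument of
`tmSuperpose()`.

**Q-score.** An alignment-free comparison of intramolecular CA–CA
distance matrices over the Nc common positions:
$Q=\frac{2}{(N_c-1)(N_c-2)}\sum_{k\ge j+2}
\exp\!\big(-(d^A_{jk}-d^B_{jk})^2/2\sigma_{jk}^2\big)$,
$\sigma_{jk}=|j-k|^{0.15}$. Pairs of sequence separation < 2 are
excluded as trivially constrained by the chain. Q needs no superposition,
which makes it cheap and robust, at a price documented in its tests: it
is invariant under mirror reflection and cannot detect chirality errors.
The σ exponent is configurable (`sigmaExponent`); 0.15 is the
conventional value and nothing in the package's guarantees depends on its
exact magnitude.

## Global score, local scores

The global score blends the two consensus means,
$G_i = w\,\overline{TM}_i + (1-w)\,\overline{Q}_i$ with default
$w = 0.5$. The combination is stated in the method lineage without
weights; an unweighted mean is the neutral reading, and `weight` is a
user-visible parameter for anyone wanting a TM-only ($w=1$) or Q-only
($w=0$) engine.

Local quality uses the S-score of each superposition distance:
$S_i = 1/(1+(d_i/d_0)^2)$ with $d_0=3.9$ Å and a hard zero for
$d_i > 3.9$ Å. The cutoff is applied per alignment, *before* averaging,
because it is attached to the definition of $S_i$ itself. The mean over
the N−1 alignments divides by N−1 regardless of coverage: a partner model
lacking the residue contributes 0 rather than being skipped, since
skipping would silently re-weight residues by coverage and inflate scores
in sparsely modelled regions. Per-residue distances come only from
TM-score superpositions; Q contributes no per-residue distances.

The predicted distance inverts the mean S-score,
$d_r = d_0\sqrt{1/S_r - 1}$, capped at 15 Å; the inversion is exact for
$d \in [0, 3.9]$ (`predictedDistance(residueSScore(d)) == d`). Positions
absent from the scored model are reported as `X`, so per-residue coverage
plus gap markers always equals L.

## P-values

The global score of a model is converted into the probability that the
model is *incorrect* — that it shares no similarity with the native
structure. Models with TM-score to the native strictly below 0.2 define
the null: their global scores are collected, a Gaussian kernel density
(Silverman's bandwidth) is fitted with boundary reflection on [0, 1] so no
mass leaks outside the score's support, and the upper-tail mass at a
score s is the P-value. The direction is forced by the question asked:
high scores make "incorrect" unlikely. P-values are floored at 1e-6 — a
reportable minimum, not a statistical claim, since no desk-scale
calibration set resolves smaller tails. A nonparametric density was
chosen over a parametric (e.g. extreme-value) fit because the null score
distribution's shape depends on pool composition; the KDE makes no shape
commitment and the `bandwidth` argument allows overriding the default.

Calibration inputs are a two-column text file (`global_score native_tm`)
so users can calibrate against their own decoy sets;
`makeCalibrationSet()` builds a synthetic one from random-walk decoys
scored inside mixed pools (each batch of incorrect models is pooled with
a few near-native companions, so the null scores are produced by the same
engine and pool shape as real runs).

# Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `weight` (w) | 0.5 | – | TM vs Q blend in the global score |
| `d0` (S-score) | 3.9 | Å | distance threshold; S(3.9) = 0.5, S = 0 beyond |
| `cap` | 15 | Å | upper limit of the predicted distance d_r |
| `sigmaExponent` | 0.15 | – | sequence-separation width of the Q-score |
| `threshold` | 0.2 | TM | native-TM cutoff defining "incorrect" (strict <) |
| `minIncorrect` | 50 | models | smallest calibration set accepted |
| `normLength` | L | residues | TM-score normalization length |

# Numerical choices

- **TM search.** Fragment seeds of lengths {n, n/2, n/4, 4} at stride
  len/4, each refined over a cutoff schedule descending 8 Å → d₀, with
  subset-fixed-point termination (30 iterations max, fallback to the 4
  closest residues when fewer than 3 fall inside a cutoff). The inner
  loop is compiled (RcppArmadillo). Distances d_i are reported for *all*
  common positions under the final transform, because the S-score needs
  every residue. Correctness is checked against an independent direct
  numerical maximization over rigid motions (multi-start Nelder–Mead on
  quaternion + translation): at L = 40 the two agree to < 0.01 across
  TM ≈ 0.25–0.95. At very short lengths (L ≤ 21, where d₀ is floored at
  0.5 Å) the TM optimum for *essentially dissimilar* pairs is
  ill-conditioned — a handful of atoms aligned within fractions of an
  Ångström decide the score — and any two search heuristics can disagree
  by more than 0.01 in either direction at TM ≈ 0.1; the oracle
  cross-check therefore runs at L = 40, and short-target scores in that
  regime should be read as "no similarity" rather than compared at the
  third decimal.
- **Kabsch.** SVD with the usual determinant correction; reflections are
  never returned. Degenerate (collinear) inputs still yield a valid
  least-squares rotation; the rotation component around the axis is then
  arbitrary but the distances are not.
- **Failed comparisons.** A pair sharing fewer than 3 (TM) or 4 (Q)
  residues contributes TM = 0, Q = 0, S = 0, with a warning — a
  conservative penalty rather than an exclusion, so the N−1 divisor never
  silently changes.
- **Ties.** Ranked output sorts by global score descending, ties broken
  by model name, so reruns are byte-identical.
- **Atomic writes.** Every output file is written to a temp name and
  renamed, so consumers never observe a half-written QMODE2 or PDB.
- **Determinism.** All generators funnel randomness through an explicit
  seed (`withSeed` preserves the caller's RNG state); fixtures regenerate
  byte-identically.

# The synthetic-data generator

`makeNative()` builds self-avoiding CA-only folds from ideal α-helical
segments (6–12 residues) joined at randomized turn directions, with
consecutive CA–CA distances inside 3.8 ± 0.05 Å and no two
sequence-distant residues closer than 3.5 Å. `makeDecoys()` adds
isotropic Gaussian coordinate noise and optional coherent window
displacements, records the ground-truth per-residue deviation, and
applies a random rigid motion so superposition is never trivial.
Calibration sets use uncorrelated random walks (3.8 Å steps), rejection
sampled to TM < 0.2 against the native.

What this emulates: pools with a quality gradient, localized model
errors, and score nulls from no-similarity decoys. What it does not:
physically realistic decoy ensembles (side chains, secondary-structure
biased errors, template-driven correlated mistakes shared by many
models). Passing the recovery tests therefore shows the engine ranks
models by true similarity and localizes injected errors *under
independent-noise conditions*; it does not certify performance when many
pool members share the same wrong template, the known failure mode of
every consensus method.

Test problem sizes (the package's own choices, stated for
reproducibility): pools of 20 decoys at L = 30 over 20 replicates for the
ranking/localization checks; 300-model calibration plus 200 held-out
decoys at L = 30 for P-value uniformity; pools of ≤ 6 models for the
exact naive-loop equivalence check (tolerance 1e-9).

# Design decisions that were genuinely open

- **Pool de-duplication.** User submissions are never merged — duplicate
  submissions are each scored (and, by symmetry, score identically);
  reference models identical in content to a user model or an earlier
  reference are dropped. This keeps "every submitted model appears once
  in the output" true while avoiding double-counting internal references.
- **Reference models** are scored (they shape every mean) but reported
  separately: the tool answers for the models the user submitted.
- **Off-by-one numbering** between a model and its target is rejected,
  not auto-corrected: an automatic shift would be a guess presented as
  data.
- **Quasi-single-model mode** requires a non-empty reference pool by
  construction; with no pool there is no consensus signal, and the error
  message says exactly that.

# Limitations

- Consensus scores are relative to the pool. A pool of uniformly bad or
  mutually similar wrong models yields confident-looking nonsense;
  the P-value (calibrated against no-similarity decoys) flags "not
  random", not "correct".
- Only CA geometry is scored: no stereochemistry, packing or side-chain
  assessment of any kind.
- The shipped calibration procedure is synthetic; for publication-grade
  P-values, calibrate on scores of real decoys of targets with known
  structures via the calibration-file interface.
- Single-chain, single-domain operation: multi-chain and multi-MODEL
  files are truncated to the first, with a warning.
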