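# ConsensusQA

Consensus (clustering) quality assessment of 3D protein models.

Once a 3D model of a protein has been predicted, how good is it — and which
of its regions can be trusted? Without the native structure, the most
reliable answers come from *consensus*: models of the same target that
agree with many alternative models tend to be close to the native
structure. ConsensusQA implements that idea end to end for structural
biologists and method developers. Given a target sequence and a pool of
candidate models, it produces for every model

- a **global quality score** in [0, 1],
- a **P-value** that the model is incorrect (shares no similarity with the
  native structure), and
- **per-residue predicted distances** (Å) of each residue from its native
  position, written both as CASP QA (QMODE2) records and into the B-factor
  column of the model's PDB file for temperature-style colouring.

A single submitted model is handled in *quasi-single-model* mode: it is
pooled with a user-supplied reference model set and gauged against it,
preserving the predictive power of clustering methods for the
one-model-at-a-time use case.

## The method

All models of one target are numbered against the target sequence
(positions 1..L), so residue correspondence is by residue number. For the
pool of N models, all N(N−1)/2 pairwise comparisons are computed once,
combining two complementary similarity measures:

- **TM-score** under optimal rigid-body superposition, normalized by the
  target length L, with the length-dependent scale
  d₀(L) = 1.24·(L−15)^⅓ − 1.8 (floored at 0.5 Å). The superposition search
  seeds least-squares (Kabsch) fits from contiguous fragments and refines
  them by iterative cutoff-restricted re-superposition.
- **Q-score**, an alignment-free comparison of the models' internal CA–CA
  distance matrices, with sequence-separation-dependent widths
  σ_jk = |j−k|^0.15 (pairs of separation < 2 excluded).

The global score of model i is the blend

    G_i = w · meanTM_i + (1 − w) · meanQ_i,      w = 0.5 by default,

where the means run over the other N−1 models. Local quality uses the
per-residue S-score of each pairwise superposition distance d_i:

    S_i = 1 / (1 + (d_i/d₀)²),   d₀ = 3.9 Å,   S_i = 0 if d_i > 3.9 Å,

averaged over the N−1 alignments (an alignment lacking the residue
contributes 0; the divisor stays N−1):

    S_r = (1/(N−1)) Σ_a S_ia,

and inverted into a predicted distance from the native structure,

    d_r = d₀ · √(1/S_r − 1),   capped at 15 Å,

with `X` marking target positions absent from the model. P-values come
from a calibration: global scores of known-incorrect models (TM-score to
the native < 0.2) form a null distribution; a boundary-reflected kernel
density is fitted on [0, 1] and its upper-tail mass at a score is the
P-value that a model achieving that score is incorrect.

A synthetic-data module generates the benchmarking inputs: self-avoiding
helical CA traces as toy natives, decoy pools with controlled global noise
and injected local displacements (with ground-truth per-residue
deviations), and random-walk decoy calibration sets.

## Worked example

```r
library(ConsensusQA)

native <- makeNative(40, seed = 7)                 # toy native fold
target <- new("TargetSequence", id = "toy40", residues = rep("A", 40))
specs  <- lapply(1:8, function(k)
  decoySpec(globalNoise = 0.5 * k,                 # noise ladder 0.5..4 A
            perturbations = if (k == 3) list(c(15, 20, 6)) else list(),
            seed = 100 + k))
pool <- buildPool(makeDecoys(native, specs), list(), target)
pool
#> ModelPool for target 'toy40' (L = 40)
#>   8 user model(s) + 0 reference model(s); N = 8 [full-clustering mode]

res <- scorePool(pool)
globalScores(res)[, c("model", "globalScore", "meanTM", "meanQ")]
#>           model globalScore meanTM meanQ
#> 1 decoy001_s101       0.360  0.317 0.403
#> 2 decoy002_s102       0.337  0.286 0.387
#> 3 decoy003_s103       0.307  0.254 0.359
#> 4 decoy004_s104       0.286  0.235 0.337
#> 5 decoy005_s105       0.263  0.216 0.309
#> 6 decoy006_s106       0.224  0.183 0.266
#> 7 decoy008_s108       0.204  0.164 0.244
#> 8 decoy007_s107       0.199  0.164 0.234
```

The ranking recovers the noise ladder: the least-perturbed decoy scores
highest. Decoy 3 carries a 6 Å displacement injected into residues 15–20,
and its per-residue predicted distances flag exactly that region:

```r
ls3 <- localScores(res, "decoy003_s103")
mean(ls3$dr[15:20])    # inside the displaced window: 9.69 A
mean(ls3$dr[-(15:20)]) # elsewhere:                   5.86 A
```

`writeQAFile(res, mode = 2, path = "qa.txt")` emits the CASP QMODE2
records, and `writeAnnotatedPdb(annotateModel(m, res@dr[, id]), path)`
writes the model with d_r in the B-factor column. The shell interface
(`inst/scripts/qa.R`) wires the same steps together:

```sh
Rscript inst/scripts/qa.R score --target t.fasta --models dir/ \
    [--refpool dir/] [--calibration cal.txt] [--weight 0.5] --out out/
Rscript inst/scripts/qa.R calibrate --out cal.txt --length 40 --n 60
Rscript inst/scripts/qa.R fixtures  --out fx/ --length 30 --n 10
```

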