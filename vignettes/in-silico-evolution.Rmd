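---
title: "In silico evolution of bicyclic peptide inhibitors: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico evolution of bicyclic peptide inhibitors: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepdca)
```

## The problem

Bicyclic peptides are short linear peptides with three cysteines cyclized
onto a trivalent organic linker, forming two constrained loops on a fixed
scaffold. Phage display can select potent inhibitors of protease targets
such as human urokinase-type plasminogen activator (huPA) or coagulation
factor XIIa, but the affinity-matured families it yields are tiny — tens of
fixed-length sequences with measured inhibition constants (Ki) spanning two
to three orders of magnitude. That regime is far too small for deep
generative models, yet the design space (20^L for loop length L) is far too
large for exhaustive exploration.

`pepdca` implements a pipeline for this regime that combines an unsupervised
statistical sequence model with a supervised affinity regressor:

1. fit a **Potts model** to the family alignment by regularized
   **pseudolikelihood maximization** (plmDCA);
2. generate novel scaffold-constrained sequences by **Metropolis Monte
   Carlo**, using the Potts score as the effective energy;
3. predict Ki for every novel sequence with a **random-forest regressor**
   trained on the measured family, and keep sequences predicted strictly
   below a percentile threshold;
4. distill the selected pool into a **position-frequency logo** and
   **consensus design candidates**.

A leave-out harness reruns the whole pipeline with known binders removed and
checks whether they are regenerated de novo — the validation experiment that
motivates trusting the designs.

## The Potts model and its fit

Sequences `s` of fixed length `L` over the 20-letter alphabet are scored by

    S(s) = sum_i h_i(s_i) + sum_{i<j} J_ij(s_i, s_j),      P(s) ∝ exp(S(s))

where the fields `h` capture per-position conservation and the couplings `J`
capture residue covariation. The joint likelihood is intractable (its
normalizer sums over 20^L states), so the fit maximizes the pseudolikelihood
— the product of per-site conditionals, each an ordinary softmax:

    P(s_r | s_{-r}) = exp(h_r(s_r) + sum_{j≠r} J_rj(s_r, s_j)) / Z_r .

`fit_plmdca()` minimizes the weighted, Meff-normalized negative
pseudolikelihood plus per-parameter L2 penalties `lambda_h ||h||^2 +
lambda_J sum ||J_ij||^2` with an analytic gradient and L-BFGS-B from the
zero model. Choices worth knowing:

* **Symmetric fit.** One shared coupling tensor enters both conditionals it
  affects (the "joint" pseudolikelihood), rather than the asymmetric
  per-site variant with post-hoc averaging. The sampler needs one coherent
  energy, and at n ≈ 30–60 the computational argument for asymmetric fitting
  disappears.
* **Regularization defaults** `lambda_h = lambda_J = 0.01` (per parameter,
  on the normalized objective): conventional plmDCA magnitudes, and
  essential — the families have far fewer sequences than parameters.
* **Reweighting off by default.** Similarity reweighting (`w_m = 1/#{m':
  identity ≥ 0.8}`) is standard for evolutionary alignments but these
  curated families are deliberately similar; silently collapsing Meff would
  be surprising. `sequence_weights()` is available and logged when enabled.
* **Fixed scaffold positions are ordinary columns** during fitting — their
  fields absorb the perfect conservation — and are constrained only at
  sampling time. Under the zero-sum gauge a frozen column contributes no
  coupling norm, so this is the simplest consistent treatment.
* **Convergence**: projected-gradient max-norm ≤ 1e-5 or 500 iterations;
  non-convergence returns the best-so-far model with a warning and is
  recorded in `$meta`, never thrown. The fit is deterministic given data and
  configuration.

Couplings are reported in the **zero-sum gauge** (every block centered so
rows and columns sum to zero; the removed means are absorbed into fields,
leaving all score differences unchanged to numerical precision). Pair
rankings use the Frobenius norm of the centered blocks with the
**average-product correction** `APC_ij = F_ij − F_i·F_·j / F_··`, the
standard background correction for uneven coupling mass. Ties (e.g. the zero
model) fall back to lexicographic `(i, j)` order so output is stable.

## Monte Carlo sequence generation

`sample_sequences()` runs independent single-site Metropolis chains:
a uniformly chosen variable position is mutated to a uniformly chosen
different residue (a symmetric proposal; scaffold-fixed positions are never
touched) and accepted with probability `min(1, exp((S' − S)/T))`. Scores are
updated incrementally in O(L) per step; the chain's running score agrees
with a full O(L^2) rescore to 1e-9 over 10^4 steps (tested). At stationarity
the records follow the Boltzmann distribution `exp(S/T)/Z` — verified
against exhaustive enumeration on a 256-state model, where 10^5 recorded
states land within total-variation distance 0.02 of the exact table.

Defaults: `T = 1` (the plmDCA score used as-is as the effective energy —
exposed for annealing experiments), 50 chains x 2000 steps, burn-in 500,
thinning 10, chain `k` seeded as `seed + k`, chains started from random
training sequences (keeping them in the data basin; random conformant starts
are available). Recorded states are deduplicated (first occurrence,
multiplicity kept as `count`) and partitioned into novel vs training. Runs
are bitwise-reproducible for a fixed seed within this implementation; across
implementations with different generators only distributional equivalence
can be promised.

The published campaigns report pool sizes of roughly 10^3–10^4 unique
sequences per round without stating chain counts or run lengths; pool sizes
here are treated as scale indicators only, never as reproduction targets.

## Affinity regression and the selection rule

`fit_regressor()` trains a random forest on `y = log10(Ki / 1 nM)` — the
families span 250–750-fold Ki ranges, so an untransformed target would be
dominated by the weakest binders. Features are a one-hot block over the
variable positions plus sequence-level descriptors (Kyte–Doolittle mean
hydropathy, additive net charge at pH 7.4 with D/E = −1, K/R = +1, H = 0,
molecular weight, and residue-class counts); the per-residue constants ship
as a versioned CSV in `inst/extdata/`. The exact feature table used in the
original campaigns is unpublished, so this descriptor block is a documented
surrogate; the one-hot block alone carries most of the signal at these
family sizes.

The report pairs an in-sample RMSE with a k-fold cross-validated RMSE
(`k = min(5, n)`, folds fixed by the seed). At n ≈ 37 the gap between the
two is substantial — the overfitting that motivates using the forest only as
a *filter*, not as a designer. The synthetic learning-curve test shows the
gap closing and held-out rank correlation exceeding 0.5 once n reaches 200.

Selection keeps sequences predicted **strictly below** the
linear-interpolation percentile threshold (`pct = 50` is the sample median).
The published campaigns quote "the 50th percentile" alongside selected
fractions that range from half the pool down to a few percent, so the
reference distribution is ambiguous; both options are implemented
(`percentile_reference = "generated"` — the default, the percentile of the
pool's own predictions — or `"training"`, the percentile of the measured
family Ki) and the choice is recorded in the manifest.

## Candidate design

`design_candidates()` implements the reproducible part of the published
design step: the consensus (top-frequency residue per variable position)
first, then combinatorial expansion at positions where the runner-up
frequency reaches `runner_up_fraction` x the top frequency, positions
expanded in decreasing runner-up-ratio order, capped at `max_candidates`,
frequency ties broken by alphabet order. Three binary-ambiguous positions
yield the familiar 2^3 = 8 candidate panel. The published final designs were
additionally curated with target-complex structures; that expert step is
deliberately out of scope — the runner-up ratios are surfaced so a human can
replicate it.

Iterative campaigns (augmenting the family with newly measured designs and
rerunning) are expressed by calling `run_generation_round()` on the extended
record table; there is no special second-round code path.

## The leave-out validation

`suggest_holdouts()` mirrors the published protocol: candidates for removal
have Ki strictly below the family median, exclude the single most potent
record, and are capped at `floor(max_fraction * n)` (about 5%).
`leave_out_experiment()` reruns the full round on the depleted family and
reports which held-out sequences reappear in the selected pool, with their
pool ranks by Potts score and by predicted Ki. A held-out sequence that
still equals a remaining training sequence is flagged as degenerate rather
than celebrated.

## The synthetic-data module

Every stage is tested against generators with known ground truth, so the
package needs no external data:

* `make_planted_model()` draws small-variance background fields/couplings,
  boosts one residue at each conserved position by `field_scale`, and boosts
  the coupling entry of the background-favored residue pair at each planted
  position pair by `coupling_scale`. Planted pairs are spread over positions
  as a matching: piling several planted pairs onto few positions puts their
  signal exactly where the average-product correction subtracts background,
  which benchmarks the corrector, not the method. Similarly, couplings
  planted between residues the fields make rare would be invisible in any
  finite family. The default conserved-position strength (field scale 2,
  top-residue frequency ≈ 0.5 at q = 8) keeps conservation and covariation
  distinguishable: at near-frozen positions the L2 penalty starts spreading
  the conservation signal into coupling rows, a known small-L artifact.
* `enumerate_distribution()` is the exact Boltzmann oracle (refuses state
  spaces above 10^6); `sample_family()` draws i.i.d. from it, or takes
  well-spaced MC states when the space is too large.
* `make_landscape()` + `observe_ki()` provide a ground-truth affinity
  surface: additive per-(position, residue) effects, sparse pair effects,
  and lognormal observation noise (0.15 log10 units by default). When
  aligned with a planted model, conserved residues and planted coupling
  entries receive favorable contributions — in the real campaigns binders
  were phage-selected, so sequence statistics and affinity are entangled,
  and the tests should reflect that coupling. The intercept is calibrated so
  the median Ki of the relevant population is ~100 nM and the realized range
  covers well over 250-fold, matching the published family spreads.

Two standard configurations are exported. `standard_benchmark()` (L = 10,
q = 8, 2 conserved positions, 5 planted pairs, coupling boost 10x the
background sd, family of 2000, generator seed 20240101) is the
planted-coupling recovery setting. `synthetic_family_benchmark()` (same
alphabet, fixed termini, 6 strongly conserved positions with field scale 4,
3 planted pairs, 50 unique records from an aligned landscape) is the
full-pipeline setting used by the leave-out harness; its stronger
conservation matches the near-fixed consensus stretches of the real families
and keeps the model's typical set small enough that a desk-scale pool can
cover it.

What the generators deliberately do **not** emulate: phage-display selection
dynamics, assay error structure beyond lognormal noise, linker chemistry
(the cyclization linker is excluded from featurization — it is constant
within a family and imposes no binding contacts), or 20-letter alphabets at
benchmark scale. Passing tests therefore demonstrate correctness of the
machinery and recoverability under realistic-but-idealized statistics, not
wet-lab performance.

## Numerical choices and degenerate inputs

* Site conditionals use max-shifted softmax; objectives are in nats.
* 1-based positions everywhere; 0-based indices exist only at the C++
  boundary.
* Gap characters are rejected: the families are fixed-length ungapped
  alignments by construction.
* Ki are stored in molar units internally; I/O states units explicitly
  (`M`, `mM`, `uM`/`µM`, `nM`).
* Logo heights are information content in bits without small-sample
  correction — at n ≈ 30–60 the correction term would dominate the heights.
* Empty novel pools and empty selections return empty results with warnings,
  never exceptions; stage failures propagate with a stage tag.
* `percentile_threshold()` accepts `pct = 100` (the maximum), which under
  the strict `<` rule keeps everything except the top ties.
* A single master seed derives all stage seeds (sampler `+1e6`, regressor
  `+2e6`); the manifest records every seed, count, threshold and a result
  hash, and identical inputs give identical hashes.

## Problem sizes in the test-suite and acceptance runs

The suite fits L = 5–10, q = 4–8 models (n up to 2000), compares the sampler
to a 256-state exact table with 10^5 recorded states, and repeats the
leave-out round for 10 master seeds at 50 chains x 3000 steps — sizes chosen
so the whole suite runs in about a minute on a laptop while keeping every
statistical check comfortably away from its tolerance.

## Known limitations

* At L ≈ 10 the average-product correction is aggressive; coupling rankings
  on real 14–17-mers should be read together with the raw Frobenius norms.
* The forest extrapolates poorly outside the training alphabet usage; its
  predictions are a ranking device, and the absolute thresholds it produces
  inherit the family's measurement scale.
* The design rule is frequency-based and position-independent; epistatic
  combinations present in the couplings but absent from the selected pool's
  marginals will not surface as candidates.
* Bitwise reproducibility is promised within this implementation only.
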