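---
title: "Sequence-based chemical-shift prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-based chemical-shift prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqcs)
```

## The problem

NMR chemical shifts (CS) are exquisitely sensitive probes of protein local
structure. For folded proteins, accurate predictors usually exploit the
3D structure; for intrinsically disordered proteins (IDPs) no stable
structure exists, and the shifts are governed almost entirely by the local
sequence. `seqcs` predicts shifts from sequence alone: a statistical
(kernel-density) model for disordered chains, and a secondary-structure
conditioned variant — plus a small neural refiner — for folded chains
whose 3-state (Q3) secondary structure is known or predicted.

## The kernel model

For an atom type $A$ of residue type $i$, the training shifts
$\delta_1,\dots,\delta_n$ of that category define a Gaussian-kernel
density

$$\hat d_i^A(\delta) = \frac{1}{n}\sum_{l=1}^{n} G_K(\delta-\delta_l),$$

with $G_K$ a unit-mass Gaussian of width equal to the kernel bandwidth.
The **primary prediction term** $\delta_i^A$ is the expectation of this
density: the density-weighted mean when the category is rich
(`n_min_mean`, default 50, or more observations), otherwise the mode,
which is more robust for sparse categories. Ties at the mode break toward
lower ppm.

**Neighbour corrections.** The local sequence within ±2 residues
modulates the shift. For a centre residue $i$ with neighbour $j$ at
offset $o \in \{-2,-1,+1,+2\}$, the pair-conditioned density
$\hat d_{i,j}^A$ over the matching sub-dataset yields a correction
$\Delta\delta_{i,j}^A = \delta_{i,j}^A - \delta_i^A$. Pairs with fewer
than `n_min` (default 20) observations fall back to an **averaged**
correction: the pooled effect of neighbour $j$ at that offset on all
centre types, computed on residuals (observed minus the centre's primary
expectation).

Each correction carries a weight equal to the *negative overlap* of the
primary and pair densities,

$$w = 1 - \int \min\!\big(\hat d_i^A(\delta), \hat d_{i,j}^A(\delta)\big)\,d\delta ,$$

so a neighbour whose conditional distribution is indistinguishable from
the marginal contributes nothing ($w=0$), while a strongly displacing
neighbour (e.g. a following proline) gets full weight. For averaged
corrections the same overlap is taken between the pooled residual density
and the neighbour-conditioned residual density — the paper-level
definition applies only to specific pairs, so this is the package's own
(documented) extension.

The assembled per-residue prediction is

$$CS_i^A = \delta_i^A + \frac{1}{N_W}\sum_{o} w^A_{i,j_o}\,\Delta\delta^A_{i,j_o},$$

where $N_W$ is a per-atom normalisation balancing the primary term
against the corrections, calibrated by grid search (0.5–10, step 0.1)
minimising the training RMSD; ties break to the smallest value. Missing
neighbours at chain termini simply contribute no summand.

### Numerical choices

* **Bandwidth**: Silverman's rule per sample, floored at 0.02 ppm (1H)
  and 0.05 ppm (13C/15N). The floor prevents degenerate spikes for
  near-duplicate samples.
* **Grid**: uniform, step = bandwidth/4, extended 5 bandwidths beyond the
  sample range. This bounds the trapezoidal normalisation error below
  1e-6 (asserted for every density the tests build).
* **Overlap integrals**: both densities are linearly resampled onto the
  union grid at the finer step and renormalised before taking
  $\int\min$; this makes $w(d,d)$ exactly 0 in floating point.
* **Serialisation**: JSON with 17 significant digits, which round-trips
  IEEE-754 doubles bit-exactly (the jsonlite default of 15 does not).

## Curation

Training collections pass three filters. (1) *Redundancy*: greedy
representative selection — entries visited by decreasing record count,
kept only if global Needleman–Wunsch identity (match 1, mismatch 0,
gap −1; identity = matches / alignment columns) to every kept entry is
≤ 90%. (2) *Referencing*: per nucleus (inferred from the atom name's
first letter), the mean offset of an entry's shifts from the collection's
expected centres; entries fail beyond 1.5 / 0.5 / 3.5 ppm for
13C / 1H / 15N. (3) *Outliers*: individual values more than 3.5 SD from
their category centre are dropped. Because removal shrinks the
re-estimated spreads, the pipeline iterates step 3 to a fixed point,
which makes the whole curation idempotent. Reference centres and spreads
are estimated from the collection itself (per atom × residue, and per Q3
state when labels exist), so no external tables are needed.

## Folded proteins: Q3 conditioning and boundaries

Separate kernel models are trained for helix (H), strand (E) and coil
(C); DSSP-style 8-state labels collapse as H,G→H, E→E, rest→C. Each
record contributes only to its own state's model. By default the first
and last 2 residues of every segment are excluded from the per-state
statistics (`interior_trim = 2`): boundary regions systematically morph
between the adjacent states' secondary shifts, and leaving them in biases
the state expectations by exactly the effect the boundary profiles are
meant to capture. The same 2-residue figure is the standard evaluation
mask for Q3-segment benchmarks.

**Boundary profiles.** For every ordered transition type (H→C is not
C→H) and atom, the mean and SD of the *secondary shifts* (observed minus
the coil-state expectation — the package's random-coil reference) are
tabulated at signed distances −6…−1 (last residues of the first segment)
and +1…+6 (first residues of the second). At prediction time, a residue
within the half-window of its nearest boundary (ties to the preceding
one) receives an additive correction that replaces its state's mean
secondary-shift contribution with the profile value:
`correction = profile_mean − state_mean_secondary`. Missing profile
cells leave the prediction uncorrected and flagged.

## The neural refiner

When Q3 comes from a secondary-structure predictor rather than a
structure, label errors propagate directly into the per-state kernel
prediction. A feedforward regressor — 143 inputs, one hidden layer of 50
tanh units, linear output — absorbs part of this uncertainty by looking
at a 7-residue window of labels (4 nodes per position: three state
indicators plus a terminal-region indicator) and a 5-residue sequence
window (23 nodes per position: BLOSUM-62 row scores extended to the
23-letter alphabet, variants inheriting their parent's row with their own
diagonal slot). Targets are secondary shifts, z-scored per atom; inputs
are standardised per node; training minimises MSE with Adam
(lr 1e-3, β = 0.9/0.999, batch 64, ≤200 epochs, fixed seed).

The training-protocol details are not prescribed anywhere, and they
matter: without regularisation the network memorises observation noise
(on synthetic data with amide-N noise σ = 1 ppm we measured train RMSD
0.11 ppm vs held-out 1.76 ppm). The package therefore holds out a
deterministic 10% validation split and keeps the weights of the
best-validation epoch, stopping after 20 epochs without improvement.
With this protocol the refiner's held-out RMSD under 10% Q3 label
corruption beats the kernel predictor on CA by ~16% on the synthetic
preset, reproducing the qualitative rationale for coupling a network to
the kernel model. Whether the network *replaces* or *augments* the kernel
prediction is left open in the source method; `seqcs` exposes both
(`--mode kernel` / `--mode nn`) and treats the NN output as
`coil expectation + network secondary shift`.

## The synthetic world

Every stage is testable without downloads because the generator emits
databases whose ground truth is known exactly:

* per-(residue, atom) base shifts on a realistic random-coil scale
  (synthetic stand-ins, not literature values);
* sparse additive neighbour effects, independent across offsets — by
  construction exactly the structure the assembled predictor can
  represent, so recovery tests probe correctness, not model adequacy.
  The preset plants strong, chemically plausible effects (following
  proline −6σ, preceding glycine +4σ, following aspartate +3σ,
  tryptophan at −2 −3σ, scaled by each atom's noise SD), chosen a priori
  and never tuned against test outcomes;
* per-Q3-state offsets (helix−coil CA = +3.2 ppm, helix N = −0.95 ppm,
  strand CA = −2.0 ppm, …) with alternating segments of geometric length
  (minimum 8, mean ≈ 30);
* a one-sided linear boundary ramp: entering a new segment, the state
  offset interpolates from the previous segment's value over `ramp_len`
  residues (preset: 2). Real boundary profiles deviate on both sides of
  the boundary and can be non-monotonic (amide N famously overshoots);
  the stated world is deliberately simpler so that recovery is exact;
* Gaussian observation noise per atom (preset: 0.3 ppm 13C, 0.05 ppm 1H,
  1.0 ppm 15N), plus optional planted outliers and per-nucleus
  referencing offsets for the curation tests.

A green test on this world therefore establishes that the estimators
recover what they model — it does not establish accuracy on real BMRB
data, whose neighbour effects are dense, heteroscedastic and
pH-dependent.

## Known limitations

* Two pH parameterisations only (6.4 / 2.8, bin boundary 4.5); no
  interpolation at intermediate pH.
* No triplet or longer-range corrections; no structure-based terms (ring
  currents, hydrogen bonds), which bound accuracy for folded side-chain
  protons.
* The greedy identity clusterer is exact but quadratic; it is meant for
  desk-scale collections, not full-archive deduplication.
* `predict_folded` applies at most one boundary correction per residue
  (nearest boundary); residues of very short segments inside two
  half-windows get the nearer one only.

## A worked round trip

```{r example, eval = FALSE}
g <- generate_synthetic(idp_preset(seed = 7))
model <- train_kernel_model(g$entries)
pred <- predict_idp(g$entries[[1]]$sequence, model)
head(pred)

bench <- loo_benchmark(
  g$entries,
  train_fn   = function(tr) train_kernel_model(tr),
  predict_fn = function(m, e) predict_idp(e$sequence, m))
bench$per_atom   # per-atom RMSD ~ the planted noise floor
```
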