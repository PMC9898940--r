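---
title: "Atom-based uncertainty quantification for molecular property regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atom-based uncertainty quantification for molecular property regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Deep-learning regressors for molecular properties are increasingly used to
triage compounds in drug discovery and materials screening, where acting on
a wrong prediction is costly. Two questions matter beyond the point
estimate: *how uncertain* is a prediction, and *why*. `atomuq` implements a
heteroscedastic graph neural network that answers both at the atomic level:
every prediction decomposes into per-atom property contributions with
per-atom aleatoric (label-noise) and epistemic (model-ignorance)
uncertainties, so a chemist can see *which part of the molecule* the model
is unsure about.

## Model

### Encoder

Molecules enter as SMILES and are featurized into heavy-atom graphs
(hydrogens are implicit and enter as an atom feature, the common convention
for message passing on molecular graphs). Atom features are element one-hot
(C/N/O/F/P/S/Cl/Br/I/other), degree, formal charge, bonded-H count,
hybridization, aromaticity and scaled mass (35 columns); bond features are
a no-bond slot, bond-type one-hot, conjugation and ring membership
(7 columns). SMILES interpretation, aromatic perception and hydrogen counts
come from OpenBabel (via ChemmineOB); ring bonds are identified with igraph
(a bond is in a ring iff it is not a bridge).

The encoder is a directed message passing neural network (D-MPNN). Each
directed edge u→v carries a hidden state initialized from the source atom's
features concatenated with the bond features, projected through a linear
layer and ReLU. Each of `t` iterations updates every edge state from the
states of edges incoming at its source, *excluding the reverse edge* — the
directionality that prevents immediate echo. The update adds a skip
connection from the initial state, applies a linear transform and ReLU.
After `t` steps each atom's incoming edge states are summed, concatenated
with its raw features, and passed through the atom transform to give the
learned atomic fingerprint `h_i` (width `d`). Defaults: `t = 2` iterations;
`d = 300` in full-scale configurations, `d = 16` in the desk-scale
experiments below (`hidden_dim` is a config knob; tests use 8–32).

### Heteroscedastic readout

A shared fully connected trunk followed by two parallel output layers — the
mean layer and the variance layer — turns fingerprints into Gaussians.

* **Atom-based mode** (the package's main contribution): each atomic
  fingerprint maps to an atomic mean `mu_i` and an atomic standard
  deviation `sigma_i`. The molecular mean is the sum of atomic means. The
  molecular variance is the full quadratic form over the atomic covariance
  matrix, whose off-diagonal entries are `rho_ij * sigma_i * sigma_j` with
  `rho_ij` the Pearson correlation between the fingerprints of atoms i and
  j across their `d` coordinates. Because a correlation matrix is positive
  semidefinite, the quadratic form is non-negative for any sigmas.
* **Molecule-based mode** (baseline): fingerprints are sum-pooled first and
  the heads emit the molecular mean and variance directly.

Positivity of the variance-layer output is enforced by softplus — to the
standard deviation in atom mode, to the variance in molecule mode — plus a
small floor (1e-6). The variance layer also carries a scalar `log_scale`
multiplying the standard deviation by `exp(log_scale)` (initialized at 0).
It is part of the variance-layer parameter group, so post-hoc calibration
can adjust it, and it gives `inflate_variance()` an exact handle for
emulating overestimated uncertainty in the calibration experiments.

### Loss and training

A single model minimizes the Gaussian negative log-likelihood
`(y − mu)^2 / (2 sigma^2) + log(sigma^2)/2 + log(2*pi)/2` averaged over
molecules (the heteroscedastic loss). Training choices, all exposed in
`train_config()`:

* Targets are standardized with the training-split mean and standard
  deviation; outputs are mapped back to property units (variances scaled by
  `sd^2`; the train mean is distributed equally over the atoms of a
  molecule so atomic means always sum exactly to the molecular mean).
* Adam, learning rate 1e-3, batch size 50, gradient norm clipped at 10.
* The first 5 epochs hold the variance at 1 (an MSE-equivalent warm-up)
  before enabling the variance path; this stabilizes the joint
  optimization, which is otherwise prone to shrinking `sigma` onto early
  residuals. Set `warmup_epochs = 0` to disable.
* Early stopping: training halts when the validation heteroscedastic loss
  has not improved for 15 epochs; the best-validation weights are returned.
* The molecular variance is floored at 1e-8 before entering the loss:
  perfectly anticorrelated atom pairs can drive the quadratic form to 0,
  which would make the likelihood singular.
* **Stop-gradient on the correlation matrix.** During backpropagation the
  Pearson matrix is treated as a constant of the forward pass; gradients
  flow through the atomic means and sigmas (and through the fingerprints
  into both heads). Differentiating through the correlation itself adds an
  ill-conditioned term with no clear benefit; treating it as a similarity
  weighting keeps the optimization stable. All gradients are hand-derived
  and verified against finite differences in the test suite.
* Splits are 8:1:1 (`floor(0.8N)` train, `floor(0.1N)` validation,
  remainder test) under a dedicated split seed, independent of the model
  seed that governs weight initialization and batch shuffling.

### Deep Ensembles and the uncertainty decomposition

`train_ensemble()` trains `M` networks differing only in initialization
(member seeds `base + 0..M-1`). The ensemble prediction is the uniform
Gaussian mixture with:

* `mu_ens`: mean of member means;
* `sigma2_ale` (aleatoric): mean of member variances;
* `sigma2_epi` (epistemic): population variance (divisor `M`) of member
  means.

The same decomposition applied to the per-atom means and variances defines
the atomic decomposition. The atomic aleatoric/epistemic values deliberately
ignore inter-atomic covariance, which is reported only at molecule level —
an analogy-based definition of this package, chosen because the molecular
decomposition has no unique atomic refinement.

The reference configuration uses `M = 30`; the experiments here use 3–8.

### Post-hoc calibration

Averaging member variances overestimates the ensemble's aleatoric
uncertainty: the ensemble mean is more accurate than any member, so the
averaged member variances describe errors the ensemble no longer makes.
`calibrate_ensemble()` runs a second round of training in which *only the
variance layers* (including `log_scale`) of all members are relaxed and
everything else is frozen. The loss is the heteroscedastic NLL of
(`mu_ens`, `sigma2_ale`) against the calibration targets — by convention
the training split — optimized jointly over all members with full-batch
Adam (learning rate 0.01) and early stopping on the validation ensemble NLL
with the same patience rule; the returned state is the best validation
state including the incumbent. Because means are never touched, `mu_ens`
and `sigma2_epi` are bit-identical before and after calibration — the
package treats that as a hard contract and the tests verify it down to
frozen-weight checksums.

## Calibration diagnostics

* `confidence_curve()`: for each confidence level (1%–99% by default, central
  two-sided intervals) the fraction of observations inside the predictive
  interval; ECE is the mean absolute gap between nominal and empirical.
  The paper-style curve plots empirical fraction against level.
* `error_curve()`: data sorted by predicted variance (stable sort), split
  into `B = 10` near-equal bins (remainder spread over the first bins);
  each bin compares its RMSE with its root mean uncertainty
  `RMU = sqrt(mean(sigma2))`; ENCE is the mean of `|RMSE − RMU| / RMU`.
* Both operate on whichever variance the caller passes, so aleatoric and
  epistemic components are evaluated side by side
  (`evaluate_predictions()` reports `ece_ale`, `ece_epi`, `ence_ale`,
  `ence_epi` along with MAE and RMSE).

The number of confidence levels, the sidedness of the intervals and the
bin count are package conventions (the underlying definitions leave them
open); they are config-exposed.

## The synthetic generator and what it does (not) show

`generate_molecules()` assembles random valence-respecting graphs (trees
with an occasional ring closure) over a C/N/O/F vocabulary, 3–12 heavy
atoms, and labels them with an exact sum of per-element contributions
(defaults `C = -1.2, N = 0.8, O = 2.3, F = -0.5`, order-one values on an
arbitrary property scale) plus independent per-atom Gaussian noise with
element-keyed scales (default 0.1 per atom — a mildly noisy floor). The
ground-truth contribution sum and per-molecule noise variance are recorded,
which makes atomic attribution and predicted variances directly checkable.

This emulates exactly the structure the atom-based model assumes: additive
atomic contributions and element-keyed heteroscedastic noise. Real
properties are not exactly additive, real noise is not element-keyed, and
real chemical space is vastly larger; passing the synthetic experiments
therefore validates the *uncertainty semantics* of the machinery — that
aleatoric variance tracks label noise to its structural source and
epistemic variance flags unseen structure — not benchmark accuracy on real
datasets. Scaled-down runs on the public benchmark CSVs can use
`read_molecule_table()` directly.

## Diagnostic experiments

**Noise injection (heterogeneous data quality).** `inject_label_noise()`
adds to each molecule the sum of `r` unit-variance Gaussian draws, `r` the
number of nitrogen atoms; nitrogen-free molecules are bit-unchanged.
`run_noise_experiment()` (1,000 molecules, `M = 3`, 30-epoch members)
trains a base ensemble on clean labels and a noisy ensemble on injected
labels and groups the test-set aleatoric variances by nitrogen count
(0/1/2/3+). The expected signature, asserted in the acceptance tests over
five seeds: mean aleatoric variance increasing with nitrogen count in the
noisy model and exceeding the base model in nitrogen-containing groups,
with the per-atom aleatoric decomposition concentrating on the nitrogens.

**Element ablation (heterogeneous data quantity).**
`run_ablation_experiment()` trains a nitrogen-ignorant ensemble on
nitrogen-free molecules and predicts on a test set that contains nitrogen.
Its defaults are larger than the noise experiment's — 4,000 molecules,
`M = 8`, up to 80 epochs — for two reasons rooted in what the experiment
measures. First, the per-atom epistemic value is a variance across member
means, and with very few members its argmax over atoms is dominated by
estimator noise (the reference setup uses 30 networks). Second, members
genuinely disagree about how to allocate atomic contributions among
*trained* elements — the sum constraint does not identify the split, an
effect that also explains why atoms can carry more uncertainty than their
molecule. That background disagreement shrinks with training data, while
the untrained-element signal does not. The asserted signature: higher mean
epistemic variance for nitrogen-containing test molecules than
nitrogen-free ones, and the maximum atomic epistemic variance landing on a
nitrogen atom in at least 60% of nitrogen-containing molecules.

## Numerical and design notes

* Featurization is deterministic and memoized per session; identical
  SMILES always produce identical graphs, so member predictions align
  atom-by-atom.
* Constant fingerprints make the Pearson correlation 0/0; the convention
  is `rho = 0` (independence), with a unit diagonal.
* `error_curve()` breaks variance ties by input order (stable radix sort).
* Duplicate SMILES are kept as distinct records; deduplication would
  change dataset-size semantics silently.
* Stereochemistry in SMILES is accepted but not featurized; 3D geometry is
  out of scope.
* Checkpoints are RDS files with a JSON sidecar (config + history); an
  ensemble directory holds `member_XXX.ckpt` plus `ensemble.json`.
* All randomness is seeded: generator, split, injection, member
  initialization and batch shuffling draw from separate, documented seeds.

## Limitations

* The desk-scale experiments use small fingerprints and few members;
  headline benchmark numbers from full-scale (30-network, 10^5-molecule)
  configurations are out of reach here, and the package asserts only the
  qualitative signatures above.
* Aleatoric and epistemic components can confound each other: an ensemble
  asked about structure it never saw mispredicts its variance head too, so
  high aleatoric estimates on unseen structure should not be
  over-interpreted; likewise heavy label noise inflates member
  disagreement. Interpret the decomposition jointly.
* The predictive family is Gaussian; non-Gaussian heads are out of scope.
* The atomic decomposition of epistemic/aleatoric uncertainty ignores
  inter-atomic covariance by definition; the molecular variance is the
  authoritative total.
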