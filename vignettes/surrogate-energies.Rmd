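---
title: "Surrogate conformational energies: model, validation and design notes"
author: "gpconf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate conformational energies: model, validation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpconf)
```

## Scope and assumptions

`gpconf` models the conformational energy surface of **one** molecule with
fixed atom composition and fixed atom ordering. That restriction is what
makes the simple representation work: with the atom indexing pinned down, the
strict lower triangle of the Coulomb matrix is a fixed-length, smooth,
rigid-motion-invariant function of geometry, and no permutation-invariance
machinery (atom sorting, eigenspectra, symmetry functions) is needed. The
`ensemble` container enforces the contract — any frame whose atom sequence
differs from the first is rejected.

The package does not compute reference energies. They come from whatever
expensive method the user runs (in the motivating application,
dispersion-corrected DFT single points on relaxed MD snapshots) and enter as
a per-conformer table in kJ/mol. The surrogate interpolates *between* those
references; it is useless outside the conformational space they cover, which
is exactly what the predictive-variance gate quantifies.

## The regression model

For descriptors $x_i$ and energies $y_i$ the predictor is the standard
Gaussian-process / kernel-ridge dual form

$$f(x) = \sum_{i=1}^n \alpha_i\, k(x_i, x), \qquad
  \alpha = (K + \lambda I)^{-1} y,$$

with the linear kernel $k(a,b) = a \cdot b$ by default. The linear kernel is
deliberate: descriptor dimensions are strongly correlated and the energy is
locally nearly linear in inverse interatomic distances, so a nonlinear
squared-exponential kernel (provided for comparison) buys little and adds a
length-scale to tune.

**Predictive variance.** The epistemic part only is reported:
$v(x) = k(x,x) - l(x)^\top (K+\lambda I)^{-1} l(x)$. The observation-noise
term $\lambda$ is *not* added. The adaptive gate compares test variances
against the distribution of training-point variances, so a constant additive
offset would cancel; leaving it out keeps $v$ interpretable as "distance
from the training data" and makes $v \to 0$ at well-covered points.

**Label centering** is off by default (`center = FALSE`): preprocessing
variants (standardization, kernel centering) were explored in the original
study without measurable benefit. One documented consequence: with the
linear kernel an all-zero descriptor predicts 0, and under y-randomization
on labels with a large positive mean, heavy regularization (which shrinks
predictions toward 0, not toward the label mean) is *not* attractive, so the
selected noise level for scrambled data may collapse to the grid minimum
rather than explode. With centered or zero-mean labels the classical
"noise level increases by orders of magnitude" signature reappears. The
acceptance script reports the selected $\lambda$ medians for both real and
scrambled runs without asserting a direction.

**Hyper-parameter selection.** $\lambda$ is chosen by minimizing the
energy-stratified 10-fold cross-validated MAE over a logarithmic grid of 13
points, $10^{-8} \dots 10^{4}$ (the grid end points bracket every selection
observed in practice by several decades). Ties break toward the smallest
$\lambda$. No marginal-likelihood optimization is attempted — grid CV is
what the validation protocol nests.

## Numerical choices

* For the linear kernel with $\lambda > 0$ the model is fitted through a
  thin SVD of the descriptor matrix, $X = USV^\top$, making fitting
  $O(nd^2)$ instead of $O(n^3)$. Mean, coefficients and variance are
  algebraically identical to the dense dual solve; the test suite verifies
  agreement with brute-force dense linear algebra at $10^{-8}$.
* Two cancellation traps are handled explicitly. The variance is computed
  as $\lambda \sum_j t_j^2/(s_j^2+\lambda) + \|x - VV^\top x\|^2$ (both
  terms nonnegative — no large-minus-large subtraction), and in the
  $\alpha$ solve the component of $y$ outside the column span of $U$ is
  zeroed when its norm is at roundoff level, because dividing a $10^{-15}$
  remnant by $\lambda = 10^{-10}$ would inject spurious coefficients.
* Small negative variances are clipped at zero; the error threshold is
  relative ($10^{-8}$ scaled by $k(x,x)$), since descriptor self-kernels are
  of order $10^4$ and an absolute $10^{-8}$ is below achievable double
  precision.
* `lambda = 0` is allowed only when the kernel matrix is numerically
  invertible (`rcond` $\ge 10^{-12}$); otherwise the fit aborts advising
  regularization. For $\lambda > 0$ a failed Cholesky gets one $10^{-10}$
  jitter retry.

## Validation protocol

Folds are energy-stratified by *sort-and-deal*: indices sorted by energy are
cut into consecutive blocks of $k$, and each block is dealt across the $k$
folds in seeded random order. Every fold then spans the full energy range
and fold sizes differ by at most one. (The stratification procedure is a
design choice; any scheme producing energy-balanced folds would do.)

`nested_cv()` runs `reps` repetitions of `k`-fold CV; within each outer
training portion `select_noise()` runs its own stratified 10-fold grid
search, so the held-out fold never influences $\lambda$. Metrics per fold:
RMSE and MAE in kJ/mol, MAE as a percentage of the *training* energy range,
and $R^2$ defined as the **squared Pearson correlation** — not the
coefficient of determination; the two differ for biased predictors, and the
reported convention matters when comparing against published tables.
Summaries are reported both over all $k \cdot \text{reps}$ fold reports and
over repetition means; the mean is identical, only the spread estimate
differs.

`y_randomization()` refits the whole protocol after destroying the
descriptor–energy association: label mode shuffles $y$ as a block,
descriptor mode shuffles each descriptor column independently (a whole-row
shuffle would just be a label permutation again, not a second test). Real
and scrambled fold-MAE distributions are compared with a two-sided
Mann–Whitney U test (normal approximation with tie correction at
$n = 100$ vs 100). A test hook (`.permutation`) can force the identity
permutation, which must — and does — reproduce the real metrics exactly.

## Learning on the fly

The controller starts from an energy-stratified initial training set
(default 50 conformations), then walks the stream in order. A conformation
is predicted if its variance is below `variance_threshold()`, the
interpolated empirical $\kappa$-quantile (default 0.95) of the training
points' variances; otherwise the oracle is called, the conformation joins
the training set, and the model is refitted. Two design points the original
description leaves open:

* the threshold is **recomputed after every retrain**, because the quantile
  is defined on the training data and the training data just changed;
* $\lambda$ is selected once on the initial set and held fixed
  (`fixed_after_init`): re-running the grid search after every rejection
  would make the controller quadratic in oracle calls for little benefit.
  A `reoptimize_each` mode exists for users who want it.

$\kappa = 0$ disables the surrogate outright. (The quantile at
$\kappa = 0$ is the training minimum, and a stream point can numerically
undercut it; "compute everything" is the intended semantics, so the gate
special-cases it.) Full adaptive runs need not be monotone in $\kappa$ —
each rejection changes the model — but with retraining frozen the predicted
sets are provably nested, and the tests check exactly that.

## The synthetic study

The generator stands in for the unavailable MD + DFT pipeline. It is a
first-class, tested module, and its defaults define the package's study
conditions:

| parameter | default | meaning |
|---|---|---|
| chain length | 12 atoms (C/H alternating) | 66-dimensional descriptor, 9 torsions |
| bond length / angle | 1.5 Å / 111° | fixed internal geometry |
| torsion amplitudes | 6, 4, 2 kJ/mol (cycling) | cosine well depths |
| multiplicities | 1 | single-well torsional terms |
| Lennard-Jones | ε = 0.1 kJ/mol, σ = 2.0 Å | pairs ≥ 4 bonds apart |
| noise | 0.5 kJ/mol | per-conformer Gaussian, id-keyed |
| runs | 4 × 240 frames | biases −2.0, −0.7, 0.7, 2.0 rad |
| torsion jitter | 0.25 rad | within-run spread |

Design rationale: the descriptor is a smooth function of torsions, so the
energy must be one too if a linear-in-descriptor surrogate is to reach the
noise floor — single-multiplicity cosine wells plus a mild nonbonded term
give a multimodal but locally near-linear surface. The four run biases
place the runs in distinct torsional basins, which is what makes training
on one run generalize badly to the others (the sampling effect), while
pooled random subsets of the same size cover all basins. Noise is keyed to
the conformer id, not the call, so repeated oracle queries are consistent
the way a deterministic quantum-chemistry code would be. Geometries whose
atoms approach within 0.5 Å are resampled.

What the generator does **not** emulate: real electronic-structure physics,
anharmonic couplings between torsions, conformer relaxation (all frames are
exact chain geometries), or ROESY spectra. Passing tests therefore show that
the machinery is correct and that the claimed phenomenology (noise-floor
accuracy, sampling effects, variance gating) emerges under controlled
conditions — not that any particular accuracy will be achieved on a given
real molecule.

Problem sizes throughout the tests and the acceptance script (full 4 × 240
study, 10 × 10 nested CV, five-seed sampling experiments, one full adaptive
pass) were chosen so the complete suite runs in well under a minute on a
single CPU while keeping every fold ≥ 90 training points.

## Constraint scoring and landscapes

ROESY/NOE bounds are strict: a group-averaged distance exactly at the class
bound (2.5/3.5/5 Å) *fails*. Proton–methyl and methyl–methyl distances use
the arithmetic mean over all proton pairs; $r^{-6}$ NOE averaging is
available as an option but off by default, since plain averaging is the
documented protocol. Constraints satisfied by all or by none of an
ensemble's conformers are filtered out before scoring — they cannot rank
conformers.

The 2-D maps use covariance-eigendecomposition PCA (components sign-fixed so
the largest-magnitude loading is positive) and a Nadaraya–Watson smoother
with a Gaussian kernel. Bandwidths follow the normal reference rule
$h = 1.06\,\sigma\,m^{-1/5}$ per axis, multiplied by a smoothing factor
(default 0.3). The original landscapes used locally density-adaptive
bandwidths from a proprietary visualization tool; the global rule used here
is a documented approximation, and the smoothing factor is interpreted as a
bandwidth multiplier. Grid cells receiving no kernel weight are masked, not
extrapolated; smoothed values are convex combinations of the data and can
never overshoot the observed energy range.

## Known limitations

* No forces/gradients: the surrogate's derivatives are only trustworthy
  along directions covered by training data, and the package does not
  expose them.
* The descriptor's atom-count question is left to the user: the
  114-atom/6441-dimension figure from the motivating study does not match
  that molecule's full 123-atom formula, and the generic implementation plus
  an optional `atom_mask` lets users reproduce either choice.
* One global $\lambda$; no per-region noise modelling.
* The adaptive controller processes a fixed stream; it does not bias an
  ongoing MD simulation.
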