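---
title: "Estimating whole-brain effective connectivity with the MOU model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating whole-brain effective connectivity with the MOU model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`mouec` treats each brain region's BOLD activity $x_i(t)$ as one node of a
multivariate Ornstein–Uhlenbeck (MOU) process,

$$
\mathrm{d}x_i \;=\; \Big( -\frac{x_i}{\tau_x} \;+\; \sum_{j \neq i} C_{ij}\, x_j \Big)\,\mathrm{d}t \;+\; \mathrm{d}B_i ,
$$

where $\tau_x$ is a global decay time constant, $C_{ij} \ge 0$ is the directed
coupling from region $i$ to region $j$ (the *effective connectivity*, EC), and
$\mathrm{d}B_i$ are independent Wiener inputs with variance rates $\Sigma_{ii}$.
In matrix form $\mathrm{d}x = A x\,\mathrm{d}t + \mathrm{d}B$ with state matrix
$A = -I/\tau_x + C^\top$ (we store $C$ source-row × target-column everywhere,
so `ec[i, j]` is always the link $i \to j$; directed links are reported as
`(source, target)` with 1-based indices in human-readable outputs).

When $A$ is stable (all eigenvalue real parts negative), the stationary spatial
covariance $Q^0$ solves the Lyapunov equation
$A Q^0 + Q^0 A^\top + \Sigma = 0$, and the lagged covariance is
$Q^\ell = Q^0 e^{A^\top \ell}$. These two matrices are the model counterparts
of the empirical zero-lag and lagged BOLD covariances (FC0, FC1). Because
$Q^\ell$ is asymmetric, the pair carries directed information that a
correlation matrix does not — that asymmetry is what makes the EC
identifiable.

**Assumptions.** Linear, stationary dynamics around a fixed point; a single
$\tau_x$ shared by all nodes (a per-node $\tau$ is a possible extension, not
implemented); noise that is white, independent across nodes, and diagonal;
couplings that are non-negative and restricted to an anatomical admissibility
mask. No hemodynamic forward model is applied: the time series are taken as
region-level BOLD after upstream preprocessing.

## From data to the fitted model

1. **Filtering.** Sessions are narrowband-filtered at 0.04–0.07 Hz with a
   2nd-order Butterworth applied forward–backward (zero phase), the common
   fMRI choice for isolating slow BOLD fluctuations; the band is exposed as a
   parameter. Outputs are demeaned exactly.
2. **Empirical covariances.** After demeaning,
   $\widehat{FC0} = \tfrac{1}{T-\ell-1}\sum_{t=1}^{T-\ell} x(t)x(t)^\top$ and
   $\widehat{FC1} = \tfrac{1}{T-\ell-1}\sum_{t=1}^{T-\ell} x(t)x(t+\ell)^\top$;
   both matrices use the same time points and denominator for consistency,
   and FC0 is symmetrized by averaging with its transpose. The lag defaults
   to $\ell = 1$ sample (one TR = 2 s); the fit works in sampling-period
   units, so $\tau_x$ is passed in samples.
3. **Time constant.** $\hat\tau_x = -1/\text{slope}$ of a linear regression of
   the log mean autocovariance on lags $0..2$; a non-decaying autocovariance
   falls back to a default (1 sample) and is flagged.
4. **Masked gradient descent.** Starting from $C = 0$, $\Sigma = I$, each
   iteration solves the Lyapunov equation for the current parameters,
   forms the residuals $\Delta_0 = \widehat{FC0} - Q^0$,
   $\Delta_1 = \widehat{FC1} - Q^\ell$, and takes the state-matrix increment
   $\Delta A = \big[(Q^0)^{-1}(\Delta_0 + \Delta_1 e^{-A^\top\ell})\big]^\top$.
   EC moves by $\epsilon_C \Delta A^\top$ restricted to the mask and clipped
   at zero; the variances move by $-\epsilon_\Sigma\,
   \mathrm{diag}(A^\top\Delta_0 + \Delta_0 A)$, floored at
   $\sigma_{\min} = 10^{-6}$. Masked sparsity and non-negativity therefore
   hold at every iteration, not just at return. The tracked model error is
   $E = \tfrac12\big(\|\Delta_0\|_F/\|\widehat{FC0}\|_F +
   \|\Delta_1\|_F/\|\widehat{FC1}\|_F\big)$, alongside the Pearson
   correlations between vectorized model and empirical matrices; the
   returned parameters are those of the best-error iteration.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `eps_c`, `eps_sigma` | 5e-4, 0.05 | learning rates for EC / noise variances |
| `max_iter` | 10000 | iteration cap (early stopping usually triggers first) |
| `tol_improve`, `patience` | 1e-5, 20 | stop when E fails to improve by `tol_improve` for `patience` iterations |
| `sigma_min` | 1e-6 | variance floor |
| `stab_margin` | 1e-6 | required $-\max\mathrm{Re}\,\lambda(A)$ after a step |
| `cond_max` | 1e10 | above this condition number, $Q^0$ is inverted by pseudo-inverse (flagged) |
| `lag` | 1 sample | FC1 lag (`lag_tr`) |
| band | 0.04–0.07 Hz | Butterworth passband, order 2 |

**Numerical choices.** A candidate step that would destabilize $A$ is
rejected and both learning rates are halved (counted in the diagnostics); a
non-finite covariance or a failed decomposition ends the descent at the best
parameters seen. The stopping rule is deliberately earlier than "fit to the
last digit": on data generated with $C = 0$, descending all the way to the
noise floor inflates spurious clipped-at-zero weights (≈11% of the mean
fitted weight of a matched signal case), while stopping at
`tol_improve = 1e-5` / `patience = 20` leaves them below 5% with an identical
recovery correlation on signal data. The Lyapunov solve and matrix
exponential run in compiled code (Armadillo's Sylvester solver and `expmat`),
which is what makes whole-cohort fits cheap enough to run thousands of
iterations per session.

## Anatomical masks and feature vectors

Structural matrices are symmetrized ($\,(SC + SC^\top)/2$, since tractography
is direction-blind), thresholded to keep the $k = \mathrm{round}(0.30 \cdot
n(n-1)/2)$ strongest undirected pairs (rounding half away from zero; ties at
the cutoff are broken by (row, column) order and reported), and group masks
are intersected (elementwise AND) to form the shared analysis mask — on the
original cohort this intersection produced a ~27% density; on synthetic
cohorts the value is whatever the data give, we only guarantee the
containment and counting arithmetic. Group-level masks are built from the
across-subject *mean* SC of each group.

Symmetric matrices (SC, FC0) are vectorized as the strict lower triangle in
row-major order — $n(n-1)/2$ features, 6670 for 116 ROIs. EC, being directed,
is vectorized over *all* ordered pairs admitted by the mask ($2m$ features
for $m$ undirected links); the orderings are fixed, documented, and invertible
(`feature_index()`, `devectorize_features()`).

## Classification, surrogates, and support networks

Each session's feature vector is z-scored with its own mean and *population*
standard deviation (divisor $n$, matching the convention of the usual
machine-learning scalers). Two classifiers are used: a first-nearest-neighbour
rule with Pearson correlation as inverse distance (exact ties broken by a
seeded shuffle, reported), and a ridge-penalized multinomial logistic
regression (glmnet, $\alpha = 0$) with fixed penalty $\lambda = 1/n_{train}$ —
the analogue of unit-strength L2 regularization — whose weights also drive
feature elimination. Accuracy is estimated over 50 independent stratified
80/20 session splits, reporting test-set accuracy only. Because condition
classification places two sessions of each subject in the pool, a
subject-aware split (both sessions on the same side) is available and used
for the condition tasks in the demo. Surrogate baselines permute the
training labels within each repeat, leaving everything else identical;
distributions are compared with two-sided Wilcoxon rank-sum tests.

Recursive feature elimination repeatedly fits the MLR and removes the
features with the smallest summed absolute weights (step 1 by default;
the demo uses step 5 to keep its runtime proportionate). The accuracy-vs-k
curve re-ranks on each training split; the support network is the smallest
$k$ whose mean accuracy is within one standard deviation (configurable) of
the maximum — a quantitative reading of "performance stable under adding
features". Selected links are annotated with ROI, network and hemisphere
from the parcellation table, and hemisphere/network tallies are computed
outputs, never assertions.

## Network-based statistic

Edgewise two-sample pooled-variance t statistics are computed over the
intersected mask, one one-sided contrast at a time. Edges exceeding the
primary threshold — $t = \sqrt{N}\times d$ with $d = 0.5$, i.e. 3.08 → 3 for
$N = 38$ — form a graph whose connected components are measured in edges.
Family-wise error control comes from permuting group labels (10,000 by
default; tiny designs switch to exhaustive enumeration) and recording the
maximal component extent per permutation; each observed component gets the
add-one estimate $p = (1 + \#\{\text{perm max} \ge \text{size}\})/(1 +
n_{perm})$, which can never be zero. Zero-pooled-variance edges get $t = 0$
and are flagged. Raising the threshold can only prune components, and under
an exchangeable null the max-component p-value is conservative — both are
verified by simulation in the test suite.

## What the synthetic cohorts emulate — and what they do not

The generator provides the complete study design at desk scale: a connected
random admissibility mask (40 nodes, 30% density by default); log-normal
baseline EC weights (median 0.04 s⁻¹, log-sd 1.0 — connectome weights are
heavy-tailed, and that heterogeneity is what makes single-session EC recovery
well-posed); four parameter sets (2 groups × 2 conditions) differing by
+0.20 s⁻¹ on 20 planted directed links per contrast (disjoint sets, group
links placed 70% within the first half of the nodes to emulate a lateralized
effect), uniformly rescaled until every set has stability margin ≥ 0.05;
per-subject fingerprint jitter (Gaussian, sd 0.01 s⁻¹, truncated at zero,
drawn once per subject and shared by both conditions so subject identity is
a nuisance factor for condition classification); Euler–Maruyama integration
(step $0.05\tau_x$, burn-in $10\tau_x$) sampled at TR = 2 s for 500 volumes
per session, matching a ~15-minute scan; and per-subject SC matrices with a
planted connected 3-edge path strengthened in one group by 2 noise-sd.
The planted EC increments sit near the upper tail of the natural weight
distribution; that is the regime in which session-level fits separate the
groups at accuracies comparable to the reference analysis (~0.85–0.90)
rather than saturating or collapsing to chance.

Not emulated: hemodynamic convolution and regional HRF variability, scanner
and physiological noise spectra, motion artifacts, non-stationarity within a
session, and distance-dependent SC weights. Passing tests on these cohorts
therefore demonstrates that the estimation and inference machinery is
correct and calibrated under the model's own assumptions — not that the
assumptions hold for any particular scanner dataset. A useful honest number:
at 500 filtered volumes the median per-session correlation between fitted
and generating EC is ≈ 0.4 (it is ≈ 0.85–0.9 at 5000 unfiltered samples);
group-level discrimination works because classifiers pool hundreds of noisy
links, which mirrors how the method behaves on real scan lengths.

## Problem sizes and reproducibility

The packaged demo profile (40 nodes, 19 + 19 subjects × 2 conditions,
500 samples/session, 50 classification splits, 10 RFE repeats, 1000 NBS
permutations) exercises every stage in a few minutes on one CPU and is
bit-reproducible under a fixed seed; the recovery and calibration suites use
20-node/T = 5000 sessions, 10⁵-sample simulations, and 200 null SC cohorts
at 500 permutations. All randomness flows from explicit integer seeds.

## Known limitations

Sign-free (inhibitory) couplings, task-regressor (input-driven) variants,
per-node time constants, nested hyperparameter tuning for the classifiers,
and edge-level NBS inference are out of scope. The $\tau_x$ estimator is
biased upward when network coupling slows the aggregate autocovariance
decay; the fit partially absorbs this through the EC scale, which is why
recovery is assessed by correlation rather than absolute weight error.
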