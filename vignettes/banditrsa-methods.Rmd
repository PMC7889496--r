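---
title: "Models and methods in banditrsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in banditrsa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

banditrsa implements, end to end on synthetic data, the analysis stack for a
question about *structure-generalizing representations*: when two of three
one-armed bandits share a latent reward process, do learners exploit that
relational structure, and can a neural (or here, simulated-voxel) code for
the structure be detected independently of the sensory particulars? This
vignette is the package's account of the models, the knobs that matter, and
the design choices made where the design was genuinely open.

## The task generator

Each block presents three stimuli A, B, C as one-armed bandits. Latent
good-outcome probabilities live on $\{0.9, 0.1\}$ and flip with a fixed
per-trial switch probability (0.15 in scanner blocks, 0.05 in training and
pre-scan blocks — scanner blocks are short, so the environment must move
faster). A and B are *related*: in `+Corr` blocks they share one latent
process; in `-Corr` blocks their probabilities are exact mirrors
($p_A + p_B = 1$) flipping together. C runs its own independent process.
The subject accepts (predicting the good outcome) or rejects; accepting
pays $\pm 1$ point, rejecting pays nothing, and the outcome is shown either
way — except on the last 15 trials of training-day-3/4 blocks, where
rejected trials hide the outcome.

Design choices the task description leaves open, fixed once here:

* **Switch process.** A Bernoulli(switch probability) flip is evaluated at
  every trial for every independent process; no refractory period. Each
  process starts at 0.9 or 0.1 with equal probability.
* **Stimulus order.** A seeded uniform shuffle with exactly
  `trials_per_stimulus` presentations of each stimulus; no run-length
  constraint.
* **Trial timing.** 1.5 s pre-choice window, a lognormal RT with median
  1 s (sdlog 0.3), 0.5 s choice highlight, a choice–outcome delay drawn
  from an exponential with mean 4.5 s truncated to [3.5, 5.5] s (rejection
  sampling), 1 s outcome, and an ITI from an exponential with mean 3 s
  truncated to [2.5, 4] s. Trials average ≈ 11.5 s.
* **Counterbalancing.** Block order within a run is a Latin-square cyclic
  shift of the four block types by subject and run.
* **Seeds.** One master seed; every subject, session and stage receives a
  deterministic child seed (`derive_seed()`), so whole cohorts are
  bit-reproducible.

The default simulated cohort consists of agents that have *learned the
correct structure*: cross-term of the related pair at the true sign with
magnitude drawn from U(0.6, 1), learning rate U(0.25, 0.55), inverse
temperature U(3, 6) — moderate heterogeneity a behavioral scientist would
call realistic for trained subjects. `structured = FALSE` yields
structure-naive agents for null cohorts. One bookkeeping note: quoted
per-structure trial totals for this design sometimes read 202 while the
block lengths sum to 204 (4×30 + 2×42); the generator exposes the counts
explicitly and forces neither number.

## The cross-term learner

Each stimulus carries a value estimate $g \in [-1, 1]$ (the good-outcome
probability mapped from $[0,1]$), reset to 0 at every block start. After
outcome $y \in \{-1, +1\}$ on presented stimulus $X$:

$$g'_X = (1 - \alpha)\, g_X + \alpha y, \qquad
  g'_Y = (1 - \alpha |H_{XY}|)\, g_Y + \alpha H_{XY}\, y$$

with cross-terms $H_{XY} \in [-1, 1]$ for the three unordered pairs.
$H = +1$ treats two bandits as the same, $-1$ as opposites, $0$ as
unrelated. Every update is a convex combination of the previous estimate
and a value in $[-1,1]$, so $|g| \le 1$ always. Choices follow a sigmoid,
$P(\text{accept}) = (1 + e^{-\beta g})^{-1}$, with inverse temperature
$\beta \in [0, 8]$. The STRUCT model fits $(\alpha, \beta, H_{AB}, H_{AC},
H_{BC})$ — 5 parameters per dataset; NAIVE pins all $H$ at 0 (2
parameters) and is an exact special case of STRUCT, which the likelihood
code preserves to machine precision. Belief updates are skipped on
no-feedback trials, but the choice on such trials still enters the
likelihood.

Two derived per-trial signals feed the imaging models: the
**chosen-action value** (the stimulus value, sign-flipped on reject trials
— a confident rejection is a high-value action) and the **correctness
prediction error** (magnitude $|y - g|$, positive exactly when the outcome
matches the choice).

### Fitting and its numerics

Fits minimize the negative log likelihood under the box constraints with
`optim(method = "L-BFGS-B")` from 10 seeded Latin-hypercube starts,
keeping the best optimum (convergence tolerance ~1e-6 on the NLL;
probabilities floored at 1e-12 inside the log so a boundary $\beta$ cannot
produce infinities). The hot recursion is compiled (Rcpp). One
identifiability caveat, visible in testing: $\alpha \to 0$ silences the
selector at *any* $\beta$, so for choice data that carries no signal the
fitted $\beta$ is meaningless on its own — the identifiable statement is
that the fitted model predicts chance. Tests assert exactly that.

## Model comparison

`crossval_matrix()` fits both models per block type (102 trials each at
the pooled pre-scan + scanner granularity) and evaluates every fit on
every block type, giving 4×4 test-NLL matrices per model per subject. Cell
masks: *within-structure* (off-diagonal, same structure sign; 4 cells),
*across-structure* (different sign; 8 cells), *same-data* (diagonal; 4
cells). Because the masks select different numbers of cells, the group
contrast compares **per-cell means**, not raw sums (with equal counts the
paired t statistic is identical; with unequal counts raw sums differ by
construction — implementing the sums literally made a null comparison
reject at ~0.9, a pure bookkeeping artifact).

A caveat worth stating for interpretation: the within/across STRUCT
contrast is a statement about the *fitted models'* generalization. The
schedule itself carries the structure (a naive agent's belief about B
still correlates with A's outcomes through the shared latent), so
exchangeability arguments for null calibration are clean only for the
NAIVE model's cells, which cannot read the structure labels; the package's
calibration tests use those.

`cross_term_test()` is the one-tailed paired t-test of $|H_{AB}|$ against
$(|H_{AC}| + |H_{BC}|)/2$ across subjects. `information_criteria()`
reports both AIC ($2k + 2\,\mathrm{NLL}$) and BIC ($k \ln n +
2\,\mathrm{NLL}$), per subject and group-summed, since either is a
reasonable reading of a "formal model comparison". Degenerate
zero-variance contrasts are flagged and given limit p values rather than
NaN. Divergent-trial histograms select trials where the two models'
predicted choices differ (accept iff $P > 0.5$; exact ties excluded).

## Event GLMs

The HRF is a double-gamma with unit-scale gamma densities whose *mode* sits
at the configured peak delay (6 s default, 8.5 s for slow-responding
regions), undershoot delay scaled proportionally (16 × delay/6) at 1/6
amplitude, unit-peak normalized. Regressors are delta sticks on a 0.1 s
grid, scaled by their parametric modulator where one exists (modulators are
mean-centered per block — conventional, and it keeps main effects and
parametrics separable), convolved and resampled at the TR (1.235 s).
Button-press regressors are locked to press time (stimulus onset + wait +
RT): locking them to stimulus onset would make accept + reject sticks sum
exactly to the stimulus mains and the design singular. Each block is its
own scan segment, so run designs are block-diagonal with per-block
intercepts; six smooth motion series per block enter as nuisance columns
in synthetic runs, and a discrete-cosine drift basis (100 s cutoff)
is available but off by default on synthetic data. The four layouts
(`glm1`, `glm2`, `glm2a`, `glm3`) implement the standard regressor sets
for this design:
value competition (STRUCT and NAIVE chosen values unorthogonalized),
per-stimulus mains, related-pair-collapsed mains, and the outcome-locked
correctness-PE parametric. Estimation is voxelwise OLS with an explicit
rank check that names offending columns.

## RSA and group inference

Within each searchlight the condition patterns are prewhitened by the
inverse square root of a shrinkage-regularized residual spatial covariance
(Schäfer–Strimmer intensity toward the diagonal) — standard multivariate
noise normalization; the exact estimator is the package's choice, and
both the shrinkage intensity and the cluster statistic below are
config-exposed.
The dissimilarity between conditions $i, j$ is the **cross-run correlation
distance** $d_{ij} = \tfrac12[(1 - r(run1_i, run2_j)) + (1 - r(run1_j,
run2_i))]$: symmetric by construction, bounded in $[0,2]$, and with a
meaningful diagonal (a condition's distance to itself across runs).
Zero-variance patterns propagate as flagged missing entries. Hypothesis
contrasts are mean(dissimilar) − mean(similar) over labeled element sets,
with optional controls that exclude same-stimulus or same-stimulus-set
pairs so a structure effect cannot ride on visual identity.

Searchlights are volumetric: the k = 100 nearest in-mask voxels by
Euclidean distance within an anatomical-style mask; surface-geodesic
searchlights are out of scope. Group inference sign-flips the
per-subject contrast maps (flips shared across voxels within a
permutation, drawn from one seeded stream), with the cross-subject mean as
the statistic and the +1-corrected one-tailed p. Cluster-level FWE
thresholds the uncorrected p map (0.001 by default), scores
face-connected clusters by the sum of the t-like statistic (mean/SE) over
member voxels, and compares against the permutation null of the maximum
cluster mass; null iterations threshold each permuted map by its
within-permutation-distribution p (the standard
permutation-of-permutations construction). One numerical interplay to
respect: a cluster-forming threshold below $1/n_{perm}$ is unreachable by
any permutation, so reduced-permutation runs (e.g. calibration at
$n_{perm} = 500$) must use a correspondingly reachable threshold (0.01 in
the calibration suites); the default 0.001 pairs with the default 10,000
permutations. ROI tests average the searchlight RDMs over the ROI per
subject before contrasting (one-tailed t). Leave-one-out reruns the whole
group stage per held-out subject, reusing one flip stream so reruns are
comparable.

## The BOLD phantom

The phantom plants known geometry on a 20×20×20 grid: four disjoint
~150-voxel regions (structure, stimulus, PE×structure, null), analyzed
within their union as the mask. Per subject, true coefficients are built
on the generating design (per-stimulus mains, the correctness-PE
parametric, buttons, motion) and BOLD = design × betas + noise — white
Gaussian with sd 1 by default, with an optional AR(1) toggle (`ar`); the
downstream inference is permutation-based and assumes no particular noise
family. Effects default to 0.5
(prototype SD) — a level the pipeline should detect comfortably at
n = 20.

* **Structure region:** every stimulus-presentation pattern equals a
  per-structure prototype — a *block-context* code, present on C trials
  too. This is not only the natural reading of a structure code; it is
  what makes the double dissociation exact. If the prototype were planted
  on A/B only, the stimulus-identity contrast would be unbalanced in this
  region: its "similar" set (same stimulus, both structures; 24 cells in
  the 12-condition RDM) and its "dissimilar" set would contain unequal
  shares of prototype-sharing pairs, leaving a genuine positive contrast
  (~0.13) that a 20-subject cohort detects. With the context code the two
  sets balance exactly and the contrast is 0 in expectation.
* **Stimulus region:** prototypes keyed by (stimulus set, stimulus) — six
  visual identities, shared across structures.
* **PE×structure region:** the outcome-locked PE parametric pattern equals
  a per-structure prototype; nothing at stimulus time.
* **Null region:** noise only.

Prototypes are drawn once per subject per region from a seeded standard
normal. What the phantom does *not* emulate: autocorrelated or
physiological noise, motion artifacts beyond smooth nuisance series,
inter-subject anatomical variability, surface geometry, and
distance-dependent noise correlations (the prewhitening tests plant those
synthetically instead). Passing tests therefore certify the statistics and
their calibration, not robustness to every property of real scanner data.

## Problem sizes

The test and acceptance suites run at sizes chosen to make the statistics
stable while keeping a full run on one core pleasant: simulator
calibration over ~100,000 trials; parameter recovery at ~2,000 trials
certified against a 6,384-point grid-search oracle; the cross-validation
pattern on 20 agents at the pooled 102-trials-per-block-type granularity;
inference calibration over 500 null cohorts at 500 permutations;
enumeration oracles at $2^{10}$–$2^{12}$ flip patterns; and the full
double-dissociation phantom at its defaults (20 subjects, k = 100, 5,000
permutations). Every default in `pipeline_config()` carries the full-scale
settings (switch probability 0.15, k = 100, 10,000
permutations, cluster-forming p = 0.001, HRF delay 6 s); the demo
configurations in the test suite shrink the grid, cohort and permutation
counts to keep a full run on one core pleasant.

## Known limitations

Hierarchical/Bayesian parameter estimation, lapse-rate selectors, AR
noise modeling in the GLM, surface-based searchlights and atlas handling
are out of scope. The cross-term model is a descriptive tool — the
within/across generalization caveat above applies to any use of its
contrast as evidence about *agents* rather than about fitted models.
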