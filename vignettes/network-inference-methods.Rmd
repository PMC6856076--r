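---
title: "Sparse lagged regression, Granger pruning, and perturbation weights: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse lagged regression, Granger pruning, and perturbation weights: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causnet)
```

## The model

`causnet` infers a signed, directed gene regulatory network from short,
replicated time-course expression data. The generative picture is a
discrete-time linear model: the next-time expression of gene $i$ is a linear
combination of the current expression of its regulators plus a Gaussian
nominal production term,

$$x_i(t+1) = a_{ii}\, x_i(t) + \sum_{j \ne i} a_{ij}\, x_j(t) + b_i + \eta_{i,t},
\qquad \eta_{i,t} \sim \mathcal N(0, \sigma^2).$$

Regulation is assumed sparse: each target has at most a small number $k$ of
regulators. A positive $a_{ij}$ is activation of $i$ by $j$, a negative one
repression. There is no $\Delta t$ term — consecutive sampling times are one
model step even when the clock-time gaps are uneven, which is the standard
assumption for this model class and the reason the package ignores uneven
spacing (e.g. daily samples 8 h apart with a longer overnight gap).

Inference proceeds in three stages.

**Stage I — best-subset lagged regression.** For each target gene, every
size-$k$ subset of candidate regulators is fitted by least squares with a
design of $[\text{intercept},\ \text{target's own lag},\ k\ \text{candidate
lags}]$, and the subset with the minimum residual sum of squares wins.
Observations are the per-condition transitions between consecutive sampling
times, computed on replicate means. With the *virtual time shift* enabled,
the day's first time point also serves as the destination of a wrapped
transition from the last time point of the same condition, so the overnight
interval contributes a lagged observation pair. The target's own lag is
always in the model but never reported as a self-edge; exactly-$k$ subsets
are searched (not $\le k$) and Stage II removes superfluous members.

**Stage II — Granger F-test.** Each selected regulator is tested one by one
for marginal contribution: the reduced model without it (but with the other
$k-1$ regulators, the self lag, and the intercept) is refit, and
$F = (\mathrm{RSS}_{\text{reduced}} - \mathrm{RSS}_{\text{full}})\,/\,
(\mathrm{RSS}_{\text{full}} / \mathrm{df})$ with 1 numerator degree of
freedom and $\mathrm{df} = n - (k + 2)$ denominator degrees of freedom is
referred to the upper F tail. A regulator is kept iff $p < \alpha$
(default $\alpha = 0.05$). Tests are marginal and simultaneous — no
stepwise re-pruning and no multiple-testing correction, matching the single
preset level of the original procedure. Survivors are refit jointly.

**Stage III — perturbation analysis.** The replicate mean $\bar x$ and
unbiased sample variance $s^2$ of every (gene, condition, time) cell
parameterize a Gaussian truncated below at zero, from which one value per
cell is drawn; Stages I–II run on each of $B$ such perturbed datasets
(default $B = 100$), and the $B$ reconstructed networks are aggregated:
an edge's *existence weight* is the fraction of runs in which it appeared,
its *sign weight* the fraction of those appearances carrying the majority
sign. This is a Gaussian approximation of bootstrapping; with the default
variance $s^2/n$ it matches the mean and variance of a size-2 bootstrap
resample mean when $n = 3$ replicates, while giving the perturbed values a
wider support than the empirical replicates.

## Design choices where the design was open

* **Granger decision rule.** The literal reading of the procedure this
  package implements — "reject the regulator when $p$ is below the level" —
  would delete precisely the significant regulators, contradicting the
  test's stated purpose of removing false positives. The default therefore
  keeps a regulator iff $p < \alpha$; `granger_literal = TRUE` reproduces
  the literal rule for users who want the inverted behavior.
* **Perturbation variance.** `variance_mode = "sem"` ($s^2/n$) is the
  default because it is the only choice consistent with the size-2
  bootstrap equivalence above; `"sample"` ($s^2$) and `"population"`
  ($s^2(n-1)/n$) are selectable.
* **Intercept.** Included by default: the Gaussian nominal production rate
  has no reason to be zero-mean, and the intercept absorbs it (and the
  per-gene shift applied by the simulator's nonnegativity mode). A flag
  disables it.
* **Replicates.** Biological replicates at different time points are
  unpaired individuals, so regressions use replicate *means* per cell;
  replicates inform only the Stage III variance model. This avoids an
  arbitrary pairing of replicates across time.
* **Ties.** Equal-RSS subsets (within $10^{-12}$ relative) resolve to the
  subset earliest in lexicographic canonical gene order, making every run
  deterministic. Canonical order is the gene-list order when one is given,
  else first appearance in the input.
* **Weights as fractions.** Existence weights are reported as fractions of
  $B$ (not counts), which is what cut-offs such as 0.1 / 0.2 / 0.6 presume.
* **Condition subsets.** Whether all experimental conditions are analyzed
  jointly or split (e.g. per photoperiod) is left to the caller via the
  `conditions` argument; the package does not guess.

## Numerical and performance notes

Stage I precomputes the Gram matrix $Z^\top Z$ of the full lagged design
once per perturbation and solves each subset's $(k+2)\times(k+2)$ normal
system from it in compiled code (Cholesky with a tiny-ridge fallback on a
collinear subset, which is flagged on the returned fit). At the study scale
of 74 genes, $k = 3$, $B = 100$ this is roughly $74 \cdot \binom{73}{3}
\cdot 101$ small solves and completes in a few minutes on one CPU. A greedy
forward-selection engine (`engine = "greedy"`) is available for gene sets
where exhaustive enumeration is out of reach; tests verify it agrees with
the exhaustive search on strong-signal instances. Degenerate Stage II cases
are handled explicitly: a perfect full fit with a worse reduced fit yields
$F = \infty$, $p = 0$ (kept); when both fits are perfect (RSS below
$10^{-12}\sum y^2$) there is no information to attribute and the regulator
is removed.

Reproducibility: `causnet_infer()` requires a master seed whenever
perturbations are requested; per-perturbation substream seeds are derived
deterministically from it, so repeated runs are bit-identical and
aggregation is invariant to run order.

## The simulator and what passing tests mean

`sample_network()` draws a ground truth from exactly the model class above:
$k_\text{true}$ off-diagonal regulators per row, magnitudes uniform in a
configured range with a configurable repression probability, a
self-persistence diagonal in $(0,1)$, rescaled to spectral radius
$\le 0.95$ so trajectories stay bounded, with off-diagonal magnitudes then
floored at (approximately — stability takes precedence) 0.3 so "true"
edges are statistically visible at designs with very few time points. Feedback loops and cycles are permitted — never
forced acyclic — because feedback is a central feature of real regulatory
networks. `simulate_dataset()` runs the recursion per condition from
initial states drawn around the fixed point $(I-A)^{-1}b$ (cross-condition
diversity standing in for genotype/photoperiod contrasts), adds replicate
measurement noise, and by default shifts each gene by a constant to make
values nonnegative — an affine change that alters only the effective
intercept, so coefficients remain exactly recoverable (hard clipping at
zero exists but breaks linearity and is off by default). Defaults mirror a
realistic study geometry: 18 conditions, 3 time points, 3 replicates, and
process/measurement noise of 0.1 on the normalized scale.

Because the simulator *is* the model the inference assumes, recovery
results on simulated data are a best case: they demonstrate correctness of
the machinery (exact recovery at zero noise, calibrated type-I error for
the null-regulator test, AUPR degrading with measurement noise), not
performance on real transcriptomes, where nonlinearity, unmodeled lags,
circadian forcing, and hidden regulators all violate the model. The wrapped
virtual-shift transition is likewise not generated by the simulator's
dynamics, so simulation-based recovery checks run without it; on real daily
time courses it is a modeling judgment, enabled by default in
`causnet_infer()`.

Problem sizes used by the test-suite and acceptance checks — 50 random
oracle instances, 100 noiseless recovery instances at $G = 8$–$12$, 1,000
calibration datasets, 10,000 truncated-normal draws, one 74-gene
study-shaped run at $B = 100$, and a 3-level noise ladder repeated 10
times — were chosen as the smallest designs at which each property is
statistically decidable.

## Worked example

```{r example}
gt <- sample_network(8, k_true = 2, seed = 1)
ds <- simulate_dataset(gt, n_conditions = 10, seed = 2)
fit <- causnet_infer(ds, k = 2, n_perturbations = 50, seed = 3,
                     virtual_shift = FALSE, weight_threshold = 0.2)
fit
tidy(fit)
evaluate_recovery(fit$full_network, gt, threshold = 0.5)
```

```{r plot, fig.width = 5, fig.height = 4}
autoplot(fit)
```

## Known limitations

* First-order dynamics only: one lag, no multi-lag or continuous-time
  variants, no nonlinear (Hill-type) kinetics.
* No FDR control across edges; the Granger level applies per test, as in
  the original procedure.
* Confidence weights come only from the perturbation ensemble; no
  closed-form edge-stability probabilities.
* Exhaustive search cost grows as $\binom{G-1}{k}$ per target; beyond a few
  hundred genes use the greedy engine or a candidate restriction.
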