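---
title: "Two-stage kernel CCA: model, tuning and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage kernel CCA: model, tuning and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tskcca)
```

## The problem

Given two sample-aligned data blocks — say expression of $p$ genes and
concentrations of $q$ metabolites on the same $N$ subjects — canonical
correlation analysis (CCA) looks for one projection of each block such that
the projected scores correlate maximally. Linear CCA misses associations
that are nonlinear (a quadratic or even link has zero linear correlation on
symmetric support), and classical kernel CCA (KCCA) captures them but
selects no features: every input feeds the kernel, and with a full-rank
kernel matrix the regularized training correlation is driven close to one
whether or not any real association exists.

`tskcca` implements a two-stage remedy. **Stage one** expresses each view's
kernel as a non-negative combination of small *sub-kernels* — one Gaussian
kernel per feature, optionally one per unordered feature pair — and selects
a sparse set of sub-kernel weights by a penalized decomposition of the
matrix of pairwise dependence scores. **Stage two** runs standard
regularized KCCA on the weighted kernel combinations, one canonical pair
per weight vector, giving interpretable nonlinear components supported on
few features.

## Stage one: HSIC matrix and sparse decomposition

Dependence between two kernels is measured by the empirical
Hilbert–Schmidt independence criterion,
$$
\mathbb{D}(K_x, K_z) = \frac{\operatorname{Tr}(K_x H K_z H)}{(N-1)^2},
\qquad H_{nn'} = \delta_{nn'} - \tfrac1N ,
$$
the plug-in estimator of the squared Hilbert–Schmidt norm of the
cross-covariance operator. With $K_x = \sum_m \eta_m K_x^{(m)}$ and
$K_z = \sum_l \mu_l K_z^{(l)}$ the criterion is bilinear,
$\mathbb{D} = \eta^\top M \mu$, where
$M_{ml} = \mathbb{D}(K_x^{(m)}, K_z^{(l)})$ is computed once per bank pair
(each gram centered once; the implementation is contract-tested against the
naive double loop).

The weights solve
$$
\max_{\eta \ge 0,\, \mu \ge 0}\; \eta^\top M \mu
\quad \text{s.t.}\quad
\lVert\eta\rVert_2 = \lVert\mu\rVert_2 = 1,\;
\lVert\eta\rVert_1 \le c_1,\; \lVert\mu\rVert_1 \le c_2 ,
$$
a penalized matrix decomposition. `pmd_rank1()` alternates
soft-thresholded power iterations — `mu` then `eta` per sweep — where each
threshold $\Delta$ is found by bisection so the normalized iterate meets
its L1 budget exactly. Further components come from rank-1 deflation
($M \leftarrow M - d\,\eta\mu^\top$) in `pmd_decompose()`.

Numerical choices worth knowing:

* **Initialization** is the dense leading left singular vector of $M$,
  sign-flipped to non-negative orientation and clamped; the algorithm is
  deterministic given $M$.
* **Non-negativity** is enforced by clamping at every update, on the weight
  vectors only — deflated residuals may legitimately hold negative entries.
* **Exact ties** at a budget of 1 cannot be separated by soft-thresholding;
  that corner resolves to the lowest-index coordinate vector.
* The bisection tolerance on $\Delta$ is `1e-8`; the objective ascent is
  monotone up to that tolerance, and convergence is declared when neither
  vector moves by more than `1e-6`.
* A budget at its Cauchy–Schwarz bound ($c = \sqrt{M}$) deactivates the
  constraint, and the algorithm reduces to the power method: the tests
  require agreement with the dense SVD to `1e-6` there.

## Sub-kernels, bandwidths, normalization

Feature-wise sub-kernels are
$K^{(m)}_{nn'} = \exp\{-\gamma (x_{nm} - x_{n'm})^2\}$; pair-wise
sub-kernels evaluate the same Gaussian on the 2-D block $(x_{.m}, x_{.m'})$
and are enumerated lexicographically, by default alongside the feature-wise
ones ($d + d(d-1)/2$ kernels in total).

The bandwidth follows the median heuristic, $\gamma^{-1}$ = median of
pairwise Euclidean distances — by default computed **per sub-kernel** from
that kernel's own (1-D or 2-D) input. A single per-view $\gamma$ (median of
full-row distances) and a fixed numeric $\gamma$ are available through the
`gamma` argument. The per-kernel default is the only reading that keeps the
heuristic meaningful for the 2-D pair-wise inputs; on the benchmarks below
the two readings give materially identical selection behavior. Constant
features have no usable scale; they fall back to $\gamma = 1$, are flagged,
and are subsequently dropped at normalization.

Because every sub-kernel lives on its own scale, each gram is divided by
its RKHS variance $\sigma^2 = \overline{\operatorname{diag} K} -
\overline{K}$ before entering the HSIC matrix, so all sub-kernels carry
unit variance in feature space and the weights are comparable.
Zero-variance kernels are removed (with a logged warning) rather than kept
at zero weight, keeping the L2-normalized weight vectors well defined.

## Stage two: regularized kernel CCA

For each weight pair the combined kernels enter
$$
\max_{\alpha, \beta}\; \alpha^\top K_x K_z \beta
\quad\text{s.t.}\quad
\alpha^\top (K_x + \tfrac{N\kappa}{2} I)^2 \alpha =
\beta^\top (K_z + \tfrac{N\kappa}{2} I)^2 \beta = 1 ,
$$
solved through the whitened cross-operator
$R = A^{-1} K_x K_z B^{-1}$ (with $A, B$ the regularized kernels): its
leading singular pair yields $\alpha = A^{-1}u$, $\beta = B^{-1}v$. This is
half the dimension of the raw $2N \times 2N$ generalized eigenproblem and
better conditioned; a regression test keeps the two routes within `1e-6`
of each other. Kernel matrices are used **uncentered** — the constraints
make the problem well-posed either way, and the benchmark behavior is
insensitive to the choice. $\kappa = 0.02$ is the conventional default for
variance-normalized Gaussian kernels; only the leading canonical pair is
extracted per component. Held-out correlations reuse the training
bandwidths and normalizations through cross-kernels; nothing is
re-estimated from test data.

## Permutation tuning

With full-rank kernels the training correlation is uninformative for
choosing $(c_1, c_2)$, so significance is judged against an empirical null:
permute the sample order of one view (Z), re-run *both* stages end to end
at the same budget, and record the same statistic — the tested component's
training canonical correlation. Permuting one view is sufficient to break
every cross-view dependence while preserving within-view structure.
P-values use the add-one estimator $(1 + \#\{\text{null} \ge
\text{obs}\})/(B+1)$, bounded below by $1/(B+1)$; replicate failures count
conservatively as null $\ge$ observed. The grid search evaluates the first
component only, reuses one set of permutation draws across grid points
(paired comparison, deterministic given the seed), and breaks p-value ties
toward the smaller $c_1 + c_2$ — the sparser model. Budgets are not
re-optimized inside permutations. Multiple components share one set of
permutations, and no multiplicity correction is applied to the per-component
p-values.

On the benchmark generators below the association signal is strong enough
that *every* candidate budget attains the minimum attainable p-value, so
the tie-break governs and the selected budget is the sparsest candidate.
That choice recovers the single-association benchmark's support exactly
(one sub-kernel per side); its consequences for multi-feature associations
are discussed under *Limitations*.

## What the synthetic generators emulate

Three generators reproduce standard benchmark designs, each with uniform
features on $[-0.5, 0.5]$ and Gaussian noise, and each carrying
ground-truth relevance labels for precision/recall scoring
(`score_selection()`):

* `simulate_dataset1()` — one quadratic link $z_1 = x_1^2 + \varepsilon$,
  invisible to linear CCA; defaults $N = 100$, $D = 10$, $s = 0.05$.
* `simulate_dataset2()` — three additive two-feature links (linear + even,
  even + sine, absolute value + sigmoid) among 25 features per view, noise
  sd 0.1. The sample size is a free parameter; the default $N = 100$
  matches the middle setting of the first benchmark. The subscript-
  ambiguous second term of $z_1$ is read as $\exp(-x_4^2)$.
* `simulate_dataset3()` — a pure interaction $z_1 = x_1 x_2 +
  \varepsilon$: neither factor is marginally associated with $z_1$, so only
  the pair-wise sub-kernel on $(x_1, x_2)$ can carry the signal.

They emulate low-dimensional, uncorrelated, noise-free-design settings
with known sparse truth. They do **not** emulate correlated features,
heavy tails, heteroscedastic noise, or $p \gg N$ — passing these benchmarks
shows the machinery recovers planted sparse nonlinear structure, not that
it is robust to real omics pathologies (standardize real data first; the
CLI exposes `--standardize`).

A note on evaluation: the three planted associations of the second
benchmark have nearly equal dependence strength, so which one is extracted
first is draw-dependent (classical label switching). Benchmark summaries
therefore match components to associations by the dominant right-singular
weight (`dominant_kernels()`) before averaging across replications.

## Problem sizes used in the shipped checks

The packaged end-to-end checks run 20 replications of each benchmark at
$N = 100$ with $B = 100$ permutations in the budget search (and one
$B = 1000$ significance run), sizes chosen to keep each protocol's Monte
Carlo error comfortably inside the asserted tolerances while remaining
desk-scale; oracle comparisons (naive HSIC loop, dense SVD, generalized
eigenproblem) run at $N \le 10$ where the brute-force route is exact.

## Known limitations

* The plug-in HSIC estimator carries an $O(1/N)$ positive bias; at
  $N = 100$ with tens of sub-kernels per side the bias floor makes a dense
  all-positive direction of $M$ competitive with genuine sparse structure
  once the L1 budgets pass roughly 1.4, so weight vectors can delocalize at
  loose budgets. The sparsest-tie-break default avoids that regime.
* At the sparsest budget each component carries a single sub-kernel per
  side, so an association driven by *two* features of one view is split
  across two components: the weaker feature surfaces as a later, separately
  significant component rather than as a secondary weight inside the first.
  A fixed budget around 1.2 merges them when the weaker feature's
  dependence is strong enough to beat the noise floor; with a weak even
  link (variance share of a few percent, and HSIC quadratic in it) it
  generally is not at $N = 100$.
* Regularized KCCA at $\kappa = 0.02$, $N = 100$ is conservative on
  held-out data: even near-linear planted links reach test correlations
  around 0.93, and the noisier nonlinear links 0.7–0.8.
* Significance is per component against an independence null; no
  correction for selecting the budget on the same data is attempted.
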