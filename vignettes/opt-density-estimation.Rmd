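---
title: "Optional Pólya trees for many-category factor data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optional Pólya trees for many-category factor data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the model it fits, the choices
made where the method leaves room, and what the accompanying simulation
evidence does and does not show.

## The estimation problem

We observe `n` samples of `p` jointly distributed factor variables, the
`i`-th taking one of `m_i` unordered categories; the estimand is the
probability of every combination cell, `C = prod(m_i)` of them. When the
`m_i` reach tens to hundreds, `C` dwarfs `n`: the cell-wise maximum
likelihood estimate (counts over `n`) is mostly zeros with a few spikes,
and kernel smoothing in the usual sense is unavailable because unordered
categories have no neighbourhoods. The only structure left to exploit is
*conditional uniformity*: groups of categories whose cells are
(approximately) exchangeable. The optional Pólya tree (OPT) prior encodes
exactly that — a posterior over recursive binary partitions of the product
space into regions within which cells are uniform.

## Model

A region `A` is a product of per-variable category subsets, with `C(A)`
cells and `N(A)` (possibly weighted) samples. Likelihoods obey

* stop: `Phi0(A) = C(A)^(-N(A))`, the uniform likelihood; the measure of a
  discrete region is defined as its cell count, which makes `Phi0` the
  exact uniform-multinomial likelihood;
* recurse: `Phi(A) = rho * Phi0(A) + (1-rho)/p * sum_i w_i *
  Phi(A_i1) * Phi(A_i2)` with
  `w_i = B(N(A_i1)+alpha, N(A_i2)+alpha) / B(alpha, alpha)`;
* terminal regions — a single cell, or no sample — take
  `Phi(A) = Phi0(A)`.

Posterior quantities at a region are the stopping probability
`rho(A|D) = rho * Phi0(A) / Phi(A)`, selection probabilities proportional
to the summands `w_i * Phi(A_i1) * Phi(A_i2)`, a Beta(`N1+alpha`,
`N2+alpha`) mass allocation between committed children (read as the
normalized pair `theta_1/(theta_1+theta_2)`, the standard Pólya-tree
posterior form), and, inside stopped regions, a symmetric
Dirichlet(`N/C + beta`) allocation over cells.

### Candidate splits from marginal populations

Scoring all bipartitions of a variable's categories is exponential in
`m_i`. Instead, within each region the categories of variable `i` are
ranked by their *local marginal population* (their sample count within the
region), and only prefix cuts of that ranking are candidates; the cut
position minimizes the within-group dispersion `T(s)`, the sum over the
two groups of squared deviations of the marginal counts about the group
mean. One detail is deliberately resolved here: `T` is read as a
*sum of squared per-category deviations* (not the square of a summed
deviation), which is the reading under which `T` measures within-group
variation and vanishes exactly when both groups are internally constant.
Ties in the ranking keep storage order; ties in the cut position take the
smallest `s`. Both choices are arbitrary but deterministic, and the
package's tests verify that the result depends on the data only through
the multiset of marginal counts.

The split is constrained to the ranked prefix by design; arbitrary
bipartitions are intentionally not searched, so the method scores exactly
`p` options per region.

### Limited lookahead and commitment

Exact evaluation of `Phi` recurses to terminal regions and is exponential.
The package constructs trees with limited lookahead (LL-OPT): `Phi` is
evaluated `h` levels deep with `Phi0` at the frontier, the single best
action at the current region — stop, or split on one variable — is
committed (`q = 1`; deeper commitment is not implemented, matching
standard practice), and construction recurses into the committed children,
re-evaluating at full depth `h` there. Stop wins ties, which makes the
construction fully deterministic. `log_phi_exact()` retains the exact
recursion for small spaces and is used as the oracle in the test suite;
lookahead values provably coincide with it once `h` exceeds the recursion
depth.

### Inference

Three modes are provided; the deterministic posterior **mean** is the
default output (`predict(fit)`), since the method's headline error metric
is an expectation and reproducibility matters more than a single
maximum-a-posteriori tree:

* *mean*: each internal node contributes `stop_prob` of its incoming mass
  uniformly over its region; the rest flows to the committed children in
  proportion to the Beta means `(N_child + alpha)/(N + 2 alpha)`. Leaves
  are uniform. The symmetric Dirichlet cell extension has mean `1/C(A)`
  regardless of `beta`, so `beta` influences sampled draws only.
* *mode*: descend while the best split's posterior weight exceeds the
  stopping probability; stopped regions tile the space and carry their
  posterior-mean mass uniformly.
* *sample*: draw stop/continue, allocations, and Dirichlet cell masses;
  used for uncertainty assessment. Draws average to the posterior mean
  (verified in the suite by a law-of-large-numbers check).

All likelihood arithmetic is in log space with log-sum-exp combination and
log-Gamma Beta functions: `Phi0` alone is `10^-600000`-scale on a `100^3`
space with `10^5` samples, far below double-precision underflow.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `rho` | prior stop weight per region, in (0,1) | 0.5 | indifference between stopping and continuing |
| `alpha` | Beta pseudo count for child allocations | 0.5 | Jeffreys-style; rewards unbalanced children mildly |
| `beta` | Dirichlet pseudo count inside stopped regions | 0.5 | affects sampled draws' dispersion only |
| `lookahead` (`h`) | depth of truncated likelihood evaluation | 3 | precision/time trade-off; the simulation study uses 3 throughout |
| `commit_q` | levels committed per lookahead | 1 | fixed |

The source method leaves `rho`, `alpha`, `beta` unstated; the defaults
above are common OPT practice and make the package's closed-form
micro-examples exact (e.g. the one-variable two-category space with counts
(1,1) has `Phi = 0.1875` and stopping probability `2/3`). They are
deliberate package defaults, chosen once, and all configurable. One
consequence documented under *Limitations* below: these defaults yield
noticeably smoother trees than the source experiments apparently used.

A second open point is the `(1-rho)/p` weight when some variables cannot
be split within a region: the package keeps the literal constant weight
(no renormalization over splittable variables), which slightly favours
stopping in thin regions. `p` is always the number of variables of the
whole space.

## Synthetic data and what the tests show

The generators return both observations and the designed truth table, so
estimation error (root sum square error over all cells,
`rsse()`) is exact, not estimated.

* **Two-level uniform** (`sim_two_level`): each variable's `m_i`
  categories aggregate into two hidden super categories of equal size with
  masses `p_i` / `1-p_i`; cells are uniform within blocks. The dependent
  mode shares the super indicator across variables (block-diagonal truth);
  the independent mode multiplies marginals — with `p = (0.7, 0.8, 0.9)`
  the all-low block cell probability is `0.504/prod(m_i/2)`. Truths are
  stored as a handful of uniform blocks, not `10^6` cells.
* **Discretized multivariate normal** (`sim_mvnormal`): the density is
  evaluated at cell midpoints of a uniform grid spanning the mean ±3
  standard deviations per axis and renormalized — that midpoint rule *is*
  the definition of the discretized truth here (the source does not state
  a discretization); samples are drawn from the discretized truth itself,
  so truth and data are exactly consistent. Default correlations 0.2
  (low) and 0.8 (high) are package choices.
* **Auxiliary families** (`sim_auxiliary`): independent normals, additive
  exponentials (`Y_i = Z_0 + Z_i`, shared exponential component), a
  Clayton copula pair with uniform third axis (truth exact via
  copula-CDF inclusion–exclusion), log-normals, and `K`-super-category
  uniforms with linearly decreasing default masses. Where no closed-form
  discretized truth exists (exponential, log-normal) the truth is defined
  as the discretization of a large latent Monte-Carlo sample under a fixed
  internal seed, so it depends only on the stated parameters. The exact
  parameters of the corresponding source settings are not public;
  these families are therefore generic and excluded from numeric
  comparisons.
* Category labels are **shuffled** by default
  (`shuffle_category_labels`), permuting observations and truth
  consistently, so no estimator can exploit generative storage order.

What passing tests show: the estimator's exact closed forms, oracle
equivalences (exhaustive split scans, exact-vs-lookahead likelihoods,
dense-vs-sparse RSSE), conservation and determinism properties, the
analytic multinomial calibration of the conventional estimator
(`mean RSSE^2 = (1 - sum p^2)/n`), and the headline improvement on the
independent two-level setting at `100^3` cells with `10^4` samples. What
they do not show: behaviour on real clinical or genomic data (dependence
structures are far richer than block uniformity), or robustness to
misspecified spaces (categories never observed and never declared).

## Problem sizes

The default suite runs the full `100^3`-cell experiment at 10 conventional
and 5 tree replicates, the `20^3`-cell stability experiment at 100
replicates per setting, and the ordering comparison at 20 replicates —
about three minutes total on one CPU; the standalone
`scripts/acceptance.R` reruns them from scratch in about two. A single
tree fit at `100^3` cells / `10^4` samples commits ~7,000 nodes in ~7 s in
pure R; no compiled code is needed.

## Known limitations

* **Prior sensitivity of second-order behaviour.** With the defaults
  (`rho = alpha = 0.5`, `h = 3`) the fitted trees are smoother than those
  behind the source experiments: mean error on the two-level settings is
  *lower* than the source reports, but replicate-to-replicate variation of
  the error is correspondingly larger (coefficient of variation ~0.3 at
  `20^3` cells / 800 samples rather than below 0.01), and the
  random-partition variant — which stops very early and thus approaches a
  near-uniform estimate — is not consistently worse than the guided tree
  on near-uniform truths at small scale. Both effects are measured, not
  hidden, by the acceptance suite; matching the source's second-order
  numbers would require its unpublished prior values.
* The committed (`q = 1`) tree is a greedy approximation of the full OPT
  posterior; inference conditions on the committed structure.
* Sampling a posterior distribution materializes every cell of each
  stopped region and is guarded accordingly; on very large spaces use the
  posterior mean (block-structured and cheap) instead.
* Missing values are rejected; there is no missing-data mechanism.
* The co-occurrence network counts *terminal regions* sharing labels
  (weight 1 per region with at least one sample); an alternative reading
  weighting by sample count is available via `weight = "samples"`. Which
  the source figure used is not stated.
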