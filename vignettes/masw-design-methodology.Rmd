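---
title: "Designing multiarm stepped-wedge cluster randomized trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing multiarm stepped-wedge cluster randomized trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maswdesign)
```

## The design problem

A stepped-wedge cluster randomized trial (SW-CRT) rolls an intervention out
across $C$ clusters over $T$ time periods, with $m$ measurements per
cluster-period. In the multiarm extension there are $D \ge 2$ arms, labelled
$0, \dots, D-1$, and the allocation is described by a $C \times T$ matrix
$X$ with $X_{ij}$ the arm cluster $i$ receives in period $j$. We work in the
nested-intervention setting — arm $d$ extends arm $d-1$, as when successive
arms add components of a multifaceted intervention — so rows of $X$ are
nondecreasing: once a cluster has stepped up it never steps back.

A design is the tuple $\mathcal{D} = \{m, C, T, X\}$. The question this
package answers is: given the analysis model and its (assumed known)
variance components, which $\mathcal{D}$ in a constrained space of candidate
designs should the trial use, balancing statistical efficiency against cost?

## Analysis model and treatment-effect covariance

Responses are analyzed with the linear mixed model
$$
y_{ijk} = \mu + \pi_j + \beta_1 \mathbb{1}\{X_{ij} \ge 1\} + \dots +
\beta_{D-1} \mathbb{1}\{X_{ij} \ge D-1\} + c_i + \theta_{ij} + s_{ik} +
\varepsilon_{ijk},
$$
with $\pi_1 = 0$ for identifiability, cluster effects
$c_i \sim N(0, \sigma_c^2)$, cluster-period interactions
$\theta_{ij} \sim N(0, \sigma_\theta^2)$, subject effects
$s_{ik} \sim N(0, \sigma_s^2)$ (a closed cohort: subject $k$ is the same
individual in every period; cross-sectional sampling is exactly
$\sigma_s^2 = 0$) and residuals
$\varepsilon_{ijk} \sim N(0, \sigma_\varepsilon^2)$. The cumulative
indicators mean $\beta_d$ is the direct effect of arm $d$ relative to arm
$d-1$, giving $q = D - 1$ effects of interest.

With total variance $\sigma^2 = \sigma_c^2 + \sigma_\theta^2 + \sigma_s^2 +
\sigma_\varepsilon^2$, the implied correlations are the within-period
correlation $\rho_0 = (\sigma_c^2 + \sigma_\theta^2)/\sigma^2$, the
interperiod correlation $\rho_1 = \sigma_c^2/\sigma^2$ and the individual
autocorrelation $\rho_2 = (\sigma_c^2 + \sigma_s^2)/\sigma^2$. Either
parameterization can be supplied (`variance_components()`,
`vc_from_correlations()`); they are exact inverses of one another. The
components are taken as *known* throughout: this is a design-stage package
and contains no variance estimation.

Writing $A_i$ for cluster $i$'s fixed-effect matrix and $V_i$ for its
within-cluster covariance (which has the closed form $\sigma_c^2 J +
\sigma_\theta^2 (I_T \otimes J_m) + \sigma_s^2 (J_T \otimes I_m) +
\sigma_\varepsilon^2 I$), the covariance of the GLS estimator of all
$p = T + D - 1$ fixed effects is
$$
\Lambda = \Big( \sum_{i=1}^{C} A_i^\top V_i^{-1} A_i \Big)^{-1},
$$
and $\Lambda_q$ is its $q \times q$ block on the intervention coordinates.
`compute_information()` evaluates this blockwise; because information is
additive over clusters and $V_i$ is common, each *distinct treatment
sequence* contributes a cached $p \times p$ block weighted by its
multiplicity. This cache is what makes exhaustive search over large design
spaces feasible, and it also makes $\Lambda_q$ exactly invariant under
permutation of clusters.

## Power for the one-sided Wald tests

The hypotheses are $H_{0f}: \beta_f \le 0$ against one-sided alternatives,
rejected when $Z_f = \hat\beta_f \sqrt{I_f} > e$, with information
$I_f = 1/\Lambda_q[f,f]$. The boundary $e$ is the upper-$\alpha$ normal
quantile, or upper-$\alpha/q$ under the Bonferroni correction
(`critical_value()`). Two power notions are supported at the clinically
relevant effects $\delta$:

* **individual power** — $\min_f P(\text{reject } H_{0f} \mid \delta_f)$,
  with each term $1 - \Phi(e - \delta_f \sqrt{I_f})$;
* **combined (disjunctive) power** — the probability of rejecting at least
  one hypothesis, $1$ minus a multivariate normal rectangle probability
  with mean $\delta \circ I^{1/2}$ and correlation
  $\mathrm{diag}(I^{1/2}) \Lambda_q \mathrm{diag}(I^{1/2})$.

The rectangle probability is computed with the Miwa algorithm of
**mvtnorm** at 512 grid points per dimension. Miwa is a deterministic
quadrature, so repeated evaluations are bit-identical — important because
search results and reports must be exactly reproducible — and its error at
the small $q$ arising in trial design (here $q \le 3$) is far below the
$10^{-4}$ resolution at which powers are compared. Two-sided tests are a
deliberate non-goal; the one-sided formulation matches how nested
intervention packages are evaluated.

## Optimality, cost and admissibility

Three classical criteria scalarize $\Lambda_q$ (`criterion_value()`):
D-optimality $\det(\Lambda_q)$ (confidence-ellipsoid volume), A-optimality
$\mathrm{tr}(\Lambda_q)/q$ (average variance) and E-optimality
$\max \mathrm{diag}(\Lambda_q)$ (worst variance). For $D = 2$ all three
coincide. The *admissible* design minimizes
$$
w \cdot \frac{f(\mathcal{D}) - \min f}{\max f - \min f} +
(1 - w) \cdot \frac{g(\mathcal{D}) - \min g}{\max g - \min g},
$$
where $f$ is the trial cost (the shipped default is the total number of
observations $mCT$; the cost function is pluggable), $g$ the chosen
criterion, the ranges are taken over the whole candidate space, and
$w \in [0, 1]$ weights cost against efficiency — subject to the design
attaining power $1 - \beta$. Numerical choices here:

* a degenerate range ($\min = \max$) makes the rescaling undefined; that
  term then contributes 0, which is rank-neutral;
* $w = 1$ is allowed but warned about, since many designs share a cost;
* if no design meets the power requirement the search signals an error, or
  (with `fallback = TRUE`) relaxes to $\beta = 1$, $w = 0$ and minimizes
  the raw criterion.

## Design spaces and exhaustive search

A `design_space()` lists allowed periods $T$, per-$T$ cluster counts, and
per-$(C, T)$ sample sizes, with a `constraint_set()` restricting the
allocation matrices: monotone rows, starting on control, finishing on the
top arm, every cluster receiving every arm, or equal allocation of clusters
to sequences (each of $k$ distinct sequences used by exactly $C/k$
clusters).

Clusters are exchangeable under the model, so enumeration is over
*multisets* of sequences, one canonical representative (rows sorted
lexicographically) per equivalence class — for example the $7^{10}$ ordered
two-arm matrices with $C = 10$, $T = 6$ collapse to $\binom{16}{10} = 8008$
canonical designs, with no loss of exactness for any criterion used.
`space_size()` counts designs by multiset-coefficient arithmetic without
materializing them (exact in double precision for any size arising in
practice); the identifiability screen, which requires building each
design's fixed-effect matrix, is applied during enumeration and search, so
a search reports both the arithmetic count and the number actually
evaluated.

Estimability can fail structurally — an arm never allocated, or an
intervention indicator collinear with a period effect — and near-collinear
designs arise constantly during search. A single singularity rule is used
everywhere: the information matrix is declared singular when its smallest
singular value is below $p \cdot \epsilon_{\text{machine}} \cdot
\text{(largest singular value)} \cdot 10^3$. Ties in the search (relative
$10^{-12}$ on criterion and cost) are resolved to the canonical,
lexicographically smallest design, and all ties are reported; results are
therefore independent of enumeration order.

For two-arm cross-sectional designs the efficiency of a design is indexed
by the cluster mean correlation $E(\rho) = mT\rho / \{1 + (mT - 1)\rho\}$.
The printed form of this quantity in the reference material is
typographically garbled; the reading implemented here is confirmed
empirically — exhaustive searches at $\rho$ values chosen to hit target
$E(\rho)$ levels recover exactly the known optimal two-arm allocation
matrices across the whole range from parallel-group-like to classical
stepped-wedge designs. The inverse map
(`icc_from_cluster_mean_correlation()`) is closed-form and exact.

## Cross-entropy stochastic search

When $C$ and $T$ are fixed but the space is still enormous (the four-arm
setting with $T = 8$ has $\binom{170}{6} \approx 3 \times 10^{10}$
canonical designs), `ce_search()` optimizes the raw criterion — rescaling
is unavailable without known range extremes — by the cross-entropy method:
each cluster carries a categorical distribution over the constrained
sequence set; each iteration samples a population of allocation matrices,
retains the elite fraction with the best criterion values, and moves the
categorical probabilities toward the elite frequencies with smoothing.
Defaults (population 1000, elite fraction 0.1, smoothing 0.7, at most 100
iterations, stop after 5 iterations without elite improvement) are all
overridable; the seed is mandatory and fixes the result bit-for-bit. The
returned design is the best identifiable design seen anywhere in the
sampling history, so the reported optimum can never be worse than anything
the search actually visited. On small spaces where exhaustive search is
possible, seeded restarts recover the exact optimum essentially always;
the test suite requires at least 9 of 10 restarts on a 210-design space.

## Sensitivity to variance-parameter misspecification

Optimal designs depend on variance parameters that are never known
exactly. `sensitivity_map()` quantifies the exposure: over a grid of
$(\sigma_c^2, \sigma_\varepsilon^2)$ values (two-arm cross-sectional
reduction), it finds the optimal design at each grid point and reports the
ratio of a probe design's effect-estimator variance to the optimum's. The
ratio is $\ge 1$ by construction and equals 1 exactly where the probe is
optimal; a probe whose ratio stays near 1 across the grid is robust to
misspecification.

## The Monte-Carlo simulator and what it does (not) show

`simulate_trial()` draws trials from the same mixed model;
`gls_estimate()` applies the known-variance GLS estimator; and
`empirical_power()` turns replicated Wald tests into rejection
frequencies. This is deliberately a *design-stage* oracle: the estimator
uses the true variance components, so agreement between empirical and
analytic power validates the information-matrix and power algebra, not a
full analysis pipeline with estimated variance components (REML refitting,
open cohorts, missing data and non-normal outcomes are out of scope). The
generator reproduces the model's correlation structure exactly — the test
suite checks the simulated within-period, interperiod and
individual-autocorrelation covariances against $\rho_0 \sigma^2$,
$\rho_1 \sigma^2$ and $\rho_2 \sigma^2$ — but real trial data can of
course deviate from the model (secular trends interacting with arms,
cluster-size imbalance, attrition), and passing tests say nothing about
those departures.

Because power under the linear model is invariant to the intercept and
period effects, the simulation truth defaults to $\mu = 0$, $\pi_j = 0$; a
test asserts the invariance rather than assuming it.

## Reference designs and a printed-matrix discrepancy

`sohip_designs()` bundles the allocation matrices of the SO-HIP setting —
a three-arm trial of sensor monitoring in occupational therapy after hip
fracture ($C = T = 6$, $m = 8$, $\delta = (1.5, 0.75)$, $\rho = 0.05$,
Bonferroni $\alpha = 0.05$) — together with its published optimized
alternatives and a hypothetical four-arm extension. Re-evaluating these
matrices reproduces the published criterion values and powers to their
printed precision, with one exception: the tabulated allocation matrix for
the receives-all-arms A/E-optimal columns does not reproduce its own
tabulated metrics. Re-running the constrained exhaustive search identifies
an optimum differing from the tabulated string in a single cluster-period
cell (row 4, `001222` versus `001122`) whose metrics match the tabulated
values exactly, at both cost weights; we therefore treat the tabulated
string as a transcription error and recover that optimum by search wherever
it is needed.

## Problem sizes used in the test suite

The suite exercises every component at sizes chosen to keep a full run in
tens of seconds while still covering the real structure: the two-arm
optimal-design recoveries run the full $8008$- and $1001$-design spaces;
the three-arm admissibility machinery runs multi-stratum spaces of a few
thousand designs and a single-stratum sweep of $\sim 3 \times 10^4$
designs; the simulator battery uses 2000 replicates per design across six
designs spanning $D \in \{2, 3, 4\}$ and both sampling schemes; and the
four-arm cross-entropy searches run at their default settings. The same
API reproduces the full-size multi-stratum searches (around $10^6$
designs) unchanged; with per-sequence caching these complete well within
an hour on one core.

## Known limitations

* Variance components are assumed known; no uncertainty in them propagates
  into the power statements (use `sensitivity_map()` to probe this).
* One intervention per cluster-period; general combination allocations are
  an extension point.
* One-sided tests with at most a Bonferroni correction; closed testing or
  step-down procedures are out of scope.
* Gaussian responses only.
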