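# maswdesign

Design and optimization of **multiarm stepped-wedge cluster randomized
trials** (MA-SW): trials in which clusters step through nested intervention
arms over time, analyzed with a linear mixed model with known variance
components.

## Who this is for

Trial statisticians planning a stepped-wedge trial with two or more
intervention arms who need to (i) compute the power of a proposed
allocation matrix, (ii) compare candidate designs on classical optimality
criteria and cost, and (iii) search a constrained space of allocation
matrices for the best design — exhaustively when the space is finite and
small enough, stochastically otherwise.

## The model and the quantities computed

A design is $\mathcal{D} = \{m, C, T, X\}$: $m$ measurements per
cluster-period, $C$ clusters, $T$ periods, and a $C \times T$ allocation
matrix $X$ with $X_{ij} \in \{0, \dots, D-1\}$ the arm cluster $i$ receives
in period $j$ (rows nondecreasing in the nested-arm setting). Responses
follow

$$y_{ijk} = \mu + \pi_j + \textstyle\sum_{d=1}^{D-1} \beta_d
\mathbb{1}\{X_{ij} \ge d\} + c_i + \theta_{ij} + s_{ik} +
\varepsilon_{ijk},$$

with independent normal random effects for cluster, cluster-period,
subject (closed cohort; zero for cross-sectional sampling) and residual.
The covariance of the GLS treatment-effect estimators is
$\Lambda_q$, the $q = D-1$ intervention block of
$\Lambda = \{\sum_i A_i^\top V_i^{-1} A_i\}^{-1}$. From it the package
computes:

* per-hypothesis and minimum **individual power**, and **combined
  (disjunctive) power**, for one-sided Wald tests with optional Bonferroni
  correction;
* **D/A/E-optimality** criteria $\det(\Lambda_q)$,
  $\mathrm{tr}(\Lambda_q)/q$, $\max\mathrm{diag}(\Lambda_q)$;
* the weighted **admissibility score** trading rescaled cost ($mCT$ by
  default) against the rescaled criterion;
* optimal designs by **exhaustive enumeration** (with exact symmetry
  reduction over multisets of cluster sequences and per-sequence
  information caching) or by a seeded **cross-entropy search**;
* **Monte-Carlo** empirical power as an independent check of the analytic
  calculations.

## Worked example: the SO-HIP setting

The SO-HIP trial (sensor monitoring in occupational therapy rehabilitation
after hip fracture) is a three-arm cross-sectional MA-SW with $C = 6$,
$T = 6$, $m = 8$, effects of interest $\delta = (1.5, 0.75)$ (units of the
total SD), intracluster correlation $\rho = 0.05$, and Bonferroni-corrected
familywise $\alpha = 0.05$:

```r
library(maswdesign)
vc  <- vc_from_correlations(1, 0.05)
ds  <- sohip_designs()
hyp <- hypothesis_spec(q = 2, alpha = 0.05, delta = c(1.5, 0.75), beta = 0.12)

compute_information(ds$sohip_proposed, vc)
#> Treatment-effect covariance (q = 2):
#>            arm1       arm2
#> arm1 0.05695858 0.01242733
#> arm2 0.01242733 0.05695858
#> det = 0.00309, trace/q = 0.05696, maxDiag = 0.05696
```

The proposed design's minimum individual power is 0.88 (the binding
hypothesis is arm 2 versus arm 1, power 0.8815). Comparing it with the
optimized alternatives for the same setting:

```r
report_designs(ds[c("sohip_proposed", "sohip_optimal_w0",
                    "sohip_optimal_w05")], vc, hyp)
#>               sohip_proposed  sohip_optimal_w0  sohip_optimal_w05
#> C                          6                 6                  6
#> T                          6                 6                  5
#> m                          8                 8                  4
#> P(reject H01)              1           1 (±0%)     0.9937 (-0.6%)
#> P(reject H02)         0.8815   0.9878 (+12.1%)       0.8818 (±0%)
#> cost                     288         288 (±0%)       120 (-58.3%)
#> det                  0.00309 0.000999 (-67.7%) 0.006377 (+106.4%)
#> trace/q              0.05696  0.03175 (-44.3%)   0.08508 (+49.4%)
#> maxDiag              0.05696  0.03175 (-44.3%)    0.1132 (+98.8%)
```

Read: keeping the same 288 observations, reallocating the clusters raises
the binding power from 0.8815 to 0.9878 (+12.1%); alternatively the same
power is maintained with 58.3% fewer observations. Searches that produce
such designs:

```r
# exhaustive, two-arm: recover the optimal design at a target cluster
# mean correlation
rho <- icc_from_cluster_mean_correlation(0.45, m = 10, T = 6)
exhaustive_search(design_space(6, 10, 10, D = 2),
                  admissible_spec("D"), vc_from_correlations(1, rho))

# stochastic, four-arm (space of ~3e10 designs), seeded and reproducible
ce_search(6, 8, 8, 4, spec = admissible_spec("A"), vc = vc, seed = 1)
```

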