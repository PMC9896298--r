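---
title: "Controlling the population-wise error rate: models, calibration and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Controlling the population-wise error rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popwise)
```

## The error rate

Precision-medicine trials often test several treatment policies
$(P_i, T_i)$, $i = 1, \dots, m$, whose target populations $P_i$ overlap:
a patient carrying two biomarkers is eligible for two targeted strategies
and is therefore affected by two test decisions, while a patient in a
complement is affected by one.  The family-wise error rate (FWER) protects
every patient against the *worst case* over all hypotheses, including
combinations of rejections that no single patient can experience.  The
population-wise error rate (PWER) instead averages the relevant multiple
type I error over the population.  Partition the overall population into
disjoint strata $P_J$, $J \subseteq \{1,\dots,m\}$, where $P_J$ collects
the patients belonging to exactly the populations indexed by $J$, with
relative prevalences $\pi_J$ summing to one.  Then

$$\mathrm{PWER} \;=\; \sum_J \pi_J\, P(\text{falsely reject any } H_i,\ i \in J),$$

the probability that a randomly drawn future patient is exposed to at
least one falsely rejected null among the hypotheses that concern their
stratum.  Since every stratum term is bounded by the probability of any
false rejection, $\mathrm{PWER} \le \mathrm{FWER}$, with equality exactly
when a single stratum carries the entire population.  Controlling the
PWER therefore needs smaller critical values, and the saving grows as the
overlaps shrink.

`population_structure()` holds the strata and validates them (non-empty
index subsets, prevalences non-negative and summing to 1 within $10^{-6}$
on input, $10^{-9}$ internally).  Zero-prevalence strata contribute
nothing to the PWER and are dropped with a warning; alternatively a floor
$\pi_{\min}$ resurrects them conservatively, with the added mass removed
proportionally from the unfloored strata.  Proportional renormalization
is our choice — any scheme that keeps the vector a probability
distribution would do, and the difference is second-order in
$\pi_{\min}$ — and it is flagged here because it is not forced by the
methodology.

## Calibration

Let $Z_1, \dots, Z_m$ be one-sided test statistics with a known
(at least asymptotic) joint null distribution — multivariate normal, or
multivariate $t$ when a common residual variance is estimated
(`joint_null_model()`).  Under the global null, which is least favourable
for the pivotal statistics considered here, the calibrated critical value
$c^*$ is the smallest root of

$$\mathrm{PWER}(c) \;=\; \sum_J \pi_J\,
  P\Bigl(\max_{i \in J} Z_i \ge c\Bigr) \;=\; \alpha .$$

`pwer_critical_value()` solves this with a bracketed scalar root search.
The bracket is analytic: with equal weights and identical marginals $c^*$
cannot fall short of the marginal $(1-\alpha)$-quantile $z_\alpha$
(each stratum term is then at least $\alpha$ at any smaller threshold),
and the Bonferroni quantile $z_{\alpha/k}$ plus a margin bounds it from
above; the bracket expands automatically when user weights shift the
root.  The absolute tolerance on $c^*$ is $10^{-9}$ for the standard
calibrations (the umbrella calibration uses $10^{-7}$, far below anything
a simulation can resolve).  Per-hypothesis thresholds $c_i^* = w_i c^*$
support prevalence-driven weighting; adjusted p-values evaluate the PWER
at $c = z_j^{\mathrm{obs}}/w_j$, which preserves the duality
$p_j \le \alpha \iff z_j^{\mathrm{obs}} \ge c_i^*$.

Multivariate normal and $t$ probabilities are evaluated with **mvtnorm**.
For non-singular normal problems in up to six dimensions we use Miwa
quadrature, which is fully deterministic and accurate well beyond
$10^{-10}$ at 512 grid points.  Singular correlation matrices and
$t$ problems use Genz–Bretz quasi-Monte-Carlo under a fixed internal
seed (absolute tolerance $10^{-8}$ up to four dimensions, $10^{-6}$
above, where the quasi-Monte-Carlo effort would otherwise explode), so
every result is deterministic to tolerance and identical run to run.
The caller's RNG state is saved and restored around these evaluations.

## Strata-wise consequences

PWER control caps the strata-wise FWER
$\mathrm{FWER}_J(c) = P(\max_{j \in J} Z_j \ge c)$ in several ways:
by $\alpha/\pi_J$; by
$\tilde\alpha_J = P(\max_{j\in J} Z_j \ge z_\alpha)$, since
$c^* \ge z_\alpha$; and by the Bonferroni bound
$\min(|J|\alpha, 1)$.  A sharper small-$\pi_J$ approximation removes
$P_J$ from the population, renormalizes the remaining prevalences
($\tilde\pi_{J'} = \pi_{J'}/(1-\pi_J)$), and calibrates this
*complementary PWER* at $\alpha$; its root $d_J^*$ satisfies
$\mathrm{FWER}_J(c^*) = \mathrm{FWER}_J(d_J^*) + O(\pi_J)$ with linear
convergence.  We verify the linear rate numerically (the package makes no
claim to an analytic proof): for the nested three-population example with
triple-intersection prevalence $\varepsilon \in \{0.02, 0.01, 0.005,
0.0025\}$ and fixed complementary proportions, the test suite checks that
$|\mathrm{FWER}_J(c^*) - \mathrm{FWER}_J(d_J^*)|/\varepsilon$ stays
bounded (observed $\approx 0.07$ and nearly constant).
`strata_error_report()` tabulates all of these per stratum.

One labelling subtlety: for the nested worked example the quantity
reported as the small-prevalence upper bound is
$\mathrm{FWER}_J(d_J^*) \approx 0.0572$ — the strata-wise FWER evaluated
at the complementary threshold — not the complementary PWER itself, which
is $\alpha$ at $d_J^*$ by construction.  The report column
`fwer_at_dstar` makes this explicit.

## Two-population design calculators

For two overlapping populations of equal size the package provides the
closed forms used in design discussions.  With two *independent* samples
the PWER level is met by
$c_P^* = \Phi^{-1}\bigl[\{-(1-\pi) + \sqrt{(1-\pi)^2 +
4\pi(1-\alpha)}\}/(2\pi)\bigr]$ for overlap $\pi = \pi_{\{1,2\}}$, while
FWER control requires the Šidák value $\Phi^{-1}(\sqrt{1-\alpha})$.  We
deliberately use the Šidák threshold for the FWER reference: it is the
unique root of $1-\Phi(c)^2 = \alpha$ for independent statistics and it
reproduces the familiar ≈21% sample-size penalty at
$\alpha = 0.025$, $1-\beta = 0.8$; an unadjusted $\Phi^{-1}(1-\alpha)$
reference would make the FWER penalty zero and contradict that figure.

In a single trial with a shared control the statistics correlate through
the overlap.  With different treatments per population (1:1 randomization
in the complements, 1:1:1 in the intersection, population means estimated
by prevalence-weighted strata means) only the control group is shared and
$\rho = \tfrac{3}{2}\pi_{\{1,2\}}/(1 + 2\pi_{\{1,2\}})$; with one
treatment in both populations (1:1 everywhere, pooled means) both arms
are shared and $\rho = 2\pi_{\{1,2\}}/(1 + \pi_{\{1,2\}})$, which
dominates the former for every overlap.  (At $\pi_{\{1,2\}} = 0.2$ the
first formula gives $\rho = 3/14 \approx 0.214$; a stray "$\rho \approx
0.01$" sometimes quoted for this case is inconsistent with the formula
and with the downstream thresholds 2.23/2.03, which our Monte-Carlo
oracle confirms for $\rho \approx 0.214$.)  Sample-size penalties are
summarized by
$q_\alpha(c) = \{(\Phi^{-1}(1-\beta)+c)/(\Phi^{-1}(1-\beta)+
\Phi^{-1}(1-\alpha))\}^2$, in which the per-population non-centrality
cancels, and `inflation_curve()` tabulates $c$ and $q$ for both error
rates over an overlap grid (default 41 points).

## Umbrella trials

For $l$ disjoint biomarker strata with stratum-specific experimental
treatments against a shared control, the subset-selection procedure tests
every pooled sub-strategy $H_S\colon \theta_S \le 0$,
$\theta_S = \sum_{i \in S} (\pi_i/\pi_S)\theta_i$, with least-squares
$t$-statistics from the cell-means model
$Y_{ij} = \mu_i + \theta_i X_{ij} + \varepsilon_{ij}$,
$\varepsilon_{ij} \sim N(0, \sigma^2)$ i.i.d.  Under the global null the
$2^l - 1$ statistics are jointly $t$ with $N - 2l$ degrees of freedom;
their correlation matrix follows from the contrast weights and the
per-stratum estimator variances, with no need to materialize the design
matrix.  The FWER procedure compares $\max_S T_S$ with its upper
$\alpha$-quantile; the PWER procedure calibrates
$\sum_i \pi_i P_0(\bigcup_{S \ni i} \{T_S \ge c_P^*\}) = \alpha$, which
is strictly smaller whenever some subsets are disjoint.  The selected set
is the arg-max statistic when it clears the threshold, otherwise empty;
exact ties (a measure-zero event, relevant only for degenerate inputs)
go to the smallest, lexicographically first subset so that outputs are
stable.

Effect configurations are parameterized by the null fraction $q$
(with $ql$ integral), the relative half-range
$\tau = (\theta_{\max}-\theta_{\min})/(\theta_{\max}+\theta_{\min})$ of
the positive effects, and their mean $\theta_{\mathrm{overall}}$; the
positive effects form the unique equidistant grid meeting these three
constraints (equal prevalences assumed; with at most one positive effect
$\tau = 0$ is forced).  Performance is summarized per replicate by
power (any false $H_S$ rejected), the prevalence fractions of correctly
and falsely selected strata within the chosen subset (zero when nothing
is selected — this convention is what makes the falsely-selected fraction
equal the realized one-sided FWER under the global null), and the
relative average effect
$\mathrm{RAE} = 100\,E(\sum_{i \in S^*}\pi_i\theta_i)/
\theta_{\mathrm{overall}}$, reported as 0 under the global null where the
denominator is undefined.

The default study conditions are $N = 1056$, $\alpha = 0.025$,
$\theta_{\mathrm{overall}} = 0.1$, equal prevalences, intercepts zero,
10{,}000 replicates and $\sigma = 1$.  The residual standard deviation is
a modelling choice of this package: with $\sigma = 1$ the calibrated
procedures reproduce the published operating characteristics of this
design (e.g. ≈36% power at $l = 2$), and the parameter is exposed for
other settings.  Replicates are simulated subject-level and reduced per
treatment group to means and sums of squares across replicates; this
reduction *is* the least-squares fit of the cell-means model (the test
suite checks equality with `stats::lm` to $10^{-10}$), so the vectorized
study and the single-trial fitting path are the same estimator.  One RNG
stream per study, seeded by the caller, makes runs byte-reproducible.

## Estimated prevalences

When the $\pi_J$ are estimated by the multinomial MLE $n_J/N$, the
critical value becomes random.  The robustness study draws count vectors
from the multinomial at each true prevalence point, calibrates from the
estimates together with the correlation implied by the *realized* counts
(the joint distribution used at analysis time is conditional on the
counts, so the conditional correlation — not the one implied by expected
counts — is the right plug-in), and then evaluates the true PWER with the
true prevalences and that same conditional correlation.  Two design
choices deserve a note.  First, a population with zero recruited patients
cannot be tested; in such replicates its hypothesis drops from both the
calibration and the evaluation, mirroring what an analyst could actually
do, and the optional $\pi_{\min}$ floor is exposed for users who prefer
to keep the stratum conservatively.  Second, replicate results depend on
the draw only through the count vector, so the study memoizes on counts;
at $N = 50$ this cuts the work by an order of magnitude without touching
the estimator.  At the default conditions ($N \in \{50, 100\}$, 10,000
replicates) the mean true PWER stays within about
$2.49\text{–}2.51 \times 10^{-2}$ of the nominal 0.025, with
single-replicate standard deviations of order $10^{-3}$ — estimation
noise mostly cancels on average, but individual trials can run at
$\approx 0.026$.

## Confidence intervals

Inverting the calibrated single-step test gives Wald-type simultaneous
bounds $\tilde\theta_i = \hat\theta_i - c^* \mathrm{SE}_i$ (one-sided)
and $\hat\theta_i \mp c^* \mathrm{SE}_i$ with the $\alpha/2$ calibration
(two-sided, doubling the one-sided non-coverage).  They control an
*average simultaneous coverage*: averaged over the stratum of a randomly
drawn patient, the probability that all bounds relevant to that patient
cover their parameters is at least $1-\alpha$.  Only Wald pivots are
implemented; the general min-$\delta$ inversion requires a user-supplied
monotone statistic family and adds nothing for the location problems
covered here.  Wald bounds are shift-invariant, so the coverage does not
depend on the true effects — `sci_coverage()` exposes the effect vector
anyway so the property is checkable.

## What the simulator does and does not emulate

`simulate_trial()` generates exactly the structure the analyses assume:
deterministic stratum sizes (largest-remainder rounding of $N\pi_J$; a
multinomial mode for the robustness study), within-stratum randomization
per the scenario's allocation rule with experimental arms rounded down on
odd counts, and homoscedastic normal outcomes.  Passing tests therefore
demonstrate internal correctness of the calibration–simulation loop, not
robustness to features real trials have and this model lacks: unequal or
non-normal outcome variances across strata, covariate drift, dropout,
interim analyses, or treatment effects that vary within a stratum.
Asymptotic normal approximations for non-normal endpoints are outside the
simulator's scope, although the calibration functions accept any
correlation matrix a user derives.

## Numerical choices and limitations

* Root solving is `stats::uniroot` on analytically guaranteed brackets;
  degenerate weight configurations that defeat the bracket expansion fail
  loudly with diagnostics rather than returning a boundary value.
* Subset enumeration is by cardinality, then lexicographic order,
  everywhere — matrices, labels and tie-breaks are stable across calls.
* The umbrella machinery enumerates $2^l - 1$ hypotheses and is guarded
  at $l \le 12$; the published configurations use $l \le 8$.
* Equal population sizes are assumed by the closed-form two-population
  correlations; unequal realized counts route through the
  conditional-correlation construction instead.
* Prevalence weighting of the umbrella contrasts uses design prevalences,
  matching the definition of $\theta_S$; plug-in estimated weights would
  change the statistics only at higher order under equal allocation.
* Step-down extensions are deliberately absent: with the PWER level
  exhausted by the single-step test, no uniform step-down improvement
  exists, and single-step tests extend directly to informative
  simultaneous intervals.

## Problem sizes used in the shipped checks

The test suite runs the worked examples exactly, the Monte-Carlo oracles
at $10^5$–$10^6$ draws, the umbrella performance study at 10,000
replicates for the two headline configurations ($l = 2$ power,
$l = 4$ global-null false-selection), and the robustness study on a
nine-point prevalence grid at $N = 50$ with 2,000 replicates — sizes at
which every Monte-Carlo tolerance in the checks is three standard errors
or wider.  `scripts/acceptance.R` recomputes the same quantities from a
fresh seed.
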