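---
title: "Methods: scalability coefficients, cluster-robust uncertainty, and test-guided item selection"
author: "ClusterMokken"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scalability coefficients, cluster-robust uncertainty, and test-guided item selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ClusterMokken)
```

This vignette documents the statistical machinery of `ClusterMokken`: the
models and estimators it implements, the numerical choices made where
several constructions were defensible, what the synthetic-data generator
does and does not emulate, and the known limitations. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. Scalability coefficients

The data are an $N \times J$ matrix of integer item scores
$X_{ri} \in \{0, \dots, m_i\}$ (any integer coding works: every statistic
below is invariant to shifting an item's scores by a constant, so the
package keeps scores exactly as read). For items $i$ and $j$ let $S_{ij}$
be their sample covariance and $S^{\max}_{ij}$ the largest covariance any
joint distribution with the same two margins can attain. That maximum is
reached by the *comonotonic coupling* — sort both items' scores in the same
order and pair them rank by rank, the "perfect Guttman" arrangement — and
equals the integral of the product of the two quantile functions. The
scalability coefficients are the normed covariances

$$
H_{ij} = \frac{S_{ij}}{S^{\max}_{ij}}, \qquad
H_i = \frac{\sum_{j \ne i} S_{ij}}{\sum_{j \ne i} S^{\max}_{ij}}, \qquad
H = \frac{\sum_{i<j} S_{ij}}{\sum_{i<j} S^{\max}_{ij}},
$$

which always satisfy
$\min(H_{ij}) \le \min(H_i) \le H \le \max(H_i) \le \max(H_{ij}) \le 1$.
A *Mokken scale* is an item set with $H_{ij} > 0$ for all pairs and
$H_i \ge c$ for all items, for a chosen lowerbound $c$ (0.3 by convention);
$H \ge 0.5$ marks a strong scale, $\ge 0.4$ medium, $\ge 0.3$ weak. Under a
monotone homogeneity model with positively discriminating items, all
inter-item covariances — hence all $H_{ij}$ — are positive in the
population, which is what the first criterion checks empirically.

**Numerical conventions.** Both $S_{ij}$ and $S^{\max}_{ij}$ use the
population-style $N$ denominator; the $H$ ratios are invariant to that
choice, and it matches the coupling construction exactly. The diagonal of
the pairwise table is reported as `NA`, never 1: $H_{ii}$ is undefined and
a sentinel value invites silent misuse. Items with zero sample variance are
accepted at data ingestion (they may carry meaning for other purposes) but
rejected with an explicit error by every scalability computation, since
$S^{\max} = 0$ makes the ratio undefined; the selection procedure instead
marks them unscalable with a warning. Missing values are rejected at
ingestion; listwise deletion exists but must be requested explicitly
(`dropIncomplete = TRUE`), so that missing-data handling is always a
visible, deliberate decision.

## 2. Standard errors: one-level and two-level

Each coefficient is a smooth function of the empirical distribution of
score patterns, so its sampling variance can be estimated by the delta
method. The package works with *influence functions*: for each respondent
$r$, $\mathrm{IF}_r(T)$ is the Gateaux derivative of the statistic $T$ at
the empirical distribution in the direction of a point mass at $r$'s score
pattern. For the covariance part these derivatives are closed-form
($\mathrm{IF}_r(S_{ij}) = (X_{ri}-\bar X_i)(X_{rj}-\bar X_j) - S_{ij}$).
The maximum-covariance part is a piecewise-*linear* functional of the two
margins (segment lengths of the merged quantile functions are linear in the
category masses), so its directional derivative along
$(1-\varepsilon)\,\hat m + \varepsilon\, \delta_k$ is computed by a single
forward difference with $\varepsilon = 10^{-6}$ — exact within a linearity
region, and the correct one-sided derivative at a kink (kinks occur when
cumulative margins tie, which discrete data produce routinely; there the
estimator is genuinely non-smooth and any delta method is approximate —
the bootstrap cross-checks below are the guard). Quotient and sum rules
then assemble influences for every $H_{ij}$, $H_i$ and $H$ at cost
$O(NJ^2)$.

The two sampling models differ only in how influences aggregate:

* **one-level** (simple random sample): respondents i.i.d., multinomial
  covariance of the pattern proportions, giving
  $\widehat{\mathrm{Var}} = N^{-2} \sum_r \mathrm{IF}_r^2$;
* **two-level** (two-stage cluster sample): the $G$ groups are the
  independent units, giving the cluster-robust form
  $\widehat{\mathrm{Var}} = \frac{G}{G-1} N^{-2} \sum_g
  \big(\sum_{r \in g} \mathrm{IF}_r\big)^2$,
  which absorbs within-group dependency through the correlation of
  influences inside a group.

Point estimates are identical under both levels — the pooled empirical
distribution is the same — which the test suite asserts on every clustered
input it generates. With singleton groups the two-level variance reduces to
the one-level one times $G/(G-1)$, a deliberate design contract (singleton
clusters carry no clustering information). The factor $G/(G-1)$ is the
standard small-sample correction for a variance estimated from $G$
independent units.

Because this cluster-robust construction was built from the published
*contract* of the two-level method (correct point estimates, standard
errors that account for between-group variation) rather than from a printed
formula, the package carries its own ground truth: `clusterBootstrapSE()`
resamples whole groups with replacement and recomputes every coefficient
per replicate. The test suite requires the delta-method standard errors to
agree with the bootstrap within 15% relative difference, to track the
empirical sampling standard deviation of $\hat H$ over 1000 simulation
replicates within 10% (at latent ICC 0 and 0.3, 40 groups of 10, 4 items),
and to give 95% Wald intervals with coverage in $[0.92, 0.97]$ at latent
ICC 0.3 with 50 groups of 20 over 500 replicates — conditions under which
the one-level intervals demonstrably undercover. These problem sizes were
chosen to make Monte-Carlo error small relative to the tolerances while
keeping the default test run comfortable on a single CPU.

## 3. Hypothesis tests and confidence intervals

Three test families, all one-sided against "greater":

* **Mokken's $\Delta$** statistics test marginal independence
  ($H \le 0$) from the covariance-to-product-of-SDs ratio scaled by
  $\sqrt{N-1}$; asymptotically standard normal, valid only for simple
  random samples.
* **Wald**: $z = (\hat H - c)/SE_{\hat H}$ for any null value $c$, usable
  with either level of standard error. This is the default flavour: in the
  range where scale-construction hypotheses live ($c \le 0.55$, $\hat H$
  rarely near 1) it is accurate and symmetric.
* **Range-preserving**: the same test on the transformed scale
  $g(H) = \log(1-H)$, with $SE_{g(\hat H)} = SE_{\hat H}/(1-\hat H)$ by the
  delta method and the sign oriented so larger $\hat H$ gives a larger
  statistic. The transformation maps $(-\infty, 1)$ onto the real line, so
  the back-transformed confidence interval
  $1 - \exp\{\log(1-\hat H) \mp z\, SE_g\}$ can never exceed the
  theoretical maximum of 1 — the defect of Wald intervals for very strong
  scales. $\log(1-H)$ is the simplest transformation with exactly this
  property, which is why it was adopted.

Tests are one-sided (that is the scale-construction question); confidence
intervals are two-sided with the $(1+\gamma)/2$ normal quantile, 1.96 at
95%.

## 4. Item selection: AISP and T-AISP

Both procedures share the greedy algorithm: start a scale with the
qualifying pair maximising $\hat H_{ij}$; repeatedly add the qualifying
item maximising the enlarged scale's $\hat H$; when no item qualifies,
start the next scale from the leftovers. They differ in what "qualifying"
means:

| criterion | classic AISP | T-AISP |
|---|---|---|
| 1: $H_{ij} > 0$ | $\Delta_{ij} \ge z_{crit}$ | $z_{ij} \ge z_{crit}$ (null $H_{ij} \le 0$) |
| 2: $H_i \ge c$ | $\Delta_i \ge z_{crit}$ **and** $\hat H_i \ge c$ | $z_i \ge z_{crit}$ (null $H_i \le c$) |

The classic procedure never *tests* the lowerbound requirement — it checks
the point estimate, ignoring its sampling error, which admits items too
liberally. The T-AISP tests it, with one-level or two-level standard errors
as the design dictates, making the procedure per-step more conservative: an
accepted $z_i \ge z_{crit} > 0$ implies $\hat H_i > c$, so the T-AISP never
admits an item the classic point-estimate check would reject in the same
situation. For a two-item scale $H_i = H_{ij}$, so criterion 2 for the
starting pair is evaluated on the pair coefficient.

**Sequential Bonferroni.** The critical value is adjusted for the number of
tests performed so far: a single global counter accumulates over the whole
procedure, each step first adds its own test count (2 per candidate pair in
a start step — one per criterion; $s + 1$ per candidate in an extension
step onto a scale of size $s$ — $s$ new pair tests plus one item test), and
every test in the step uses $z_{crit} = \Phi^{-1}(1 - \alpha/\text{counter})$.
Whether the counter should instead reset per scale is a genuinely open
convention; the global counter is the more conservative reading, and the
full accounting — counts, counter, critical value, decisions — is logged in
the partition's `trace` slot so any deviation from another implementation's
scheme is auditable rather than silent. The trace invariant (logged tests
sum exactly to the final counter) is tested.

**Determinism.** Ties in $\hat H_{ij}$ or in the enlarged-scale $\hat H$
are broken toward the lexicographically smallest item indices. Degenerate
items are excluded up front, warned about, and reported as unscalable (0) —
never silently dropped. The whole greedy path is validated against an
independent plain-loop re-implementation on 6-item problems.

## 5. Within-group dependency: ICC and F test

For each candidate final scale, the total score's intraclass correlation is
estimated from the one-way ANOVA decomposition with the unequal-group-size
correction $n_0 = (N - \sum_g n_g^2/N)/(G-1)$:
$\widehat{\mathrm{ICC}} = (MSB - MSW)/(MSB + (n_0 - 1) MSW)$, with
$F = MSB/MSW$ on $(G-1, N-G)$ degrees of freedom testing ICC $= 0$ (upper
tail). The ANOVA estimator was chosen over a variance-components (REML)
fit because it is the closed-form classical estimator tied directly to the
F test the workflow uses; the mean squares come from `stats::lm`/`anova`.
Negative estimates are reported as computed (truncation at zero is opt-in):
a negative value is informative about the F test's behaviour and truncating
silently would hide it. Degenerate case: zero within-group variance yields
$F = \infty$, $p = 0$, with a warning. The estimator's calibration (mean
estimate within Monte-Carlo error of the truth at $\rho \in \{0, 0.2, 0.4\}$,
F-test size near $\alpha$ at $\rho = 0$; 50 groups of 20, several hundred
replicates) is part of the acceptance suite.

## 6. The two-step workflow

`twoStepMSA()` encodes the decision flow for scale construction:

1. **Step 1** — T-AISP sweep over increasing lowerbounds (default 0 to
   0.55 in steps of 0.05), with two-level tests if and only if the data
   carry a cluster design. Deliberately, *no* ICC screening happens before
   this step: total scores over an unvetted item pool can mask or mimic
   within-group dependency, and a one-level T-AISP on high-ICC items risks
   admitting them on spuriously small standard errors. Final scales are
   then selected — a judgment call about stability across the sweep,
   discrimination, and theory that the package does not automate. The
   choice is encoded reproducibly in `finalScaleRule` (a partition at a
   named lowerbound, or explicit item lists) and recorded in the report.
   No automated "stability statistic" is invented; the sweep table is the
   evidence the analyst reads.
2. For clustered designs, each final scale's ICC and F test decide the
   estimation level for Step 2 (two-level iff the F test rejects at
   $\alpha$).
3. **Step 2** — scalability coefficients with standard errors at that
   level, 95% Wald intervals, and strength labels read off the *CI lower
   bound* (falling back to the point estimate, flagged, only if no SE is
   available). Using the lower bound means "strong" asserts that the whole
   plausible range clears 0.5, not merely the estimate.

The report's Step-2 coefficients are bit-identical to what `scalability()`
returns on the final item sets — the workflow never re-estimates through a
different path.

## 7. The synthetic-data generator

`multilevelGrmSpec()` + `simulateGrm()` generate clustered polytomous
scores from a multilevel graded response model: latent trait
$\theta_{gr} = \tau_g + \varepsilon_{gr}$ with $\mathrm{Var}(\tau) = \rho$
(the latent ICC) and $\mathrm{Var}(\varepsilon) = 1 - \rho$, total latent
variance 1; cumulative category probabilities logistic (probit optional) in
$a_i(\theta - b_{ik})$ with discriminations $a_i > 0$ and strictly
increasing thresholds. Two-dimensional specifications assign items to two
latent dimensions correlated at `dimCor`, applied at both levels so each
dimension keeps latent ICC $\rho$. The logistic link is the conventional
choice; nothing downstream depends on it.

The defaults emulate the kind of clustered questionnaire survey the
methods target: 13 five-category Likert items in a 7 + 6 two-dimensional
structure, 30 groups of 21 respondents ($N = 630$), discriminations
2.0–2.8 and a between-dimension correlation of 0.4 (giving within-dimension
total $H$ near 0.6 — strong scales — and clear cross-dimension separation
in a lowerbound sweep), and latent ICC 0.25, which attenuates on observed
total scores to roughly 0.15–0.2, inside the 0–0.5 band typical for
quality-of-life measures. The attenuation is expected — categorical
measurement error adds purely within-group variance — so the observable
total-score ICC is measured empirically, never asserted equal to $\rho$.
The shipped `swmdk_synthetic.csv` is one draw from these defaults (639
respondents split 21×21 + 9×22) and is labelled synthetic everywhere: it
shares the *layout and population character* of the questionnaire data the
package's worked example is modelled on, not its values.

What the generator does *not* emulate — and hence what passing tests do
not certify about real data: item-level group effects beyond what a shared
latent trait induces (no item-by-group interactions), missing data,
response styles (e.g. acquiescence on reversed items), unequal-sized or
informative cluster sampling, and three-level or cross-nested designs.

`populationH()` is the generator's oracle: it integrates the model-implied
category probabilities over the latent distribution (dense Gaussian grid on
$[-8, 8]$, 401 nodes; product grid with the bivariate normal density for
cross-dimension pairs), builds population covariances and comonotonic
maxima, and assembles population $H$ values. Accuracy is self-checked by
recomputing on a half-resolution grid and insisting the total coefficient
moves by less than $10^{-4}$; a failure raises an error rather than
returning a silently inaccurate oracle.

## 8. Known limitations

* The two-level variance estimator is the standard cluster-robust form; it
  assumes many groups. With few groups ($G \lesssim 20$) it is noisy, and
  the bootstrap oracle is the better reference. At kinks of the
  max-covariance functional (tied cumulative margins) all delta methods
  are approximations.
* The Bonferroni accounting follows this package's explicit, traced
  scheme; other implementations may count tests differently and produce
  occasionally different partitions near decision boundaries.
* Assumption checks of the underlying nonparametric IRT model —
  conditional association, manifest monotonicity, non-intersection — and
  reliability or parametric IRT follow-ups are outside this package's
  scope, as are three-level and cross-nested designs.
* The $\Delta$ tests are asymptotic; their size is verified at $N = 500$
  in the test suite, not at small $N$.
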