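---
title: "Transect-based welfare assessment: models, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transect-based welfare assessment: models, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aviarytransect)
```

## The problem

Commercial loose-housed laying-hen flocks of several thousand birds cannot
be assessed bird by bird. Two families of on-farm welfare protocols exist:

* **whole-flock transect counting** — observers walk every aisle
  ("transect") of the house and tally each bird seen with one of 12 binary
  indicators (feather loss on head/back/breast/tail, wounds on
  head/back/tail/feet, dirty plumage, enlarged crop, sick, dead); and
* **fixed-n bird sampling** — 50 randomly chosen birds are handled or
  closely inspected and scored on ordinal 0/1/2 scales (two such schemes
  are encoded, differing in indicator sets and definitions).

This package implements both, plus the statistical machinery to compare
flocks, observers and house locations, and a simulator to study when each
design detects real differences.

## Geometry and bird apportionment

A house of width $W$ with $S$ rows of tiered aviary structures has $S+1$
aisles with measured widths $a_1,\dots,a_{S+1}$. The structure-row width is
derived, not measured:

$$ w_s = \frac{W - \sum_i a_i}{S}. $$

Each transect consists of its aisle plus half of each flanking structure:
wall transects (the first and last) absorb one half-structure, central
transects two, so transect widths $t_i$ partition $W$ exactly. Under the
homogeneity assumption the flock of $N$ birds apportions as

$$ n_i = \mathrm{round}\!\left(N \, t_i / W\right), $$

with *round half away from zero*: a 7,500-bird flock in a 14 m house with
four 1.75 m aisles puts exactly 1,562.5 birds in each wall transect, and
the field tallies show 1,563, ruling out banker's rounding. Working from
the derived $w_s$ rather than a 2-decimal rounded value is likewise what
reproduces whole-house tallies cell-for-cell; the rounded value is kept
only as a 0.01 m cross-check. Stocking density is birds per m² of usable
area **truncated** (not rounded) to two decimals — two of the six
reference houses (7,700/990 = 7.777... printed 7.77; 7,840/915 = 8.568...
printed 8.56) discriminate truncation from rounding.

```{r geometry}
g <- house_geometry("demo", house_width = 14,
                    aisle_widths = rep(1.75, 4), n_structures = 3,
                    flock_size = 7500, usable_area = 1850)
estimate_birds_per_transect(g)
animal_density(7840, 915)
```

## Prevalence estimation

Transect-scheme prevalence is the tally divided by the apportioned transect
population, $p = 100\,k/n_i$; a hen may be tallied under several indicators,
so indicator counts are not disjoint. For the 50-bird graded schemes, the
prevalence of score level $\ell$ is $p = 100\,k/n$ with standard error

$$ \mathrm{SE} = 100 \sqrt{\hat p (1-\hat p) / (n-1)}, $$

the $n-1$ (sample-variance) form. The choice is empirical: at $p = 24\%$,
$n = 50$ the $1/n$ form gives 6.0 while published tables print 6.1; the
$n-1$ form reproduces 29 of 30 published cells at the printed decimal and
is within 0.07 of the remaining one (32% → 6.66 vs printed 6.6, which no
single formula we tried reproduces simultaneously with the 24% cell).
Group summaries (per flock, observer, transect type, vertical level)
average subunit prevalences with the SE of the mean across subunits; the
published flock tables do not state their per-cell basis, so we document
this choice rather than assert numeric agreement with them.

## The comparison models

One binomial logit model is fitted per indicator, with fixed factors only
(flock, observer, transect type for the transect scheme; flock, transect
type and vertical level for the located graded scheme; flock alone for the
other), estimated by iteratively reweighted least squares with step
halving, which makes the log-likelihood trace provably non-decreasing
(asserted per iteration in the tests). Convergence is declared when the
largest coefficient change falls below $10^{-8}$ *or* the log-likelihood
gain falls below $10^{-10}$; the second clause matters under quasi-complete
separation (e.g. a flock with zero affected birds), where the deviance
converges while a coefficient drifts to $\pm\infty$. Separated fits are
flagged (any |coefficient| > 10 logits) and their contrasts treated as
non-estimable, but deviance-based tests remain valid and are reported.

Factor significance is a likelihood-ratio chi-square (deviance of the
reduced model minus the full model, on levels − 1 df). The original
variance-components software reports F-type tests by default and the
source publication does not state which statistic it used, so its printed
P values are not numeric targets; the likelihood-ratio construction was
chosen as the cleanest fully-specified test, and is checked against an
independent log-likelihood oracle instead. Responses with no variation
(all-zero columns such as back wounds in most flocks) are refused with an
explicit `no_variation` condition and reported descriptively.

Pairwise flock differences use LS-means on the logit scale (other factors
averaged uniformly), with Tukey adjustment from the studentized-range
distribution on residual df = cells − parameters (normal reference with a
warning when that is not positive), and a greedy-insertion compact letter
display at $\alpha = 0.05$. Between-method agreement uses Spearman
correlation with average ranks for ties and the t approximation on $n-2$
df.

```{r glm}
d <- data.frame(flock = c("A", "A", "B", "B"),
                kind = c("wall", "central", "wall", "central"))
fit <- fit_binomial_glm(c(13, 18, 2, 3), c(1563, 2188, 1563, 2188),
                        d, model_spec(c("flock", "kind")))
factor_test(fit, "flock")
```

## What the simulator emulates — and what it does not

`simulate_flock()` generates a flock of the configured geometry's size
(the study conditions: ~7,500 hens, 2–4 transects, 4 vertical levels):

* **placement** — multinomial over transects with weights proportional to
  transect width; affected birds' weights are additionally multiplied by
  `wall_bias` in wall transects (default 1 = homogeneous), mirroring the
  observed tendency of affected birds to sit near walls as a *simulated
  property*, not a calibrated estimate (no quantitative bias magnitude has
  been published, so `wall_bias` is a free parameter);
* **indicators** — independent Bernoulli per bird per indicator
  (multi-label). Real indicators co-occur within birds; no dependence
  structure has been published, so independence is the stated default;
* **observation** — each affected bird present is tallied with probability
  `sensitivity`, each unaffected bird miscounted with probability
  `fp_rate`, independently per observer (defaults 1 and 0: perfect
  detection);
* **graded sampling** — simple random sample without replacement of
  `sample_n` birds (default 50); an affected bird presents as score 2 with
  probability `severity_p2` (default 0.5, an uninformed split), else 1.

Not emulated: bird movement over time, feeding-cycle aggregation,
correlated observer errors, and per-tier area differences (the assessment
is purely width-proportional). Passing tests therefore show the estimators
and tests behave correctly *under the method's own assumptions*, not that
real flocks satisfy those assumptions.

Determinism: one global seed drives a per-operation stream keyed on
`(seed, operation name)`, so identical configurations are byte-for-byte
reproducible and adding an operation never perturbs existing draws.

## Numerical and design choices

* Reference level is the first by sort order; LRT results are
  reference-invariant (property-tested).
* Rank-deficient designs error naming the aliased columns rather than
  silently dropping them.
* Density truncation guards exact quotients with a $10^{-9}$ epsilon
  against binary representation error.
* `aggregate_prevalence()` sets SE = 0 with an explicit flag for
  single-subunit groups and drops empty groups with a warning.
* One reference house (house 2) has ambiguous published aisle widths; it
  is shipped with its closest reading, marked in the fixture, and excluded
  from golden geometry checks.

## Problem sizes used in the test-suite experiments

Monte-Carlo checks use sizes chosen to bound their standard errors well
below the effects being asserted: 400 placement replicates for the
homogeneity expectation, 400 null replicates for type-I calibration
(3 MC-SE band around 0.05), 2,000 replicates for estimator-recovery bias
at 1% prevalence, and 300 paired replicates per design for the
transect-vs-50-bird power comparison at 0.8% vs 0.05% prevalence, where
the whole-flock design's advantage is essentially saturated (power ≈ 1 vs
≈ 0).

## Known limitations

* Fixed effects only; no overdispersion or random-effect machinery, so
  clustered extra-binomial variation in real flocks would make the LRT
  anti-conservative.
* The LS-mean averaging is uniform over observed factor levels, which
  matches balanced walk designs; heavily unbalanced data would need
  weighted margins.
* The compact letter display is the greedy insertion algorithm; for
  pathological overlap patterns a minimal letter assignment could differ
  (group membership at $\alpha$ is unaffected).
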