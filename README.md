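# aviarytransect

Welfare surveillance toolkit for loose-housed laying-hen flocks in
multitiered aviary systems. It implements whole-flock **transect
counting** — observers walk every aisle of the house and tally birds
showing each of 12 binary welfare indicators (feather loss, wounds, dirty
plumage, enlarged crop, sick, dead) — alongside two 50-bird graded (0/1/2)
scoring schemes, and the statistics needed to compare them.

## What it computes

**Geometry & apportionment.** A house of width *W* with *S* structure rows
and measured aisle widths *aᵢ* has derived structure width
*wₛ = (W − Σaᵢ)/S*; each transect spans its aisle plus half of every
flanking structure, so transect widths partition *W*. The flock of *N*
birds is apportioned per transect as *nᵢ = round(N·tᵢ/W)* (half away from
zero), giving the denominators for whole-flock prevalence. Stocking
density is birds/m² of usable area, truncated to 2 decimals.

**Prevalence.** Transect prevalence is *100·k/nᵢ*; 50-bird scheme
prevalence is *100·k/n* with SE = *100·√(p̂(1−p̂)/(n−1))*.

**Comparison models.** Per-indicator binomial logit models (IRLS with step
halving; fixed factors: flock, observer, transect type, vertical level),
likelihood-ratio factor tests, Tukey-adjusted pairwise LS-mean contrasts
with compact letter display, and tie-aware Spearman correlations between
assessment methods.

**Simulator.** Seeded synthetic flocks (placement proportional to transect
width, optional wall bias for affected birds, observer
sensitivity/false-positive model, random 50-bird samples) for estimator
recovery checks and transect-vs-fixed-n power experiments.

## Worked example

```r
library(aviarytransect)

g <- house_geometry("demo", house_width = 14, aisle_widths = rep(1.75, 4),
                    n_structures = 3, flock_size = 7500, usable_area = 1850)
estimate_birds_per_transect(g)
#>   index    kind    width estimated_birds
#> 1     1    wall 2.916667            1563
#> 2     2 central 4.083333            2188
#> 3     3 central 4.083333            2188
#> 4     4    wall 2.916667            1563
```

The 7,500-bird flock splits 1,563 / 2,188 / 2,188 / 1,563 across the four
transects: each wall transect carries 2.92 m of the 14 m width (aisle plus
half a structure row), each central transect 4.08 m (aisle plus two
half-structures). A tally of 13 feather-pecked birds in transect 1 is then
a prevalence of 100·13/1563 ≈ 0.83 %.

```r
rec <- data.frame(house_id = 1, fl_head = rep(c(1, 0), c(12, 38)))
sample_prevalence(rec, "fl_head", 1)
#>   indicator score_level  k n_basis  p       se
#> 1   fl_head           1 12      50 24 6.101188
```

Twelve of 50 sampled birds with minor head feather loss is 24 ± 6.1 %.

A command-line wrapper for the `validate` / `assess` / `compare` /
`correlate` / `simulate` / `power` commands lives in
`inst/cli/aviarytransect.R` and is driven by a YAML run configuration.

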