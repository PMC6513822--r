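---
title: "Small-area expenditure estimation by spatial microsimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area expenditure estimation by spatial microsimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Household expenditure surveys record, for a few thousand respondents a year,
detailed socio-demographics and a commodity-coded spending diary — but only
coarse geography (one of twelve regions). Zone-level marginal counts (local
authority districts and similar) are, conversely, abundant: population by age
and sex, ethnicity, student status, unemployment, household life-stage and
wage percentiles. Spatial microsimulation bridges the two: it reweights the
survey so that, for every zone, the weighted sample reproduces that zone's
marginal counts, then reads zone-level expenditure estimates off the
reweighted diaries. The output is average weekly expenditure per person, per
zone, per commodity category of the hierarchical COICOP classification.

`microspend` implements the whole pipeline: constraint-table construction and
scaling, iterative proportional fitting (IPF) of individual-to-zone weights,
a separate child model, relative regional price adjustment, per-capita
estimation, and internal/external validation — together with a synthetic-world
generator used to test every stage against a known ground truth.

## The model

Let $w_{iz}$ be the weight of survey individual $i$ for zone $z$, initialised
to 1 for every pair — no geographic restriction is imposed, so any respondent
can serve any zone; restricting respondents to their own region would shrink
the effective sampling pool far too much. For a constraint variable $c$ that
classifies individuals into categories $k$ with zone targets $T_{zk}$, one
IPF update per zone rescales

$$ w_{iz} \leftarrow w_{iz}\,\frac{T_{z,k(i)}}{\sum_{j:\,k(j)=k(i)} w_{jz}}, $$

which makes the weighted ("simulated") marginal of $c$ match its target
exactly. Updates cycle through the constraint variables; each update perturbs
the previously matched marginals, and repeated sweeps converge to weights
consistent with all constraints simultaneously. The fitted point of IPF does
not depend on the update order, but the iterate path does, so the order is
fixed (and configurable): age-sex, household type, ethnicity, student,
unemployment, income.

Adults (16+) and children (15 and under) are fitted separately. Most
constraint variables are meaningless for children, so the child model uses a
single four-category age-sex constraint; single-constraint IPF converges in
one sweep with the closed form $w_{iz} = T_{z,k(i)} / n_{k(i)}$, which
`fit_child_model()` applies directly (and the tests verify against the
generic fitter).

### Constraints and the baseline

IPF needs the same per-zone total in every constraint. That total — the
baseline population — is the household-resident count: mid-year population
minus communal-establishment residents (care homes, halls of residence),
subtracted cellwise over the age-sex table by `build_baseline()`. Communal
counts are typically available for a single census year and are held constant
across study years; the other constraint sources already exclude most
communal residents, so the subtraction is applied to age-sex only. Every
other table is then rescaled row-by-row to the baseline
(`scale_constraint()`), preserving its category proportions exactly. Counts
stay fractional throughout — the targets feed a real-valued reweighting, not
a discrete population, so integerisation would only add error.

### The income constraint

Wage data arrive as per-zone gross-weekly-pay percentiles P10–P80 for
employees. By construction, the eight brackets P0–P10 … P70–P80 each hold a
tenth of the zone's employees and the open P80–P100 bracket a fifth;
self-employed and other adults fall outside the wage source and enter as two
whole categories. Because every zone has its own boundaries, the microdata
are re-bracketed per zone before each income update (`income_category()`),
with a left-closed convention: a wage equal to a boundary opens the next
bracket. Missing boundaries merge the adjacent brackets (their decile shares
add); non-monotone boundaries mark the constraint unavailable for that zone.
The merge rule is this package's choice for partially missing percentiles —
any rule that preserves the decile shares would do, and the merges are
logged.

### Missing constraints and empty cells

Not every zone has every constraint. `harmonise_missing()` resolves, per
zone: binary variables (student, unemployment) are dropped where unavailable;
a partially complete ethnicity table merges each missing category into a
present catch-all (`other`, falling back to the largest present category),
relabelling that zone's microdata identically and rescaling the remaining
targets to the baseline. Age-sex and household type are required everywhere —
the model runs on those two as a minimum. A category with a positive target
but no microdata individuals (an "empty cell") cannot be fitted
multiplicatively; the default strategy drops the category and rescales the
remainder to the baseline with a logged warning, while `empty_cells =
"error"` makes it fatal for audit runs.

### Regional price adjustment

Reweighting can place a respondent from a cheap region into an expensive one.
Diary values are therefore rescaled through the UK-average price level:
$x \mapsto x \cdot (I_{\mathrm{dest}}/100)/(I_{\mathrm{source}}/100)$, where
$I$ is the relative regional consumer price level (UK = 100) for the
commodity's price group — food and non-alcoholic beverages (COICOP division
1), alcohol and tobacco (division 2) or restaurants and hotels (the catering
division 11). Detailed per-group indices exist for London, Scotland, Wales
and Northern Ireland; other regions carry a single aggregate index repeated
across groups. The adjustment preserves zero, is positively homogeneous,
exactly invertible and multiplicative across chained regions. Price tables
are not published annually; `select_vintage()` uses the 2010 table for study
years 2008–2012 and the 2016 table from 2013 onwards. The shipped 2016 table
holds the published indices; the 2010 file is a constructed synthetic
stand-in (named accordingly) since that release is not redistributable here.
Northern Ireland respondents remain in the sampling pool and use NI's
detailed indices as a source region, but no NI zones are simulated.

### Estimates

Zone totals are
$\mathrm{total}_{zc} = \sum_i w_{iz}\,\mathrm{adjust}(x_{ic},\, r_i \to r_z)$
with missing diary entries contributing zero; per-capita estimates divide the
merged adult and child totals by the combined baseline population, giving
pounds per person (all residents) per week. Child diaries are accepted but
default to zero — children account for a negligible share of recorded
spending, and whether child-level diaries exist at all in a given survey
extract is ambiguous; attributing all diary spend to adults while dividing by
the full population is the conservative reading. Aggregates over the COICOP
hierarchy (`aggregate_categories()`) are exact sums of their member codes, so
cumulative categories such as "all food and drink" are additive by
construction.

## Validation

**Internal**: for each zone, the Pearson correlation between the concatenated
constraint targets (in fitting order) and the corresponding simulated
marginals (`internal_validation()`). A converged, well-posed fit yields
correlations indistinguishable from 1; the test suite requires the minimum
over 30 zones to be at least 0.9876. Raw counts are correlated, not
baseline-normalised shares — with a common baseline the two differ only by a
per-zone scale factor, and raw counts are the convention; per-constraint
correlations are attached for debugging. A zone whose target vector has zero
variance is reported as undefined rather than 1.

**External**: (a) `regional_comparison()` aggregates zone estimates to
regions (population-weighted) and flags whether each falls within 1.96
standard errors of an independently computed survey mean; (b)
`rank_correlation()` computes Spearman's rho (average ranks, two-sided
p-value by the t approximation) between zone estimates and an external
deprivation-style ranking. On synthetic data with deprivation-linked effects
the expected sign pattern — positive for food and for fruit and vegetables,
negative for tobacco — is reproduced; the magnitudes depend on the synthetic
effect sizes and are deliberately not pinned.

## The synthetic world

`world_config()` fixes the study conditions; its defaults are used by the
tests and the acceptance script:

* **30 zones** with adult populations between 4,000 and 11,000 (deterministic
  in the zone index) and children at 21% of adults — a desk-scale stand-in
  for local-authority districts, small enough that the full pipeline runs in
  seconds yet large enough that constraint counts are smooth.
* **Survey of 12,000 individuals**, sampled without replacement across zones,
  mirroring the roughly 12,000 annual respondents of the UK expenditure
  survey; the zone label is dropped from the emitted microdata (only the
  region is kept), which is precisely the degradation the method exists to
  undo. The configured minimum is ten respondents per distinct attribute
  category.
* **Two latent zone axes**: a deprivation axis (raising unemployment and
  non-employment, lowering wages, tilting the age and household structure)
  and a diversity axis (driving ethnicity and student shares). All
  categorical attributes are drawn independently within a zone given these
  axes.
* **Expenditure model**: weekly spend per category is lognormal,
  $x = \exp(\log\beta_c + \sum \text{effects} + \varepsilon)$ with
  $\varepsilon \sim N(0, \sigma_c^2)$, a per-category participation
  probability (zero weeks are omitted from the diary, mirroring diary
  sparsity), and the regional price level baked in — so the pipeline's price
  adjustment is correctly specified for this world. Effects are additive on
  the log scale per attribute category: unemployment raises tobacco
  (+0.85) and depresses fruit and vegetables (−0.5 to −0.55) and eating out,
  students favour beer and take-aways, older adults smoke and eat out less,
  households with children buy more staples. Ground truth per zone is the
  population mean of the deterministic part
  ($p_c \exp(\mu + \sigma_c^2/2)$, the lognormal mean).
* **Wages** are lognormal per employment type with the location shifted by
  deprivation; percentile boundaries use type-7 (linear interpolation)
  quantiles, fixed so that the sort-based test oracle is exact.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: household-level clustering (household type is
an individual attribute, as it is in the formatted microdata; diaries are
individual-level, the natural reading of an id-keyed diary), spatial
autocorrelation between zones, seasonality within the year, survey
non-response and measurement error, and cross-attribute dependence beyond
the two latent axes. Real attribute interactions (e.g. age × employment)
would stress IPF's implicit independence structure harder than this world
does.

## Numerical choices

* Initial weights are 1 for every (individual, zone) pair.
* Convergence: stop when the maximum over constraints and zones of total
  absolute error divided by the zone baseline falls below `tol` (default
  `1e-4`), or after `max_iter = 50` sweeps; non-convergence is reported, not
  hidden.
* Immediately after an update the updated marginal matches its target to
  machine precision; total absolute error is non-increasing between sweeps.
* Weights are invariant to microdata row permutation; seeded runs are
  bit-reproducible and every output file carries the package version, seed
  and a configuration hash.
* Age bins are closed on both ends as printed ("25–34" is $25 \le a \le 34$);
  ages 15 and under route to the child model. Non-employees are categorised
  by employment type, never by wage.

## Problem sizes

The test suite and the acceptance script run the full study at 30 zones and a
12,000-person survey (about 270,000 simulated people); the end-to-end
pipeline test uses 3 zones and 1,200 respondents. At these sizes the complete
suite runs in well under a minute on a single core; the dominant cost is
population generation, not the fit, which converges in about four sweeps.

## Limitations

Estimates carry no zone-level uncertainty intervals — the reweighting is
deterministic given its inputs, and survey sampling error propagates in a way
the framework does not quantify. Validation against a real deprivation index
or published regional survey means requires those external datasets; the
package ships only the procedures and synthetic stand-ins. Acquiring and
parsing the real licensed microdata and census tables is out of scope: the
formatted-CSV layouts written by the synthetic module define the interface
such data would need to be brought into.
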