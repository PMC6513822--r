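# microspend

Small-area estimates of weekly household expenditure by spatial
microsimulation.

Household expenditure surveys pair rich individual detail — socio-demographics
and a commodity-coded spending diary (COICOP categories) — with only coarse
geography: one of twelve regions. Planning questions, though, are local:
which districts spend most on tobacco, least on fruit and vegetables?
`microspend` answers them by **iterative proportional fitting (IPF)**: survey
respondents are fractionally reweighted, zone by zone, until the weighted
sample reproduces each zone's known marginal counts for age–sex, household
type, ethnicity, student status, unemployment and income brackets. The
reweighted diaries — adjusted for relative regional price levels — then yield
average weekly expenditure per person for every zone and commodity category.

The package is aimed at quantitative geographers, public-health and retail
analysts who have (a) survey microdata with a diary and (b) zone-level
constraint tables, and want reproducible zone × category expenditure
estimates with built-in validation. Because the real survey and census
sources are licensed, the package ships a seeded synthetic-world generator
with known ground truth; every stage is tested end to end against it.

## The method in brief

For individual *i* and zone *z*, weights start at *w<sub>iz</sub>* = 1 (no
geographic restriction) and each constraint *c* with targets *T<sub>zk</sub>*
is fitted by the multiplicative update

> *w<sub>iz</sub>* ← *w<sub>iz</sub>* · *T<sub>z,k(i)</sub>* / Σ<sub>j: k(j)=k(i)</sub> *w<sub>jz</sub>*

which matches the weighted marginal of *c* exactly; sweeps over all
constraints converge to weights consistent with every table at once. Adults
(16+) and children (15 and under) are fitted separately — the child model is
a single age–sex constraint with a one-sweep closed form — and merged into
per-capita estimates. Diary values are price-adjusted between the
respondent's source region and the zone's region via relative regional
consumer price levels (UK = 100). See the vignette
(`vignettes/expenditure-microsimulation.Rmd`) for the full account.

## Worked example

A complete synthetic study — 30 zones, a 12,000-person survey, all six
constraints — fitted and estimated:

```r
library(microspend)

wc     <- world_config(n_zones = 30, survey_size = 12000, seed = 42)
world  <- generate_population(wc)
survey <- sample_survey(world$population, wc)
tabs   <- world$ground_truth$true_population_tables

bl   <- build_baseline(tabs$adult$age_sex)
cons <- tabs$adult
for (v in setdiff(names(cons), "age_sex"))
  cons[[v]] <- scale_constraint(cons[[v]], bl$baseline)
cons$age_sex <- bl$constraint
inc <- build_income_constraint(tabs$income$boundaries,
                               tabs$income$employment, bl$baseline)

pools <- split_adult_child(validate_microdata(survey$microdata))
fit   <- ipf_fit(pools$adults, cons, bl$baseline, inc)
fit
#> Spatial microsimulation fit (IPF)
#>   9887 individuals x 30 zones
#>   4 sweep(s); converged (tol 0.0001, max rel. TAE 2.83e-05)

min(internal_validation(fit)$r)
#> [1] 0.99999999999999
```

Every zone's simulated marginals correlate with the constraint targets at
essentially 1 — the internal-validation check that the reweighting has
worked. Estimates and the deprivation cross-check:

```r
tot <- zone_expenditure(fit, survey$diary, survey$microdata,
                        wc$region_of_zone, wc$rrcpl)
est <- merge_per_capita(tot, NULL, tabs$baseline$adult, tabs$baseline$child)
agg <- aggregate_categories(est, standard_aggregates())
head(agg[agg$coicop == "all_food_and_drink", ], 3)
#>   zone_code             coicop mean_weekly_expenditure_gbp
#> 1 E06000001 all_food_and_drink                       20.37
#> 2 E06000002 all_food_and_drink                       21.17
#> 3 E06000003 all_food_and_drink                       19.99
```

so a person in zone `E06000001` spends an estimated £20.37 a week on food
and drink. Rank-correlating the aggregates against the world's deprivation
ranking (1 = most deprived) reproduces the expected directions — food and
fruit-and-vegetable spending rise away from deprivation, tobacco falls:

```r
#> all_food_and_drink       rho = +0.48  (p = 0.0067)
#> fruit_and_vegetables     rho = +0.84  (p = 8.7e-09)
#> tobacco_and_cigarettes   rho = -0.87  (p = 4.4e-10)
```

and the estimates recover the known ground-truth zone expenditure with
Pearson r = 0.9995 across zones. The same flow is available as a cached,
file-based pipeline (`run_simulate()`, `run_fit()`, `run_estimate()`,
`run_validate()`, `run_audit()`) driven by a YAML config.

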