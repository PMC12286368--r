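---
title: "Methods: dietary risk assessment for toxic elements in bread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dietary risk assessment for toxic elements in bread}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breadrisk)
```

## The model

breadrisk implements the U.S. EPA chronic-exposure framework for a staple
food. For each element with concentration $C$ (mg/kg dry weight) in the
consumed bread, the chronic daily intake of a cohort is

$$\mathrm{CDI} = \frac{C \cdot IR \cdot EF \cdot ED}{BW \cdot AT}
\quad \text{(mg/kg/day)},$$

with ingestion rate $IR$ (kg/day), exposure frequency $EF$ (days/year),
exposure duration $ED$ (years), body weight $BW$ (kg) and averaging time
$AT$ (days). Non-carcinogenic hazard is the quotient
$\mathrm{HQ} = \mathrm{CDI}/\mathrm{RfD}$ against the element's oral
reference dose, and the hazard index $\mathrm{HI} = \sum_e \mathrm{HQ}_e$
sums the quotients over elements; values above 1 flag concern.
Carcinogenic risk is the linear slope-factor model
$\mathrm{CR} = \mathrm{CDI}\cdot\mathrm{OSF}$, summed over carcinogens to
the total $\mathrm{TCR}$ and classified against the $10^{-6}$ (de minimis)
and $10^{-4}$ (unacceptable) bounds. Both thresholds are configurable
because regulatory practice quotes both the $10^{-6}$–$10^{-4}$ band and
stricter variants.

The built-in parameter set describes the Mashhad bakery survey population:
adults $IR = 0.420$, $ED = 70$, $BW = 70$, $AT = 10550$; children
$IR = 0.210$, $ED = 6$, $BW = 20$, $AT = 2100$; $EF = 365$ for both. Two
remarks on this set, which the package reproduces verbatim rather than
repairs:

* the adult $AT$ (10550 days) is not $365 \times ED$ (25550 days); the
  printed pair is internally inconsistent but is what the survey used;
* with these values the child:adult intake ratio per unit concentration is
  $0.01095/0.014531 \approx 0.754$, while the survey's reported hazard
  tables show child:adult ratios of 1.14–1.25. The parameter set behind
  those tables is not recoverable, so identities *among* reported outputs
  (column sums, ranges, means, ratios) are the validation surface, and the
  reported per-element hazard tables ship with the package
  (`mashhad_reference()`) as data.

A related inconsistency is retained as data: the West-adult total
carcinogenic risk is reported as $4.23\times10^{-3}$ although its own
components sum to $4.77\times10^{-3}$, and reported totals were rounded
from unrounded components, so summing reported components reproduces
totals to roughly one part in $10^3$, not always to the third printed
figure.

## Censored concentrations

Mercury and lead are below the detection limit in every sample of the
survey. Records therefore carry an explicit `censored` flag plus the LOD
instead of sentinel numbers. The default policy `exclude` drops censored
cells — so fully censored elements vanish from intake, hazard, compliance
and apportionment, matching the survey's published tables — while `zero`,
`half_lod` and `full_lod` substitution policies are available for
sensitivity checks. Censoring is resolved *before* any averaging or
distribution fitting, keeping the substitution choice in one place.

## Aggregation choices

Only bread-stage records enter dietary exposure: the consumed product is
bread; flour and dough exist to attribute contamination, not to be eaten.
Regional intake uses the arithmetic mean of bakery-level bread
concentrations (the survey reports means; by linearity of the CDI this
equals the mean of per-bakery intakes). Stage apportionment decomposes the
region-pooled stage means per element as flour level, dough-minus-flour
and bread-minus-dough, each increment clipped at zero before normalising
to percentage shares of the bread burden — the simplest mass-balance
reading of a three-stage sampling design; clipping absorbs measurement
noise that would otherwise produce negative shares. Shares are
scale-invariant and sum to 100 by construction.

## Group statistics

The survey's inferential procedure is reproduced as stated: a
Kolmogorov–Smirnov test against a normal law with sample-estimated mean
and standard deviation gates each element into one-way ANOVA (normal) or
Kruskal–Wallis (otherwise), at $\alpha = 0.05$, element by element and
without multiple-testing correction (a Holm option exists). Plain KS with
estimated parameters is the Lilliefors situation: its p-values are
conservative, so the gate routes to ANOVA more often than a calibrated
normality test would. This is deliberate — the procedure is the survey's —
and the package's tests treat the KS rejection rate under a normal null as
bounded above by $\alpha$ rather than equal to it. The gate-then-compare
procedure as a whole holds its type-I error at $\alpha$ because both
branches are level-$\alpha$ tests.

## Monte Carlo uncertainty and sensitivity

`simulate()` propagates input uncertainty through the risk equations with
10,000 iterations by default, reporting percentile summaries (the 95th
percentile is the headline risk measure) and cumulative distribution
curves. Default input distributions are minimal: lognormal maximum-
likelihood fits to the pooled bakery-level bread concentrations of each
element — positive and right-skewed, consistent with the survey's
rejection of normality — and point masses for the exposure parameters.
Any variable can be overridden with point, normal, lognormal, triangular
or uniform specifications; inputs are drawn independently (no correlation
structure is asserted by the data). All sampling is governed by one
integer seed with a fixed draw order, making runs bit-reproducible; the
empirical quantile uses R's default linear interpolation (type 7), fixed
so reruns agree exactly.

Sensitivity follows the contribution-to-variance convention of commercial
risk software: the squared Spearman rank correlation between each input
and the output, normalised to sum to 100% across inputs. Rank correlation
makes the measure invariant under monotone transformation of inputs;
negative associations contribute by their square with the direction
reported in a separate sign column. Zero-variance inputs contribute
exactly zero.

## The synthetic survey generator

`generate_study()` emulates the design of the bakery survey so that every
pipeline stage is testable without the original measurements: 5 regions
× 18 bakeries × 3 stages × 12 elements = 3,240 records (270 per element).
Its defaults are fixed study conditions, not tuning knobs:

* **Flour concentrations** are lognormal with `sigma_log = 0.15`, the
  within-region dispersion implied by the survey's reported regional
  SD/mean ratios (~0.15).
* **Stage structure** is multiplicative: dough = flour × 1.175, bread =
  dough × 1.0253 (small mean-one lognormal noise, sdlog 0.05), so flour
  contributes 83%, dough additions 14.5% and oven contact 2.5% of the
  bread burden. Cobalt deviates (dough × 1.5, bread × 1.1), reproducing
  the survey's finding that cobalt alone is not flour-dominated.
* **Regional structure**: As, Co, Cr, Ni and V carry region-specific mean
  factors (As: North 0.82, South 1.08, East 1.05, West 0.96, Center 1.11;
  the others with comparable or larger spreads placing their peaks in the
  survey's reported regions), while Al, Cu, Cd, Fe and Zn share one
  distribution across regions. At these effect sizes the Kruskal–Wallis
  test detects every varying element with power above 0.99 per element.
* **Magnitudes**: bread-stage target means back-calculated from the
  survey's reported adult hazard quotients where those are self-consistent
  (Fe 20.3, Zn 3.9, Al 1.59, As 1.0, Cu 0.91, Ni 0.5 mg/kg …), placing
  Fe, Zn and Al highest and Co and V lowest. Cadmium is the exception:
  its back-implied mean would rank below vanadium, contradicting the
  survey's own ordering claim, so it is set to 0.03 mg/kg. Aluminium,
  arsenic, chromium and iron exceed the bundled example limits in every
  region; the others do not.
* **Censoring** is structural: Hg and Pb are emitted censored at their
  LODs in every record, independent of any draw.
* **Bread types** are assigned independently of concentrations, so
  type-wise comparisons are null by construction.

What the generator does *not* emulate: spatial correlation between
neighbouring bakeries, seasonal drift over the sampling window,
inter-element correlation within a bakery (shared flour suppliers), and
partial censoring (values straddling the LOD). Tests passing on synthetic
data therefore demonstrate the correctness of the computational pipeline
under the survey's stated design, not robustness to those real-data
features.

## Numerical and degenerate-input conventions

Risk values are carried at full double precision; rounding to reported
precision happens only in print methods and reports. Compliance uses a
strict inequality at the limit boundary (equality does not exceed).
Empty inputs error rather than return 0 (an HI or TCR of an empty set is
undefined); elements lacking an RfD are skipped from HI with a warning
rather than silently contributing zero. Degenerate Monte Carlo inputs
(all point masses) reproduce the deterministic point estimate exactly at
any iteration count, which the test suite asserts bit-for-bit. CSV
round-trips write numerics at 17 significant digits so read-back is
lossless.

## Problem sizes used in the test suite

Simulation-based checks run at sizes chosen to keep Monte Carlo error
well inside their tolerances: 1,000 replicates for type-I error of the
gated comparison (binomial standard error 0.007 against a ±0.02 band),
200 replicate surveys for the significance-split power check, 10,000
draws for parameter-recovery and 50/50 symmetry checks, and a single
$10^6$-draw Spearman oracle for the asymmetric linear sensitivity toy.

## Limitations

Ingestion is the only exposure route (no dermal or inhalation terms), the
cancer model is the linear slope-factor form without age-dependent
adjustment factors, and no attempt is made to reconcile the survey's
internally inconsistent parameter set — the package reproduces the
published computation and flags, it does not re-derive the survey's raw
tables from concentrations.
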