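# breadrisk

Human health risk assessment for arsenic and other potentially toxic
elements ingested through bread, for food-safety scientists and exposure
modellers working with bakery survey data (concentrations measured in
flour, dough and bread across city regions).

## The model

For each element with bread concentration *C* (mg/kg dry weight), a
cohort's chronic daily intake is

    CDI = C · IR · EF · ED / (BW · AT)        [mg/kg/day]

(ingestion rate IR, exposure frequency EF, exposure duration ED, body
weight BW, averaging time AT). Non-carcinogenic hazard is the quotient
HQ = CDI/RfD against the oral reference dose, summed over elements to the
hazard index HI = Σ HQ (concern above 1). Carcinogenic risk is
CR = CDI · OSF with the oral slope factor, summed over carcinogens (As,
Cd) to the total TCR and classified against the 10⁻⁶/10⁻⁴ bounds.

Around that core the package provides:

- **Data model & I/O** — long-format concentration CSVs with explicit
  left-censoring (flag + LOD, never sentinel numbers), regulatory limit
  tables, full-precision risk report CSVs.
- **Deterministic risk** — `risk_assessment()` returns a classed object
  with `print`, `summary`, `plot`, `simulate` methods; `classify_risk()`
  applies threshold policies.
- **Compliance screening** — region means against permissible limits,
  strict boundary.
- **Source apportionment** — flour / dough-addition / oven-contact shares
  of the bread burden by increment decomposition.
- **Group statistics** — KS normality gate, then one-way ANOVA or
  Kruskal–Wallis across regions or bread types.
- **Monte Carlo uncertainty** — seeded simulation (10,000 iterations by
  default) over fitted lognormal concentration distributions, percentile
  and CDF summaries.
- **Sensitivity** — contribution to variance as normalised squared
  Spearman rank correlation.
- **Synthetic survey generator** — `generate_study()` reproduces the
  survey design (5 regions × 18 bakeries × 3 stages × 12 elements,
  fully censored Hg and Pb) so the whole pipeline runs without the
  original measurements.

## Worked example

```r
library(breadrisk)

rec <- generate_study(default_study_config(seed = 7))  # 3,240 records
fit <- risk_assessment(rec)
summary(fit)
#> Cross-region risk summary
#>  cohort mean_hi min_hi max_hi mean_tcr min_tcr max_tcr
#>   adult   7.810  6.537  8.675  0.02304 0.01784 0.02616
#>   child   5.885  4.926  6.537  0.01736 0.01344 0.01971

mc <- simulate(fit, nsim = 10000, seed = 7)
percentile(mc$adult$hi, 0.95)
#> [1] 9.975383
percentile(mc$adult$tcr, 0.95)
#> [1] 0.03257721

head(subset(sensitivity_report(mc), cohort == "adult" & endpoint == "HI"), 3)
#>   cohort endpoint variable contribution_pct sign
#> 1  adult       HI     C_As        95.476171    1
#> 2  adult       HI     C_Cr         2.076934    1
#> 3  adult       HI     C_Co         1.557808    1
```

Every regional hazard index exceeds 1 (arsenic's quotient alone is above
5 for adults) and every total cancer risk exceeds the 10⁻⁴ acceptability
bound — the 95th-percentile values even more so — with the arsenic
concentration driving essentially all of the output variance. Those are
the qualitative conclusions the synthetic defaults are designed to
exhibit. The child:adult ratio of 0.754 follows from the built-in
exposure parameters; see the methods vignette
(`vignettes/bread-risk-methods.Rmd`) for why the published survey tables
show ratios above 1 instead, and for every modelling choice and
limitation.

One orchestration call writes all report CSVs (risk tables, flags,
compliance, apportionment, statistics, Monte Carlo summary, sensitivity)
plus a parameter log:

```r
run_risk_report(rec, "out/", seed = 7)
```

A thin CLI wrapper with `generate` / `risk` / `mc` / `sensitivity` /
`report` subcommands ships at `inst/cli/breadrisk`.

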