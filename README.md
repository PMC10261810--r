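# pcbrisk

Probabilistic dietary-exposure and cancer-risk assessment for the six
indicator **non-dioxin-like polychlorinated biphenyls** (NDL-PCBs:
PCB 28, 52, 101, 138, 153, 180) in fermented dairy products — yogurt,
doogh (the diluted yogurt drink) and kashk (the concentrated form).

The package is aimed at food-safety and exposure-assessment analysts who
need a reproducible pipeline from per-sample congener concentrations
(ng/g fat) to health-risk classifications, in a setting where the
underlying market survey published only summary statistics. It provides:

* a **synthetic-data generator** that draws per-sample concentrations
  from truncated lognormals moment-calibrated to published per-congener
  min/max/mean/SD tables (by product and by brand), with labelled RNG
  streams for column-stable reproducibility;
* **analytical QC arithmetic**: calibration linearity (OLS), blank-based
  LOD/LOQ (`mean + 3·sd` / `mean + 10·sd`), spike recovery, RSD, and
  left-censoring substitution (LOD/2 by default);
* **grouped summaries and tests**: min/max/mean/SD per congener and for
  the Σ6 total, with normality-gated group comparisons
  (Kolmogorov–Smirnov → ANOVA/t-test or Kruskal–Wallis/Mann–Whitney);
* **Monte Carlo risk simulation** of the estimated daily intake

  `EDI = C · fat_fraction · IR · EF · ED / (BW · AT)`  [ng/(kg·day)]

  and the incremental lifetime cancer risk

  `ILCR = EDI · 10⁻⁶ · SF`,  `SF = 2 (mg/(kg·day))⁻¹`

  with 5/50/75/95 percentile tables, congener contribution shares, and
  strict checks against the EU limit (40 ng/g fat for Σ6), the WHO TDI
  (10 ng/kg bw/day) and the 10⁻⁴ ILCR threshold. Because the survey's
  exposure-parameter values are unpublished, `calibrate_exposure()`
  back-solves the per-product exposure multiplier from the published
  median intakes so that reproduction runs reach the published scale;
* **congener-profile clustering**: scaled profile matrices, Euclidean
  average-linkage dendrograms (verified against a brute-force
  agglomeration oracle), Newick export and pheatmap heat maps.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods on fitted objects, `autoplot()` for every result
type, and a thin command-line driver in `inst/cli/pcbrisk.R`
(`simulate`, `summarize`, `compare`, `risk`, `cluster`, `report`,
`reproduce-paper`).

## Worked example

The packaged defaults run the whole assessment on the reference survey
configuration (Σ6 moment specs for all three products, 40 samples each,
calibrated exposure multipliers, 10,000 Monte Carlo iterations):

```r
library(pcbrisk)
report <- run_pipeline(pipeline_config(seed = 1), quiet = TRUE)
report
#> <pcb_run_report> seed 1 | config b4d64f7bdb89b1cf0b343c1bd21e78d2
#>
#> EU limit check (total mean, ng/g fat):
#>   group  total_mean limit compliant margin
#> 1 doogh        12.4    40 TRUE        27.6
#> 2 kashk        18.7    40 TRUE        21.3
#> 3 yogurt       14.5    40 TRUE        25.5
#>
#> TDI check (mean total EDI, ng/(kg day)):
#>   product    edi   tdi below_tdi
#> 1 yogurt  14.3      10 FALSE
#> 2 doogh    1.01     10 TRUE
#> 3 kashk    0.509    10 TRUE
#>
#> ILCR classification:
#>    yogurt   2.87e-05 -> acceptable
#>    doogh    2.02e-06 -> acceptable
#>    kashk    1.02e-06 -> acceptable
#>
#> First congener cluster: PCB101 + PCB153
```

Reading the numbers: every product's mean Σ6 concentration sits well
below the EU maximum level of 40 ng/g fat (margins of 21–28 ng/g fat),
and the mean lifetime cancer risk is 1–2 orders of magnitude below the
10⁻⁴ acceptability threshold. The yogurt intake median exceeds the WHO
TDI under the calibrated configuration — a consequence of the published
median intake the calibration reproduces, and the pipeline reports it
as such rather than smoothing it over.

Drilling into one product:

```r
tidy(report$mcs$yogurt) |>
  tidyr::pivot_wider(names_from = percentile, values_from = edi, names_prefix = "p")
#>   congener      p5     p50    p75    p95
#> 1 PCB28     0.0430  0.0853  0.114  0.139
#> 2 PCB52     0.0494  0.136   0.183  0.223
#> 3 PCB101    0.0609  0.0859  0.104  0.122
#> 4 PCB138    0.408   0.484   0.534  0.582
#> 5 PCB153    3.23    4.05    4.72   5.49
#> 6 PCB180    8.51    9.27    9.85  10.4
#> 7 total    12.9    14.3    15.0   16.0

report$contributions$yogurt
#>   congener fraction
#> 1 PCB180    0.653
#> 2 PCB153    0.291
#> 3 PCB138    0.0340
#> ...
```

PCB 180 dominates the intake (about 65% of the mean total EDI) and the
95th-percentile congener ranking is PCB180 > PCB153 > PCB138 > PCB52 >
PCB28 > PCB101.

The methods vignette (`vignettes/pcb-dietary-risk.Rmd`) documents the
concentration model, the truncation-aware moment calibration, the
exposure calibration, and every numerical choice.

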