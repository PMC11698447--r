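# occultsim

Individual-level microsimulation of non-small-cell lung cancer (NSCLC)
natural history, detection and screening, built to answer a question no
registry can: **how much undetectable ("occult") metastatic disease is
already present when a lung cancer is diagnosed, and what would earlier
detection by CT screening change?**

Every simulated person carries a complete latent disease history —
smoking-driven tumor onset, exponential growth, metastatic seeding — so
the observed stage at diagnosis can be cross-tabulated against the true
disease extent, screening policies can be replayed against the same
disease counterfactually, and mortality reduction can be estimated by
paired comparison.

## The model in brief

* **Onset**: a smoking-based two-stage clonal expansion (TSCE)
  carcinogenesis model — initiation ν, clonal expansion (α, β), malignant
  conversion μ, each modified by smoking dose–response — yields the age
  `T0` of the first malignant cell. The survival function uses the exact
  piecewise closed form over each person's exposure profile.
* **Growth**: from one cell (10⁻⁹ cm³) the primary grows exponentially
  with rate λ ~ Gamma(K, θ), fixed per tumor. TVDT = ln 2/λ.
* **Metastasis**: nodal and distant seeding are indexed by primary
  volume S with c.d.f. `F(S) = 1 − exp(−μ/(ξ+1) · S^(ξ+1))`
  (seeding hazard μ·S^ξ per unit volume); each seeded compartment grows
  exponentially from one cell with its own (faster) rate.
* **Occult metastasis**: a deposit larger than one cell but smaller than
  a 0.618 mm sphere (1.24×10⁻⁴ cm³, the CT resolution limit) is present
  but invisible — to staging and to screening alike.
* **Detection**: symptomatic detection is a hazard linear in total tumor
  volume with stage-dependent offsets, `η(Sp+Sn+Sm) + W_k`; screening
  detects deterministically at the first scan with any compartment above
  the CT threshold, under configurable eligibility policies (age window,
  pack-years, quit recency, frequency).
* **Outcome**: AJCC-style stage from (size, detectable N, detectable M);
  survival sampled by inverting stage/size-specific mixture-cure curves;
  competing Gompertz–Makeham other-cause mortality.

Progression/detection parameters (K, θ, ξ, μn, μm, η, W0–W2) default to
values calibrated against published occult-metastasis and stage-by-size
cross-tabulations; see the methods vignette
(`vignettes/occultsim-methods.Rmd`) for the calibration account and every
default's rationale.

## Worked example

```r
library(occultsim)
library(dplyr)

cfg <- run_config(
  scenario = "baseline_symptomatic",
  cohort   = cohort_config(birth_years = 1900:1960, births_per_year = 2000),
  seed     = 1
)
res <- run_scenario(cfg)
glance(res)
#> # A tibble: 1 x 9
#>   scenario             n_persons n_cases n_detected frac_occult n_lc_deaths
#> 1 baseline_symptomatic    122000    3727       1078       0.334         252

# Observed vs true disease extent among symptomatic detections
xt <- occult_crosstab(res$records)
xt %>% filter(size_bin == "Total", observed == "N0M0")
#> # A tibble: 3 x 5
#>   observed true      n size_bin   pct
#> 1 N0M0     M1      235 Total    24.7
#> 2 N0M0     N0M0    627 Total    65.9
#> 3 N0M0     N1M0     89 Total     9.36
```

Read: among cases *observed* as N0M0 (no visible nodal or distant
disease), about 66% truly had no metastases, while ~9% had occult nodal
and ~25% occult distant deposits already growing at diagnosis. The
numbers above are what this configuration printed at seed 1; at this
cohort size the Monte-Carlo error on the percentages is about one point.

Screening and mortality reduction on counterfactually paired arms
(screening layered on usual care, same natural histories in both arms):

```r
arms <- run_paired(cfg, scenarios = c("baseline_symptomatic", "combined"))
mortality_reduction(arms$baseline_symptomatic, arms$combined,
                    window = c(1979, 1999))
#> Mortality reduction 21.54% (10.71%-32.86%), 65 vs 51 LC deaths in 1979-1999
```

`autoplot()` methods exist for the cross-tab objects, `plot_timeline()`
for the progression timeline, and `tidy()`/`glance()` for records and
summaries.

## Command line

A thin CLI over the same functions lives at
`inst/scripts/occultsim-cli.R`:

```sh
Rscript inst/scripts/occultsim-cli.R simulate --config cfg.yaml --out-dir out/
Rscript inst/scripts/occultsim-cli.R compare  --seed 7 --out-dir out/
```

`simulate` writes the standard CSV tables (records, occult cross-tab,
unperturbed cross-tab, timeline); `compare` runs paired baseline/screening
arms and adds the screening summary and mortality-reduction tables.
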