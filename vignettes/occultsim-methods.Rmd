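---
title: "Modelling lung-cancer natural history, occult metastasis and CT screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lung-cancer natural history, occult metastasis and CT screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`occultsim` is an individual-level microsimulation of non-small-cell lung
cancer (NSCLC). Its purpose is to quantify something that cannot be observed
directly in patients: how often a clinically or screen-detected lung cancer
already carries *occult* metastases — nodal or distant deposits that are
real, growing, and invisible to imaging — and what earlier detection by
low-dose CT screening could change about that. Because every simulated
person carries a complete latent disease history, the simulation can
cross-tabulate the *observed* stage at diagnosis against the *true* disease
extent, something no registry can do.

This vignette documents the model, its assumptions, the tunable parameters
and their defaults, the numerical choices, and the limits of what the
simulation can show.

## The model, end to end

Each simulated person passes through five modules:

1. **Smoking history.** A parametric stand-in for a smoking-history
   generator draws, per sex and birth band, ever-smoking status, age at
   initiation (truncated normal), possible cessation age, and an intensity
   class in cigarettes/day. Pack-years accrue at `intensity/20` per year
   while smoking.
2. **Tumor onset.** The two-stage clonal expansion (TSCE) model of
   carcinogenesis turns the exposure profile into an age `T0` at the first
   malignant cell. Normal cells are initiated at rate $\nu$, initiated
   cells divide ($\alpha$) and die ($\beta$) as a birth–death process, and
   convert to malignancy at rate $\mu$. Smoking multiplies $\nu$, the net
   promotion rate $\alpha-\beta$, and $\mu$ through power-law dose–response
   terms $1 + c\,d^{e}$ that equal one at zero dose.
3. **Growth and metastatic seeding.** From one cell of volume
   $10^{-9}\,\mathrm{cm}^3$ the primary grows exponentially,
   $S(t) = V_\mathrm{cell} e^{\lambda (t - T_0)}$, with $\lambda$ drawn
   once per tumor from a Gamma$(K,\theta)$ distribution. Seeding of nodal
   and distant metastases is indexed by primary *volume*: with detachment
   exponent $\xi$ and transfer/deposition rates $\mu_n, \mu_m$, the
   probability that seeding has occurred by volume $S$ is
   $$F_x(S) = 1 - \exp\!\Big(-\frac{\mu_x}{\xi+1} S^{\xi+1}\Big),
     \qquad x \in \{n, m\},$$
   i.e. a seeding hazard $\mu_x S^{\xi}$ per unit of volume growth. The two
   seeds are drawn independently; each seeded compartment then grows
   exponentially from one cell with its own rate.
4. **Detection.** Symptomatic (clinical) detection is a hazard linear in
   tumor volume with stage-dependent offsets:
   $$h(t) = \eta\,\big(S_p + S_n + S_m\big)(t) + W_k,$$
   where $k$ indexes the true extent (N0M0 / N1M0 / M1) and
   $W_1, W_2 \gg W_0$: metastatic disease presents spontaneously far more
   often. All three compartments enter the volume term because a nodal or
   distant deposit can itself bring the disease to clinical attention.
   Screening, by contrast, is deterministic: a CT scan finds the cancer iff
   any compartment has reached the detectability threshold.
5. **Staging, survival, death.** At detection the observed stage is a
   lookup on (detected primary size, *detectable* nodal disease,
   *detectable* distant disease); occult deposits do not upstage. Years
   from diagnosis to lung-cancer death are sampled by inverting a
   stage/size-specific mixture-cure exponential survival curve — these are
   *cause-specific* curves (death from lung cancer), because other-cause
   mortality competes separately through a Gompertz–Makeham life table
   whose hazard is multiplied by a smoking-status rate ratio (current and
   former smokers die of other causes substantially earlier, which both
   matches the epidemiology and properly shortens the time a smoker's
   latent tumor has to grow). The earlier of the two deaths wins; ties go
   to lung cancer by convention.

### Occult metastasis and the CT threshold

A sphere of 0.618 mm diameter has volume
$\pi/6 \cdot 0.0618^3 = 1.24\times 10^{-4}\,\mathrm{cm}^3$; thin-slice CT
cannot reliably resolve anything smaller (about three 0.3 mm
reconstruction slices). The package therefore classifies any compartment
volume in $(10^{-9}, 1.24\times 10^{-4})\,\mathrm{cm}^3$ — more than one
cell, less than the CT threshold — as **occult**, and at or above the
threshold as **detectable**. The same threshold is used for primary,
nodal and distant disease, both for staging at diagnosis and for screen
detection.

## Parameters, defaults, and where they come from

Two groups of parameters behave very differently and it is worth being
explicit about the difference.

**Structural/behavioral defaults** (smoking prevalence and intensity
distributions, TSCE rates and dose–response, the Gompertz–Makeham life
table, stage-group survival levels) are round, literature-flavored values
chosen once to make the simulated population realistic: never-smoker
lifetime lung-cancer risk near 1%, lifelong heavy smokers near 15–18%,
onset concentrated between ages 55 and 85, life expectancy in the
mid-to-high 70s, and stage-specific five-year survival stepping down from
about 80% (sub-centimetre stage IA) to a few percent (stage IV). They are
configuration, not estimates, and each constructor documents its fields.

**Progression/detection parameters** — the Gamma growth-rate shape and
scale $(K, \theta)$, the seeding parameters $(\xi, \mu_n, \mu_m)$, the
detection efficiency $\eta$ and offsets $(W_0, W_1, W_2)$, and the
metastasis growth-rate factor — are the quantities the package's headline
tables are sensitive to. Their defaults were **calibrated** against the
published cross-tabulations this package is designed to reproduce:

* The seeding c.d.f. is identified *exactly* by the unperturbed
  population's true-stage-by-size margins: given a tumor currently at
  volume $S$, the probability it is still N0M0 is
  $\bar F_n(S)\bar F_m(S)$ regardless of the growth rate, so the
  percentage of clean tumors in each size bin is a direct, selection-free
  measurement of the seeding curve. A two-parameter fit of
  $(\xi, \mu_n + \mu_m)$ to those bin margins, followed by a one-parameter
  split of the nodal/distant shares, reproduces the unperturbed stage-by-
  size structure to within a few percentage points in every bin.
* The remaining parameters were fitted by direct search (Nelder–Mead on
  log scale, common random numbers) on simulated cohorts against the
  occult-metastasis distribution of symptomatically detected cases, the
  detected-tumor volume doubling time, and the width of the "window of
  opportunity" (below).

### What the calibrated defaults do and do not reproduce

With the default configuration the simulation reproduces, within
Monte-Carlo tolerance: the occult-metastasis composition of observed-N0M0
symptomatic detections (about 64/9/26 percent truly clean / occult nodal
/ occult distant), the detected-tumor median volume doubling time
(~77 days against a ~79-day target), the prevalent population's clean
fraction by size bin (including the sharp drop between the 1–2 cm and
2–3 cm bins, ~79% vs ~35%), and the dominance of sub-0.5 cm tumors in
the undiagnosed pool (~74%).

Three published features are *not* reproducible in this model class, and
the package reports its own values rather than forcing them:

* The overall clean share of the undiagnosed pool plateaus near 76–78%
  rather than 86%, because tumors in the unperturbed scenario are never
  removed: fast growers that would be diagnosed in reality accumulate in
  the >3 cm bin, which carries almost no clean tumors.
* Among observed-N1M0 detections the occult-distant share reaches only
  ~30–45% rather than ~57%; with a single shared detachment exponent the
  nodal/distant asymmetry cannot be made much stronger without breaking
  the prevalence margins that pin the seeding curve.
* The median "window of opportunity" lands near 1.2 years rather than
  0.75. This is structural: the prevalence margins fix the seeding curve
  (median first-seed volume ≈ 5 cm³), seed volume is independent of the
  growth rate by construction, and seed *age* depends on seed volume only
  logarithmically — so no detection-selection mechanism can pull the
  detected cases' typical seeding volume down to the ~0.7 cm³ a 0.75-year
  window at a 79-day doubling time would require. The three targets are
  jointly infeasible under volume-indexed seeding; the package prioritises
  the cross-tabulations and the doubling time.

Two structural choices deserve their own explanation:

* **Metastatic compartments grow faster than primaries and with their own
  rate.** If a metastasis reused the primary's growth rate, it could only
  reach the CT threshold after the primary had grown by the same
  $1.24\times 10^{5}$-fold factor — a primary of $\sim 10^{5}$ cm$^3$ —
  so *no* diagnosis would ever show detectable nodal or distant disease,
  contradicting the observed predominance of stage III/IV presentations.
  Metastatic deposits in fact tend to double faster than the primaries
  that seeded them. Each compartment therefore draws its own rate from the
  same Gamma distribution scaled by `met_rate_factor` (default chosen in
  calibration, with median metastasis doubling times kept at a clinically
  plausible 25+ days). The shared-rate variant remains available as
  `sim_config(met_growth = "shared")` with `met_rate_factor = 1`.
* **All three compartments drive symptomatic detection.** Clinical
  presentation of metastatic disease is usually precipitated by the
  metastases, not the primary. Restricting the volume term to the primary
  (`detection_params(include_mets = FALSE)`) makes detectable metastases
  at diagnosis essentially impossible, for the same threshold-ratio
  reason as above.

## The window of opportunity

The progression timeline summarises, per tumor, the ages at which the
primary passes 2 mm and 5 mm diameter (analytic inversion of the growth
law), the age of first metastatic seeding (the *cure threshold* — beyond
it local therapy can no longer be curative), and detection. The **window
of opportunity** is the median time from 5 mm — a size a CT program can
reasonably find — to first seeding, computed on detected cases: the time
a screening program has to catch a visible tumor while it is still
curable. The tumor volume doubling time is $\ln 2/\lambda$, reported in
days.

Because fast-growing tumors reach detectable and symptomatic sizes within
a lifetime far more often than slow ones, the *detected* population is
strongly enriched in fast growers: its median doubling time (~80 days) is
several times shorter than the population median. This selection effect is
a genuine prediction of the model, and it is why the unperturbed
population is dominated by small, slow, still-localised tumors while
symptomatic diagnoses are dominated by large and metastasised ones.

## Screening scenarios and mortality reduction

The screening machinery applies a policy (age window, minimum pack-years,
maximum years since quitting, screens per year in {0.5, 1, 2, 4}).
Scans happen at exact ages `start + j/frequency` while the person is
eligible (no adherence model); detection occurs at the first scan with any
compartment at or above the CT threshold; schedules are optionally clipped
to the analysis calendar window. Total scans delivered to the whole
cohort, including people who never develop cancer, are counted for the
cost summary (unit cost $3074 per scan by default).

Three scenarios use it. `"unperturbed"` switches all detection off and is
the substrate for prevalence cross-sections. `"screening"` runs CT as the
*only* detection route — useful for characterising what scans alone would
find, but pathological for mortality comparison: a person whose disease
would have presented symptomatically years before the program's first
scan has their tumor run free until screening finally catches it, later
and at a worse stage than in the baseline arm, manufacturing harm that no
real program causes. `"combined"` therefore layers screening on usual
care — each case is detected by whichever route comes first — and is what
the mortality analysis uses, mirroring what a screening trial measures.

Mortality reduction over a calendar window (default 1979–1999) is
$(D_\mathrm{base} - D_\mathrm{screen})/D_\mathrm{base}$ on lung-cancer
deaths whose calendar year falls in the window, computed on
counterfactually paired arms: `run_paired()` simulates the natural history
once and applies each detection mode to it, so differences between arms
are purely due to detection. The confidence interval is a person-level
Poisson bootstrap (default 1000 replicates).

Two lead-time subtleties are handled explicitly. *Observed survival*
(diagnosis to death, as reported by `screening_summary()`) includes lead
time, exactly as screen-detected survival does in registry data. But for
*mortality accounting*, restarting the survival clock at an earlier
detection age without a stage change would move the death earlier — the
classic artifact by which naive models make screening look harmful for
stage-unchanged cases. `run_paired()` therefore carries the baseline death
date over to any screen-detected case whose stage group and size bin (and
hence survival curve) are unchanged: no survival benefit without a stage
shift, the standard assumption in screening microsimulation. Cases whose
stage *is* shifted draw from their new curve.

## Numerical choices

* **TSCE survival** uses the exact closed form of the two-stage model
  with piecewise-constant parameters: the backward Riccati equation for
  the extinction probability is solved segment by segment via its
  logistic-in-$w$ representation, and the cumulative hazard accrues
  $\nu[(1-r_1)\Delta + \log((1-w_1)/(1-w_0))/\alpha]$ per segment. The
  fixed point $y = r_2$ (which arises when $\mu = 0$) is special-cased at
  tolerance $10^{-14}$. The implementation agrees with an independent
  `deSolve` integration of the characteristic ODEs to better than
  $10^{-8}$ relative error.
* **Onset sampling** is inverse-transform on the cumulative hazard,
  evaluated exactly on a 1-year age grid and interpolated linearly in the
  hazard between grid points (error second order in the grid step, far
  below Monte-Carlo noise at every cohort size used).
* **Symptomatic detection times** are sampled exactly: within each
  true-stage segment every compartment volume is a pure exponential, so
  the cumulative hazard is closed-form and the inversion uses a
  safeguarded Newton iteration (60 steps, bracketed by bisection).
  No quadrature is involved in the sampler; numeric quadrature appears
  only as the independent oracle in the test suite.
* **Degenerate inputs**: a seeding threshold drawn below one cell volume
  is clamped so seeding never precedes onset; tumors frozen at other-cause
  death keep their death-day size in prevalence snapshots; exact ties in
  competing mortality go to lung cancer.

## What the synthetic data does and does not emulate

The cohort generator reproduces the *structure* of US birth-cohort
smoking histories — prevalence by sex and birth band, start/quit ages,
intensity classes — not any particular survey. It does not model relapse,
intensity changes over a lifetime, or secular detail within bands. The
life table is parametric, not a vital-statistics table. Stage-specific
survival curves are mixture-cure exponentials matched to published
five-year survival levels, not fits to registry micro-data; consequently
the absolute mortality-reduction percentages are indicative, and the
package's tests assert their structural properties (bounds, scale
invariance, stability across screening intensity) along with the values
themselves. Passing tests show that the *model mechanics* — seeding,
selection, staging, pairing — behave correctly, and that the calibrated
configuration reproduces the published cross-tabulations; they do not
validate the model against patient-level data.

## Problem sizes

The test suite simulates cohorts of a few hundred thousand persons at
most (tens of thousands of tumors); the acceptance script uses about 2.5
million persons, giving on the order of $2\times10^4$ detected cancers.
At these sizes the Monte-Carlo error on the headline percentages ranges
from a fraction of a point (whole-cohort tabulations) to a few points
(the sparsest size-bin cells), and the test tolerances are set at three
binomial standard errors of the realized counts, floored at three
percentage points. These sizes are the package's chosen defaults for a
desk-scale reproduction; all counts scale linearly with
`cohort_config(births_per_year, scale)`.

## Known limitations

* The extent model is three-state (N0M0/N1M0/M1): N2/N3 nodal disease and
  T4 primaries are not representable, so stage groups IIIA/IIIB are only
  reachable through user-supplied staging rules.
* Observed survival is conditioned on stage and size only; within-bin
  size resolution is lost, so small survival differences between
  screening frequencies are not resolvable (an artifact shared by any
  grouped-survival design).
* No false positives, no Lung-RADS-style nodule management, no
  overdiagnosis accounting beyond what the volume threshold implies, no
  radiation risk modelling (scan counts and cost are reported instead).
* A metastatic compartment, once seeded, grows without bound; no
  dormancy, no treatment effects on progression.
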