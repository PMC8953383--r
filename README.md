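# spheroidGNP

Image-based quantification of gold-nanoparticle (GNP) redistribution from
extracellular matrix (ECM) to 3D tumor nodules, and of its consequences for
radiotherapy scheduling.

Ultrasmall GNPs delivered to 3D cultures of lung-carcinoma cells grown on a
Matrigel bed do not reach the cancer cells immediately: they first lodge in
the ECM and redistribute into the multicellular nodules over many days. The
day on which X-rays are delivered therefore changes how much the particles
sensitize the tumor cells. This package provides the complete analysis
pipeline for such studies — spheroid segmentation and morphometry, growth
kinetics, compartmental fluorescence kinetics, clonogenic
sensitivity-enhancement analysis — together with a fully seeded synthetic
microscopy/assay generator that supplies ground truth for every stage. It is
aimed at quantitative-imaging and radiation-biology groups running (or
planning) longitudinal 3D-culture nanoparticle studies.

## Models and statistics

**Growth.** Nodule size follows the Gompertz law

    N(t) = N0 · exp( A (1 − e^{−αt}) / α ),

exponential at early times (`N/N0 ≈ e^{At} = 2^{t/τ}`, doubling time
`τ = ln 2 / A`) and saturating at `N0·e^{A/α}`. `fit_gompertz()` estimates
(N0, A, α) by Levenberg–Marquardt least squares on log residuals;
`doubling_time_hours()` converts A (day⁻¹) to hours.

**Size distributions.** 2D-projection areas are modelled as lognormal;
`fit_size_mixture()` fits 1- and 2-component Gaussian mixtures in log-area
space and reports both BICs, capturing the emergence of a bimodal
population (persistent single cells / small nodules alongside an
aggressively growing large-nodule mode) from a unimodal day-0 culture.

**Morphometry.** `segment_nodules()` (Otsu threshold, opening, hole fill,
8-connected labelling, physical-unit size filter) yields the foreground
(nodule) mask and its negative (ECM) mask; `fit_ellipse()` derives
semi-axes a ≥ b from second central moments and `ellipsoid_volume()`
applies `V = 4/3 π a b²`.

**Uptake kinetics.** After control-based background subtraction,
`build_series()` tracks mean nodule and ECM intensities per day;
`fit_two_phase()` fits the early/late uptake slopes of the nodule/ECM
ratio with an exhaustive break-day search; `detect_peak_day()` and
`crossover_day()` locate the accumulation plateau and the day nodule
signal overtakes ECM signal.

**Radiosensitization.** `survival_factor()` summarises clonogenic colony
counts; `compute_ser()` forms the sensitivity enhancement ratio
`SER = SF(RT) / SF(RT + GNP)` with delta-method standard errors;
`schedule_comparison()` contrasts accumulation schedules.

**Synthetic studies.** `simulate_study()` renders darkfield + fluorescence
time-lapse frames of growing nodule populations (single-rate
two-compartment ECM→nodule transfer, Poisson-like camera noise), plus
no-treatment controls, monolayer contrast series, lysate-absorbance tables
and binomial colony counts — all reproducible from one master seed, with
truth tables for every frame.

## Worked example

```r
library(spheroidGNP)

## growth: fit a noisy Gompertz volume series and read off the doubling time
t   <- 0:9
vol <- gompertz_size(t, N0 = 3764, A = 0.8, alpha = 0.35)
set.seed(1)
fit <- fit_gompertz(t, vol * exp(rnorm(10, 0, 0.05)))
fit
#> Gompertz growth fit (log-residual least squares)
#>   N0 = 3650   A = 0.8354 /day   alpha = 0.3605 /day
#>   doubling time tau = 19.91 h   rss = 0.01183   converged

## a complete synthetic study, analysed end-to-end
cfg    <- study_config(frame_dim = c(224L, 224L), n_cells = 8L,
                       imaging_days = 7:16, seed = 1)
study  <- simulate_study(cfg)
report <- analyze_study(study)

series <- report$kinetics$series
round(series[series$day %in% c(7, 10, 13, 16),
             c("day", "fg_mean", "bg_mean", "ratio")], 2)
#>    day fg_mean bg_mean ratio
#> 1    7    3.45  118.95  0.03
#> 4   10   78.58   38.31  2.05
#> 7   13   98.29   23.31  4.22
#> 10  16  100.76   17.82  5.65
report$kinetics$peak$peak_day        # 13
round(report$kinetics$crossover$day) # 9 (8.7)

report$ser$comparison
#> SER by schedule:
#>  schedule     sf_rt sf_rt_gnp      ser         se
#>      day1 0.4263333 0.3006667 1.417960 0.02815066
#>      day4 0.6983333 0.2370000 2.946554 0.08872854
#> Pairwise SER ratios:
#>  schedule_hi schedule_lo    ratio doubled              note
#>         day4        day1 2.078023    TRUE more than doubled
```

Reading the output: GNPs sit in the ECM on the delivery day (ratio 0.03),
overtake it around day 8.7, and the nodule signal plateaus at day 13 — six
days after delivery. Colony counts drawn at the four treatment-arm survival
levels recover a sensitivity enhancement ratio roughly twice as large when
irradiation follows a four-day accumulation period instead of one day.

A command-line wrapper over the same functions lives at
`inst/cli/spheroidgnp-cli.R` (`simulate` / `analyze` subcommands, YAML
configuration).

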