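# myorelax

Quantifying myosin relaxed states from Mant-ATP chase decays, and a
single-fiber proteomics workflow, in one tidyverse-style R package.

## The problem

Resting skeletal-muscle myosin splits between two relaxed states: the
**disordered-relaxed state (DRX)** — heads mobile, basal ATPase — and the
**super-relaxed state (SRX)** — heads folded onto the thick filament,
hydrolysing ATP roughly ten-fold slower. Shifts of this balance toward DRX
raise a fiber's resting energy consumption and are implicated in myopathies
(e.g. X-linked myotubular myopathy) and targeted by drugs such as
mavacamten. The Mant-ATP chase assay reads the balance out as a
fluorescence decay; single-fiber proteomics asks what the proteome does in
parallel. This package implements both analysis arms for people working on
muscle energetics: decay fitting and energetic scoring, group statistics at
fiber and subject level, MYH-based fiber typing, and the abundance-matrix
workflow (normalization, filtering, imputation, differential abundance,
treatment-restoration sets, enrichment, PCA), plus seeded simulators so the
whole chain is testable without instrument data.

## The model

A background-subtracted trace, normalized to 1 at the washout frame, is fit
by nonlinear least squares to the two-state decay

$$F(t) = 1 - P_1\,(1 - e^{-t/T_1}) - P_2\,(1 - e^{-t/T_2}), \qquad T_1 < T_2,$$

where \(P_1, T_1\) are the DRX amplitude (%) and lifetime (s) and
\(P_2, T_2\) the SRX pair. Assuming 220 µM myosin per fiber, the
theoretical resting ATP consumption per cell is

$$\mathrm{ATP} = \tfrac{P_1}{100}\cdot 220\cdot\tfrac{60}{T_1} +
                 \tfrac{P_2}{100}\cdot 220\cdot\tfrac{60}{T_2}
  \quad [\mu M\,\mathrm{min}^{-1}],$$

with a `variant = "verbatim"` flag reproducing the alternative convention
that divides both terms by \(T_1\). Fitting uses variable projection
(amplitudes profiled out in closed form, non-negative), multistarted over a
fixed grid of time constants; see the methods vignette
(`vignettes/myorelax-methods.Rmd`) for all numerical choices.

## Worked example

Simulate a small two-group cohort, fit every fiber, score ATP consumption,
and compare groups at the subject level:

```r
library(myorelax)
library(dplyr)

cohort <- gen_cohort(cohort_spec(n_subjects = 3, n_fibers = 5), seed = 42)
fits <- fit_relaxation(cohort$traces) |> atp_consumption()
fits |> select(fiber_id, group, P1, P2, T1, T2, atp_corrected) |> head(4)
#> # A tibble: 4 × 7
#>   fiber_id        group      P1    P2    T1    T2 atp_corrected
#>   <chr>           <chr>   <dbl> <dbl> <dbl> <dbl>         <dbl>
#> 1 control_s01_f01 control  27.2  45.1  32.1  289.          132.
#> 2 control_s01_f02 control  31.5  44.9  29.9  302.          158.
#> 3 control_s01_f03 control  17.6  43.8  23.7  255.          120.
#> 4 control_s01_f04 control  21.9  31.0  15.0  231.          209.
```

Each row is one fiber: `P1` says what fraction of myosin heads sit in the
ATP-hungry DRX state (here ~18–32 %), `T1`/`T2` are the DRX/SRX turnover
lifetimes in seconds, and `atp_corrected` is the theoretical resting
consumption in µM ATP min⁻¹. Averaging fibers within subjects and testing:

```r
subj <- aggregate_by_subject(fits, vars = c("P1", "atp_corrected"))
welch_t_test(subj, "P1", "group")
#> # A tibble: 1 × 8
#>   statistic    df p_value estimate group1  group2     n1    n2
#>       <dbl> <dbl>   <dbl>    <dbl> <chr>   <chr>   <int> <int>
#> 1    -0.660  2.39   0.567    -2.58 control disease     3     3
```

With only 3 subjects per group this toy cohort has no power (p = 0.57); at
the bundled default design (7 subjects × 10 fibers) the same 8-point DRX
separation is detected in well over 90 % of simulated cohorts.

A single fit prints its estimates and diagnostics, and `tidy()`/`glance()`/
`autoplot()` work as usual:

```r
tr <- gen_decay_trace(P1 = 25, T1 = 20, P2 = 45, T2 = 230,
                      noise_sd = 0.01, seed = 1)
fit_decay(tr$time_s, tr$intensity)
#> Double-exponential relaxed decay fit
#>   P1 (DRX) = 23.26 %   T1 = 19.08 s
#>   P2 (SRX) = 43.85 %   T2 = 196.83 s
#>   plateau = 0.3289   rss = 0.00292   converged = TRUE   n = 40
```

The proteomics arm chains the same way — see `run_proteome_pipeline()` for
the one-call version operating on files (bundled examples under
`inst/extdata/`), and `inst/scripts/myorelax.R` for a shell wrapper.

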