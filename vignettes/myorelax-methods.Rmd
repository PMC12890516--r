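---
title: "Methods: relaxed-state kinetics and single-fiber proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relaxed-state kinetics and single-fiber proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myorelax)
```

## The biology in one paragraph

Resting skeletal-muscle myosin partitions between two relaxed biochemical
states: the disordered-relaxed state (DRX), with heads mobile and hydrolysing
ATP at a basal rate, and the super-relaxed state (SRX), with heads folded
back against the thick filament and ATP turnover roughly ten-fold slower.
The balance between the two sets a fiber's resting energy consumption, and
its disruption is implicated in myopathies such as X-linked myotubular
myopathy and in the mechanism of myosin-targeted drugs like mavacamten. The
Mant-ATP chase assay reads this balance out optically: fluorescent Mant-ATP
loaded onto myosin is chased with unlabeled ATP, and the fluorescence decay
separates a fast phase (DRX release) from a slow phase (SRX release).

## The decay model and its fit

After background subtraction and normalization to the final pre-washout
frame (`preprocess_traces()`), a trace is modeled as

$$F(t) = 1 - P_1\left(1 - e^{-t/T_1}\right) - P_2\left(1 - e^{-t/T_2}\right),$$

with amplitudes $P_1, P_2$ in percent and time constants $T_1 < T_2$ in
seconds. The plateau $1-(P_1+P_2)/100$ absorbs fluorescence that never
chases out on the 300 s window. No third component is fitted for rapid
washout of nonspecifically bound nucleotide; amplitudes are reported without
that correction.

`fit_decay()` estimates the four parameters by nonlinear least squares with
**variable projection**: for fixed $(T_1, T_2)$ the model is linear in the
amplitudes, so the optimal non-negative $(P_1, P_2)$ solve a closed-form
2×2 problem and the nonlinear search runs over $(\log T_1, \log T_2)$ only.
The search is multistarted from the fixed grid
$T_1 \in \{10, 30, 60\}$ s × $T_2 \in \{150, 250, 400\}$ s; starts are
ranked by their profiled residual sum of squares and the three most
promising are optimized (`nlminb`, then a Nelder–Mead polish). Because the
amplitudes are profiled out exactly, no amplitude starting values are
needed. The best residual wins, ties break toward the smaller fast time
constant, and components are relabeled after fitting so the fast phase is
always reported first — swapping starting values can never flip the
DRX/SRX assignment.

Numerical choices worth knowing:

* Amplitudes are constrained non-negative and time constants positive (log
  parameterization). The fit is otherwise unconstrained; negative
  amplitudes are physically meaningless for a chase decay and constraining
  them is what makes the nested single-phase case collapse cleanly
  ($P_2 \to 0$ rather than oscillating).
* Any strictly increasing grid with at least 6 points is accepted; the
  standard protocol (one frame / 5 s to 90 s, then one / 10 s to 300 s — 40
  frames, `mant_atp_grid()`) is the default everywhere but not required.
* A fit is flagged `converged = FALSE` only when the optimizer fails
  outright or hits its iteration budget on every start; such fits are
  refused by the ATP scorer rather than silently propagated.

On noiseless traces the fit recovers generating parameters to better than
$10^{-4}$ relative error across the design grid; at the realistic noise
level (sd 0.01 on normalized fluorescence) the mean bias of $P_1$ is well
under one percentage point and of $T_1$ under 5 % (both checked in the test
suite against an exhaustive grid-search fitter).

## Theoretical ATP consumption

Assuming 220 µM myosin within the fiber, the theoretical resting ATP
consumption per cell per minute combines amplitudes and lifetimes:

$$\mathrm{ATP} = \frac{P_1}{100}\cdot 220\cdot\frac{60}{T_1}
             + \frac{P_2}{100}\cdot 220\cdot\frac{60}{T_2}
  \quad (\mu M\ \mathrm{min}^{-1}).$$

`atp_score()` defaults to this `"corrected"` form, in which each
population's amplitude is divided by its own turnover lifetime. The source
protocol prints the second term with $T_1$ in the denominator as well; that
`"verbatim"` variant is selectable and both are tested (e.g. $P_1=20$,
$T_1=30$, $P_2=40$, $T_2=250$ gives 109.12 vs 264.0). We treat the printed
form as a likely typographical slip — dividing the SRX amplitude by the DRX
lifetime has no dimensional reading consistent with "their respective ATP
turnover lifetimes" — but we do not resolve the question; the flag exists so
either convention can be reproduced exactly.

## Group comparisons

Readouts are reported at two levels, mirroring standard practice in fiber
physiology: each fiber as one observation, and each subject's fiber-average
as one observation. `welch_t_test()` (two groups), `anova_tukey()` (one
factor, Tukey HSD post hoc) and `two_way_anova_tukey()` (genotype ×
treatment, type-II sums of squares — identical to type I/III on the balanced
layouts these designs use) cover the comparisons; `aggregate_by_subject()`
produces the subject level. Fiber-level tests pool fibers across subjects
without nesting; that matches the source analyses but ignores
within-subject correlation, so the subject-level analysis is the
conservative one. Mixed-effects models are a deliberate non-goal.
Phosphorylation-challenge designs are expressed as per-fiber folds of the
within-stratum vehicle-group mean (`relative_change()`); a paired
same-fiber normalization would also be defensible but the per-stratum
vehicle mean is what the relative-change figures describe.

## Fiber typing

`classify_fiber_types()` implements the proteomic percentage rule: sum the
four adult myosin heavy-chain isoform abundances, express each as a
percentage, call the sample *pure* when one isoform reaches 80 %
(inclusive) and otherwise *mixed*, named by the top two contributions
highest-first (MYH7 → I, MYH2 → 2A, MYH1 → 2X, MYH4 → 2B). Percentage ties
are broken by the fixed order MYH7 > MYH2 > MYH1 > MYH4 — the rule's source
is silent on ties, and a fixed order keeps the label deterministic.

## The proteomics workflow

* **Normalization** (`normalize_total_abundance()`): every reporter channel
  is rescaled to the same total abundance. The reference total is the
  highest channel total by default; the description of the original
  correction ("based on the highest peptide abundance present in one
  channel") is ambiguous between that and per-channel-max anchoring, so the
  reference is configurable (`max` / `median` / `mean`) rather than
  guessed. The companion filtration step that reduced the published canine
  matrix to 232 proteins is likewise unstated, so it is exposed as the
  `max_missing_frac` configuration rather than hard-coded.
* **Missingness filter** (`filter_by_missingness()`): a protein is dropped
  when *more than* half of its values are missing within any single group
  (strict inequality; a protein at exactly 50 % survives).
* **Mixed imputation** (`mixed_impute()`): per protein per group, missing
  entries are KNN-imputed when the group has at least 60 % valid values;
  everything still missing is drawn from a down-shifted Gaussian
  (mean $= m - 1.8\,s$, sd $= 0.3\,s$, with $m, s$ the observed mean and sd
  of that sample) — the MinProb model of left-censored low-abundance
  missingness. KNN details are not pinned down by the source method, so we
  chose and documented: $k = 3$, Euclidean distance over the group's
  jointly observed samples, donors averaged at the missing coordinate; all
  configurable. MinProb moments default to per-sample (the method's
  standard definition) with a whole-matrix variant by flag. Observed values
  are never modified, and the imputed mask is returned so that invariant is
  testable.
* **Differential abundance** (`differential_abundance()`): per-protein
  unpaired two-tailed t tests (Welch by default; pooled-variance Student by
  flag), Benjamini–Hochberg adjustment across all tested proteins, and the
  joint gate $q \le 0.05$ **and** fold change $\ge 2$. The
  reporter-intensity (TMT) arm of the source analysis names only the t test,
  so a raw-p gate (`p_adjust = "none"`) is available for that mode; the
  DIA arm uses the BH + fold-change gate as printed.
* **Restoration sets** (`restoration_sets()`): with two contrasts against
  the same reference — disease vs control untreated, and under treatment —
  the untreated hits partition into *maintained* (significant in both, same
  direction), *restored* (no longer significant under treatment; the rescue
  readout), and *discordant* (flipped direction); hits only present under
  treatment are *emergent*. The partition property (disjoint, union equals
  the untreated hit set) is enforced by construction and tested on random
  set pairs.
* **Enrichment** (`hypergeometric_enrichment()`): upper-tail hypergeometric
  p per term against the full identified background, terms intersected with
  the background first, tested only when at least 5 hits fall in the term,
  BH across tested terms.
* **PCA** (`pca_scores()`): centered sample-space scores with explained
  variance, for the heterogeneity-reduction readout.

## What the simulators emulate — and what they do not

`gen_decay_trace()` / `gen_cohort()` render the decay model on the standard
grid with i.i.d. Gaussian noise on normalized fluorescence and a
subject-within-group, fiber-within-subject hierarchy. Defaults were chosen
once to resemble a disease-vs-control chase study: control P1/P2/T1/T2 of
20 % / 45 % / 25 s / 230 s, disease 28 % / 37 % / 20 s / 210 s (an
8-percentage-point DRX shift), between-subject sd 3 pp (20 s for T2),
within-subject sd 4 pp (25 s for T2), 7 subjects × 10 fibers per group, and
noise sd 0.01 — a magnitude that visually matches typical chase scatter.
The noise model is deliberately simple: no photobleaching drift, no
heteroscedasticity, no correlated residuals from focus drift, no washout
transient. Passing recovery tests on these traces validates the estimator
under the model's own assumptions, not the imaging pipeline upstream.

`gen_abundance_matrix()` draws per-protein baselines from a log-normal
proteome (log2 mean 25, sd 2), adds signed log2 effects to designated
proteins in case groups, attenuates a chosen fraction of them to zero in
treated groups (the restoration ground truth), and censors entries with
probability `plogis(intercept - slope * value)` — a logistic left-censoring
surrogate consistent with the MinProb assumption. It does not emulate
peptide-level rollup, shared-peptide ambiguity, batch structure, or
correlated protein modules. `gen_annotation()` adds random term memberships
plus one deliberately enriched term. All generators are bit-reproducible
given (spec, seed).

## Problem sizes used in validation

The validation suite exercises: a 36-point noiseless design grid; 200 noisy
traces per recovery study (noise sd 0.01, 40-frame grid); 200 simulated
cohorts of 7 subjects × 10 fibers per group for the power study; 100
null matrices of 1000 proteins × 12 samples for FDR calibration and 20
effect matrices for sensitivity; 10,000+ MinProb draws for moment recovery;
and 100 random set pairs for the partition invariants. These sizes give
Monte-Carlo standard errors comfortably inside the asserted margins while
keeping a full run in the minutes range on one core.

## Known limitations

* Fiber-level inference ignores the within-subject correlation structure;
  use the subject level when in doubt.
* The fitter reports least-squares point estimates without standard errors;
  the decay problem is ill-conditioned when $T_2/T_1 < 5$ or the slow phase
  is barely sampled, and amplitude/lifetime trade-offs inflate variance
  before they bias means.
* KNN imputation quality degrades when a group has few jointly observed
  samples; the MinProb fallback then dominates, which is conservative for
  differential analysis but not unbiased.
* The enrichment test treats terms independently; no term-overlap
  correction is attempted.
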