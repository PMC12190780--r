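---
title: "Methods: FGF21 ELISA validation and steatosis diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FGF21 ELISA validation and steatosis diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgf21val)
```

This vignette explains the statistical machinery in `fgf21val`: the models,
the tunable parameters and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices that were genuinely open.

## Calibration model

Ligand-binding assays are calibrated with a sigmoidal standard curve. We use
the four-parameter logistic (4PL),

$$y = d + \frac{a - d}{1 + (x/c)^b},$$

where $y$ is the optical signal, $x$ the concentration in pg/mL, $a$ the
signal at zero concentration, $d$ the saturation signal, $c$ the inflection
concentration and $b > 0$ the slope factor. Sandwich ELISAs are ascending
($a < d$); the code infers orientation from the standards, so competitive
(descending) formats work unchanged. The kit's documentation implies a
quantifiable range of 31.3–2000 pg/mL but does not state a curve family;
4PL is the de facto standard for this assay class and is an explicit
modelling assumption of this package. A 5PL (asymmetric) extension is a
non-goal.

Fitting is least squares via Levenberg–Marquardt with the usual immunoassay
initialisation — asymptotes from the extreme-concentration signals, $c$ at
the concentration whose signal is nearest mid-range, $b = 1$ — plus three
perturbed restarts before a fit failure is raised. Replicate standard wells
are averaged (uniform weights) before fitting, matching duplicate-testing
practice. Box constraints keep $c$ positive and $b \in [0.05, 20]$.

Inverse prediction uses the closed form
$x = c\,((a-d)/(y-d) - 1)^{1/b}$. Signals at or beyond an asymptote are
*censored*, returned as `NA` with a directional flag rather than an error or
an infinite value: a plate well can legitimately saturate, and the pipeline
must keep running. Signals that invert to a concentration outside the
working range keep their finite value but carry a `below_range`/
`above_range` flag.

## Analytical-validation statistics

All dispersion statistics use the sample standard deviation ($n-1$
denominator), the bioanalytical convention; this choice reproduces the
bundled kit precision table exactly from its printed means and SDs (with
one known ±0.1 rounding artifact in the intra-assay low cell, where the
printed mean/SD recompute to a CV of 5.3 against a printed 5.4).

- **Precision.** CV% $= 100\,s/\bar x$ per replicate set, passed if below
  the acceptance threshold (default 15%, the conventional ligand-binding
  criterion). The inter-assay CV pools all values of a level across runs
  into one total CV rather than extracting a between-run variance
  component; a single CV per level is what validation reports quote, and
  the run structure is preserved in the data model should an ANOVA
  decomposition be wanted later.
- **LLOQ.** The mean blank *signal* plus $k$ SD (default $k = 10$),
  interpolated through the calibration curve. Blanks are signals, not
  concentrations: the threshold is defined on the instrument scale.
- **Dilution linearity.** Per-factor recovery $100\cdot$ observed/expected
  with expected $=$ top/factor; the linear range is the maximal *prefix* of
  factors meeting both the deviation limit (default: the TCL, i.e. 14% at
  the default TCL inputs) and the replicate-CV limit. A prefix, not a
  subset: once linearity is lost at high dilution it does not return.
- **Spike recovery.** Two conventions exist and genuinely conflict in
  practice. The *marginal* formula $100\,(m_{spiked}-m_{neat})/added$
  measures recovery of the increment; the *total* convention
  $100\,m_{spiked}/(m_{neat}+added)$ treats neat + added as the theoretical
  value. Spike-recovery tables in kit validations are usually
  self-consistent only under the total reading (theirs list
  "theoretical" = neat + spike), so `total` is the default and both are
  reported side by side by `spike_table()`. Spike amounts are interpreted
  directly as pg/mL increments.
- **Total change limit.** $\mathrm{TCL} =
  \sqrt{(2.77\,CV_a)^2 + (0.5\,CV_b)^2}$, with $CV_a$ the assay's
  analytical imprecision and $CV_b$ the within-run variability of the
  tested sample, both in percent. The default report inputs
  ($CV_a = 5$, $CV_b = 4$) give TCL $= 13.99\%$, consistent with the ~14%
  bound conventionally quoted for an assay with ~5% imprecision; the
  inputs are configurable because published reports rarely state them.
- **Tube comparison.** Spearman correlation on midranks; Wilcoxon
  signed-rank with zero differences dropped (Wilcoxon's original rule) and
  midranks for tied absolute differences — exact p for ≤ 25 clean pairs,
  tie/continuity-corrected normal approximation otherwise; ordinary least
  squares for the fitted line. OLS rather than Deming is an assumption:
  comparison plots in kit validations are typically OLS, and
  measurement-error-in-x regression is out of scope.

## Clinical-diagnostics stage

Eligibility is strict: age 20–69 years, BMI < 30 kg/m², FIB-4 < 2.67 and
weekly alcohol below 140 g (female) / 210 g (male). FIB-4
$=(AST \times age)/(platelets \times \sqrt{ALT})$ takes platelets in
$10^9$/L; laboratory values printed in $10^4/\mu$L are multiplied by 10 by
the caller. The weekly alcohol phrasing is implemented (the daily phrasing
is an equivalent average).

Steatosis categories follow the established attenuation-coefficient bands
< 0.58 / 0.58–0.70 / > 0.70 dB/cm/MHz. The band boundaries' inclusivity is
not standardised; we assign both 0.58 and 0.70 to the middle band because
the band is written "0.58–0.70". The binary diagnosis for ROC purposes is
attenuation ≥ 0.66 dB/cm/MHz, with higher FGF21 treated as more steatotic.

Rank statistics use midranks throughout. Spearman p-values come from the
$t$-approximation $t = r\sqrt{(n-2)/(1-r^2)}$, with an exact permutation
null available for small tie-free samples; Mann–Whitney p-values are exact
for small tie-free samples and otherwise use the tie- and
continuity-corrected normal approximation. AUC is computed by the rank
method and is *identically* $U/(n_1 n_0)$ — a cross-operation invariant the
tests assert on random tied instances.

Dual thresholds are selected from the observed score values: the rule-out
cut-off is the largest threshold whose sensitivity still meets the floor;
the rule-in cut-off is the smallest threshold whose specificity meets its
floor. How published dual cut-offs were actually selected is usually not
documented; floors are therefore configurable, with defaults 0.84 and 0.81
mirroring commonly reported operating points for this biomarker. Likelihood
ratios are reported at each cut-off and satisfy
$LR^+ (1 - spec) = sens$ and $LR^- spec = 1 - sens$ exactly by
construction. With every score tied there is no separating threshold and
the selection raises an explicit infeasibility condition rather than
returning a degenerate cut-off. Pairwise category comparisons are
unadjusted by default (a Bonferroni option exists) since small
three-group biomarker comparisons are conventionally reported raw;
two-tailed tests and $\alpha = 0.05$ throughout.

## The synthetic-data generator

The generator exists so that every stage is testable with known truth and
no instrument data. Design sizes mirror the standard validation designs:
20 intra-assay replicates at three levels, a 5 × 5 inter-assay design, 16
blanks, 20 near-LLOQ replicates, a ×2…×512 serial dilution in duplicate,
three samples spiked at 0/100/200 pg, five interferent titrations at six
points, four stability conditions, 18 subjects × 3 tube types, and a
97-patient cohort.

Noise is multiplicative (constant CV), matching how immunoassay imprecision
is reported; precision replicates carry the end-to-end measurement CV
directly, while plate *signals* carry the CV on the signal scale, which
propagates to back-calculated concentrations with the delta-method factor
$y(1+u)^2 / ((d-a)\,b\,u)$, $u = (x/c)^b$ (a property the tests verify by
simulation). Inter-assay values additionally carry a lognormal between-run
effect (default CV 5%), so the pooled inter-assay CV concentrates near
$\sqrt{CV_{within}^2 + CV_{run}^2}$. Blank wells get their own, smaller CV
(default 1.2%): absolute noise at zero analyte is below mid-curve noise,
and this places the synthetic LLOQ in the low single-digit pg/mL region
typical of this kit class.

Stability is first-order exponential decay per condition (hourly rates for
4 °C, room temperature and −20 °C) with freeze-thaw as a per-cycle step
loss, the low level decaying more slowly under refrigeration — matching the
qualitative shapes of published stability panels: ~10% loss after seven
freeze-thaw cycles, ~14% after seven days at 4 °C for medium/high, ~30%
after seven days at room temperature, minimal loss at −20 °C. The serum
tube carries a −12% offset emulating proteolytic loss of FGF21 during
clotting; heparin and EDTA differ only by noise. Dilution linearity is
broken deliberately below 15 pg/mL expected (recovery fraction 0.5) so the
pipeline's linear-range logic has a planted truth to find.

The cohort uses a Gaussian copula: a latent bivariate normal with Pearson
correlation $2\sin(\pi\rho_s/6)$ is pushed through a truncated-normal
marginal for the attenuation coefficient (mean 0.64, SD 0.13, truncated to
0.32–0.97 dB/cm/MHz) and a lognormal marginal for FGF21 (median 300 pg/mL,
$\sigma_{\log} = 0.7$). Spearman correlation is a copula property, so the
target (default $\rho_s = 0.44$) survives both marginal transforms; the
tests confirm recovery within ±0.03 at $n = 5000$. The lognormal FGF21
marginal is an assumption — the distributional form of circulating FGF21
is not established beyond its ranges. Remaining covariates are drawn
independently within realistic screening-population ranges chosen so ≥ 90%
of records pass eligibility.

What the generator does **not** emulate: plate spatial effects (edge
effects, drift), carry-over, true biological covariance among liver
chemistry values, age or alcohol effects on FGF21, and assay
cross-reactivity. Passing tests on synthetic data therefore demonstrate
the *statistical machinery* — not that a real laboratory or cohort would
meet the acceptance criteria.

## Numerical choices and degenerate inputs

- Signals exactly at an asymptote map to a flagged censored value, never
  infinity; all-zero paired differences give a signed-rank p of 1.
- CV is undefined at mean 0 and correlation at zero variance; both raise
  typed conditions (`fgf21val_input_error` / `fgf21val_infeasible`) that
  the CLI maps to distinct exit codes (2 and 3).
- Report tables round percentages to one decimal at render time only.
- Seeds: every generator function derives all randomness from the single
  config seed (the cohort offsets it by one so suite and cohort draws are
  distinct streams); identical config + seed gives byte-identical outputs.

## Problem sizes

The test suite works at the native design sizes (n = 20/25/16/97), with
Monte-Carlo checks at 200–500 replicate suites and one 5000-patient cohort;
the whole suite runs in well under a minute, and the acceptance script uses
200 replicate suites and the same cohort sizes.

## Known limitations

The inter-assay CV is a pooled total CV, not a variance-component estimate;
Deming/Passing–Bablok regression, Bland–Altman analysis, Westgard rules,
measurement-uncertainty budgets and 5PL calibration are out of scope; the
dual-threshold selector conditions on the observed cohort and does not
bootstrap uncertainty for the cut-offs; and the synthetic cohort cannot
stand in for clinical evidence about FGF21 itself.
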