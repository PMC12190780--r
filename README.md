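# fgf21val

Analytical validation and hepatic-steatosis diagnostics for a plasma FGF21
ELISA.

Circulating fibroblast growth factor 21 (FGF21) is a liver-derived hormone
under evaluation as a blood biomarker of steatotic liver disease. Before an
ELISA measuring it can support clinical decisions, two things must be
demonstrated: that the assay itself is analytically reliable (precision,
quantification limit, linearity, recovery, interference resistance, sample
stability, tube-type robustness), and that the measured concentrations
discriminate patients with hepatic steatosis from those without.
`fgf21val` implements both stages as a reusable, tested R pipeline, aimed at
clinical-laboratory scientists validating ligand-binding assays and at
biostatisticians analysing biomarker cohorts.

## What it computes

**Calibration.** The four-parameter logistic (4PL) standard curve

```
signal = d + (a − d) / (1 + (x / c)^b)
```

is fitted by multi-start least squares (`fit_4pl`) and inverted in closed
form (`signal_to_concentration`), with working-range flags and
dilution-factor adjustment (`apply_dilution`).

**Analytical validation.** With sample SD throughout:

- intra-/inter-assay precision: CV% = 100·SD/mean against a 15% acceptance
  threshold (`precision_summary`, `inter_assay_summary`);
- LLOQ: the blank mean signal + 10·SD interpolated through the curve
  (`lloq_from_blanks`);
- dilution linearity: %recovery = 100·observed/expected per serial-dilution
  step with a maximal-linear-prefix verdict (`dilution_linearity`);
- spike recovery in both conventions, total 100·measured/(neat + added) and
  marginal 100·(measured − neat)/added (`spike_recovery`);
- the total change limit TCL = √((2.77·CV_a)² + (0.5·CV_b)²) used to judge
  interference biases and stability percent changes
  (`total_change_limit`, `interference_bias`, `stability_series`);
- blood-collection-tube comparison: Spearman correlation, Wilcoxon
  signed-rank test and an OLS fit (`tube_comparison`).

**Clinical diagnostics.** FIB-4 = (AST·age)/(platelets·√ALT), strict
eligibility filtering (age 20–69, BMI < 30, FIB-4 < 2.67, alcohol below the
metabolic-dysfunction limits), steatosis categories from the ultrasound
attenuation coefficient (< 0.58 normal / 0.58–0.70 suspected / > 0.70
confirmed, dB/cm/MHz), Spearman/Mann–Whitney statistics, ROC/AUC by the
rank method, and dual cut-off selection (`select_dual_thresholds`): the
largest threshold keeping sensitivity ≥ 0.84 rules steatosis out
(LR⁻ = (1 − sens)/spec), the smallest threshold reaching specificity ≥ 0.81
rules it in (LR⁺ = sens/(1 − spec)). `cohort_analysis` chains all of it.

**Synthetic data.** `simulate_validation_suite` and `simulate_cohort`
generate every input with known ground truth — 4PL plate reads with
multiplicative noise, the standard replicate designs (20 intra, 5×5 inter,
16 blanks, ×2…×512 dilution, 3×3 spikes, six-point interference panels,
stability time courses, an 18-subject three-tube panel) and a Gaussian-copula
patient cohort with a target rank correlation (default 0.44) between the
attenuation coefficient and log-FGF21.

## Worked example

```r
library(fgf21val)

cfg   <- sim_config(seed = 7)
suite <- simulate_validation_suite(cfg)

curve <- fit_4pl(data.frame(concentration = suite$standards$concentration_pg_ml,
                            signal        = suite$standards$signal))
curve
#> 4PL calibration curve
#>   signal = 2.063 + (0.05091 - 2.063) / (1 + (x/375.6)^1.285)
#>   working range: 31.3 - 2000 pg/mL; RMS residual 0.00375 (7 levels)

lloq_from_blanks(suite$blanks$signal, curve)$lloq
#> [1] 3.88436

precision_summary(subset(suite$replicates, sample_id == "intra_medium")$value)
#>    n     mean       sd cv_percent passes
#> 1 20 586.0563 23.50055   4.009947   TRUE

total_change_limit(5, 4)
#> TCL = 13.99% (CV_a = 5.00%, CV_b = 4.00%)

cohort_analysis(simulate_cohort(cfg))
#> Cohort analysis: 96/97 eligible
#>   FGF21 vs attenuation coefficient: r = 0.364 (p = 0.000266)
#>   Steatosis (att >= 0.66): AUC = 0.689
#> AUC = 0.689
#> Rule-out: < 202.3 pg/mL (sens 85%, LR- = 0.37)
#> Rule-in:  >= 415.9 pg/mL (spec 82%, LR+ = 2.55)
```

Reading the output: the fitted curve recovered the generating 4PL closely;
the synthetic LLOQ of ~3.9 pg/mL is far below the medium-level sample, whose
within-run CV of 4.0% passes the 15% criterion; a TCL of 13.99% is the bound
against which stability and interference changes are judged. In the cohort,
FGF21 rank-correlates with ultrasound-measured liver-fat attenuation
(r = 0.36), discriminates steatotic from non-steatotic patients with
AUC 0.69, and yields a rule-out threshold at 202 pg/mL (85% sensitivity,
LR⁻ 0.37) and a rule-in threshold at 416 pg/mL (82% specificity, LR⁺ 2.55).

The package also bundles, under `inst/extdata/`, the published validation
tables of the kit (dilution-linearity, spike-recovery and precision
summaries) as worked inputs for the report commands.

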