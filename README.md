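# gaitsym

Bilateral asymmetry analysis of running gait from three-axis ground
reaction force (GRF) waveforms.

Healthy runners are not symmetric: the left and right limbs produce
systematically different force waveforms, and running-induced fatigue can
worsen the imbalance — a risk factor for overuse injury. `gaitsym` is an R
implementation of the full analysis chain used to quantify and detect this
from force-plate recordings:

1. **Preprocessing** — stance-phase detection at a 30 N vertical-force
   threshold, cubic-spline time normalisation to 101 nodes (0–100% of
   stance), and body-weight scaling (`BW = N / (10 × mass in kg)`).
2. **Symmetry Function (SF)** — the time-varying bilateral asymmetry
   measure of Nigg,
   `SF(t) = A · |x_R(t) − x_L(t)|` with `A = 2 / (range(x_R) + range(x_L))`,
   its trapezoidal integral, and asymmetric stance intervals (`SF > 0.05`).
3. **1D statistical parametric mapping (SPM)** — a paired t-statistic field
   over the 101 nodes, residual-smoothness (FWHM) estimation, a
   random-field-theory critical threshold at familywise α, and sign-flip
   permutation p-values for suprathreshold clusters.
4. **Kernel SVM gait classification** — a soft-margin SVM (SMO dual
   solver, written here) with linear / RBF / polynomial kernels,
   `σ² = 1/(2G)` width convention, C–G grid search by stratified five-fold
   cross-validation, and ACC / SEN / SEP evaluation with
   `SEN = T1/(T1+F2)`, `SEP = T2/(T2+F1)` (the cross-denominator
   convention used in the gait-recognition literature). A companion
   exhaustive solver inverts printed ACC/SEN/SEP triples back to integer
   confusion matrices to audit published tables.
5. **Synthetic GRF generator** — seeded bilateral three-axis stance
   waveforms (Gaussian-bump templates; distinct vertical impact and active
   peaks, braking/propulsion anterior–posterior lobe, small medial-lateral
   component) with injectable limb-dominance asymmetry, a late-stance
   medial-lateral fatigue effect, and temporally smooth noise so the SPM
   smoothness machinery is exercised honestly.

Everything composes into one reproducible pipeline (`run_full()`), with
plain CSV/JSON intermediates at every stage.

## Worked example

Simulate the default study design (14 subjects × 3 trials × 2 sides ×
2 conditions), compute Symmetry Functions, and test whether fatigue
changed medial-lateral (X) asymmetry:

```r
library(gaitsym)

curves <- simulate_curves(n_subjects = 14, n_trials = 3,
                          asymmetry = "dominance+fatigue",
                          noise = noise_spec(sd = 0.02, smooth_fwhm = 10),
                          seed = 42)
sf <- sf_dataset(curves)

# subject-mean SF matrices for the X axis, post vs pre
s <- sf[sf$axis == "X", ]
agg <- function(cond) {
  d <- s[s$condition == cond, ]
  a <- aggregate(sf ~ subject + node, d, mean)
  m <- matrix(NA_real_, 14, 101)
  m[cbind(match(a$subject, sort(unique(a$subject))), a$node + 1)] <- a$sf
  m
}
fit <- spm_paired_test(agg("post"), agg("pre"), alpha = 0.05,
                       n_perm = 999, seed = 1)
print(fit)
#> SPM paired t-test (1D), n = 14 pairs, df = 13, 2-tailed
#>   residual FWHM = 8.78 nodes, resels = 11.38
#>   RFT critical threshold t* = 4.006 (alpha = 0.05)
#>   1 suprathreshold cluster(s) [Monte-Carlo permutation p]:
#>     85%-92% of stance (extent 8, p = 0.0030)
```

The injected fatigue effect (a 0.08 BW medial-lateral bump on the left
limb, present only post-fatigue) is recovered as a significant cluster at
85–92% of stance: asymmetry worsened in late stance after fatigue. The
`t*` of about 4.0 is the random-field-theory threshold controlling the
familywise error over all 101 nodes at α = 0.05, given the estimated
residual smoothness (FWHM ≈ 8.8 nodes).

Classifying left vs right stance curves with a polynomial-kernel SVM:

```r
fs <- build_feature_sets(curves, task = "lr", axis = "X")
ev <- svm_evaluate(fs$X, fs$y, kind = "poly", test_n = 34, seed = 1)
print(ev)
#> <svm_eval> kernel poly | best C = 0.03125, best G = -, CVAcc = 1.000
#>   test (n = 34): confusion: T1=17 T2=17 F1=0 F2=0 | ACC=1.000 SEN=1.000 SEP=1.000
```

Auditing a published metric triple (test-set size 24, printed
ACC = 54.167%, SEP = 52.2%):

```r
recover_confusion(24, acc = 0.54167, sep = 0.522, digits = c(acc = 5, sep = 3))
#> <confusion_recovery> n = 24: unique solution
#>  T1 T2 F1 F2       acc sen       sep
#>   1 12 11  0 0.5416667   1 0.5217391
```

Exactly one integer confusion matrix is consistent with those two printed
values — and it forces SEN = 100%.

The full pipeline (all axes, all SPM comparisons, all six classification
tasks) is one call:

```r
report <- run_full(gaitsym_config(seed = 1, out_dir = "my_run"))
print(report)
```

or, from a shell, `Rscript inst/exec/gaitsym.R run --seed 1 --out my_run`.

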