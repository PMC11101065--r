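# pathnomo

Benign/malignant classification of H&E-stained breast-pathology images from
three whole-image statistics, for pathologists and image-analysis researchers
who want an interpretable, hardware-light alternative to deep models.

Each image is reduced to its mean red, green and blue channel intensities

    avg_C = (C_1 + C_2 + ... + C_N) / N,   C in {R, G, B}

and the Shannon entropy of its 256-bin grayscale histogram

    H = - sum_i P_i log2 P_i   (bits),

where `P_i` is the proportion of pixels at gray level `i` (BT.601 luma). A
multivariable logistic regression of malignancy on the informative subset
(`avg_r`, `avg_b`, `entropy` under the bundled reference cohort) is fitted by
maximum likelihood, presented as a 0–100 points nomogram, and evaluated with
Mann–Whitney AUC plus case-resampling bootstrap CIs, the Hosmer–Lemeshow
test, calibration curves and decision-curve analysis. A synthetic-data module
simulates class-conditional feature tables at the reference cohort's printed
means and SDs, and renders actual PNG images with controlled channel means
and entropy, so the full pipeline runs without clinical data.

## Worked example

```r
library(pathnomo)

tab   <- simulate_feature_table(sim_config(), seed = 7)   # 2214 malignant / 509 benign
split <- split_dataset(tab, 0.3, seed = 8)                # 1907 training / 816 validation
fit   <- nomo_fit(label ~ avg_r + avg_g + avg_b + entropy,
                  tab[split$training, ], select = TRUE)
summary(fit)
#> Logistic benign/malignant classifier
#> n = 1907 (1560 malignant), converged in 7 IRLS iterations
#>
#>         term     beta       se wald_chisq         p     or or_low or_high
#>  (Intercept) 76.37000 5.732000     177.50 1.697e-40     NA     NA      NA
#>        avg_r -0.18900 0.018650     102.70 3.863e-24 0.8278 0.7980  0.8586
#>        avg_g -0.08343 0.007556     121.90 2.410e-28 0.9200 0.9064  0.9337
#>        avg_b -0.11370 0.012670      80.47 2.947e-19 0.8926 0.8707  0.9150
#>      entropy  2.06400 0.150300     188.50 6.727e-43 7.8770 5.8670 10.5800

evaluate_model(fit, tab[split$validation, ], B = 1000, seed = 9)
#> Evaluation on n = 816 (prevalence 0.801)
#> AUC = 0.9501 (654 malignant vs 162 benign), bootstrap 95% CI (0.9278, 0.9691), B = 1000
#> Hosmer-Lemeshow chi^2 = 25.172, df = 8, p = 0.001 (10 groups)
```

Each unit increase in entropy multiplies the odds of malignancy by the `or`
column (here ≈ 7.9); channel coefficients are negative because malignant
tissue is darker. On this synthetic cohort all four features survive
selection (identity feature correlations remove the collinearity that
suppresses the green channel in real slides), the AUC is higher than on real
data, and the Hosmer–Lemeshow test correctly detects the mild miscalibration
that unequal class covariances impose on a linear logit — see the methods
vignette (`vignettes/he-image-nomogram.Rmd`) for why.

Scoring a new image profile with the bundled reference coefficients:

```r
m <- nomo_model(with(reference_cohort()$coefficients, setNames(beta, term)))
predict(m, data.frame(avg_r = 219.969, avg_b = 220.340, entropy = 5.425))
#> [1] 0.9325995
```

`plot(fit)` draws the nomogram; `run_pipeline(run_config(seed = 1))` runs the
whole analysis (simulate → compare → split → select/fit → nomogram →
evaluate) and `write_run_report()` serialises it to JSON/CSV/PNG. The same
stages are scriptable via the CLI wrapper `inst/cli/pathnomo`
(`simulate`, `extract`, `stats`, `fit`, `evaluate`, `run`).

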