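# tabareg

Maximum-likelihood classification with the **Taba distribution** as the
response function, for binary, multinomial (unordered), and ordinal
outcomes — the niche occupied by `glm(family = binomial)`, baseline-category
logit, and `MASS::polr`, but with a different, asymmetric sigmoid link.
Intended for biostatisticians and methods researchers who want this model
family with proper likelihood inference (Wald tables from the observed
Fisher information, AIC/BIC), classification metrics (confusion-matrix
rates and Mann–Whitney AUC), seeded simulators for recovery studies, and a
built-in reproduction of a published liver-cirrhosis survival
classification analysis on the Mayo PBC trial cohort.

## The model

The standard Taba CDF is

    F(x) = 1 / (1 + sinh²(exp(−asinh x)))  =  sech²(u),   u = √(1+x²) − x,

a strictly increasing sigmoid with F(0) ≈ 0.41997 and closed-form inverse
`sinh(−ln asinh √((1−p)/p))`. The three regression families are

* **binary** — P(y=1|x) = F(β₀ + βᵀx), Bernoulli likelihood;
* **multinomial** — with s(φ) = sinh(e^(−asinh φ)) and one linear predictor
  per non-reference category, πⱼ = s²(φⱼ) / (1 + Σ s²(φₛ)), reference
  category by normalisation (note: a positive coefficient *lowers* its own
  category's probability, and the reference choice is not a mere
  reparameterisation — see the vignette);
* **ordinal** — proportional-odds style, P(y ≤ j|x) = F(αⱼ − βᵀx) with
  strictly increasing cutpoints.

All fits are by BFGS with analytic gradients plus Newton refinement on an
internally standardised design, with covariance from the inverse observed
information and t(n) Wald p-values (the convention that reproduces the
published cirrhosis table to printed precision).

## Worked example

```r
library(tabareg)
md  <- simulate_taba_binary(1000, beta = c(0.3, 0.6, -0.4), seed = 42)
fit <- taba_binary(md)
fit
#> Taba binary regression
#>   n = 1000  parameters = 3
#>          term  estimate        se   t_value     p_value
#> 1 (Intercept)  0.255196 0.0370985   6.87888 1.06202e-11
#> 2          x1  0.645007 0.0496564  12.98940 9.19359e-36
#> 3          x2 -0.456861 0.0427807 -10.67914 2.76601e-25
#> -2 logLik = 966.907   AIC = 972.907   BIC = 987.63

metrics_report(md$outcome, predict(fit), model_name = "sim")
#>   Model   TPR   TNR   FPR   FNR   PRE    FS Accuracy   AUC
#> 1   sim 0.803 0.713 0.287 0.197 0.751 0.777     0.76 0.843
```

The true coefficients (0.3, 0.6, −0.4) are recovered within two standard
errors; the metrics row is the in-sample confusion summary at threshold
0.5 plus the rank-based AUC.

Reproducing the published cirrhosis analysis (20-parameter binary Taba fit
on the 312 trial patients, mean-imputed labs):

```r
res <- reproduce_cirrhosis()
head(wald_table(res$fit), 3)
#>         term     estimate          se  t_value     p_value
#> 1   Constant -5.74765e+00 1.43430e+00 -4.00728 7.68722e-05
#> 2        Age  7.35213e-05 2.07435e-05  3.54431 4.53886e-04
#> 3 Sex Female -4.55767e-01 2.49713e-01 -1.82517 6.89318e-02
res$criteria[c("aic", "bic")]   # published: 284.584 / 359.444
#> $aic 285.1618  $bic 360.0219
res$metrics
#>   Model   TPR   TNR   FPR   FNR  PRE   FS Accuracy   AUC
#> 1  Taba 0.752 0.866 0.134 0.248 0.79 0.77    0.821 0.902
```

Coefficients, criteria and metrics land within a few percent of the
published table (exact decimals are unattainable because the original
study's imputation of the missing labs is undocumented; the published
AUC 0.902 reproduces to three decimals). The significance pattern at
α = 0.05 — age, prothrombin, alkaline phosphatase, SGOT, stage 1,
bilirubin, constant — matches row for row.

A command-line front end covers fit/predict/metrics/simulate/reproduce:

```sh
Rscript inst/cli/tabareg simulate --family binary --n 500 --coef 0.2,0.7 --seed 7 --out sim.csv
Rscript inst/cli/tabareg fit --family binary --data sim.csv --out fit
Rscript inst/cli/tabareg reproduce --out cirrhosis
```

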