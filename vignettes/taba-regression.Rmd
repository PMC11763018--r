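---
title: "Taba regression: models, estimation, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Taba regression: models, estimation, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tabareg)
```

## The model

`tabareg` fits classification models in which the response function is the
CDF of the Taba distribution,

$$F(x) \;=\; \frac{1}{1+\sinh^2\!\big(e^{-\operatorname{asinh} x}\big)}
       \;=\; \operatorname{sech}^2(u), \qquad u = \sqrt{1+x^2}-x,$$

playing the role the logistic CDF plays in logistic regression.  The second
form follows from $e^{-\operatorname{asinh} x}=\sqrt{1+x^2}-x$ and
$1+\sinh^2 = \cosh^2$, and is how everything is computed: it involves no
`exp`/`asinh` composition, never overflows for $|x|\le 10^8$, and has the
stable log-forms $\log F = -2\log\cosh u$ and
$\log(1-F) = 2\log\tanh u$ used by every likelihood in the package
(`log(cosh(u))` itself is evaluated as $u+\log(1+e^{-2u})-\log 2$ so large
$u$ cannot overflow).  For positive $x$, $u$ is computed as
$1/(x+\sqrt{1+x^2})$ to avoid cancellation.

Three points about this link worth internalising before interpreting
coefficients:

* It is **asymmetric**: $1-F(-x) \neq F(x)$.  The response approaches 1
  polynomially fast ($1-F \approx 1/(4x^2)$) but 0 essentially like
  $e^{-4|x|}$ on the log scale.  $F(0)\approx 0.41997$, not $1/2$; the
  median of the distribution is $\approx 0.12661$.
* Because of the asymmetry, *orientation matters* in ways logistic users
  will not expect (see the family reductions below).
* The quantile function is closed-form,
  $F^{-1}(p)=\sinh(-\ln\operatorname{asinh}\sqrt{(1-p)/p})$, which makes
  inverse-CDF sampling exact.  (The source publication's typeset inverse
  omits the radical and its printed density is not normalizable as typeset;
  the package uses the round-trip-verified inverse and the analytic
  derivative $f = 2u\tanh(u)\operatorname{sech}^2(u)/\sqrt{1+x^2}$, which
  integrates to 1 by quadrature.)

### Binary family

$\pi(x) = F(\beta_0 + \beta^\top x)$ with Bernoulli log-likelihood.  For a
single predictor the model is the distribution in location–scale form with
$L=-\beta_0/\beta_1$, $S=1/\beta_1$ (`location_scale_view()`); a negative
slope flips the orientation and is reported as a negative scale with a
warning rather than silently re-parameterised.

### Multinomial family

With $s(\varphi)=\sinh(e^{-\operatorname{asinh}\varphi})$ and one linear
predictor $\varphi_j$ per non-reference category,
$$\pi_r = \frac{1}{1+\sum_{s\ne r} s^2(\varphi_s)},\qquad
  \pi_j = \frac{s^2(\varphi_j)}{1+\sum_{s\ne r} s^2(\varphi_s)}.$$
The numerator uses the $-\operatorname{asinh}$ exponent; the $+$ sign that
appears in one typeset numerator cannot normalise against the
$-\operatorname{asinh}$ denominator terms, and normalisation is
non-negotiable.  Two consequences are documented prominently instead of
being "fixed":

* $s$ is *decreasing* in $\varphi$, so a positive coefficient **lowers**
  its own category's probability.
* The family is **not invariant to the reference category** once
  predictors are present.  In baseline-category logit a reference switch
  is a linear reparameterisation because ratios of exponentials are
  exponentials of differences; ratios of $s^2$ terms are not of the $s^2$
  form in any linear predictor.  Different references are genuinely
  different models; they coincide for intercept-only fits (saturated) and
  at $k=2$.  Choose the reference scientifically, as one chooses a
  baseline hazard.  The default is the last category in label order.

### Ordinal family

Proportional-odds-style cumulative model:
$P(y\le j\mid x) = F(L_j)$, $L_j = \alpha_j - \beta^\top x$, with strictly
increasing cutpoints, category probabilities by differencing (telescoping
to 1 exactly), and the ordinal log-odds
$\gamma_j = \ln\frac{F_j}{1-F_j} = -2\ln s(L_j)$.  (The source also prints
a $\pi_j = 1/(1+e^{\gamma_j})$ display that contradicts its own definition
of $\gamma_j$ and its "equivalently" block; the internally consistent
cumulative-CDF form is implemented.)

**Reductions.**  At $k=2$ the three families meet, but orientation is
dictated by the asymmetric link: the ordinal *first* category satisfies
$\pi_1 = F(\alpha_1-\beta^\top x)$, a binary model for category 1 with
intercept $\alpha_1$ and negated slopes; the multinomial *reference*
category satisfies $\pi_r = F(\varphi)$, the binary success probability.
So "binary ≡ multinomial($k{=}2$) ≡ ordinal($k{=}2$)" holds at the
maximized log-likelihood when the ordinal outcome is coded success-first
and the multinomial reference is the success class — the coding the test
suite uses and asserts to $10^{-6}$.

## Estimation and inference

All families are fitted by maximum likelihood:

* **Standardisation.**  Non-constant design columns are internally
  z-scored and the estimates/covariance mapped back exactly (an affine
  reparameterisation; the optimum is equivariant).  Without this, the
  cirrhosis design — age in days next to 0/1 indicators — is too
  ill-conditioned for quasi-Newton steps.
* **Optimizer.**  BFGS (`stats::optim`) with analytic gradients for all
  three families, followed by Newton refinement with a central-difference
  Hessian.  Convergence requires gradient max-norm $<10^{-6}$ (default
  `tol`) and relative objective change $<10^{-10}$; failures restart from
  up to three deterministically jittered inits and are *flagged*, never
  thrown.  The ordinal cutpoints are optimised as
  $(\alpha_1, \ln\Delta_2, \dots)$ so ordering holds at every iterate
  (increments capped at $e^{80}$ to keep wild line-search steps finite);
  results return to the natural scale by the delta method.
* **Covariance.**  Inverse observed Fisher information: the
  central-difference Hessian at the optimum with per-coordinate step
  $\max(10^{-5}, 10^{-5}|\theta_j|)$, symmetrised.  Non-positive-definite
  information flags the covariance and the affected Wald rows rather than
  failing.
* **Wald table.**  $t_j=\hat\beta_j/\mathrm{se}_j$ referred to Student-t
  with **df = n**.  This is an empirical decision: among df = ∞, n−q, and
  n, only df = n reproduces every p-value of the published cirrhosis
  coefficient table at printed precision (df = n−q puts the prothrombin p
  at 0.000754 against a printed 0.000748).
* **Criteria.**  $-2\hat\ell$, AIC $=-2\hat\ell+2q$, BIC
  $=-2\hat\ell+q\ln n$.
* **Separation.**  On separated data this link's likelihood flattens so
  quickly that coefficients stall at modest magnitudes with a tiny
  gradient; a magnitude guard alone would never fire.  The binary fit
  therefore also warns when the fitted linear predictor splits the classes
  perfectly.

## What the simulators emulate

`simulate_taba_*` draw independent observations with standard-normal
predictors by default (optionally Bernoulli columns with a given
prevalence, mimicking indicator-coded clinical covariates) and outcomes
from the exact family probabilities at user-supplied true coefficients —
the data-generating process the estimators assume, nothing more.  They do
not emulate correlated covariates, missingness, measurement error, or the
cirrhosis covariate joint distribution, so a green recovery test
establishes *internal* correctness (estimator consistency, SE calibration,
interval coverage under the model), not robustness.

The parameter-recovery acceptance test uses n = 2000, 500 replicates, and
moderate effects (binary $\beta=(0.3,0.6,-0.4)$; multinomial rows
$(0.4,0.6)$ and $(-0.2,0.5)$; ordinal $\alpha=(-0.8,0.9)$, $\beta=0.5$),
chosen to keep event probabilities in a realistic 0.1–0.9 band.  Note a
property of the "bias within 3 Monte-Carlo SEs" criterion: MC-SE shrinks
like $R^{-1/2}$ while the finite-sample MLE bias is $O(1/n)$ and grows
with effect size, so at fixed $(n, R)$ the criterion is an effect-size
statement as much as a correctness one; very large slopes would sit at the
band's edge for any correct implementation.  Replicate seeds are drawn
from a master-seeded generator rather than used consecutively —
consecutive `set.seed` values give measurably correlated Mersenne–Twister
streams (we observed ~20% deflation of the empirical SD).

## The cirrhosis reproduction

`cirrhosis_cohort()` rebuilds the 312-patient Mayo PBC randomized-trial
cohort in the published encoding (death indicator outcome; female, drug,
ascites/hepatomegaly/spiders "yes", edema "S" vs merged "N or Y", stage
I–III indicators against stage IV; ten untransformed lab/demographic
columns; age in days).  The public UCI export of this dataset is the same
Mayo trial data distributed as `survival::pbc`, which is how the package
reconstructs it offline; a UCI-schema CSV path is also accepted.

The published table's preprocessing is partly unrecoverable: every column
is reported with N = 312 although four labs have missing values, and the
printed cholesterol/copper minima are negative, which no imputation of the
raw data can produce.  The package defaults to transparent column-mean
imputation and treats agreement with the published decimals as
tolerance-based: signs and the significance pattern reproduce exactly,
headline coefficients agree within a few percent, AIC/BIC within ~0.6 of
the published 284.584/359.444, and the in-sample metrics row (TPR … AUC)
within ~0.01.  The one sub-noise divergence — the triglyceride
coefficient, published at −0.000577 with SE 0.001325 — flips sign under
mean imputation; it is within one SE of zero in both analyses.

## Degenerate inputs and conventions

* Non-finite arguments to the distribution kernels are errors, not `NaN`s.
* Classification uses the `score >= threshold` convention everywhere;
  multinomial/ordinal class prediction breaks probability ties toward the
  lower category index.
* AUC is the Mann–Whitney statistic with half-credit ties (identical to
  the trapezoidal ROC area); single-class inputs return an `NA` marker,
  as do zero-denominator confusion ratios.
* Zero-variance predictor columns are left unstandardised; single-class
  binary outcomes and absent categories are hard errors.
* The proportional-odds diagnostic is deliberately descriptive (per-split
  binary fits and the spread of each predictor's slope): the source
  publication cites score/Brant/Wolfe–Gould tests without defining them,
  so no p-value is manufactured.

## Known limitations

No offsets, observation weights, or regularisation; no likelihood-ratio or
score tests; no partial proportional odds or category-specific designs;
multi-class AUC is out of scope.  The multinomial reference-dependence
described above is a property of the published model, not an
implementation artefact — treat cross-reference comparisons of fit as
model comparisons.
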