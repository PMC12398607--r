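---
title: "Linking effort-based decision-making and apathy to fronto-motor connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking effort-based decision-making and apathy to fronto-motor connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effortconn)
library(dplyr)
```

`effortconn` implements a complete analysis chain for studies that relate
individual differences in effort-based decision-making and apathy to
measures of fronto-motor brain connectivity: a parametric choice model
fitted per subject by maximum likelihood, paired-pulse TMS (ppTMS)
motor-evoked-potential processing, streamline-count connectivity features,
and a conservative two-step statistical procedure that selects and then
confirms brain-behavior associations. A synthetic-cohort generator
reproduces the data structure of such a study so every stage can be
exercised, calibrated and tested without access to human data.

## The choice model

On each trial of the effort-based decision-making task a subject sees an
offer: exert a grip force at one of four levels (20, 40, 60 or 80% of
maximal voluntary contraction, MVC) to earn one of four rewards (1, 5, 10
or 20 euro cents), and accepts or rejects it within the response window.
With 10 repetitions per cell the session has 160 trials. The subjective
value of an offer in the winning model is

$$
V = \beta_{\mathrm{Effort}}\cdot E^2\cdot(1 + \beta_{\mathrm{Time}}\cdot t)
  + \beta_{\mathrm{Reward}}\cdot R + \beta_0 ,
$$

with $E$ the effort as a fraction of MVC, $R$ the reward in cents and $t$
the 1-based trial index; acceptance probability is the logistic
(softmax) transform $P(\text{accept}) = 1/(1+e^{-V})$. The model family
crosses three effort-cost shapes — linear ($E$), quadratic ($E^2$) and
exponential ($e^{k_e E}-1$, with $k_e$ a fitted positive shape) — with the
presence or absence of the time-modulation factor, giving six candidates
compared by BIC ($2\,\mathrm{NLL} + k\ln n$). No separate softmax
temperature is fitted: it is non-identifiable against a common rescaling of
the weights, which already carry the scale.

Conventions that matter:

* Effort enters as a fraction in $(0,1]$, not percent, keeping
  $\beta_{\mathrm{Effort}}$ of order 1–10; reward is raw cents. Users of
  other unit systems must rescale.
* Missed trials (no response) carry `NA` choices and are excluded from the
  likelihood.
* Probabilities are clipped to $[10^{-12}, 1-10^{-12}]$ inside the
  logarithm; this cannot move an interior optimum at the optimizer's
  tolerance.
* For reporting, $\beta_{\mathrm{Effort}}$ is multiplied by $-1$
  (`flip_effort_sign()`), so larger reported values mean stronger effort
  aversion; raw values are kept alongside.

### Fitting

`fit_choice_model()` minimises the negative log-likelihood with L-BFGS-B
and an analytic gradient, from (default) 20 starting points drawn
uniformly within the fitting bounds under a seed, keeping the best
solution. The bounds — $\beta_{\mathrm{Effort}}\in[-40,0]$,
$\beta_{\mathrm{Reward}}\in[0,2]$, $\beta_{\mathrm{Time}}\in[-0.05,0.05]$,
$\beta_0\in[-5,5]$, $k_e\in(0,10]$ — are chosen commensurate with the
behavioral range of the 4×4 design (subjective values stay of order 10).
This is deliberate: sessions that are (nearly) separable — a subject who
accepts or rejects deterministically by effort level — have likelihoods
that are flat along some direction, and inside a very wide box the
optimizer can stop anywhere along that direction, producing arbitrarily
large estimates that never touch a bound and therefore never get flagged.
With bounds near the plausible range, such sessions end at a bound and are
flagged (`boundary = TRUE`), as are all-accept/all-reject sessions.

### What recovery simulations can and cannot show

At 160 binary trials the asymptotic (Fisher) standard error of
$\beta_{\mathrm{Effort}}$ is about 1.4 for a typical subject and grows
roughly as $0.24\,|\beta_{\mathrm{Effort}}|$ because the quadratic-cost
regressor and its time-modulated copy ($E^2$ vs $E^2 t$) are highly
collinear. Population-level recovery correlations therefore plateau around
0.85–0.93 and the median absolute error sits near 20–35% of the population
SD no matter how the generating population is placed; these are properties
of the design, not of the optimizer (refits from the returned solution are
NLL fixed points, and the generating parameters never beat the fit). The
recovery checks in the test-suite and acceptance script should be read
with this limit in mind.

## The synthetic cohort

`generate_cohort()` produces the full data structure of a 45-subject
study. Design constants (effort and reward levels, 10 trials per cell,
seven probed circuits, nineteen tract features, four confounds) follow the
emulated study; everything stochastic derives from one master seed through
a fixed per-stage splitting rule, so cohorts are bit-reproducible.

* **Choice parameters.** The effort and reward weights are truncated
  *log-normal* in magnitude — the canonical population model for
  discounting-type parameters, which vary over an order of magnitude
  across subjects while keeping one sign. Defaults:
  $|\beta_{\mathrm{Effort}}|\sim\mathrm{LN}(\ln 4, 0.9)$ on $[0.4, 35]$
  (sign negative), $\beta_{\mathrm{Reward}}\sim\mathrm{LN}(\ln 0.2, 0.7)$
  on $[0.03, 1.2]$; $\beta_{\mathrm{Time}}\sim N(0.005, 0.003)$ on
  $[-0.004, 0.014]$ and $\beta_0\sim N(0.4, 0.5)$ on $[-1, 1.5]$ are
  truncated normals. These were chosen once to give graded acceptance
  across the 4×4 grid for the median subject and a realistic spread from
  near-indifferent to extremely effort-averse; the published work reports
  only density plots for these distributions, so the defaults are declared
  assumptions, fully configurable.
* **Confounds.** Age $\sim N(24, 3)$ (young healthy adults), gender a
  balanced 0/1 code from a latent normal (the minimal testable coding for
  a control variable), depression $\sim N(3, 2.5)$ truncated at 0 (DASS-21
  depression scale range) and anhedonia $\sim N(1.5, 1.2)$ truncated at 0
  (SHAPS range); the depression and anhedonia latents correlate at 0.3.
* **Apathy.** The apathy score is the mean of $(5-\text{grade})$ over
  rating-scale items (`score_lars()`), giving the range $[0,4]$; synthetic
  totals load weakly (0.25, 0.20) on the depression/anhedonia latents,
  with three subscores (action initiation, emotional response,
  intellectual curiosity) generated as correlated components of the total,
  since no item-to-subscore mapping is published.
* **Planted associations.** A feature with a target confound-adjusted
  partial correlation $r$ against an outcome is built linear-Gaussian:
  the outcome's confound-orthogonal residual (unit-scaled) enters with
  weight $r$, independent noise with weight $\sqrt{1-r^2}$, plus a
  confound loading that the adjustment removes again. The construction
  makes the target exact in expectation and checkable at large $n$;
  $|r|\ge 1$ is rejected as infeasible (it would need negative noise
  variance). Features are then mapped affinely to their natural scale
  (streamline counts in the hundreds, circuit ratios around their typical
  values), which leaves partial correlations untouched.
* **MEP trials and connectivity stacks.** Per-circuit trial tables draw
  log-normal amplitudes whose condition means embed the subject's latent
  ratio; stacks of per-iteration count matrices are symmetric
  negative-binomial draws (variance $\mu + \phi\mu^2$, default
  $\phi=0.02$) around a mean matrix that embeds the tract features —
  overdispersed counts being the standard model for iteration-to-iteration
  tractography variability. `dispersion = 0` is the degenerate noise-free
  limit.

What the generator does *not* emulate: raw EMG spectra (amplitudes and RMS
are drawn directly), DWI images or tractography, item-level questionnaire
structure, and any nonlinearity or heteroscedasticity in the
feature-phenotype relations. Passing tests therefore demonstrate that the
*procedures* are correct and calibrated under the linear-Gaussian,
correctly-specified regime — not that the assumptions hold in real data.

## MEP processing

Trials are cleaned per condition (circuit × pulse type) by two rules in a
fixed order: first, trials whose pre-stimulus RMS over $[-250, -50)$ ms
exceeds 200 µV are discarded (background muscle activity); second, in a
single non-iterative pass, trials whose amplitude deviates from the
condition mean by strictly more than 3 SD are discarded, with mean and SD
computed over the survivors of rule 1 *including* the candidate (leave-in;
configurable in principle, fixed here and documented because the published
procedure does not specify it). A trial violating both rules is logged
once, under rule 1; zero amplitude spread means rule 2 cannot fire. The
circuit ratio is the ratio of condition means —
$\overline{\mathrm{CS{+}TS}}/\overline{\mathrm{TS}}$, computed *after*
averaging, not the mean of per-trial ratios — so it is scale-invariant and
$>1$ means facilitation, $<1$ suppression. The peak-to-peak response
window defaults to 15–60 ms post-pulse and the pre-stimulus window is
half-open so boundary samples are attributed unambiguously. With 24 trials
per condition and a retained-count floor of 17 (the minimum observed in
the emulated study), low-count conditions are flagged but still computed.

## Connectivity features

Tractography upstream of this package is out of scope: the boundary is the
per-iteration streamline-count matrix. `average_connectivity()` validates
(square, symmetric, non-negative, zero diagonal, shared labels) and takes
the entrywise mean over iterations; `extract_tract_features()` reads the
19 canonical pairs (SMA/OFC to M1 and the five basal-ganglia nuclei, the
BG–pallidal connections, and the pallido-thalamo-cortical limb) by label,
orientation-insensitively. Averaging is linear and commutes exactly with
extraction — both are asserted in the tests. Values may be non-integer
(e.g. after streamline filtering); the functions accept reals.

## The two-step association procedure

For each outcome (apathy, reported effort weight, reported reward weight)
against each feature set (19 tract counts; 7 circuit ratios):

1. **Selection.** LASSO with the objective
   $\frac{1}{2n}\sum_i(y_i - x_i^\top\beta)^2 + \lambda\|\beta\|_1$,
   unpenalized intercept, features and outcome standardized internally
   (coefficients reported back on the original scale — configurable off).
   $\lambda$ comes from 10-fold cross-validation on a 100-point
   log-spaced grid from $\lambda_{\max} = \max_j |\langle x_j,
   y\rangle|/n$ (closed form on the standardized scale; everything is
   exactly zero there) down to $10^{-4}\lambda_{\max}$; because the
   CV-optimal $\lambda$ fluctuates with the fold partition, it is averaged
   over 100 independently seeded partitions before the final refit. Ties
   in the CV curve break toward the larger (more regularized) $\lambda$.
   Selection is the exactly-non-zero set — soft-thresholding zeros, never
   post-hoc thresholding.
2. **Confirmation.** Each selected feature is tested by a
   confound-adjusted partial correlation (Pearson on double residuals
   against age, gender, depression and anhedonia; Spearman by flag), two
   sided at $\alpha = 0.05$ with $df = n-2-k$. *No multiple-testing
   correction is applied across the selected features* — each test stands
   at $\alpha$, mirroring the emulated analysis; the report surfaces this
   prominently rather than hiding it.
3. **Null evidence and replication.** Non-selected features (by default
   those sharing an anatomical family with a selected one) receive a
   Bayes factor BF$_{01}$ for the null of zero partial correlation. The
   sampling model is the Fisher-z approximation
   $\mathrm{atanh}(r)\sim N(\mathrm{atanh}(\rho), 1/(n-3-k))$ with a
   $N(0, 1/\sqrt2)$ prior on the Fisher scale under the alternative,
   integrated numerically (the Gaussian marginal also has a closed form,
   which serves as the independent oracle in the tests). The published
   analysis names no Bayes-factor model, so this default is declared, not
   inferred. The selection is replicated with a less conservative Elastic
   Net (mixing 0.5, same CV/averaging machinery) and a bidirectional
   stepwise regression. The stepwise criterion is BIC: with the AIC
   penalty a pure-noise 19-feature problem admits a median of about four
   spurious variables, which is out of character for a conservative
   replication; BIC brings the null median to zero. AIC remains available.

### Calibration

With three features planted at partial $r = 0.4$ in a 45-subject cohort,
each planted feature is selected *and* confirmed in roughly 70% of seeded
runs, while each pure-noise feature is confirmed in well under 10%; on
all-noise cohorts the mean number of confirmed features is below one of
nineteen. At $n = 45$ with four confounds the two-sided $\alpha = 0.05$
critical partial correlation is $\approx 0.31$, so power at $\rho = 0.4$
is only moderate — the procedure is conservative by construction, and
single-cohort null results should be read as "not detectable at this
$n$", not "absent".

## Pipeline and reproducibility

`run_all()` executes simulate → fit choices → MEP ratios → tract features
→ associations in dependency order, validates that the subject set is
identical across stages (aborting rather than silently dropping), writes
the CSV/JSON artifact set and a manifest of md5 file hashes, and is
byte-reproducible under the config seed (asserted in the tests by hashing
two independent runs). Stage seeds derive from the master seed by a fixed
congruential rule (`effortconn:::derive_seed`), so stages can be re-run in
isolation.

Problem sizes used by the test-suite and the acceptance script — 45
subjects × 160 trials for parameter recovery, 100 subjects for model
recovery under the documented strong-effect condition
(`strong_effects_config()`: the time drift quadruples the cost over the
session, so the families are discriminable; under weak effects BIC rightly
prefers smaller models), 50 seeded cohorts per calibration arm, and a
reduced 5-iteration λ-average for the byte-identity check — were chosen as
the smallest sizes at which the quantities stabilise.

## Known limitations

* The β recovery limits discussed above are intrinsic to 160-trial
  sessions; studies needing tighter per-subject estimates need more trials
  or hierarchical pooling (deliberately out of scope: each subject is fit
  independently, as in the emulated analysis).
* The Bayes factor rests on the Fisher-z Gaussian approximation; for
  $n - k < 20$ or $|r| > 0.9$ exact-likelihood methods would be
  preferable.
* The planted-association construction guarantees expected partial
  correlations, not joint feature covariance structure; collinear feature
  blocks (realistic for neighbouring tracts) are not emulated, and LASSO
  behaviour under strong feature collinearity is therefore untested here.
* Gender enters as a single binary control column; the emulated analysis
  gives no coding details.
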