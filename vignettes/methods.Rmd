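---
title: "Simulating and analyzing behavioral listening-effort tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing behavioral listening-effort tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effortbench)
```

## Scope and rationale

`effortbench` is a simulation and analysis bench for two dual-task
behavioral listening-effort tests as used with cochlear-implant (CI)
listeners:

* **SVT** (sentence verification test): spoken statements are categorized
  as true or false. Reaction time relative to the sentence end measures
  listening effort; the proportion of correctly categorized statements
  measures speech intelligibility.
* **SWIRT** (sentence-final word identification and recall test): the final
  word of each sentence in a list is repeated immediately (intelligibility)
  and recalled after the whole list (effort).

Both tests are administered at two signal-to-noise ratios placed relative
to each individual's 50% speech reception threshold — SRT50 + 4 dB and
SRT50 + 8 dB — just below maximum intelligibility, where effort measures
are believed to be more informative than intelligibility measures. The
package simulates whole cohorts at trial level, estimates SRT50 with the
adaptive staircase used in practice, and reproduces the statistical
pipeline such data are analyzed with: validity filtering, item outlier
screening, learning-effect correction, generalized linear mixed models
(GLMMs) with crossed random effects, and an intra-individual
smallest-detectable-change analysis based on test–retest variability.

Because the virtual cohort's generative truth is known, every stage can be
validated against an oracle: staircase bias against the generating
psychometric function, GLMM estimates against the simulated coefficients,
detection thresholds against their nominal false-positive rate.

## The virtual listener

Each participant carries a four-parameter logistic psychometric function
for word recognition in noise,

$$p(x) = g + (p_{\max} - g)\,\sigma\!\left(k + \beta\,(x - \mathrm{SRT50})\right),
\qquad k = \mathrm{logit}\!\left(\tfrac{0.5 - g}{p_{\max} - g}\right),$$

re-anchored so that $p(\mathrm{SRT50}) = 0.5$ exactly, whatever the floor
$g$ and asymptote $p_{\max}$. CI users typically do not reach 100%
intelligibility, so the default asymptote is $p_{\max} = 0.95$ with floor
$g = 0$. The slope for CI users is not pinned down by published group
curves; the default $\beta = 0.5$/dB is an assumption chosen so that the
intelligibility gap between the two test conditions,
$p(\mathrm{SRT50}{+}8) - p(\mathrm{SRT50}{+}4)$, is about 0.088 — inside
the 0.04–0.10 range expected when the conditions sit on the flattening
part of the curve. Population SRT50 values default to Normal(3.1, 2.9²) dB,
the observed CI-cohort distribution for these sentence materials.

## Adaptive SRT50 procedure

The staircase starts at +2 dB SNR and updates after each sentence by
$4 \cdot (0.5 - P_c)$ dB, where $P_c$ is the proportion of correctly
repeated words of the previous sentence (a stochastic-approximation rule
with steps bounded in ±2 dB). Twenty-six sentences are presented; the 27th
SNR is computed but never presented, and the SRT50 estimate is the mean of
SNRs 5 through 27. Sentence lengths are drawn uniformly from 5–9 words
when not fixed (only the range and median of the material are known).
No SNR rounding or clipping is applied — the procedure as specified has
none, and the simulator's responder is defined for all finite SNRs.
Calibration check: across many simulated tracks the generating
psychometric function evaluated at the estimate averages 50% correct
within a percentage point.

## Generative model for SVT

**Accuracy.** Each statement is understood with probability
$\mathrm{logit}^{-1}\{a + u_i + \tfrac{1}{2}\gamma\,c + \lambda(w_i - 0.875)\}$,
where $c = \pm 1$ codes the SNR condition, $u_i \sim N(0, 0.9^2)$ is a
participant offset and $w_i$ the participant's word score in quiet
(uniform on 0.75–1; everyone passes the >70%-in-quiet inclusion rule). An
understood statement is answered according to its truth value. A statement
that is *not* understood cannot be verified, and the guess is biased
toward "false" with probability $b$: unintelligible statements tend to be
categorized as false. This one mechanism produces the truth-type accuracy
asymmetry. With pooled comprehension $\bar p = 0.799$ and
$b = 0.6567$, accuracy is $\bar p + (1-\bar p)b = 93.1\%$ on false and
$\bar p + (1-\bar p)(1-b) = 86.8\%$ on true statements; $a = 1.614$ was
solved (by quadrature/Monte-Carlo over $u_i$ and $w_i$) so the pooled
comprehension hits 0.799. The condition effect on comprehension is kept
small ($\gamma = 0.3$) — the real test's accuracy was insensitive to the
SNR difference.

**Reaction time.** The *shifted* reaction time (raw RT + 0.8 s, so that
0 s is the earliest response that counts) is Gamma with constant
per-participant shape ($\nu = 6$) and a log-mean

$$\mu = \mu_0 + u_i + e_{\text{item}} + s_{\text{session}}
 \pm \tfrac{1}{2}\beta_{\text{cond}} + \log(g_{\text{learn}})\,[\text{retest}]
 - \beta_{\text{order}}\,[\text{second}] + \beta_{\text{err}}\,[\text{incorrect}]
 + \beta_{\text{false}}\,[\text{false}],$$

matching the Gamma-log-link analysis model. Defaults: participant SD 0.25,
item SD 0.10, per-session noise SD 0.03, condition effect 0.05 (slower in
the harder condition), within-session order effect 0.02, incorrect-answer
slowdown 0.08, false-statement offset −0.01, and learning gain
$g_{\text{learn}} = 0.92$ (retest about 8% faster — a clear learning
effect for the correction stage to find). The baseline $\mu_0 = 0.509$
(mean shifted RT ≈ 1.65 s) was solved so that the probability of a draw
beyond the 3.0-s response window is 2.2%: **misses arise mechanistically
from window censoring**, not from an independent coin flip, which couples
the miss rate to slow responders exactly as the recording procedure does.

## Generative model for SWIRT

The training rule sets the list length: participants recalling 0–4 of the
5 training words get five-sentence lists, those recalling all 5 get
seven-sentence lists. The package defaults to a training recall of 3
(lists of five) for the whole cohort; the real mix is not reported, and a
CI cohort will mostly sit below ceiling.

**Repetition** of the final word is Bernoulli at
$p(\mathrm{SRT50} + \Delta - d_i)$: the psychometric function evaluated at
the condition SNR minus a final-word difficulty penalty
$d_i \sim N(0.638, 0.3^2)$ dB (final words carry less context than running
speech). The penalty's mean was solved so the per-participant repetition
difference between conditions is 11.6 percentage points.

**Recall** is Bernoulli on the logit scale:
$\alpha_{\text{pos}} + \tfrac{1}{2}\gamma_r c + \tfrac{1}{2}\delta_r s + v_i$
with position intercepts $\alpha_{\text{first}} = 0.677$,
$\alpha_{\text{middle}} = 0.322$, $\alpha_{\text{last}} = 2.734$, condition
effect $\gamma_r = 0.208$, session effect $\delta_r = 0.148$ and
participant ability $v_i \sim N(0, 0.8^2)$. These five constants were
solved jointly (Gauss–Hermite quadrature over $v_i$) so that the marginal
recall rates are 92.2% / 64.4% / 57.0% for last / first / middle
positions, the condition difference is 3.8 and the session difference
2.7 percentage points — the recency-dominated serial-position profile and
small condition effect characteristic of this task. Because participants
are instructed to substitute and remember another word when the final word
is not understood, a misheard word whose token is reproduced counts as a
correct recall; recall is therefore independent of repetition by default
(`count_misheard_recall = TRUE`).

All draws use named RNG substreams keyed by participant, session,
condition and stage, so enlarging a cohort never perturbs existing
participants and every table is bit-reproducible from `(config, seed)`.

## Preprocessing choices

* **Validity window.** Responses between 0.8 s before and 3.0 s after the
  sentence end are valid; both boundaries are treated as inclusive (the
  permissive reading of "between"). Invalid or absent responses are
  retained as rows with missing outcomes — no stage deletes trials.
* **Outlier screening.** All trials of the hardest condition (SRT50 + 4 dB)
  are pooled; binary outcomes get an ML binomial fit and each item an
  exact two-sided binomial tail probability (doubled smaller tail) for its
  own trial count; reaction times get an ML Gamma fit, and an item's mean
  of $n$ draws is referred to its exact Gamma($n\nu$, rate $n\lambda$)
  distribution. Items with tail probability < 1% are flagged. The
  two-sided reading matches screening by a 99% confidence band around the
  pooled fit; with discrete outcomes the exact test is conservative, so
  the null flag rate stays at or below 1%.
* **Learning correction.** Retest RT means are regressed on test means by
  least squares, collapsed across SNR conditions and order (separate fits
  are not warranted by the data sizes involved). Each participant's
  correction — test mean minus fitted retest mean — is added to their
  retest trials, so corrected retest data sit at the test session's
  expected level. The choice of the test session as the anchor is the
  package's own; the residual identities (slope 1, intercept 0 after
  correction, idempotence) hold regardless. No correction is attempted for
  within-session (condition-order) learning.

## GLMM layer

Fitting is delegated to `lme4::glmer` with the Laplace approximation
(binomial-logit and Gamma-log families only; Gamma fits operate on shifted
RTs, which are strictly positive). The package adds:

* **Wald-z inference** (no finite-sample df theory exists for GLMMs).
* **Backward AIC selection**: one fixed or random term removed per step,
  refit, keep the lowest AIC; ties within 1e-9 go to the simpler model; a
  fixed effect is not removable while its random slope remains. If the
  full model does not converge, random slopes are removed first —
  item/list slopes before participant slopes — since those are the
  weakest-identified parameters.
* **Interaction LRTs** between nested fits: $\chi^2 = 2\,\Delta\ell$ with
  df equal to the parameter difference.
* **Standardized coefficients** by refitting after z-scoring continuous
  covariates only. The response is left untouched for both families (a
  logit or log response cannot be z-scored) and binary dummies are not
  scaled; this predictors-only convention is an explicit assumption, and
  for a single continuous covariate it reduces to
  $\beta_{\text{std}} = \beta \cdot \mathrm{SD}(x)$.
* **Nakagawa R²** on the link scale, with random-slope contributions via
  the mean row variance of the random-effect design (Johnson's extension)
  and distribution-specific residual variance $\pi^2/3$ (logit) or
  $\psi_1(\nu)$ (trigamma of the shape; Gamma-log).
* **Overdispersion** as Pearson $\chi^2$ over residual df, flagged above
  1.5 (configurable). With Bernoulli rows the statistic is uninformative;
  the tests aggregate to binomial counts before judging it.

Optimizer identity is treated as incidental: any optimizer meeting the
gradient-tolerance contract is acceptable, and convergence failures are
flagged on the object rather than raised.

## Intra-individual detection

For each measure, a normal distribution is fitted by maximum likelihood
(SD with divisor $n$ — a distribution fit, not a t-interval) to the
per-participant mean test–retest differences (RT after learning
correction). The significance threshold is the mean of the absolute 5th
and 95th percentiles of that fit,
$\tfrac{1}{2}(|\mu - 1.645\sigma| + |\mu + 1.645\sigma|)$, which equals
$1.645\sigma$ whenever $|\mu| < 1.645\sigma$ and is invariant to flipping
the sign of every difference. A participant's condition difference — the
mean at SRT50 + 8 minus at SRT50 + 4, signed so positive means better in
the easier condition, pooled over both sessions (the pooling is an
assumption; the sessions are equivalent after correction) — counts as a
significant detection when it exceeds the threshold *in that direction*.
The construction puts 5% of null participants beyond the threshold in the
detection direction, which is the false-positive rate of the detection
rule; the proportion with any positive difference is the measure's maximum
detection rate. Degenerate fits ($\sigma = 0$) yield threshold $|\mu|$
with a warning.

## Numerical choices and problem sizes

Calibration constants quoted above were solved once (40-node Gauss–Hermite
quadrature for logit-normal marginals; Monte-Carlo root-finding at n = 2·10⁶
for the censoring baseline) and are frozen as the package defaults; the
test suite re-verifies the resulting marginals by simulation. Tests and
the calibration checks use cohorts of 150–500 virtual participants, 500–1000
adaptive tracks, 2000 null participants for the threshold rate and 10,000
null items for the outlier rate, sized so Monte-Carlo error is a fraction
of each stated tolerance. GLMM property studies (quadrature-oracle
agreement, CI coverage at 150 refits, selection behavior at 20–25
replicates) use 12–60 groups of 10–40 observations.

## What passing tests do and do not show

The simulator reproduces the *marginal* structure the analysis assumes:
binomial outcomes with logit-scale effects, Gamma reaction times with
log-scale effects, window censoring, crossed participant/item
heterogeneity, session learning and test–retest noise, calibrated to the
published group descriptives. It does not emulate acoustics, fatigue or
attention drift within a session, item-content effects beyond a scalar
difficulty, correlations between a participant's comprehension and recall
ability, or non-normal population tails. Passing calibration therefore
shows that the pipeline recovers what it assumes, at realistic effect
sizes and sample sizes — not that real CI data satisfy those assumptions.
Quantities that are properties of the original participant sample (its
R² values, coefficient tables, 211-ms / 11.1% / 14.4% / 11.5% thresholds
and 2-of-18-style detection counts) are not reproduction targets; the
package recomputes their analogues on simulated cohorts.
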