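---
title: "Estimating disability weights from paired comparisons and companion instruments"
author: "dwpaired"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating disability weights from paired comparisons and companion instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwpaired)
```

## The problem

A disability weight (DW) quantifies the severity of a health state on a
scale from 0 (full health) to 1 (equivalent to being dead).  It is the
morbidity valuation that enters years-lived-with-disability, and through
them DALYs, so national burden-of-disease studies need defensible per-state
weights.  Classically these are elicited with cardinal trade-off
instruments — person trade-off variants, standard gambles — that are
cognitively demanding and theoretically contested.

`dwpaired` implements an alternative pipeline: include *full health* and
*being dead* themselves among the health states compared in a simple
paired-comparison task ("which of these two states is healthier?"), fit a
Thurstone-style probit model to the pooled choices, and anchor the latent
scale at those two states.  The ordinal instrument then yields cardinal
disability weights without any trade-off task.  Three companion estimators
are provided for comparison:

* **Model 1** — paired comparison only, probit regression with anchoring
  (the core model);
* **Model 2** — a hybrid that rescales the paired-comparison probabilities
  through population-health-equivalence (PHE) ladder responses, the
  approach of the GBD 2010 lineage;
* **Model 3** — visual analogue scale (VAS) disutilities;
* **Model 4** — standard gamble (SG) disutilities.

## The choice model and Model 1

Each paired comparison of states $a$ and $b$ is modelled as a probit
regression on a signed indicator design: the response row has $+1$ in the
column of $a$, $-1$ in the column of $b$, the *being dead* column is dropped
as the reference ($\beta_{dead} = 0$), and

$$\Pr(\text{a judged healthier}) = \Phi(\beta_a - \beta_b).$$

This is Thurstone's Case V discriminal process: $\beta_h$ is the state's
position on a latent healthiness scale in units of the comparison noise.
`fit_pc_probit()` computes the MLE (a `glm` probit start polished by Newton
steps to a gradient max-norm below $10^{-8}$) and the covariance as the
inverse *observed* information at the optimum.  Perfect separation — a
state that wins or loses every comparison it appears in — is a hard error
naming the state; a `"drop"` policy and an optional ridge penalty are
available where a hard stop is not wanted (for example inside holdout
loops).

`predicted_probabilities()` reports $p_h = \Phi(\beta_h)$, the probability
that state $h$ is judged healthier than *being dead*, with confidence
limits obtained by pushing the Wald limits of $\beta_h$ through $\Phi$.

### Anchoring

With $FH$ and $dead$ among the fitted states, Model 1 weights are the
affine rescaling that sends them to 0 and 1.  `anchor_to_dw()` offers two
scales for that rescaling:

* `scale = "probit"` (default):
  $dw_h = (\beta_{FH} - \beta_h) / (\beta_{FH} - \beta_{dead})$, i.e. the
  affine map applied to the latent probit index (equivalently to
  $\Phi^{-1}(p_h)$);
* `scale = "probability"`:
  $dw_h = (p_{FH} - p_h) / (p_{FH} - p_{dead})$.

The default is a deliberate design choice.  Under the Thurstone model the
coefficients are an affine image of the latent severities, so anchoring on
the index scale is the transform that recovers them; anchoring on the
probability scale composes that affine map with the nonlinear $\Phi$, which
compresses mid-scale states whenever discrimination is informative (with
choice noise around 0.25 the compression reaches several tenths of a
weight).  In simulation the index-scale anchoring recovers latent weights
with correlation above 0.99 and maximum absolute error below 0.1 at the
package's default study size, while probability-scale anchoring does not;
both orderings always coincide.  The probability-scale variant is retained
for sensitivity analysis and for comparability with descriptions that
anchor predicted probabilities directly.  Confidence limits are mapped
through the same monotone transform with the anchors treated as fixed
constants, so only the per-state probability uncertainty is propagated.

Anchors return weights of exactly 0 and 1 by construction.  Out-of-range
estimates for other states are reported unclipped, with a warning.

### Holdout fit assessment

`pc_holdout()` splits the *individual comparisons* (not respondents) into a
fit fraction (default 80%) and a holdout fraction, fits on the former, and
reports the mean absolute difference between observed holdout choice
frequencies and predicted probabilities per unordered pair.  With one to a
few observations per holdout pair this statistic is dominated by binomial
sampling noise, so it is a calibration check rather than an error measure;
values around 0.14 are what a perfectly specified model produces at 500
respondents and 30 substantive states.

## Model 2: the PHE hybrid

The PHE task asks whether averting 1,000 deaths (program A) or preventing
$X$ cases of a state (program B) produces more population health, walking
$X$ monotonically over the ladder 1,500 / 2,000 / 3,000 / 5,000 / 10,000
until the preference flips.  Taking one averted death as one unit of full
health, indifference at $X$ implies $dw \approx 1000 / X$, so a flip
bracketed by $(X_{lo}, X_{hi})$ is the weight interval
$[1000/X_{hi},\, 1000/X_{lo}]$.  Open-ended responses map to $[2/3, 1]$
(B preferred even at 1,500) and $[0.001, 0.1]$ (A preferred even at
10,000); the 0.001 floor keeps the log-scale likelihood finite and is
below the ladder's resolution, where the data carry no information anyway.

`fit_phe_intervals()` maximises the interval-censored normal likelihood of
$\log dw$ with a dummy mean per state and a common scale (via
`survival::survreg`, interval2 censoring, log-normal distribution).  The
log scale keeps estimates positive and follows the GBD 2010 antecedent; a
natural-scale variant is behind `scale_model = "natural"` for sensitivity
analysis.  A degenerate geometry deserves note: when every state's
intervals share a common interior the likelihood is flat (the scale
collapses to zero), so the function reports analytic suprema — the
geometric midpoint of the common interior, flagged `flat_likelihood` —
instead of pretending the regression converged.

`link_hybrid()` then regresses the interval-regression estimates on the
paired-comparison probabilities $p_h$ (unweighted OLS with intercept, the
plain reading of a linear linkage) and predicts a Model 2 weight for
*every* state, including those without ladder data; intervals are the
regression's confidence band for the mean response.  Because the linkage
compresses toward the regression line, Model 2 outputs typically span a
much narrower range than Model 1 — the same compression visible in
published hybrid estimates.

## Models 3 and 4: direct disutilities

Both direct models equate the disability weight with disutility,
$1 - \text{utility}$.

**VAS.**  Each respondent rates states on a 0–100 line and also rates
*being dead*.  Utilities are rescaled against the respondent's own dead
rating: $u = v/100$ when $v_{dead} = 0$, else
$u = (v - v_{dead}) / (100 - v_{dead})$.  A respondent who rates dead at
100 leaves the rescaling undefined; the block is excluded and logged.
States rated below dead yield disutilities above 1, which are flagged and
deliberately *not* clipped — clipping would bias the state means.

**SG.**  The staircase titrates the probability $p$ of restoration to full
health (versus immediate death) against remaining in the state, on a 5%
grid starting at 50%.  The utility is the indifference $p$; states judged
worse than dead at the opening question are censored at utility 0 rather
than measured on a negative scale.

`estimate_state_dws()` regresses disutility on state dummies without
intercept, which is algebraically the per-state arithmetic mean; an
intercept would be unidentifiable with the full dummy set.  Confidence
intervals use the pooled residual variance of that single regression
(equal-variance assumption), as a single linear fit implies.  Single-record
states are estimated but flagged; when no residual degrees of freedom
remain the CI is reported as undefined rather than invented.

## The survey simulator

No individual-level response data from published valuation studies are
available, so the package ships a seeded generator
(`simulate_survey()` and the per-instrument functions) that emulates the
survey designs from known latent weights.  It exists to make every
estimator testable by parameter recovery; its defaults are fixed once:

| Parameter | Default | Meaning |
|---|---|---|
| `k_pairs` | 15 | paired comparisons per respondent |
| `sigma_pc` | 0.25 | latent choice noise (weight units) |
| `sigma_vas` | 15 | VAS rating noise (VAS points) |
| `sigma_sg` | 0.15 | SG internal-utility noise (utility units) |
| `sigma_phe` | 0.2 | PHE internal-weight noise (weight units) |
| `k_phe` | 1 | ladder tasks per respondent |

The choice model is the Thurstone responder
$\Pr(\text{a chosen}) = \Phi((d_b - d_a)/\sigma_{pc})$ — matching the
analysis model, which is what makes parameter recovery well-posed.  The
noise scales are not estimated from any survey; 0.25 gives realistic
discriminability (adjacent states 0.1 apart are confused ~35% of the
time), 15 VAS points and 0.15 utility units are plausible within-rater
dispersions for these instruments, and the PHE scale is set larger than
the SG scale because person-trade-off answers are the noisiest of the
four tasks.  One ladder task per respondent reflects the task's burden.
Latent truths are drawn uniformly on $[0.02, 0.95]$ so that no substantive
state coincides with an anchor.  Anchor states enter the paired
comparisons only; VAS, SG and PHE draw substantive states (the VAS third
slot rates *being dead* by design, which is what identifies the
respondent's rescaling).  Respondents may see the same state in several
instruments.

Deterministic responder mechanics are exposed directly
(`sg_staircase()`, `phe_ladder()`) with documented tie rules: SG
indifference is the grid value nearest the internal utility, ties toward
the lower probability, endpoints capped to the reachable grid
$[0.05, 0.95]$ (a 5% staircase from 50% cannot reach 0 or 1); the PHE
responder prefers program B exactly when $X \cdot w \ge 1000$, equality
counting as B.

What the simulator does *not* emulate: respondent covariates and
heterogeneity in noise scales, quota sampling, interviewer effects,
nonresponse, ordering effects.  Passing recovery tests therefore shows the
estimators invert the stated response processes — not that real survey
answers follow those processes.

## Numerical choices

* Probit MLE: Newton with step-halving, gradient max-norm below $10^{-8}$,
  observed-information covariance; separation detected before iteration.
* Interval regression: `survreg` with relative tolerance $10^{-10}$; flat
  likelihoods handled analytically as above.
* Decile binning: half-open $[lo, hi)$ bins with the final bin closed —
  the convention under which the packaged reference table reproduces its
  published distribution shares; out-of-range values go to a counted
  overflow bucket with a warning.
* Correlations on the packaged table use its printed 3-decimal values;
  agreement with published coefficients is expected to ±0.002 for print
  rounding.
* All randomness flows from a single integer seed per simulated survey
  (per-instrument streams are derived from it by fixed offsets), and a
  registry seed; identical seeds reproduce results bit for bit.

## Problem sizes used in the tests

The recovery checks run at 30 substantive states and 500 respondents
(7,500 comparisons, 1,500 VAS ratings, 1,500 staircases, 500 ladders) —
large enough that Model 1 recovers truth with $r > 0.99$ and maximum error
well under 0.1, small enough to run in seconds.  Oracle-equivalence tests
(grid-search likelihood maximisation against the package's estimators) use
at most four states and a few hundred responses, where exhaustive grids
are feasible.  The packaged reference table (256 states, 220 with a
reference weight) drives the evaluation-layer checks at its full printed
size.

## Known limitations

* The anchoring propagates only the per-state probability uncertainty;
  anchor uncertainty is ignored, so Model 1 intervals are slightly
  anti-conservative near the anchors.
* Model 2's confidence band reflects linkage-regression uncertainty only,
  not the interval-regression uncertainty of its inputs.
* Worse-than-dead severities are censored, not measured: Model 4 cannot
  distinguish "as bad as dead" from "worse than dead".
* The probit model pools all respondents; covariate effects, mixed/random
  coefficients and logit (Bradley–Terry) variants are out of scope.
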