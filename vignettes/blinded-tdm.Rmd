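---
title: "Sham TDM results for blinded dose individualisation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sham TDM results for blinded dose individualisation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shamtdm)
```

## The problem

In a double-blind, placebo-controlled trial of a narrow-therapeutic-index
drug (the motivating case is lithium, therapeutic range 0.6–1.0 mmol/L),
dosing must be individualised from measured plasma concentrations. A
placebo participant's concentration is zero — the laboratory reports it
below the limit of detection (LOD) — so handing raw laboratory results to
the dose-adjusting investigator would unblind every placebo participant at
their first visit. `shamtdm` implements the workaround operated by an
unblinded statistician: placebo results are replaced by simulated "sham"
concentrations statistically matched to the treatment arm, and all results
are passed on in a single file with no arm information.

## The sham model and its assumptions

Sham values are drawn from a Gaussian fitted to the accumulating
treatment-arm concentrations and truncated to a reporting window by
rejection sampling. The model makes three deliberate simplifications:

* **Pooled, not per-participant.** One running `(mean, SD)` pair is
  estimated from all treatment-arm values received so far, regardless of
  participant or visit. With ~30 participants per arm the per-visit data
  are far too sparse to fit individual concentration trajectories; the
  cost is that a placebo participant's sham series has no within-person
  autocorrelation (see Limitations).
* **Gaussian shape.** Concentrations under a common dosing rule are
  unimodal and roughly symmetric; truncation to the window removes the
  tails where the Gaussian approximation is worst anyway.
* **Truncation to a plausibility window.** A sham value far outside the
  therapeutic range would itself be suspicious, and a sham value low
  enough to suggest non-adherence would trigger a real intervention
  (adherence counselling) on a possibly fully-adherent participant.
  Rejection sampling into `[lower, upper]` guarantees every issued value
  is clinically plausible. The price is a sham distribution with a
  narrower range than the observed data — visible in every assessment this
  package produces — which is accepted by design.

### Sequential estimation and the burn-in prior

Estimates refresh with each laboratory batch *before* that batch's sham
values are drawn, so sham values always reflect the treatment-arm
distribution up to and including the current batch. Before `n_min = 3`
values have accrued there is nothing to estimate from (reference ranges
for the target population were essentially unavailable before the trial),
so the sampler uses a prior of mean 0.7 and SD 0.2 mmol/L: centred in the
therapeutic window, wide enough to cover it. The sample SD additionally
requires two values; between one and `n_min` values the prior SD is kept.

Treatment-arm values below the LOD pass through to the re-blinded report
unchanged (they are real data), but are **excluded from estimation** by
default: a point mass at an arbitrary substitution value would bias the SD
estimate. A `lod_action = "substitute"` option imputes LOD/2 for users who
prefer the classical convention.

### The threshold policy

When treatment-arm adherence is poor, observed concentrations sit below
the window while sham values stay inside it — a systematic difference a
sharp-eyed investigator could learn. The remedy is a one-way lowering of
the window's lower bound, 0.6 → 0.3 mmol/L by default. In the motivating
trial this was a human decision sanctioned by the Data Safety and
Monitoring Board; a reproducible pipeline needs a data-driven stand-in, so
`threshold_policy()` fires when at least half (`trigger_fraction = 0.5`)
of the last 10 (`trigger_window`) treatment values fall below the original
bound, and also exposes `manual_override` to replay an oversight-board
decision directly. The switch is one-way: re-raising the bound would
re-introduce the leak it fixed. The bound is *not* lowered all the way to
the observed minimum, because sham values low enough to indicate
non-adherence would trigger real interventions.

## Numerical choices

* **Rejection sampling with exact fallback.** Rejection from the fitted
  Gaussian is exact for the truncated target. If a batch of proposals is
  rejected `max_iter = 10000` times (acceptance probability pathologically
  small, e.g. estimates far outside the window), remaining draws switch to
  inverse-CDF sampling `qnorm(runif(Φ(a), Φ(b)))`, which is
  exact for the same target; the event is counted and messaged. A test
  verifies the two routes agree in distribution.
* **Degenerate fit.** `sd_hat = 0` (all accrued values identical) returns
  the mean when it lies inside the window and is an error otherwise.
* **Rounding.** Sham values are rounded half-even to 2 decimals — the
  precision of laboratory reports — and re-blinded output is formatted at
  a fixed 2 decimals so sham and true values are typographically
  indistinguishable. A rounded draw that would leave the window (possible
  only when a bound is not a multiple of 0.01) is clamped to the bound.
* **Dose rounding.** Increases round to the *nearest* tablet increment
  with ties toward the lower dose; decreases round *down*. Both choices
  are dose-conservative. Emitted doses never exceed the usual maximum
  (1500 mg/day); decreases may pass below the usual minimum, since the
  500–1500 mg range qualifies upward adjustment only.
* **RNG state.** The sampler can carry an explicit RNG state, serialised
  with the rest of its state to JSON between laboratory batches, so any
  sham draw can be replayed exactly from the audit trail.

## The dose engine

Initiation is 20 mg/kg/day rounded to tablets and clamped to the usual
range. Thereafter, linear pharmacokinetics gives
`dose_new = dose_current × C_target / C_observed`. The point target within
the window is not dictated by the protocol; the engine uses the window
midpoint, 0.8 mmol/L, which keeps the fixed point of the rule at the
centre of the range. Four guard rules complete the protocol: in-window
concentrations hold; drug-related adverse events block any increase;
a scaled dose beyond 1500 mg/day becomes an adherence-confirmation note
with the dose unchanged (upward adjustment judged unsafe); below-LOD
concentrations become adherence notes too, since scaling by a near-zero
concentration is meaningless. The tablet increment defaults to 250 mg, a
common lithium carbonate strength, and is configurable.

## What the synthetic trial generator emulates — and what it does not

`run_trial()` exists so the whole workflow is testable without trial data.
It emulates a two-arm trial of 66 participants over 8 visits (about 260
measurements per arm, matching the scale of the motivating trial's 257
sham / 242 true measurements) with:

* **Linear steady-state PK**: `C = k · D · a / (CL_i · W)` with
  `k = 0.0375` mmol/L per mg/kg/day, calibrated so the 20 mg/kg/day
  initiation rate lands at 0.75 mmol/L — mid-window — at median clearance
  and full adherence. Individual clearance is lognormal (CV 0.25, median
  1) and scales linearly with body weight, so the weight-based initiation
  rule is approximately concentration-neutral across body sizes.
* **Imperfect adherence**: per-participant propensities and per-visit
  adherence fractions are Beta-distributed around a population mean of
  0.75 (concentration parameter 10), reflecting the substantial
  non-adherence the motivating setting saw. Beta keeps draws in [0, 1] and
  passes the degenerate means 0 and 1 through exactly, so noise-free
  configurations stay noise-free.
* **Non-trough sampling**: participants do not always arrive at the
  scheduled trough; a Normal(0, 2 h) timing deviation enters through an
  exponential decay factor `exp(−λt)` with `λ = 0.023`/h, the largest rate
  keeping a 6-h deviation under a 15% concentration change and of the
  order of lithium's elimination rate (t½ ≈ 24 h).
* **Assay noise**: multiplicative lognormal with CV 0.05, mean 1.
* **The closed loop**: each visit's laboratory batch is re-blinded and fed
  to the dose engine, whose recommendations set the next visit's doses —
  for both arms, so placebo doses are titrated on sham values exactly as
  in a blinded trial. Adverse-event flags occur with probability 0.08 per
  visit, identically in both arms.

The generator does **not** emulate: dropout; multi-compartment or
time-course PK (a single steady-state proportionality); correlated
adherence over time; sham adverse events (deliberately — dosing on
fabricated AEs could jeopardise efficacy and safety, so AE inputs are
always real flags). Passing tests on this generator therefore demonstrate
the pipeline's logic, determinism, and blinding guarantees; they cannot
certify distributional realism of any specific real trial.

## Blinding diagnostics

`assess_blinding()` is descriptive, matching how blinding success is
actually judged in this setting: arm-wise median and IQR (quantiles by
linear interpolation between order statistics, R type 7 — the convention
is stated because published summaries rarely state theirs), sample ranges,
the exact two-sample ECDF sup distance between sham and true values, and
the dose-action contingency table with marginals — similar adjustment
rates in both arms being the working evidence that blinding held. No
formal blinding index is computed; with the sham mechanism sitting inside
the trial's machinery, an inferential test would dress a design property
up as a hypothesis.

## Problem sizes in the test suite

The suite exercises the truncated-normal oracle at 10^5 draws, the
distribution-agreement check at 10^4 draws per route, window containment
at 10^4 draws, the dose grid exhaustively (324 cells), and end-to-end
trials of 8–66 participants over 2–8 visits; the whole suite runs in a few
seconds.

## Limitations

* Independent sham draws per visit: a placebo participant's sham series
  lacks within-person correlation, so longitudinal scrutiny of individual
  trajectories could in principle distinguish arms. Fitting per-individual
  trajectories would need richer data than a small trial accrues.
* The data-driven threshold trigger is a reproducible stand-in for what
  was, in practice, a judgement call; its defaults (half of the last ten
  values) are sensible but not canonical.
* The truncation-induced narrowing of the sham distribution is
  irreducible within this design; diagnostics report it rather than hide
  it.
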