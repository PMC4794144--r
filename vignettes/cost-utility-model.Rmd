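---
title: "A decision-tree cost-utility model for capsaicin 8% patch versus pregabalin in peripheral neuropathic pain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-tree cost-utility model for capsaicin 8% patch versus pregabalin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnpcea)
```

## The decision problem

Adults with peripheral neuropathic pain (PNP) who have not tolerated or
responded to first- and second-line systemic therapy can receive either a
single application of capsaicin 8% patch (with clinic-based retreatment as
needed) or daily dose-optimized pregabalin. `pnpcea` models this choice as
a decision tree from a health-service payer perspective, in GBP 2013/14.

At the 8-week assessment each patient is either a **responder** (≥30%
reduction in the 24-hour average pain score), a **non-responder**, or has
**discontinued** for intolerable adverse events. Response probability is
applied *conditionally on not discontinuing* — so an arm's responder share
is $(1-p_{disc})\,p_{resp}$ — and non-responders and discontinuers both
switch to last-line therapy (duloxetine as a proxy), which succeeds with
probability 0.20. That yields five terminal branches per arm; all expected
values are probability-weighted sums over them.

Two deliberate simplifications carried by the model structure: responders
are assumed to keep responding for the whole horizon (unless the waning
scenario is active), and there is no mortality, no adverse-event
disutility, and 100% adherence. Costs of adverse events that do not cause
discontinuation are excluded.

## Utilities and QALY accrual

Each branch has a piecewise-linear utility trajectory built by
`build_trajectory()`:

* responders rise linearly from the baseline utility $u_0 = 0.57$ to
  $u_0 + \Delta u$ over the median time to onset (7.5 days capsaicin,
  36 days pregabalin), then stay there;
* non-responders and discontinuers sit at $u_0$ until the assessment day
  (56); last-line responders then step to $u_0 + 0.2284$ *immediately*
  (a conservative assumption favouring the comparator pathway), the rest
  stay at $u_0$.

The response increments are used at four decimals — 0.2284 (capsaicin,
also assumed for last-line response) and 0.1989 (pregabalin) — rather than
their two-decimal display values; the extra precision matters at the
third decimal of the arm totals. `integrate_qaly()` integrates the
trajectory exactly on its segments (no time grid) and discounts by model
year:

$$\mathrm{QALY} = \sum_{y=1}^{H} (1+r)^{-y}\,\frac{1}{365}\int_{(y-1)\cdot 365}^{y\cdot 365} u(t)\,dt .$$

**Discounting convention.** Two conventions are implemented behind
`options$discounting`: `"all_years"` (default), where year 1 is already
discounted by $(1+r)^{-1}$, and `"after_first"`, where year 1 is
undiscounted. The default was chosen because only it reconciles the
published per-arm totals and every scenario delta of the analysis this
model re-implements; with the alternative convention the totals are
uniformly ~3.5% higher. The residual mismatch of the capsaicin arm total
(1.3586 here vs 1.360 published) is at the level of the source's own
"values subject to rounding" note.

## Costs

`derived_costs()` computes everything the model charges from unit inputs.
The capsaicin application cost is
$210 \times 1.3830 + 119 \times 0.5 + 0.06 = £349.99$. The mean patches
per treatment is stored at full precision 1.3830 — recovered as the
published acquisition cost per treatment divided by the patch price —
because the displayed 1.38 does not reproduce £290.43.

Accrual conventions (`branch_costs()`):

* capsaicin responders: per-application cost at the *continuous* rate
  $365/t_{retreat}$ applications per year ($t_{retreat}=179$ days), every
  model year. The microsimulation's `retreat_mode = "event"` charges whole
  applications at days $0, 179, 358, \dots$ instead and quantifies the
  discretization gap (5 applications vs 4.08 over 2 years);
* capsaicin non-responders/discontinuers: exactly one application, year 1;
* pregabalin responders: £839.50 per annum every year; non-responders pay
  the 56/365 assessment fraction in year 1 only. Discontinuers pay the
  same fraction times `options$discontinuer_drug_fraction` (default 1 —
  no AE-onset timing is available, so they are costed like
  non-responders; the option exposes the convention because it moves the
  cost side by a few pounds);
* last-line branches: duloxetine £361.35 per annum from the assessment day
  (fraction 309/365 in year 1), *regardless of last-line response status*;
* discontinuers additionally see a GP (£45) and a pain specialist (£125)
  once, in year 1.

Currency is kept at full precision throughout; rounding to whole pounds
and 3-decimal QALYs happens only in the report writers, which always also
emit a `_raw` companion CSV.

## Scenarios and structural analysis

`scenario_registry()` holds the seven named scenarios: observed (rather
than equalized) pregabalin efficacy 54.51%; equal onset (7.5 days); 0%
pregabalin discontinuation; equal response utilities; all four at once
(the QALY delta is then exactly zero, a useful engine check); waning; and
topical anesthesia.

**Waning** reshapes only the capsaicin responder trajectory: within each
179-day retreatment cycle the utility holds at full response until day 56
of the cycle, declines linearly to $u_0 + 0.61\,\Delta u$ (39% of the
increment lost) by cycle end, and recovers linearly over 14 days after
retreatment. **Anesthesia** adds £34.19 to capsaicin applications; by
default to *every* application (`options$anesthesia_mode = "all"`), which
reproduces the published incremental cost of that scenario, with a
`"first"`-application-only variant available since the source is silent on
retreatment anesthesia.

`horizon_sweep()` re-runs the model for horizons of 1–10 years with
constant extrapolation of health-state utilities and costs beyond year 1.
At one year the up-front patch cost is not yet recouped (low four-figure
ICER); from two years on the patch dominates.

## Sensitivity analyses

**One-way (`one_way()`).** Each parameter moves to its plausible low/high
bound — the 95% CI where reported, otherwise ±25% — with the rest at base
values. Bars are ranked by the absolute span of incremental net monetary
benefit (NMB) at £20,000/QALY because a raw ICER span is undefined when
one end of a bar is dominant.

**Threshold (`threshold_solve()`).** Solves
$\Delta C - \lambda\,\Delta Q = 0$ for one parameter by grid bracketing
plus bisection to relative tolerance $10^{-8}$, *restricted to the region
where the patch still gains QALYs*: an ICER target is only meaningful in
the north-east quadrant, and without the restriction a spurious
south-west-quadrant crossing appears for e.g. the capsaicin response
probability, which correctly reports NA. Multiple crossings raise an
error asking for a bracket split. Solving bounds are deliberately wider
than the one-way ranges (threshold values can sit far outside a CI, e.g.
the nurse hourly rate).

**PSA (`run_psa()`).** Families are beta for probabilities and the
baseline utility (method-of-moments on the base value and the CI-implied
SE $(high-low)/3.92$), gamma for costs, times and counts, and normal for
utility increments; a draw that violates any structural invariant (a
negative increment, an onset past the assessment day) is rejected and
redrawn, with the count reported. Parameters are sampled independently —
no correlation structure is available. Two deliberate choices: the
discount rate is held fixed in the PSA (varied deterministically instead,
standard HTA practice), and the pregabalin response is sampled around its
*observed* trial mean 54.51% rather than the equalized base-case value,
which is what makes the PSA mean QALY gain (≈0.052) sit slightly above
the deterministic delta (0.049), as in the source analysis. With 10,000
draws the probability of cost-effectiveness at £20,000/QALY is ≈97%.

## The microsimulation oracle

`simulate_cohort()` draws each patient's path (discontinuation, then
response conditional on continuing, then last-line response) and accrues
QALYs by *daily* time-stepping — utility evaluated at day midpoints —
and costs from daily rates or discrete events, under the same
year-indexed discounting. Within a branch the path is deterministic, so
per-branch accrual is computed once and the Monte Carlo varies branch
membership; this keeps $n = 50{,}000$ patients essentially free while the
daily route stays an independent check on the engine's exact integration
(midpoint-rule error on the ramps is $\mathcal{O}(10^{-5})$ QALYs, well
inside Monte Carlo noise). `generate_random_params()` produces random
valid parameter sets for property-based testing; the test suite requires
engine/oracle agreement within 3 standard errors in at least 95 of 100
random models at 20,000 patients per arm.

What the generator deliberately does **not** emulate: patient
heterogeneity in response depth or timing, partial adherence,
adverse-event timing, or mortality. Passing tests therefore show the
expected-value machinery is correct under the model's assumptions, not
that the assumptions hold in real cohorts.

## Numerical choices and problem sizes

* Exact piecewise-linear integration everywhere in the engine; the
  near-vertical last-line response step is represented as a
  $10^{-9}$-day segment.
* 8 weeks = 56 days; 365-day years; horizon in whole years.
* PSA: 10,000 draws; CEAC grid £0–£50,000 in £500 steps (covers the
  £20,000 and £30,000 decision thresholds).
* Oracle validation: 100 random parameter sets at 20,000 patients;
  branch-frequency chi-square at $\alpha = 0.01$ with 50,000 patients.
* Threshold solving: 61-point bracketing grid, bisection to $10^{-8}$
  relative tolerance; solutions reproduce the target ICER to < £1/QALY.

## Known limitations

The model inherits the source analysis's structure: a two-year horizon
with constant extrapolation, response as a single binary state, no
re-treatment discontinuation (every responder is retreated indefinitely),
and a single proxy for last-line therapy. The cost side of the base case
is reproduced to within ~£15 per patient rather than exactly, because
several accrual conventions (notably discontinuers' index-drug days) are
not pinned down by the published totals; the QALY side, scenario deltas,
threshold solutions and PSA summaries reproduce closely.
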