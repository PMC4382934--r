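---
title: "Constructing drug use periods from dispensing records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing drug use periods from dispensing records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxperiods)
library(dplyr)
```

## The problem

Prescription registers record dispensing events, not drug exposure. Two
naive translations fail in opposite directions: assuming a fixed supply
per purchase splits episodes whenever a patient is late or in hospital,
while generous grace periods merge genuinely separate treatment episodes.
Elderly cohorts make both failure modes common — doses are often below the
nominal Defined Daily Dose (DDD), hospitalizations pause purchasing, and
patients stockpile before travel or to smooth co-payments.

`rxperiods` models each person's purchasing behavior directly. The
package's output is one row per drug use period: person, ATC code, start
and end dates, total purchased DDDs, hospital days inside the period, the
number of purchases, and the average daily dose in DDD/day (total DDDs
over exposure days, i.e. calendar days minus hospital days).

## The model

### Sliding dose average and regularity

For purchase $i$ with dispensed amount $\mathrm{DDD}_i$ and
hospital-adjusted time $T_i$ to the next purchase,

$$\mathrm{DDDAVG}_i =
  \frac{\mathrm{DDD}_{i-1} + 4\,\mathrm{DDD}_i + \mathrm{DDD}_{i+1}}
       {T_{i-1} + 4\,T_i + T_{i+1}},$$

a weighted local estimate of the daily dose: heavy weight on the current
purchase, equal weight on its neighbours. The first purchase of a segment
uses weights $(5, 1)$ over (current, next), the last $(1, 5)$ over
(previous, current), with the last purchase's own interval imputed under
the assumption that the previous interval's dose continues:
$T_n = \mathrm{DDD}_n / (\mathrm{DDD}_{n-1}/T_{n-1})$. All times are *net*
gaps — days in institutional care are subtracted, because no purchasing
(and no consumption of the home supply) happens there — floored at one day
so the ratio stays finite when a stay spans a whole gap. A net gap above
the maximum refill time (300 days) restarts the averaging: such purchases
cannot belong to one treatment episode. Averages require at least three
purchases in the segment; shorter segments reach the decision walk without
a dose profile and are handled by parameter-based rules.

The coefficient of variation of a person's dose averages
(`ddd_avg_cv`, sample SD over mean) measures purchasing regularity and
feeds the connection rules below: an irregular purchaser earns more slack.

### Connecting purchases

The expected refill length of purchase $i$ is

$$\mathrm{ERFL}_i = \frac{\mathrm{DDD}_i\,(1 + \mathrm{DVAR}\cdot cv)}
                         {\mathrm{DDDAVG}_i},$$

with $\mathrm{DVAR} = 0.5$: half the regularity penalty is granted as
extra reach. The dose in the denominator is clamped from above by the
global cap (10 DDD/day) and the package's dose at its minimum refill
length; the result is truncated to the package maximum refill length times
the number of packages (else the ATC-class maximum). If the dose average
falls below the package's dose at maximum refill length (else the
ATC-class lower dose limit), the purchase pattern is too sparse for
continuous use: the period is closed after the current purchase with a
package-based duration. Purchases connect when
$\mathrm{ERFL}_i \ge$ the net gap (ties connect).

When the reach falls short, a strict local minimum of the dose average —
$\mathrm{DDDAVG}_i$ below both neighbours — signals stockpiling (a short
gap followed by a long one while the stock is consumed). The current and
previous purchase are then re-evaluated as one dispensing at the earlier
date; if their combined reach covers both gaps the period continues,
otherwise it closes.

Histories without a dose profile use the expert parameters directly: two
purchases join when the raw gap is within the package maximum refill
length times the package count (else the ATC maximum; else, with no
parameters at all, the global single-purchase cap — a deliberate
conservative fallback).

### Ending a period

From the last purchase of a $k$-purchase period the supply extends

$$\frac{\mathrm{DDD}\,(1 + 0.5\,cv)}{\mathrm{DDDAVG}\,(1 + e^{-k})}$$

days. The damping $1 + e^{-k}$ halves the extension of one-purchase
periods and vanishes for long ones, limiting terminal stockpiling.
Hospital days inside the extension do not consume supply and are added by
fixed-point iteration (extend, re-count stay days inside, repeat; a
100-iteration guard has never been reached in testing because each round
adds a non-negative, bounded count). A continuous stay longer than 30 days
is never bridged: the period is truncated at that stay's admission date.

Single purchases use, in order of evidence quality: a daily dose borrowed
from the person's nearest multi-purchase period of the same ATC code; the
population-learned refill mode of the package, times packages; the
dispensed amount with a 20% non-adherence allowance over the expert
typical dose; the ATC-class minimum period; and finally one flagged day.
Whatever the source, a single-purchase period never exceeds 150 days, and
— unlike multi-purchase periods — is not hospital-extended: the cap is
documented as absolute, and the hospital rule is defined for the last
purchase of constructed periods.

### Learning refill lengths

After each pass, refill-length histograms are built per package (vnr) from
periods with at least six purchases: the raw calendar gap after every
non-final member purchase, divided by the package count for multi-package
rows, rounded to whole days (register granularity). Dose-dispensing
purchases and rows mixing different packages are excluded. Counts are then
consolidated by hill-climbing to the nearest local maximum within a ±3-day
window (ties toward the shorter length) — the histogram's week-scale
shoulders collapse onto the peaks — and the mode is accepted when its
joined count strictly exceeds 10 purchases. Learned modes override expert
typical refill lengths for single purchases in the next iteration; the
outer loop stops when the period set repeats (typically 2–3 iterations).

The ±3-day window and the shorter-length tie rule are this package's
choices — no tighter algorithmic definition of "joining to the nearest
local maximum" exists to our knowledge — and both are isolated inside
`join_to_local_maxima()` for easy replacement.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `max_refill_gap_days` | 300 | days | net gap that restarts averaging and always splits |
| `max_hospital_days_in_period` | 30 | days | longest continuous stay bridged at period end |
| `max_ddd_per_day` | 10 | DDD/day | cap on any applied dose (guards 1-day gaps) |
| `max_single_purchase_days` | 150 | days | absolute cap on one-purchase periods |
| `dvar` | 0.5 | — | weight of the cv in the reach multiplier |
| `adherence_slack` | 0.2 | — | non-adherence allowance in typical-dose durations |
| `mode_min_purchases` | 10 | purchases | joined count a refill mode must exceed |
| `refill_source_min_purchases` | 6 | purchases | period size needed to teach refill lengths |
| `ddd_avg_min_purchases` | 3 | purchases | segment size needed for dose averages |

Below the globals sit two expert tables: ATC-class parameters (lower dose
limit, common dose, minimum period, maximum refill length), resolved at
the finest defined prefix of the 7-character code; and package (vnr)
parameters (refill-length window and corresponding doses), which override
class values. Global caps can never be overridden. The package ships small
illustrative tables (`example_parameter_space()`,
`inst/extdata/params-*.{yml,csv}`); production values are register- and
cohort-specific and must be supplied by the user.

## What the synthetic generator does and does not emulate

`generate_cohort()` produces purchase streams with known ground truth:
regular refilling at the package supply interval, stockpiling bursts
(early purchase, stretched follow-up), irregular timing, mid-stream dose
changes, refills delayed by institutional stays, single purchases, and
restarts after 300+-day breaks. Episode truth is fixed by the construction
(a person discontinues only where the profile says so), never by a gap
heuristic, so the generator cannot smuggle in the method under test.

Interval noise is a mixture: a fraction `on_time_prob` (default 0.4) of
refills happens exactly at pack exhaustion, the rest get multiplicative
log-normal deviations truncated at the jitter bound (three standard
deviations). The point mass is deliberate. Empirical refill histograms for
fixed packs show a dominant spike exactly at the pack length with spread
around it; under purely continuous noise the three bins around the truth
are near-equiprobable argmaxes, so no histogram-mode method — this one
included — could pin the refill length, and the generated data would
misrepresent the registers the package targets.

Not emulated: switching between packages within an ATC code, seasonal
purchasing, co-payment–driven batching, multi-drug interactions, dose
titration schedules, or mortality. Passing tests therefore demonstrate
correctness of the mechanics and recoverability under realistic-but-clean
behavior, not performance on any particular national register.

## Numerical choices and degenerate inputs

* Dates are calendar days; all gap arithmetic is whole-day differences.
  Day-quantity comparisons use a `1e-9` tolerance; period end dates round
  down to whole days.
* Same-day purchases of one ATC code are merged (amounts and packages
  summed) before modelling — the dose average divides by gaps, which must
  be positive. Merged rows with differing vnr numbers are flagged and
  excluded from refill learning.
* Missing amounts/packages are explicit `NA`s, never zeros; a purchase
  whose three-purchase window touches a missing or zero amount gets a
  missing dose average, and decision rules fall back to parameters.
* The cv uses the sample (n−1) standard deviation and is computed per
  person × ATC across segments jointly; segment boundary weights apply per
  segment.
* Period ends are clamped to the day before the next period's start, so
  periods of one history never overlap even when the damped extension
  overshoots a split point.
* Empty inputs yield empty outputs (not errors) throughout.

## Problem sizes

The shipped checks run at desk scale by design: the cap/partition sweep
uses 1,000 synthetic person × ATC histories (~7,600 purchases), mode
recovery 40 persons × 10 purchases of a 98-unit package, and dose recovery
50 persons per dose level at four levels. These sizes give stable medians
and exhaust every decision branch; register-scale behavior (hundreds of
thousands of periods) is beyond what synthetic data can attest.

## Known limitations

* The method estimates *supply-based* exposure; it says nothing about
  ingestion or about drug remaining in the body after a period ends.
* Expert parameter quality matters: a package maximum refill length set
  below a drug's real low-dose use pattern will split legitimate periods
  (the lower-dose split is a feature, but only as good as its limits).
* With small purchase counts the cv is a noisy regularity estimate; the
  $1+e^{-k}$ damping compensates only at period ends.
* Borderline gaps — a locally long interval just beyond the earned reach
  with no stockpiling signature — split by design; at 5% interval jitter
  this occasionally splits a genuinely continuous user. Dose and start
  estimates are robust to such splits.
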