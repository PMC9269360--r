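---
title: "Estimating phytoplankton bloom stage from pigment proportions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating phytoplankton bloom stage from pigment proportions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloomstage)
```

## The scientific question

A mid-summer bottle sample tells you how much chlorophyll-a is in the water,
but not whether the bloom that produced it is still growing or already
collapsing. `bloomstage` answers that question two ways and calibrates one
against the other:

* **Satellite route.** A multi-year surface chlorophyll-a time series at a
  fixed station resolves the bloom's seasonal curve, so the position of the
  sampling day relative to the bloom's start, peak, and end determines the
  stage directly.
* **Pigment route.** The pheophytin proportion,
  `p = Pheo / (Chl-a + Pheo)`, rises as chlorophyll is grazed and degraded.
  A single threshold on `p` separates growing from mature blooms once that
  threshold is calibrated against the satellite stages.

The satellite route is treated as the reference because stations are
observed continuously through time; there is no independent ground truth for
"bloom stage", so the calibration is an agreement analysis, not validation
against a gold standard.

## Satellite phenology

For each station-year of irregular observations (day of year, mg/m3):

1. **Ice masking.** Days whose sea-ice concentration exceeds 15% are removed:
   ice contaminates the ocean-color retrieval. Days with *missing* ice data
   are retained — a missing retrieval is not evidence of ice.
2. **Quality control.** A series is staged only if it has at least 6
   observations, no gap longer than 25 days, and at least 3 observations in
   the extended sampling window (DOY 174–219). The gap rule also applies
   between the window's bounds and the nearest observation: a series that
   stops 30 days short of the window cannot resolve the curve where it
   matters. The gap test runs after masking, so ice removal can disqualify a
   year.
3. **Smoothing.** A tricube-weighted locally weighted linear regression is
   evaluated at each observation day. The span is `max(7, ceiling(0.3 n))`
   points — wide enough to be stable at the ~27 observations/year that cloud
   cover typically leaves, narrow enough to keep a mid-summer secondary
   bloom visible. The smoother runs a single pass: robustness reweighting
   iterations would treat genuine bloom peaks as high outliers and erode
   them (measured on synthetic pulses, two robustness iterations halve the
   peak-recovery rate).
4. **Daily curve.** Smoothed points are joined by linear interpolation onto
   the daily grid between the first and last observation. The curve is never
   extrapolated; a sampling day outside its extent yields the
   missing-data stage (`NAN`), distinct from No Bloom.

### Bloom cycles

The daily curve is segmented at strict local minima, with a minimum plateau
collapsed to its first day. A segment becomes a **bloom cycle** when its
peak rises at least 0.5 mg/m3 above the starting minimum; `t1` is the
starting minimum, `t2` the earliest day attaining the segment maximum, `t3`
the closing minimum. Two conventions resolve cases the rise threshold leaves
open:

* **Sub-threshold continuation.** A following segment that rises less than
  0.5 mg/m3 is absorbed into the preceding bloom when the minimum between
  them stays *above* that bloom's starting chlorophyll (`chl_t1`) — the
  curve never returned to baseline, so the wiggle is part of the same cycle.
  If the intervening minimum falls to or below the baseline, the segment is
  minor variability and contributes no cycle. This replaces a case-by-case
  judgment with a deterministic rule.
* **Peak plateaus.** The earliest day of a maximal plateau is `t2`, making
  the EB/PB partition deterministic.
* **Truncated series.** A bloom whose closing minimum is the last grid day
  *and* whose curve is still above its starting level there is flagged
  `truncated_end`; a bloom that has returned to its baseline exactly at the
  series end is not. The end-of-series case is genuinely ambiguous — one
  more day of data would resolve it — and the flag records that ambiguity
  rather than hiding it.

The stage at sampling day `d` is `EB` if `t1 <= d <= t2` for some cycle,
`PB` if `t2 < d <= t3`, else `NB`. Every grid day receives exactly one
stage; the peak day itself counts as Early, keeping EB strictly "not yet
declining".

## Threshold calibration

Matched station-years (satellite stage EB or PB, surface pigment sample
available) feed an exhaustive scan over integer thresholds T = 0..100.
Sample classification is **strict-less**: `p < T/100` is EB, equality goes
to PB, so EB remains strictly pre-peak. No-Bloom and missing-data
station-years are excluded before the scan: a No-Bloom sample may carry
residual pheophytin from an ended bloom or reflect a long unproductive
state, and the two cannot be distinguished from the pigment pair alone.

Each T is scored with a 2x2 error matrix (field rows, satellite reference
columns): overall accuracy, per-reference-class producer's accuracy and
omission, per-predicted-class user's accuracy and commission. Selection is
lexicographic:

1. maximum overall accuracy;
2. smallest `|omission(EB) - omission(PB)|` (balanced classification bias;
   an undefined omission, from an empty reference class, sorts last);
3. smallest T.

The third rule is needed because perfectly separated data make a whole
interval of thresholds equally accurate; choosing the smallest is arbitrary
but deterministic and documented. Surface samples only (the 5 m bottle)
enter calibration; depth-integrated proportions are reserved for the group
comparisons, where their insensitivity to surface mixing is the point.

## Sea-ice year classification

Two independent schemes, because breakup timing and spring ice persistence
capture different limitations on early-season light:

* **Breakup scheme.** Breakup is the first day of the earliest 2-day run
  with concentration strictly below 15%, searched strictly after the last
  day attaining the annual maximum (so winter open-water interludes inside
  the pack cannot register as breakup). Years whose concentration never
  reaches 15% never formed winter ice; they carry no breakup date and are
  classed low-ice outright — the low-ice extreme, not missing data. Per
  station, an at-most-one-change (AMOC) changepoint on the year-ordered
  breakup dates gives a DOY threshold: an exhaustive single-split scan
  (minimum segment length 2) minimizing within-segment sum of squares,
  accepted only when the SSE reduction over the no-change model exceeds
  `2 ln(n)` times the pooled variance, with the threshold the midpoint of
  the two segment means (the overall mean when no change is accepted).
  Stations with fewer than four datable breakups inherit the pooled
  all-station changepoint threshold so that every station-year stays
  classifiable. Breakup before the threshold is low ice.
* **Concentration scheme.** A run of *strictly more than* five consecutive
  zero-ice days between March 1 and May 1 (computed from the calendar, so
  leap years shift the window) marks a low-ice year; high ice is the
  default. "Zero" means the concentration rounds to 0 at integer percent,
  absorbing sub-0.5% retrieval noise; missing days break runs.

## Group comparisons

Pheophytin proportions are compared between low- and high-ice bins with
Welch's unequal-variance t-test, four cells in all: {surface,
depth-integrated} x {concentration, breakup}. Surface proportions pool
pigment mass across replicate 5 m bottles; depth-integrated proportions are
the ratio of trapezoidally integrated chlorophyll and pheophytin over the
sampled depths (no extrapolation to the surface or seafloor), i.e. a
mass-weighted proportion rather than a mean of pointwise ratios. Standard
deviations use the n-1 denominator; p-values are two-sided. A bin with
fewer than two station-years renders that cell not-computable without
affecting the others. The raw-data path delegates to `stats::t.test`; the
summary-statistic path (`welch_t_from_summary`) evaluates the Welch
statistic and Welch–Satterthwaite degrees of freedom directly and is the
route for auditing published summary tables — the two paths agree to 1e-12
when fed the same data, which the suite asserts.

## What the synthetic generator does and does not emulate

`gen_chl_series` draws observations from a baseline-plus-Gaussian-pulses
truth (optional rise/fall asymmetry), thins days by i.i.d. Bernoulli cloud
loss, and applies mean-one multiplicative lognormal noise. Defaults are the
study conditions the package targets: observation window DOY 121–273 (the
May–September optical season at these latitudes), cloud probability 0.82
(about 27 retained observations per year), noise CV 0.15, and a large
spring bloom plus a smaller mid-summer pulse. `gen_ice_series` builds a
winter plateau with a logistic decline placed so the detected breakup day
equals the requested one exactly, and can punch zero-ice episodes into the
pack. `gen_pigment_samples` draws surface proportions below (EB) or above
(PB) a generating boundary of 0.28 and drifts proportions upward with depth.
`gen_full_study` ties the three together mechanistically: high-ice springs
seed an early bloom that is mature by the July sampling window, low-ice
springs delay the bloom so July catches it growing, and pigments follow the
stage actually sampled.

Deliberately not emulated: bio-optical retrieval error structure beyond a
lognormal CV, autocorrelated cloud systems (a persistence parameter exists
but defaults off), spatial correlation between stations, under-ice blooms,
and within-bloom community succession. Passing tests therefore demonstrate
the pipeline's correctness and statistical calibration under the assumed
data structure — not that a 28% threshold is right for any particular sea.

## Numerical choices and degenerate inputs

* Units: 1 ug/L equals 1 mg/m3 for these pigments; the two appear where
  each community expects them and are numerically interchangeable.
* DOY is 1-based (Jan 1 = 1); leap years carry DOY 366.
* A proportion is undefined when `chl + pheo = 0`; such samples are read,
  flagged `below_detection`, and excluded from proportions rather than
  treated as 0 or 1.
* Boundary conventions, all chosen once and asserted in tests: ice masking
  is strictly-greater-than 15%; breakup days are strictly-below 15%;
  threshold classification is strict-less with equality to PB; the
  open-water rule is strictly-more-than five days.
* Result tables write numerics at 17 significant digits so CSV round-trips
  are bit-exact.
* Changepoint sequences shorter than 4 usable years are an error at the
  function level (and fall back to the pooled threshold at the pipeline
  level); both-zero-variance Welch inputs and empty calibration sets are
  errors, not silent NAs.

## Known limitations

* **Peak-day resolution is sampling-limited.** The daily curve interpolates
  between smoothed values at observation days, so the detected peak `t2`
  always falls on an observation day. Its error is bounded below by the
  distance from the true peak to the nearest cloud-free observation: at ~27
  observations spread over a 153-day season, some observation falls within
  3 days of the peak in only about three-quarters of years. Peak timing
  from sparse ocean-color series is honest to roughly the local sampling
  interval, not to the day. The suite measures this recovery rate at the
  default density; the noiseless-recovery and stage-boundary checks pass
  exactly.
* The smoothed curve can undershoot the raw observation range near series
  ends (a local linear fit extrapolates the local trend); values are not
  clamped.
* The AMOC penalty (`2 ln(n)` x pooled variance) is one reasonable choice
  among several; it is exposed as a configuration knob
  (`amoc_penalty_factor`) rather than hidden.
* Station-years are pooled in the group comparisons; no station-level
  random effects are modelled.

## Problem sizes used by the test suite

Unit and property tests run on curves of 10–200 grid days and a 13-station
x 7-year synthetic study (91 station-years). The statistical checks use
100 seeds for threshold recovery (n = 50 station-years each), 200 seeds for
peak recovery, 500 replicates for changepoint step recovery, and 1000 null
replicates for the Welch type-I calibration; all sizes were chosen to make
the Monte Carlo error small relative to the margins being asserted.
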