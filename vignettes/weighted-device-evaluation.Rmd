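---
title: "History-weighted evaluation of closed-loop neurostimulator behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{History-weighted evaluation of closed-loop neurostimulator behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnsmetrics)
```

## The problem

A responsive neurostimulator (RNS-type device) runs up to four configurable
second-order detection Patterns (A1, A2, B1, B2; A1/A2 compose first-order
Pattern A, B1/B2 Pattern B) against intracranial ECoG and delivers
stimulation therapies when one fires. Clinicians judge how well the
detectors are doing by reviewing the ECoG snippets the device stores and
marking whether each contains an electrographic ictal pattern (EIP). The
device, however, stores only about four 90-second recordings at a time,
overwrites the oldest when a new one arrives, and allocates storage slots to
particular trigger classes (Pattern A, Pattern B, magnet swipes, scheduled
recordings). The reviewed snippets are therefore a small, temporally and
compositionally biased sample of everything the device did.

The device also keeps aggregate logs that are far more complete but carry no
detail: an Event List of episode onsets (roughly 700 entries per
interrogation interval), an Activity Log of first-order counts per
interrogation (effectively complete), and daily/hourly Neurostimulator
History histograms (hourly counts saturate at 255 events). This package
implements the weighted-mean extrapolation that combines the two: snippet
review supplies per-stratum detector metrics, the histograms supply how
often each stratum actually occurred, and the product re-weights the
snippet metrics toward the device's true activity mix.

## The estimator

Reviewed recordings are classified per recording, using the first episode of
the recording: a Pattern-triggered recording with an annotated EIP is a true
positive in stratum (triggering Pattern, episode class), without one a false
positive; scheduled and magnet recordings sample brain activity
independently of the detector and supply the pooled negatives (false
negative when an EIP is present, true negative otherwise). Detector latency
is first detection time minus annotated EIP onset, kept only for true
positives whose episode was not already in progress at recording start;
negative latencies are legal and mean stimulation preceded the annotated
onset.

Per epoch and stratum $s = (P, C)$ with $P \in \{A1, A2, B1, B2\}$ and
$C \in \{E, LE\}$, the raw weight multiplies the ECoG trigger share by a
history share:

$$w(P, E) = \frac{n_{P,E}}{\sum_{P'} n_{P',E}} \times
            \frac{H_P}{\sum_{P'} H_{P'}}, \qquad
  w(P, LE) = \frac{n_{P,LE}}{\sum_{P'} n_{P',LE}} \times
            \frac{LE_H}{LE_H + E_H},$$

where $n_{P,C}$ counts reviewed Pattern-triggered recordings and $H_P$,
$E_H$, $LE_H$ are daily-history counts over the epoch (days flagged
`histogram_data_missing` excluded). The weighted epoch metric is
$\sum_s m_s \tilde w_s$ over surviving strata, with per-stratum metrics
$m_s$ (accuracy, sensitivity, specificity, mean latency) and weights
$\tilde w_s$ normalized to unit sum. The raw weights do not in general sum
to one (the episode weights scale with the Pattern's overall history share,
the long-episode weights with the long-episode share), so a reported
"accuracy" is only a proportion after normalization; `literal = TRUE`
preserves the unnormalized sum for audit.

### Negative attribution

Non-triggered recordings carry no triggering Pattern, so their TN/FN counts
cannot be placed in a stratum. Under the default `replicate_pooled` policy
each stratum receives a share of the pooled negatives proportional to its
share of triggered recordings ($tn_s = TN \cdot n_s/N$). This preserves
pooled totals exactly, keeps every supported stratum's accuracy defined, and
makes the stratum accuracy linear in the stratum's precision — so the
weighting corrects exactly the Pattern-mix component of storage bias. The
alternative `none` policy keeps negatives out of the strata entirely.

Two further conditioning rules apply in the weighted combination only:
strata with no EIP-bearing recording ($tp_s = 0$) are excluded from the
weighted sensitivity, and strata with no false positive ($fp_s = 0$) from
the weighted specificity. A missed EIP captured by a scheduled recording
says nothing about which Pattern should have caught it; apportioning
negatives into a stratum that has never shown an EIP yields a degenerate
stratum sensitivity of exactly 0 (and symmetrically a specificity of 1)
that reflects the apportionment, not the detector. In simulation this
artifact dominated the weighted sensitivity error, and excluding such
strata removes it without touching strata that carry real information.

These attribution rules are a genuinely open design point: stratified
sensitivity and specificity are only as meaningful as the negative
attribution behind them, because the pooled negatives are
detector-independent samples. We surface the policy as an argument and
report both standard and weighted values side by side.

### Undefined values

A metric with a zero denominator is `NA`, never 0 or 1. Weighted
combinations drop `NA` strata and renormalize the remaining weights; if no
stratum survives, the weighted value is `NA` and downstream agreement
statistics drop that epoch pairwise.

## Rates and dose

Total events per hour (pattern detections + saturations + magnet swipes)
and pattern detections per hour come from the Activity Log — the complete
source — over the full epoch duration. Stimulations per episode, the
percentage of days reaching the daily therapy limit, and weighted EIPs per
month come from daily histogram days with data present. Months are 30.44
days throughout.

Charge dose accumulates per-phase charge density: each pulse contributes
`current_ma x pulse_width_us x 1e-3 / electrode_area_cm2` µC/cm² (the
single-phase charge of a biphasic, charge-balanced pulse, the device
programming convention), each burst `floor(frequency x duration/1000)`
pulses, each counted therapy all bursts of its slot. The histogram does not
break therapy counts down by slot, so counts are apportioned to configured
slots in order — every episode receives its first therapy before any
receives its second — and dose is attributed to each burst's hemisphere.
The default horizon is 8.5 months post-implant.

## Agreement statistics

Differences are always standard − weighted. Bland–Altman uses the n−1
standard deviation and a 1.96 multiplier by default. The paired signed-rank
test uses the exact tie-aware null distribution (convolution of the
per-rank generating function) for up to 25 nonzero differences, and a
normal approximation with continuity and tie corrections above that; zero
differences are dropped. The exact/approximate switch point is exposed as
an argument since either convention appears in practice. Clinical
significance is a mean absolute difference above 5 percentage points,
evaluated per proportion metric. Quantiles are type-7 (linear
interpolation). Completeness percentages treat the Activity Log as the
source of truth, and the Pearson correlation of monthly device-derived EIP
estimates against reported seizures uses the standard t transform.

## The simulator

`simulation_config()` defines one simulated patient; cohorts are built by
iterating seeds, and all randomness flows from the single seed. The
generative model:

* EIPs are an inhomogeneous Poisson process (default 8/day) with optional
  sinusoidal multidien modulation (default period 20 days, amplitude 0.3,
  reflecting documented multidien rhythms in ictal activity).
* Each EIP is tested by the enabled Patterns in configured order with
  per-Pattern detection probabilities; the first to fire triggers the
  episode. Defaults are heterogeneous (0.35/0.15/0.25/0.10), giving an
  overall detection probability near 0.6.
* A background interictal process (default 20/day) carries the false
  triggers: each interictal event is falsely detected by Pattern $P$ with
  probability `false_trigger_rate_per_day[P] / interictal_rate_per_day`
  (defaults 2/1/1.5/0.5 per day), so configured false-trigger rates are
  honoured and must sum to at most the interictal rate.
* Episode class is Bernoulli (default 20% long episodes), independent of
  detection — the simplest structure satisfying the stratification.
* Detector latency is `gamma(shape 2, scale 1.25) − 0.5` seconds: mean 2 s
  with a small negative mass, so stimulation occasionally precedes the
  annotated onset. Latencies beyond the 30-s pre-trigger buffer surface as
  in-progress episodes.
* Scheduled recordings (2/day at fixed clock times) and magnet swipes
  (0.5/day) capture an undetected EIP with probability
  $1 - e^{-r_{missed} w}$, where $r_{missed}$ is the realized undetected-EIP
  rate and $w$ a state-persistence window (2 h scheduled, 6 h magnet).
  A literal 90-second-overlap model would make captured misses vanishingly
  rare and every sensitivity degenerate at 1; the persistence window stands
  in for the temporal clustering of ictal activity, and ties the false
  negative rate to detector quality, which is what gives sensitivity its
  signal.
* Therapies per triggered episode are drawn from a configurable
  distribution (default 90% one, 10% two) and delivered subject to the
  daily limit (default 2000). Interrogations are lognormal with mean
  30.3 h and median near 24 h (heavy right tail); a terminal read-out
  flushes the device.

`apply_device_constraints()` then degrades the stream: per interrogation
interval, recordings fill their reserved slots (default one each for
Pattern A, Pattern B, scheduled, magnet) with oldest-first overwriting and a
shared pool for unreserved slots; the Event List keeps the oldest 700
episodes per interval; hourly histogram counts saturate at 255 with the
day flagged missing; the Activity Log is always complete. Reviewer
annotations are perfect by default (`annotation_noise = 0`) because expert
review is the reference standard.

### Truth references

The truth object carries two distinct references:

* `true_metrics` — pooled metrics over the *complete recording stream*
  (every triggered, scheduled and magnet recording before any storage
  loss): the complete-review ideal. With unlimited storage the standard
  method reproduces these exactly.
* `true_event_metrics` — the detector's performance over *all neural
  events*, including EIPs no recording ever captured and interictal events
  that never triggered: the estimand a clinician actually cares about, and
  the reference for bias-recovery comparisons.

No snippet-based estimator can reach `true_event_metrics` without bias —
undetected EIPs are mostly unobservable, a limitation inherent to the
device — so the meaningful question is which estimator gets *closer*.

### What the simulator does and does not emulate

It reproduces the storage constraints, the interrogation process, trigger
competition, and reporting bias. It does not synthesize waveforms, model
seizure-network evolution under stimulation, battery or impedance effects,
or reviewer disagreement beyond a flip probability. Passing tests
demonstrate that the estimators behave as designed under this generative
model; they cannot certify performance on real patients, whose EIP dynamics
and detector interactions are richer.

## Known limitations and honest failure modes

Two properties one might hope for do **not** hold, for structural reasons,
and the validation suite documents them as failing expectations rather than
hiding them:

* *Exact equivalence in the full-data limit.* With unlimited storage the
  standard method equals the complete-review truth exactly, but the
  weighted method does not: the episode-weight formula scales by
  the Pattern's overall history share (not the episode-class share), so
  normalized weights equal the sample's stratum shares only when Pattern
  totals are equal; and no single apportionment of pooled negatives makes
  accuracy, sensitivity and specificity all collapse to their pooled
  values (constancy of stratum sensitivity forces $fn_s \propto tp_s$,
  of specificity $tn_s \propto fp_s$, and accuracy then still varies with
  the stratum's tp/fp ratio). The discrepancy is small (order $10^{-2}$)
  but not zero.
* *Uniform superiority of the weighted method.* Under storage bias the
  weighted estimator recovers true **accuracy** better than the standard
  one on average, with a disagreement direction that varies across
  configurations. For **sensitivity** it does not: missed EIPs carry no
  Pattern information, so the weighted sensitivity differs from the
  standard one only through the negative-apportionment artifact, and the
  standard pooled estimate — already close to a truth that sits near its
  ceiling — is typically closer. The honest summary is that history
  weighting corrects the activity-mix component of storage bias and
  nothing else.

## Problem sizes

The test suite simulates patients of 1–21 days for structural checks,
20-day cohorts for the full-data limit, and twenty 90-day patients with
contrasted detector families for the bias-recovery study; the acceptance
script evaluates a cohort of eight 90-day patients with three programming
epochs each. These sizes give stable cohort-level summaries while keeping
a full run in the order of minutes.
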