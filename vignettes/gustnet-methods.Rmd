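---
title: "Quantifying GABAergic gain control of brainstem taste coding with gustnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying GABAergic gain control of brainstem taste coding with gustnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gustnet)
```

## The scientific problem

Neurons in the rostral nucleus of the solitary tract (rNST), the first
central relay for taste, sit in a dense local GABAergic network. When that
network is activated optogenetically while taste stimuli flow over the
tongue, responses shrink — but *how* they shrink matters. Purely **divisive**
inhibition scales every response by a common factor and leaves the shape of
a neuron's chemosensitive profile (and hence the across-neuron code for
taste quality) intact; purely **subtractive** inhibition removes a fixed
amount from every response, clipping weak responses to zero and narrowing
tuning. gustnet implements the complete analysis chain used to distinguish
these regimes in extracellular recordings, together with the companion
brief-access licking analysis for chemogenetic activation of the same
network, and a calibrated synthetic-data generator so that every stage can
be validated by parameter recovery.

## Net responses and the response criterion

The primitive measurement is the **net response**: spikes during the 10-s
stimulus window minus spikes during the matched 10-s prestimulus
artificial-saliva (AS) window, averaged across trials
(`net_response()`). Baselines are computed separately per light condition
because activating the inhibitory network also depresses resting firing.
Negative nets are retained — suppression below baseline is real signal, and
a GABA taste cell can be silenced outright by a stimulus.

A response is **significant** (`apply_criterion()`) when it passes both
clauses of a joint criterion:

* net evoked rate ≥ 1 Hz (≥ 10 spikes over the 10-s window), and
* net ≥ 2.5 × the across-trial SD of the baseline-window counts.

Two readings of "SD of the response to AS" are defensible; we use the
across-trial sample SD of prestimulus counts computed per light condition,
with a pooled-across-stimuli option. A single trial leaves the SD undefined
and raises an explicit error rather than silently passing (a configurable
`fallback_sd` exists for screening). Historical exceptions to the criterion
(e.g., a clearly delayed bitter response) are supported only through an
`override` flag that is recorded in the output — never applied
automatically. For mouth-light (2-s) responses the same arithmetic runs
against an equal-length unstimulated window, since AS does not flow during
light stimulation.

Under a Poisson null with 3 trials and baselines up to 20 Hz the joint
criterion's false-positive rate stays below 10%, while a +4-Hz evoked
response over a 3-Hz baseline is detected in well over 90% of 2-trial
sessions; both operating characteristics are exercised in the test suite at
1,000 simulations each.

Multiunit traces are quantified separately (`multiunit_auc()`): counts are
leakily integrated with a 0.1-s time constant, the area under the
integrated trace during stimulation is adjusted by the immediately
preceding baseline, and responses are expressed relative to the maximum
control response of the subject (`normalize_to_max_control()`).

## Optotagging

ChR2-expressing (putative GABAergic) units are identified by their
pulse-locked responses to brain-directed light. For each pulse a 10-ms
half-open search window is opened at pulse onset (`pulse_metrics()`);
latency is the time to the *first* spike in the window, computed from raw
timestamps (no binning error), the following fraction counts windows with
at least one spike (bursts count once), and jitter is the sample SD of the
latencies. Metrics are averaged across repeated trains at the same nominal
frequency.

No numeric tagging thresholds are canonical, so `classify_unit()` defaults
— following ≥ 0.75 at the lowest tested frequency, latency ≤ 10 ms, jitter
≤ 2 ms — sit far from both observed distributions (tagged populations
follow ~96% of 1-Hz pulses with sub-millisecond jitter; untagged units
follow at chance). The lowest tested frequency is used because faithful
low-frequency following is the operative benchmark; thresholds are
config-exposed and the margin to each is reported so borderline units are
visible. The sub-label is `TASTE` when any taste response passes the
criterion, `MECH` for units flagged as responsive to oral mechanical
stimulation (a label stub — no mechanical simulation is attempted), else
`UNR`. On 500 simulated units at calibration defaults classification
accuracy exceeds 99%.

## Breadth of tuning

Three measures (`tuning_metrics()`):

1. the number of stimuli with significant responses;
2. the noise:signal ratio — second-best / best response over the panel's
   included stimuli, negatives floored at zero. MSGai is excluded by
   default (at 600 mM it co-activates sugar/umami and amiloride-insensitive
   sodium cells, making the ratio uninterpretable); the exclusion list
   lives in the `stimulus_panel`, not in code;
3. response entropy `H = -1.43 * sum(P_i log10 P_i)` where `P_i` is each
   stimulus's share of the summed responses. `K = 1.43 ≈ 1/log10(5)` scales
   a uniform five-stimulus profile to ~1. Entropy cannot accommodate zeros
   or negatives, so responses ≤ 0 are replaced by a very small value; we
   use `1e-6 ×` the sum of positive responses (configurable). An entirely
   unresponsive profile is flagged undefined rather than forced to a
   number.

Both H and N:S are scale-invariant, and n-significant under light is, on
average, no larger than under control for any divisive generator — the
"sharpening" direction.

## Clustering, stability, and the ensemble code

Profiles are clustered (`cluster_profiles()`) on `1 − Pearson r` distances
with average linkage, so clustering reflects profile *shape*, not
magnitude. Constant profiles have no defined correlation and are excluded
with a warning (mirroring the practice of omitting such neurons).
The amalgamation schedule (scree) is returned; the number of groups is a
judgment call, so no automatic cut is applied — `cluster_cut()` accepts a
chosen `k` or offers a largest-gap heuristic. Average-linkage heights are
verified against a brute-force agglomeration oracle in the tests. The tree
exports to newick via `cluster_newick()`.

Per-unit **profile stability** (`profile_stability()`) is the Pearson
correlation between a unit's control and light profiles: exactly 1 under
pure division, and ~0.96 on average for the calibrated noisy generator when
computed, as in the recordings, over units still responsive under light.

The **ensemble** analysis (`ensemble_mds()`) treats each stimulus ×
condition as a point described by its net responses across neurons:
stimulus-by-stimulus correlations within condition, within-stimulus
correlations across conditions, and classical (metric) MDS on the pooled
`1 − r` distances. The original analysis used a commercial package whose
MDS flavor is unstated; classical scaling was chosen for determinism (it
has a closed-form eigendecomposition, verified against a direct oracle in
the tests), coordinates are centered, and each axis's sign is fixed so the
first stimulus's control point is nonnegative. Profile correlations use
net responses; over a fixed 10-s window this is equivalent to using rates.

## Divisive vs subtractive decomposition

`tuning_curve_assembly()` orders one neuron's control responses from
largest to smallest (ties broken by panel order and recorded), permutes the
light-condition responses by the *control* ordering — never independently
sorted — and normalizes both vectors by the maximum control response.
`threshold_linear_fit()` then regresses light on control by OLS. Slope 1 /
intercept 0 means no effect; slope < 1 is divisive, a negative intercept
subtractive. The `population_mean` scope averages each rank across neurons
before fitting — the headline decomposition — while per-neuron fits are
reported alongside. Points that are ordered, normalized and averaged are
not independent, so the slope ≠ 1 / intercept ≠ 0 p-values are labeled
descriptive in the output.

Two estimator properties are worth knowing and are covered by tests:

* **Ordering attenuation.** Ordering and max-normalizing *noisy* control
  responses inflates the top rank and deflates the rest, biasing the
  fitted slope below the true gain. At the calibrated rate scale (~1.2 Hz
  baselines, tens of net spikes per window) the bias is ~0.01–0.02; at
  much noisier scales it can be substantial.
* **Floor effects.** When responses are clipped at a firing floor,
  subtraction masquerades as division: the flattened low end *lowers* the
  fitted slope and pulls the intercept toward zero. Net responses are
  therefore kept negative by default; an optional clip-at-zero mode exists
  for studying the floor effect itself.

Mouth-light frequency series (2-s trains at ~2–50 Hz, a graded surrogate
taste stimulus) run through the identical machinery with frequencies in
place of stimuli.

## Brief-access licking

For each mouse × session, `modal_ili()` takes the mode of the interlick
interval histogram restricted to a within-burst band. The band (50–250 ms)
and bin width (5 ms) are unspecified in the source procedure; the band
excludes pauses and double-cranks, 5-ms bins balance resolution against
counts, ties break toward the smaller ILI and are flagged, and both are
configurable. The **standardized lick ratio** (`standardized_lick_ratio()`)
divides a trial's licks by the maximum possible licks in the access window
at the modal ILI, compensating for drift in lick rate across sessions.
Quinine is instead expressed relative to same-session water licks
(`water_ratio()`); water trials must be in-session — no cross-session
fallback. Mice sampling any concentration on fewer than 2 trials per
session are excluded with a logged message.

Concentration-response curves use the log-logistic equation
`Y = Min + (Max − Min) / (1 + 10^((LogEC50 − X) * Hill))` with
`X = log10(concentration)` in each stimulus's own units
(`fit_logistic()`). Fitting is nonlinear least squares with multi-start
initialization (asymptotes from the data extremes, a LogEC50 grid across
the tested range, Hill ∈ {±0.5, ±1, ±2}); the best converged start wins,
and total failure returns `converged = FALSE` rather than an error —
some response patterns (quinine under strong network activation) genuinely
have no sigmoid fit. Curves are fitted to group (per-concentration) means
by default, with per-mouse fitting optional. Paired saline-vs-CNO
comparisons per concentration are plain paired t tests with Bonferroni
adjustment — deliberately delegated to standard routines
(`paired_concentration_tests()`).

## The synthetic generator and its calibration

`simulate_session()` generates piecewise-homogeneous Poisson spiking:
baseline at each unit's spontaneous rate, stimulus windows at baseline +
evoked rate, and under brain light the evoked rate becomes
`max(0, g·evoked − β)` while the spontaneous rate is scaled by `g_spont`
(default `= g`, since network activation also depresses resting activity;
negative evoked rates are clamped at zero with a warning). ChR2 units add
one pulse-locked spike per brain-light pulse with probability
`follow_prob`, at a Normal(latency, jitter) delay. A 1-ms absolute
refractory period is enforced by default (no spike-generating model is
canonical here; Poisson with a refractory floor is the minimal standard
choice). One master seed spawns per-unit substreams, so adding a unit
never perturbs the others, and identical inputs reproduce the dataset
bit-for-bit — the `ground_truth` element carries everything needed to do
so. Whether brain light covers the prestimulus window is exposed as a flag
(default: yes, covering prestim + stimulus, which is why light-trial
baselines are computed separately).

Calibration defaults come from printed population summaries of the
recordings this pipeline targets: ~96% per-pulse following with
5.9 ± 0.72 ms latency/jitter for ChR2 units; AS-period firing near 1.2 Hz;
best-stimulus responses of a few tens of net spikes per 10-s window; GABA
taste cells responding at ~0.37× the gain of non-GABA taste cells; roughly
half of orally unresponsive GABA cells silent at rest; and sideband evoked
rates drawn so the population's second-best/best ratio centers near 0.27
and control entropy near 0.54. Mouth-light series use an
entrained-response model — each mouth pulse is followed with probability
`rate_fun(f)/f` — whose default frequency-response rises to a peak near
15 Hz and then declines, the saturating shape seen when light frequency
stands in for concentration.

`simulate_lick_study()` draws each trial's target lick ratio from the
mouse's logistic concentration-response (default: half-max near 228 mM
sucrose under saline, right-shifted under CNO) plus Gaussian noise
(σ = 0.05), converts it to a lick count at the modal ILI (default
115.5 ms), and lays timestamps at Normal-distributed ILIs truncated above
50 ms with occasional pauses.

What the generator does **not** emulate — and what passing recovery tests
therefore cannot certify on real data: non-Poisson spike-train statistics
(bursting, adaptation, slow drifts), response latency structure and
within-trial dynamics, correlated noise across simultaneously recorded
units, oral somatosensory (mechanical) responses, electrode drift or
isolation failures, and session-level behavioral state beyond the modal
ILI. Recovery results certify the *analysis chain*, under the stated
statistical assumptions, not the biology.

## Validation problem sizes

The test suite validates, among other properties: the no-inhibition
identity (slope 1, intercept 0, machine precision); criterion arithmetic at
the 10-spike boundary; entropy against direct formula evaluation on 1,000
random profiles (1e-10); average-linkage heights against brute-force
agglomeration on panels of up to 8 profiles (1e-10); divisive recovery
(g = 0.37, 40 neurons, 100 replicate sessions — median slope within ±0.05,
median |intercept| ≤ 0.05); subtractive recovery (β = 1 Hz against a fixed
8/6/4.4/3.2/2.2-Hz profile, 4 trials, 50 replicates — slope within ±0.03 of
1, intercept within ±0.03 of −β/max); optotag accuracy on 500 units
(≥ 99%); criterion operating characteristics at 1,000 simulations each;
profile stability (exact under pure division; mean r ≥ 0.9 over 50 noisy
units); and EC50 recovery (6 concentrations × 4 trials, 200 replicates —
median relative error ≤ 15%, with a +0.3 LogEC50 shift detected in ≥ 95%
of replicates). The subtractive-recovery profile was fixed with gaps large
relative to counting noise so that the test isolates the decomposition
identity rather than ordering noise, which is covered separately.

## Known limitations

* The threshold-linear decomposition is a two-parameter line; mixed or
  nonlinear (e.g., sigmoidal) suppression models are out of scope.
* Cluster count selection is intentionally manual; the largest-gap
  heuristic is a convenience, not a recommendation.
* The G+MECH class is a label stub; no somatosensory responses are
  simulated or analyzed.
* Inference on ordered, averaged regression points is descriptive only;
  the package reports it as such rather than pretending independence.
* Lick timestamps are generated count-first; a trial's last lick can
  slightly overrun the nominal access window. Lick-count measures are
  unaffected.
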