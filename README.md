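# gustnet

Analysis of taste-evoked spike trains in the rostral nucleus of the
solitary tract (rNST) under optogenetic activation of the local GABAergic
network, plus the companion brief-access licking analysis for chemogenetic
activation of the same network.

The rNST is the first central relay for taste. Activating its inhibitory
network while tastants flow over the tongue suppresses responses; the
scientific question is *how*. gustnet implements the full analysis chain a
physiologist needs to answer it:

* **Response quantification** — net responses (stimulus-window spikes minus
  the matched 10-s artificial-saliva prestimulus window, per light
  condition) and the joint response criterion: net ≥ 1 Hz **and** ≥ 2.5 ×
  the across-trial SD of baseline counts; plus a leaky-integrator
  (τ = 0.1 s) AUC measure for multiunit traces.
* **Optotagging** — per-pulse first-spike latency, jitter and following
  fraction in a 10-ms search window, and classification into putative GABA
  (G+) vs non-GABA (G−) cells with TASTE / UNR / MECH sub-labels.
* **Breadth of tuning** — significant-response counts, the noise:signal
  ratio (second-best / best, with panel-driven exclusions), and response
  entropy `H = −1.43 Σ P_i log10 P_i`.
* **Population structure** — hierarchical clustering of chemosensitive
  profiles on `1 − Pearson r` with average linkage (newick export),
  per-unit cross-condition profile stability, and across-neuron ensemble
  correlations with classical multidimensional scaling.
* **Gain decomposition** — the threshold-linear fit: order control
  responses descending, normalize both conditions to the maximum control
  response, regress light on control. Slope < 1 ⇒ divisive inhibition;
  negative intercept ⇒ subtractive.
* **Behavior** — modal interlick interval, standardized lick ratios,
  water-relative quinine ratios, and log-logistic concentration-response
  fits `Y = Min + (Max−Min)/(1 + 10^((LogEC50−X)·Hill))` with multi-start
  nonlinear least squares.
* **Synthetic data** — a calibrated, seeded generator (Poisson spiking,
  pulse-locked ChR2 responses, divisive/subtractive suppression, rhythmic
  lick trains) with full ground truth, so every stage is validated by
  parameter recovery. `run_all()` chains simulate → quantify → optotag →
  coding → gain → behavior with a digest-based run manifest.

## Worked example

Simulate a small recorded session — 12 non-GABA taste cells, 4 GABA taste
cells, 4 orally unresponsive GABA cells, true divisive gain 0.5 — and run
the main stages:

```r
library(gustnet)

panel <- standard_panel("A")                       # SUC MSGai NaCl CIT BIT
specs <- population_specs(12, 4, 4, panel, seed = 42, gain = 0.5)
sim   <- simulate_session(specs, panel, trial_plan(panel), seed = 42)

prof <- flag_responses(response_profile(sim$spikes$gm001, sim$trials, panel))
subset(as.data.frame(prof), light_condition == "control",
       select = c(stimulus, net_spikes_per_window, baseline_sd, significant))
#>   stimulus net_spikes_per_window baseline_sd significant
#> 1      SUC                  22.5    1.414214        TRUE
#> 3    MSGai                   6.5    2.828427       FALSE
#> 5     NaCl                   4.5    2.828427       FALSE
#> 7      CIT                   8.0    7.071068       FALSE
#> 9      BIT                   4.5    2.121320       FALSE
```

This sucrose-best cell passes the criterion only for SUC: 22.5 net spikes
clears both the 10-spike rate clause and 2.5 × 1.41 baseline SDs. Optotag
metrics separate the classes:

```r
classify_unit(pulse_metrics(sim$spikes$gm001, sim$pulses), prof)
#> <optotag_class> gm001: G_minus / TASTE (follow 0.00 at 1 Hz, ...)
gpt <- sim$spikes$gpt001
classify_unit(pulse_metrics(gpt, sim$pulses),
              flag_responses(response_profile(gpt, sim$trials, panel)))
#> <optotag_class> gpt001: G_plus / TASTE (follow 0.95 at 1 Hz,
#>                                        latency 6.0 ms, jitter 0.57 ms)
```

The GABA cell follows 95% of 1-Hz light pulses at 6-ms latency with
sub-millisecond jitter; the non-GABA cell never follows. Tuning narrows
under light, and the population decomposition recovers the programmed
divisive gain:

```r
rbind(tuning_metrics(prof, "control", panel),
      tuning_metrics(prof, "light_br", panel))[,
  c("light_condition", "n_significant", "ns_ratio", "entropy_H")]
#>  light_condition n_significant  ns_ratio entropy_H
#>          control             1 0.3555556 0.8603372
#>         light_br             1 0.3448276 0.6590718

profs <- lapply(sim$spikes[1:12], response_profile,
                trials = sim$trials, panel = panel)
gain_from_profiles(profs)
#> <gain_fit> (population_mean, n = 5): slope 0.538, intercept -0.002, r^2 0.970
mean(profile_stability(profs)$r)
#> [1] 0.943
```

A fitted slope of 0.54 with an intercept near zero — against a ground
truth gain of 0.5 — says the programmed suppression is read out as almost
purely divisive, while profile correlations near 1 show the tuning shapes
survived. The same calls run on real data loaded with `read_spikes()`,
`read_trials()`, `read_pulses()` and `read_licks()` (CSV schemas in their
help pages; JSON sidecars via `read_sidecar()`).

The behavioral arm works the same way: `simulate_lick_study()` →
`lick_metrics()` → `fit_logistic()` recovers EC50s and detects
drug-induced shifts of the concentration-response curve.

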