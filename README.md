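# critperturb

Simulation and analysis of single-neuron perturbation experiments in
critically balanced cortical networks, for computational neuroscientists
studying how a handful of extra action potentials in one layer-2/3
pyramidal neuron propagates through its neighbourhood while ongoing
activity is dominated by scale-invariant avalanches.

The package bundles four things that are usually scattered across ad-hoc
scripts:

1. **A 2D excitable-lattice simulator.** Units on a torus with
   distance-dependent connectivity
   `Pconn(r) = 0.05 exp(-r²/(2·100²)) + 0.03 exp(-r/290)` (r in μm) follow
   rest → active → refractory dynamics in 2-ms steps; a resting unit fires
   with probability `1 − (1−Ppoiss)(1−pstim)(1−Ptrans)^m`. The branching
   parameter σ controls criticality through the degree-normalised
   transmission probability `Ptrans = σ/k̄`. Stimulation protocols
   (10 targets, 100-ms pulses, interleaved trials) produce spike-count
   recordings restricted to the central 456×456-μm field of view.
2. **Perturbation-response statistics.** Trial windowing (6-frame windows
   at 22 ms/frame), responder classification (one-tailed mean-difference z
   at α = 2.5%, Welch variant, FDR control), power-law response-scaling
   fits `⟨response⟩ ∝ (TC spike count)^h`, mean-matched Fano factors,
   correlation analyses, trial splits, distance profiles.
3. **Avalanche statistics.** Soft-thresholding `pΘ(t) = max(p(t)−Θ, 0)`
   with data-driven (log-normal) threshold selection, temporal
   coarse-graining into k-phase ensembles, epoch extraction, and the
   double power-law fit `S(d) = C d^χsh [1+(d/Φ)^γ]^((χlg−χsh)/γ)` of mean
   avalanche size versus duration (γ fixed at 4).
4. **Decoding of perturbation origin.** Gradient-boosted trees (xgboost)
   and random forests (ranger) on non-target spike counts, repeated
   stratified 80/20 evaluation, Shapley-guided iterative neuron
   elimination, spatial exclusion zones, temporal profiles, and baseline
   pseudo-trial decoding.

A synthetic-recording generator with planted ground truth (negative
binomial baselines, AR(1) rate modulation, responders with known scaling
exponent) backs parameter-recovery tests for every stage.

## Worked example

```r
library(critperturb)

# a reduced lattice with the documented degree-matched kernel (k ~ 43)
net <- build_lattice(side = 120, fov_side = 38,
                     trunc_radius_um = trunc_radius_for_degree(43),
                     seed = 1)
cs <- find_critical_sigma(net, seed = 2)
cs
#> critical_sigma: sigma_c = 1.0278 (criterion: survival)

# the three dynamical regimes of the drive-response curve
drive_response_curve(net, sigma = 0.5, seed = 5)$gamma        # 0.996
drive_response_curve(net, sigma = cs$sigma_c, seed = 5)$gamma # 0.271
drive_response_curve(net, sigma = 1.2, seed = 5)$gamma        # 0.011
```

The three slopes are the signature of the phase transition: activity grows
linearly with drive in the subcritical network (γ ≈ 1), saturates in the
supercritical one (γ ≈ 0), and follows the two-dimensional
directed-percolation power law (γ ≈ 0.285, finite-size reduced here) at
the calibrated critical point.

```r
# a stimulation experiment at criticality, analysed end to end
net <- calibrate_poisson_drive(set_branching(net, cs$sigma_c),
                               target_rate = 0.05, seed = 3)
tcs <- select_tcs(net, 10, seed = 4)
rec <- bin_to_frames(run_protocol(net,
         stim_protocol(tcs, iti_steps = 750, trials_per_tc = 50), seed = 5))
cnt <- remove_outlier_trials(extract_trial_counts(rec))
tab <- classify_responders(cnt)          # PosR / NegR / NonR per (TC, cell)
scaling_fit(cnt, tab, mode = "per_neuron")
#> scaling_fit (PosR, per_neuron, stim): h = 0.224 [0.019, 0.429], R2 = 0.696
```

`h` is the exponent of the mean positive-responder spike count against the
target's evoked spike count (bins 1..7) — a compressive (< 1) response
characteristic of amplification near criticality. On synthetic recordings
with a planted exponent the fit recovers it with bias < 0.03 and > 90% CI
coverage (see the test suite).

```r
# decode the stimulated target from a recording with planted signatures
gt <- fixture_ground_truth(n_cells = 150, n_tc = 5, h_true = 0.3, seed = 7)
rec_fx <- make_recording(gt, trials_per_tc = 60, seed = 8)
train_eval(build_dataset(rec_fx), "xgb", n_splits = 20, nrounds = 50,
           seed = 9)
#> decoding_result (xgb, 20 splits): accuracy 0.999 +/- 0.001 (chance 0.200), macro F1 0.999
```

A thin command-line wrapper over the same functions ships in
`inst/cli/critperturb.R`
(`Rscript critperturb.R {sim|fixtures|responders|avalanches|decode} ...`).

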