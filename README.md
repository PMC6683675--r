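# tastespike

Analysis of taste-evoked spike trains recorded in the gustatory
brainstem of freely licking rodents.

In brief-access taste testing an animal licks a spout at the
species-typical 6–7 Hz rhythm; a taste trial is a block of five
consecutive reinforced licks, separated from the next trial by five
artificial-saliva rinse licks, each delivered after 4–6 dry licks.
Single units recorded during such sessions mix three things: baseline
firing, firing locked to the lick cycle, and taste-evoked rate
changes. `tastespike` implements the standard analysis chain for this
preparation:

* **Response detection** at two time scales, by sliding-window
  threshold crossing against the pre-trial baseline (mean ± 2 SD for
  three consecutive windows): *five-lick* responses (100 ms window,
  20 ms steps, 4 s horizon) and *lick-by-lick* responses (10 ms
  window, 2 ms steps, 170 ms horizon, 50 ms pre-lick baseline), each
  reported with sign, magnitude (sps), latency and duration.
* **Spike–lick coherence**: Welch magnitude-squared coherence of the
  1 ms-binned point processes, summarized as the peak in the 4–9 Hz
  licking band, with a circular time-shift null.
* **Cell classification** into taste / lick / anti-lick / lick-bout /
  lick-anti-lick mix / non-responsive, with taste precedence.
* **Licking microstructure**: per-stimulus trial counts, inter-lick
  intervals, intra-trial pauses, five-lick completion times.
* **Metric-space (Victor–Purpura) analysis** of taste coding:
  spike-train edit distances `D_count` and `D_spike[q]`
  (insert/delete = 1, move = q·Δt; compiled dynamic program), a
  nearest-mean classifier over a q grid, plug-in mutual information
  `H(q)` with `H_max`, `H_count`, label-shuffle (40×) and spike-
  exchange (10×) controls, coding-mode classification, and the
  0.2–2 s response-window sweep.
* **Group statistics** (lean vs diet-induced-obese presets):
  Mann-Whitney U, chi-square on class proportions,
  Kolmogorov-Smirnov on coding proportions, t tests on response
  parameters; end-to-end `run_pipeline()`.
* A **seeded synthetic session generator** (`generate_session()`)
  whose `lean`/`DIO` presets encode the published group differences,
  providing ground truth for every stage — the whole package runs
  with no external data.

## Worked example

```r
library(tastespike)

g <- generate_session("lean", n_cells = 6, trials_per_stimulus = 6, seed = 42)
s <- g$session
s
#> session lean_synth (lean): 6 units, 4027 licks, 72 trials, 648 s

det <- detect_responses(s)
head(subset(det, significant), 4)
#>    unit_id stimulus_id    timescale       sign magnitude latency duration
#> 9     u001         Caf    five_lick excitatory      10.3   3.140     0.10
#> 15    u001       Clm J    five_lick excitatory      11.5   2.760     0.10
#> 25    u002       Hi Su    five_lick excitatory      12.2   0.100     0.10
#> 26    u002       Hi Su lick_by_lick excitatory      20.7   0.062     0.01
```

Unit `u002` is a generated taste cell (ground truth is in `g$specs`):
among its detected responses is a 40 sps five-lick response to low
sucrose at 220 ms latency lasting 1.64 s, and short-latency
lick-by-lick responses (e.g. 51 sps at 16 ms to low grape juice). Its
spike–lick coherence and taste information:

```r
lick_coherence(s$units[[2]], s$licks, duration = s$duration,
               n_shifts = 200, seed = 3)
#> coherence_result: peak 0.542 at 6.35 Hz (null 95% = 0.019, significant)

msa(extract_responses(s, "u002", traditional_quartet(), window = 2), seed = 7)
#> info_result: H_max 1.358 bits at q = 2 1/s; H_count 0.868 bits
#>   shuffle 0.615 +/- 0.153, exchange 0.850; coding class: spike_timing
```

The cell is significantly phase-locked to licking (peak coherence
0.54 at the 6.3 Hz lick rate, far above the 0.019 circular-shift
threshold) and conveys 1.36 bits about the traditional tastant
quartet, clearing the shuffled floor (0.62 ± 0.15 bits); since its
`H_max` (at `q` = 2 s⁻¹) exceeds both the count-only information
(0.87 bits) and the exchange control (0.85 bits), spike timing
contributes to its coding. Licking microstructure:

```r
head(lick_behavior_metrics(s), 3)
#>   stimulus_id trials   ili n_pauses pause_length five_lick_time
#> 1       Lo Su      6 0.152        0           NA          0.645
#> 2       Clm J      6 0.155        0           NA          0.610
#> 3          AS      6 0.149        0           NA          0.607
```

(~0.15 s inter-lick intervals, five licks completed in ~0.6 s.)
A full two-group run is one call:

```r
res <- run_pipeline(list(n_cells = 50, out_dir = "run1"), seed = 1)
res$comparison   # U / chi-square / t / KS table, lean vs DIO
```

A command-line interface with `synth`, `validate`, `dedupe`, `detect`,
`coherence`, `behavior`, `msa` and `run` subcommands lives at
`inst/cli/tastespike.R` (after installation:
`Rscript $(Rscript -e 'cat(system.file("cli/tastespike.R", package="tastespike"))') synth --preset lean --n-cells 10 --out ses1`).

## Vignette

`vignettes/methods.Rmd` documents the model behind the synthetic
world (rates, lick-phase gain, response kernels, excitability drift),
every numerical choice in the detectors and the information analysis
(SD floors, latency conventions, shuffle-maximum null), the preset
calibrations, and what the synthetic benchmarks do and do not
establish.
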