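---
title: "Models and methods behind tastespike"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tastespike}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`tastespike` analyzes single-unit recordings made in the gustatory
brainstem of freely licking rodents during brief-access taste testing:
an animal licks a spout, every fifth reinforced lick block delivers a
tastant, and artificial-saliva rinse licks on a variable-ratio-5
schedule separate trials. The package implements the full analysis
chain for such sessions — response detection at two time scales,
spike–lick coherence, lick-relation cell classification, licking
microstructure, and metric-space temporal-coding analysis — together
with a seeded synthetic session generator with `lean` and `DIO`
(diet-induced obese) presets, so every stage can be exercised and
validated with no external data.

# The synthetic world

## Licking

Rodents lick in bouts at 6–7 Hz. `generate_lick_train()` draws
within-bout inter-lick intervals (ILIs) from a truncated normal
(floor 50 ms, the motor limit); bout lengths are lognormal with a
median near 90 licks, and pauses mix short rests (~1–4 s) with
occasional long (15–30 s) lick-free periods. Two of these choices
deserve comment:

* *Long bouts.* Published microstructure tables for this preparation
  report only a handful of intra-trial pauses per several hundred
  trials for most tastants, which implies near-continuous licking on
  the scale of tens of seconds. Short bouts would also place bout-end
  rate transients inside the 4 s post-trial scan window of the
  response detector, where they masquerade as taste responses.
* *Occasional long rests* exist so that the spontaneous-rate
  estimator (which needs 14 s of no licking) has material to work on.

Trials are scheduled on the lick train exactly as in the behavioral
protocol: five consecutive reinforced licks per trial, then five rinse
licks, each preceded by 4–6 dry licks (uniform draw); stimuli run in
shuffled blocks with low sucrose always first (it is the motivating
starter stimulus). The default panel has the twelve canonical stimuli
(five traditional tastants at the usual concentrations, six
naturalistic tastants, and the artificial-saliva rinse as a stimulus
in its own right).

## Spike trains

Each unit is an inhomogeneous Poisson process realized by thinning:

    lambda(t) = [ base(t) * g_phase(t) + kernels(t) + edge(t) ] * g_drift(t)

* `base(t)` is the spontaneous rate outside lick bouts and the in-bout
  baseline inside. For lean taste cells these default to 12.18 and
  18.9 sps; for DIO, 15.4 and 13.7 sps (the published group means,
  which notably reverse the in-bout elevation in DIO).
* `g_phase` is a von Mises-shaped gain locked to lick phase with unit
  circular mean, so modulation does not change the mean rate. Its
  concentration (`lick_mod_depth`) is the knob behind spike–lick
  coherence.
* `kernels` are rectangular rate steps per (stimulus, cell): onset at
  `latency` after the trial's first lick (five-lick time scale) or
  after every reinforced lick (lick-by-lick time scale), lasting
  `duration`, of the given signed `magnitude`. A rectangle is the
  simplest shape consistent with the detector's definitions; nothing
  downstream assumes it.
* `edge` is an optional peri-bout bump used by anti-lick cells
  (suppressed during bouts, phasic increases at bout edges).
* `g_drift` is a slow multiplicative excitability drift: lognormal
  knots (mean 1, configurable CV) every 60 s, linearly interpolated.
  This term is essential realism: real across-trial baseline
  variability is strongly super-Poisson, and the published 2-SD
  detection rule is only workable against such variability (see
  below). A plain `cell_spec()` has drift 0 (pure Poisson); the group
  presets use CV 0.4.

A 2 ms refractory period is enforced by deletion (matching the
unit-isolation criterion) and all event times are quantized to the
25 µs acquisition grid. An inhibitory kernel that would drive the rate
negative is rejected at specification time.

## Group presets

`group_preset("lean")` / `group_preset("DIO")` encode the published
group differences as sampling distributions: cell-class proportions
from the published taxonomy counts (74/174/65/9/43/150 of 515 lean;
49/65/12/3/19/80 of 228 DIO for taste / lick / anti-lick / lick-bout /
mix / non-responsive); spontaneous and baseline rates as above; DIO
lick-by-lick kernels smaller (30 vs 13 sps mean), later (12 vs 28 ms)
and shorter (75 vs 35 ms); DIO five-lick kernels smaller (16.4 vs
11 sps generative mean), later (0.25 vs 0.40 s) and shorter (1.4 vs
0.55 s); DIO more narrowly tuned (per-stimulus response probability
0.65 vs 0.40); DIO licking slightly slower (mean ILI 0.165 vs
0.155 s). Inhibitory kernel magnitudes are capped at just under half
the cell's rate floor so that even overlapping tails of consecutive
trials' kernels cannot drive the rate negative.

Three preset families are *calibrated fixtures*, documented here
rather than asserted as universal truths:

* *Modulation depths* are tuned so that group coherence medians sit
  near the published values (taste cells ≈ 0.345 lean / 0.163 DIO)
  under the default coherence estimator. Coherence values depend on
  estimator parameters, so the calibration is tied to the defaults.
* *Generative magnitudes* are the latent kernel heights, not the
  detector's measurements. The detector only reports responses that
  clear its threshold, so the mean of *detected* magnitudes is
  selection-biased upward relative to the generative mean; DIO
  five-lick generative magnitude (11 sps) was chosen so detected DIO
  means land near the published table values.
* *Across-stimulus heterogeneity* (magnitude CV 1.0) reflects the
  graded best-stimulus tuning of real gustatory neurons and is what
  gives taste cells their discriminability in the metric-space
  analysis; homogeneous tuning would make the four-tastant
  classification nearly impossible at realistic trial counts.

Phasic lick-by-lick responders are drawn with a reduced in-bout
baseline (factor 0.45) and a preferred phase just after the lick,
matching the sparse-background raster profile of published examples —
and, importantly, making their responses detectable by the
conservative lick-by-lick rule (below).

What a green test on this world does *not* establish: the generator
has no electrode drift, no sorting errors, no correlated noise across
units, no session-length fatigue beyond the drift term, no
stimulus-specific licking differences (real aversive tastants induce
pauses), and rectangular kernels only. Conclusions about the method's
behavior on real data must respect those gaps.

# Response detection

## Five-lick detector

Baseline is the firing rate in the 1 s before the first reinforced
lick, mean and SD across trials. A 100 ms window steps in 20 ms
increments across the 4 s after trial onset; a response onsets when
three consecutive windows are beyond mean ± 2 SD, latency is the
trailing edge of the first such window (the word in the source
protocol is read as "trailing"; a `leading` switch exists), the scan
continues to the first window back inside bounds, duration runs from
the latency to the trailing edge of the last significant window, and
magnitude is the mean evoked rate minus baseline.

Numerical choices:

* *SD floor.* The across-trial SD is replaced by
  `sqrt(2 * baseline / (n_trials * window))` (min 0.5 sps) whenever it
  is smaller. At the 20-trial reference design this floor coincides
  with the across-trial Poisson SD, so it changes nothing there; at
  small trial counts it prevents the (5-df, badly underdispersed) SD
  estimate from collapsing the threshold. Flagged in the result.
* *Magnitude interval.* The onset convention already excludes the
  first, partially covered window; symmetrically the last significant
  window overhangs the true response by up to one width, so its final
  window is trimmed from the magnitude interval (reported duration is
  unchanged). Without the trim, recovered magnitudes are biased low
  by ~15%.
* Windows are half-open `[t, t + w)`; times are zero-based at trial
  onset.

Empirically (frozen as regression bounds in the acceptance suite): at
20 trials the no-kernel false-positive rate is ≈ 7% per scan; median
recovery error over the magnitude × latency × duration grid is ≤ 3
window steps in latency and ≤ 15% in magnitude. At the 6-trial
session default the rule is markedly weaker (≈ 6% per scan but with
much lower power and, across a 12-stimulus panel, most cells acquire
at least one spurious response). This is a property of the rule, not
of the implementation; classification-fidelity tests therefore run at
trial counts in the validated regime.

## Lick-by-lick detector

Each reinforced lick is a sweep; a 10 ms window steps in 2 ms
increments over the 170 ms after the lick, against a baseline from the
50 ms before each lick (mean and SD across sweeps). At typical rates a
50 ms window holds under one spike, so the across-sweep SD is large
and the criterion is conservative: it resolves only phasic responses
rising well above a sparse pre-lick background. That is exactly the
published firing profile of lick-by-lick responders, and the generator
draws such cells accordingly. The one structural consequence is that
cells with a *high* pre-lick rate can essentially never show a
detectable lick-by-lick response — which also protects strongly
phase-locked lick cells from being misread as taste-responsive at this
time scale.

# Spike–lick coherence

Both point processes are binned at 1 ms; magnitude-squared coherence
is estimated by Welch's method (Hann taper, 4.096 s segments, 50%
overlap, frequency resolution 0.244 Hz), and the statistic is the peak
within 4–9 Hz, the licking band. Absolute coherence values depend on
these parameters; the preset calibration is tied to them.

Significance uses a circular time-shift null: the spike segment
spectra are rotated against the lick spectra by random whole-segment
offsets (200 by default), which preserves both autospectra exactly
while destroying spike–lick alignment; the 95th percentile of the null
peak is the threshold. Restricting the shift to whole segments is what
lets the null reuse the precomputed segment FFTs (hundreds of times
faster than recomputing spectra per shift); with hundreds of segments
the shift granularity is immaterial.

# Cell classification

Precedence: any significant taste response at either time scale makes
the cell *taste* (taste cells with lick-related firing are still
classified solely as taste). Otherwise phase-locked (coherence above
the shift null) and bout-suppressed → *mix*; phase-locked → *lick*;
bout-suppressed → *anti-lick*; bout-elevated → *lick-bout*; else
*non-responsive*. Bout suppression/elevation compares in-bout and
out-of-bout rates (ratio beyond 0.75 or its reciprocal) against a
circular-shift permutation null. Because bout-edge transients of
anti-lick and mix cells are genuine rate changes inside the scan
window, a fraction of such cells legitimately lands in *taste* under
the precedence rule; the test suite asserts that this is the only
confusion direction for them.

# Metric-space analysis

Spike-train distances: `count_distance` is the absolute spike-count
difference; `vp_distance` is the classic edit distance
(insert/delete = 1, move = q·Δt) via the standard dynamic program
(compiled; verified against a brute-force matching oracle). The
classifier assigns each response to the label minimizing the
generalized mean (exponent z = −2, the traditional choice) of its
distances to that label's other responses, self excluded, ties to the
smallest label index (counted). Information is the plug-in mutual
information of the confusion matrix; the q grid is the geometric
ladder 0, 1, 2, …, 512 s⁻¹.

Controls:

* *Shuffle* (40 reps): labels permuted, distances reused. The null
  for `H_max` is the *shuffled `H_max`* — each shuffle replicate's
  maximum over the q grid — not the per-q shuffled mean. `H_max`
  itself is a maximum over 11 correlated estimates, and comparing it
  against a single-q null would ignore that selection; with the
  per-replicate-max null, noise response sets pass the
  `H_max > mean + 2 SD` gate at roughly the nominal rate.
* *Exchange* (10 reps): within each label, pooled spike times are
  randomly redealt preserving each response's count, conserving the
  label-wise rate envelope exactly while destroying response-specific
  timing. Read out at the q attaining `H_max`.

Coding classes follow the significance ladder: not significant; rate
(count) if `H_max` equals `H_count` within tolerance (10⁻⁹ bits exact,
relative option available); rate envelope if `H_max` does not exceed
the exchange mean; spike timing otherwise. The window sweep evaluates
0.2, 0.5, 1, 1.5, 2 s windows aligned at the trial's first reinforced
lick and reports mean `H_max` (zeros for non-significant cells), mean
`H_count` among significant cells, and the proportion significant.

# Group statistics and pipeline

`compare_groups()` reproduces the published battery on pipeline
outputs: Mann-Whitney U on coherence peaks, Pearson chi-square
(df = 5) on cell-class counts, two-sample t (and U) on response
parameters, Kolmogorov-Smirnov on per-window temporal-coding
proportions; summaries report SEM = SD/√n. The published chi-square
value cannot be reconstructed from the published class counts (which
are themselves internally inconsistent between text and figure), so
the package computes the statistic but asserts nothing about that
number. `run_pipeline()` chains synthesis (or loading) → validation →
de-duplication → detection → classification → behavior → metric-space
sweep → group statistics, writes CSV tables plus a JSON config
snapshot, and is bit-reproducible from `(config, seed)`.

# Known limitations

* The five-lick rule's error rates depend strongly on trial count and
  on baseline overdispersion; at the 6-trial session default its
  per-panel specificity is poor (documented above, and visible in the
  synthetic taxonomy).
* Coherence values are estimator-dependent; only comparisons under
  fixed parameters are meaningful.
* The plug-in information estimator is biased upward at small samples;
  the shuffle control is the bias yardstick, as in the original
  method, and no analytic correction is applied.
* The generator's parameter recovery validates the implementation,
  not the biological fidelity of the presets; preset gaps between
  lean and DIO are calibrated so the published contrast directions are
  resolvable at 50 cells/group, with all magnitudes stated here and
  in `group_preset()`.
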