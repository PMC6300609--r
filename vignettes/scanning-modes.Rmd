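---
title: "Scanning-mode analysis of proteins diffusing on DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning-mode analysis of proteins diffusing on DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

DNA-repair enzymes find rare lesions by facilitated diffusion: they bind DNA
nonspecifically and scan it in one dimension, alternating between distinct
kinetic regimes. Three regimes matter here:

* **interrogation** (recognition) — locally confined, very slow motion while
  bases are probed rigorously;
* **helical sliding** — 1D Brownian motion that tracks the helical groove,
  and is therefore rotationally coupled to the DNA;
* **hopping** — microscopic dissociation–reassociation steps in which the
  protein stays electrostatically confined near the DNA but is decoupled from
  the helical path, allowing diffusion *above* the sliding speed limit.

`scanmodes` takes localization-microscopy tables of single fluorescently
labelled proteins moving on an elongated DNA molecule, reconstructs
binding-event trajectories, estimates a per-frame instantaneous diffusion
coefficient, and classifies every step into one of the three modes in two
independent ways — by an Arrhenius activation-energy argument and by a
diffusion-state hidden Markov model — and then quantifies the kinetics of
mode switching.

## Trajectory reconstruction

Localizations (one detected emitter per frame; columns frame, x, y in nm,
optional precision and photon count) are rotated so the DNA axis becomes the
x-axis (`align_to_axis()`; the axis comes from configuration or a
total-least-squares fit to the localization cloud via `fit_axis()`). Linking
(`link_tracks()`) is greedy nearest-neighbour: a localization extends a track
whose last detection is one frame back and within the 600 nm gate, or two
frames back and within the 600 nm bridge gate — the latter absorbs
single-frame fluorophore blinking; two-frame gaps are never bridged. The
per-frame gate reuses the bridge value because only the bridge criterion has
an experimental anchor; it is exposed as a parameter. Quality filters
(`filter_tracks()`) then retain tracks that (i) never leave a ±200 nm band
around the axis, (ii) persist for more than 5 frames (≥ 6 detections), and
(iii) span at least 300 nm along the axis. "Moved at least 300 nm" is read as
the positional range max(s) − min(s) — the weakest well-defined reading; net
displacement and single-window displacement are stricter alternatives the
user can impose downstream.

## Instantaneous diffusion

For 1D Brownian motion ⟨x²⟩ = 2Dt. `instantaneous_diffusion()` slides a
5-frame window (37.5 ms at the 7.5 ms exposure used for EndoV, 117.5 ms at
the 23.5 ms exposure used for hOGG1) along each track and assigns to the
window's first frame

D_inst = mean over the window's 4 single-frame squared displacements / (2 Δt).

A 5-frame window contains exactly 4 displacements; this convention uniquely
matches the fact that the last **4** frames of every track carry no value.
For a pure walk at diffusion coefficient D, D_inst/D is distributed as
χ²₄/4 (mean 1, CV ≈ 0.71) — the tests verify this law by a
Kolmogorov–Smirnov check on 10⁴ non-overlapping windows. Independent
localization noise σ per position biases the estimate upward by σ²/Δt
(the variance of a noisy displacement is 2DΔt + 2σ²); no correction is
applied by default because the downstream classification operates on the
same uncorrected quantity throughout. A displacement across a bridged blink
gap spans 2Δt, so its squared displacement is halved before pooling, and the
affected windows are flagged so they can be excluded.

## Activation-energy classification

Helical sliding has a hydrodynamic speed limit: a protein tracking the helix
must translate, rotate about its own axis, and revolve around the helical
axis once per pitch ℓ, giving friction

ξ = 6πηR + (2π/ℓ)² (8πηR³ + 6πηR·R_OC²)

and D_ideal = k_B T / ξ (`hydrodynamic_limit()`). R is the protein's
hydrodynamic radius, R_OC its centre's offset from the helical axis
(default R + 1 nm, the DNA radius), ℓ = 10.5 bp × 0.34 nm = 3.57 nm,
η = 0.89 mPa·s, T = 298 K. As ℓ → ∞ rotation decouples and the expression
reduces to the Stokes–Einstein translational limit. The shipped presets
(`protein_hydro()`) use radii calibrated by root-finding so the formula
reproduces the published limits for the two study proteins —
0.89 µm²/s (hOGG1, R = 3.051 nm) and 1.3 µm²/s (EndoV, R = 2.649 nm);
they are effective radii under this geometry, not measured values, and all
parameters can be overridden.

Treating each 1-bp step as a thermally activated barrier crossing,
k = 2D/⟨x²⟩ with ⟨x²⟩ = 1 bp² (`rate_constant()`), and pinning the Arrhenius
prefactor at the friction-free limit (E_a = 0 there, so A = k_ideal) gives

E_a = ln(k_ideal / k) k_B T = ln(D_ideal / D_inst) k_B T,

where the bp↔nm conversion cancels in the ratio (`activation_energy()`).
Steps are classified (`classify_mode()`) by two thresholds, defaults
0.5 and 2 k_B T:

* E_a ≥ 2 k_B T — interrogation;
* 0.5 ≤ E_a < 2 k_B T — helical sliding (the range reported for sliding
  friction across many enzymes);
* E_a < 0.5 k_B T — hopping; E_a < 0 means the step was faster than the
  sliding limit permits.

Boundary values are closed from below (the literature leaves both boundaries
open); E_a = 0 falls in the hopping range, consistent with motion at or above
the sliding limit. D_inst = 0, which occurs on noiseless synthetic fixtures,
maps to an E_a = +Inf sentinel, classified as interrogation and excluded
from barrier histograms. A stretch factor (default 1) can rescale the bp
rise for strongly elongated DNA; it is not applied by default.

## Hidden Markov classification

`fit_hmm()` models each single-frame displacement as zero-mean Gaussian with
state-dependent variance 2 D_k Δt (optionally + 2σ_loc², off by default) and
memoryless state switching. Fitting is by Baum–Welch expectation–maximization
(forward–backward recursions in compiled code, scaled per frame for
stability) over all contiguous displacement sequences; displacements across
bridged blink gaps span 2Δt and are excluded by splitting tracks there.
Multiple seeded restarts spread the initial variances over quantiles of the
squared displacements; the best likelihood wins. The likelihood is monitored
and must be non-decreasing across iterations; a decrease aborts the fit.
`select_model()` chooses the state count by BIC on the pooled displacement
likelihood with K² + K − 1 free parameters (K(K−1) transitions, K−1 initial
probabilities, K variances), emulating the over-specify-then-converge
strategy of variational state-count selection. A full variational-Bayes
treatment is intentionally out of scope; EM + BIC is the documented
substitute, with the same model family and selection intent.

Decoding (`decode_states()`) uses posterior marginals by default so that
per-frame state fractions match expected occupancies; Viterbi is available
behind a flag. Each frame takes the state of the displacement starting
there, the last frame of a segment repeats the final displacement's state,
and the rare frame isolated between two blink gaps inherits the nearest
decoded state. States are always reported in ascending order of D, which
also defines the mapping onto modes (1 → interrogation, 2 → sliding,
3 → hopping) used by `agreement()`. For a like-for-like comparison with the
energy classification, `trim_and_recompute()` restricts the decoded path to
the frames that carry an instantaneous-D value, i.e. it excludes the same
4-frame tail of every track.

Forward–backward posteriors are verified against brute-force enumeration of
all K^N state paths on tracks of up to 8 frames (agreement to 1e-10), and
parameter recovery is verified on a noiseless 3-state fixture with ~10⁵
displacements (D within 10%, transition matrix within 0.05 entrywise,
occupancy within 0.05 — measured errors are well inside these bounds).

## Mode kinetics

* `transition_matrix()` — row-normalized counts of consecutive-frame state
  pairs, pooled within tracks only.
* `reducibility()` — zeroes transitions below eps (default 1e-3) and tests
  strong connectivity of the surviving state graph; "nearly reducible" means
  reducible at eps but irreducible at eps/10, an operational criterion for
  connectivity that hinges on rare transitions.
* `triplet_memory()` — for all maximal sojourns in a state (default the
  middle, sliding state), the odds of exiting back to the entry state divided
  by the memoryless odds computed from the empirical entry/exit marginals.
  1 means Markovian switching; 2 means returns are twice over-represented.
  The synthetic generator can inject exactly this memory (`return_bias`),
  implemented as a second-order dependence on the entry state, and the
  statistic recovers ratios ≈ 1 (Markov) and ≈ 2 (bias 2) at ~10⁴ sojourns.
* `switch_frequency()` — entries into the interrogation state per 1000 bp of
  cumulative distance Σ|Δs| travelled (0.34 nm/bp). Cumulative distance, not
  net range, is the declared reading of "DNA traversed".
* `salt_series()` — collates per-mode mean D ± SEM across buffer conditions
  and reports fold changes against the lowest-salt condition; a
  hopping-specific increase with salt is the fingerprint of a
  dissociation-dependent mode.

## The synthetic generator

`simulate_multistate()` emulates the statistical structure of the
experiment: a ~4.1 µm (12 kbp at ~95% extension) DNA axis with reflecting
ends, geometric track lifetimes, three diffusion states with sticky Markov
switching, Gaussian localization noise with per-track σ drawn from the
20–42 nm precision range, and single-frame blinking (never two consecutive
frames). Defaults: Δt = 7.5 ms, D = 0.02/0.4/1.6 µm²/s with 0.9
self-transitions — chosen so the fast state exceeds the EndoV sliding limit
of 1.3 µm²/s and produces negative activation energies, as hopping should.
`render_localizations()` embeds tracks into image coordinates on a rotated
axis and writes the localization-table dialect the reader consumes, so the
entire pipeline can be exercised end to end; `simulate_random_walk()`
provides the single-mode baseline used for the distribution comparisons.
All randomness flows from one integer seed and every output is reproducible.

What the generator does **not** emulate: photophysics beyond single-frame
blinking, 3D excursion geometry of hops (states are effective-D states, not
an electrostatic model), detection heterogeneity along the DNA, drift, or
track crossings. Passing tests therefore demonstrate correctness of the
estimators under the assumed statistical model, not robustness to every
failure mode of real microscope data.

## Numerical choices and known limitations

* Window value assigned to the window's first frame; tracks shorter than the
  window yield an empty series with a warning.
* EM variance updates are floored (relative to the pooled variance) to avoid
  collapse onto single observations; empty or duplicated states flag the fit
  as degenerate rather than erroring, since over-specified K legitimately
  produces them.
* Linking ties break by smallest distance, then lowest track id, making the
  assignment deterministic.
* The activation-energy classifier thresholds the same noisy D_inst it then
  averages, so its per-mode conditional means are truncation-biased: means in
  the flanking modes (interrogation, hopping) are pulled toward the
  thresholds under the χ²₄/4 window scatter, while the sliding mode, far
  from both thresholds, is nearly unbiased. This is why classifier
  comparisons on synthetic data show close sliding-mode agreement but larger
  relative discrepancies in the flanking modes, and why an injected 1.5×
  increase of the hopping-state D appears as a somewhat smaller fold change
  (~1.3) when measured through the classifier. The HMM per-state means do
  not share this selection effect.
* Localization noise inflates D_inst by σ²/Δt and the HMM emission variances
  by 2σ²; both corrections exist behind flags but are off by default so that
  both classifiers see the same uncorrected data.
* Occupancy from the HMM is the posterior fraction of displacements per
  state (the "proportion of time" reading); the stationary distribution of
  the fitted chain is available from the transition matrix when needed.
* Test problem sizes were chosen to make sampling error small relative to
  the asserted tolerances at desk scale: 10⁴ non-overlapping windows for
  distribution checks, ~10⁵ displacements for HMM recovery, ~10⁴ sojourns
  for the memory diagnostic, 5 seeds for model-selection consistency.
* Real-data mode consumes localization CSV exports; spot detection from raw
  images, drift correction, and multi-DNA fields of view are out of scope.
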