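# scanmodes

Scanning-mode analysis of single-molecule trajectories of DNA-repair
proteins diffusing on elongated DNA.

DNA-binding enzymes locate their targets by facilitated diffusion, mixing
several one-dimensional scanning regimes: slow, locally confined
**interrogation** of bases; **helical sliding** that tracks the DNA groove;
and **hopping** — microscopic dissociation–reassociation steps that decouple
the protein from the helical path and let it outrun the sliding speed limit.
`scanmodes` reconstructs binding-event trajectories from localization
tables, estimates per-frame diffusion, and classifies every step into these
modes two independent ways, so the classifications can be checked against
each other.

The core quantities:

* **Instantaneous diffusion.** A sliding 5-frame window over the on-axis
  positions: `D_inst = ⟨Δs²⟩ / (2Δt)` from the window's four single-frame
  displacements (⟨x²⟩ = 2Dt in 1D). The last four frames of every track
  carry no value.
* **Activation-energy classification.** Helical sliding is bounded by the
  rotation-coupled hydrodynamic limit `D_ideal = k_B T / ξ` with
  `ξ = 6πηR + (2π/ℓ)² (8πηR³ + 6πηR·R_OC²)` (0.89 µm²/s for hOGG1,
  1.3 µm²/s for EndoV under the shipped presets). Each step's barrier is
  `E_a = ln(D_ideal / D_inst) k_B T`; steps classify as interrogation
  (E_a ≥ 2 k_BT), sliding (0.5–2 k_BT), or hopping (E_a < 0.5 k_BT, with
  E_a < 0 meaning faster than sliding permits).
* **Diffusion-state HMM.** Displacements are zero-mean Gaussian with
  state variance `2 D_k Δt` and Markov switching; fitted by
  expectation–maximization with seeded restarts, state count selected by
  BIC, states decoded by posterior marginals and mapped to modes by
  ascending D.
* **Mode kinetics.** Occupancies, per-mode mean D ± SEM, empirical
  transition matrices and their reducibility, a return-memory odds ratio,
  switching frequency into interrogation per 1000 bp traversed, and
  salt-series fold changes.

A seeded synthetic-data generator reproduces the imaging model (elongated
~12 kbp DNA axis, three switching diffusion states, 20–42 nm localization
noise, single-frame blinking), so the whole pipeline is testable without
microscope data.

## Worked example

```r
library(scanmodes)

cfg <- run_config(
  sim = sim_config(n_tracks = 200, mean_track_frames = 40, seed = 1),
  protein = "endov",            # sliding limit 1.3 um^2/s
  hmm = list(K = 3, n_restarts = 3),
  seed = 1
)
run <- run_analysis(cfg)
print(run)
```

```
[scanmodes] 7618 localizations
[scanmodes] 200 tracks linked, 142 retained (rejected: boundary 0, length 24, range 34)
scanmodes run: 142 tracks, 6422 assigned frames
  D_ave = 0.7601 +/- 0.9029 um^2/s; D_ideal = 1.3
  energy-mode occupancies: interrogation 0.263, sliding 0.418, hopping 0.320
  HMM: K = 3, agreement = 0.715, reducibility = irreducible
```

The run simulates EndoV-like conditions (7.5 ms frames, three states at
0.02/0.4/1.6 µm²/s with sticky switching, 20–42 nm noise), renders them as a
localization table, and pushes that table through the full pipeline: axis
alignment, linking with 600 nm gates and one-frame blink bridging, the
>5-frame / 300 nm / ±200 nm filters (here removing 58 of 200 tracks),
windowed diffusion, and both classifiers. `D_ave` is the pooled mean ± SD of
the instantaneous coefficients; 71.5% of frames receive the same mode from
the activation-energy thresholds and the decoded HMM states.

```r
summary(run$model)
```

```
Diffusion-state HMM with 3 state(s)
  D (um^2/s): 0.1076, 0.4556, 1.587
  occupancy : 0.2455, 0.4035, 0.3511
  logLik -39195.22 on 6531 displacements; BIC 78487.07
  transition matrix (per frame):
         to_1   to_2   to_3
from_1 0.8689 0.0814 0.0497
from_2 0.0473 0.9019 0.0508
from_3 0.0379 0.0736 0.8885
```

The fitted diffusion coefficients bracket the generating values (the lowest
state is inflated by the simulated 20–42 nm localization noise, a documented
σ²/Δt bias), the chain is sticky as configured, and the transition matrix is
irreducible — all three modes communicate. `compare_classifiers(run)` prints
the per-mode occupancy and mean-D pairs for both classifications side by
side.

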