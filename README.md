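# ip3rkit

Simulation and analysis toolchain for ligand regulation of the type-1
inositol 1,4,5-trisphosphate receptor (IP3R1), the ER calcium-release
channel, as studied in planar lipid bilayers and by calcium imaging. It is
written for channel biophysicists who want a tested, reproducible version
of the full quantitative chain of such a study — from recording-solution
chemistry to fitted dose–response parameters — with synthetic-data
generators carrying known ground truth at every stage, so that each
estimator can be validated by parameter recovery.

## What it computes

* **Chelator buffering** — free vs total Ca²⁺ in EGTA/BAPTA/dibromo-BAPTA
  mixtures: solves `[Ca]_tot = c + Σ Bᵢ·c/(c+Kdᵢ)` and its closed-form
  inverse, with a documented apparent-Kd table (pH 7.4, ~22 °C).
* **Gating models** — Hill activation `Po = Pmax/(1+(EC50/L)^h)`; biphasic
  (bell-shaped) Hill for cytosolic Ca²⁺,
  `Po = Pmax·[1+(EC50/c)^ha]⁻¹·[1+(c/IC50)^hi]⁻¹`; the Nernst potential
  `E_Ca = (RT/2F)·ln([Ca]cis/[Ca]trans)` and electrochemical driving force
  `EDF = Em − E_Ca`; and a double-Hill model of normalized mean open time
  versus EDF for Ca²⁺-feedthrough analysis,
  `MOT = 1 + R·[1+(Va50/EDF)^Ha]⁻¹·[1+(EDF/Vi50)^Hi]⁻¹` (baseline 1 for
  EDF ≤ 0).
* **Bilayer simulation** — two-state Markov gating with exponential dwells,
  rendered as filtered (Gaussian FIR, −3 dB at 2 kHz), noisy multi-channel
  current traces at 20 kHz with 248 pS unitary conductance.
* **Idealization** — half-amplitude threshold event detection, 300 µs
  dead-time censoring, nPo, channel counting from stacked openings and
  amplitude-histogram modes, mean open/closed times, exponential-mixture
  dwell fits.
* **Curve fitting** — Hill, biphasic Hill, linear i–V (slope conductance in
  pS), double-Hill MOT-vs-EDF, and the flipped/scaled overlay of the MOT
  bell onto mean closed times; all with bounded multi-start
  Levenberg–Marquardt, log-parameterized ordered midpoints and
  identifiability flags.
* **Ca²⁺ puffs** — synthetic confocal linescans with Poisson-timed
  ramp/exponential events, an SD-threshold detector (5–6.5 SD) with
  component splitting for overlapping events, and kinetic measurements
  (FDHM, time to peak, 20–80 % rise, 80–20 % decay, frequency per cell).
* **Plate assay** — synthetic Fluo-8-style well transients with
  ATP-dose-dependent amplitudes, maximal ΔF/F₀ extraction and Hill fitting
  of the concentration–response.

A parameter registry (`ip3r_params()`) ships the fitted values for the
wild-type and D2594K/D2594A channels (e.g. IP₃ EC₅₀ 660 nM WT vs 406 nM
mutant; cytosolic Ca²⁺ EC₅₀/IC₅₀ 78/562 nM WT; Va₅₀ 111.5 mV).

## Worked example

Simulate a one-minute single-channel record at 2 µM IP₃, idealize it, and
recover the gating statistics:

```r
library(ip3rkit)

cfg <- sim_config(duration = 60, em = 30, seed = 42)
ex  <- simulate_experiment(list(ip3 = 2e-6), ip3r_params("wt_ip3"),
                           mot = 8e-3, cfg)
ex$po
#> [1] 0.088                 # equilibrium Po implied by the Hill surface

id <- idealize_trace(ex$trace, unitary = unitary_current(cfg),
                     dead_time = 300e-6)
st <- channel_stats(id)
c(npo = st$npo, mot_ms = st$mot * 1e3, mct_ms = st$mct * 1e3)
#>     npo  mot_ms  mct_ms
#>  0.0838    8.45   92.39          # 595 open events detected
```

The measured nPo (0.084) sits within sampling error of the generating Po
(0.088), and the mean open time recovers the 8 ms used by the simulator.
Running the full dose–response pipeline across seven IP₃ concentrations and
fitting the Hill equation:

```r
wt <- run_ip3_npo_experiment("wt", seed = 1)
wt$fit
#> hill fit (7 points)
#>       estimate        se
#> pmax 1.025e-01 5.665e-03
#> ec50 7.217e-07 1.279e-07
#> h    1.897e+00 1.663e-01
```

The fitted EC₅₀ (722 nM) recovers the generating 660 nM within its standard
error, and pmax recovers the 0.1 ceiling — the whole
simulate → idealize → nPo → fit chain is self-consistent.

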