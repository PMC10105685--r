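---
title: "Simulating and analysing IP3R1 single-channel and calcium-imaging experiments"
author: "ip3rkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing IP3R1 single-channel and calcium-imaging experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ip3rkit)
```

## Scope and model

`ip3rkit` implements the quantitative chain behind a ligand-sensitivity study
of the type-1 IP~3~ receptor (IP~3~R1), comparing a wild-type channel with the
gain-of-function pore mutant D2594K at three scales: plate-reader global
Ca^2+^ transients, confocal linescan Ca^2+^ puffs, and planar-bilayer
single-channel records. Every analysis step is paired with a synthetic-data
generator with known ground truth, so the whole pipeline can be validated by
parameter recovery.

The gating models are:

* **Hill activation** for IP~3~ (and, at the cellular scale, ATP):
  $P_o(L) = P_{max}\, /\, [1 + (EC_{50}/L)^h]$.
* **Biphasic (bell-shaped) Hill** for cytosolic Ca^2+^:
  $P_o = P_{max}\,[1+(EC_{50}/c)^{h_a}]^{-1}[1+(c/IC_{50})^{h_i}]^{-1}$,
  activation at low and inhibition at high Ca^2+^.
* **Double Hill in driving force** for the normalized mean open time under
  Ca^2+^ feedthrough:
  $MOT(EDF) = 1 + R\,[1+(Va_{50}/EDF)^{H_a}]^{-1}[1+(EDF/Vi_{50})^{H_i}]^{-1}$,
  pinned to the baseline 1 for $EDF \le 0$ - the printed form is undefined
  there for non-integer exponents, and the luminal dependence is flat when
  flux is cytosol-to-lumen.
* **Nernst arithmetic**: $E_{Ca} = (RT/2F)\ln([Ca]_{cis}/[Ca]_{trans})$ and
  $EDF = E_m - E_{Ca}$ (cis grounded; positive EDF drives lumen-to-cytosol
  flux), with $R = 8.314$ J K^-1^ mol^-1^, $F = 96485$ C mol^-1^,
  $T = 295.15$ K by default.

A shipped registry (`ip3r_params()`) carries the fitted parameter sets for
both genotypes. Po ceilings are not printed quantities; the registry uses
WT $P_{max} = 0.1$ with the mutant 3.6-fold higher on the IP~3~ axis (and
roughly 3-fold on the Ca^2+^ axis), and every midpoint-recovery analysis in
the package is invariant to these scalings.

### The joint ligand surface

The per-axis dose-response curves are measured at fixed co-ligands, and no
joint equation is given for their interaction. The simulator therefore
composes them as a normalized product,
$P_o = P_{max} \cdot f_{IP3} \cdot f_{Ca}$ (`ligand_surface()`). This is a
modelling convenience, not a claim about allosteric mechanism: all per-axis
fits operate on data generated along one axis and never depend on the
composition rule.

## Free-Ca^2+^ buffering

All recording solutions state free Ca^2+^ concentrations maintained by
chelator mixtures (EGTA, BAPTA, dibromo-BAPTA). `free_ca()` solves the
single-metal conservation equation
$[Ca]_{tot} = c + \sum_i B_i\,c/(c + K_{d,i})$, whose left side is strictly
increasing in $c$, by bracketed root finding with Newton polish (relative
error below $10^{-12}$); `total_ca_for_free()` is its closed-form inverse.
The binding constants are not stated in the study conditions (they come from
a MaxChelator-style calculation), so the package ships a frozen, documented
apparent-$K_d$ table at pH 7.4, ~22 °C and physiological ionic strength
(EGTA 150 nM, BAPTA 220 nM, dibromo-BAPTA 1.6 µM), overridable per
`chelator_spec()`. Frozen constants keep results reproducible even though
"correct" values are condition dependent. Proton, Mg^2+^ and nucleotide
competition are out of scope.

```{r buffers}
sys <- buffer_system(list(chelator_spec("egta", 1e-3)))
tot <- total_ca_for_free(sys, 140e-9)
c(total_uM = tot * 1e6,
  roundtrip_nM = free_ca(buffer_system(sys$chelators, total_ca = tot)) * 1e9)
```

## Bilayer simulation and idealization

`simulate_experiment()` draws two-state (closed/open) gating with
exponential dwells at rates implied by the target equilibrium $P_o$ and mean
open time (`rates_from_po()`), renders the summed unitary currents
($i = \gamma(E_m - E_{rev})$, 248 pS by default, upward openings at positive
potentials), low-pass filters with a Gaussian FIR kernel (-3 dB at 2 kHz,
matching the risetime behaviour of the analog Bessel filter it stands in
for), and adds Gaussian noise before 20 kHz digitization. Channels gate
independently and identically. Flicker noise, drift and capacitive
transients are deliberately excluded: the generator validates estimators,
and those artefacts would only dilute the attribution of any discrepancy.
The default noise (0.6 pA) keeps the half-amplitude threshold at +30 mV
more than 6 SDs from baseline, so false events are negligible by
construction; it is a configuration value, not a measurement of bilayer
noise.

`idealize_trace()` applies the classic half-amplitude threshold-crossing
rule - a sample is at level $k$ once the deflection passes
$(k-\tfrac12)$ unitary amplitudes - with a single threshold per level (no
hysteresis); noise chatter is instead handled by `apply_dead_time()`, which
censors events briefer than 300 µs, reassigning each censored epoch to the
preceding event (a deterministic tie-break for the rare unequal-flank case)
and concatenating equal-level neighbours. Censoring conserves total record
length exactly and is idempotent. `channel_stats()` reports
$nP_o = \sum_k k\,t_k / T$, counts channels from the maximum stacked level
(`estimate_n_channels()`, corroborated by `amplitude_modes()`), and
computes arithmetic mean open/closed times only for effectively
single-channel records - dwell attribution across stacked openings is not
attempted, mirroring the original restriction of kinetic analysis to
single-channel records. An exponential-mixture ML fit (`fit_dwell_exp()`,
1 vs 2 components by likelihood ratio at $\alpha = 0.05$) is exposed for
dwell diagnostics; the arithmetic mean is what the recovery analyses use,
since the mixture component count of the real channel is unreported.

## Curve fitting

All nonlinear fits (`fit_hill()`, `fit_biphasic_hill()`, `fit_mot_edf()`)
use bounded Levenberg-Marquardt with a fixed multi-start grid (log-spaced
midpoints spanning the data, Hill exponents {1, 2, 4}), best RSS winning and
ties broken toward the smallest exponent. Midpoints are log-parameterized
for positivity; ordered pairs (activation before inhibition) are enforced
by construction - `fit_biphasic_hill()` fits $\log IC_{50} =
\log EC_{50} + e^{gap}$ and `fit_mot_edf()` fits $Vi_{50} = Va_{50} + d$
with $d > 0$, which removes a degenerate unordered branch of the RSS
surface. Degenerate data (flat response, missing descending limb) yield
flagged, non-converged results rather than exceptions. `fit_linear_iv()` is
ordinary least squares with the slope reported in pS. `mct_overlay()`
implements the descriptive "flipped and scaled" overlay of the open-time
bell onto closed times, $MCT = a - b\cdot MOT_{model}$ with $b \ge 0$, plus
an F-test against a constant-only fit.

Weighting: `fit_hill()` uses $1/SE^2$ weights when standard errors are
supplied. The plate-assay driver `atp_dose_response()` fits unweighted by
default: with six replicates the empirical variances are unstable, and
up-weighting the quiet low-dose wells amplifies the noise floor of the
max-dF/F~0~ statistic (Monte-Carlo during development: median EC~50~ error
~9% weighted vs ~2% unweighted at 5% trace noise).

```{r fits}
cc <- run_cyto_ca_experiment("wt", seed = 7)
c(ec50_act_nM = cc$ec50_act_nM, ic50_inh_nM = cc$ic50_inh_nM)
```

## Linescan puffs

`synthesize_linescan()` lays homogeneous-Poisson events (uniform positions
within each cell's span, default 0.63 µm pixels, 0.1 s line period - the
line period is a configuration value throughout, never hard-coded) on a
noisy baseline. Each event is a linear rise to the peak followed by a
single-exponential decay, spread as a spatial Gaussian. This minimal shape
reproduces all four reported kinetic statistics in closed form:

$$rise_{20-80} = 0.6\,r,\qquad decay_{80-20} = \tau\ln 4,\qquad
FDHM = \tfrac12 r + \tau\ln 2.$$

The reported rise/decay/FDHM triples of the real genotypes are not exactly
consistent with any ramp-plus-exponential, so generators targeting a
half-duration split it equally between limbs: $r = FDHM$,
$\tau = FDHM/(2\ln 2)$ (`puff_shape_for_fdhm()`). Event peak times are
snapped to the line grid and positions to pixel centres so the noise-free
peak-pixel dF/F~0~ equals the specified amplitude exactly.

`detect_puffs()` estimates background level and SD robustly (median and MAD
of the whole image - puffs are sparse, so no hand-drawn background region
is needed), thresholds at $k$ SDs (default 5.5, the midpoint of the
conventional 5-6.5 range; the threshold is interactively chosen per
recording in practice, so tests fix it), groups pixels by 8-connected
spatiotemporal connectivity, discards components under 4 pixels as isolated
noise crossings, and splits components whose max-intensity projection
(columns first, then rows) has two peaks separated by a valley retracing
more than half of the smaller peak's elevation *above the detection
threshold* - within a component every pixel already exceeds the threshold,
so the threshold, not the background, is the meaningful floor.

### Numerical choices in the kinetic measurements

`measure_kinetics()` treats the durations as dwell statistics and counts
samples within the relevant amplitude band (with exact-threshold samples
counted half). For a profile crossing a threshold under symmetric noise the
expected count equals the noise-free dwell, so counting stays unbiased even
when the per-sample slope is smaller than the noise - the regime of these
data, where interpolated first-crossing search systematically stops early.
Counting is bounded by the first run of five sub-20% samples on each side
of the peak, so neighbouring events sharing the window never contribute.
The peak amplitude comes from a 3-point parabola on the raw samples centred
at the argmax of a lightly smoothed copy (conditioning the parabola on a
selected raw maximum would inflate amplitudes and shrink all relative-
threshold durations), and the measured profile is the 3-row spatial average
around the peak pixel - for a separable event this rescales amplitude but
leaves every relative measurement unchanged while cutting noise by
$\sqrt3$. The per-pixel baseline is the lower quartile of the pixel's
trace plus the known $0.674\sigma$ quartile offset of Gaussian noise:
unbiased on quiet pixels and robust to event occupancy, where a plain
median drifts upward. Profiles that never return below 20% of peak are
flagged right-censored with NA decay (and NA FDHM if the tail stays above
50%).

```{r puffs}
wt <- run_puff_experiment(0.68, seed = 9)
c(n = wt$n_detected, mean_fdhm_s = round(wt$mean_fdhm_s, 3),
  freq_hz = round(wt$frequency_hz, 4))
```

## Plate assay

`synthesize_well()` models a well transient as
$F(t) = F_0[1 + A(1-e^{-t/\tau_r})e^{-t/\tau_d}]$ with the amplitude $A$
given by the ATP Hill response, a 20 s pre-stimulus baseline (the agonist
lands at $t = 0$; the real acquisition is injection-triggered but states no
baseline length) and samples every 2 or 4 s. The closed-form envelope peak
(`well_kinetic_peak()`) attenuates all amplitudes by the same factor, so
EC~50~ recovery is unaffected. `max_dff()` uses the pre-stimulus mean as
$F_0$ and takes the maximum of a 5-sample moving average, which controls
the upward bias of a noisy maximum. The 0-Ca^2+^ external condition is
represented simply by the absence of any influx component; no
store-depletion model is attempted.

## Study conditions and problem sizes

The reproduction workflows (`run_*_experiment()` / `run_atp_assay()`)
encode the study conditions: 8 ATP levels spanning 0.3-100 µM with 6
replicates and 5% trace noise; 6 test potentials with 0.2 pA amplitude
noise; 7 IP~3~ levels (30 nM-10 µM) with 3 records per level - 1-minute
records are the package's default problem size for this pipeline, a scale
at which nPo at the lowest activity still rests on a handful of events,
which is exactly the regime the 25% recovery tolerance reflects; 12
log-spaced Ca^2+^ or EDF points at 3-5% noise. Kinetics linescans use 24
cells x 120 s at 0.03 events s^-1^ cell^-1^ (~86 events, sparse enough
that overlapping puffs rarely distort single-event kinetics); the
frequency experiment keeps the reported mutant rate, 0.1 s^-1^ over 64
cells, where blended event pairs are recovered by the component splitting
described above. The EDF grid is logarithmic over 60-260 mV, concentrating
points on the steep activation limb. Monte-Carlo during development showed
the $Va_{50}$ recovery at this design's 5% noise has an intrinsic spread of
~8% (the activation exponent and midpoint trade off across only a few
transition points), so single noise realizations occasionally land outside
10% of the generating value; this is a property of the design, not of the
fitter.

## What the synthetic data do and do not show

The generators reproduce the *statistical structure* the estimators rely on
(exponential dwells, Gaussian noise and filtering, Poisson event trains,
separable ramp/exponential events) with known truth, so passing tests
demonstrate calibration and absence of algorithmic bias at realistic SNR.
They do not emulate modal gating, subconductance states, anomalous
mole-fraction conductance at high luminal Ca^2+^, dye saturation or
bleaching, baseline drift, or spatially structured cellular backgrounds -
conclusions about real recordings still require the usual experimental
controls. Real-data ingestion is available through plain CSV/TSV tables and
single-channel TIFF linescans.

## Known limitations

* MOT/MCT for multi-channel records are reported NA; no stacked-dwell
  decomposition is attempted.
* The dead-time correction is censoring only; no missed-event likelihood
  correction is applied.
* The biphasic and double-Hill fits need coverage on both limbs; otherwise
  the inhibition parameters are flagged unidentifiable by design.
* Chelator constants are apparent values at fixed pH/temperature; no proton
  or divalent competition model.
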