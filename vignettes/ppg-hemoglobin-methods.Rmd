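---
title: "Methods: hemoglobin estimation from multiwavelength PPG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hemoglobin estimation from multiwavelength PPG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppghb)
```

## The measurement model

Transmissive finger photoplethysmography measures the light that survives a
path through skin, bone, venous blood and the pulsating arterial
compartment. For a narrowband source of intensity $I_s$ at wavelength
$\lambda$, Beer-Lambert attenuation gives the transmitted intensity

$$ I(t) \;=\; I_s \, 10^{-\left[\,\varepsilon_{DC}(\lambda) L \;+\;
   \textstyle\sum_i \varepsilon_{Hb_i}(\lambda)\, C_{Hb_i}\,
   \Delta L \, p(t)\right]}, $$

where $\varepsilon_{DC} L$ lumps all static absorbers over the baseline
path $L$, the sum runs over the four hemoglobin species (oxy-, reduced,
met-, carboxyhemoglobin) with concentrations $C_{Hb_i}$, $\Delta L$ is the
peak arterial path modulation, and $p(t) \in [0,1]$ is the cardiac
waveform. Writing $I_{DC}$ for the over-cycle minimum of $I(t)$ (peak
systole, full path $L + \Delta L$) and $I_{AC}$ for the over-cycle swing,
a first-order expansion of $\lg(1 + I_{AC}/I_{DC})$ yields

$$ \frac{I_{AC}}{I_{DC}} \;\approx\;
   \Big(\sum_i \varepsilon_{Hb_i}(\lambda)\, C_{Hb_i}\Big)\, \Delta L
   \cdot \ln 10 , $$

so the per-wavelength AC/DC ratio is a scale-free quantity linear in total
hemoglobin (for fixed species fractions and $\Delta L$), independent of
$I_s$, detector gain and the static tissue term. The broadband channel is
the emission-spectrum-weighted sum of narrowband responses over the
wavelength grid; its ratio aggregates the species absorbances across the
band. These eight ratios — seven narrowband LEDs plus one broadband LED —
optionally joined by the mean contact pressure, are the regression inputs
for hemoglobin in g/L.

Model assumptions worth stating explicitly: no scattering (pure
Beer-Lambert attenuation), constant species fractions within a record,
path modulation common to all wavelengths, and additive instrumentation
noise. All are idealizations; their consequences are discussed under
*What the simulator does and does not emulate*.

## The synthetic-data generator

No public recordings accompany this problem, so the package ships a
forward simulator (`simulate_ppg`, `simulate_cohort`) that makes every
downstream stage testable against known ground truth.

* **Extinction table.** `default_extinction_table()` provides synthetic
  smooth curves on a 550-1100 nm grid (the overlap of a silicon
  photodiode, a 550-1100 nm bandpass filter and the LED emission range).
  They reproduce the orderings that the method relies on — reduced
  hemoglobin absorbing more at 660 nm than at 940 nm, oxyhemoglobin
  rising toward its NIR peak — but are not literature digitizations;
  every correctness criterion in the package depends only on ordering and
  monotonicity, never on absolute coefficients.
* **Pulse waveform.** A periodic sum of two wrapped Gaussians: a systolic
  primary wave (phase 0.25 of the cycle, width 0.07) and a diastolic
  sub-wave (phase 0.55, width 0.10, relative amplitude 0.35), normalized
  to $[0,1]$ per period. The widths keep the harmonic content essentially
  inside 10 Hz, consistent with the 0.6-10 Hz analysis band.
* **Defaults as study conditions.** 500 Hz sampling, 12 s records, heart
  rate 1.0-1.5 Hz across a cohort, hemoglobin drawn uniformly on
  80-160 g/L, baseline path 10 mm, path modulation 0.05 mm, source
  intensity $4\times10^4$ ADC units (perfusion index ~2-6%), Gaussian
  noise SD 2 ADC units, 0.15 Hz sinusoidal baseline drift of 30 units.
* **Pressure coupling.** Contact force alters local vascular volume, so
  the simulator scales $\Delta L$ by
  $1 + 0.5\,(\bar P - P_{ref})/P_{ref}$ with between-subject pressure
  variation of 15%. This makes the pulsatile gain vary ~7.5% SD across
  subjects — enough that the eight-ratio model is visibly confounded and
  the ninth (mean pressure) feature carries real information, mirroring
  the motivation for collecting it.
* **Poor-quality records.** A labelled fraction receives motion-artifact
  bursts (random onset, 0.3-1 s, amplitude 1-3 times the channel AC,
  either sign) plus inflated noise, both scaled by a per-record severity
  drawn uniformly on [0.1, 1]. The severity spread is deliberate: at full
  corruption the quality classes separate perfectly and cost-sensitive
  training would be untestable; with mild cases in the mix the classifier
  must trade false alarms against misses, which is the regime the
  cost-sensitive design addresses.

**What the simulator does not emulate:** photon scattering and the
resulting nonlinearity of effective path length, melanin and temperature
effects, venous pulsation, probe-motion decoupling between channels,
respiratory modulation, and between-subject variation in species
fractions. Passing the recovery and end-to-end tests therefore
demonstrates correctness of the *algorithms* under the stated forward
model, not clinical accuracy on real fingers.

## Filtering and landmark detection

The chain is moving average, then bandpass, then landmark detection.

* The centered moving average (default 9 samples, 18 ms at 500 Hz)
  suppresses sample-level spikes. The window is kept deliberately short:
  a 50 ms smoother would attenuate the pulse's 4th-6th harmonics by
  3-14% and bias the extracted AC several percent low, while everything
  above 10 Hz is removed by the next stage anyway.
* The bandpass is a linear-phase FIR designed by the window method with a
  Dolph-Chebyshev window (50 dB equiripple sidelobes, 3501 taps at
  500 Hz, scaling with the sampling rate), passband 0.6-10 Hz. Measured
  response: better than 40 dB attenuation at 0.3 Hz and 15 Hz, passband
  flat to under 0.3%. The single-pass group delay of $(N-1)/2$ samples is
  compensated exactly and edges are reflection-padded; a causal
  delay-compensated pass (rather than forward-backward filtering) keeps
  the chain implementable in streaming hardware.
* Landmarks are local extrema screened by topographic prominence (at
  least 0.25 of the trace's inter-quartile span) and a minimum separation
  of 0.33 s (180 bpm), with strict peak/trough alternation enforced by
  dropping the lesser of two consecutive same-type landmarks. "Morphological"
  detection is interpreted as extremum-plus-prominence logic rather than
  erosion/dilation operators; the alternation repair is what removes
  diastolic sub-wave extrema, so each retained peak-trough pair spans one
  full systolic swing.

Landmarks are detected on the *negated* bandpassed intensity, so "peaks"
are systolic (minimum transmitted intensity). The DC component is read at
those systolic minima of the baseline-preserving (moving-average) trace,
matching the convention above that $I_{DC}$ corresponds to the full path
$L + \Delta L$.

## Sliding-window-variance feature extraction

Beat amplitudes are collected twice — each systolic peak minus its
preceding trough (set A) and minus its following trough (set B) — because
baseline drift makes the two differ slightly. Each set is sorted
descending and truncated to its first half (floor division, minimum 2):
with peaks and troughs near 1:1, the larger half corresponds to systolic
rises, and corrupted or sub-wave amplitudes sort to the discarded half.
A window of half the truncated length (again floored, minimum 2) slides
over each set; the window with the smallest population variance — the most
self-consistent run of beats — contributes its mean, and the two means are
combined by inverse-variance weights $1/(\sigma^2 + 10^{-12})$. The floor
makes two zero-variance estimates average with equal weight instead of
dividing by zero. The smaller selected variance, normalized by the squared
DC, doubles as a signal-quality feature. DC follows the same recipe on the
sorted trough intensities without halving.

The sliding mean and variance use exact O(1) shift updates per window
move. The printed recursive variance form this design descends from has
inconsistent index bounds (a window of $\Delta n$ elements but a sum over
$\Delta n + 1$); the contract adopted here is the direct-summation
population variance over $\Delta n$ elements, and the update is an exact
algebraic rearrangement of that definition, verified against brute-force
summation on 10,000 random sequences to $10^{-14}$ relative error.

Numerical tie-breaking: among windows whose variances agree within
$10^{-9}$ of the squared signal scale, the lowest start index wins. The
relative tolerance matters — on clean signals many windows are equally
flat, and bit-level rounding would otherwise make the selection (and with
it scale equivariance of the features) unstable.

A boundary worth knowing: appending grossly corrupted low amplitudes
leaves the AC estimate *exactly* unchanged as long as the appended count
does not change the floor-division half-count (e.g. one corrupt beat on
an even-length list); when it does, one extra genuine amplitude enters
the kept half and the estimate moves by the within-cluster spread, which
is the intended graceful degradation, not a failure.

## Cost-sensitive signal quality (AdaCost)

Each record is summarized by its worst channel: largest
variance-to-DC-squared ratio, plus that channel's landmark counts.
Channels whose extraction fails outright receive a sentinel normalized
variance of 1, ranking them worst rather than erroring — a screening
stage must not crash on the signals it exists to reject. Pooling across
channels (rather than classifying per channel) reflects that a record is
used or discarded as a whole; this was an open design point and is the
package's choice.

The classifier boosts depth-2 weighted-Gini trees with the
cost-adjustment update

$$ D_{t+1}(i) \propto D_t(i)\,
   e^{-\alpha_t\, y_i\, h_t(x_i)\, \beta_i}, \qquad
   \beta_i = 0.5 \mp 0.5\,c_i , $$

with the minus sign on correct classification, costs $c_i \in [0,1]$
(defaults: poor 0.8, satisfactory 0.2) and
$\alpha_t = \tfrac12 \ln\frac{1+r}{1-r}$,
$r = \sum_i D(i)\, y_i h(x_i) \beta_i$. A poor signal slipping through as
satisfactory is thus penalized hardest. With all costs zero,
$\beta \equiv 0.5$ and the update is an AdaBoost update at half margin
scale. Boosting stops early on a degenerate weak learner (weighted error
$\ge 0.5$) or a non-positive cost-weighted margin. In the pipeline,
records flagged poor are excluded before regression rather than
down-weighted — a gate, matching how quality assessment is positioned in
the workflow.

## Regression suite

Three families over a 7:3 split (test size `round(0.3 n)`) with 10-fold
cross-validated grid search on the training set, selection by mean CV
$R^2$ (no selection metric was prescribed; ties break toward fewer
estimators, then shallower trees), then a full retrain at the optimum and
a single held-out evaluation:

* **adaboost** — AdaBoost.R2 with depth-limited regression trees,
  deterministic (case weights, no resampling); grid: 1-10 estimators
  crossed with depth 1-6.
* **random_forest** — `randomForest`, same grid, depth controlled via
  `maxnodes` $= 2^{depth}$.
* **bpnn** — a two-hidden-layer back-propagation network written
  in-package (default sizes 16 and 8, standardized inputs and targets,
  iteration cap 10000), searching activations {identity, logistic, tanh,
  relu} and solvers {lbfgs, sgd, adam}. The published activation list
  "identity, logistic, tanh, real" and solver list "blogs, sad, Adam" are
  read as typos for relu and lbfgs/sgd/adam.

Metrics are the standard $R^2 = 1 - SS_{res}/SS_{tot}$ (undefined and
reported `NA` for a zero-variance target), MSE and MAE. Bland-Altman
limits of agreement use the population SD and the 1.96 multiplier:
$\bar d \pm 1.96\,\sigma_d$ with $d = \hat y - y$. Pearson correlations
use pairwise-complete observations with at least 3 rows per pair;
zero-variance columns report `NA` with a warning.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run the method at sizes a
single workstation handles comfortably: 12 s records at 500 Hz, a
100-record cohort (70/30 good/poor) for quality classification, and a
60-record clean cohort for end-to-end hemoglobin recovery. At these sizes
the end-to-end run reaches test $R^2 \approx 0.9$ and MAE
$\approx 4$ g/L, and the nine-feature configuration consistently beats
the eight-feature one in CV $R^2$ — directional findings; the absolute
numbers depend on the simulator's noise and coupling settings. Every
stochastic step (simulation, splits, fold assignment, weight
initialization) takes an explicit seed, and reruns are byte-identical.

## Known limitations

* The extinction curves are synthetic; absolute ratios are not comparable
  to any real device, only orderings are.
* The clinical table ships without signals, so regression on real
  recordings is out of reach by construction; the table supports
  completeness filtering and correlation analysis only.
* The printed blood-pressure column order in the source table
  ("Diastolic/Systolic") contradicts its values; the package stores the
  larger value as systolic.
* AdaCost's published description does not fix the cost-adjustment
  function; the Fan et al. $\beta^\pm$ form above is the implemented
  variant, chosen and documented as such.
* The quality classifier is trained on simulated artifacts; nothing here
  claims transfer to clinically annotated quality labels.
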