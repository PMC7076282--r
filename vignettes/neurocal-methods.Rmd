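---
title: "Methods: calcium-transient detection, Fura-2 calibration and the simulation model"
author: "neurocal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calcium-transient detection, Fura-2 calibration and the simulation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurocal)
```

# Scope and data model

`neurocal` quantifies somatic calcium signalling in differentiating human
cortical cultures from already-extracted ROI intensity tables. Three
experimental designs are covered: single-wavelength (Fluo-4) recordings of
spontaneous transients with a pharmacological abolition epoch; dual-excitation
(Fura-2, 340/380 nm) store-operated calcium entry (SOCE) experiments; and the
qPCR / differential-expression arithmetic that accompanies such studies.
Image segmentation, background subtraction and ROI geometry are deliberately
out of scope: the unit of input is a frames × cells matrix.

All frame indices in the public interface are **0-based and half-open**:
an epoch `[start, end)` covers frames `start … end − 1`. This single
convention is used by `EpochPlan`, event tables and quiet-frame sets, and is
converted internally to R's 1-based indexing. Readers accept timestamp
jitter up to 10⁻⁶ of the median frame interval (acquisition software rounds
timestamps) and regularize times onto the exact uniform grid; anything worse
is a hard error naming the offending interval.

# Transient detection

## Normalization

Each cell's raw fluorescence is divided by its intensity at a reference
frame, by default the first baseline frame: `norm = F/F0`, `dff = F/F0 − 1`.
Both are retained because published trace figures are ambiguous about which
of the two an axis labelled "ΔF" shows. Cells with non-positive reference
intensity cannot be normalized and are excluded with a logged reason, never
silently. No detrending is applied by default — the protocol this package
models reports none — but an optional exponential bleach detrend
(`detrend = TRUE`, fitted on the baseline epoch) is available.

## Event criterion

The published criterion — a calcium event is a *positive derivative value
exceeding 2×SD + average computed in regions devoid of transients* — is
operationalized as:

1. first derivative `d[t] = dff[t+1] − dff[t]` (raw finite differences;
   a "first-derivative filter" names no kernel, so no smoothing is applied
   by default; an optional moving-average pre-filter of width
   `smoothWindow` frames is exposed);
2. per-cell threshold `mean(d) + k·SD(d)` over quiet frames, with `k = 2`
   and the **population** (divide-by-n) SD — the source does not specify the
   denominator; for ≥ 20 quiet frames the two conventions differ by < 3%;
3. quiet frames found automatically: starting from all baseline-epoch
   derivative frames, frames above the current threshold are excluded and
   the threshold recomputed, to a fixpoint (≤ `maxIter`, default 10).
   Fewer than 5 quiet frames is an error; an explicit quiet set can be
   supplied instead. Only positive excursions are excluded, so the decay
   tails of transients remain in the quiet set — this is intentional, as the
   resulting threshold scales with the cell's own activity, which is what a
   human counter looking at a derivative trace effectively does.

An alternative literal reading of the criterion — statistics computed on, and
the threshold applied to, the normalized intensity itself — is available
behind `statistic = "intensity"`; the derivative reading is the default
because the published procedure measures spikes *from first-derivative
filter traces*.

## From threshold crossings to events

Manual spike counting is replaced by a deterministic rule whose parameters
expose the discretion a human counter exercised: maximal runs of frames with
`d > threshold` become candidate events; runs separated by fewer than
`minSeparation` (default 2) sub-threshold frames are merged; merged runs with
fewer than `minEventFrames` (default 1) supra-threshold frames are dropped.
Onset is the frame the first supra-threshold step lands on; the peak is the
ΔF/F₀ argmax from onset to the first local minimum after the run (truncated
before the next event, so events never overlap); the amplitude is peak ΔF/F₀
minus the **median ΔF/F₀ over the 5 frames before onset** (window clipped at
the recording start). A local pre-onset baseline rather than a global one
makes amplitudes robust to slow drift, which the source protocol does not
model. The detector is verified against an independent, loop-based
brute-force enumeration of the same rules on hundreds of random traces.

Per-cell summaries count events with onset inside a 240-s window at the
start of the baseline ("spikes / 4 min") and assess abolition per treatment
epoch: the treatment-epoch event rate must not exceed `abolitionFraction`
(default 0, i.e. strict: no events at all) times the baseline rate. The
strict default matches reports that TTX abolishes transients in essentially
all mature neurons; the fraction is configuration because the quantitative
criterion for *partial* abolition in young cultures is not stated anywhere.

Amplitude histograms use half-open bins with explicit underflow/overflow
rows, so proportions sum to exactly 1 per condition. Bin edges are user
configuration; no equivalence to any published figure's (unprinted) edges is
claimed.

# Fura-2 calibration and SOCE quantification

The 340/380 ratio `R = F340/F380` is converted per cell with the
Grynkiewicz equation

$$[\mathrm{Ca}^{2+}]\,\mathrm{nM} = K_d \cdot SF \cdot \frac{R - R_{min}}{R_{max} - R},$$

with `Kd = 225` nM (the Fura-2 value used for human cells; overridable for
other dye lots). The conversion is strictly increasing on `(Rmin, Rmax)`;
frames at or above `Rmax` are flagged `saturated_high` (undefined), frames
below `Rmin` are clamped to 0 and flagged.

Per-cell constants come from the two calibration epochs of the 17-min
protocol (12/84/60/24/24 frames at 5 s): `Rmax` is the **median of the 5
largest** ratios in the ionomycin epoch and `Rmin` the median of the **last
5** frames of the EGTA epoch — single-frame extrema are noise-biased, and
the EGTA tail is used because early EGTA frames still carry decaying
calcium. `SF` is the median F380 over the EGTA tail window (Ca²⁺-free form)
divided by the median F380 over the whole ionomycin epoch (Ca²⁺-bound form):
the dye is saturated throughout that epoch, and selecting frames by extreme
ratio values would couple the SF estimate to ratio noise. Cells with
`Rmin ≥ Rmax` are flagged invalid, never dropped. A constant per-channel
camera offset can be subtracted (`backgroundOffset`, default 0).

Per cell, `basal_nM` is the mean concentration over the basal epoch,
`store_release_delta_nM` the thapsigargin-epoch peak above basal and
`soce_delta_nM` the add-back-epoch peak above basal. The peak is the plain
per-epoch maximum by default — fidelity to the stated quantity ("rise above
basal") first — with a robust median-of-top-5 option. At realistic channel
noise the plain maximum is biased high by extreme-value statistics and the
robust peak low for sharp transients; per-cell deltas then scatter up to
~10%, while means over ~25 cells recover programmed values within ~5%
(measured in the test suite). Population-level summaries are therefore the
recommended reporting unit, as in the scatter-plot-plus-mean presentation
such studies use.

# The simulators

## What they emulate

`simulateSpiking` emulates the spontaneous-transient assay: 1 frame/s,
a 4-min baseline followed by a 4-min abolition epoch. Spikes form a
homogeneous Poisson process per epoch (default 3/min baseline, 0 after
treatment); each contributes an instantaneous rise of amplitude A (ΔF ⁄ F₀)
and single-exponential decay:

$$F(t) = f_0\, e^{-t/\tau_b}\Bigl(1 + \sum_i A_i e^{-(t-t_i)/\tau}\,[t \ge t_i]\Bigr) + \varepsilon(t).$$

Defaults and rationale: decay τ = 2 s (at 1 frame/s the rise is sub-frame,
and the source gives no kinetics, so the kernel is the simplest one
compatible with the sampling); amplitudes log-normal (median 0.5, sdlog 0.5)
— strictly positive and right-skewed like observed amplitude histograms;
baseline f₀ uniform in 80–120 a.u. (wide-field camera counts with ±20%
loading variation); additive i.i.d. Gaussian noise (default SD 0.02 a.u.);
no photobleaching by default (τ_b = ∞). Spike times are drawn so the rise
lands on a frame inside the generating epoch; otherwise a baseline spike in
the last second would register as a treatment-epoch event. One random stream
per cell is derived from the master seed, so cell k's trace is independent
of how many cells are simulated, and a fixed seed reproduces output
bit-exactly.

`simulateSOCE` emulates the five-epoch Fura-2 protocol. The true
concentration program is piecewise: constant basal (50 nM); a thapsigargin
transient with rise τ = 15 s and decay τ = 60 s (realistic for store release
sampled at 5 s) whose shape is normalized so the **frame-grid peak equals
exactly basal + 120 nM**; a saturating SOCE plateau (rise τ = 15 s)
normalized to peak at exactly basal + 200 nM; then the calibration levels.
The per-epoch normalization makes the programmed deltas exact targets for
recovery tests rather than asymptotes. The ionomycin epoch defaults to true
dye saturation (`ionoCa = Inf`, ratio exactly Rmax) and the EGTA epoch to
exactly 0 nM (ratio exactly Rmin): the calibration epochs *define* the dye's
limiting states, and finite values (e.g. `ionoCa = 1e6` nM, ratio within
0.1% of Rmax) remain available. Channels follow the exact algebraic inverse
of the Grynkiewicz relation — the ratio is the hyperbolic function of c
shown in `?simulateSOCE`, and F380 interpolates hyperbolically between its
free (SF × 100 a.u.) and bound (100 a.u.) intensities with half-point
Kd·SF — so a zero-noise simulation fed through the ratiometric module
returns the truth to floating-point accuracy, which the tests assert.

## What they do not emulate

Shot noise and photon statistics (noise is additive Gaussian), neuropil and
neurite transients (only somatic signals are quantified), bursting and
network synchrony, dye compartmentalization, focus drift, and motion. A
passing recovery test therefore shows the *analysis* is correct under the
stated model, not that the model captures every artifact of real recordings.

# Expression arithmetic

Relative expression is `2^−ΔCt` with `ΔCt = mean(technical replicate Ct of
gene) − mean(replicate Ct of GAPDH, same sample)`; the mean is the
aggregation convention (median available) and replicate SD > 0.5 cycles is
flagged. DE classification is inclusive on the fold-change boundary
(`log2FC ≥ +1.5` is "≥ +1.5 and greater") and strict on significance
(`p < 0.05`, `FDR < 0.05`); every gene gets exactly one of up/down/ns.
Overlap counts between two contrasts are plain set algebra over a shared
gene universe. The heatmap matrix z-scores log2FC per column over a
109-gene calcium-signalling panel using the population SD; the familiar
−1…+1 display range is treated as optional clipping (`clip = 1`), not a
data transformation. The panel ships as an editable text fixture — its exact
membership is a replaceable convention, since no canonical list is printed
in the protocol this package models. Marker positivity percentages are
truncated (not rounded) to two decimals, matching the reporting convention
of the study's count-based percentages (91/283 → 32.15%).

# Numerical and testing choices

* Result tables are plain UTF-8 delimited text with a schema-tag comment
  line; numerics are written as `%.17g`, so reader/writer pairs round-trip
  doubles bit-exactly.
* Population SD is used wherever an SD enters a formula (thresholds,
  z-scores); the choice is documented at each site.
* Degenerate inputs have defined behaviour: zero quiet SD with signal
  elsewhere → threshold = quiet mean with a warning; constant z-score
  columns → zeros with a warning; empty event lists → empty tables, not
  errors; fully flagged epochs → cell excluded with a reason string.
* Test problem sizes are deliberately modest (30–50 cells, 480-frame
  recordings, a 5-seed battery, ~10⁴ amplitudes for the binning check);
  they are large enough for the stated tolerances while keeping the default
  suite fast.
* The detection recovery battery (30 cells × 5 seeds, 3 spikes/min baseline,
  noise 0.02 a.u.) is scored with a greedy ±2-frame onset matcher against
  ground truth; the pooled F1 is collision-limited near 0.92 — closely
  spaced spikes merged by the run rule are the dominant loss — and
  treatment-epoch abolition is complete.

# Known limitations

* Detection quality degrades when the noise SD approaches the per-frame
  derivative step of small transients; with a 2×SD criterion, occasional
  noise crossings are expected once channel noise is a sizeable fraction of
  typical amplitudes.
* The threshold's dependence on decay tails in the quiet set means very
  inactive cells get tighter thresholds than very active ones; this mirrors
  the per-cell character of the manual procedure but is worth keeping in
  mind when comparing thresholds across cells.
* Mn²⁺-quench calibration of Fluo-4 recordings and in-situ Kd determination
  are not implemented; single-wavelength results stay in ΔF/F₀ units.
* Absolute reproduction of published population values (spike counts per
  culture age, basal nM levels per DIV) requires the original recordings,
  which are not bundled; the package's quantitative guarantees are the
  parameter-recovery results computed by its own test suite and acceptance
  script.
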