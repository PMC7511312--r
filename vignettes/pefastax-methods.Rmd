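---
title: "Models and methods behind pefastax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pefastax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pefastax)
```

`pefastax` chains four analyses that together describe a nanosecond
pulsed electric field (nsPEF) experiment on *Haematococcus pluvialis*:
a biophysical model of membrane charging, image-based astaxanthin
scoring, dye-exclusion mortality, and 2^(−ΔΔCt) transcript
quantification. A seeded synthetic-data layer generates every input with
planted truth. This vignette explains each model, its assumptions, the
tunable parameters, and the design choices made where the underlying
assay left them open.

## Membrane charging

A spherical cell of radius $a$ in a uniform field $E$ develops a
transmembrane voltage with the azimuthal cosine law and exponential
charging,

$$V_m(\theta, t) = E\,a\,\cos\theta\,(1 - e^{-t/\tau_C}), \qquad
\tau_C = a\,C_m\left(\frac{1}{\sigma_i} + \frac{1}{2\sigma_e}\right),$$

where $\theta$ is measured from the field-axis pole, $C_m$ is the
specific membrane capacitance and $\sigma_i$, $\sigma_e$ the cytoplasm
and external conductivities. Assumptions worth keeping in mind:

* **Single shell, constant properties.** The membrane is a single
  capacitive shell whose properties do not change while it charges; pore
  formation above threshold is represented only by flagging those
  voltages as *hypothetical* (unclamped, so curves remain smooth and
  invertible), not by a conductance model. No pore-kinetics
  (Smoluchowski-type) model and no second shell for the chloroplast are
  included.
* **No geometric prefactor by default.** The classical derivation
  carries a $3/2$ factor in front of $E a \cos\theta$; the default here
  is $1.0$, with `schwan_factor = 1.5` available for the textbook
  variant. With the study parameters the no-prefactor form is the one
  whose threshold geometry matches the reported coverage statements, so
  it is the default.
* **β-dispersion frequency.** `charging_time_constant()` reports
  $f_c = 1/\tau_C$, the plain reciprocal (≈1.7 MHz at the default
  parameters), not $1/(2\pi\tau_C)$; this is the convention the rest of
  the package is calibrated against.

With the defaults (a = 14 µm, C_m = 1 µF/cm², σ_i = 10 mS/cm,
σ_e = 1.6 mS/cm) the computed $\tau_C$ is 577.5 ns; the value quoted for
this parameter set in the source experiments is 598 ns, a ~3.5%
difference most plausibly explained by a unit slip in one quoted
parameter. Functions that invert the charging law accept a `tau_ns`
override so either constant can be used explicitly.

**Permeabilisation geometry.** Solving $V_m = V_{th}$ for $\theta$ at a
pulse duration $t$ gives the threshold azimuth
$\theta^* = \arccos\!\big(V_{th} / (E a (1 - e^{-t/\tau_C}))\big)$, or
*unreached* (`NA`) when even the pole stays below threshold. Because the
field polarises both hemispheres, coverage counts both polar regions:
the circumference fraction is $4\theta^*/360$ and the two-cap surface
fraction $1 - \cos\theta^*$. $V_{th}$ defaults to 1 V, the usual
irreversible-electroporation threshold, and is configurable.

**Dose.** The specific treatment energy is the rectangular-pulse Joule
dose $W = N \sigma_e E^2 \Delta t / \rho$ with $\rho$ = 1000 kg/m³ by
default and no temperature correction; for a continuous-flow chamber the
per-cell pulse count is $N = \mathrm{round}(f\,V_{ch}/Q)$. The default
chamber volume (0.5 ml) is chosen so that the default flow rate
(3.75 ml/min) and repetition rate (4 Hz) give $N = 32$; all three are
overridable. At the defaults the 25 and 50 ns pulses deliver 2.048 and
4.096 J/g.

## Astaxanthin scoring

The per-cell score follows the channel-arithmetic recipe: invert the
8-bit RGB image ($v \mapsto 255 - v$), treat the inverted green channel
as astaxanthin and the inverted red channel as chlorophyll, subtract red
from green pixel-wise, and sum over each cell (integrated density).
Numerical conventions:

* The subtraction is **signed and unclipped** by default. The assay
  software's clipping behaviour is unknown; signed arithmetic keeps the
  score additive over disjoint regions and exactly equal to
  (sum G_inv − sum R_inv), which is what the test oracles check. A
  `clip_negative` option reproduces the clamped dialect.
* The score is invariant to the blue channel and to any constant offset
  added to both red and green, which makes it robust to uniform
  illumination shifts.
* 16-bit inputs are rescaled to 8-bit on reading; the inversion constant
  is always 255.

**Segmentation** is not part of the original assay description, so the
implementation is a deliberately plain artifact choice, built on EBImage:
Otsu threshold on the inverted luminance, hole filling, connected
components, minimum area 50 px, border-touching regions discarded.
Touching cells merge into one region (no watershed split) — the
synthetic generator avoids overlaps, and on real data the `min_area` /
`discard_border` knobs are the intended first line of defence. Pixel
coordinates are 0-based, row-major.

Population summaries follow the replicated-imaging convention: mean per
independent experiment first, then mean ± s.e. across experiments, with
a warning (not an error) when a data point is backed by fewer than 500
cells.

## Mortality

Evans Blue enters only dead cells, so mortality is simply
$100\,\cdot\,\mathrm{stained}/\mathrm{total}$ per record, then mean ±
s.e. across the independent series. The tabular path (`CountRecord`
CSVs) is primary and bypasses imaging entirely; the image path classifies
a segmented cell as dead when its blue dominance
$\big((\bar R_{inv}+\bar G_{inv})/2 - \bar B_{inv}\big)/255$ exceeds a
margin (default 0.4). The original scoring was visual, with no published
colour threshold; the rule and margin are package inventions, validated
only against the package's own generator (where they recover planted
labels exactly at zero noise and at ≥99% accuracy at default noise). A
warning is raised when a group pools fewer than 1500 cells.

## Relative expression

The 2^(−ΔΔCt) pipeline collapses replicates in the standard order:
technical replicates are averaged per biological replicate; each target
Ct is normalised within its sample to the *actin* housekeeping gene
(ΔCt); ΔΔCt is computed per biological replicate against the **mean**
reference ΔCt of the baseline cell (untreated control at 18 h by
default) — the baseline gives no pairing between control and treated
replicates, so the mean is the only defensible reference. The summary
fold is $2^{-\overline{\Delta\Delta Ct}}$, i.e. the geometric mean of
the per-replicate folds, which makes the reference cell exactly 1 by
construction; the s.e. is taken across the per-replicate folds. Choices
left open by the assay and resolved here:

* **s.e. scope.** Whether reported errors span the 3 biological means or
  all 9 measurements is ambiguous in 3 × 3 designs; the biological-means
  convention is the default, `se_scope = "all"` provides the
  alternative.
* **Efficiency.** Fixed at 2 (plain 2^(−ΔΔCt)); the `efficiency`
  argument admits a Pfaffl-style generalisation but defaults off.
* Incomplete 3 × 3 designs are a warning, not an error; a missing
  housekeeping gene or missing baseline cell is a hard configuration
  error.

## Significance testing

`two_sample_t_test()` wraps the two-sided two-sample t-test with the
pooled-variance variant as default — the likeliest spreadsheet-era
choice — and Welch by flag. Stars follow strict cut-offs: `**` for
p < 0.01, `*` for p < 0.05. No multiple-testing correction is applied by
default, matching the reporting style the package emulates. The
degenerate zero-variance case returns t = 0, p = 1 for equal means
(p = 0 otherwise) instead of erroring, so scripted sweeps do not fall
over on constant columns.

## Synthetic data: what it emulates, and what it does not

The generators exist so every downstream stage can be validated by
parameter recovery without any deposited raw data. They emulate:

* **Micrographs**: bright background (230), cells as anti-aliased disks
  with sub-pixel edge coverage, radius 8–50 px at 0.5 µm/px (i.e.
  8–50 µm cell diameters), placed by dart-throwing with overlap
  rejection (10⁴ attempts). Inside a cell, the planted chlorophyll
  amount attenuates red, the planted astaxanthin amount (scaled by the
  scenario's attenuation level in [0, 1]) attenuates green; dead cells
  are blue-stained (red and green further attenuated, blue untouched),
  which leaves the astaxanthin score unchanged — mirroring the argument
  that per-cell scoring is insensitive to mortality. Gaussian pixel
  noise (sd 8 by default) precedes 8-bit quantisation.
* **Ct tables**: $Ct = \mathrm{base}(gene) - \log_2(\mathrm{fold}) +
  \mathcal{N}(0, sd)$ with actin constant across conditions up to the
  same noise (sd 0.2 cycles by default), over the full
  3 × 3 design. Baseline Cts (actin 18, psy 24, crtR-b 26, bkt 1 25
  cycles) are realistic mid-range values; only differences matter.
* **Counts**: stained ~ Binomial(1500, p) per series, three series.

The 12 presets (3 pulse × 4 inhibitor states) encode reported effect
narratives as point parameters: control mortality below 3%, the 50 ns
trajectory 14→19%, the 25 ns trajectory ~6% then rising to 17%;
two-fold transcript peaks at 72 h under 50 ns, the *crtR-b* drop to 1/3
under 25 ns, DPI's doubling of all transcripts, and the calcium-block
contrast (*crtR-b* 4× for 50 ns alone vs 2× with GdCl₃, in the
normalisation of that experiment — the inhibitor presets therefore carry
the pulse-alone companion arm in their own normalisation, with baseline
at 72 h, and are not comparable to the time-course presets). These are
emulation targets, not measurements.

What the generator does **not** model: optics (no point-spread function,
no chromatic effects), cell morphology beyond disks, overlapping or
clumped cells, staining chemistry, biological covariance between genes
or between technical replicates, and amplification-curve artefacts.
Passing recovery tests therefore demonstrates that the pipeline is
correct and calibrated under its stated noise model — not that it is
robust to every failure mode of real micrographs or real qPCR runs.

Determinism: a single user seed fans out to per-artefact child seeds via
a counter-based linear-congruential step, so each artefact is
independently reproducible and identical (config, seed) pairs give
byte-identical outputs.

## Problem sizes and numerical conventions

The validation suite runs at deliberately desk-friendly sizes: fold
recovery averages 50 seeded replicates of the full 3 × 3 design at Ct sd
0.2 (recovery within 15%); mortality recovery averages 200 seeded
binomial draws at 1500 cells per series (within 2 binomial s.e.);
scoring is checked against a brute-force per-pixel loop on twenty random
256 × 256 images; the t-test's size is estimated from 5000 null
simulations of the 3-vs-3 design. Image-based tests use a few hundred
cells per scenario rather than the ≥500-cell data points of a production
run; the per-cell score is size-independent, so this only widens
sampling error. Orchestrated runs (`run_scenario()`) write all tables
with 6 significant digits for diffability and a manifest with MD5
checksums; plots are flag-gated so headless runs stay file-only.

## Known limitations

* The charging model is outer-membrane only; differential effects on the
  chloroplast can be reasoned about from pulse duration vs $\tau_C$ but
  are not modelled.
* The segmentation and the dead-cell colour rule are package inventions;
  on real micrographs they should be treated as starting points and
  re-validated.
* Preset effect sizes are distilled from narrative summaries and carry
  no uncertainty of their own.
* The acceptance of the printed vs computed $\tau_C$ (598 vs 577.5 ns)
  cannot be resolved from the available parameter set; both are exposed.
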