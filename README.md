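# pefastax

Analysis toolkit for nanosecond pulsed electric field (nsPEF) treatment of
the astaxanthin-producing green alga *Haematococcus pluvialis*, and for the
readouts such experiments rely on. nsPEFs (tens of kV/cm for tens of
nanoseconds) permeabilise cell membranes and can steer stress signalling
and secondary metabolism; whether a given pulse reaches the plasma membrane
only or also inner membranes depends on how far the membrane charges during
the pulse. `pefastax` is aimed at researchers who design such treatments
and need to (a) predict permeabilisation geometry and dose from first
principles, and (b) quantify the downstream biology — pigment accumulation,
mortality, and transcript regulation — in a reproducible pipeline.

## What it computes

**Membrane charging (Schwan model).** For a spherical cell of radius *a*
in a uniform field *E*, the induced transmembrane voltage at azimuth θ
(measured from the field-axis pole) rises exponentially:

    V_m(θ, t) = E·a·cos(θ)·(1 − exp(−t/τ_C)),
    τ_C = a·C_m·(1/σ_i + 1/(2σ_e))

with C_m the specific membrane capacitance and σ_i, σ_e the cytoplasm and
medium conductivities. Inverting the cosine law at a threshold voltage
V_th (~1 V for irreversible electroporation) gives the largest
permeabilised azimuth θ\*, the fraction of the great-circle circumference
above threshold (4θ\*/360, both polar arcs) and the spherical-cap surface
fraction (1 − cos θ\*). The specific treatment energy of a pulse train in
a flow chamber is the Joule dose W = N·σ_e·E²·Δt/ρ, with the per-cell
pulse count N = f·V_chamber/Q from the residence time.

**Astaxanthin scoring.** Per-cell pigment from bright-field RGB
micrographs by the channel-arithmetic procedure: invert the image, split
channels (inverted green = astaxanthin, inverted red = chlorophyll),
subtract red from green, and sum the signed difference over each
segmented cell (integrated density).

**Viability.** Evans-Blue dye-exclusion mortality (% stained cells) from
hemocytometer count tables or from classified micrographs, aggregated as
mean ± s.e. across independent experimental series.

**Relative expression.** 2^(−ΔΔCt) transcript quantification for the
astaxanthin-pathway genes *psy*, *crtR-b* and *bkt 1* against an *actin*
housekeeping reference and an untreated-control baseline, honouring the
3 biological × 3 technical replicate design, with pooled-variance t-tests
and `*`/`**` significance stars.

**Synthetic data.** Seeded generators produce micrographs, Ct tables and
count tables with planted ground truth for all of the above, including 12
preset scenarios (3 pulse conditions × 4 inhibitor states) encoding
reported effect structures, so the entire pipeline is testable end to end
by parameter recovery.

## Worked example

```r
library(pefastax)

hp <- cell_model()            # 14 um radius, C_m 1 uF/cm2, sigma_i 10 / sigma_e 1.6 mS/cm
permeabilisation_summary(hp, field_kV_cm = 40, t_ns = c(25, 50))
#>    t_ns  v_th theta_star_deg circumference_coverage cap_coverage
#> 1    25     1           65.1                  0.723        0.579
#> 2    50     1           77.6                  0.862        0.785

specific_energy(pulse_protocol(duration_ns = 50))
#>   n_pulses w1_J_m3 W_J_kg W_J_g
#> 1       32  128000   4096  4.10
```

A 25 ns pulse at 40 kV/cm drives the membrane above the 1 V threshold out
to 65° of azimuth — 72% of the circumference — while 50 ns reaches 78°
(86%), at specific energies of ~2 and ~4 J/g for the 32-pulse train. A
full synthetic scenario runs the downstream pipeline:

```r
res <- run_scenario("50ns", seed = 7, n_images = 2)
res$mortality[res$mortality$condition == "50ns", c(2, 5, 6)]
#>   timepoint_h mortality_pct se_pct
#> 1          18          13.4  0.954
#> 2          24          15.0  0.422
#> 3          48          15.8  0.990
#> 4          72          19.1  0.956
#> 5          96          19.2  0.059

dplyr::filter(res$expression, condition == "50ns", timepoint_h == 72)
#>   gene   condition timepoint_h n_bio mean_ddct  fold se_fold
#> 1 bkt 1  50ns               72     3    -1.09   2.13  0.098
#> 2 crtR-b 50ns               72     3    -1.09   2.13  0.204
#> 3 psy    50ns               72     3    -1.04   2.06  0.179
```

Mortality rises from ~13% at 18 h to ~19% at 96 h (planted trajectory
14→19%, recovered within binomial error at 3 × 1500 counted cells), and
all three transcripts peak near the planted two-fold induction at 72 h.
`res$mortality_tests` annotates each timepoint against the control arm
(`**` = p < 0.01, pooled t-test across the three series).

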