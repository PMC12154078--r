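# endoquant

Quantitative analysis for brain microvascular endothelial cell studies:
one package covering the four computational workhorses of a typical
endothelium paper —

1. **Actin filament quantification** from phalloidin-stained micrographs by
   oriented template correlation (Fiberscore-style): per-pixel Pearson
   correlation against a bank of `K` line templates of half-length `L`,
   coefficient-of-variation tests along/across the best orientation
   (`CV_along ≤ M`, `CV_cross/CV_along ≥ N`), Guo–Hall thinning to
   skeletons, filament count and mean length above a 5 µm minimum, and
   polarity
   `P = √(D_x² + D_y²)`, `D_x = ⟨cos 2θ⟩`, `D_y = ⟨sin 2θ⟩`
   over fiber pixels (doubled angle: filaments are axial).
2. **Calcium transient parameterization** of Fura-2 I340/I380 ratio traces:
   amplitude, latency, duration, area, rising velocity and asymmetry `b/a`,
   plus the inter-parameter Pearson correlation matrix across cells.
3. **Scratch-assay wound width and migration rate**: texture-energy
   segmentation (difference of Gaussians + Otsu + morphology), orientation
   independent, with `rate = (w_t0 − w_t)/Δt` and normalization to control.
4. **Plate-assay normalization and significance**: viability/ROS/ATP/adhesion
   relative to control, ROS per nucleus, the Transwell apparent permeability
   coefficient `P_app = (dQ/dt)/(A·C_0)` in cm/s, and one-way ANOVA with
   Bonferroni or Fisher-LSD post hoc comparisons against the control.

Every stage has a synthetic-data generator with ground truth
(`gen_fiber_image()`, `gen_calcium_trace()`, `gen_wound_image()`,
`gen_plate_table()`), so the full pipeline is testable end to end without
any recordings. A YAML-configured driver (`validate_config()`,
`run_pipeline()`) and a thin CLI (`inst/cli/endoquant.R`) tie the stages
into reproducible, byte-identical runs.

## Worked example

```r
library(endoquant)

# a synthetic phalloidin field: 12 non-overlapping filaments, SNR 5
field <- gen_fiber_image(fiber_field_spec(seed = 42))
fs <- fiberscore(field$image, pixel_size = 0.25, min_length = 5)
fs
#> Oriented-template filament analysis
#> fiberscore params: L=6 (window 13x13), K=10, TC=0.55, M=0.3, N=2.1, T=0.25
#>   filaments >= 5 um: 12, mean length 18.55 um
#>   polarity: 0.805 (Dx -0.410, Dy 0.693)
```

Ground truth for this field is 12 filaments, mean length 16.88 µm,
polarity 0.821: the count is exact, length is within 10%, polarity within
0.02.

```r
# a noisy calcium transient with known shape
tr <- gen_calcium_trace(transient_spec(amplitude = 1.2, latency = 2,
                                       noise_sd = 0.03, seed = 7))
extract_params(tr)
#> transient: amplitude 1.17, latency 1.99 s, duration 9.65 s,
#>   area 4.75 ratio*s, rising velocity 0.761 /s, asymmetry 3.01 (a 1.91, b 5.75)

# a wound field at 60 degrees, 100 px gap, 0.5 um/px
w <- gen_wound_image(wound_field_spec(gap_width = 100, gap_orientation = 60,
                                      seed = 3))
detect_wound(w$image, pixel_size = 0.5)
#> wound: width 49.0 um (98.0 px, median of 348 rows), axis 56.1 deg

# Transwell permeability from cumulative basolateral amounts
permeability_coefficient(c(15, 30, 45), c(1.2, 2.4, 3.6),
                         C0_ug_ml = 200, area_cm2 = 0.33)
#> Papp = 2.02e-05 cm/s (flux 0.08 ug/min)

# viability plate with ANOVA + Bonferroni significance vs control
tab <- gen_plate_table(c(0.5, 0.55, 0.45, 0.25), rep(0.03, 4), 3,
                       seed = 5, assay = "viability")
anova_posthoc(tab)
#> one-way ANOVA: F(3, 8) = 51.010, p = 1.47e-05; post hoc: bonferroni vs control
#>  condition    estimate         t    p_raw p_adjusted stars
#>      cond2  0.06890664  2.653794 2.91e-02   8.73e-02    ns
#>      cond3 -0.05681323 -2.188042 6.01e-02   1.80e-01    ns
#>      cond4 -0.23724053 -9.136819 1.66e-05   4.98e-05   ***
```

The amplitude, latency and asymmetry land within a sampling interval of
their generating values; the wound width is within 2 px of the constructed
100 px gap despite the 60° orientation; the flux of 0.08 µg/min over a
0.33 cm² membrane under 200 µg/mL donor concentration gives
P_app ≈ 2.02 × 10⁻⁵ cm/s; and only the strongly reduced condition (cond4)
survives Bonferroni correction.

## Command-line use

```sh
Rscript inst/cli/endoquant.R all --seed 3 --out runs/demo
Rscript inst/cli/endoquant.R calcium --config my_config.yaml
```

Subcommands `simulate | fibers | calcium | wound | assays | report` run the
matching pipeline stage on synthetic inputs derived from the master seed;
outputs are CSV/TIFF/JSON under the output directory plus a `report.json`
echoing the fully resolved configuration and the MD5 of every file.
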