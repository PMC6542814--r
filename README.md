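# photoloc

Visual modelling of **diurnal active photolocation**: can a small benthic
fish detect camouflaged micro-prey by the light it redirects from its own
iris?

Triplefins (*Tripterygion delaisi*) focus downwelling daylight into a
bright **blue ocular spark** on the iris, immediately beside the pupil.
Gammarid prey carry strongly directional reflectors between the ommatidia
of their compound eyes: they return coaxial illumination several-fold more
strongly than side illumination. Because spark and pupil are nearly
coaxial, switching the spark on and off modulates the radiance of a nearby
prey eye — a self-generated cue invisible to anyone else. `photoloc`
implements the physical chain end-to-end and maps the distances over which
the cue is detectable.

## The model

For a prey eye at distance *d* with non-coaxial/coaxial relative
reflectances *R<sub>nc</sub>*, *R<sub>cx</sub>*, in a habitat whose
sidewelling:downwelling ratio is σ(λ):

- ambient radiance: *L*₀(λ) = *R<sub>nc</sub>* σ *L<sub>dw</sub>*
- spark-induced increment: Δ*L*(λ,d) = *R<sub>cx</sub>* ρ *L<sub>dw</sub>*
  Ω<sub>spark</sub>(d) / π, where ρ is the spark's radiance relative to a
  diffuse white standard and Ω<sub>spark</sub> the solid angle of the
  spark disc seen from the prey eye
- flux at the viewer: Φ(λ,d) = *L*(λ) Ω<sub>eye</sub>(d) *A*<sub>pupil</sub>

The increment crosses two solid angles, so it falls off as *d*⁻⁴ — the
universal inverse-fourth-power law of active sensing (16-fold per distance
doubling). The viewer's side applies a vertebrate A1 cone template
(single cone 468 nm; double cone 517 + 530 nm), ocular-media transmission,
quantum catches on the photon scale, the receptor-noise-limited chromatic
model (1:4 densities, ω = 0.05, threshold 1 JND), and Michelson achromatic
contrast (*Q*₁−*Q*₂)/(*Q*₁+*Q*₂) against thresholds 0.008 (optimistic) and
0.024 (conservative). Maximum detection distance is the farthest point on
a 5–45 mm grid whose contrast clears the threshold.

A seeded synthetic-data generator emulates every measured input from its
empirical summary statistics (spark peak 2.15 at 472 nm, band mean 1.34;
eye-reflectance ratios 2.68/4.09/9.87; eye radius 0.0625 mm; pupil radius
0.78 mm; 10 m coastal light field), so the whole pipeline runs with no
external data. See `vignette("active-photolocation")` for the full account
of the model, its assumptions, and its limits.

## Worked example

```r
library(photoloc)

inputs <- build_inputs(synth_config(seed = 1))
spark  <- generate_spark(synth_config(seed = 1))   # 0.16 mm, band mean 1.34

cc <- contrast_curve(inputs$light_fields$average,   # average shade
                     inputs$gammarids[["4.09"]],    # mean reflectance ratio
                     spark, inputs$viewer, inputs$visual)
head(cc, 3)
#>   distance_mm   contrast
#> 1           5 0.11108971
#> 2           6 0.07987614
#> 3           7 0.05996424
max_detection_distance(cc, 0.008)   # optimistic threshold -> 19 (mm)
max_detection_distance(cc, 0.024)   # conservative threshold -> 11 (mm)
```

An average-sized spark on an average gammarid in average shade is
detectable out to 19 mm (optimistic) or 11 mm (conservative) — roughly the
observed striking range of foraging triplefins. Sweeping all four factors:

```r
sc  <- sweep_config(spark_radii_mm = c(0.09, 0.17, 0.25),
                    spark_radiance_means = c(0.63, 1.36, 2.09), seed = 1)
map <- run_sweep(sc, inputs)

# mean max detection distance (mm, achromatic optimistic; NA counted as 0)
#>      none weak average strong
#> 2.68  4.6  9.3    16.4   27.3
#> 4.09  6.9 11.4    20.1   31.8
#> 9.87 11.3 19.1    29.4   38.9
```

Distances grow with shading of the prey, spark size and radiance, and the
directionality of the prey-eye reflector; unshaded prey are barely
detectable, and the most favourable corner saturates the 45 mm modelling
cap. The same sweep with `target = "body"` (the translucent gammarid body
as a negative control) never yields detection beyond 5 mm, and the
chromatic channel stays below threshold nearly everywhere — the cue is
achromatic and eye-specific. `plot_detection_map(map)` renders the
ratio × shading facet grid as a heatmap.

A YAML-driven interface (`cmd_sweep()`, `cmd_single()`,
`validate_inputs()`, `generate_fixture_set()`, plus the thin wrapper in
`inst/cli/photoloc.R`) runs the same pipeline from config files and writes
the detection map, contrast curves, and a seeded run log.

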