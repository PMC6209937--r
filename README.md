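# needleloc

Automatic localization of a straight biopsy needle in a co-registered pair
of 2D ultrasound images: a **power Doppler** image of the buzzer-excited
needle and a conventional **B-mode** image.

Needles are notoriously hard to see in B-mode ultrasound — speckle hides
them, bone and fascia mimic them, and at steep insertion angles the shaft
reflects the beam away from the transducer. Exciting the needle with a small
piezoelectric buzzer makes it light up in power Doppler as a trail of
irregular high-intensity blobs: easy to find, too blurry to localize
precisely. This package combines the two views, using Doppler to find the
needle and B-mode to pin it down. It is written for researchers in
ultrasound-guided interventions who want a reproducible, fully testable
implementation of the pipeline together with a synthetic phantom generator,
so that every stage can be exercised without access to an ultrasound
machine.

## Method

Three stages, each feeding the next:

1. **Doppler analysis.** The power Doppler image is thresholded with the
   iterative intermeans rule (`T ← (mean below + mean at/above)/2` to a
   fixed point), the surviving pixels are clustered with DBSCAN
   (radius R = 6 px, minimum size M = 100), and the strongest-and-longest
   line through the clustered intensities — the maximum of a discrete Radon
   transform over 0–179° at 1° steps — becomes the **initial needle axis**.
   Clusters are then summarized as moment-equivalent ellipses and any
   ellipse not touching the initial axis is discarded.
2. **B-mode refinement.** The B-mode image is filtered with a single
   complex Gabor kernel matched to the needle: wavelength λ = needle
   diameter in pixels, envelope widths σₓ = λ/(2√(2 ln 2)) across and
   σᵧ = λ/√(2 ln 2) along (both fixed by requiring 50% amplitude at
   x′ = λ/2 and y′ = λ), oriented along the initial axis. The response
   magnitude is kept only inside the surviving ellipses, and the Radon
   projection *at the initial angle only* refines the axis offset.
3. **Tip localization.** A window of 2 × 1 needle diameters slides along
   the refined axis, recording mean Doppler and B-mode profiles
   I̅_PD(l), I̅_BM(l). The Doppler profile is binarized at its own mean and
   the separation score
   S_PD(l) = [Σ_{i≤l} B_PD(i) + Σ_{i>l} (1 − B_PD(i))] / L
   is maximized — the best "strong before, weak after" split. Within two
   diameters of that split, the strongest drop (most negative forward
   difference) of the B-mode profile is the **tip**.

Scoring follows the field's conventions: the axis error is the larger of
the two distances from the true entry and tip to the estimated axis, a
trial *fails* when it reaches 3 mm, and errors are summarized per
insertion-angle bin (shallow 0–20°, moderate 20–40°, steep 40–65°).

## Worked example

```r
library(needleloc)

# a synthetic acquisition: 18G needle, 42 degrees, 65 mm deep, known truth
cfg <- phantom_config(seed = 17, insertion_angle = 42, insertion_depth = 65)
ph  <- generate_phantom_pair(cfg)

pc  <- pipeline_config(pixel_spacing = 0.3, needle_diameter = 1.27, verbose = TRUE)
res <- run_pipeline(ph$doppler, ph$bmode, pc)
#> intermeans threshold: 0.399
#> DBSCAN clusters: 2
#> initial axis: theta 132.0 deg, rho -22.0 px
#> ROIs retained: 1 of 2
#> refined axis: rho -24.0 px
#> tip index: doppler 221, refined 213
res
#> <localization_result> axis 42.0 deg, entry (1.0, 20.3), tip (143.5, 178.6)

axis_error(ph$truth, res$axis, 0.3)   # 0.07 mm
angle_error(ph$truth, res$axis)       # 0.00 deg
tip_error(ph$truth, res, 0.3)         # 1.03 mm
```

Reading the log: the intermeans threshold (0.399) keeps the Doppler blobs
and drops the noise floor; DBSCAN finds two clusters, of which one — a
spurious off-needle response — is eliminated because its ellipse misses the
initial axis; the B-mode stage shifts the axis offset by 2 px onto the true
shaft (final axis error 0.07 mm against ground truth, i.e. under a quarter
of a pixel); the B-mode derivative pulls the tip estimate 8 px back from
the Doppler split, landing 1.03 mm from the true tip (well under the
1.27 mm needle diameter).

A thin command-line front end over the same functions lives in
`inst/cli/needleloc.R`
(`phantom | axis-init | axis-refine | localize | evaluate`), e.g.

```sh
Rscript inst/cli/needleloc.R phantom --seed 3 --angle 35 --depth 60 --out-dir out/
Rscript inst/cli/needleloc.R localize --doppler out/phantom_seed3_doppler.tif \
    --bmode out/phantom_seed3_bmode.tif --spacing 0.3 --out out/result.json
```

## Package layout

| Path | Contents |
| --- | --- |
| `R/phantom.R` | synthetic speckle phantom generator with exact ground truth |
| `R/doppler_axis.R` | intermeans threshold, DBSCAN, Radon transform, ellipse ROIs |
| `R/bmode_axis.R` | Gabor kernel, masked filtering, fixed-angle refinement |
| `R/tip_localization.R` | axis profiles, S_PD split, B-mode drop refinement |
| `R/evaluation.R` | axis/angle/tip errors, failure rate, angle-binned scoring |
| `R/pipeline.R`, `R/image_grid.R`, `R/geometry.R` | orchestration, I/O, containers |
| `vignettes/needle-localization.Rmd` | the methods vignette: model, parameters, design notes |

See the methods vignette for the full account of the model, the phantom's
assumptions, and the numerical design decisions.
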