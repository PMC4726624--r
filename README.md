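# shgquant

Observer-independent quantification of early liver fibrosis and steatosis from
label-free, two-channel nonlinear microscopy mosaics.

Histological staging of early fibrosis in non-alcoholic fatty liver disease
(NAFLD) is notoriously rater-dependent: most disagreement between pathologists
falls in the stage-0/stage-1 range, exactly where early intervention matters.
Second-harmonic generation (SHG) microscopy images fibrillar collagen directly
and without stains, and coherent anti-Stokes Raman scattering (CARS) does the
same for fat — so a stitched SHG/CARS mosaic of a whole biopsy section carries
enough signal to score fibrosis and steatosis *continuously*, by intensity,
instead of by ordinal visual grading. The catch is that the liver capsule and
the portal tracts are collagen-rich in a perfectly healthy liver; their bright
SHG signal must be found and excluded before the weak parenchymal fibrils that
actually mark early fibrosis can be measured.

`shgquant` implements that measurement as a tested R package:

1. **Specimen border** — the SHG and CARS channels are overlaid (pixelwise
   maximum), auto-thresholded by the percentile (p-tile, *p* = 0.5) method,
   and the 0/255 binary mask is smoothed by circular mean → maximum → mean
   rank filters with radii 50/15/50 µm, then cut at 9.8 % of the 8-bit maximum
   (level 25). The largest connected component (plus any component ≥ 1 % of
   its area) is the sample mask.
2. **Capsule and portal exclusion** — SHG pixels above the mean intensity over
   the sample are smoothed with radii 15/35/25 µm, cut at 1.17 % (level 3),
   and submitted to particle analysis. Particles that are large
   (≥ 2000 µm²) and compact (roundness = 4·A/(π·major-axis²) ≥ 0.15), or that
   touch the inner 50 µm border band of the sample (the capsule), are excluded.
3. **Scoring** — per biopsy, with background *b* = mean intensity outside the
   sample and parenchyma P = sample ∖ excluded:

   `mean_shg = max(0, mean(SHG | P) − b_SHG)`, analogously for CARS, plus
   `fold_over_background = mean(SHG | P) / b_SHG`.

A synthetic biopsy-phantom generator (tissue blob, capsule band, portal
tracts, wavy 20–200 µm fibrils, lipid droplets, nonnegative noise — with
ground-truth masks) makes the whole pipeline testable end to end, and a small
statistics layer supplies the cohort tests such data calls for: an exact
Mann–Whitney U test (enumeration with midranks up to combined n = 20),
Spearman rank correlation, and linear/quadratic weighted kappa for inter-rater
agreement.

## Worked example

```r
library(shgquant)

# a stage-1, steatosis-grade-2 phantom biopsy: ~4.1 x 4.1 mm at 4 um/px
p <- generate_phantom(phantom_spec(stage = 1, steatosis_grade = 2,
                                   frame_px = c(1024, 1024),
                                   pixel_size_um = 4, seed = 7))
q <- quantify_mosaic(p$image)
q
#> <shg_quant>
#>   mean SHG     0.147  (raw 8.162, background 8.015)
#>   mean CARS   57.715  (raw 65.715, background 8.001)
#>   fold over background 1.02
#>   sample 12.276 mm^2, excluded 2.890 mm^2, parenchyma fraction 0.765
```

Reading this: the specimen covers 12.3 mm², of which 2.9 mm² (capsule +
portal areas) were excluded. After subtracting the 8.0-unit background, the
parenchyma carries a weak fibrillar SHG signal of 0.147 intensity units —
the continuous fibrosis score — and a CARS signal of 57.7 units reflecting
hepatocyte fat (grade 2 here adds bright lipid droplets to the baseline
hepatocyte signal). `tidy(q)` returns the same numbers as a one-row tibble;
`autoplot(segment_mosaic(p$image))` draws the mask map.

Cohort workflow:

```r
co  <- generate_cohort(5, seed = 1)      # 25 phantoms, stages 0-4
tab <- quantify_cohort(co)               # tidy cohort table
stage_summary(tab)                       # per-stage stats + adjacent Mann-Whitney
autoplot(tab)                            # per-sample scores by stage
```

## Command line

A thin wrapper over the same functions ships in `inst/cli/`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "shgquant.R", package = "shgquant"))')
Rscript "$CLI" simulate --out sim --n-per-stage 1 --seed 3
Rscript "$CLI" quantify sim/S01.tif sim/S02.tif --out quant
Rscript "$CLI" report quant/results.csv --out rep --manifest sim/manifest.csv
```

`quantify` writes one CSV row per biopsy plus a YAML record of the full
effective configuration; `--save-intermediates` additionally writes the
intermediate masks as 8-bit TIFFs. Mosaics are read as two-page grayscale
TIFFs; the pixel pitch comes from an explicit argument, the JSON sidecar
written by `write_mosaic()`, or TIFF resolution tags — never a silent default.

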