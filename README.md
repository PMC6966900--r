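# ramanlcw

Label-free Raman chemical imaging of plant cell-wall lignocellulose.

Confocal Raman microspectroscopy can map a plant tissue section pixel by
pixel at subcellular resolution, and cellulose, hemicellulose and lignin
each have diagnostic bands (1089 cm⁻¹ polysaccharide, 1508/1620 cm⁻¹
lignin aromatics, 1739 cm⁻¹ hemicellulose carbonyl). But plant tissue
fluoresces, and the fluorescence background often dwarfs the Raman peaks:
images of single diagnostic bands end up showing the fluorescence, with
chemically distinct polymers producing near-identical pictures. This
package implements the full-spectrum alternative for researchers
quantifying cell-wall composition (e.g. the effect of alkali pretreatment
on biomass for anaerobic digestion): unmix every pixel against full-range
reference spectra of the pure polymers.

## The model

Each map is unfolded into a pixel-by-band matrix **D** and modelled as a
linear mixture

```
D = C Pᵀ + R,      Σⱼ Cⱼ = 1,   Cⱼ ≥ 0,
```

where the rows of **Pᵀ** are the k pure-component reference spectra, **C**
holds per-pixel abundance fractions constrained to the probability
simplex, and **R** is the residual. Abundances are estimated per pixel by
fully constrained least squares (FCLS, an active-set solver) and converted
to concentrations by `(Cⱼ)cal = Cⱼ × W`, with `W` the combined dry-base
content of the k components from laboratory analysis.

Around the solver sits the full analysis chain:

* **Preprocessing** — Otsu background segmentation, cosmic-ray despiking
  (modified z-score vs a running median), PCA denoising (first three
  PCs), airPLS baseline correction (compiled pentadiagonal Whittaker
  solver), area/max normalization.
* **Wavelet features** — level-8 DWT single-branch reconstruction
  (A8, D1…D8); the mid-level D6 branch suppresses both high-frequency
  noise and the low-frequency fluorescence background.
* **Classification** — PCA clustering with loading-weight band analysis
  (|loading| > 0.025), and LDA/KNN classifiers over a grid of feature
  signals × band sets (full range vs the 1620 + 1089 cm⁻¹ fingerprint
  pair) on a stratified 3:1 split.
* **Imaging** — per-component concentration images, single-band images
  for comparison, concentration histograms, and bulk-composition
  arithmetic tying the images back to wet-chemistry measurements.
* **Synthetic scenes** — a ground-truth generator (tissue-like layouts,
  fluorescence backgrounds, cosmic spikes, Gaussian noise) used by the
  validation suite.

## Worked example

```r
library(ramanlcw)

# a synthetic alkali-treated scene (40 x 50 pixels) with fluorescence,
# noise and cosmic spikes; retention ratios 0.87/0.47/0.75
scene <- render_scene("cells", shape = c(40, 50),
                      effect = c(0.87, 0.47, 0.75), seed = 7)

refs <- default_components()$references
out <- chemical_imaging_pipeline(scene$map, refs, W = 53.4,
                                 normalize = "none")
out$result
#> <abundance_result> 40 x 50 pixels, 3 components (cellulose, hemicellulose,
#> lignin), 1658 unmixed, calibrated to W = 53.4% d.b.

fg <- scene$truth_labels != "background" & out$map$mask
mean(abs(out$result$abundance[fg, ] - scene$truth_abundance[fg, ]))
#> 0.0227
round(colMeans(out$result$calibrated[fg, ]), 2)
#>     cellulose hemicellulose        lignin
#>         29.06         11.71         12.63
```

The recovery error says the pipeline re-estimates each pixel's abundance
fractions to about two percentage points despite the nuisance signals;
the calibrated means are the map-wide concentrations in percent dry base
(summing to W = 53.4 up to the background mask). `plot(out$images$lignin)`
renders the lignin concentration image;
`concentration_histogram(out$images, 30)` tabulates the per-pixel
concentration distributions.

Bulk composition arithmetic from wet-chemistry dry-base contents:

```r
composition_report(
  before = c(cellulose = 39.5, hemicellulose = 33.2, lignin = 4.5),
  after  = c(cellulose = 34.4, hemicellulose = 15.6, lignin = 3.4),
  gas = c(126.30, 236.35))
#> <composition_report>
#>   cellulose       39.50 ->  34.40  (reduced 12.9%, ~13%)
#>   hemicellulose   33.20 ->  15.60  (reduced 53.0%, ~53%)
#>   lignin           4.50 ->   3.40  (reduced 24.4%, ~24%)
#>   totals: 77.2 -> 53.4 (delta 23.8)
#>   gas yield: 126.3 -> 236.3 (+87.1%)
```

## Documentation

The methods vignette (`vignettes/chemical-imaging-methods.Rmd`) documents
the model and its assumptions, the preprocessing chain and why denoising
precedes baseline correction, the scale conventions for unmixing, the
synthetic generator's design and its limits, and the package's numerical
edge-case behaviour.
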