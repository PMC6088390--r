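# sphericell

Dividing cells orient themselves arbitrarily, so voxel coordinates of 3D
immunofluorescence stacks cannot be compared between cells. `sphericell`
registers each mitotic cell into a standardized spherical coordinate system:
six concentric shells crossed with three latitude sectors relative to the
division plane (polar, diagonal, equatorial) give 18 regions of interest
(ROIs) aligned to the mitotic axis. On top of that registration it provides

* per-cell summary measures — concentration `c`, abundance `a`, center of
  eccentricity `r` and center of orientation `phi` — with Welch tests on
  log measures, Bonferroni correction and seeded bootstrap confidence
  intervals for group comparisons;
* a steady-state affinity model that explains the ROI intensities of every
  stained species `i` in ROI `l` of a cell with normalized totals `Ĩ_t` by

  `Ĩ_il = d_i α̃_il Ĩ_i,t (1 + Σ_j α̃_jl β_ij Ĩ_j,t)`

  — compartment affinities `α̃` (per species, ROI and mitotic phase),
  scaling factors `d`, and symmetric pairwise affinities `β` between
  species — fitted by bounded multi-start Levenberg–Marquardt in log10
  space with the heteroscedastic error `ε = 0.05·value + 0.05·max`,
  plus likelihood-ratio forward selection of new pairwise affinities and
  withdrawal (contribution) tests;
* seeded synthetic generators — image phantoms with known mitotic geometry
  and model-generated intensity tables — so the whole pipeline is testable
  without microscope data.

It is aimed at groups running multiplexed (iterative) immunofluorescence of
mitotic cells in 3D culture who need orientation-independent quantification
and a mechanistic readout of where proteins are recruited and with whom.

## Worked example

Generate a metaphase phantom, register it, and read off the per-channel
measures:

```r
library(sphericell)

cfg   <- phantom_config()                  # oblate chromatin plate, 3 channels
ph    <- make_phantom(cfg, seed = 1)
comps <- segment_chromatin(ph$stack)       # Otsu + 26-connected components
efit  <- fit_ellipsoid(comps[[1]], dim(ph$stack$voxels)[1:3], ph$stack$spacing)
frame <- build_frame("metaphase", efit)
frame
#> mitotic_frame [metaphase]
#>   center (z,y,x um): 19.50, 17.75, 17.75
#>   axis   (z,y,x):    1, 0, 0
#>   sphere radius:     11.92 um
map <- bin_stack(ph$stack, frame)
cell_measures(map)
#>     channel    c      a     r  phi
#> 1      DAPI 25.2 178285 0.293 49.4
#> 2 b-tubulin 12.7  89843 0.394 36.5
#> 3 g-tubulin 10.5  74677 0.517 42.9
```

The recovered axis and radius match the phantom's ground truth (true R = 12
µm). The measures read as expected: DAPI mass sits centrally (`r` = 0.29,
inner shells — the chromatin plate), the spindle marker b-tubulin points
along the axis (`phi` = 36.5°, toward the poles), and the centrosome marker
sits further out (`r` = 0.52).

Fit the affinity model to a simulated cohort with two known interactions:

```r
truth <- random_affinity_truth(c("DAPI", "A", "B", "C"),
                               interactions = list(c(1, 2), c(3, 4)), seed = 11)
tot   <- simulate_cell_totals(truth, 120, seed = 12)
ds    <- simulate_roi_dataset(truth, tot, seed = 13)
fit   <- fit_affinity_model(ds, list(c(1, 2), c(3, 4)), n_starts = 10,
                            seed = 3, gauge = "reference")
summary(fit)
#> Affinity model: rss = 5960.21 on 8640 residuals, 152 parameters
#>   multi-start: 11 starts, spread 2.73e-12, converged: TRUE
#>   reference gauge species: DAPI, B
#>   scaled compartment affinities (d * alpha) in [0.313, 3.278]
#>   ...
#>   pairwise affinities:
#>  species_i species_j   beta
#>       DAPI         A 1.0887
#>          B         C 0.8807
```

Both planted affinities (true value 1) are recovered on the right pairs; the
weighted RSS is at the noise floor and the multi-start spread is far below a
single residual, the fit's convergence criterion. `forward_select()` adds
candidate pairs by the χ²(1) likelihood-ratio rule and
`contribution_test()` removes them again; see the methods vignette
(`vignettes/sphericell-methods.Rmd`) for the model, its identifiability
gauge, and the calibration caveat for component-bridging candidates.

A thin command-line wrapper covering the pipeline
(`simulate-image`, `simulate-table`, `bin`, `measure`, `compare`, `fit`,
`select`, `render`) ships in `inst/cli/sphericell.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/sphericell.R", package = "sphericell"))')" --help
```

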