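---
title: "Spherical registration and affinity modelling of mitotic cells: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spherical registration and affinity modelling of mitotic cells: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sphericell)
```

## The problem

Multiplexed immunofluorescence of dividing cells produces, per cell, a 3D
stack with a DAPI channel and several antibody channels. Cells divide in
arbitrary orientations, so raw voxel coordinates are not comparable between
cells. This package registers each mitotic cell into a standardized
spherical coordinate system ("SpheriCell"): six concentric shells of equal
radial width crossed with three latitude sectors relative to the division
plane — polar, diagonal, equatorial — give 18 regions of interest (ROIs)
aligned to the mitotic axis. Mean ROI intensities are then the common
currency for per-cell summary measures, group statistics, and a steady-state
affinity model that explains the spatial intensity pattern of every stained
species by its affinity to each ROI's structures and by pairwise affinities
between species.

## Registration geometry

The mitotic axis and cell size are derived from chromatin landmarks in the
DAPI channel:

* **Metaphase.** Chromatin condenses into an oblate plate. A global Otsu
  threshold segments the DAPI signal; the largest 26-connected component is
  summarized by its second moments, and half-axes are obtained from the
  eigenvalues via the uniform-solid-ellipsoid relation
  \(a_k = \sqrt{5\lambda_k}\). The mitotic (spindle) axis is the eigenvector
  of the shortest half-axis; the sphere radius is \(R = 1.5\,a_1\), which
  places the outer edge of the fourth of six shells at the longest chromatin
  half-axis \(a_1\) (the inner four shells span the chromatin plate).
* **Segregation** (anaphase and telophase pooled). Two chromatin bodies are
  segmented; the axis is the centroid-to-centroid direction, the center the
  midpoint, and \(R = 1.5\,(d/2)\) for centroid distance \(d\), so the
  fourth shell boundary passes through both centroids.

The axis sign is normalized (nonnegative z-component, ties resolved on y
then x); all downstream binning uses the absolute latitude from the division
plane, so the sign never matters. Before binning, the stack is resampled to
isotropic voxels by linear interpolation along z at the in-plane pitch;
every voxel center inside the sphere is assigned to exactly one ROI with
lower-inclusive latitude bands (equatorial \([0^\circ, 30^\circ)\), diagonal
\([30^\circ, 60^\circ)\), polar \([60^\circ, 90^\circ]\)) and shell index
\(\min(6, \lfloor 6\rho/R \rfloor + 1)\). These tie-break rules make the
assignment a deterministic total function.

The published workflow tiles the sphere into 180 equal-area segments and
joins them into the three bands; binning voxels directly by latitude gives
mathematically identical band membership without the tiling step, and is
what this package does.

An ambiguity worth recording: for segregating cells the upstream description
mentions combining chromatin-ellipsoid eigenvectors with the
centroid-to-centroid vector. This package uses the centroid-to-centroid
vector alone as the mitotic axis — it is the construction the landmark
figures draw, and it is well defined whenever the centroids are distinct.

## Per-cell measures and group statistics

With ROI mean intensities \(I_{\mu\nu}\) and volumes \(V_{\mu\nu}\):

* concentration \(c = \sum I_{\mu\nu} V_{\mu\nu} / \sum V_{\mu\nu}\),
* abundance \(a = \sum I_{\mu\nu} V_{\mu\nu}\),
* center of eccentricity \(r = \sum I_{\mu\nu} r_\mu / \sum I_{\mu\nu}\)
  with \(r_\mu = (\mu - \tfrac12)/6\),
* center of orientation \(\varphi = \sum I_{\mu\nu} \varphi_\nu / \sum
  I_{\mu\nu}\) with \(\varphi_\nu = 15^\circ, 45^\circ, 75^\circ\) for
  polar, diagonal, equatorial.

The numeric values \(r_\mu\) and \(\varphi_\nu\) are the shell mid-radii and
sector mid-latitude angles measured from the mitotic axis — the symmetric,
monotone choice for "center of" scores. With this convention a positive
eccentricity change means movement toward the periphery, and a positive
orientation change means movement toward the division plane.

Concentrations and abundances are log-normally distributed across cells, so
group comparisons use Welch's t-test on log values and report the log2 ratio
of geometric means; the bounded location scores \(r\) and \(\varphi\) are
compared on the raw scale (their rationale for log-transforming does not
apply). Significance uses Bonferroni thresholds — \(0.05/52 \approx 9.62
\times 10^{-4}\) for the per-species measure panels, \(0.05/18\) for per-ROI
maps — and percentile bootstrap intervals (1,000 resamples, seeded). The
composition of the 52-comparison family is a parameter (`m`), not a
constant. BCa intervals were deliberately not used: the percentile method is
the simplest seeded, assumption-light choice, and the coverage check below
verifies it suffices at these sample sizes.

## The steady-state affinity model

Reversible binding of species to the structures in an ROI, plus reversible
pairwise dimerization of bound species, gives at steady state (free pools
non-limiting) a bound concentration proportional to the free concentration
over the dissociation constant, and a dimer concentration proportional to
the product of the two free concentrations over both compartment constants
and the dimer constant. After normalizing every intensity by the per-species
population median of the volume-weighted cell average, the measured ROI
intensity of species \(i\) in ROI \(l\) of a cell with normalized totals
\(\tilde I_{j,t}\) is

\[
\tilde I_{il} = d_i\,\tilde\alpha_{il}\,\tilde I_{i,t}
\left(1 + \sum_j \tilde\alpha_{jl}\,\beta_{ij}\,\tilde I_{j,t}\right),
\]

with phase-specific scaling factors \(d\) and compartment affinities
\(\tilde\alpha\) (metaphase vs. segregation fitted jointly), and symmetric,
phase-independent pairwise affinities \(\beta\) restricted to a configured
interaction set. Each data point is weighted by the heteroscedastic error
\(\varepsilon = 0.05\,\tilde I_{il} + 0.05\,\max_i \tilde I_{il}\) (maximum
per species over all included cells and ROIs); the weighted residual sum of
squares is \(-2\log L\) up to a constant. The weighted residual is
\((\text{data} - \text{model})/\varepsilon\) — the standard weighted
least-squares form consistent with treating the RSS as a chi-square.
Cell-average intensities enter the model as inputs (the totals), not as
residuals; `summary()` of a fit reports how well the volume-weighted average
of the fitted ROI intensities tracks them. For datasets normalized from raw
tables this identity holds in the data by construction, so the diagnostic
reads on the model; for simulated datasets the totals are free inputs and
the diagnostic instead reflects how far the generating parameters sit from
self-consistency — expect values near zero only in the former case.

### Identifiability and the reference gauge

The parameterization has exact flat directions: within any connected
component of the interaction graph, multiplying the \(\tilde\alpha\) rows of
all member species by a constant \(c\), dividing their \(d\) by \(c\) and
dividing the component's \(\beta\) entries by \(c\) changes no prediction.
For species with no interactions this is the familiar statement that only
the product \(d\,\tilde\alpha\) is determined. Consequently raw \(\beta\)
values are only defined up to one scale per component — in any fitting
protocol, including the original fully free one. `fit_affinity_model(gauge =
"reference")` removes every flat direction by fixing the first-phase scaling
factor of one representative species per component to 1; `gauge = "free"`
reproduces the fully free parameterization, in which case products
\(d \tilde\alpha\) and within-component ratios of \(\beta\) remain the
interpretable quantities. Warm starts are gauge-canonicalized (a
prediction-preserving rescaling) before packing, so refits across different
interaction sets stay consistent.

### Optimization

Parameters are fitted in log10 space by bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`) with an analytic Jacobian; bounds are
\([10^{-3}, 10^{2}]\) for \(\tilde\alpha\) and \(d\) and
\([10^{-7}, 10^{2}]\) for \(\beta\). Multi-start proceeds as a race: every
start (log-uniform within bounds, plus a deterministic start at the bound
midpoints and an optional warm start) receives a short iteration budget
(default 10), the best fifth continues with a tripled budget, and the top
three are polished to convergence (default cap 300 iterations, relative
tolerances \(10^{-10}\)). A fit is flagged converged when the RSS spread
between the best and runner-up start is below the largest squared
single-datapoint residual — the same convergence assurance used in the
original protocol. The racing schedule exists because a full LM polish of
every random start is wasted effort on starts that have already committed to
a poor basin; the deterministic midpoint start empirically lands in the
dominant basin and makes small-`n_starts` fits reliable.

### Forward selection and withdrawal tests

Starting from the known (literature) interaction set, each selection step
refits the model once per remaining candidate pair (homodimers included) and
accepts the candidate with the largest RSS reduction if it exceeds
\(\chi^2_{0.95}(1) = 3.841\); selection stops when no candidate passes.
Best-first acceptance (largest reduction) is used — deterministic and
standard for greedy likelihood-ratio selection. Two safeguards matter in
practice:

* every candidate refit is warm-started from the current best fit (the
  models are nested, so the comparison is meaningful), and
* after the best candidate is identified, the current model is refitted
  warm-started from the candidate optimum with the extra pair removed. This
  back-refit guards against a poorly converged reference model, which would
  otherwise inflate the apparent improvement by orders of magnitude.

`contribution_test()` implements the converse withdrawal test: remove one
fitted pair, refit, and compare the RSS increase to the same threshold.

**A caveat on bridging candidates.** When a candidate pair connects two
previously unconnected components of the interaction graph, the merged
component's relative scale becomes newly identifiable — the alternative
model effectively gains about two degrees of freedom, not one (the pairwise
affinity and the relative scale, a parameter that exists only under the
alternative). The \(\chi^2(1)\) cutoff is therefore anticonservative for
bridging pairs: in simulation their null acceptance rate is roughly what
\(\chi^2(2)\) predicts (15–20% at a nominal 5%), while within-component
candidates are correctly calibrated (5–7% measured). The selection routine
keeps the classical \(\chi^2(1)\) rule for comparability; the calibration
experiment in the acceptance suite therefore uses within-component
candidates, and discovered interactions that newly bridge components should
be read with this caveat in mind.

## The synthetic-data generators

Two generators make the pipeline testable without microscope data.

**Image phantoms** (`make_phantom()`) place a metaphase chromatin ellipsoid
(default half-axes 8, 8, 4 µm, shortest axis along the configured mitotic
axis) or two congruent segregation daughters at a configured centroid
distance into a stack with anisotropic voxels (default 1 × 0.5 × 0.5 µm, the
z-anisotropy of confocal stacks), and synthesize antibody patterns
(spindle, centrosome blobs at the poles, uniform, cytoplasmic shell) from
the same geometry. Gaussian read noise (default sd 2 at background 10,
amplitudes 80–120) and optional Poisson shot noise are added after pattern
synthesis — a standard fluorescence-microscopy approximation; both can be
switched off for exact tests. No point-spread function is simulated, so
phantom tests validate geometry and bookkeeping, not deconvolution-limited
resolution.

**Intensity tables** (`simulate_cell_totals()`, `simulate_roi_dataset()`)
draw per-cell species totals log-normally (protein levels are log-normally
distributed across cells) and evaluate the steady-state model exactly, then
optionally add Gaussian noise with the same 5% + 5%-of-max error model used
as fitting weights, truncated at zero — making recovery tests
self-consistent. The frozen defaults are the package's study conditions:
compartment affinities log-uniform over one decade centered at 1
(median-normalized data are of order 1), scaling factors 1, planted pairwise
affinities 0.5 (the recruitment-dominant regime the model itself assumes:
the dimer term is subordinate to direct compartment recruitment), log-normal
sd 0.4 (≈ 40% CV, typical cell-to-cell protein variability), equal phase
fractions. Under these conditions the simulated tables have a dynamic range
of roughly 15× and essentially no zero-truncated values — the regime the
assay actually produces. Totals are drawn independently per species;
between-species correlation is not simulated.

A consequence of the error model worth stating plainly: the 5%-of-maximum
floor makes the dimmest ROI entries unquantifiable (per-point signal-to-
noise below 1), for real data as for simulated data. Recovery of the
\(d\tilde\alpha\) products is therefore assessed by their median relative
error (about 8% at the study conditions below; the worst dim entries can be
off by over 50%), and planted \(\beta\) values are recovered with a log10
RMSE of about 0.1 under the reference gauge.

## Problem sizes used by the tests and the acceptance script

All checks run on one CPU. The acceptance script uses: 100 random toy
kinetic systems for the ODE-vs-closed-form oracle (agreement to 1e-6); 20
phantoms per mitotic phase with random axes for geometry recovery (median
axis error well under 3°, median radius error under 5%); one recovery
experiment with 4 species, 200 cells, 3 planted interactions and 50 starts;
200 single-candidate null replicates (20 cells each) and 10 planted-signal
replicates (50 cells) for selection calibration; 400 simulated
52-comparison families for the family-wise error of Welch-on-log testing;
and 500 replicates of bootstrap interval coverage (1,000 resamples each).
The test suite repeats the same checks at reduced replicate counts. Every
randomized computation flows through an explicit seed; regenerating with
the same seed is bit-identical.

## Known limitations

* No inter-round registration, mitosis classification, deconvolution or
  multi-cell scene handling — inputs are single registered cells.
* The affinity model explains enrichment; a fitted pairwise affinity is
  evidence of co-recruitment, not proof of direct binding.
* No uncertainty quantification on fitted affinities beyond the
  likelihood-ratio machinery (no profile likelihood or resampling).
* The \(\chi^2(1)\) selection threshold is anticonservative for
  component-bridging candidates (see above).
* Fitted \(\beta\) values are comparable across runs only under a fixed
  gauge convention.
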