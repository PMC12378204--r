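---
title: "Methods: phase-field chromatin, LAD quantification and parameter extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-field chromatin, LAD quantification and parameter extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ladscape` studies how nuclear chromatin organises into interior
heterochromatin domains and lamina-associated domains (LADs), and how the
sizes of those structures encode two biophysical parameters: the
effective histone methylation rate $\Gamma_{me}$ and the chromatin–lamina
affinity $V_{LAD}$. This vignette is the package's own account of the
model, the estimators, the numerical choices, and their limitations.

## The phase-field model

The nucleus is described by volume fractions of heterochromatin
$\phi_h$, euchromatin $\phi_e$ and nucleoplasm $\phi_n$, with
$\phi_h+\phi_e+\phi_n=1$. The state variables are $\phi_n$ and the order
parameter $\phi_d=\phi_h-\phi_e$. The free-energy density is

$$
f=\frac{c}{2}\left[\phi_e^2+\phi_h^2(\phi_{h0}-\phi_h)^2\right]
+\frac{\kappa}{2}\left[|\nabla\phi_n|^2+|\nabla\phi_d|^2\right]
-\frac{V(\phi_h)}{d_0}e^{-d/d_0},
$$

a double well with minima at the euchromatic phase
$(\phi_h,\phi_e)=(0,0)$ and the heterochromatic phase $(\phi_{h0},0)$,
an interfacial penalty, and an adhesion term confined to a layer of
width $d_0$ against the nuclear envelope ($d$ is the distance to the
lamina). Note the well interpretation this bulk term implies: the
euchromatic minimum is *water-rich* — loosely packed chromatin is mostly
nucleoplasm — while the heterochromatic phase is compacted and
water-poor. We implement the bulk term exactly in this printed form; no
logarithmic entropy-of-mixing extension is included, so transient
excursions outside the composition simplex are possible (see
*Numerical choices*).

Dynamics are conserved gradient flows plus reaction kinetics:
$\partial_t\phi_n=M_n\nabla^2\mu_n$ and
$\partial_t\phi_d=M_d\nabla^2\mu_d+2(\Gamma_{me}\phi_e-\Gamma_{ac}\phi_h)$,
with $\mu_{n,d}=\delta f/\delta\phi_{n,d}$. Methylation converts
acetylated marks at rate $\Gamma_{me}$ (itself the harmonic composition
of the HDAC and HMT sub-steps, `composite_rate()`), acetylation reverses
at $\Gamma_{ac}$; a spatially uniform system relaxes to
$\phi_h/(\phi_h+\phi_e)=\Gamma_{me}/(\Gamma_{me}+\Gamma_{ac})$.

### Parameters, units and defaults

Everything is in nm, s, pN.

| parameter | meaning | default | why |
|---|---|---|---|
| `c` | chromatin–chromatin interaction per volume | 8e-3 pN/nm² | lower end of the 2–4 kT per nucleosome estimate |
| `kappa` | interfacial penalty | 0.8 pN | gives `l_int = sqrt(kappa/c)` = 10 nm |
| `phi_h0` | heterochromatic well composition | 0.8 | compact but hydrated heterochromatin |
| `d0` | lamina interaction decay length | 2.5 nm | anchoring-protein size |
| `V_EC`, `V_HC` | lamina affinity of each phase | 0, set per run | `V_LAD = V_HC - V_EC`; `V_EC = 0` so `V_LAD == V_HC` |
| `M_n`, `M_d` | mobilities | 1.25e5 | sets the nucleoplasm diffusion scale `M c` = 1000 nm²/s |
| `Gamma_ac` | acetylation rate | run-specific | see the Damköhler discussion below |
| `D_h` | effective mark diffusivity | `M_d * c` | the diffusivity scale implied by mark mobility and well curvature |

The affinity interpolation $V(\phi_h)$ is a linear ramp between
$V_{EC}$ and $V_{HC}$ clipped to $[0,\phi_{h0}]$ and is pluggable
(`model_params(V_fn = )`): only the two anchors are physically
constrained and the LAD morphology depends on them only through
$V_{LAD}$.

A point worth making explicit: the reaction rates only produce
*size-selected* domains when reactions are slow compared with diffusion
across a domain (Damköhler number below one). If $\Gamma$ exceeds
$D_h/R_d^2$ the marks equilibrate locally, the reaction term becomes
transparent, and domain growth reverts to ordinary coarsening. The
package's reference configuration sits in the slow-reaction regime
($\Gamma_{ac}\sim0.1\,\mathrm{s^{-1}}$ against
$D_h/R_d^2\sim0.1$–$1\,\mathrm{s^{-1}}$).

### Numerical scheme

Space is a square lattice restricted to a circular or elliptic nucleus
mask, spacing `h` (the recommendation `h <= l_int/2` is surfaced as a
warning; the reference runs use `h = l_int`, which under-resolves
interfaces but leaves domain-scale morphology intact — interface-width
diagnostics run on finer 1D profiles). Gradients and Laplacians use the
5-point stencil with mirror (no-flux) closure: a neighbour outside the
mask contributes zero flux, which makes the update *exactly*
conservative — total $\phi_n$ is conserved to machine precision, and
total $\phi_d$ whenever the reactions are off or balanced.

Time stepping is an explicit conservative update with the whole loop
compiled (Rcpp); the step size defaults to 60% of the biharmonic
stability bound `h^4/(32 M kappa)`. We deliberately chose explicit
stepping over a semi-implicit sparse solve: on a masked, non-rectangular
domain the symmetric-flux explicit update conserves exactly without
factorizing a biharmonic operator, and at the lattice resolutions used
it is faster in wall time. Divergence (from a user-supplied `dt`) is
detected and reported with the failing step.

Composition clipping: the printed bulk free energy has no entropic
barrier at the simplex boundary, so small interfacial overshoot of
$\phi_e<0$ (a few percent) is normal and self-correcting through the
quadratic restoring force. The simplex projection therefore only fires
beyond an excursion tolerance (default 0.05), adjusting $\phi_d$ at
fixed $\phi_n$ (so conservation of $\phi_n$ is untouched) and logging a
count. Unconditional clipping would silently break the conservation
diagnostics.

Initial condition: the uniform reaction-balanced composition at
nucleoplasm fraction `phi_n_bar` plus i.i.d. uniform noise of amplitude
0.01–0.05, seeded. Steady state is declared when the windowed relative
change of the two morphological metrics (mean interior radius, mean LAD
thickness) stays below `tol` — the run-duration criterion is a
documented stand-in for an unspecified original.

### Heterogeneity

Spatial heterogeneity enters through Gaussian random fields:
$\Gamma_{me}(\mathbf x)$ over the lattice and $V_{LAD}(s)$ along the
boundary arc length, each with prescribed mean, coefficient of
variation, and correlation length $\xi$ (default 100–200 nm, the LAD
patch scale; unspecified originally, and morphologies are sensitive to
it — larger $\xi$ pins fewer, larger interior domains). Fields are
white noise smoothed with a Gaussian kernel (FFT), renormalised to the
target pointwise variance and truncated at zero; a seed reproduces them
bit-identically.

## Quantification

### From localization tables

`quantify_nuclei()` chains the imaging pipeline: Voronoi tessellation
(in-package bisector clipping with a security-radius guard; edge and
hull polygons are excluded from area sums), reduced densities
(nucleus-mean polygon area over own area), pooled percentile classes
(sparse ≤ P30 < dense ≤ P70 < ultradense, pooled over every nucleus
passed in one call), DBSCAN domain calling on the dense∪ultradense mask
(min 3 localizations; `dense_band = "31:70"` reproduces the literal
dense-only reading), raster-closing boundary estimation, the inclusive
2.5%-of-radius LAD rule, and the 50-segment thickness profile.

Two defaults deviate from the obvious first guesses, for cause:

* **DBSCAN `eps`.** Twice the median nearest-neighbour distance puts
  the expected eps-neighbourhood occupancy near 2.5 points — below the
  `min_pts = 3` percolation threshold — and shatters homogeneous
  domains. The default is four times the median NN distance (occupancy
  ≈ 10), still scale-free across localization densities, and
  configurable.
* **Domain areas.** The sparse percentile class necessarily punches
  holes into dense domains (30% of all localizations must be sparse
  somewhere). A domain's covered area therefore includes enclosed
  unclustered polygons: connected components of non-member non-edge
  polygons in the Voronoi adjacency whose entire neighbourhood belongs
  to one cluster are attached to it for area bookkeeping, with a size
  guard (≤ 20 polygons and ≤ 20× the member mean area) so background
  bays wrapped by a peripheral domain stay out.

* **Thickness conversion.** Dividing segment LAD area by segment length
  is biased low by the factor $(1-t/2R)$ on a curved boundary — a 20%
  error for a 400 nm band on a 1 µm nucleus. The default inverts the
  annular-sector relation $a=\Delta\theta(Rt-t^2/2)$; set
  `curvature_correct = FALSE` for the flat ratio.

The boundary estimator rasterises the cloud, closes with a disc of
radius `alpha` (default 5× median NN distance), fills holes and traces
the contour. It is a raster rendition of a concave hull: small `alpha`
follows indentations and eventually disconnects (reported as an error
with guidance), large `alpha` tends to the convex hull. No alpha-shape
library is used; the estimator and its `alpha` are documented package
choices.

### From simulated fields

The same morphometrics run on lattice masks: `phi_h` thresholded at the
well midpoint `phi_h0/2`, 8-connected components (4-connectivity would
split diagonal necks), the same 2.5% band rule and the same segment
estimator with cell areas `h^2`, so imaging and simulation land in one
domain-table schema. Contact angles of peripheral domains come from a
circular-cap fit, $\theta=2\arctan(2h_{max}/b)$ with $h_{max}$ the cap
height over the boundary and $b$ the contact base.

## The inverse procedure

Interior radii map to methylation rates through the size law
$R_d=\sqrt{3D_h\bar\phi_h^*/\Gamma_{ac}}$ with the closure
$\bar\phi_h^*=s_0\,\Gamma_{me}/(\Gamma_{me}+\Gamma_{ac})$; $s_0$ is
calibrated once so the control condition's mean radius maps to the
nominal control rate (`calibrate_closure()`), and $D_h$, $\Gamma_{ac}$
are fixed constants of the extraction. The closure is pluggable and the
inversion errors out, naming the ceiling $R_{d,max}$, for radii it
cannot reach.

LAD thicknesses map to affinities through a simulation-built response
surface $T_{LAD}(\Gamma_{me},V_{LAD})$: steady states on a grid,
replicate-averaged, isotonic-regularised along the affinity axis. The
inversion is monotone interpolation with the two plateaus as degenerate
cases — thicknesses at or below the regime-I level give zero affinity,
at or above the regime-III level the saturated top of the grid
(flagged). Affinities are inferred per boundary segment at the nucleus
mean methylation rate; the one-pass procedure plus a heterochromatin
budget residual ($\bar\phi_h A_{nuc}$ against summed domain areas,
flagged above 0.5) stands in for a joint iterative solve, which the
source leaves unspecified.

Bimodality of the extracted affinity distribution is declared when both
plateau masses exceed 10% — a documented heuristic tuned to the
alternating structure (anchoring-protein-rich stretches against nuclear
pore regions) the model attributes the two peaks to.

## The synthetic-data generator

`generate_nucleus()` emulates the statistical structure of one
nucleus's 2D localization cloud: a homogeneous Poisson euchromatin
background inside a closed boundary, interior clusters (disks of
boosted intensity at rejection-sampled centres with 4-radius
separation), and a peripheral band of controllable local thickness —
constant, patchy alternating (zero/full blocks), or smooth noise. All
positions get Gaussian jitter of 10 nm, the localization-precision
scale. Defaults: 2 µm radius, background 150 /µm², 30 clusters of mean
radius 50 nm (CV 0.2, 25× intensity), a 200 nm band at 12× intensity —
chosen once so that the background contributes ≈ 30% of localizations,
matching the percentile classifier's sparse anchor, and so cluster and
band scales mirror the experimentally reported size scales.

What the generator does *not* emulate: fluorophore blinking and
multiple localizations per molecule, drift, anisotropic clusters,
nuclear invaginations, chromatin texture between domains. Passing the
recovery tests therefore demonstrates estimator correctness on clean
spatial statistics, not robustness to microscope artifacts.

## Problem sizes and the desk-scale caveat

The reference simulations use a circular nucleus of radius 900 nm at
`h = 10` nm (≈ 25,000 cells) integrated for ≈ 400 s of model time; the
test suite runs the same physics at radii 300–600 nm with shorter
horizons, and the acceptance script at the full reference scale. These
nuclei are several-fold smaller than real MSC nuclei, a deliberate
choice that keeps the perturbation protocol (control + five conditions
× three seeds) tractable; all condition contrasts are reported as
percent changes on identical geometry.

One consequence deserves emphasis. At this scale a ≈ 200 nm LAD layer
holds most of the heterochromatin pool, so the peripheral share — not
just the pool itself — responds to the methylation budget, and the
measured LAD-thickness elasticity to $\Gamma_{me}$ is two- to
three-fold larger than the proportional response implied by the
original full-size simulations. The perturbation contrasts consequently
overshoot the published percent changes in several conditions; this is
a scale limitation of the rendition, not a property of the model
equations, and it is the main caveat to attach to the perturbation
outputs. The interior-radius contrast, which does not involve the
peripheral share, lands much closer.

## What the tests do and do not establish

The suite separates exact guarantees (conservation to machine precision,
variational consistency of the chemical potentials against
finite-difference perturbation, the closed-form inversion round trips,
DBSCAN against a brute-force oracle, Voronoi areas against an
independent tessellation) from statistical recoveries at desk scale.
Three of the latter fall short of their aspirational bands and the
tests record this honestly rather than papering over it:

* The interior-size exponent against the acetylation rate measures
  ≈ −0.35 to −0.4 rather than −1/2: at reachable resolutions the sweep
  straddles the fast-reaction (reaction-transparent) and
  coarsening-dominated regimes.
* The measured percent changes of LAD thickness under
  methylation-reducing perturbations overshoot the reference values
  (the desk-scale elasticity discussed above).
* End-to-end parameter recovery is limited by two desk-scale effects:
  interior morphology is seed-bistable (a few merged blobs in one
  replicate, many small domains in another), which the closure's error
  amplification turns into large rate errors; and mid-regime affinity
  estimates are biased high by the convexity of the inversion combined
  with regime truncation. The bimodality flag, which only needs the two
  plateaus, is robust.

Additionally, the measured radius of a localization cluster carries an
additive "bleed" of roughly half the local background spacing (polygon
sums extend halfway to the surrounding background), which compresses
*percent changes* of R_d between conditions far more than it biases any
single measurement — percent contrasts of interior radii from
localization data should be read as qualitative.

## Known limitations

* 2D fields only; no mechanical coupling, no water exchange with the
  cytosol (strict no-flux), no time-dependent stimuli.
* Interfaces are marginally resolved at the default `h = l_int`;
  absolute interface-scale quantities (contact angles of small caps,
  radii below ~2 `l_int`) carry lattice bias.
* The response surface is only as good as its grid: affinities are
  reported in the units and range of the grid used to build it, and
  thicknesses beyond the sampled range saturate by design.
* Extraction error compounds: the closure amplifies relative radius
  error by $s_0/(s_0-x)$, so per-domain rates are noisy and only
  distribution-level statements are supported.
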