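# ladscape

Mesoscale biophysics of nuclear chromatin organisation: a phase-field
reaction–diffusion simulator of heterochromatin/euchromatin segregation
with chromatin–lamina adhesion, a quantification pipeline for 2D
single-molecule localization (STORM-type) data, and an inverse procedure
that turns measured domain sizes into nucleus-wide distributions of two
biophysical parameters — the effective histone methylation rate
Γ<sub>me</sub> and the chromatin–lamina affinity V<sub>LAD</sub>.

## Who it is for

Chromatin biophysicists and quantitative imaging groups who have (or
simulate) per-localization super-resolution data of nuclear histones and
want to go beyond morphology: to ask *which reaction and adhesion
parameters* are consistent with the interior heterochromatin domains and
the lamina-associated domains (LADs) they see, and how those parameters
shift under perturbations (epigenetic drugs, contractility, substrate
stiffness, disease).

## The model

Composition is tracked as volume fractions φ<sub>h</sub> + φ<sub>e</sub>
+ φ<sub>n</sub> = 1 (hetero-, euchromatin, nucleoplasm) through the
state pair (φ<sub>n</sub>, φ<sub>d</sub> = φ<sub>h</sub> − φ<sub>e</sub>).
The free-energy density

f = (c/2)\[φ<sub>e</sub>² + φ<sub>h</sub>²(φ<sub>h0</sub> − φ<sub>h</sub>)²\]
\+ (κ/2)\[|∇φ<sub>n</sub>|² + |∇φ<sub>d</sub>|²\]
− V(φ<sub>h</sub>)/d₀ · e<sup>−d/d₀</sup>

couples a chromatin–chromatin double well (interface width
l<sub>int</sub> = √(κ/c) ≈ 10 nm), interfacial penalties, and an
exponential chromatin–lamina attraction within d₀ ≈ 2.5 nm of the
envelope. Dynamics are conserved gradient flows plus first-order
epigenetic kinetics,

∂φ<sub>n</sub>/∂t = M<sub>n</sub>∇²μ<sub>n</sub>,  
∂φ<sub>d</sub>/∂t = M<sub>d</sub>∇²μ<sub>d</sub> + 2(Γ<sub>me</sub>φ<sub>e</sub> − Γ<sub>ac</sub>φ<sub>h</sub>),

with Γ<sub>me</sub> the harmonic composition of the HDAC and HMT
sub-steps. Interior domains stabilise at
R<sub>d</sub> = √(3 D<sub>h</sub> φ̄<sub>h</sub>\*/Γ<sub>ac</sub>), which
the inverse procedure solves for Γ<sub>me</sub>; LAD thickness maps to
V<sub>LAD</sub> through a simulation-built monotone response surface
with its two plateaus (bead-like regime I, saturated layer regime III)
as degenerate cases. See the methods vignette
(`vignettes/lad-biophysics.Rmd`) for the full account.

## Worked example

Generate a synthetic nucleus with known ground truth, run the imaging
pipeline, and extract parameters:

```r
library(ladscape)

gen <- generate_nucleus(synthetic_spec(seed = 7))
nrow(gen$table)
#> [1] 6894

q <- quantify_nuclei(gen$table)
interior <- dplyr::filter(q$domains, type == "interior")
nrow(interior)                      # 30 clusters of 50 nm were planted
#> [1] 33
mean(interior$R_d_nm)
#> [1] 56.40733
q$profiles[["1"]]$mean_T_LAD        # a 200 nm band was planted
#> [1] 200.5481
q$geoms[["1"]]$R_nuc                # the nucleus radius was 2000 nm
#> [1] 2009.273
```

The pipeline recovered the planted cluster count (33 vs 30; the extras
are small density fluctuations), their radius scale (56 nm measured for
50 nm planted — polygon sums bleed about half a background spacing
outward), the band thickness (200.5 nm for 200 nm planted) and the
nuclear radius to 0.5%. Simulation works the same way from the other
end:

```r
ctrl <- calibrated_control()
geom <- do.call(make_geometry, ctrl$geometry)
pf   <- sample_parameter_fields(geom,
          means = list(Gamma_me = ctrl$gme_mean, V_LAD = ctrl$vlad_mean),
          cvs = ctrl$cvs, xi = ctrl$xi, seed = 11)
ss   <- run_to_steady_state(geom, pf, ctrl$params,
                            phi_n_bar = ctrl$phi_n_bar, seed = 11)
glance(ss)       # steps, convergence, mean R_d, mean T_LAD
tidy(ss)         # the domain table of the final field
autoplot(ss)     # phi_h heatmap
```

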