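# membraneprobe

Structural analysis of lipid bilayers perturbed by small amphiphilic
solutes, from four complementary kinds of data:

* **Trajectories** — leaflet assignment, number/electron density profiles,
  center-of-mass radial distribution functions, hydrogen-bond graphs and
  aggregate clustering, water penetration and water-wire detection, and
  lateral maps of the inter-leaflet center-of-mass distance (local
  thinning).
* **SAXS** — an error-function slab model of the bilayer electron density
  ρ(r) = ρ₀ + ½ Σᵢ (ρᵢ₋₁ − ρᵢ)[erf((r−Rᵢ)/√2σᵢ) − erf((r+Rᵢ)/√2σᵢ)],
  its closed-form factor F(q), a modified Caillé structure factor
  S(q) = N + 2 Σₖ (N−k) cos(kqd) e^{−(qd/2π)²η[γ+ln(πk)]} for multilamellar
  stacks, and weighted Levenberg–Marquardt fitting of
  I(q) = q⁻²|F|²[f + (1−f)S].
* **EPR** — spin-label order parameters
  S = [(A∥−A⊥)/(A_zz−(A_xx+A_yy)/2)]·(a₀/a′) from hyperfine extrema, tensor
  calibration, and rotational correlation times τ_c = 1/[6(DxDyDz)^⅓].
* **AFM** — breakthrough (bilayer rupture) detection giving yield force and
  thickness, Hertz-sphere modulus fits, and roughness statistics (R_a,
  RMS) with plane flattening.

The motivating system is a DOPC bilayer carrying dodecanedioic acid (DDA, a
model lipid-peroxidation product) and flavonoids: DDA aggregates span the
hydrophobic core, hydrogen-bond through their carboxyls, locally thin the
membrane by about 1 nm, and let water wires form — precursors of pores.
Because raw data of this kind are typically undeposited, the package ships
seeded synthetic-data generators that plant all of these features with
known ground truth; every analysis stage is tested against planted values
and independent brute-force oracles.

## Worked example

Build a bilayer with a thinned patch, a hydrogen-bonded DDA aggregate and a
planted water wire, then recover all three:

```r
library(membraneprobe)

spec <- bilayer_spec(64, c(10, 10),
  patch     = thin_patch_spec(c(5, 5), radius = 1.5, head_plane_offset_inside = 1.35),
  aggregate = aggregate_spec(8, c(5, 5), lateral_sigma = 0.6),
  water     = water_spec(c(2.3, 3.2), 120, wire = wire_spec(8, 0.3, c(-1.1, 1.1))),
  seed = 1)
traj <- build_trajectory(spec, n_frames = 4)

tmap <- interleaflet_distance_map(traj, cell = 0.5, window = NULL)
thickness_patch_contrast(tmap, c(5, 5), 1.5)
#> $inside  1.500571   # nm, under the aggregate
#> $outside 2.499337   # nm, remainder of the bilayer

hb <- hbond_statistics(traj, window = NULL)
#> DDA-DDA hydrogen bonds: 8.0 +- 0.0 per frame (4 planted pairs x 2 carboxyl ends)

water_analysis(traj)$wire_present
#> TRUE TRUE TRUE TRUE
```

The patch cells sit ~1 nm below the rest of the map — the hallmark of
local thinning under an aggregate — and the planted spanning water chain is
reported in every frame.

Order parameters from a hyperfine-extrema table (the packaged reference
table for 5-doxyl-stearate-labelled DOPC liposomes):

```r
tab <- read_epr_table(system.file("extdata", "dsa_hyperfine.csv", package = "membraneprobe"))
round(epr_analysis(tab)$S, 3)
#> 0.608 0.582 0.623 0.617 0.621 0.630 0.626
```

DDA lowers S relative to the control (more fluid chains); every flavonoid
raises it back above the control.

A full pipeline run (simulate → analyze → SAXS fit → EPR → AFM) from a YAML
configuration:

```r
run_pipeline(system.file("extdata", "demo_pipeline.yaml", package = "membraneprobe"),
             output_dir = "demo_out")
```

See `vignettes/membraneprobe-methods.Rmd` for the models, their
assumptions, parameter defaults, and the package's account of what the
synthetic data do and do not emulate.

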