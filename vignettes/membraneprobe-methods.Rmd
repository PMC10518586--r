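---
title: "Models and methods in membraneprobe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in membraneprobe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(membraneprobe)
```

membraneprobe post-processes four kinds of data that together characterize
how a small amphiphilic solute — here a C12 dicarboxylic acid (DDA), a model
product of lipid peroxidation — perturbs a phosphatidylcholine bilayer:
coarse particle trajectories, 1D SAXS curves, spin-label EPR hyperfine
splittings, and AFM force curves and topographs. Raw experimental or
all-atom simulation data of this kind are rarely redistributable, so the
package also ships seeded generators that plant every feature of interest
(aggregates, hydrogen bonds, water wires, thinned patches, breakthrough
events, surface roughness) with known ground truth; every analysis stage is
tested against those planted values and against independent brute-force
implementations.

## The synthetic bilayer

A lipid is modelled as a chain of `beads_per_lipid` (default 11) equal-mass
beads: the head bead sits on the leaflet head plane at |z| =
`head_plane_offset` (default 1.85 nm) and the remaining beads step
`bead_spacing` (default 0.12 nm) toward the midplane. With equal masses the
lipid center of mass lies (n−1)·spacing/2 = 0.6 nm below the head bead, so
the center-of-mass inter-leaflet distance of the default bilayer is
2·(1.85 − 0.6) = 2.5 nm. This choice makes the thickness map a real
computation on chain geometry rather than an echo of an input plane.
Gaussian jitter (default σ = 0.05 nm) is applied to the z coordinate of
every lipid bead; lateral placement is a deterministic grid. Restricting
jitter to z keeps planted lateral structure (patch membership, aggregate
position) exact, which is what makes planted-recovery tests sharp; it also
means the generator does not emulate lateral diffusion, area fluctuations,
or any in-plane disorder of a real membrane.

A thinned patch moves the head planes inside a circular region closer to
the midplane (default 1.35 nm, i.e. a 1.5 nm center-of-mass distance inside
versus 2.5 nm outside — a 1 nm thinning contrast). A planted aggregate
places vertical 12-carbon DDA chains, with terminal carboxyl groups, at
Gaussian lateral offsets around a center; a configurable fraction of
consecutive molecule pairs is positioned so that one hydroxyl O–H points at
the partner's carbonyl O at an exact O···O distance and D–H···A angle
(defaults 0.28 nm, 175°), at both chain ends. A water wire places oxygens
on a vertical line spanning the hydrophobic slab; when the requested O–O
spacing exceeds the vertical step the chain zig-zags laterally so the
consecutive 3D distances equal the request exactly. Waters are O + 2H
triplets; flavonoids are single electron-rich beads placed just below the
head planes, where polyphenols preferentially reside.

All randomness flows from one integer seed through a single generator
stream in a fixed draw order (aggregate placement, bulk water, flavonoids,
then per-frame lipid jitter, upper leaflet before lower); identical specs
and seeds give bitwise-identical trajectories. Planted molecules are static
across frames — only the lipid jitter is redrawn — so multi-frame averages
exercise the windowing logic without pretending to be dynamics. Electron
counts per bead are effective values chosen for contrast (head 50 e, tail
8 e, water O 8 e, flavonoid 120 e), not atomistic bookkeeping.

What passing tests on these synthetics do *not* show: force-field realism,
water dynamics, lateral correlations, or the kinetics of aggregate and pore
formation. They show that the estimators measure what they claim to measure
on data whose true values are known.

## Trajectory statistics

The midplane is the mean z of lipid head beads, recomputed per frame;
leaflets are assigned by the sign of the head z relative to it. Density
profiles recenter every frame on its midplane, histogram z with bins
covering the whole box, divide by bin volume and average over frames — the
profile integrates back to the mean particle (or electron) count to 1e-9
relative, which the tests assert. The electron-density profile of the
synthetic bilayer shows the canonical two head-group maxima and central
minimum.

RDFs are computed on molecule centers of mass under the minimum-image
convention, normalized by the ideal-gas expectation (spherical shells in 3D
mode, lateral annuli in 2D mode; 3D is the default as the natural reading
of a molecular-aggregation RDF, with the lateral mode provided). The
thickness map bins lipid centers of mass into lateral cells (default
0.5 nm) and subtracts per-cell leaflet means; cells lacking lipids in
either leaflet over the window are flagged `NA`, never zero.

Hydrogen bonds use the standard geometric criterion — donor–acceptor
distance ≤ 0.35 nm and D–H···A angle ≥ 150°, both configurable — since the
headline bond counts in this literature rarely state their criterion.
Donors are identified topologically (an O with an H of the same molecule
within 0.12 nm). Aggregates are connected components of the molecule graph
under either hydrogen-bond or center-of-mass-distance edges (igraph
backend; an independent union–find oracle checks the decomposition in the
tests). Water analysis counts oxygens inside the hydrophobic slab
(|z − z₀| < 1.0 nm by default) and reports a wire when a connected
component under the O–O adjacency cutoff (0.35 nm) spans the whole slab.

Averaging windows are expressed as fractions of the trajectory: statistics
default to the last three quarters and localization maps to the last
quarter, mirroring the common practice of discarding equilibration and
mapping late-time structure. On static synthetic data the window choice is
immaterial; it matters when the package is pointed at real trajectories.

## SAXS: erf-slab profile, form factor, modified Caillé structure factor

The bilayer electron density is a symmetric three-step profile

$$\rho(r) = \rho_0 + \tfrac12\sum_{i=1}^{3}(\rho_{i-1}-\rho_i)
\left[\operatorname{erf}\!\frac{r-R_i}{\sqrt2\,\sigma_i}
- \operatorname{erf}\!\frac{r+R_i}{\sqrt2\,\sigma_i}\right]$$

with solvent baseline ρ₀, step positions R₁<R₂<R₃ and widths σᵢ. Its form
factor has the closed form
$F(q) = \sum_i (\rho_i-\rho_{i-1})\,\frac{2\sin(qR_i)}{q}\,e^{-q^2\sigma_i^2/2}$,
validated in the tests against adaptive quadrature of the profile to 1e-6
relative. Stacked lamellae contribute a modified Caillé structure factor

$$S(q) = N + 2\sum_{k=1}^{N-1}(N-k)\cos(kqd)\,
e^{-(qd/2\pi)^2\eta\,[\gamma_E+\ln(\pi k)]},$$

which at η = 0 reduces exactly to the ideal finite-lattice interference
function and at N = 1 to unity. The measured intensity is modelled as
$I(q) = q^{-2}|F(q)|^2[f + (1-f)S(q)]$ with a Lorentz factor for unoriented
lamellae and a diffuse fraction f of uncorrelated bilayers — a standard
lamellar composition that the upstream fitting literature leaves implicit;
it is a documented modelling choice here, with N fixed by the user
(a small discrete number is not meaningfully fittable) and f fixed.

Fitting is weighted least squares (weights 1/σ_I²) via Levenberg–Marquardt
with R-ordering enforced through log-increments and σ, scale, d, η
log-parameterized. Two structural facts about this inverse problem shape
the defaults and deserve emphasis:

* Only |F(q)| over a finite band is observed, so sharp-step "alias"
  solutions (σ → 0) can reproduce a band as well as the true smooth
  profile. The default bounds confine σ to a physically smeared regime
  (0.1–1 nm), which removes the collapsed aliases; near-degenerate smooth
  aliases still exist, and the fit surface is rugged near the Bragg peaks.
  Consequently the optimizer is a *local* refiner: it needs a starting
  point within a few percent of the answer, and `saxs_init_guess()`
  (Bragg-position d, generic phospholipid levels) is a rough first step,
  not a global solver.
* The intensity is exactly invariant under scaling all density contrasts by
  c and the scale by 1/c², so absolute density levels and scale are only
  jointly determined. For curves on a known scale, `fit_scale = FALSE`
  pins this gauge and makes the levels themselves identifiable.

The package's parameter-recovery study (in the acceptance tests) therefore
generates absolute-scale synthetic curves at 1% relative noise on the full
instrument band, 0.05–6 nm⁻¹, starts the fit from the generator truth
perturbed uniformly by ±1–2%, holds the scale at its known value and fits
the nine profile parameters plus d and η. Under those conditions the
per-parameter median relative errors over 20 seeds are a few percent
(widths σ being the softest direction), which is the honest content of a
recovery claim for this model class: local statistical identifiability,
not global phase retrieval. Fits of real multilamellar curves in the
conventional 0.5–2.5 nm⁻¹ window (the package default) determine the
profile *shape* well but should be interpreted on a relative density scale.

`edp_report()` compares fitted profiles across systems through
descriptors — head-peak position, center density ρ(0), head-region
width — and signed contrasts against a reference system, which is how
center-density increases upon solute insertion are read off.

## EPR order parameters

From the outer and inner hyperfine splittings 2A∥ and 2A⊥ of a 5-doxyl
stearate probe, the polarity-corrected order parameter is

$$S = \frac{A_\parallel - A_\perp}{A_{zz} - (A_{xx}+A_{yy})/2}\cdot
\frac{a_0}{a'},\qquad a' = \frac{A_\parallel + 2A_\perp}{3},\quad
a_0 = \frac{A_{xx}+A_{yy}+A_{zz}}{3}.$$

The principal tensor defaults to the doxyl literature values
Axx = Ayy = 6.1 G, Azz = 32.9 G, which reproduce published 5-DSA order
parameters for DOPC systems within ±0.005 without further adjustment. Since
only the ratio a₀/[Azz − (Axx+Ayy)/2] enters, `calibrate_tensor()` fits
that single ratio to reference S values (holding Axx at the literature
value and solving Azz), rather than pretending three tensor components are
identifiable from S alone. No additive polarity correction to A⊥ is applied
by default. The anisotropic rotational correlation time is
τ_c = 1/[6(DxDyDz)^{1/3}]; the diffusion tensor itself must come from
spectral simulation, which is out of scope, so τ_c is computed only when D
is supplied.

## AFM post-processing

Force curves are modelled on a decreasing tip–sample separation grid: zero
force, Hertz-sphere contact $F = \tfrac{4}{3}\frac{E}{1-\nu^2}\sqrt{R}\,
\delta^{3/2}$ (ν = 0.5, incompressible film), a rupture jump at the yield
force in which the force falls to the baseline across the jump width (the
film thickness), and a stiff linear substrate wall at zero separation.
Breakthrough detection subtracts a far-field force baseline (making it
offset-invariant), locates the largest force drop of at least 50 pN within
0.5 nm of separation, and measures thickness as the drop separation minus
the zero-force intercept of the substrate branch — exact for the generator
at zero noise. The modulus fit linearizes Hertz as F^{2/3} vs separation on
the pre-breakthrough contact segment, estimating contact point and modulus
jointly; post-breakthrough points are excluded, so a rupture curve returns
the same modulus as a rupture-free curve of the same film.

Roughness statistics (R_a = mean|z − fit|, RMS) are computed per region
after first-order plane subtraction (matching the usual first-order 2D
flattening of images), over four seeded random regions by default. Two
numerical caveats are built into the closed-form sinusoid checks: a sampled
sine has an O(1/m²) discretization bias in mean|·| (m = points per period),
and the least-squares plane over whole periods of a *sine* phase is not
exactly flat (the odd phase correlates with the lateral coordinate), while
a *cosine* phase is benign. The tests therefore verify R_a = 2A/π and
RMS = A/√2 on a dense cosine-phase grid with mean detrend, which isolates
the statistic being checked from sampling artifacts.

## Pipeline

`run_pipeline()` executes simulate → traj-analyze → saxs-fit → epr → afm
from a YAML configuration, writing per-stage TSV/JSON plus a combined
report. One top-level seed fans out as stage seed = seed + stage position,
so a rerun is byte-identical. Unknown configuration keys anywhere are
rejected by name before any stage runs; stage failures are isolated and
recorded. Default problem sizes (a 128-lipid bilayer, a few frames, one
curve per fit) run in seconds to a few minutes on a single core, which is
the scale the test suite and the acceptance script use throughout.

## Known limitations

* The generator's bilayers are static and laterally ordered; no dynamics,
  no undulations, no area-per-lipid physics.
* SAXS fitting is local; global phase retrieval from |F| is not attempted,
  and absolute densities require an absolute-scale curve (or a fixed
  gauge).
* EPR covers scalar order parameters and τ_c only — no lineshape
  simulation.
* AFM assumes Hertz sphere contact with ν = 0.5 and a linear substrate
  wall; adhesion (DMT-type offsets) is not modelled.
* Orthorhombic boxes only; triclinic cells are out of scope.
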