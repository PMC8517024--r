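---
title: "A coarse-grained bead-spring model of cell mechanics, and the quantification toolbox around it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained bead-spring model of cell mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cellmech)
```

## The model

`cellmech` simulates a single adherent cell (or a small colony) as a
two-dimensional bead-spring system with three structural elements:

* a **plasma membrane**: a closed ring of 201 beads (type 0) forming a
  5.25 µm circle;
* a **nuclear membrane**: a ring of 33 beads (type 1) forming a 1.5 µm
  circle;
* **radial actin filaments** of two kinds: type I (10 beads, 1.5 µm
  contour length, innermost bead bonded to the nuclear membrane, outermost
  bead labelled type 3) and type II (8 beads, 1.2 µm, free at both ends,
  outer bead type 3), interspersed two type II per type I.  By default 11
  type I filaments give 33 filaments, tiling the 33 nuclear beads.

Four potentials govern the dynamics:

* **Lennard-Jones**, \(U_{LJ}(r) = \varepsilon[(\sigma/r)^{12} -
  2(\sigma/r)^6]\), minimum \(-\varepsilon\) at \(r = \sigma\), for the two
  attractive couplings;
* **WCA**, its purely repulsive truncation (zero at and beyond \(\sigma\)),
  for excluded volume between all other bead-type pairs;
* **FENE** bonds, \(U = -\tfrac{\kappa_F \Delta r_{max}^2}{2}
  \log[1 - ((r - r_0)/\Delta r_{max})^2]\), which diverge at the maximal
  extension \(\Delta r_{max}\) and prevent bond crossing;
* a **bend** term \(U = \tfrac{\kappa_B}{2}(\cos\theta - \cos\theta_0)^2\)
  on every three consecutive ring or filament beads.

Bond stiffness comes in three classes — membrane (\(\kappa_{F00}\)),
filament/nuclear (\(\kappa_{F11} = \kappa_{F00}\)), and filament-head to
membrane (\(\kappa_{F13} = 5\kappa_{F11}\)).  The head-to-membrane FENE
bond is assigned to type I filaments, whose heads sit opposite the
membrane; type II filaments touch the membrane only through the (0,3)
attraction.

The two biological control parameters are attraction well depths:

* \(\varepsilon_{00}\) — membrane–membrane attraction, the model's
  **cell–cell adhesion** (it also gives the membrane weak self-cohesion);
* \(\varepsilon_{03}\) — attraction between filament heads and the
  membrane, the model's **cortical contractility**: it is the actomyosin
  grip of the actin cortex on the plasma membrane.

### Units and geometry choices

All dynamics are dimensionless.  The length scale is fixed so that the
as-built spacing of adjacent membrane beads is 1 reduced unit, i.e. one
unit is \(\pi \cdot 5.25/201 \approx 0.082\) µm (stored as `length_unit`);
bead mass and the membrane–membrane \(\sigma_{00}\) are also 1.  Every
bond's equilibrium length is its as-constructed length, which makes the
built state an exact bonded-energy minimum — a property the test-suite
asserts at \(10^{-9}\).  Equilibrium bend angles default to \(\pi\)
(locally flat), which leaves a tiny residual bend energy on closed rings;
passing `theta0 = "constructed"` removes it, and the energy-conservation
tests use that variant.  \(\Delta r_{max} = 0.5\,r_0\) per bond, standard
FENE practice.

Neither the total filament count nor the angular placement of filaments is
fixed by the reference architecture beyond the 1:2 type ratio; the default
(33 filaments at the nuclear-bead angles) is the declared choice and is
configurable via `geometry_config()`.

The cortical grip is contact-scale: free (type II) filament heads are
placed 1.2 units from the membrane at construction (`head_standoff`) and
\(\sigma_{03}\) defaults to that standoff, so at rest the free heads sit
at the bottom of the (0,3) well and the well curvature — proportional to
\(\varepsilon_{03}\) — acts directly as a cortical coupling stiffness.
An earlier design placed all heads at the type I geometric standoff
(≈2.5 units, with \(\sigma_{03}\) to match); its long-range multi-head
attraction contracted the cell so strongly that the shallow indentation
response *softened* between the low and middle contractility levels —
the opposite of the mechanism the model exists to express — which is why
the contact-scale default replaced it.  Type I heads keep their
geometric standoff (their FENE bond carries their coupling) and feel
only the weak tail of the (0,3) well.

### Junction-mediated contractility across cells

In a colony, a cell's filament heads could in principle attract every
membrane, including its neighbours'.  Neither extreme reproduces sensible
colony mechanics: a fully promiscuous grip glues cells together even with
\(\varepsilon_{00} = 0\), while a strictly intra-cellular grip makes
contractility *shrink* the adhesive contact and weaken cohesion.  The
package's junctional-coupling model takes the biological middle ground:
the cortex can only pull on a neighbouring membrane through an adhesive
junction, so the cross-cell head–membrane well depth is
\(\varepsilon_{00}\,\varepsilon_{03}\) (in units of the baseline adhesion
energy).  Without adhesion it vanishes — pulling a cell out of an
\(\varepsilon_{00}=0\) colony costs nothing beyond bath drag — while at
the baseline \(\varepsilon_{00}=1\) contractility strengthens cohesion, as
the pull-out assay measures.

## Integration

`run_md()` advances the system with velocity Verlet wrapped in a
BAOAB-split Langevin thermostat: friction \(\gamma\) and reduced
temperature \(T\) (both zero gives plain NVE, used by the
energy-conservation tests; production runs are overdamped, \(\gamma\) of
order 1–10 with small \(T\)).  The thermostat noise comes from a counter
seeded by `sim_config(seed=)`, independent of R's RNG, so trajectories are
bitwise reproducible.  Apparatus-driven beads (the AFM tip, pull-assay
grab beads) are excluded from the thermostat — they are moved by their
clamp springs, not by the bath; without this exclusion the bath drag on
the tip shows up as a spurious pre-contact force.

Defaults: `dt = 0.002` (about 1/60 of the fastest bond period at the
default \(\kappa_{F13}=150\)), \(\gamma = 2\), \(T = 0.01\).  Forces use a
spatial-bin pair search, so colonies of several thousand beads integrate
at \(O(N)\) per step.

## The virtual AFM

The probe is a single type-7 bead clamped to a moving apparatus by two
orthogonal springs (`kx`, `ky`); the apparatus advances at constant
velocity toward the cell and the reported force is the spring deformation
projected on the approach direction — zero before contact (exactly, at
\(T=0\)), rising as the membrane resists.  The tip interacts with all
cell beads by WCA only (\(\sigma_{07}\) = tip radius + bead radius): the
probe pushes, it does not adhere.

Choices that matter:

* **Pre-equilibration** (4000 steps, apparatus held): the contractile
  cortex shrinks the cell by up to several percent; equilibrating first
  keeps the approach itself stationary.
* **Contact point**: first sample whose force exceeds 1% of the curve
  maximum (configurable).
* **Readout**: the sweep statistic is the force at a fixed post-contact
  depth (contact + half of `max_travel`), insensitive to the
  contractility-dependent contact shift; `stiffness_proxy()` reports the
  least-squares slope over the central half of the post-contact range.
* **Quasi-staticity** is verified (not assumed) by the rigid-wall
  property test: against a frozen wall, doubling the clamp stiffness or
  halving the approach velocity moves the shallow-contact force curve by
  less than 5%.

## Hertz–Sneddon elastography

For experimental (or synthetic) force–indentation data in physical units,
`fit_hertz()` fits

\[F(\delta) = C\,\frac{E}{1-\nu^2}\tan(\alpha)\,\delta^2, \qquad
  \delta = \text{travel} - \text{contact},\]

jointly estimating the modulus \(E\) and the contact point by
Levenberg–Marquardt least squares, with \(C = 2/\pi\) for a conical
(Sneddon) indenter — the default treatment of pyramidal probes — or
\(C = 0.7453\) for a four-sided pyramid.  The defaults \(\alpha = 9°\)
and \(\nu = 0.45\) are the standard silicon-nitride probe and cell values.
With travel in µm and force in nN, \(E\) is in kPa.  `filter_moduli()`
implements the 20 kPa substrate-effect cutoff used for sparse cultures
where some indentations hit the dish.  Recovery is within 1% on noiseless
synthetic curves and within 5% median error under 2% multiplicative noise
(50 replicates) — both asserted in the tests.

## The two sweep scenarios and the cohesion assay

`run_sweep()` probes one cell per (level, seed) by virtual AFM, varying
either \(\varepsilon_{03}\) at fixed \(\varepsilon_{00}\) or vice versa;
levels default to \(\{0.5, 1, 2\}\times\) baseline with seeds
\(\{1,2,3\}\).  `compare_scenarios()` reports each scenario's dynamic
range of mean force and their ratio.  At the defaults the contractility
scenario's response dominates the adhesion scenario's by more than an
order of magnitude, and the mean mid-indentation force is strictly
increasing in \(\varepsilon_{03}\) — the model's central, ordinal claim
(no physical force units are claimed, only orderings).

`run_pull_assay()` ramps a spring (distributed over the 9 membrane beads
facing outward) away from a colony at constant speed and reports the
maximum spring force before the target cell's centroid has moved one cell
diameter.  The reported value is corrected for the exact steady towing
drag \(\gamma N v\) of a free cell in the Langevin bath, so the
no-adhesion control is zero up to thermal noise.  Assay defaults (spring
20, ramp 0.15, \(\gamma = 0.5\)) were set by feasibility — softer springs
cannot out-pull the bath drag and never detach a cell — before any
ordering was measured.  Pulling the centre cell of a 7-cell hexagonal
colony takes more force than pulling an edge cell, and the mean pull-out
force is non-decreasing in \(\varepsilon_{03}\).

## Image quantification

* **Circularity** \(= 4\pi\,\mathrm{area}/\mathrm{perimeter}^2\).  The
  perimeter is a Crofton multi-direction estimate (transition counts
  along eight lattice scan families — axes, diagonals and knight moves —
  Cauchy–Crofton weighted), because naive boundary counting is biased by
  ~27% on smooth shapes and can never return 1.0 for a disc.  The
  estimator is exact under 90° rotation and integer translation, within
  0.5% under arbitrary rotation at ≥100 px radius, and within ~1.5% even
  on a 20:1 ellipse; on grid-aligned polygons it overestimates mildly
  (~4% on a rectangle), the documented trade-off of anchoring the disc.
* **Solidity** = area / convex-hull area, with the hull over pixel
  *corners* so the ratio never exceeds 1.
* **Neighbour distances**: `nn_distance_density()` pools each point's
  five nearest neighbours and returns a unit-area histogram plus a kernel
  density.
* **Ruffles**: `count_ruffles()` counts local maxima of topographic
  prominence strictly exceeding 15 (nm), summed over a cell's (typically
  four) profiles.  Prominence — height above the higher of the two deepest
  flanking valleys — is the declared reading of "amplitude", which
  otherwise has no baseline; profile orientation is left to the caller.
* **Focal adhesions**: rolling-ball background subtraction (radius 30 px,
  a true ball-shaped structuring element in compiled code), Tsai
  moments auto-threshold on paxillin, fill holes; mean auto-threshold on
  actin, dilate / fill / open (3×3 box, one pass — the source defaults
  being undocumented); AND of the two masks; connected components are the
  FAs and FAs-per-cell divides by the nucleus count.  Nuclei segmentation
  itself is a pluggable input (any instance segmenter, or
  `make_fa_scene()`).
* **FRET**: ratiometric index \(R = (\mathrm{FRET} - \alpha\,\mathrm{CyPet}
  - \beta\,\mathrm{YPet})/\mathrm{CyPet}\) per masked region, and the
  single-chain index FRET/CFP per focal adhesion.  Non-positive donor
  pixels are excluded with a warning.
* **Compartment classifiers**: N>C / N=C / N<C with a relative "equal"
  band (default 10%, stated in outputs — "equal" has no canonical
  definition), and the boundary/cytoplasm mean-intensity ratio.

The CLAHE + Laplacian-of-Gaussian masking variant used for
vinculin-sensor images specifies operations but no parameters (clip
limits, scales, size/intensity bounds), so it is deliberately not
implemented rather than guessed.

## Synthetic data: what it does and does not show

Every analyzer input has a seeded generator with the ground truth stored
alongside (`make_sneddon_curve()`, `make_shape_mask()`, `make_fa_scene()`,
`make_fret_stack()`, `make_point_pattern()`, `make_height_profile()`), and
`write_fixture()` serializes fixture + truth sidecar in the formats the
analyzers read.  Noise defaults are conservative (2% of signal) so
recovery tests stay sharp.

The generators emulate geometry and noise, not optics: no point-spread
function, no photon statistics, no uneven illumination beyond what the
rolling ball is asked to remove, no segmentation errors in the nuclei
masks.  Passing round-trips therefore certify the *quantification
formulas and pipelines*, not robustness to real microscopy artefacts.
Similarly, the bead-spring cell is two-dimensional, its nucleus does not
deform internally, and filaments neither polymerize nor turn over; the
simulation claims are orderings of forces under parameter changes, never
absolute kilopascals.

## Problem sizes

The suite runs the indentation sweeps on the full 201-bead cell
(two scenarios × 3 levels × 3 seeds, ~40,000 steps each) and the cohesion
assay on a reduced 41-bead-membrane desk cell (7-cell colony, 3 levels ×
3 seeds), the package's chosen balance between resolution and a
minutes-scale test suite; the architecture (ring + nucleus + interspersed
filaments, all constants scaled) is identical at both resolutions.

## Known limitations

* The Crofton perimeter retains a small positive bias on grid-aligned
  polygons (documented above); adding scan directions reduces it further
  if polygonal masks matter.
* `compare_scenarios()` compares dynamic ranges at matched relative
  spans only; it does not test interaction effects between
  \(\varepsilon_{00}\) and \(\varepsilon_{03}\).
* The pull assay's detachment criterion (centroid displaced one cell
  diameter) is unambiguous but coarse; censored runs are flagged, not
  extrapolated.
* Membrane rupture (FENE overextension) truncates an indentation curve
  and flags it; the sweeps record such rows rather than failing, but no
  rupture-mechanics claims are made.
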