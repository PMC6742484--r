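---
title: "Diffusion-to-capture on microtubule lattices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion-to-capture on microtubule lattices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

EB1 targets growing microtubule plus-ends. One candidate mechanism is purely
structural: EB1's binding site is a *pocket* at the vertex between four
tubulin dimers, so a closed, intact lattice sterically shields the site,
while protofilament edges, tapered tips, and lattice defects expose partial
(two-dimer) sites that a diffusing molecule can reach far more easily. If
arrival (on-rate) is diffusion-limited, the structural state of the polymer
end alone can concentrate EB1 there, independent of nucleotide chemistry.
`mtarrival` implements a rigid-body Brownian-dynamics simulation of this
diffusion-to-capture process, plus the quantification methods used on the
accompanying fluorescence and electron-microscopy measurements.

## The simulation model

Three rules define the simulation:

1. The molecule diffuses translationally and rotationally with
   Stokes–Einstein coefficients
   $D_c = k_B T / (6 \pi \rho r)$ and
   $D_{rot} = k_B T / (8 \pi \rho r^3)$,
   where $r$ is the molecule's effective radius (the mean distance of its
   polyhedron vertices from its centre, about 1.9 nm here), $T = 298$ K and
   $\rho = 8.9\times10^{-4}$ Pa s (water). Both are configuration fields.
2. The molecule cannot pass through tubulin: each proposed move is rejected
   and resampled if the moved polyhedron would overlap any dimer.
3. Binding is stereospecific: an arrival occurs only when every
   binding-interface anchor of the molecule is simultaneously within 1 nm of
   its corresponding interface centre at some binding site (and, for
   single-anchor sites, the binding face points toward the site, so the
   molecule cannot bind "upside down").

Each molecule starts at a uniformly random point on a 500 nm sphere around
the lattice centroid with uniform random orientation, and the trajectory
ends on arrival, on crossing a 2000 nm escape radius, or at a step cap
(recorded as censored, never dropped).

### Geometry

All geometric constants live in `mt_constants()`. The lattice is the
canonical 13-protofilament B-lattice with one seam: 8.0 nm axial dimer
repeat, 12/13 nm helical rise per protofilament (3-start helix), 12.5 nm
radius to dimer centres. Four configurations are built: `blunt` (equal
protofilament lengths; the "closed" condition), `tapered` (a monotone
protofilament-length ramp at the same total dimer count; the
"disrupted-structure" condition), `sheet` (no lateral bond between the
first and last protofilament) and `single_dimer`. The default comparisons
use 207 dimers (average protofilament length ~16).

The tubulin dimer is a chamfered octagonal prism, 7.6 nm (axial) x 5 nm
(tangential) x 4.5 nm (radial); the chamfer on the four axial edges keeps
neighbouring protofilaments from touching at the inner lattice radius and
approximates the rounded cryo-EM envelope. The axial extent is slightly
below the 8 nm repeat so consecutive dimers in a protofilament do not
touch. The binder is a square frustum tapering toward its binding face;
its side slope was chosen so that the mated molecule sits in the
inter-protofilament groove with a hydration-scale clearance (~0.15 nm),
and its mean vertex radius is ~1.9 nm (diameter ~3.8 nm). These polyhedra
are this package's own approximations; published work in this area builds
equivalent shapes manually from cryo-EM reconstructions, and the absolute
arrival statistics are sensitive to such shape detail (see *Limitations*).

### Binding sites

Pocket-mode sites are enumerated at every inter-protofilament, inter-layer
vertex. Each of the (up to) four surrounding dimers contributes a contact
anchor — the mid-height point of its corner edge facing the pocket — and
the site centre is the mean of the anchors present. Sites are classified
by the number of adjacent dimers k: k = 4 "lattice" sites, k = 2 "edge"
sites (protofilament ends and exposed lateral edges), and k = 1 or 3
sites, which exist and can receive arrivals but are excluded from the
edge/lattice statistic by convention. Face-mode sites (the kinesin-like
control) sit at the centre of each dimer's outward face, one per dimer,
with a single anchor plus the orientation rule.

At the seam the 3-start helix leaves a ~4 nm lateral mismatch, so seam
pockets are geometrically incongruent with the binder's anchor pattern and
essentially never capture; they are flagged and can be excluded
(`include_seam = FALSE`). With the default 207-dimer blunt tube the
edge/lattice fold changes by <10% between the two conventions.

### Time stepping

The step length adapts to the current separation `Dist` between the
molecule and the lattice: `Dist/5` beyond 100 nm, `Dist/20` within 1 nm,
with the divisor interpolating linearly in between, and the time step
follows $\langle \Delta x^2 \rangle = 2 d D_c \Delta t$ with $d = 3$.
Within 1 nm of a site centre a fixed step of 0.05 nm (0.5 Å) typical
displacement is used. Two numerical guards are ours:

* **Step floor.** As printed, the `Dist/20` rule has no lower bound, so a
  molecule pinned against a wall takes ever-smaller steps (we observed
  separations grinding below $10^{-8}$ nm, where floating-point
  certification of "touching vs overlapping" becomes meaningless).
  Away from binding sites the step length is floored at 0.1 nm — twice the
  near-site step, still far below every geometric feature (smallest
  clearance ~0.15 nm at the mated pose, groove width ~1 nm), so the
  collision boundary layer remains well resolved while wall-hugging
  trajectories stay finite.
* **Far-field separation bound.** Beyond 8 nm the separation used for
  step planning is a capped-bounding-cylinder lower bound (tight to about
  1 nm) instead of the exact polyhedron narrow phase; it is conservative
  (shorter steps only) and never used for collision or arrival decisions.

### Collision detection

The narrow phase is a support-function (GJK) distance between convex
polytopes with warm starts, validated against an exhaustive feature-pair
oracle and a separating-axis oracle on thousands of random pose pairs
including overlaps. Numerical honesty matters at skimming separations:
the implementation only reports a distance on a certified duality gap,
only reports an overlap on a volume-margin simplex-containment
certificate, and falls back to the certified lower bound otherwise, which
is conservative for collision decisions. The broad phase is a static
hierarchical binary tree of dimer bounding boxes, with a cached near-list
and a motion-bound shortcut: a proposal whose total sweep (translation
plus rotation times bounding radius) is smaller than the current
separation bound cannot create a contact and skips the narrow phase
entirely. Colliding proposals are resampled at the same time step up to
`retry_cap` (100) times, then the time step is halved — the halving is our
addition to prevent live-lock in crevices.

### Randomness and reproducibility

Each (replicate, molecule) pair has its own counter-derived RNG stream
(splitmix64-seeded xoshiro256**), so ensembles are independent of
execution order, reproducible bit-for-bit under a fixed master seed, and
ensembles run with disjoint replicate sets merge exactly.

## Arrival statistics

`per_site_class_fractions()` normalizes arrivals per molecule per
available site in each class; the headline statistic is the ratio of the
k = 2 edge fraction to the k = 4 lattice fraction. `compare_configurations()`
reports the percent change in mean arrivals per replicate between two
geometries with an exact binomial test on pooled counts and a bootstrap
CI over replicates (the bootstrap is our addition; the original analyses
report point estimates and test p-values only).
`em_bead_statistics()` is a worked-example calculator for gold-bead
counts: raw and length-normalized defect/lattice folds, and the per-site
edge preference = (sheet-edge : sheet-middle bead ratio) x (total : edge
site ratio, 14:2 per sheet layer). The alternative middle : edge (12:2)
normalization is exposed as an option since the published arithmetic uses
14:2.

### Problem sizes

The packaged analyses use ensembles of 10 replicates x 2000 molecules
(20,000 trajectories) per geometry for pocket mode and 10 x 1000 per
geometry for the face-binding control, with a 3e6 step cap (censoring
measured below 0.1%). These sizes give ~50-150 arrival events per
condition; the per-site fold ratios carry Poisson errors of roughly
20-35%, which is the package's chosen balance between statistical
precision and a desk-scale run.

## Optics

The line-scan generator emulates a fluorescently labelled filament under a
Gaussian PSF: a plateau whose ends fall off as
$\tfrac{1}{2}\,\mathrm{erfc}\!\big((x - \mu)/(\sigma\sqrt{2})\big)$ with
combined width $\sigma^2 = \sigma_{true}^2 + \sigma_{psf}^2$, plus
Poisson-Gaussian noise. `fit_tip_errorfunction()` fits the four-parameter
erfc model (amplitude, background, tip position, width), initialized by
moment matching, with `minpack.lm::nlsLM`. Since the instrument PSF is a
required input that published tip-fitting work does not state numerically,
$\sigma_{psf}$ defaults to 120 nm and is configurable; the tip standard
deviation subtracts the PSF in quadrature by default, with
`deconvolve = FALSE` exposing the raw fitted width (both conventions
appear in the literature). The generator does not emulate TIRF
illumination inhomogeneity, camera gain calibration, or filament
curvature, so parameter-recovery tests demonstrate estimator correctness,
not robustness to those real-data effects.

Ensemble averaging orients each two-channel scan by the 9-pixel end-sum
rule (brighter binder end right), rebins to the mean length by linear
interpolation and averages with per-point standard errors. The intensity
ratio and coverage metrics follow the stated pixel geometry exactly
(signal ±4 pixels of the centreline; background 8–22 pixels above and
below; coverage = binder-positive filament length over total filament
length, Otsu-initialized thresholds with manual override, mirroring the
original semi-automated procedure).

The comet model composes complete occupancy of edge sites along the
tapered tip region (edge density 2/14 per layer, default taper length
96 nm = the default ramp's 12-layer spread) with an exponentially
decaying lattice occupancy (default decay length 100 nm) behind the
closed-tube boundary, convolved with the PSF; with defaults the intensity
peak lies strictly behind the distal end, the hallmark of comet-shaped
plus-end tracking profiles.

## Kinetics

Dwell times are modelled as a one- or two-component exponential mixture
left-truncated at the detection floor (one 10 ms frame at 100 Hz).
Estimation is by maximum likelihood on the truncated density — bin-free,
unlike the histogram fits used historically; a histogram-fit mode is
retained for fidelity checks. The extrapolated total event count is
$N_{total} = N_{obs} / P(\text{dwell} \ge \text{floor})$ under the fitted
model, and the on-rate constant is $N_{total}$ per second, per micrometre
of filament, per nanomolar binder (the unit convention is fixed here
because it is not restated where the published on-rates are plotted).
Model order is chosen by BIC, a documented substitute for an unstated
selection criterion; on clearly separated mixtures (dwell-time ratio ≥ 5,
both weights ≥ 0.2, $n \ge 20{,}000$) it selects two components in
essentially every seeded repetition. Sub-frame events are not partially
detectable: the floor is a hard truncation.

## Numerical choices, in one place

* Convexity validation tolerance 1e-9 nm; every edge must border exactly
  two faces; degenerate (zero-volume) shapes fail loudly.
* GJK relative termination 1e-10; overlap containment margin 1e-9 x
  scale^3; distance values validated to <1e-6 nm against the exhaustive
  feature-pair oracle.
* Binding distance 1 nm per anchor pair; arrival is checked after every
  accepted move once the separation bound is below 3 nm.
* Mated poses are Kabsch alignments of anchor sets (exact for congruent
  patterns); for k < 3 the site frame resolves the remaining freedom.
* Dwell-fit optimisation: BFGS from three starts on (log tau, logit w);
  boundary-pinned solutions warn; degenerate samples error.

## Limitations

* The polyhedra are independent approximations with the published
  bounding dimensions; absolute fold preferences between site classes are
  sensitive to groove clearances and anchor placement at the few-angstrom
  level, so cross-study comparisons of those folds should expect
  factor-of-a-few geometry sensitivity. The internal consistency relation
  (single-dimer/lattice = single-dimer/edge x edge/lattice) is exact in
  the simulation and is the better-conditioned quantity.
* No unbinding: a trajectory ends at its first arrival, so the simulation
  measures on-rates only.
* No hydrodynamic wall corrections, no flexibility, no crowding, one
  molecule at a time.
* The seam is modelled as a plain helical mismatch; A-lattice contacts at
  the seam are not given their own interaction geometry.
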