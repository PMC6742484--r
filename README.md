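# mtarrival

Brownian-dynamics simulation of diffusion-limited protein arrival at
structured microtubule lattices, with the accompanying fluorescence and
single-molecule quantification methods.

## The problem

EB1 and related +TIP proteins concentrate at growing microtubule plus-ends.
Beyond nucleotide-state affinity, a purely structural mechanism is possible:
EB1's binding site is a *pocket* between four tubulin dimers, so an intact
closed lattice sterically shields it, while tapered tips, sheet edges and
lattice defects expose partial two-dimer sites that a diffusing molecule can
reach much more easily. If binding is diffusion-limited, lattice structure
alone modulates the arrival (on-) rate. `mtarrival` lets you quantify that
mechanism in silico and analyze the corresponding experiments.

The core model: a rigid convex-polyhedron molecule diffuses with
Stokes–Einstein coefficients

    Dc    = kB T / (6 pi rho r)         (translation)
    Dcrot = kB T / (8 pi rho r^3)       (rotation)

taking Gaussian steps `dx = N(0, 2 Dc dt)` per axis with a time step that
adapts to its distance from the lattice (`<dx^2> = 2 d Dc dt`, step length
Dist/5 far away down to a fixed 0.5 Å step at binding sites). It cannot
penetrate tubulin (exact convex–convex collision detection, GJK narrow
phase under an AABB-tree broad phase), and it *arrives* when every
binding-interface anchor is simultaneously within 1 nm of its matching
interface centre at some site — a stereospecific, pocket-shaped target.
Sites are classified by their number of adjacent dimers: k = 4 (closed
lattice), k = 2 (edge), k = 1/3 (reported, excluded from the edge/lattice
statistic). The package builds blunt, tapered, open-sheet and single-dimer
geometries (13-protofilament B-lattice, 8 nm repeat, 12/13 nm rise, one
seam), aggregates arrival statistics, and also provides: error-function
fitting of tapered-tip intensity profiles, background-normalized intensity
ratios and coverage fractions, a comet occupancy model, and censored
exponential dwell-time / on-rate estimation for 100 Hz single-molecule
data.

## Worked example

Simulate a pocket-binding molecule against a small closed microtubule and
compare edge and lattice sites per available site:

```r
library(mtarrival)

mt     <- build_microtubule("blunt", n_dimers = 207)
sites  <- enumerate_sites(mt, "pocket")
binder <- build_binder_shape("pocket")
model  <- diffusion_model(binder)
cfg    <- simulation_config(seed = 101, max_steps = 3e6)

tab <- run_ensemble(mt, sites, binder, model, cfg,
                    n_molecules = 2000, replicates = 1:10)
table(tab$status)
#>  arrived  escaped
#>       57    19943

per_site_class_fractions(tab, sites)
#>      class n_sites arrivals n_molecules     fraction
#> 1     edge      24       27       20000 5.625000e-05
#> 2 excluded       4       17       20000 2.125000e-04
#> 3  lattice     193       13       20000 3.367876e-06

edge_lattice_fold(tab, sites)$fold
#> [1] 16.70192
```

Out of 20,000 molecules released on a 500 nm sphere, 57 arrive; per
available site, the two-dimer edge sites capture ~17x more molecules than
the four-dimer closed-lattice pockets — the steric signature of the
pocket-shaped binding site (the handful of k = 1/3 sites are even more
accessible per site, which is why they are reported separately). A
face-binding molecule (`build_binder_shape("face")`, `enumerate_sites(mt,
"face")`) shows no such preference, and a tapered, "disrupted-structure"
geometry with the same 207 dimers receives significantly more total
arrivals than the blunt one (`compare_configurations()`).

The EM bead-count calculator reproduces its worked examples exactly:

```r
em_bead_statistics(list(lattice = 74, defect_or_sheet = 128,
                        sheet_edge = 7, sheet_middle = 1))
#> $raw_fold                  1.729730
#> $per_site_edge_preference  49
```

A thin command-line front end is installed at
`system.file("scripts", "mtarrival", package = "mtarrival")` with
subcommands `build-lattice`, `simulate`, `analyze-arrivals`, `em-beads`,
`fit-tip`, `simulate-comet`, `fit-dwell` and `make-fixtures`; simulations
are driven by a validated YAML run configuration and write their resolved
configuration and model next to their outputs for bit-identical reruns.

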