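# fibcount

Absolute nanoparticle dose in a single cell from FIB/SEM slice-and-view
image stacks.

## The problem

A focused ion beam / scanning electron microscope alternates between
milling a thin slice (≈ 40 nm) off a resin-embedded cell and imaging the
freshly cut face, until the entire cell has been consumed. Metallic
nanoparticles (NPs) inside the cell show up bright in the
secondary-electron images without staining — their electron yield is
about twice that of the organic matrix — so the resulting stack contains,
in principle, the *absolute* number of particles in that one cell. No
bulk technique gives this: elemental analysis (ICP-MS) averages over
thousands of cells, and a single TEM section samples a sliver of the
volume.

Getting from the stack to a count requires undoing two features of the
image formation. Secondary electrons escape from a characteristic depth
*l* below the cut face, so a still-buried particle "glows" through the
matrix (intensity ∝ e^(−z/l)) before it is ever exposed, inflating its
apparent volume. And a particle hidden behind another along the slicing
axis is *shaded* — its electrons are absorbed by the anterior particle —
so the glow offset is incurred once per projected footprint, not once per
particle.

## The model

All intensities are expressed in background-referenced units ("a.i.u.":
matrix median subtracted, divided by the robust matrix noise). From
isolated single particles found in the stack, the package calibrates the
detected single-particle volume `V_s`, its decomposition into actual
volume `V_s0` and glow offset `V_s'` (with `V_s = V_s0 + V_s'` exact by
construction), the projected single-particle area `A_s`, and the escape
depth `l` (log-linear fit of the pre-exposure intensity rise). Each
detected cluster with detected volume `V_c` and projected area `A_c` then
contains

```
n_c = (V_c − V_s' · A_c / A_s) / V_s0
```

particles, and the whole-cell dose is the sum over clusters. The pipeline
around this formula covers drift registration (FFT cross-correlation),
tilted-view correction (1/cos stretch), adaptive denoising,
trench-anchored cell segmentation, Roberts-edge particle detection with
per-cluster multilevel-Otsu refinement in 3D, calibration, dose
aggregation with uncertainty, cluster-size distributions, surface-mesh
export (STL/PLY), and a physically motivated synthetic phantom generator
that makes every stage testable without microscope data.

## Worked example

Simulate a ground-truthed scene — five isolated particles, a stacked
pair, an in-plane pair and a random-touching triple (12 particles in 8
clusters) — render it with the imaging model (glow, shading, drift,
noise), and run the full pipeline:

```r
library(fibcount)

ph <- generate_phantom(
  agglomerates = data.frame(n = c(1, 1, 1, 1, 1, 2, 2, 3),
                            packing = c(rep("random", 5), "stacked",
                                        "in-plane", "random")),
  shape = c(160, 240, 40), seed = 11)
r <- render_stack(ph)
res <- run_pipeline(pipeline_config(), stack = r$stack)
print(res)
```

```
FIB/SEM quantification run
  drift-corrected, max |shift| 28 px
  cell: 28% of slices below contrast limit
  calibration: n_ref = 5, l = 96.9 nm
Absolute NP dose: 12 +- 1 particles in 8 clusters
  fraction in clusters of 1-5 particles: 100.0%
  fraction in clusters of >= 20 particles: 0.0%
```

The dose (12 particles in 8 clusters) matches the ground truth exactly.
The calibration was measured from the five isolated particles the screen
found in the stack:

```r
print(res$calibration)
```

```
Single-particle calibration (n = 5, empirical estimator)
  escape depth l:    96.9 +- 25 nm
  detected  V_s:     2725 +- 2.4e+02 a.i.u.
  offset    V_s':    672.5 +- 2.2e+02 a.i.u.
  actual    V_s0:    2053 +- 92 a.i.u.
  projected A_s:     109.2 +- 1.9 px
```

`A_s = 109 px` is the full projected disc of a 74 nm sphere at 6.3 nm
pixels (π·(37/6.3)² ≈ 108), and the fitted escape depth brackets the 89 nm
the phantom was rendered with. The per-cluster table shows the formula at
work — the stacked pair (`A_c ≈ A_s`, one shared footprint) and the
in-plane pair (`A_c ≈ 2·A_s`) both resolve to two particles:

```
  id voxel_count  V_c A_c   n_p   n_c n_int
1  1         299 2455 109 0.998 0.869     1
2  2         732 5606 218 1.996 2.077     2
4  4         533 4538 106 0.971 1.893     2
6  6         918 7775 310 2.839 2.858     3
...
```

`plot(res$dose)` draws the cluster-size histogram with the
particle-weighted cumulative distribution; with `out_dir` set,
`run_pipeline()` also writes the cluster CSV, calibration and dose JSON,
the figure, surface meshes of cell and particles, and a run log.

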