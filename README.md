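# granulattice

3D structural analysis of crystalline protein-granule assemblies in
electron tomograms, for structural biologists and electron microscopists
who want the full chain — granule localisation, unit-cell inference,
twin-boundary analysis, 2D class averaging and interaction energetics —
as tested, reproducible R code.

The package targets a striking observation: ~20 nm granules of human
islet amyloid polypeptide (hIAPP) in *Drosophila* fat-body aggregates
pack into genuine Bravais lattices — a body-centered tetragonal (BCT)
cell (a = b = 27.9 nm, c = 33 nm) and a triclinic cell (a = 28.4,
b = 26.5, c = 24.2 nm; α = 78°, β = 66°, γ = 61°) — arranged as five
crystalline wedges about a common axis, a cyclic five-fold twin with
wedge angles 76/70/71/73/69°. Because no tomograms were deposited, the
package pairs every estimator with a synthetic tomogram generator whose
defaults *are* the measured parameters, so every claim is testable as
parameter recovery against known ground truth.

## What is inside

| module | main functions |
|---|---|
| synthetic assemblies | `unit_cell()`, `build_lattice_points()`, `twin_spec()`, `build_twinned_assembly()`, `apply_disorder()`, `render_volume()`, `extract_slab_projection()`, `apply_missing_wedge()` |
| granule detection & morphometry | `detect_granules()`, `measure_diameter()`, `nn_spacing()`, `compare_groups()` |
| unit-cell inference | `fit_lattice()` (S3: `print`, `summary`, `coef`, `predict`, `residuals`, `simulate`, `plot`), `neighbor_vectors()`, `infer_primitive_basis()`, `niggli_reduce()`, `conventionalize_and_classify()` |
| twin analysis | `analyze_twins()`, `local_orientation_field()`, `segment_domains()`, `boundary_planes_and_axis()`, `wedge_angles()` |
| class averaging | `box_particles()`, `classify_particles()`, `measure_linker_angles()` |
| energetics | `hamaker_energy()`, `hamaker_sensitivity()`, `axial_resolution()` |
| orchestration | `pipeline_config()`, `run_pipeline()`, I/O for MRC/TIFF/CSV, CLI at `inst/scripts/granulattice-cli.R` |

The core estimator, `fit_lattice()`, works in direct space: neighbour
displacement vectors are pooled and clustered into lattice-translation
candidates, the three shortest non-coplanar cluster centroids form a
primitive basis, the basis is reduced to the successive minima
(unimodularity verified), and a small integer-combination search finds
the conventional cell — recognising simple cubic, FCC, BCT (including
the interior lattice point at (½, ½, ½)), triclinic cells, and an HCP
layering motif. Twin analysis segments domains by lattice-row
orientation, fits boundary half-planes, and measures the wedge angles
about the common axis, with the boundary azimuths pinned jointly by
maximum-margin splits and lattice-vacancy constraints. Class averaging
is reference-free and translational-only, as required for linker-angle
conservation. The Hamaker two-body energy of two equal spheres at
centre distance d is

    E(d) = -(A/6) [ 2r²/(d²-4r²) + 2r²/d² + ln((d²-4r²)/d²) ]

## Worked example

```r
library(granulattice)

## the experimental BCT cell, as a point assembly in a 300 x 300 x 85 nm box
bct <- unit_cell(27.9, 27.9, 33, centering = "body_centered")
pts <- build_lattice_points(bct, box = c(300, 300, 85))   # 726 granules

fit <- fit_lattice(pts)
summary(fit)
#> Lattice fit over 726 granule centres
#>   class label : BCT
#>   centering   : body_centered
#>   a = 27.90 +/- 0.00  b = 27.90 +/- 0.00  c = 33.00 +/- 0.00 nm
#>   alpha = 90.00  beta = 90.00  gamma = 90.00 deg
#>   residuals: median 2.22e-14 nm, max 7.84e-14 nm

mean(nn_spacing(pts))   # centre-to-centre spacing, brute force
#> 25.7                  # = half the body diagonal; measured: 25.6 +/- 1.5 nm

## the five-fold twin at the experimental volume
tw <- build_twinned_assembly(twin_spec(), box = c(600, 600, 85))
analyze_twins(tw$points)
#> twin_partition: 5 domains over 2317 granules
#>   wedge angles: 75.9, 69.6, 71.7, 72.9, 69.8 deg
#>   closure deficit: 0.00 deg (cyclic)
#>   common axis: (0.000, 0.000, 1.000)

## closed-form physics
hamaker_energy(r = 10.05, d = 25.6)$energy_eV   # -0.021 eV, attractive
axial_resolution()                              # 2.972 nm -> "3 nm"
```

The wedge angles recover the generator's 76/70/71/73/(69+1)° sectors to
better than a degree, the spacing matches the closed-form half body
diagonal ½√(2a² + c²), and the binding energy at the measured geometry
is of order 0.02 eV.

## Command line

A thin CLI over the package functions ships in
`inst/scripts/granulattice-cli.R`:

```sh
Rscript inst/scripts/granulattice-cli.R simulate --box 600,600,85 --render --out out/
Rscript inst/scripts/granulattice-cli.R lattice --centers out/centers.csv
Rscript inst/scripts/granulattice-cli.R twins   --centers out/centers.csv
Rscript inst/scripts/granulattice-cli.R energetics
Rscript inst/scripts/granulattice-cli.R run-all --seed 1 --out report/
```
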