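---
title: "Methods: lattice, twin and class-average analysis of granule assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lattice, twin and class-average analysis of granule assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granulattice)
```

## The scientific problem

Electron tomography of protein aggregates in *Drosophila* fat-body tissue
shows that human islet amyloid polypeptide (hIAPP) can condense into
non-amyloid aggregates built from quasi-spherical ~20 nm granules. The
granules pack into genuine three-dimensional crystals: a body-centered
tetragonal (BCT) lattice (a = b = 27.9 nm, c = 33 nm) and a triclinic
lattice (a = 28.4, b = 26.5, c = 24.2 nm; alpha = 78, beta = 66,
gamma = 61 degrees), arranged as five wedge-shaped crystalline domains
sharing one axis - a cyclic (five-fold) twin with wedge angles near
76/70/71/73/69 degrees. Granules in the densest lattice planes are
connected by thin filamentous "linkers" whose directions are conserved
under purely translational class averaging.

`granulattice` re-implements this entire analysis chain as testable code,
and couples it to a synthetic tomogram generator so that every estimator
can be validated against a known ground truth. The package has no access
to the original tomograms (none were deposited); all quantitative claims
it makes are parameter-recovery results on synthetic assemblies plus two
closed-form physics calculations.

## The synthetic generator: what it emulates

`build_lattice_points()` enumerates lattice sites of a `unit_cell()`
inside a half-open axis-aligned box, `build_twinned_assembly()` composes
angular sectors about a common axis (each sector's lattice rotated to its
opening azimuth), `apply_disorder()` adds a sinusoidal bending field,
isotropic Gaussian jitter and Bernoulli vacancies, and `render_volume()`
converts centres into a voxel volume of soft-edged spheres with optional
linkers, noise and a dual-axis missing-wedge Fourier filter.

Generator defaults are the measured values wherever one exists:

| parameter | default | origin |
|---|---|---|
| BCT cell | 27.9 / 27.9 / 33 nm, body-centered | measured lattice parameters |
| triclinic cell | 28.4 / 26.5 / 24.2 nm, 78/66/61 deg | measured lattice parameters |
| wedge angles | 76, 70, 71, 73, 69 deg | measured twin geometry |
| granule diameter | 20.1 nm | measured hIAPP diameter |
| voxel size | 1.1 nm | reconstruction slice thickness |
| tilt range | +/- 60 deg, dual axis | acquisition geometry |
| box (full assembly) | 600 x 600 x 85 nm | analysed volume |

Where the experiments are silent the package makes one documented choice:

* **Sphere edge profile.** Granules are rendered with an error-function
  radial falloff, `pnorm((R - r)/s)`, with `edge_softness` s = 1.5 nm.
  The half-maximum then falls exactly at radius R, so the rendered FWHM
  equals the nominal diameter by construction - which is what the
  diameter estimator measures.
* **Closure policy.** The five wedge angles sum to 359 degrees. Whether
  the missing degree is measurement error or genuine angular strain is
  undecidable from the published numbers, so `twin_spec()` exposes both
  readings: `"append_last"` (default; the deficit widens the last sector)
  and `"rescale"` (all wedges inflated by 360/359).
* **Linkers.** Cylinders of radius 3 nm at peak intensity 0.8 (granule
  peak = 1) are drawn between near-minimal neighbour pairs whose
  connecting vector lies within 10 degrees of a selected lattice plane.
  The experiments show linkers as clearly discernible filaments but do
  not quantify their contrast; these defaults make the rendered slab
  reproduce that qualitative appearance. Values much below ~0.5 would
  leave the linkers buried under the projected caps of granules in the
  adjacent lattice plane (see *Limitations*).
* **Inter-sector orientations.** Only the wedge angles are published.
  By default each sector's lattice is rotated about the common axis by
  the sector's opening azimuth; arbitrary per-sector cells and extra
  rotations can be supplied.

What the generator does **not** emulate: membranes and cellular context
around aggregates, amyloid fibrils, tilt-series acquisition and weighted
back-projection (volumes are generated in real space; the missing wedge
is applied as a Fourier mask), beam damage, or contrast transfer. Passing
tests therefore demonstrate correctness of the estimators under the
stated geometric and noise model, not robustness to every artefact of
real tomograms.

## Unit-cell inference (`fit_lattice()`)

The estimator works in direct space, mirroring how the cells were
originally determined from marker positions:

1. **Neighbour vectors.** All displacement vectors between centres closer
   than 1.6x the modal nearest-neighbour distance are pooled
   (`neighbor_vectors()`). Granules with fewer than half the median
   neighbour count (box-edge granules) do not vote.
2. **Clustering.** Vectors are clustered antipodally (v and -v identified)
   with 15 degree / 20% tolerances (`cluster_neighbor_vectors()`).
3. **Primitive basis.** The three shortest pairwise non-coplanar cluster
   centroids form the basis candidate; it must index at least 60% of all
   neighbour vectors as near-integer combinations, otherwise there is no
   3D lattice (random clouds and 2D sheets are rejected here).
4. **Reduction.** `niggli_reduce()` greedily selects the shortest, the
   shortest non-collinear and the shortest non-coplanar integer
   combination - the successive minima, which in three dimensions always
   generate the same lattice; unimodularity is verified explicitly.
5. **Conventionalisation and labelling.**
   `conventionalize_and_classify()` searches integer combinations
   (coefficients in [-2, 2]) of the reduced basis for cells with at most
   two lattice points that maximise metric symmetry, with tolerances of
   1 degree and 2% (the reported experimental uncertainties). Precedence:
   simple cubic, FCC (recognised by its all-60-degree rhombohedral
   primitive cell - this ordering matters because every FCC lattice is
   also expressible as a BCT cell with an axial ratio of sqrt 2), BCT
   (right angles, a = b != c, and a verified lattice point at
   (1/2, 1/2, 1/2)), and a hexagonal close-packing layering signature.

**The triclinic canonical cell.** The published triclinic parameters are
not a reduced cell: |a - b| = 27.91 nm is shorter than a = 28.4 nm, so
every shortest-vector reduction replaces a and produces mixed or obtuse
angles. Reduced cells are not unique representations of a lattice, and
the cell actually printed corresponds to the *shortest primitive cell
whose three angles are all acute*. The package therefore reports, for
lattices with no symmetric supercell, that all-acute canonical cell
(falling back to the all-obtuse representative when no acute one exists,
which the sign parity of the basis dot products decides), with edges
ordered a >= b >= c and angles mapped accordingly. On noiseless input
this reproduces the published triclinic parameters exactly; the strict
shortest-vector reduction remains available as `niggli_reduce()`.

**Uncertainties** are the standard deviations of realised edge lengths
and inter-edge angles across the matched raw neighbour vectors - the
same kind of spread the published plus/minus values describe.

**HCP.** An ABAB close-packed stack is not a Bravais lattice; it is
detected separately by a hexagonal in-plane net, equally spaced layers at
c/2, and a two-layer registry period, and labelled `HCP_layering`.

## Twin analysis (`analyze_twins()`)

The chain is: contact-shell neighbour field (cutoff 1.3x modal spacing);
common-axis estimate; per-granule row orientations; domain segmentation;
boundary-plane fits; wedge angles.

* **Common axis.** All sectors share one lattice direction (the c axis
  here). It is estimated as the pooled translation cluster supported by
  the largest fraction of granules, computed on a wider 1.6x cutoff
  because the shared direction (33 nm) can exceed the contact shell.
  Averaging over every granule makes this estimate far more precise than
  the boundary-normal eigen-axis, which is retained as a diagnostic.
* **Orientations.** Each granule's in-plane neighbour azimuths (within
  20 degrees of the plane) are clustered; the densest cluster's circular
  mean, taken modulo the in-plane symmetry (90 degrees for a tetragonal
  net, 180 for oblique), is its row orientation. Exact ties break toward
  the shorter translation. Granules with fewer than 3 neighbours are
  undetermined and later inherit the majority label of their contacts.
* **Segmentation.** One smoothing pass (each granule adopts the densest
  orientation cluster among itself and its contacts) prevents
  single-linkage percolation through noisy boundary granules; contacts
  differing by less than 5 degrees are then united, and domains smaller
  than max(10, 4% of the assembly) are absorbed into their
  best-connected neighbour.
* **Boundaries and wedge angles.** Cross-label contact midpoints are fit
  by total least squares with trimming capped at 0.6x the modal spacing
  (a twin boundary cannot generate legitimate midpoints farther out).
  Because every boundary is a half-plane radiating from the twin axis,
  the angles are then refined jointly against the labelled granules:
  each boundary's offset is the maximum-margin split of the two domains'
  projected positions, the apex is the least-squares intersection of the
  refined lines, and each azimuth is re-estimated by a hinge-loss scan
  that also uses *lattice vacancies* - sites predicted by a domain's own
  translation clusters that hold no granule of that domain yet sit
  inside the assembly (near-full contact shell of granules of any
  domain). Such sites necessarily lie beyond the boundary and pin it
  from the far side. Wedge angles are consecutive azimuth gaps; they sum
  to 360 degrees by construction for a cyclic arrangement, and an open
  fan (a gap beyond 150 degrees) is flagged with an undefined closure
  deficit.

On the full-volume five-sector assembly (about 2.3 thousand granules)
this recovers each wedge to better than a degree; precision degrades on
substantially smaller assemblies because it scales with boundary length.

## Class averaging (`classify_particles()`)

Reference-free and translational-only, exactly as in the original
analysis - rotational alignment would destroy the linker-angle
conservation that the analysis is designed to demonstrate. Particles are
normalised to zero mean and unit variance, classified initially by
principal-component projection and k-means, then iterated: integer-pixel
cross-correlation alignment to the class average (search range +/-
box/4), reassignment to the best-correlating class, average recomputed.
Defaults: k = 3 classes, 8 iterations, box = 2.5 granule diameters
(45 px at 1.1 nm); an emptied class is reseeded from the worst-fitting
particle; the whole trace is reproducible bit-for-bit under the seed.

`measure_linker_angles()` reads the angular intensity profile of an
annulus between the granule edge and half the lattice spacing. The
profile uses the lower quartile over annulus radii rather than the mean:
a linker ridge spans the whole annulus, whereas the projected caps of
granules in the adjacent lattice plane (an unavoidable consequence of a
20 nm slab over a 16.5 nm layer spacing) intrude only near its outer
edge. Peaks need a third of the profile range in prominence, and a
featureless annulus (profile range below 10% of the image range) returns
no directions. The principal angle is the separation of the two
strongest non-antipodal directions; antipodal partners are reported
separately, so a square linker net reads as 90 and 180 degrees.

## Granule detection and morphometry

`detect_granules()` is scale-matched Laplacian-of-Gaussian filtering
(sigma = D / (2 sqrt 3)), Otsu thresholding of the response, greedy
minimum-separation suppression (strongest response wins; default
separation 0.8 D), and a three-pass intensity-weighted centroid within
one radius. `measure_diameter()` takes the FWHM of background-subtracted
profiles along the three axes, sampled at quarter-voxel steps, with
background estimated as the median intensity in a 1.5-2 R shell over 26
directions; a profile that never crosses half maximum marks the granule
invalid. `nn_spacing()` is deliberately the brute-force all-pairs
computation - it doubles as the oracle that any accelerated neighbour
search in the package must match exactly.

`compare_groups()` computes the one-way ANOVA F from group sums of
squares and two-sided Dunnett-adjusted p values against a designated
reference group on the multivariate t distribution (correlation
`sqrt(n_i n_j / ((n_i + n0)(n_j + n0)))`), evaluated by the seeded
Genz-Bretz algorithm; a single comparison reduces to the closed-form
t-test. All-tied degenerate input is defined to give F = 0 for identical
groups and F = Inf (p = 0) for separated ones.

## Energetics

`hamaker_energy()` is the unretarded equal-sphere Hamaker expression
with centre-to-centre distance (matching how spacings were measured).
The default Hamaker constant A = 1.3e-19 J is *reverse-consistent*: it
is the value at which the measured geometry (r = 10.05 nm, d = 25.6 nm)
yields a binding energy of order 0.02 eV, and it is deliberately a
first-class argument with a sensitivity table
(`hamaker_sensitivity()`, A in 0.45-2.9 x 1e-19 J) rather than a hidden
constant. A word of caution on the near-contact limit -A r/(12 h): its
logarithmic corrections decay slowly, so it is 27% off at h = r/20 and
reaches 10% agreement only around h = r/100. `axial_resolution()` is the
linear elongation formula R = in-plane x elongation + alignment error,
with the dual-axis elongation factor 1.44 taken as an input constant.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run everything at desk
scale, chosen as the smallest sizes at which the estimators' asymptotic
behaviour is already visible: 300 nm boxes (roughly 0.3-2.3 thousand
granules) for cell recovery, the full 600 x 600 x 85 nm assembly for the
twin and census checks, 81 rendered granules for diameter calibration,
and 30 particles for class averaging. Every stochastic element draws
from an explicit integer seed: the pipeline derives per-stage seeds from
one global seed, and identical configuration plus seed reproduces every
report byte for byte.

## Known limitations

* Real tomograms carry reconstruction artefacts (ray artefacts, contrast
  transfer, non-Gaussian noise) that the generator does not model.
* Wedge-angle precision depends on boundary length; assemblies much
  smaller than the experimental volume lose the sub-degree regime.
* Classification covers only the classes needed here (cubic_P, FCC, BCT,
  triclinic_P, HCP layering); there is no general 14-type Bravais
  determinator, and no reciprocal-space indexing path.
* The boundary between "distorted BCT" and "triclinic" is set by the
  1 degree / 2% tolerances; no further criterion separates a strained
  cell from a genuinely lower-symmetry one.
* Whether linkers are biological structures or preparation artefacts is
  an open question in the source material; the package measures their
  geometry only.
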