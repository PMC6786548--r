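Package: granulattice
Title: Lattice, Twin and Class-Average Analysis of Protein Granule
    Assemblies in Electron Tomograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the three-dimensional structural analysis of
    crystalline protein-granule assemblies imaged by electron tomography.
    Provides a synthetic tomogram generator (Bravais point lattices,
    cyclically twinned assemblies, positional disorder, soft-sphere
    rendering with linker filaments, missing-wedge filtering), granule
    localisation and morphometry (blob detection, FWHM diameter profiling,
    nearest-neighbour spacings, one-way ANOVA with Dunnett comparisons),
    unit-cell inference from granule point clouds (neighbour-vector
    clustering, basis reduction, Bravais-class labelling including
    body-centered tetragonal and triclinic cells), cyclic twin-boundary
    analysis (domain segmentation, boundary-plane fitting, wedge angles),
    reference-free translational 2D class averaging with linker-angle
    measurement, and closed-form Hamaker sphere-sphere binding energies and
    tomographic axial resolution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    mvtnorm,
    tiff
Suggests:
    multcomp,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
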