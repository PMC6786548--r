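# --- closed-form physics: Hamaker binding energy, axial resolution ---

EV_PER_JOULE <- 1 / 1.602176634e-19
KB <- 1.380649e-23

#' Hamaker two-body binding energy of two equal spheres
#'
#' Unretarded Hamaker expression for the van der Waals interaction of two
#' equal spheres of radius `r` at centre-to-centre distance `d`:
#' \deqn{E(d) = -\frac{A}{6}\left[\frac{2r^2}{d^2-4r^2} + \frac{2r^2}{d^2}
#'   + \ln\frac{d^2-4r^2}{d^2}\right]}
#' Negative values are attractive. The default Hamaker constant
#' `A = 1.3e-19` J is the documented package default for protein granules in
#' the cellular matrix: it is the value consistent with a binding energy of
#' order 0.02 eV at the measured granule geometry (r = 10.05 nm,
#' d = 25.6 nm), and should be treated as an assumption, not a measurement -
#' see [hamaker_sensitivity()].
#'
#' @param r Sphere radius in nm.
#' @param d Centre-to-centre distance in nm (must exceed 2r; the contact and
#'   overlap regime is outside the model's validity).
#' @param A Hamaker constant in joules (> 0).
#' @param temperature Temperature in K for the kT report (default 298).
#' @return List with `energy_J`, `energy_eV`, `energy_kT`, and the inputs.
#' @examples
#' hamaker_energy(r = 10.05, d = 25.6)$energy_eV # about -0.02
#' @export
hamaker_energy <- function(r, d, A = 1.3e-19, temperature = 298) {
  stopifnot(A > 0, r > 0)
  if (any(d <= 2 * r))
    stop("d must exceed 2r: spheres in contact or overlapping")
  x <- d^2 - 4 * r^2
  E <- -(A / 6) * (2 * r^2 / x + 2 * r^2 / d^2 + log(x / d^2))
  list(energy_J = E, energy_eV = E * EV_PER_JOULE,
       energy_kT = E / (KB * temperature),
       A = A, r = r, d = d, temperature = temperature)
}

#' Sensitivity of the Hamaker energy to the Hamaker constant
#'
#' The energy is strictly proportional to A, so the table simply spans the
#' plausible range for protein-protein interactions across aqueous media,
#' a factor of a few around the package default.
#'
#' @param r,d Geometry in nm.
#' @param A_values Hamaker constants to tabulate (J).
#' @return Data frame with A, energy in J, eV and kT.
#' @export
hamaker_sensitivity <- function(r = 10.05, d = 25.6,
                                A_values = c(0.45e-19, 0.65e-19, 1.3e-19,
                                             2e-19, 2.9e-19)) {
  rows <- lapply(A_values, function(A) {
    e <- hamaker_energy(r, d, A)
    data.frame(A_J = A, energy_J = e$energy_J, energy_eV = e$energy_eV,
               energy_kT = e$energy_kT)
  })
  do.call(rbind, rows)
}

#' Axial resolution of a dual-axis tomogram
#'
#' The axial (beam-direction) resolution is the in-plane resolution (set by
#' the first zero of the contrast transfer function) multiplied by the
#' missing-wedge elongation factor, plus the tilt-series alignment error:
#' `R = in_plane * elongation + alignment_error`.
#'
#' @param in_plane In-plane resolution in nm (default 1.3).
#' @param elongation Elongation factor (dimensionless; 1.44 for dual-axis
#'   +/- 60 degree acquisition).
#' @param alignment_error Alignment error in nm (default 1.1, about 2
#'   voxels).
#' @return Axial resolution in nm.
#' @examples
#' axial_resolution() # 2.972, i.e. 3 nm at reporting precision
#' @export
axial_resolution <- function(in_plane = 1.3, elongation = 1.44,
                             alignment_error = 1.1) {
  stopifnot(in_plane > 0, elongation > 0, alignment_error >= 0)
  in_plane * elongation + alignment_error
}
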