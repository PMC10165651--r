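#' Photophysical parameter set for the singlet/triplet ladder
#'
#' Bundles the cross sections and quantum yields of the four-state ladder
#' (S0, S1, T1, Tn) used throughout the simulator. The fast states S1 and Tn
#' are treated as instantaneous branch points relative to microsecond time
#' bins, so the parameters below fully determine the reduced three-state
#' dynamics: primary excitation S0 -> S1 branches into prompt fluorescence
#' (`phi_f`), intersystem crossing to the triplet shelf T1 (`phi_ISC`) or dark
#' relaxation; secondary excitation T1 -> Tn branches into reverse intersystem
#' crossing back to S1 (`phi_RISC`) or return to T1.
#'
#' @param sigma_S0 Singlet ground-state absorption cross section (cm^2).
#' @param sigma_T1 Triplet T1 -> Tn absorption cross section (cm^2).
#' @param phi_f Fluorescence quantum yield of S1 (dimensionless, in `[0, 1]`).
#' @param phi_ISC Intersystem-crossing quantum yield of S1 (dimensionless).
#'   `phi_f + phi_ISC` must not exceed 1.
#' @param phi_RISC Reverse-intersystem-crossing quantum yield of Tn
#'   (dimensionless).
#' @param k_T Unimolecular T1 decay rate (1/s), covering all secondary-laser
#'   independent triplet loss.
#' @param dipole_angle Angle between the S0->S1 and T1->Tn transition dipoles
#'   (radians). Collinear dipoles (`0`, the default) give the maximal
#'   fundamental anisotropy.
#'
#' @return An object of class `oadfa_photophysics` (a named list).
#' @examples
#' ph <- photophysics_params()
#' ph$phi_ISC
#' @export
photophysics_params <- function(sigma_S0 = 1e-16,
                                sigma_T1 = 1e-17,
                                phi_f = 0.05,
                                phi_ISC = 0.9,
                                phi_RISC = 0.1,
                                k_T = 3e5,
                                dipole_angle = 0) {
  stopifnot(
    is.numeric(sigma_S0), length(sigma_S0) == 1, sigma_S0 >= 0,
    is.numeric(sigma_T1), length(sigma_T1) == 1, sigma_T1 >= 0,
    is.numeric(k_T), length(k_T) == 1, k_T >= 0,
    is.numeric(dipole_angle), length(dipole_angle) == 1
  )
  for (y in c(phi_f = phi_f, phi_ISC = phi_ISC, phi_RISC = phi_RISC)) {
    if (!is.numeric(y) || y < 0 || y > 1) {
      stop("quantum yields must lie in [0, 1]", call. = FALSE)
    }
  }
  if (phi_f + phi_ISC > 1 + 1e-12) {
    stop("phi_f + phi_ISC must not exceed 1", call. = FALSE)
  }
  structure(
    list(
      sigma_S0 = sigma_S0, sigma_T1 = sigma_T1,
      phi_f = phi_f, phi_ISC = phi_ISC, phi_RISC = phi_RISC,
      k_T = k_T, dipole_angle = dipole_angle
    ),
    class = "oadfa_photophysics"
  )
}

#' Excitation protocol: pulsed primary + CW secondary lasers
#'
#' Describes one OADFA acquisition: a linearly polarized primary pulse at
#' t = 0 followed by a continuous-wave secondary laser whose polarization acts
#' as the analyzer. Delayed-fluorescence photons are histogrammed into bins of
#' `bin_width` over `[0, window]`. Setting `secondary_on_delay > 0` implements
#' the delayed-secondary protocol that mitigates differential triplet
#' depletion for slowly rotating species.
#'
#' @param primary_fluence Primary pulse fluence (photons/cm^2 per pulse).
#'   `sigma_S0 * primary_fluence` is the per-pulse excitation probability of a
#'   perfectly aligned molecule (clipped to 1).
#' @param secondary_intensity Secondary laser intensity (photons/cm^2/s).
#'   `sigma_T1 * secondary_intensity` is the peak triplet pump rate.
#' @param secondary_on_delay Time after the primary pulse at which the
#'   secondary laser turns on (s, default 0 = continuous coillumination).
#' @param window Total collection time after the pulse (s).
#' @param bin_width Histogram bin width (s).
#' @param primary_pol_axis Lab-frame primary polarization axis (unit vector,
#'   default x).
#' @param secondary_pol_axis Lab-frame secondary polarization axis used by the
#'   single-channel operations (unit vector, default x = parallel). The full
#'   simulator always runs both the parallel and the in-plane perpendicular
#'   channel.
#' @param leakage_in_plane Fractional polarization impurity leaking into the
#'   in-plane orthogonal axis (dimensionless, in `[0, 1)`).
#' @param leakage_out_of_plane Fractional impurity leaking into the optical
#'   (z) axis (dimensionless, in `[0, 1)`).
#'
#' @return An object of class `oadfa_protocol`.
#' @examples
#' pr <- excitation_protocol(window = 2e-6, bin_width = 50e-9)
#' pr$bin_width
#' @export
excitation_protocol <- function(primary_fluence = 1e16,
                                secondary_intensity = 2.5e24,
                                secondary_on_delay = 0,
                                window = 2e-6,
                                bin_width = 50e-9,
                                primary_pol_axis = c(1, 0, 0),
                                secondary_pol_axis = c(1, 0, 0),
                                leakage_in_plane = 0,
                                leakage_out_of_plane = 0) {
  stopifnot(
    primary_fluence >= 0, secondary_intensity >= 0,
    window > 0, bin_width > 0,
    secondary_on_delay >= 0, secondary_on_delay < window,
    leakage_in_plane >= 0, leakage_in_plane < 1,
    leakage_out_of_plane >= 0, leakage_out_of_plane < 1,
    leakage_in_plane + leakage_out_of_plane < 1
  )
  primary_pol_axis <- normalize_axis(primary_pol_axis)
  secondary_pol_axis <- normalize_axis(secondary_pol_axis)
  structure(
    list(
      primary_fluence = primary_fluence,
      secondary_intensity = secondary_intensity,
      secondary_on_delay = secondary_on_delay,
      window = window, bin_width = bin_width,
      primary_pol_axis = primary_pol_axis,
      secondary_pol_axis = secondary_pol_axis,
      leakage_in_plane = leakage_in_plane,
      leakage_out_of_plane = leakage_out_of_plane
    ),
    class = "oadfa_protocol"
  )
}

#' Rotational diffusion parameters
#'
#' A spherical rotor is characterized by a single rotational correlation time
#' `theta_rot`, the decay constant of the second-rank orientational
#' correlation `<P2(u(0).u(t))> = exp(-t/theta_rot)`, related to the
#' rotational diffusion coefficient by `theta_rot = 1/(6 * D_rot)`.
#'
#' @param theta_rot Rotational correlation time (s). Give either this or
#'   `D_rot`.
#' @param D_rot Rotational diffusion coefficient (rad^2/s).
#'
#' @return An object of class `oadfa_diffusion` with both parametrizations.
#' @examples
#' diffusion_params(theta_rot = 200e-9)$D_rot
#' @export
diffusion_params <- function(theta_rot = NULL, D_rot = NULL) {
  if (is.null(theta_rot) && is.null(D_rot)) {
    stop("supply theta_rot or D_rot", call. = FALSE)
  }
  if (!is.null(theta_rot) && !is.null(D_rot) &&
      abs(theta_rot * 6 * D_rot - 1) > 1e-9) {
    stop("theta_rot and D_rot are inconsistent (theta = 1/(6 D))",
         call. = FALSE)
  }
  if (is.null(theta_rot)) theta_rot <- 1 / (6 * D_rot)
  if (is.null(D_rot)) D_rot <- 1 / (6 * theta_rot)
  stopifnot(theta_rot > 0)
  structure(list(theta_rot = theta_rot, D_rot = D_rot),
            class = "oadfa_diffusion")
}

#' Solution conditions for hydrodynamic size conversion
#'
#' @param eta Dynamic viscosity. Interpreted as Pa s when `unit = "Pa.s"`
#'   (default) or centipoise when `unit = "cP"` (1 cP = 1e-3 Pa s).
#' @param temperature Absolute temperature (K).
#' @param unit Viscosity unit of the supplied `eta`.
#'
#' @return An object of class `oadfa_solution` with `eta` in Pa s.
#' @examples
#' solution_conditions(eta = 1.0005, temperature = 293, unit = "cP")
#' @export
solution_conditions <- function(eta, temperature, unit = c("Pa.s", "cP")) {
  unit <- match.arg(unit)
  if (unit == "cP") eta <- eta * 1e-3
  stopifnot(eta > 0, temperature > 0)
  structure(list(eta = eta, temperature = temperature),
            class = "oadfa_solution")
}

normalize_axis <- function(v) {
  if (!is.numeric(v) || length(v) != 3 || !all(is.finite(v))) {
    stop("polarization axis must be a finite numeric 3-vector", call. = FALSE)
  }
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("polarization axis must be nonzero", call. = FALSE)
  v / n
}

#' @export
print.oadfa_photophysics <- function(x, ...) {
  cat("<oadfa photophysics>\n")
  cat(sprintf("  sigma_S0 = %.3g cm^2, sigma_T1 = %.3g cm^2\n",
              x$sigma_S0, x$sigma_T1))
  cat(sprintf("  phi_f = %.3g, phi_ISC = %.3g, phi_RISC = %.3g\n",
              x$phi_f, x$phi_ISC, x$phi_RISC))
  cat(sprintf("  k_T = %.3g 1/s, dipole_angle = %.3g rad\n",
              x$k_T, x$dipole_angle))
  invisible(x)
}

#' @export
print.oadfa_protocol <- function(x, ...) {
  cat("<oadfa excitation protocol>\n")
  cat(sprintf("  primary fluence %.3g photons/cm^2; secondary %.3g photons/cm^2/s\n",
              x$primary_fluence, x$secondary_intensity))
  cat(sprintf("  window %.3g s in %.3g s bins; secondary on at %.3g s\n",
              x$window, x$bin_width, x$secondary_on_delay))
  invisible(x)
}

#' @export
print.oadfa_diffusion <- function(x, ...) {
  cat(sprintf("<oadfa diffusion> theta_rot = %.4g s (D_rot = %.4g rad^2/s)\n",
              x$theta_rot, x$D_rot))
  invisible(x)
}

#' @export
print.oadfa_solution <- function(x, ...) {
  cat(sprintf("<oadfa solution> eta = %.4g Pa.s, T = %.4g K\n",
              x$eta, x$temperature))
  invisible(x)
}
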