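#' Orientation-dependent excitation rate (photoselection)
#'
#' Polarized excitation photoselects molecules with probability proportional
#' to `cos^2(alpha)`, where `alpha` is the angle between the transition dipole
#' (taken along the molecular orientation vector) and the laser polarization.
#' For the pulsed primary channel the return value is a per-pulse excitation
#' probability `min(sigma_S0 * fluence * cos^2 alpha, 1)`; for the CW
#' secondary channel it is a pump rate `sigma_T1 * I_sec * cos^2 alpha` in
#' 1/s. With nonzero polarization leakage the squared cosine is replaced by a
#' purity-weighted mixture over the polarization axis, its in-plane orthogonal
#' and the out-of-plane (z) axis.
#'
#' @param photo A [photophysics_params()] object.
#' @param protocol An [excitation_protocol()] object; the channel polarization
#'   axis and leakage fractions are taken from it.
#' @param orientation Unit 3-vector, the molecular transition dipole axis.
#' @param channel `"primary"` or `"secondary"`.
#' @return A single number: probability (primary) or rate in 1/s (secondary).
#' @examples
#' ph <- photophysics_params(); pr <- excitation_protocol()
#' excitation_rate(ph, pr, c(1, 0, 0), "primary")
#' excitation_rate(ph, pr, c(0, 1, 0), "secondary")
#' @export
excitation_rate <- function(photo, protocol, orientation,
                            channel = c("primary", "secondary")) {
  channel <- match.arg(channel)
  stopifnot(inherits(photo, "oadfa_photophysics"),
            inherits(protocol, "oadfa_protocol"))
  if (!is.numeric(orientation) || length(orientation) != 3 ||
      abs(sum(orientation^2) - 1) > 1e-6) {
    stop("orientation must be a unit 3-vector", call. = FALSE)
  }
  axis <- if (channel == "primary") protocol$primary_pol_axis else
    protocol$secondary_pol_axis
  w <- polarization_weights(axis, protocol$leakage_in_plane,
                            protocol$leakage_out_of_plane)
  eff <- effective_cos2(orientation, w)
  if (channel == "primary") {
    if (protocol$primary_fluence < 0) stop("negative fluence", call. = FALSE)
    min(photo$sigma_S0 * protocol$primary_fluence * eff, 1)
  } else {
    if (protocol$secondary_intensity < 0) {
      stop("negative intensity", call. = FALSE)
    }
    photo$sigma_T1 * protocol$secondary_intensity * eff
  }
}

# Orthonormal triad (axis, in-plane orthogonal, out-of-plane) and purity
# weights for a polarization axis lying in the lab xy plane.
polarization_weights <- function(axis, leak_in, leak_out) {
  a <- normalize_axis(axis)
  if (abs(a[3]) > 1e-9 && (leak_in > 0 || leak_out > 0)) {
    stop("leakage model requires a polarization axis in the xy plane",
         call. = FALSE)
  }
  z <- c(0, 0, 1)
  if (abs(abs(a[3]) - 1) < 1e-9) {
    b <- c(1, 0, 0)
  } else {
    b <- c(z[2] * a[3] - z[3] * a[2],
           z[3] * a[1] - z[1] * a[3],
           z[1] * a[2] - z[2] * a[1])
    b <- b / sqrt(sum(b^2))
  }
  cc <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  list(basis = rbind(a, b, cc),
       weights = c(1 - leak_in - leak_out, leak_in, leak_out))
}

effective_cos2 <- function(u, pw) {
  sum(pw$weights * as.numeric(pw$basis %*% u)^2)
}

#' Integrate the reduced photophysical rate equations (frozen rotation)
#'
#' Solves the coupled state populations of the reduced three-state model
#' (S0, S1, T1; the fast states S1 and Tn are adiabatically eliminated as
#' instantaneous branch points) for a molecule with a fixed orientation under
#' a polarized primary pulse at t = 0 followed by CW secondary pumping. This
#' no-rotation limit is the model-checking companion of the Monte Carlo
#' engine: immediately after the pulse the triplet shelf holds
#' `P(excite) * phi_ISC`, and while the secondary laser is on it drains with
#' total rate `k_T + k_pump * phi_RISC * (1 - phi_ISC)` where
#' `k_pump = sigma_T1 * I_sec * cos^2(alpha')`. The delayed-fluorescence
#' photon emission rate is `T1(t) * k_pump * phi_RISC * phi_f`.
#'
#' @param photo A [photophysics_params()] object.
#' @param protocol An [excitation_protocol()] object (its
#'   `secondary_pol_axis` and `secondary_on_delay` are honored).
#' @param orientation Fixed unit 3-vector orientation of the molecule.
#' @param horizon Integration horizon (s); defaults to `protocol$window`.
#' @param n_out Number of output time points.
#' @return A tibble of class `oadfa_populations` with columns `time`, `S0`,
#'   `S1`, `T1` and `oadf_rate` (delayed photons per second per molecule).
#' @examples
#' ph <- photophysics_params(k_T = 1e5)
#' pr <- excitation_protocol(window = 5e-6)
#' pop <- integrate_populations(ph, pr, c(1, 0, 0))
#' max(abs(pop$S0 + pop$S1 + pop$T1 - 1))
#' @export
integrate_populations <- function(photo, protocol, orientation,
                                  horizon = protocol$window, n_out = 201) {
  stopifnot(horizon > 0)
  p_exc <- excitation_rate(photo, protocol, orientation, "primary")
  k_pump <- excitation_rate(photo, protocol, orientation, "secondary")
  k_deplete <- k_pump * photo$phi_RISC * (1 - photo$phi_ISC)
  t1_0 <- p_exc * photo$phi_ISC
  delay <- protocol$secondary_on_delay

  deriv <- function(t, y, parms) {
    on <- as.numeric(t >= delay)
    loss <- (photo$k_T + on * k_deplete) * y[["T1"]]
    list(c(S0 = loss, T1 = -loss))
  }
  times <- seq(0, horizon, length.out = n_out)
  # force the secondary turn-on instant onto the solver grid
  solver_times <- sort(unique(c(times, delay[delay < horizon])))
  sol <- deSolve::ode(
    y = c(S0 = 1 - t1_0, T1 = t1_0), times = solver_times, func = deriv,
    parms = NULL, method = "lsoda", rtol = 1e-9, atol = 1e-12
  )
  if (attr(sol, "istate")[1] < 0) {
    stop("population integration failed; see deSolve diagnostics",
         call. = FALSE)
  }
  sol <- sol[match(times, solver_times), , drop = FALSE]
  out <- tibble::tibble(
    time = times,
    S0 = as.numeric(sol[, "S0"]),
    S1 = 0,
    T1 = as.numeric(sol[, "T1"])
  )
  out$oadf_rate <- out$T1 * ifelse(times >= delay, k_pump, 0) *
    photo$phi_RISC * photo$phi_f
  class(out) <- c("oadfa_populations", class(out))
  out
}
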