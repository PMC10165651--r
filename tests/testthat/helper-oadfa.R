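# Shared builders for the test suite. Fixtures are generated in code; no
# binary data ships with the package.

default_photo <- function(...) photophysics_params(...)

quick_protocol <- function(...) {
  args <- utils::modifyList(list(window = 2e-6, bin_width = 50e-9),
                            list(...))
  do.call(excitation_protocol, args)
}

# Poisson-noised trace pair drawn from the weak-depletion closed forms,
# wrapped as an oadfa_trace so the analysis pipeline can consume it.
synthetic_closed_form_trace <- function(theta_rot, total_photons,
                                        window = 2e-6, bin_width = 50e-9,
                                        survival_rate = 0, seed = 1) {
  set.seed(seed)
  edges <- seq(0, window, by = bin_width)
  mid <- edges[-length(edges)] + bin_width / 2
  ints <- closed_form_intensities(mid, theta_rot, survival_rate)
  scale <- total_photons / sum(ints$I_par)
  df <- tibble::tibble(
    bin_start = edges[-length(edges)],
    counts_par = stats::rpois(length(mid), ints$I_par * scale),
    counts_perp = stats::rpois(length(mid), ints$I_perp * scale),
    prompt_counts = 0L
  )
  tr <- df
  attr(tr, "protocol") <- excitation_protocol(window = window,
                                              bin_width = bin_width)
  attr(tr, "diffusion") <- diffusion_params(theta_rot = theta_rot)
  attr(tr, "photo") <- photophysics_params()
  attr(tr, "mode") <- "oadfa"
  attr(tr, "n_molecules") <- NA_real_
  attr(tr, "seed") <- seed
  class(tr) <- c("oadfa_trace", class(tr))
  tr
}

# noiseless anisotropy tibble for exact-recovery fitting tests
exact_aniso <- function(r0, theta, times, r_err = 1e-3) {
  an <- tibble::tibble(time = times, r = r0 * exp(-times / theta),
                       r_err = r_err, mask = FALSE)
  class(an) <- c("oadfa_anisotropy", class(an))
  an
}
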