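#' Build an anisotropy decay from a polarized trace
#'
#' Converts binned parallel/perpendicular photon counts into a per-bin
#' anisotropy with Poisson standard errors. Two denominator conventions are
#' supported: `"standard"` uses `(Ipar - Iperp)/(Ipar + 2*Iperp)`, which in
#' the weak-depletion limit decays as a single exponential with fundamental
#' anisotropy 2/5 and is the fitting default; `"total"` uses the
#' total detected OADF intensity `(Ipar - Iperp)/(Ipar + Iperp)` (no emission
#' analyzer exists, so the total intensity is just the channel sum), which
#' starts at 1/2 and is not single-exponential at early times. The first
#' `blind_bins` bins are masked: prompt fluorescence is unpolarized between
#' the two secondary channels and swamps the delayed signal there.
#'
#' @param trace An `oadfa_trace` tibble (both channels), or the parallel
#'   trace when `trace_perp` is supplied.
#' @param trace_perp Optional second `oadfa_trace` whose `counts_perp` column
#'   replaces the perpendicular channel; binning must match exactly.
#' @param convention `"standard"` or `"total"`.
#' @param blind_bins Number of leading bins to mask (default 2).
#' @param include_prompt Add `prompt_counts` to both channels before forming
#'   the ratio (default TRUE, mimicking a detector that cannot separate
#'   prompt from delayed photons). Masked bins make this immaterial for
#'   fitting.
#' @return A tibble of class `oadfa_anisotropy`: `time` (bin centers, s),
#'   `r`, `r_err`, `mask` (TRUE = excluded), with the convention and bin
#'   width as attributes.
#' @examples
#' tr <- simulate_oadfa(photophysics_params(), excitation_protocol(),
#'                      diffusion_params(theta_rot = 200e-9), 2e4, seed = 1)
#' an <- compute_anisotropy(tr)
#' head(an)
#' @export
compute_anisotropy <- function(trace, trace_perp = NULL,
                               convention = c("standard", "total"),
                               blind_bins = 2, include_prompt = TRUE) {
  convention <- match.arg(convention)
  stopifnot(inherits(trace, "oadfa_trace") || is.data.frame(trace),
            blind_bins >= 0)
  if (!is.null(trace_perp)) {
    if (nrow(trace_perp) != nrow(trace) ||
        max(abs(trace_perp$bin_start - trace$bin_start)) > 1e-15) {
      stop("parallel and perpendicular traces have mismatched binning",
           call. = FALSE)
    }
    trace$counts_perp <- trace_perp$counts_perp
  }
  bw <- attr(trace, "protocol")$bin_width
  if (is.null(bw)) bw <- diff(trace$bin_start[1:2])

  p <- as.numeric(trace$counts_par)
  q <- as.numeric(trace$counts_perp)
  if (include_prompt && "prompt_counts" %in% names(trace)) {
    p <- p + as.numeric(trace$prompt_counts)
    q <- q + as.numeric(trace$prompt_counts)
  }
  if (convention == "standard") {
    den <- p + 2 * q
    r <- (p - q) / den
    r_err <- 3 * sqrt(p * q * (p + q)) / den^2
  } else {
    den <- p + q
    r <- (p - q) / den
    r_err <- 2 * sqrt(p * q / den) / den
  }
  mask <- seq_along(p) <= blind_bins | !is.finite(r) | den <= 0
  out <- tibble::tibble(
    time = trace$bin_start + bw / 2,
    r = ifelse(den > 0, r, NA_real_),
    r_err = ifelse(den > 0, r_err, NA_real_),
    mask = mask
  )
  attr(out, "convention") <- convention
  attr(out, "blind_bins") <- blind_bins
  attr(out, "bin_width") <- bw
  attr(out, "diffusion") <- attr(trace, "diffusion")
  class(out) <- c("oadfa_anisotropy", class(out))
  out
}

#' Fit the single-exponential anisotropy decay
#'
#' Weighted nonlinear least squares of `r(t) = r0 * exp(-t/theta)` to an
#' anisotropy trace, with weights `1/r_err^2` and parameter uncertainties
#' from the covariance matrix. Bins that are masked, have non-finite values
#' or a zero standard error are excluded. A fit that converges to a
#' non-positive or effectively unbounded `theta` (longer than 100x the fit
#' span, the signature of a constant trace) is reported as a failure rather
#' than as a spurious finite correlation time.
#'
#' @param aniso An `oadfa_anisotropy` tibble from [compute_anisotropy()].
#' @param window Optional numeric length-2 time range `c(tmin, tmax)` in
#'   seconds. The default runs from the first unmasked bin to the last bin
#'   whose relative error is below 50%.
#' @return An object of class `oadfa_fit`: list with `r0`, `theta`,
#'   `r0_err`, `theta_err`, `success`, `reason`, `convention`, `fit_window`,
#'   `n_bins`, `chisq_red` and the fitted data subset. Use [generics::tidy()]
#'   / [generics::glance()] for rectangular summaries.
#' @examples
#' t <- seq(25e-9, 2e-6, by = 50e-9)
#' an <- tibble::tibble(time = t, r = 0.4 * exp(-t / 200e-9),
#'                      r_err = 0.005, mask = FALSE)
#' class(an) <- c("oadfa_anisotropy", class(an))
#' fit <- fit_decay(an)
#' fit$theta
#' @export
fit_decay <- function(aniso, window = NULL) {
  stopifnot(is.data.frame(aniso),
            all(c("time", "r", "r_err", "mask") %in% names(aniso)))
  convention <- attr(aniso, "convention") %||% "standard"

  usable <- !aniso$mask & is.finite(aniso$r) & is.finite(aniso$r_err) &
    aniso$r_err > 0
  if (is.null(window)) {
    idx <- which(usable)
    if (!length(idx)) stop("no unmasked bins to fit", call. = FALSE)
    # keep the contiguous run of bins whose relative error stays below 50%;
    # the signal level is taken from a 5-bin rolling mean so that single-bin
    # noise neither truncates nor extends the window
    r_smooth <- stats::filter(ifelse(usable, aniso$r, NA), rep(1 / 5, 5),
                              sides = 2)
    r_smooth <- ifelse(is.na(r_smooth), aniso$r, r_smooth)
    rel_ok <- usable & aniso$r_err < 0.5 * abs(r_smooth)
    bad <- idx[!rel_ok[idx]]
    last <- if (length(bad)) {
      if (bad[1] == idx[1]) idx[1] else max(idx[idx < bad[1]])
    } else {
      max(idx)
    }
    last <- max(last, idx[min(length(idx), 8)])  # never fewer than ~8 bins
    window <- c(aniso$time[idx[1]], aniso$time[last])
  }
  sel <- usable & aniso$time >= window[1] & aniso$time <= window[2]
  if (sum(sel) < 4) {
    stop("fit window contains fewer than 4 usable bins", call. = FALSE)
  }
  d <- aniso[sel, c("time", "r", "r_err")]

  failure <- function(reason) {
    structure(list(r0 = NA_real_, theta = NA_real_, r0_err = NA_real_,
                   theta_err = NA_real_, success = FALSE, reason = reason,
                   convention = convention, fit_window = window,
                   n_bins = nrow(d), chisq_red = NA_real_, data = d,
                   model = NULL),
              class = "oadfa_fit")
  }

  if (sum(d$r > 0) < 3) {
    return(failure("too few positive anisotropy bins for a decay fit"))
  }
  # robust start: profile the weighted SSE over a grid of decay times, with
  # the amplitude solved linearly at each candidate
  span <- diff(range(d$time))
  w <- 1 / d$r_err^2
  cand <- span * c(0.02, 0.05, 0.1, 0.2, 0.35, 0.5, 0.75, 1, 1.5, 2.5, 5, 10)
  lf <- stats::lm(log(r) ~ time, data = d[d$r > 0, ],
                  weights = w[d$r > 0] * d$r[d$r > 0]^2)
  th_lm <- -1 / stats::coef(lf)[2]
  if (is.finite(th_lm) && th_lm > 0) cand <- c(cand, th_lm)
  prof <- vapply(cand, function(th) {
    x <- exp(-d$time / th)
    a <- sum(w * x * d$r) / sum(w * x^2)
    sum(w * (d$r - a * x)^2)
  }, numeric(1))
  theta0 <- cand[which.min(prof)]
  x0 <- exp(-d$time / theta0)
  r00 <- sum(w * x0 * d$r) / sum(w * x0^2)
  if (!is.finite(r00) || r00 <= 0) {
    return(failure("no decaying positive-amplitude exponential fits the trace"))
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(
      r ~ r0 * exp(-time / theta), data = d,
      start = list(r0 = unname(r00), theta = unname(theta0)),
      weights = 1 / d$r_err^2,
      lower = c(r0 = -1, theta = span / 1e4),
      upper = c(r0 = 2, theta = span * 1e4),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(failure(paste("nonlinear fit did not converge:",
                         conditionMessage(fit))))
  }
  est <- stats::coef(fit)
  span <- diff(range(d$time))
  if (!is.finite(est[["theta"]]) || est[["theta"]] <= 0) {
    return(failure("fitted correlation time is non-positive"))
  }
  if (est[["theta"]] > 100 * span) {
    return(failure("fitted correlation time unbounded (trace has no decay)"))
  }
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) {
    c(r0 = NA_real_, theta = NA_real_)
  })
  resid_w <- (d$r - stats::predict(fit)) / d$r_err
  structure(list(
    r0 = unname(est[["r0"]]), theta = unname(est[["theta"]]),
    r0_err = unname(se[["r0"]]), theta_err = unname(se[["theta"]]),
    success = TRUE, reason = NULL, convention = convention,
    fit_window = window, n_bins = nrow(d),
    chisq_red = sum(resid_w^2) / max(1, nrow(d) - 2),
    data = d, model = fit
  ), class = "oadfa_fit")
}

#' @export
print.oadfa_fit <- function(x, ...) {
  cat("<oadfa anisotropy fit>\n")
  if (!x$success) {
    cat("  FAILED:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("  r0    = %.4f +/- %.4f\n", x$r0, x$r0_err))
  cat(sprintf("  theta = %.4g +/- %.2g s\n", x$theta, x$theta_err))
  cat(sprintf("  convention %s, %d bins in [%.3g, %.3g] s, chisq/dof = %.2f\n",
              x$convention, x$n_bins, x$fit_window[1], x$fit_window[2],
              x$chisq_red))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.oadfa_fit <- function(x, ...) {
  tibble::tibble(
    term = c("r0", "theta"),
    estimate = c(x$r0, x$theta),
    std.error = c(x$r0_err, x$theta_err)
  )
}

#' @export
glance.oadfa_fit <- function(x, ...) {
  tibble::tibble(
    r0 = x$r0, theta = x$theta, r0_err = x$r0_err, theta_err = x$theta_err,
    chisq_red = x$chisq_red, n_bins = x$n_bins,
    convention = x$convention, success = x$success
  )
}

# Boltzmann constant, J/K
.kB <- 1.380649e-23

#' Rotational correlation time to hydrodynamic size (Stokes-Einstein-Debye)
#'
#' For a sphere rotating in a continuum solvent the rotational correlation
#' time is `theta = eta * V / (kB * T)`, so a measured `theta` inverts to the
#' hydrodynamic volume `V = theta * kB * T / eta` and the equivalent-sphere
#' diameter `d = (6 V / pi)^(1/3)`.
#'
#' @param theta Rotational correlation time (s), or an `oadfa_fit` object
#'   (its `theta` and `theta_err` are used).
#' @param conditions A [solution_conditions()] object.
#' @param theta_err Optional 1-sigma uncertainty on `theta` (s); the relative
#'   error maps to the diameter divided by 3 (cubic law).
#' @return A one-row tibble: `theta`, `volume` (m^3), `diameter` (nm),
#'   `diameter_err` (nm).
#' @examples
#' theta_to_size(1.5e-6, solution_conditions(1.0005, 293, unit = "cP"))
#' @export
theta_to_size <- function(theta, conditions, theta_err = 0) {
  if (inherits(theta, "oadfa_fit")) {
    if (!theta$success) {
      stop("cannot size a failed anisotropy fit", call. = FALSE)
    }
    theta_err <- if (is.finite(theta$theta_err)) theta$theta_err else 0
    theta <- theta$theta
  }
  stopifnot(inherits(conditions, "oadfa_solution"),
            is.numeric(theta), theta > 0, theta_err >= 0)
  v <- theta * .kB * conditions$temperature / conditions$eta
  d_m <- (6 * v / pi)^(1 / 3)
  tibble::tibble(
    theta = theta,
    volume = v,
    diameter = d_m * 1e9,
    diameter_err = d_m * 1e9 / 3 * theta_err / theta
  )
}

#' Hydrodynamic diameter to rotational correlation time
#'
#' Inverse of [theta_to_size()]: `theta = eta * V / (kB * T)` with
#' `V = pi d^3 / 6`.
#'
#' @param diameter Equivalent-sphere hydrodynamic diameter (nm).
#' @param conditions A [solution_conditions()] object.
#' @return Rotational correlation time (s).
#' @examples
#' size_to_theta(23, solution_conditions(1.0005, 293, unit = "cP"))
#' @export
size_to_theta <- function(diameter, conditions) {
  stopifnot(inherits(conditions, "oadfa_solution"),
            is.numeric(diameter), all(diameter > 0))
  v <- pi * (diameter * 1e-9)^3 / 6
  v * conditions$eta / (.kB * conditions$temperature)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
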