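# Position-dependent diffusivity from restrained-window fluctuations and the
# inhomogeneous solubility-diffusion permeability. The diffusivity estimator
# is D = var(z)^2 / int_0^tau_c C_zz(t) dt, the restrained-window form that
# is exact for an Ornstein-Uhlenbeck process (equivalently D = var/tau_int
# with tau_int the integrated autocorrelation time).

#' Position autocorrelation of a window series
#'
#' Biased estimator with fixed 1/n normalization at every lag,
#' C_zz(t) = (1/n) sum_i dz(i) dz(i + t) with dz = z - mean(z), computed
#' via FFT. The integral timescale is int C dt / var, truncated at the
#' first zero crossing of C (the noise-dominated tail otherwise biases
#' the integral).
#'
#' @param z_series numeric series (A).
#' @param dt sampling interval (ps).
#' @param max_lag maximum lag (ps); must be below the series span.
#' @return object of class `acf_series`: `lags` (ps), `C_zz` (A^2),
#'   `variance`, `integral_timescale` (ps), `truncation_lag` (ps).
#' @export
autocorrelation <- function(z_series, dt, max_lag) {
  n <- length(z_series)
  span <- (n - 1) * dt
  if (max_lag >= span) stop("max_lag must be smaller than the series span")
  n_lag <- floor(max_lag / dt)
  if (n < 2 * n_lag) stop("series too short for requested max_lag")
  dz <- z_series - mean(z_series)
  # biased ACF via zero-padded FFT
  m <- stats::nextn(2L * n, 2)
  ft <- stats::fft(c(dz, numeric(m - n)))
  ac <- Re(stats::fft(ft * Conj(ft), inverse = TRUE))[seq_len(n_lag + 1L)] /
    (as.numeric(m) * n)
  lags <- (0:n_lag) * dt
  variance <- ac[1]
  if (variance <= 0) {
    return(structure(list(lags = lags, C_zz = numeric(n_lag + 1L),
                          variance = 0, integral_timescale = 0,
                          truncation_lag = 0),
                     class = "acf_series"))
  }
  zero <- which(ac <= 0)[1]
  cut <- if (is.na(zero)) n_lag + 1L else zero
  integral <- .trapz(lags[seq_len(cut)], ac[seq_len(cut)])
  structure(list(lags = lags, C_zz = ac, variance = variance,
                 integral_timescale = integral / variance,
                 truncation_lag = lags[cut]),
            class = "acf_series")
}

#' @export
print.acf_series <- function(x, ...) {
  cat(sprintf(
    "Autocorrelation: var = %.4g A^2, tau_int = %.4g ps (truncated at %.4g ps, %d lags)\n",
    x$variance, x$integral_timescale, x$truncation_lag, length(x$lags)))
  invisible(x)
}

#' Diffusivity of one restrained window
#'
#' D = var(z)^2 / int_0^tau_c C_zz(t) dt with the integral truncated at the
#' first zero crossing of C_zz. Pathological series (zero variance or
#' non-positive integral) yield `D = NA` with a warning so the profile
#' builder can exclude them.
#'
#' @param window a [window_trajectory].
#' @param max_lag truncation of the ACF (ps); default 5% of the window span.
#' @return list with `mean_z` (A), `D` (A^2/ps), `variance` (A^2),
#'   `tau_int` (ps), `usable` (logical).
#' @export
window_diffusivity <- function(window, max_lag = NULL) {
  z <- window$z_values
  if (is.null(max_lag)) max_lag <- 0.05 * (window$n_samples - 1) * window$dt
  v <- mean((z - mean(z))^2)
  if (v <= 0) {
    warning("window ", window$window_id, " has zero variance; excluded")
    return(list(mean_z = mean(z), D = NA_real_, variance = v,
                tau_int = NA_real_, usable = FALSE))
  }
  ac <- autocorrelation(z, window$dt, max_lag)
  integral <- ac$integral_timescale * ac$variance
  if (!is.finite(integral) || integral <= 0) {
    warning("window ", window$window_id,
            " has non-positive autocorrelation integral; excluded")
    return(list(mean_z = mean(z), D = NA_real_, variance = v,
                tau_int = NA_real_, usable = FALSE))
  }
  list(mean_z = mean(z), D = ac$variance^2 / integral, variance = ac$variance,
       tau_int = ac$integral_timescale, usable = TRUE)
}

#' Position-dependent diffusivity profile
#'
#' One (mean z, D) point per usable window, sorted by mean z. Downstream
#' integration interpolates linearly between window positions and
#' extrapolates as a constant beyond the outermost windows.
#'
#' @param windows list of [window_trajectory] objects (at least 2 usable).
#' @param max_lag see [window_diffusivity].
#' @return object of class `diffusivity_profile`: `records` data.frame
#'   (bias_center, mean_z, variance, tau_int, D_A2_ps) and `n_excluded`.
#' @export
diffusivity_profile <- function(windows, max_lag = NULL) {
  recs <- lapply(windows, function(w) {
    d <- window_diffusivity(w, max_lag)
    data.frame(bias_center = w$bias_center, mean_z = d$mean_z,
               variance = d$variance, tau_int = d$tau_int, D_A2_ps = d$D,
               usable = d$usable)
  })
  recs <- do.call(rbind, recs)
  usable <- recs[recs$usable, , drop = FALSE]
  if (nrow(usable) < 2L) {
    stop("fewer than 2 usable windows for the diffusivity profile")
  }
  usable <- usable[order(usable$mean_z), ]
  structure(list(records = usable[, setdiff(names(usable), "usable")],
                 n_excluded = sum(!recs$usable)),
            class = "diffusivity_profile")
}

#' @export
print.diffusivity_profile <- function(x, ...) {
  r <- x$records
  cat(sprintf(
    "Diffusivity profile: %d windows (%d excluded), D in [%.3g, %.3g] A^2/ps (%.3g-%.3g cm^2/s)\n",
    nrow(r), x$n_excluded, min(r$D_A2_ps), max(r$D_A2_ps),
    convert_diffusivity(min(r$D_A2_ps), "A2/ps", "cm2/s"),
    convert_diffusivity(max(r$D_A2_ps), "A2/ps", "cm2/s")))
  invisible(x)
}

#' @export
as.data.frame.diffusivity_profile <- function(x, ...) x$records

# D (A^2/ps) at arbitrary z: linear between window means, constant outside.
.diffusivity_at <- function(D, z) {
  if (inherits(D, "diffusivity_profile")) {
    stats::approx(D$records$mean_z, D$records$D_A2_ps, xout = z, rule = 2)$y
  } else if (inherits(D, "zprofile")) {
    .profile_interp(D, z)
  } else if (is.numeric(D) && length(D) == 1L) {
    rep(D, length(z))
  } else stop("D must be a diffusivity_profile, zprofile, or a single value")
}

#' Permeability by inhomogeneous solubility-diffusion theory
#'
#' P = (int_{z_in}^{z_out} exp(beta G(z)) / D(z) dz)^{-1}, with the local
#' resistance R(z) = exp(beta G(z)) / D(z) and the effective resistance
#' R_eff = 1/P. The integral is trapezoidal with z in cm and D in cm^2/s;
#' the exponential is accumulated in log space so large barriers cannot
#' overflow. G must be referenced to zero in bulk.
#'
#' @param pmf a `pmf_fit` or [zprofile] of G(z) (kcal/mol).
#' @param D a `diffusivity_profile`, a [zprofile] of D (A^2/ps), or a single
#'   constant D (A^2/ps).
#' @param thermo a [thermo_state] or temperature (K).
#' @param z_in,z_out integration bounds (A), bulk to bulk.
#' @param grid_spacing integration grid step (A, default 0.05).
#' @return object of class `permeability_fit`: `P` (cm/s), `R_eff` (s/cm),
#'   `R_profile` ([zprofile], s/cm^2), `log_integrand` ([zprofile] of
#'   beta G - ln D), `z_in`, `z_out`.
#' @export
permeability <- function(pmf, D, thermo = thermo_state(), z_in, z_out,
                         grid_spacing = 0.05) {
  thermo <- .as_thermo(thermo)
  if (z_in >= z_out) stop("z_in must be less than z_out")
  prof <- if (inherits(pmf, "pmf_fit")) pmf$profile else pmf
  if (!inherits(prof, "zprofile")) stop("pmf must be a pmf_fit or zprofile")
  z <- seq(z_in, z_out, by = grid_spacing)
  if (z[length(z)] < z_out) z <- c(z, z_out)
  G <- .profile_interp(prof, z)
  D_A2ps <- .diffusivity_at(D, z)
  if (any(D_A2ps <= 0)) stop("D(z) must be positive on the integration grid")
  D_cm2s <- convert_diffusivity(D_A2ps, "A2/ps", "cm2/s")
  logR <- thermo$beta * G - log(D_cm2s)          # log resistance, s/cm^2
  # trapezoid weights in cm
  n <- length(z)
  w_cm <- c(diff(z)[1] / 2, (z[3:n] - z[1:(n - 2)]) / 2, diff(z)[n - 1] / 2) * 1e-8
  log_Reff <- .logsumexp(logR + log(w_cm))
  structure(
    list(P = exp(-log_Reff), R_eff = exp(log_Reff),
         R_profile = zprofile(z, exp(logR), unit = "s/cm^2"),
         log_integrand = zprofile(z, logR, unit = "ln(s/cm^2)"),
         z_in = z_in, z_out = z_out, thermo = thermo),
    class = "permeability_fit"
  )
}

#' @export
print.permeability_fit <- function(x, ...) {
  cat(sprintf(
    "Permeability over [%g, %g] A: P = %.3g cm/s, R_eff = %.3g s/cm\n",
    x$z_in, x$z_out, x$P, x$R_eff))
  invisible(x)
}

#' Full permeation analysis of an umbrella-window set
#'
#' Chains the three estimation stages: WHAM free-energy profile (optionally
#' with bootstrap errors), per-window diffusivity, and the
#' solubility-diffusion permeability integral.
#'
#' @param windows list of [window_trajectory] objects.
#' @param thermo a [thermo_state] or temperature (K).
#' @param z_in,z_out integration bounds (A).
#' @param n_boot bootstrap replicates for the PMF error band (0 to skip).
#' @param seed seed for the bootstrap resampling.
#' @param ... passed to [wham_solve].
#' @return object of class `permeation_fit` with `pmf`, `landmarks`,
#'   `diffusivity`, `permeability` components.
#' @examples
#' \donttest{
#' ls <- default_landscape()
#' wins <- simulate_window_set(ls, centers = seq(0, 70, by = 2),
#'                             n_steps = 2e5, seed = 7)
#' fit <- permeation(wins, thermo_state(310), z_in = 18, z_out = 62)
#' print(fit)
#' }
#' @export
permeation <- function(windows, thermo = thermo_state(), z_in = 18,
                       z_out = 62, n_boot = 0, seed = 1, ...) {
  thermo <- .as_thermo(thermo)
  pmf <- wham_solve(windows, thermo, ...)
  if (n_boot > 0) {
    pmf$profile$stderr <- .profile_interp(
      bootstrap_pmf(windows, thermo, n_boot = n_boot, seed = seed, ...),
      pmf$profile$z)
  }
  D <- diffusivity_profile(windows)
  perm <- permeability(pmf, D, thermo, z_in, z_out)
  # landmark extraction only applies when the profile spans the membrane
  # landmark regions; elsewhere (e.g. partial scans) it is skipped
  lm <- tryCatch(extract_landmarks(pmf), error = function(e) NULL)
  structure(list(pmf = pmf, landmarks = lm,
                 diffusivity = D, permeability = perm, thermo = thermo),
            class = "permeation_fit")
}

#' @export
print.permeation_fit <- function(x, ...) {
  print(x$pmf)
  if (!is.null(x$landmarks)) print(x$landmarks)
  print(x$diffusivity)
  print(x$permeability)
  invisible(x)
}

#' @export
summary.permeation_fit <- function(object, ...) print(object)

#' @export
plot.permeation_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$pmf$profile, ylab = "G(z) (kcal/mol)")
  r <- x$diffusivity$records
  graphics::plot(r$mean_z, convert_diffusivity(r$D_A2_ps, "A2/ps", "cm2/s"),
                 type = "b", log = "y", xlab = "z (Å)",
                 ylab = "D(z) (cm²/s)")
  invisible(x)
}
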