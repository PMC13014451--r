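# WHAM: combine harmonically biased window histograms into one unbiased
# free-energy profile by iterating the coupled equations
#   p(z_b) = sum_i n_i(z_b) / sum_i N_i exp(beta (f_i - w_i(z_b)))
#   f_i    = -kT ln sum_b p(z_b) exp(-beta w_i(z_b))
# to self-consistency on the f_i. Empty bins carry no free energy (they are
# masked, never interpolated).

.wham_bins <- function(z_all, bin_width, breaks = NULL) {
  if (is.null(breaks)) {
    lo <- floor(min(z_all) / bin_width) * bin_width
    hi <- ceiling(max(z_all) / bin_width) * bin_width
    breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  }
  breaks
}

.wham_counts <- function(windows, breaks) {
  B <- length(breaks) - 1L
  counts <- matrix(0, nrow = B, ncol = length(windows))
  for (i in seq_along(windows)) {
    idx <- findInterval(windows[[i]]$z_values, breaks,
                        rightmost.closed = TRUE, all.inside = FALSE)
    idx <- idx[idx >= 1L & idx <= B]
    counts[, i] <- tabulate(idx, nbins = B)
  }
  counts
}

.wham_core <- function(windows, thermo, bin_width, tolerance, max_iter,
                       breaks = NULL, f_init = NULL) {
  z_all_range <- range(unlist(lapply(windows, function(w) range(w$z_values))))
  breaks <- .wham_bins(z_all_range, bin_width, breaks)
  centers <- (head(breaks, -1) + tail(breaks, -1)) / 2
  counts <- .wham_counts(windows, breaks)
  n_b <- rowSums(counts)
  N <- vapply(windows, function(w) w$n_samples, 0)
  z0 <- vapply(windows, function(w) w$bias_center, 0)
  kk <- vapply(windows, function(w) w$spring_k, 0)
  # bias energy matrix: w_bi[b, i] = k_i/2 (z_b - z0_i)^2
  w_bi <- sweep(0.5 * outer(centers, z0, "-")^2, 2, kk, `*`)
  expw <- exp(-thermo$beta * w_bi)
  if (is.null(f_init)) f_init <- numeric(length(windows))
  sol <- cpp_wham_iterate(n_b, expw, N, f_init, thermo$beta, tolerance,
                          as.integer(max_iter))
  list(breaks = breaks, centers = centers, counts = counts, n_b = n_b,
       p = sol$p, f = sol$f, iterations = sol$iterations,
       converged = sol$converged, delta = sol$delta)
}

.check_overlap <- function(windows, counts, min_counts = 10) {
  z0 <- vapply(windows, function(w) w$bias_center, 0)
  ord <- order(z0)
  for (j in seq_len(length(ord) - 1L)) {
    a <- ord[j]; b <- ord[j + 1L]
    if (max(pmin(counts[, a], counts[, b])) < min_counts) {
      warning(sprintf(
        "weak histogram overlap between windows at z0 = %g and %g (shared bin < %d counts)",
        z0[a], z0[b], min_counts))
    }
  }
}

#' Reconstruct a potential of mean force by WHAM
#'
#' Solves the WHAM self-consistency equations over all windows and returns
#' the free-energy profile G(z) = -kT ln p(z), shifted so its minimum over
#' the bulk reference region is zero. Only populated bins carry a value.
#'
#' @param windows list of [window_trajectory] objects.
#' @param thermo a [thermo_state] or temperature (K).
#' @param bin_width histogram bin width (A, default 0.2).
#' @param tolerance convergence tolerance on the window shift constants f_i
#'   (kcal/mol, default 1e-7).
#' @param max_iter iteration cap (default 1e5); non-convergence is flagged,
#'   not fatal.
#' @param reference_region z interval over which G is pinned to zero
#'   (default c(66, 72), bulk water).
#' @return object of class `pmf_fit` with elements `profile` (a [zprofile]
#'   of G in kcal/mol), `f` (window shift constants), `converged`,
#'   `iterations`, `thermo`, `bin_width`, `reference_region`, plus the
#'   histogram internals used by the bootstrap.
#' @export
wham_solve <- function(windows, thermo = thermo_state(), bin_width = 0.2,
                       tolerance = 1e-7, max_iter = 1e5,
                       reference_region = c(66, 72)) {
  thermo <- .as_thermo(thermo)
  if (!length(windows)) stop("need at least one window")
  core <- .wham_core(windows, thermo, bin_width, tolerance, max_iter)
  if (length(windows) > 1L) .check_overlap(windows, core$counts)
  if (!core$converged) {
    warning(sprintf("WHAM did not converge in %d iterations (max |df| = %.3g)",
                    core$iterations, core$delta))
  }
  keep <- core$n_b > 0 & core$p > 0
  G <- -log(core$p[keep]) / thermo$beta
  z <- core$centers[keep]
  in_ref <- z >= reference_region[1] & z <= reference_region[2]
  shift <- if (any(in_ref)) min(G[in_ref]) else min(G)
  if (!any(in_ref)) {
    warning("reference region contains no populated bins; pinning global minimum to 0")
  }
  G <- G - shift
  structure(
    list(profile = zprofile(z, G, unit = "kcal/mol"),
         f = core$f, converged = core$converged, iterations = core$iterations,
         thermo = thermo, bin_width = bin_width,
         reference_region = reference_region,
         breaks = core$breaks, n_windows = length(windows)),
    class = "pmf_fit"
  )
}

#' @export
print.pmf_fit <- function(x, ...) {
  cat(sprintf(
    "WHAM PMF: %d windows, %d bins of %.3g A, %s after %d iterations\n",
    x$n_windows, length(x$profile$z), x$bin_width,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  cat(sprintf("  G range [%.3f, %.3f] kcal/mol; reference region [%g, %g] A\n",
              min(x$profile$values), max(x$profile$values),
              x$reference_region[1], x$reference_region[2]))
  invisible(x)
}

#' @export
coef.pmf_fit <- function(object, ...) object$f

#' @export
plot.pmf_fit <- function(x, ...) {
  plot(x$profile, ylab = "G(z) (kcal/mol)", ...)
}

#' @export
summary.pmf_fit <- function(object, ...) {
  lm <- extract_landmarks(object)
  cat("WHAM potential of mean force\n")
  print(object)
  print(lm)
  invisible(lm)
}

#' Moving-block bootstrap uncertainty for a WHAM profile
#'
#' Window samples are autocorrelated, so plain resampling underestimates
#' the error; instead, contiguous blocks of `block_length` samples are
#' resampled with replacement within each window, WHAM is re-solved per
#' replicate (warm-started from the full-data solution on the same bins),
#' and the per-bin standard deviation across replicates is returned.
#'
#' @param windows list of [window_trajectory] objects.
#' @param thermo a [thermo_state] or temperature (K).
#' @param n_boot number of bootstrap replicates (>= 20).
#' @param block_length block size in samples (default 200); must be shorter
#'   than every window.
#' @param seed RNG seed (resampling is deterministic given it).
#' @param bin_width,tolerance,max_iter,reference_region as in [wham_solve].
#' @return a [zprofile] of the per-bin standard error of G (kcal/mol), on
#'   the full-data grid (bins seen in fewer than 2 replicates are dropped).
#' @export
bootstrap_pmf <- function(windows, thermo = thermo_state(), n_boot = 50,
                          block_length = 200, seed = 1, bin_width = 0.2,
                          tolerance = 1e-7, max_iter = 1e5,
                          reference_region = c(66, 72)) {
  thermo <- .as_thermo(thermo)
  if (n_boot < 20) stop("n_boot must be >= 20")
  nmin <- min(vapply(windows, function(w) w$n_samples, 0))
  if (block_length >= nmin) {
    stop("block_length (", block_length, ") must be smaller than the shortest window (",
         nmin, " samples)")
  }
  fit <- wham_solve(windows, thermo, bin_width, tolerance, max_iter,
                    reference_region)
  breaks <- fit$breaks
  set.seed(seed)
  Gmat <- matrix(NA_real_, nrow = length(breaks) - 1L, ncol = n_boot)
  for (r in seq_len(n_boot)) {
    wins_r <- lapply(windows, function(w) {
      n <- w$n_samples
      n_blocks <- ceiling(n / block_length)
      starts <- sample.int(n - block_length + 1L, n_blocks, replace = TRUE)
      idx <- as.vector(outer(0:(block_length - 1L), starts, `+`))[seq_len(n)]
      window_trajectory(w$bias_center, w$spring_k, w$times, w$z_values[idx],
                        window_id = w$window_id)
    })
    core <- .wham_core(wins_r, thermo, bin_width, tolerance, max_iter,
                       breaks = breaks, f_init = fit$f)
    keep <- core$n_b > 0 & core$p > 0
    G <- rep(NA_real_, length(breaks) - 1L)
    G[keep] <- -log(core$p[keep]) / thermo$beta
    zc <- core$centers
    in_ref <- keep & zc >= reference_region[1] & zc <= reference_region[2]
    G <- G - if (any(in_ref)) min(G[in_ref]) else min(G, na.rm = TRUE)
    Gmat[, r] <- G
  }
  centers <- (head(breaks, -1) + tail(breaks, -1)) / 2
  n_rep <- rowSums(!is.na(Gmat))
  se <- apply(Gmat, 1, stats::sd, na.rm = TRUE)
  keep <- n_rep >= 2 & !is.na(se)
  zprofile(centers[keep], se[keep], unit = "kcal/mol (SE)")
}

#' Extract free-energy landmarks from a PMF
#'
#' Locates the interfacial minima and the core barrier maximum of the
#' profile and the barrier heights measured from each minimum: `dG_right`
#' = G(max) - G(min_right) and `dG_left` = G(max) - G(min_left), computed
#' exactly as differences of the located values. Ties are broken toward
#' the z closest to the region center.
#'
#' @param pmf a `pmf_fit` or a [zprofile] of G(z).
#' @param interface_right z interval of the extracellular-side interface
#'   (default c(50, 65) A).
#' @param core z interval of the bilayer core (default c(30, 50) A).
#' @param interface_left z interval of the cytoplasm-side interface
#'   (default c(15, 30) A).
#' @return object of class `pmf_landmarks`: list with `min_right`, `max`,
#'   `min_left` (each `c(z, G)`), `dG_right`, `dG_left`.
#' @export
extract_landmarks <- function(pmf, interface_right = c(50, 65),
                              core = c(30, 50), interface_left = c(15, 30)) {
  prof <- if (inherits(pmf, "pmf_fit")) pmf$profile else pmf
  if (!inherits(prof, "zprofile")) stop("pmf must be a pmf_fit or zprofile")
  pick <- function(region, what) {
    sel <- prof$z >= region[1] & prof$z <= region[2]
    if (!any(sel)) {
      stop(sprintf("region [%g, %g] lies outside the profile support",
                   region[1], region[2]))
    }
    z <- prof$z[sel]; G <- prof$values[sel]
    target <- if (what == "min") min(G) else max(G)
    cand <- which(G == target)
    best <- cand[which.min(abs(z[cand] - mean(region)))]
    c(z = z[best], G = G[best])
  }
  mr <- pick(interface_right, "min")
  mx <- pick(core, "max")
  ml <- pick(interface_left, "min")
  structure(
    list(min_right = mr, max = mx, min_left = ml,
         dG_right = unname(mx["G"] - mr["G"]),
         dG_left = unname(mx["G"] - ml["G"])),
    class = "pmf_landmarks"
  )
}

#' @export
print.pmf_landmarks <- function(x, ...) {
  cat("PMF landmarks (kcal/mol, positions in A):\n")
  cat(sprintf("  Min_right %6.2f (%5.1f A)   Max %6.2f (%5.1f A)   Min_left %6.2f (%5.1f A)\n",
              x$min_right["G"], x$min_right["z"], x$max["G"], x$max["z"],
              x$min_left["G"], x$min_left["z"]))
  cat(sprintf("  dG_right %6.2f   dG_left %6.2f\n", x$dG_right, x$dG_left))
  invisible(x)
}

#' @export
as.data.frame.pmf_landmarks <- function(x, ...) {
  data.frame(min_right_G = x$min_right["G"], min_right_z = x$min_right["z"],
             max_G = x$max["G"], max_z = x$max["z"],
             min_left_G = x$min_left["G"], min_left_z = x$min_left["z"],
             dG_right = x$dG_right, dG_left = x$dG_left, row.names = NULL)
}
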