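#' Profile along the membrane normal
#'
#' Light container for any quantity sampled on a strictly increasing z grid:
#' free energy, diffusivity, resistance, densities, hydration counts.
#'
#' @param z numeric, strictly increasing grid (Angstrom).
#' @param values numeric, same length as `z`; no NaN permitted.
#' @param stderr optional per-point standard error (same unit as `values`).
#' @param unit character unit label carried through to reports.
#' @return object of class `zprofile`.
#' @export
zprofile <- function(z, values, stderr = NULL, unit = "") {
  z <- as.numeric(z); values <- as.numeric(values)
  if (length(z) != length(values)) stop("z and values must have equal length")
  if (length(z) == 0L) stop("empty profile")
  if (any(diff(z) <= 0)) stop("z grid must be strictly increasing")
  if (any(is.nan(values))) stop("values must not contain NaN")
  if (!is.null(stderr)) {
    stderr <- as.numeric(stderr)
    if (length(stderr) != length(z)) stop("stderr length mismatch")
    if (any(stderr < 0, na.rm = TRUE)) stop("stderr must be >= 0")
  }
  structure(list(z = z, values = values, stderr = stderr, unit = unit),
            class = "zprofile")
}

#' @export
print.zprofile <- function(x, ...) {
  cat(sprintf("z-profile (%s): %d points on [%.2f, %.2f] A, range [%.4g, %.4g]\n",
              if (nzchar(x$unit)) x$unit else "unitless", length(x$z),
              min(x$z), max(x$z), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.zprofile <- function(x, ...) {
  d <- data.frame(z_angstrom = x$z, value = x$values)
  if (!is.null(x$stderr)) d$stderr <- x$stderr
  d
}

#' @export
plot.zprofile <- function(x, ..., xlab = "z (Å)", ylab = x$unit, type = "l") {
  graphics::plot(x$z, x$values, type = type, xlab = xlab, ylab = ylab, ...)
  if (!is.null(x$stderr)) {
    graphics::polygon(c(x$z, rev(x$z)),
                      c(x$values + x$stderr, rev(x$values - x$stderr)),
                      border = NA, col = grDevices::adjustcolor("steelblue", 0.3))
    graphics::lines(x$z, x$values)
  }
  invisible(x)
}

# Linear interpolation with constant extrapolation beyond the grid ends.
.profile_interp <- function(profile, z_new) {
  stats::approx(profile$z, profile$values, xout = z_new, rule = 2)$y
}

#' Write a profile as CSV
#'
#' Columns are `z_angstrom`, the quantity named by `value_name`, and
#' optionally `stderr`.
#'
#' @param profile a [zprofile].
#' @param path output file path.
#' @param value_name column name for the values (defaults to the unit-tagged
#'   name `value`).
#' @export
write_profile_csv <- function(profile, path, value_name = "value") {
  d <- as.data.frame(profile)
  names(d)[2] <- value_name
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

# Trapezoidal integral on a (possibly non-uniform) grid.
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# log(sum(exp(x))) without overflow.
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
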