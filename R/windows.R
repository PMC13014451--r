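#' Umbrella-window trajectory
#'
#' One umbrella-sampling window: the permeant's z(t) series together with the
#' harmonic bias that restrained it, U(z) = k/2 (z - z0)^2. A leading
#' fraction of the series may be discarded as equilibration; the object
#' stores the retained samples only.
#'
#' @param bias_center bias center z0 (Angstrom).
#' @param spring_k harmonic spring constant (kcal mol-1 A-2).
#' @param times sampling times (ps), strictly increasing, uniform step.
#' @param z_values sampled z coordinates (Angstrom), same length as `times`.
#' @param equilibrated_fraction fraction of leading samples discarded as
#'   equilibration (default 0; manifest reading applies the configured value,
#'   conventionally 0.5 — the final half of each production window).
#' @param window_id optional identifier used in messages and manifests.
#' @return object of class `window_trajectory` with fields `bias_center`,
#'   `spring_k`, `times`, `z_values`, `n_samples`, `dt`,
#'   `equilibrated_fraction`, `window_id`.
#' @export
window_trajectory <- function(bias_center, spring_k, times, z_values,
                              equilibrated_fraction = 0, window_id = NA) {
  times <- as.numeric(times); z_values <- as.numeric(z_values)
  if (length(times) != length(z_values)) {
    stop("times and z_values must have equal length (window ", window_id, ")")
  }
  if (length(times) < 2L) stop("window series needs at least 2 samples")
  dts <- diff(times)
  if (any(dts <= 0)) stop("times must be strictly increasing (window ", window_id, ")")
  dt <- dts[1]
  if (max(abs(dts - dt)) > 1e-9 * dt) {
    stop("time step must be uniform within 1e-9 relative (window ", window_id, ")")
  }
  if (equilibrated_fraction < 0 || equilibrated_fraction >= 1) {
    stop("equilibrated_fraction must be in [0, 1)")
  }
  n_drop <- floor(equilibrated_fraction * length(times))
  keep <- if (n_drop > 0L) -seq_len(n_drop) else seq_along(times)
  times <- times[keep]; z_values <- z_values[keep]
  if (!all(is.finite(z_values))) stop("z_values must be finite")
  structure(
    list(bias_center = bias_center, spring_k = spring_k,
         times = times, z_values = z_values, n_samples = length(z_values),
         dt = dt, equilibrated_fraction = equilibrated_fraction,
         window_id = window_id),
    class = "window_trajectory"
  )
}

#' @export
print.window_trajectory <- function(x, ...) {
  cat(sprintf(
    "Umbrella window %s: z0 = %g A, k = %g kcal/mol/A^2, %d samples, dt = %g ps\n",
    if (is.na(x$window_id)) "" else x$window_id,
    x$bias_center, x$spring_k, x$n_samples, x$dt))
  invisible(x)
}

#' Read an umbrella-window manifest
#'
#' The manifest is tab- or whitespace-separated text with a header row and
#' columns `window_id`, `bias_center`, `spring_k`, `series_path`. Each series
#' file holds two whitespace-separated columns, time (ps) and z (Angstrom);
#' `#` comment lines are skipped. Series paths are resolved relative to the
#' manifest's directory.
#'
#' @param path manifest file path.
#' @param equilibrated_fraction leading fraction of each series discarded as
#'   equilibration (default 0.5: the final half of each window is kept).
#' @param min_samples minimum number of retained samples per window below
#'   which reading aborts (default 100).
#' @return list of [window_trajectory] objects, in manifest order.
#' @export
read_window_manifest <- function(path, equilibrated_fraction = 0.5,
                                 min_samples = 100) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("window_id", "bias_center", "spring_k", "series_path")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  base <- dirname(path)
  lapply(seq_len(nrow(man)), function(i) {
    sp <- man$series_path[i]
    if (!file.path_is_absolute(sp)) sp <- file.path(base, sp)
    if (!file.exists(sp)) {
      stop("series file missing for window ", man$window_id[i], ": ", sp)
    }
    ser <- utils::read.table(sp, header = FALSE, comment.char = "#",
                             col.names = c("time_ps", "z_angstrom"))
    if (nrow(ser) == 0L) stop("empty series for window ", man$window_id[i])
    w <- window_trajectory(as.numeric(man$bias_center[i]),
                           as.numeric(man$spring_k[i]),
                           ser$time_ps, ser$z_angstrom,
                           equilibrated_fraction = equilibrated_fraction,
                           window_id = man$window_id[i])
    if (w$n_samples < min_samples) {
      stop("too few samples retained in window ", man$window_id[i],
           " (", w$n_samples, " < ", min_samples, ")")
    }
    w
  })
}

file.path_is_absolute <- function(p) grepl("^(/|[A-Za-z]:)", p)

#' Write a set of umbrella windows to disk
#'
#' Writes one two-column series file per window plus a manifest referencing
#' them, in the format [read_window_manifest] expects. Times and coordinates
#' are written with full double precision (17 significant digits) so a
#' write/read round trip is value-faithful.
#'
#' @param windows list of [window_trajectory] objects.
#' @param dir output directory (created if needed).
#' @param manifest_name manifest file name within `dir`.
#' @return path to the manifest, invisibly.
#' @export
write_window_set <- function(windows, dir, manifest_name = "windows.tsv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    id <- if (is.na(w$window_id)) sprintf("w%03d", i) else as.character(w$window_id)
    series <- sprintf("%s.dat", id)
    con <- file(file.path(dir, series), "w")
    writeLines(sprintf("# umbrella window %s: z0=%.17g k=%.17g", id,
                       w$bias_center, w$spring_k), con)
    writeLines(sprintf("%.17g %.17g", w$times, w$z_values), con)
    close(con)
    data.frame(window_id = id, bias_center = w$bias_center,
               spring_k = w$spring_k, series_path = series,
               stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  manifest <- file.path(dir, manifest_name)
  utils::write.table(man, manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
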