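#' Default run configuration
#'
#' Returns the full configuration list with documented defaults; a YAML file
#' read by [read_run_config()] overrides any subset of these fields.
#'
#' Fields: `temperature` (K), `manifest` (window manifest path), `frames`
#' (frame file path(s)), `equilibrated_fraction`, `bin_width` (A),
#' `wham_tolerance` (kcal/mol on the window shift constants), `max_iter`,
#' `bootstrap_replicates`, `block_length` (samples), `seed`, `z_in`/`z_out`
#' (A, integration bounds), `hydration_cutoff` (A), `contact_cutoff` (A),
#' `hbond_dmax` (A), `hbond_angle_min` (degrees), `out_dir`.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    temperature = 310,
    manifest = NULL,
    frames = NULL,
    equilibrated_fraction = 0.5,
    bin_width = 0.2,
    wham_tolerance = 1e-7,
    max_iter = 1e5,
    bootstrap_replicates = 50,
    block_length = 200,
    seed = 1,
    z_in = 18,
    z_out = 62,
    hydration_cutoff = 3.0,
    contact_cutoff = 7.0,
    hbond_dmax = 3.5,
    hbond_angle_min = 135,
    out_dir = "."
  )
}

#' Read a YAML run configuration
#'
#' Unknown keys abort with a message naming them; missing keys take the
#' [default_config()] values. Validates `z_in < z_out` and positive cutoffs.
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!is.numeric(cfg$z_in) || !is.numeric(cfg$z_out) || cfg$z_in >= cfg$z_out) {
    stop("config requires z_in < z_out")
  }
  for (f in c("hydration_cutoff", "contact_cutoff", "hbond_dmax", "bin_width")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) stop("config field ", f, " must be > 0")
  }
  if (cfg$temperature <= 0) stop("temperature must be positive")
  cfg
}
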