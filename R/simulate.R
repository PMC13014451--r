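# Biased 1-D Brownian dynamics. The generator's defining contract is the
# overdamped Ito Euler-Maruyama update
#   z <- z + [-beta D(z) (G'(z) + U'_bias(z)) + D'(z)] dt + sqrt(2 D(z) dt) xi
# with reflecting boundaries at the domain edges; the D'(z) spurious-drift
# term is required for the correct stationary density when D varies with z.

.derive_seed <- function(seed, i) {
  # distinct, reproducible 31-bit streams per window
  (as.numeric(seed) * 2654435761 + i * 97561) %% 2147483647
}

.check_stability <- function(ls, thermo, spring_k, dt) {
  zg <- seq(ls$domain[1], ls$domain[2], length.out = 2001)
  sigma <- sqrt(thermo$kT / max(spring_k, 1e-12))
  fmax <- max(abs(landscape_dG(ls, zg))) +
    if (spring_k > 0) spring_k * 4 * sigma else 0
  step <- thermo$beta * max(landscape_D(ls, zg)) * fmax * dt
  if (step >= 0.1) {
    stop(sprintf(
      "unstable integration: beta*D*max|force|*dt = %.3g A >= 0.1 A; reduce dt", step))
  }
  invisible(step)
}

#' Simulate one umbrella window by overdamped Langevin dynamics
#'
#' Runs biased Brownian dynamics on a [landscape] with harmonic bias
#' U = k/2 (z - z0)^2 and returns the stride-thinned series as a
#' [window_trajectory]. Deterministic for a fixed seed. The integrator is
#' the Ito Euler-Maruyama scheme with the D'(z) drift correction and
#' reflecting boundaries; a stability precondition
#' beta * D * max|force| * dt < 0.1 A is checked before running.
#'
#' @param ls a [landscape].
#' @param bias_center harmonic bias center z0 (A).
#' @param spring_k spring constant (kcal mol-1 A-2); 0 for unbiased runs.
#' @param thermo a [thermo_state] or temperature in K.
#' @param n_steps number of integration steps (default 2e6, giving 2e5
#'   retained samples at the default stride).
#' @param dt time step (ps, default 0.01).
#' @param sample_stride keep every `sample_stride`-th step (default 10).
#' @param seed RNG seed (required; integer below 2^31).
#' @param z_init starting position; defaults to the minimum of
#'   G(z) + U_bias(z) located on a fine grid, so the window starts in its
#'   own basin and needs no further equilibration discard.
#' @param window_id optional identifier.
#' @return a [window_trajectory] with `equilibrated_fraction = 0`.
#' @export
simulate_window <- function(ls, bias_center, spring_k, thermo = thermo_state(),
                            n_steps = 2e6, dt = 0.01, sample_stride = 10,
                            seed, z_init = NULL, window_id = NA) {
  thermo <- .as_thermo(thermo)
  stopifnot(inherits(ls, "landscape"), n_steps >= sample_stride)
  .check_stability(ls, thermo, spring_k, dt)
  if (is.null(z_init)) {
    zg <- seq(ls$domain[1], ls$domain[2], length.out = 4001)
    utot <- landscape_G(ls, zg) + 0.5 * spring_k * (zg - bias_center)^2
    z_init <- zg[which.min(utot)]
  }
  z <- cpp_simulate_window(unclass(ls), z_init, bias_center, spring_k,
                           thermo$beta, as.integer(n_steps), dt,
                           as.integer(sample_stride),
                           ls$domain[1], ls$domain[2], as.numeric(seed))
  times <- seq_along(z) * dt * sample_stride
  window_trajectory(bias_center, spring_k, times, z,
                    equilibrated_fraction = 0, window_id = window_id)
}

#' Constant-velocity pull schedule
#'
#' @param start,end pull endpoints (A).
#' @param velocity pull speed (A/ns, > 0; default 0.972).
#' @param spring_k spring constant (kcal mol-1 A-2, default 2.5).
#' @param spacing snapshot spacing along the pull (A, default 1).
#' @return object of class `pull_schedule`.
#' @export
pull_schedule <- function(start = 70, end = 0, velocity = 0.972,
                          spring_k = 2.5, spacing = 1) {
  if (velocity <= 0) stop("velocity must be > 0")
  if (spacing <= 0) stop("spacing must be > 0")
  structure(list(start = start, end = end, velocity = velocity,
                 spring_k = spring_k, spacing = spacing),
            class = "pull_schedule")
}

#' Seed umbrella windows from a steered pull
#'
#' Simulates a single steered pass with a moving harmonic center
#' z0(t) = start + v t and records the instantaneous particle position each
#' time the center crosses a grid point spaced by `spacing`, mimicking
#' window extraction from a constant-velocity steered trajectory.
#'
#' @param ls a [landscape].
#' @param schedule a [pull_schedule].
#' @param thermo a [thermo_state] or temperature (K).
#' @param dt integration step (ps).
#' @param seed RNG seed.
#' @return data.frame with columns `bias_center` and `start_z`, one row per
#'   seed (`floor(|end - start| / spacing) + 1` rows).
#' @export
seed_windows <- function(ls, schedule, thermo = thermo_state(), dt = 0.01,
                         seed) {
  thermo <- .as_thermo(thermo)
  stopifnot(inherits(schedule, "pull_schedule"))
  if (schedule$start == schedule$end) {
    return(data.frame(bias_center = schedule$start, start_z = schedule$start))
  }
  .check_stability(ls, thermo, schedule$spring_k, dt)
  v_ps <- schedule$velocity / 1000  # A/ns -> A/ps
  res <- cpp_steered_pull(unclass(ls), schedule$start, schedule$end, v_ps,
                          schedule$spring_k, schedule$spacing, thermo$beta,
                          dt, as.numeric(seed))
  data.frame(bias_center = res$bias_center, start_z = res$start_z)
}

#' Generate a full synthetic umbrella-window set
#'
#' Convenience wrapper: one [simulate_window] per bias center with seeds
#' derived deterministically from `seed`.
#'
#' @param ls a [landscape].
#' @param centers bias centers (default 0..70 A in 1 A steps, 71 windows).
#' @param spring_k spring constant (default 2.5 kcal mol-1 A-2).
#' @param thermo a [thermo_state] or temperature in K (default 310 K).
#' @param seed master seed.
#' @inheritParams simulate_window
#' @return list of [window_trajectory] objects.
#' @export
simulate_window_set <- function(ls, centers = 0:70, spring_k = 2.5,
                                thermo = thermo_state(310), n_steps = 2e6,
                                dt = 0.01, sample_stride = 10, seed = 1) {
  lapply(seq_along(centers), function(i) {
    simulate_window(ls, centers[i], spring_k, thermo, n_steps, dt,
                    sample_stride, seed = .derive_seed(seed, i),
                    window_id = sprintf("w%03d", i))
  })
}

#' Generate labeled toy membrane frames
#'
#' Places pseudo-atoms with known geometry for exercising the structural
#' analyses: tail (OL) and cholesterol (CHL) particles uniformly in the
#' hydrophobic band |z - 40| < 17 A, headgroup particles (PC/PE/PS/PG) in
#' two interfacial shells around z = 57 and 23 A, water oxygens uniformly
#' outside the band, and a single drug (DRG) particle at `drug_z`.
#'
#' @param n_frames number of frames.
#' @param n_water water molecules (one O pseudo-atom each).
#' @param slab_spec list with `lx`, `ly` lateral box lengths (A), `z_range`
#'   full z extent, `n_tail`, `n_chl`, `n_head` particle counts.
#' @param drug_z z position of the DRG particle (A).
#' @param seed RNG seed.
#' @return list of [mem_frame] objects with a box attribute.
#' @export
generate_toy_frames <- function(n_frames = 10, n_water = 200,
                                slab_spec = list(lx = 40, ly = 40,
                                                 z_range = c(0, 75),
                                                 n_tail = 120, n_chl = 40,
                                                 n_head = 60),
                                drug_z = 40, seed = 1) {
  set.seed(seed)
  lx <- slab_spec$lx; ly <- slab_spec$ly
  zr <- slab_spec$z_range
  box <- c(lx, ly, diff(zr))
  head_labels <- c("PC", "PE", "PS", "PG")
  # fixed composition across frames: the same pseudo-atoms are tracked from
  # frame to frame, only their positions are resampled
  n_head_half <- ceiling(slab_spec$n_head / 2)
  n_top <- if (n_water > 0) {
    rbinom(1, n_water, (zr[2] - 57) / ((zr[2] - 57) + (23 - zr[1])))
  } else 0
  spec <- rbind(
    data.frame(element = "C", label = rep("OL", slab_spec$n_tail),
               zlo = 23, zhi = 57),
    data.frame(element = "C", label = rep("CHL", slab_spec$n_chl),
               zlo = 23, zhi = 57),
    data.frame(element = "P",
               label = sample(head_labels, n_head_half, replace = TRUE),
               zlo = 55, zhi = 59),
    data.frame(element = "P",
               label = sample(head_labels, n_head_half, replace = TRUE),
               zlo = 21, zhi = 25),
    if (n_top > 0) data.frame(element = "O", label = rep("WAT", n_top),
                              zlo = 57, zhi = zr[2]),
    if (n_water - n_top > 0) data.frame(element = "O",
                                        label = rep("WAT", n_water - n_top),
                                        zlo = zr[1], zhi = 23)
  )
  spec$element[spec$label %in% c("PE", "PS")] <- "N"
  lapply(seq_len(n_frames), function(f) {
    n <- nrow(spec)
    mem_frame(c(spec$element, "Pt"), c(spec$label, "DRG"),
              c(runif(n, 0, lx), lx / 2), c(runif(n, 0, ly), ly / 2),
              c(runif(n, spec$zlo, spec$zhi), drug_z), box = box)
  })
}
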