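# Independent brute-force oracles and fixture builders shared by the suite.
# Oracles are deliberately written as plain double loops / direct sums so
# they share no code path with the package implementations they check.

TH310 <- thermo_state(310)

flat_landscape <- function(D_base = 0.1, domain = c(-20, 20)) {
  landscape(G_terms = data.frame(center = 0, height = 0, width = 1),
            D_base = D_base, domain = domain)
}

# Two-window fixture drawn exactly (inverse-CDF on stratified uniforms, then
# shuffled) from the biased Boltzmann densities of a harmonic free energy
# G = kg/2 (z - c0)^2 under bias k/2 (z - z0)^2: the biased density is the
# Gaussian N(mu, kT/(kg + k)) with mu = (kg c0 + k z0)/(kg + k).
exact_harmonic_windows <- function(centers, kg = 0.2, c0 = 5, k = 2.5,
                                   n = 5e4, kT = TH310$kT, shuffle_seed = 71) {
  set.seed(shuffle_seed)
  lapply(centers, function(z0) {
    ktot <- kg + k
    mu <- (kg * c0 + k * z0) / ktot
    u <- sample((seq_len(n) - 0.5) / n)
    window_trajectory(z0, k, seq_len(n) * 0.1, qnorm(u, mu, sqrt(kT / ktot)))
  })
}

# direct Boltzmann-inversion oracle for the harmonic G above
harmonic_G <- function(z, kg = 0.2, c0 = 5) 0.5 * kg * (z - c0)^2

rmsd_to <- function(a, b) sqrt(mean((a - b)^2))

# RMSD between two free-energy profiles after removing the additive gauge
rmsd_free_shift <- function(a, b) {
  d <- a - b
  sqrt(mean((d - mean(d))^2))
}

# O(N^2) contact oracle: counts probe-partner pairs within cutoff per label
brute_contacts <- function(frame, probe_label, cutoff) {
  p <- which(frame$label == probe_label)
  o <- which(frame$label != probe_label)
  hits <- list()
  for (i in p) for (j in o) {
    d <- sqrt((frame$x[i] - frame$x[j])^2 + (frame$y[i] - frame$y[j])^2 +
              (frame$z[i] - frame$z[j])^2)
    if (d <= cutoff) {
      hits[[length(hits) + 1L]] <- data.frame(i = i, j = j,
                                              label = frame$label[j], d = d)
    }
  }
  if (!length(hits)) return(data.frame(i = integer(), j = integer(),
                                       label = character(), d = numeric()))
  do.call(rbind, hits)
}

# direct lag-by-lag biased autocorrelation
brute_acf <- function(z, n_lag) {
  dz <- z - mean(z)
  n <- length(z)
  vapply(0:n_lag, function(t) sum(dz[1:(n - t)] * dz[(1 + t):n]) / n, 0)
}

# direct double-loop Coulomb sum
brute_coulomb <- function(frame, eps = 1) {
  e <- 0
  n <- nrow(frame)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- sqrt((frame$x[i] - frame$x[j])^2 + (frame$y[i] - frame$y[j])^2 +
              (frame$z[i] - frame$z[j])^2)
    e <- e + 332.0637 * frame$charge[i] * frame$charge[j] / (eps * r)
  }
  e
}

# direct double-loop Lennard-Jones sum with Lorentz-Berthelot combining
brute_lj <- function(frame, sig, eps) {
  e <- 0
  n <- nrow(frame)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- sqrt((frame$x[i] - frame$x[j])^2 + (frame$y[i] - frame$y[j])^2 +
              (frame$z[i] - frame$z[j])^2)
    s <- (sig[i] + sig[j]) / 2
    e <- e + 4 * sqrt(eps[i] * eps[j]) * ((s / r)^12 - (s / r)^6)
  }
  e
}

# random charged LJ cluster for the energetics oracles
random_cluster <- function(n, seed, spread = 6) {
  set.seed(seed)
  mem_frame(element = rep("C", n), label = rep("DRG", n),
            x = runif(n, 0, spread), y = runif(n, 0, spread),
            z = runif(n, 0, spread),
            charge = round(runif(n, -0.5, 0.5), 3))
}

# rigid-body rotation of a frame about its centroid
rotate_frame <- function(frame, angles = c(0.3, 0.7, 1.1), shift = c(5, -3, 2)) {
  rot1 <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  rot2 <- function(a) rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  R <- rot1(angles[1]) %*% rot2(angles[2]) %*% rot1(angles[3])
  co <- cbind(frame$x, frame$y, frame$z)
  ctr <- colMeans(co)
  co2 <- sweep(sweep(co, 2, ctr) %*% t(R), 2, ctr + shift, `+`)
  out <- frame
  out$x <- co2[, 1]; out$y <- co2[, 2]; out$z <- co2[, 3]
  attr(out, "box") <- NULL
  out
}
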