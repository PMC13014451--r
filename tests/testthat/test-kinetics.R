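test_that("autocorrelation matches the direct lag-by-lag sum and white-noise limits", {
  set.seed(51)
  z <- rnorm(5000, sd = 2)
  ac <- autocorrelation(z, dt = 0.1, max_lag = 5)
  expect_equal(ac$C_zz, brute_acf(z, 50), tolerance = 1e-10)
  expect_equal(ac$C_zz[1], ac$variance)
  # white noise: C(0) = sigma^2, later lags at the sqrt(n) noise floor
  zz <- rnorm(1e5, sd = 1.5)
  aw <- autocorrelation(zz, dt = 1, max_lag = 100)
  expect_equal(aw$variance, 1.5^2, tolerance = 0.03)
  expect_lt(quantile(abs(aw$C_zz[-1]), 0.95), 3 * 1.5^2 / sqrt(1e5))
  # constant series: zero variance, zero function
  a0 <- autocorrelation(rep(3, 1000), dt = 1, max_lag = 10)
  expect_equal(a0$variance, 0)
  expect_true(all(a0$C_zz == 0))
  expect_error(autocorrelation(rnorm(100), dt = 1, max_lag = 200), "span")
})

test_that("autocorrelation of a discrete OU process recovers its timescale", {
  # z_{t+1} = a z_t + noise with a = exp(-dt/tau)
  tau <- 2; dt <- 0.1; n <- 2e5
  a <- exp(-dt / tau)
  set.seed(52)
  innov <- rnorm(n, sd = sqrt(1 - a^2))
  z <- stats::filter(innov, a, method = "recursive")
  ac <- autocorrelation(as.numeric(z), dt, max_lag = 50)
  # fit the exponential decay over the first two timescales
  sel <- ac$lags <= 2 * tau & ac$C_zz > 0
  fit <- lm(log(ac$C_zz[sel]) ~ ac$lags[sel])
  expect_equal(-1 / coef(fit)[[2]], tau, tolerance = 0.05)
})

test_that("restrained-window diffusivity recovers the true D of OU windows", {
  ls1 <- flat_landscape(D_base = 0.1)
  D1 <- vapply(1:6, function(s) {
    w <- simulate_window(ls1, 0, 2.5, TH310, n_steps = 2e6, seed = 60 + s)
    window_diffusivity(w)$D
  }, 0)
  expect_equal(mean(D1), 0.1, tolerance = 0.10)
  # variance itself matches equipartition on average
  ls2 <- flat_landscape(D_base = 0.02)
  D2 <- vapply(1:6, function(s) {
    w <- simulate_window(ls2, 0, 2.5, TH310, n_steps = 2e6, seed = 80 + s)
    window_diffusivity(w)$D
  }, 0)
  expect_equal(mean(D2), 0.02, tolerance = 0.10)
  # constant series is flagged unusable
  wc <- window_trajectory(0, 2.5, 1:1000, rep(1, 1000))
  expect_warning(d <- window_diffusivity(wc), "variance")
  expect_false(d$usable)
})

test_that("diffusivity profile is flat for constant D and dips where D dips", {
  ls <- flat_landscape(D_base = 0.1, domain = c(-25, 25))
  wins <- lapply(seq(-9, 9, by = 3), function(z0) {
    simulate_window(ls, z0, 2.5, TH310, n_steps = 6e6,
                    seed = 700 + z0, window_id = z0)
  })
  dp <- diffusivity_profile(wins)
  expect_equal(nrow(dp$records), 7)
  expect_true(all(abs(dp$records$D_A2_ps - 0.1) / 0.1 < 0.15))
  expect_lt(max(abs(dp$records$D_A2_ps - mean(dp$records$D_A2_ps))) /
            mean(dp$records$D_A2_ps), 0.10)
  # halved D in a core band shows up at the matching window
  lsd <- landscape(G_terms = data.frame(center = 0, height = 0, width = 1),
                   D_base = 0.1,
                   D_terms = data.frame(center = 0, height = -0.5, width = 2),
                   domain = c(-25, 25))
  wd <- lapply(c(-12, 0, 12), function(z0) {
    simulate_window(lsd, z0, 2.5, TH310, n_steps = 2e6, seed = 800 + z0)
  })
  dpd <- diffusivity_profile(wd)
  r <- dpd$records
  ratio <- r$D_A2_ps[r$bias_center == 0] /
    mean(r$D_A2_ps[r$bias_center != 0])
  expect_equal(ratio, 0.5, tolerance = 0.15)
  expect_error(diffusivity_profile(wins[1]), "fewer than 2")
})

test_that("permeability closed forms: flat profile and square barrier", {
  # G = 0, D = D0 across width L: P = D0/L (trapezoid exact for a constant)
  pmf <- zprofile(c(0, 35), c(0, 0), unit = "kcal/mol")
  p <- permeability(pmf, 0.1, TH310, 0, 35)  # 0.1 A^2/ps = 1e-5 cm^2/s
  expect_equal(p$P, 1e-5 / 35e-8, tolerance = 1e-12)
  # square barrier dG over width w in total width L:
  # P = D0 / ((L - w) + w exp(beta dG))
  z <- seq(0, 35, by = 0.001)
  dG <- 5
  G <- ifelse(z >= 10 & z <= 20, dG, 0)
  p2 <- permeability(zprofile(z, G), 0.1, TH310, 0, 35, grid_spacing = 0.001)
  closed <- 1e-5 / (25e-8 + 10e-8 * exp(TH310$beta * dG))
  expect_equal(p2$P, closed, tolerance = 0.01)
  expect_error(permeability(pmf, -1, TH310, 0, 35), "positive")
})

test_that("permeability identities: reciprocity, monotonicity, D scaling, grid", {
  z <- seq(0, 44, by = 0.05)
  mkG <- function(h) zprofile(z, h * exp(-(z - 22)^2 / 18), unit = "kcal/mol")
  p1 <- permeability(mkG(8), 0.1, TH310, 0, 44)
  expect_equal(p1$P * p1$R_eff, 1, tolerance = 1e-12)
  # raising the barrier strictly decreases P
  p2 <- permeability(mkG(10), 0.1, TH310, 0, 44)
  expect_lt(p2$P, p1$P)
  # scaling D by c scales P by c exactly
  p3 <- permeability(mkG(8), 0.2, TH310, 0, 44)
  expect_equal(p3$P / p1$P, 2, tolerance = 1e-12)
  # halving the grid changes log10 P negligibly
  p4 <- permeability(mkG(8), 0.1, TH310, 0, 44, grid_spacing = 0.025)
  expect_lt(abs(log10(p4$P) - log10(p1$P)), 0.01)
  # a large barrier is handled in log space without overflow
  p5 <- permeability(mkG(400), 0.1, TH310, 0, 44)
  expect_true(is.finite(log(p5$R_eff)) || p5$P == 0)
  expect_gt(p5$R_eff, 0)
})

test_that("full permeation fit chains PMF, D(z) and P coherently", {
  ls <- flat_landscape(D_base = 0.1, domain = c(-25, 25))
  wins <- lapply(seq(-10, 10, by = 2), function(z0) {
    simulate_window(ls, z0, 2.5, TH310, n_steps = 1e6, seed = 900 + z0)
  })
  fit <- permeation(wins, TH310, z_in = -8, z_out = 8,
                    reference_region = c(-2, 2))
  # flat landscape: P approaches D0/L; residual deviation reflects the
  # exp(beta G) amplification of PMF noise at this sampling depth
  expect_lt(abs(log(fit$permeability$P / (1e-5 / 16e-8))), log(1.5))
  expect_equal(fit$permeability$P * fit$permeability$R_eff, 1,
               tolerance = 1e-12)
  expect_s3_class(fit$pmf, "pmf_fit")
  expect_output(print(fit), "Permeability")
})
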