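test_that("Coulomb energy matches its definition and the pairwise oracle", {
  pair <- mem_frame(c("Na", "Cl"), c("ION", "ION"), c(0, 1), c(0, 0), c(0, 0),
                    charge = c(1, -1))
  expect_equal(coulomb_energy(pair), -332.0637)
  lone <- mem_frame("Na", "ION", 0, 0, 0, charge = 1)
  expect_equal(coulomb_energy(lone), 0)
  cl <- random_cluster(10, seed = 81)
  expect_equal(coulomb_energy(cl), brute_coulomb(cl), tolerance = 1e-10)
  expect_equal(coulomb_energy(cl, dielectric_in = 4),
               brute_coulomb(cl, eps = 4), tolerance = 1e-10)
  co <- pair; co$x <- c(0, 0)
  expect_error(coulomb_energy(co), "coincident")
})

test_that("Lennard-Jones energy has the right minimum, zero and oracle", {
  pair <- function(r) mem_frame(c("C", "C"), c("OL", "OL"), c(0, r),
                                c(0, 0), c(0, 0))
  sig <- c(3.4, 3.4); eps <- c(0.1, 0.1)
  expect_equal(lj_energy(pair(2^(1 / 6) * 3.4), sig, eps), -0.1,
               tolerance = 1e-12)
  expect_equal(lj_energy(pair(3.4), sig, eps), 0, tolerance = 1e-12)
  cl <- random_cluster(10, seed = 82)
  s <- runif(10, 2, 4); e <- runif(10, 0.05, 0.3)
  expect_equal(lj_energy(cl, s, e), brute_lj(cl, s, e), tolerance = 1e-10)
})

test_that("generalized Born reduces to the Born ion and screened Coulomb limits", {
  ion <- mem_frame("Na", "ION", 0, 0, 0, charge = 1)
  born <- -0.5 * (1 - 1 / 80) * 332.0637 / 2
  expect_equal(gb_energy(ion, 2, 1, 80), born, tolerance = 1e-9)
  # zero charge, zero energy
  neutral <- mem_frame(c("C", "C"), c("OL", "OL"), c(0, 3), c(0, 0), c(0, 0),
                       charge = c(0, 0))
  expect_equal(gb_energy(neutral, c(2, 2)), 0)
  # no dielectric contrast, exactly zero
  cl <- random_cluster(8, seed = 83)
  expect_equal(gb_energy(cl, rep(1.7, 8), eps_in = 5, eps_out = 5), 0)
  # long range: the cross term tends to the screened Coulomb interaction
  r <- 100  # = 50 * max Born radius
  pair <- mem_frame(c("Na", "Cl"), c("ION", "ION"), c(0, r), c(0, 0), c(0, 0),
                    charge = c(0.7, -0.4))
  a <- mem_frame("Na", "ION", 0, 0, 0, charge = 0.7)
  b <- mem_frame("Cl", "ION", 0, 0, 0, charge = -0.4)
  cross <- gb_energy(pair, c(2, 2)) - gb_energy(a, 2) - gb_energy(b, 2)
  screened <- -332.0637 * (1 - 1 / 80) * 0.7 * (-0.4) / r
  expect_equal(cross, screened, tolerance = 0.01)
  expect_error(gb_energy(ion, -1), "positive")
})

test_that("Shrake-Rupley surface area matches sphere geometry", {
  lone <- mem_frame("O", "WAT", 0, 0, 0)
  s <- sasa(lone, 1.6)
  expect_equal(s$total, 4 * pi * 3^2, tolerance = 0.005)
  # two distant spheres are independent
  two <- mem_frame(c("O", "O"), c("WAT", "WAT"), c(0, 100), c(0, 0), c(0, 0))
  s2 <- sasa(two, c(1.6, 1.2))
  expect_equal(s2$total, 4 * pi * (3^2 + 2.6^2), tolerance = 0.005)
  # a small atom fully inside a large one is buried
  nested <- mem_frame(c("C", "O"), c("OL", "WAT"), c(0, 0.2), c(0, 0), c(0, 0))
  s3 <- sasa(nested, c(5, 0.5))
  expect_equal(s3$per_atom[2], 0)
  # total area never grows as atoms approach
  sep <- c(6, 4, 3, 2, 1)
  areas <- vapply(sep, function(d) {
    sasa(mem_frame(c("C", "C"), c("OL", "OL"), c(0, d), c(0, 0), c(0, 0)),
         c(1.7, 1.7))$total
  }, 0)
  expect_true(all(diff(areas) <= 1e-9))
  expect_error(sasa(lone, 1.6, n_sphere_points = 5), ">= 10")
})

test_that("decomposition identities hold and limits vanish", {
  set.seed(84)
  for (i in 1:5) {
    mk <- function() {
      structure(list(E_int = 0, E_ele = rnorm(1, 0, 50),
                     E_vdW = rnorm(1, 0, 20), G_GB = rnorm(1, 0, 50),
                     G_SA = rnorm(1, 0, 5)), class = "energy_components")
    }
    d <- mmgbsa_decompose(mk(), mk(), mk())
    expect_equal(d$dE_MM, d$dE_int + d$dE_ele + d$dE_vdW, tolerance = 1e-9)
    expect_equal(d$dG_sol, d$dG_GB + d$dG_SA, tolerance = 1e-9)
    expect_equal(d$dG_total, d$dE_MM + d$dG_sol, tolerance = 1e-9)
    expect_identical(d$TdS, "omitted")
  }
  zero <- structure(list(E_int = 0, E_ele = 0, E_vdW = 0, G_GB = 0, G_SA = 0),
                    class = "energy_components")
  dz <- mmgbsa_decompose(zero, zero, zero)
  expect_true(all(unlist(dz[c("dE_MM", "dG_sol", "dG_total")]) == 0))
  # complex equal to receptor + ligand term by term: all differences vanish
  a <- structure(list(E_int = 0, E_ele = -12, E_vdW = -3, G_GB = 4, G_SA = 1),
                 class = "energy_components")
  b <- structure(list(E_int = 0, E_ele = -10, E_vdW = -1, G_GB = 3, G_SA = 0.5),
                 class = "energy_components")
  ab <- structure(list(E_int = 0, E_ele = -22, E_vdW = -4, G_GB = 7, G_SA = 1.5),
                  class = "energy_components")
  expect_equal(mmgbsa_decompose(ab, a, b)$dG_total, 0, tolerance = 1e-12)
})

test_that("single-trajectory MM-GBSA agrees with a monolithic oracle", {
  # 3-atom ligand docked onto a 10-atom slab
  set.seed(85)
  slab <- expand.grid(x = c(0, 3.5, 7, 10.5, 14), y = c(0, 3.5), z = 0)
  lig <- data.frame(x = c(5, 7, 6), y = c(1, 1, 2.5), z = c(3.5, 3.5, 4.5))
  all <- rbind(slab, lig)
  q <- c(runif(10, -0.3, 0.3), 0.4, -0.5, 0.1)
  fr <- mem_frame(c(rep("C", 10), "N", "O", "H"),
                  c(rep("OL", 10), rep("DRG", 3)),
                  all$x, all$y, all$z, charge = q)
  sig <- c(rep(3.4, 10), 3.2, 3.0, 1.0)
  eps <- c(rep(0.1, 10), 0.17, 0.21, 0.02)
  d <- mmgbsa(fr, ligand_idx = 11:13, sigma_i = sig, epsilon_i = eps)
  # oracle route: direct cross-group interaction plus solvation differences
  cross_ele <- 0; cross_lj <- 0
  for (i in 1:10) for (j in 11:13) {
    r <- sqrt(sum((all[i, ] - all[j, ])^2))
    cross_ele <- cross_ele + 332.0637 * q[i] * q[j] / r
    s <- (sig[i] + sig[j]) / 2
    cross_lj <- cross_lj + 4 * sqrt(eps[i] * eps[j]) * ((s / r)^12 - (s / r)^6)
  }
  expect_equal(d$dE_ele, cross_ele, tolerance = 1e-9)
  expect_equal(d$dE_vdW, cross_lj, tolerance = 1e-9)
  expect_equal(d$dE_int, 0)
  sub <- function(idx) {
    f <- fr[idx, , drop = FALSE]
    class(f) <- c("mem_frame", "data.frame")
    f
  }
  dGB <- gb_energy(fr, sig / 2) - gb_energy(sub(1:10), sig[1:10] / 2) -
    gb_energy(sub(11:13), sig[11:13] / 2)
  dSA <- 0.0072 * (sasa(fr, sig / 2)$total - sasa(sub(1:10), sig[1:10] / 2)$total -
                   sasa(sub(11:13), sig[11:13] / 2)$total)
  expect_equal(d$dG_total, cross_ele + cross_lj + dGB + dSA, tolerance = 1e-9)
})
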