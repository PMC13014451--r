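wat_shell_frame <- function(n, r, extra = NULL) {
  # n water oxygens on an exact r-Angstrom shell around a DRG atom at origin
  i <- seq_len(n)
  phi <- acos(1 - 2 * (i - 0.5) / n)
  theta <- pi * (1 + sqrt(5)) * i
  el <- c("Pt", rep("O", n)); lab <- c("DRG", rep("WAT", n))
  x <- c(0, r * sin(phi) * cos(theta))
  y <- c(0, r * sin(phi) * sin(theta))
  z <- c(0, r * cos(phi))
  if (!is.null(extra)) {
    el <- c(el, extra$element); lab <- c(lab, extra$label)
    x <- c(x, extra$x); y <- c(y, extra$y); z <- c(z, extra$z)
  }
  mem_frame(el, lab, x, y, z)
}

test_that("contact classification splits native from non-native pairs", {
  # reference: 5 waters at 2.0 A; later frame adds 3 waters at 2.5 A
  ref <- wat_shell_frame(5, 2.0,
                         extra = list(element = rep("O", 3),
                                      label = rep("WAT", 3),
                                      x = c(30, 31, 32), y = c(0, 0, 0),
                                      z = c(0, 0, 0)))
  fr <- ref
  fr$x[7:9] <- c(2.5, -2.5, 0); fr$y[7:9] <- 0; fr$z[7:9] <- c(0, 0, 2.5)
  rep_ <- count_contacts(list(fr), "DRG", ref, cutoff = 7)
  expect_equal(rep_$native[rep_$label == "WAT"], 5)
  expect_equal(rep_$nonnative[rep_$label == "WAT"], 3)
  # empty case: nothing within cutoff
  none <- count_contacts(list(ref), "DRG", ref, cutoff = 0.5)
  expect_true(all(none$native == 0) && all(none$nonnative == 0))
  expect_error(count_contacts(list(ref), "XXX", ref), "absent")
})

test_that("contact counts agree exactly with the all-pairs oracle", {
  set.seed(71)
  ref <- generate_toy_frames(1, n_water = 60, drug_z = 45, seed = 5)[[1]]
  attr(ref, "box") <- NULL  # open boundaries for the oracle comparison
  frames <- lapply(1:10, function(i) {
    fr <- ref
    fr$x <- fr$x + rnorm(nrow(fr), sd = 0.3)
    fr$y <- fr$y + rnorm(nrow(fr), sd = 0.3)
    fr$z <- fr$z + rnorm(nrow(fr), sd = 0.3)
    fr
  })
  got <- count_contacts(frames, "DRG", ref, cutoff = 7)
  ref_hits <- brute_contacts(ref, "DRG", 7)
  key <- function(h) paste(h$i, h$j)
  for (lb in got$label) {
    nat <- nonnat <- numeric(0)
    for (fr in frames) {
      h <- brute_contacts(fr, "DRG", 7)
      h <- h[h$label == lb, , drop = FALSE]
      rk <- key(ref_hits[ref_hits$label == lb, , drop = FALSE])
      nat <- c(nat, sum(key(h) %in% rk))
      nonnat <- c(nonnat, sum(!key(h) %in% rk))
    }
    expect_equal(got$native[got$label == lb], round(mean(nat)))
    expect_equal(got$nonnative[got$label == lb], round(mean(nonnat)))
  }
})

test_that("contact and hydration results are rigid-motion invariant", {
  fr <- wat_shell_frame(13, 2.8)
  fr2 <- rotate_frame(fr)
  a <- count_contacts(list(fr), "DRG", fr, cutoff = 5)
  b <- count_contacts(list(fr2), "DRG", fr2, cutoff = 5)
  expect_equal(a$native, b$native)
  expect_equal(a$mean_min_distance, b$mean_min_distance, tolerance = 1e-9)
  h1 <- hydration_profile(list("0" = list(fr)), "DRG")
  h2 <- hydration_profile(list("0" = list(fr2)), "DRG")
  expect_equal(h1$values, h2$values)
})

test_that("hydration counts waters within the threshold, with a 1-sigma band", {
  # 13 waters exactly on a 2.8 A shell: count 13, zero spread
  fr <- wat_shell_frame(13, 2.8)
  h <- hydration_profile(list("70" = list(fr, fr)), "DRG", threshold = 3)
  expect_equal(h$values, 13)
  expect_equal(h$stderr, 0)
  # vanishing threshold finds nothing
  h0 <- hydration_profile(list("70" = list(fr)), "DRG", threshold = 0.1)
  expect_equal(h0$values, 0)
  # alternating 4- and 6-water frames: mean 5, sigma 1
  f4 <- wat_shell_frame(4, 2.5); f6 <- wat_shell_frame(6, 2.5)
  h46 <- hydration_profile(list("40" = list(f4, f6, f4, f6)), "DRG")
  expect_equal(h46$values, 5)
  expect_equal(h46$stderr, 1)
})

test_that("hydrogen bonds obey the distance-plus-angle criterion", {
  # linear O-H...O at 2.8 A heavy-heavy separation
  mk <- function(acc_pos, h_pos = c(1.0, 0, 0)) {
    mem_frame(c("O", "H", "O"), c("DRG", "DRG", "WAT"),
              c(0, h_pos[1], acc_pos[1]), c(0, h_pos[2], acc_pos[2]),
              c(0, h_pos[3], acc_pos[3]))
  }
  donors <- data.frame(heavy = 1L, h = 2L)
  lin <- hydrogen_bonds(mk(c(2.8, 0, 0)), donors, acceptors = 3L)
  expect_equal(lin$n_bonds, 1)
  expect_equal(lin$probe_as_donor, 1)
  expect_equal(lin$mean_angle, 180)
  # 90-degree geometry fails the angular cutoff
  bent <- hydrogen_bonds(mk(c(1.0, 2.6, 0)), donors, acceptors = 3L)
  expect_equal(nrow(bent), 0)
  # distance beyond d_max fails even when linear
  far <- hydrogen_bonds(mk(c(4.0, 0, 0)), donors, acceptors = 3L)
  expect_equal(nrow(far), 0)
  expect_error(hydrogen_bonds(mk(c(2.8, 0, 0)),
                              data.frame(heavy = 1L, h = 99L), 3L),
               "missing hydrogen")
})

test_that("radial distribution function is 1 for an ideal gas, a spike for a shell", {
  set.seed(72)
  box <- c(40, 40, 40)
  frames <- lapply(1:100, function(i) {
    n <- 1e4
    mem_frame(c("Pt", rep("O", n)), c("DRG", rep("WAT", n)),
              c(20, runif(n, 0, 40)), c(20, runif(n, 0, 40)),
              c(20, runif(n, 0, 40)), box = box)
  })
  g <- rdf(frames, "DRG", "WAT", r_max = 16, bin_width = 0.5)
  sel <- g$z >= 5 & g$z <= 15
  expect_true(all(g$values[sel] > 0.95 & g$values[sel] < 1.05))
  # delta shell: all partners on an exact 3 A shell occupy the single bin
  # containing r = 3 (bin edges chosen off the shell radius)
  sh <- wat_shell_frame(24, 3.0)
  gs <- rdf(list(sh), "DRG", "WAT", r_max = 6, bin_width = 0.4, density = 0.033)
  expect_true(all(gs$values[gs$z != 3.0] == 0))
  expect_gt(gs$values[gs$z == 3.0], 0)
  # no partners at all: zero profile
  lone <- mem_frame("Pt", "DRG", 0, 0, 0)
  expect_error(rdf(list(lone), "DRG", "WAT", r_max = 5), NA)
  g0 <- rdf(list(mem_frame(c("Pt", "C"), c("DRG", "OL"), c(0, 50), c(0, 0),
                           c(0, 0))), "DRG", "WAT", r_max = 5)
  expect_true(all(g0$values == 0))
})

test_that("rdf refuses r_max beyond the minimum-image radius", {
  fr <- wat_shell_frame(5, 2)
  attr(fr, "box") <- c(10, 10, 10)
  expect_error(rdf(list(fr), "DRG", "WAT", r_max = 8), "half the smallest box")
})

test_that("electron density bins, partitions and conserves electrons", {
  # one O in a 1 A bin over 100 A^2: 8/(100*1) electrons per A^3
  fr <- mem_frame("O", "WAT", 5, 5, 10.5)
  ed <- electron_density(list(fr), z_breaks = 10:12, area = 100)
  expect_equal(ed$densities$WAT[1], 0.08)
  expect_equal(ed$densities$WAT[2], 0)
  # partition identity and conservation on a mixed system
  frames <- generate_toy_frames(3, n_water = 80, drug_z = 40, seed = 8)
  ed2 <- electron_density(frames, z_breaks = seq(0, 75, by = 1))
  summed <- Reduce(`+`, ed2$densities[setdiff(names(ed2$densities), "ALL")])
  expect_identical(summed, ed2$densities$ALL)
  integral <- sum(ed2$densities$ALL * ed2$bin_heights) * ed2$area
  expect_equal(integral, ed2$total_electrons, tolerance = 1e-6)
  # uniform water slab is flat within counting noise
  set.seed(73)
  uf <- lapply(1:40, function(i) {
    n <- 400
    mem_frame(rep("O", n), rep("WAT", n), runif(n, 0, 30), runif(n, 0, 30),
              runif(n, 0, 20), box = c(30, 30, 20))
  })
  edu <- electron_density(uf, z_breaks = seq(0, 20, by = 2))
  dens <- edu$densities$WAT
  expect_lt(max(abs(dens - mean(dens))) / mean(dens), 0.1)
  bad <- mem_frame("Pt", "DRG", 0, 0, 5)
  bad$element <- "Xx"
  expect_error(electron_density(list(bad), z_breaks = 0:10, area = 10), "Xx")
})
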