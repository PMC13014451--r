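# MM-GBSA interaction-energy bookkeeping over toy systems: pairwise Coulomb
# and Lennard-Jones terms, the Still pairwise generalized Born polar
# solvation term with supplied Born radii, and Shrake-Rupley numerical
# solvent-accessible surface area for the nonpolar term G_SA = gamma*SASA + b.

#' Pairwise Coulomb energy of a frame
#'
#' E = sum_{i<j} k_e q_i q_j / (eps_in r_ij) with
#' k_e = 332.0637 kcal A mol-1 e-2; no periodic images (toy systems).
#'
#' @param frame a [mem_frame] with a `charge` column.
#' @param dielectric_in interior dielectric constant (default 1).
#' @return energy in kcal/mol.
#' @export
coulomb_energy <- function(frame, dielectric_in = 1) {
  q <- frame$charge
  if (is.null(q) || anyNA(q)) stop("all atoms must carry charges")
  n <- nrow(frame)
  if (n < 2L) return(0)
  d <- .pair_dist(.coords(frame), .coords(frame))
  if (any(d[upper.tri(d)] == 0)) stop("coincident atoms")
  qq <- outer(q, q)
  sum((qq / d)[upper.tri(d)]) * .k_coulomb / dielectric_in
}

#' Pairwise Lennard-Jones energy of a frame
#'
#' 12-6 form with Lorentz-Berthelot combining: sigma_ij arithmetic mean,
#' eps_ij geometric mean; E = sum 4 eps [(sigma/r)^12 - (sigma/r)^6].
#'
#' @param frame a [mem_frame].
#' @param sigma_i per-atom sigma (A).
#' @param epsilon_i per-atom epsilon (kcal/mol).
#' @return energy in kcal/mol.
#' @export
lj_energy <- function(frame, sigma_i, epsilon_i) {
  n <- nrow(frame)
  if (length(sigma_i) != n || length(epsilon_i) != n) {
    stop("sigma_i and epsilon_i must have one entry per atom")
  }
  if (n < 2L) return(0)
  d <- .pair_dist(.coords(frame), .coords(frame))
  if (any(d[upper.tri(d)] == 0)) stop("coincident atoms (r = 0)")
  sij <- outer(sigma_i, sigma_i, `+`) / 2
  eij <- sqrt(outer(epsilon_i, epsilon_i))
  sr6 <- (sij / d)^6
  e <- 4 * eij * (sr6^2 - sr6)
  sum(e[upper.tri(e)])
}

#' Generalized Born polar solvation energy (Still pairwise form)
#'
#' G = -1/2 k_e (1/eps_in - 1/eps_out) sum_{i,j} q_i q_j / f_GB with
#' f_GB = sqrt(r^2 + R_i R_j exp(-r^2 / (4 R_i R_j))); self terms (i = j,
#' r = 0, f_GB = R_i) are included, so a single ion reduces exactly to the
#' Born formula. Born radii are inputs, not computed self-consistently.
#'
#' @param frame a [mem_frame] with a `charge` column.
#' @param born_radii per-atom effective Born radii (A, > 0).
#' @param eps_in,eps_out interior and solvent dielectric constants
#'   (defaults 1 and 80).
#' @return energy in kcal/mol.
#' @export
gb_energy <- function(frame, born_radii, eps_in = 1, eps_out = 80) {
  q <- frame$charge
  if (is.null(q) || anyNA(q)) stop("all atoms must carry charges")
  n <- nrow(frame)
  if (length(born_radii) != n) stop("born_radii must have one entry per atom")
  if (any(born_radii <= 0)) stop("Born radii must be positive")
  d2 <- .pair_dist(.coords(frame), .coords(frame))^2
  RR <- outer(born_radii, born_radii)
  fgb <- sqrt(d2 + RR * exp(-d2 / (4 * RR)))
  -0.5 * .k_coulomb * (1 / eps_in - 1 / eps_out) * sum(outer(q, q) / fgb)
}

# deterministic quasi-uniform sphere points (golden-spiral lattice)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Point-sampling on each atom's solvent-expanded sphere of radius
#' r_i + probe; a point is accessible if outside every other atom's
#' expanded sphere. Per-atom area = (accessible fraction) * 4 pi (r+probe)^2.
#'
#' @param frame a [mem_frame].
#' @param radii per-atom radii (A).
#' @param probe_radius solvent probe radius (A, default 1.4).
#' @param n_sphere_points quadrature points per atom (default 960, >= 10).
#' @return list with `total` (A^2) and `per_atom` (A^2 vector).
#' @export
sasa <- function(frame, radii, probe_radius = 1.4, n_sphere_points = 960) {
  if (n_sphere_points < 10) stop("n_sphere_points must be >= 10")
  n <- nrow(frame)
  if (length(radii) != n) stop("radii must have one entry per atom")
  co <- .coords(frame)
  R <- radii + probe_radius
  pts <- .sphere_points(n_sphere_points)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    p <- sweep(pts * R[i], 2, co[i, ], `+`)
    exposed <- rep(TRUE, n_sphere_points)
    for (j in seq_len(n)) {
      if (j == i) next
      dj2 <- (p[, 1] - co[j, 1])^2 + (p[, 2] - co[j, 2])^2 +
             (p[, 3] - co[j, 3])^2
      exposed <- exposed & dj2 > R[j]^2
      if (!any(exposed)) break
    }
    per_atom[i] <- mean(exposed) * 4 * pi * R[i]^2
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' Energy-component ledger for one system
#'
#' Evaluates the nonbonded and solvation terms of one species (complex,
#' receptor, or ligand) with a shared parameter set. The internal term
#' E_int is identically zero under the single-trajectory convention
#' (component geometries are extracted from the complex, so bonded terms
#' cancel in the difference).
#'
#' @param frame a [mem_frame] with charges.
#' @param sigma_i,epsilon_i Lennard-Jones parameters per atom.
#' @param born_radii effective Born radii per atom; defaults to sigma_i/2.
#' @param eps_in,eps_out dielectric constants (1, 80).
#' @param gamma surface-tension coefficient for G_SA = gamma*SASA + b
#'   (kcal mol-1 A-2, default 0.0072).
#' @param b SASA offset (kcal/mol, default 0).
#' @param probe_radius,n_sphere_points passed to [sasa].
#' @return object of class `energy_components` with fields `E_int`,
#'   `E_ele`, `E_vdW`, `G_GB`, `G_SA` (kcal/mol) and the SASA (`sasa_A2`).
#' @export
energy_components <- function(frame, sigma_i, epsilon_i, born_radii = NULL,
                              eps_in = 1, eps_out = 80, gamma = 0.0072,
                              b = 0, probe_radius = 1.4,
                              n_sphere_points = 960) {
  if (is.null(born_radii)) born_radii <- sigma_i / 2
  sa <- sasa(frame, sigma_i / 2, probe_radius, n_sphere_points)
  structure(
    list(E_int = 0,
         E_ele = coulomb_energy(frame, eps_in),
         E_vdW = lj_energy(frame, sigma_i, epsilon_i),
         G_GB = gb_energy(frame, born_radii, eps_in, eps_out),
         G_SA = gamma * sa$total + b,
         sasa_A2 = sa$total),
    class = "energy_components"
  )
}

#' @export
print.energy_components <- function(x, ...) {
  cat(sprintf(
    "E_int %.4f  E_ele %.4f  E_vdW %.4f  G_GB %.4f  G_SA %.4f  (kcal/mol)\n",
    x$E_int, x$E_ele, x$E_vdW, x$G_GB, x$G_SA))
  invisible(x)
}

#' MM-GBSA decomposition of a binding free energy
#'
#' Every Delta term is complex - receptor - ligand; the derived sums obey
#' dE_MM = dE_int + dE_ele + dE_vdW, dG_sol = dG_GB + dG_SA and
#' dG_total = dE_MM + dG_sol. The conformational-entropy term -T dS is
#' carried as an explicit "omitted" marker, never a silent zero.
#'
#' @param complex,receptor,ligand [energy_components] ledgers computed with
#'   identical parameters.
#' @return object of class `energy_decomposition`.
#' @export
mmgbsa_decompose <- function(complex, receptor, ligand) {
  dterm <- function(f) complex[[f]] - receptor[[f]] - ligand[[f]]
  dE_int <- dterm("E_int"); dE_ele <- dterm("E_ele"); dE_vdW <- dterm("E_vdW")
  dG_GB <- dterm("G_GB"); dG_SA <- dterm("G_SA")
  dE_MM <- dE_int + dE_ele + dE_vdW
  dG_sol <- dG_GB + dG_SA
  structure(
    list(dE_int = dE_int, dE_ele = dE_ele, dE_vdW = dE_vdW, dE_MM = dE_MM,
         dG_GB = dG_GB, dG_SA = dG_SA, dG_sol = dG_sol,
         dG_gas = dE_MM, dG_total = dE_MM + dG_sol, TdS = "omitted"),
    class = "energy_decomposition"
  )
}

#' @export
print.energy_decomposition <- function(x, ...) {
  cat("MM-GBSA decomposition (kcal/mol):\n")
  cat(sprintf("  dE_int %8.4f  dE_ele %8.4f  dE_vdW %8.4f  -> dE_MM %8.4f\n",
              x$dE_int, x$dE_ele, x$dE_vdW, x$dE_MM))
  cat(sprintf("  dG_GB  %8.4f  dG_SA  %8.4f                 -> dG_sol %8.4f\n",
              x$dG_GB, x$dG_SA, x$dG_sol))
  cat(sprintf("  dG_total %8.4f   (-TdS %s)\n", x$dG_total, x$TdS))
  invisible(x)
}

#' @export
as.data.frame.energy_decomposition <- function(x, ...) {
  data.frame(dE_int = x$dE_int, dE_ele = x$dE_ele, dE_vdW = x$dE_vdW,
             dE_MM = x$dE_MM, dG_GB = x$dG_GB, dG_SA = x$dG_SA,
             dG_sol = x$dG_sol, dG_total = x$dG_total, TdS = x$TdS)
}

#' Single-trajectory MM-GBSA of a ligand in a complex frame
#'
#' Splits one complex frame into receptor and ligand by atom indices,
#' evaluates the three ledgers with identical parameters, and decomposes.
#'
#' @param frame complex [mem_frame] with charges.
#' @param ligand_idx integer indices of the ligand atoms.
#' @param sigma_i,epsilon_i per-atom LJ parameters for the complex.
#' @param ... passed to [energy_components].
#' @return an `energy_decomposition`.
#' @export
mmgbsa <- function(frame, ligand_idx, sigma_i, epsilon_i, ...) {
  n <- nrow(frame)
  rec_idx <- setdiff(seq_len(n), ligand_idx)
  sub <- function(idx) {
    f <- frame[idx, , drop = FALSE]
    attr(f, "box") <- frame_box(frame)
    class(f) <- c("mem_frame", "data.frame")
    f
  }
  born <- list(...)$born_radii
  args <- list(...)
  comp <- function(idx) {
    a <- args
    if (!is.null(born)) a$born_radii <- born[idx]
    do.call(energy_components,
            c(list(sub(idx), sigma_i[idx], epsilon_i[idx]), a))
  }
  mmgbsa_decompose(comp(seq_len(n)), comp(rec_idx), comp(ligand_idx))
}
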