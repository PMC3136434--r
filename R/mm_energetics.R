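# Gas-phase molecular-mechanics interaction energies: Coulomb and 12-6
# Lennard-Jones with infinite cutoff, Lorentz-Berthelot combination
# (arithmetic r_min/2 radii, geometric well depths).

cross_distances <- function(xyzA, xyzB) {
  # |A| x |B| matrix of pair distances
  dx <- outer(xyzA[, 1], xyzB[, 1], "-")
  dy <- outer(xyzA[, 2], xyzB[, 2], "-")
  dz <- outer(xyzA[, 3], xyzB[, 3], "-")
  sqrt(dx * dx + dy * dy + dz * dz)
}

check_singularity <- function(r, groupA, groupB) {
  if (any(r == 0)) {
    ij <- which(r == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("zero interatomic distance between atoms serial %d and %d",
                 groupA$serial[ij[1]], groupB$serial[ij[2]]))
  }
}

#' Coulomb interaction energy between two atom groups
#'
#' Vacuum point-charge electrostatics, no cutoff, no periodicity:
#' `sum_ij k q_i q_j / r_ij` with `k = 332.0637` kcal A/(mol e^2).
#'
#' @param groupA,groupB atom data.frames (rows of a system's `atoms`) or
#'   `molecular_system`s; the groups must be disjoint atom sets.
#' @return kcal/mol.
#' @export
coulomb_interaction <- function(groupA, groupB) {
  a <- if (inherits(groupA, "molecular_system")) groupA$atoms else groupA
  b <- if (inherits(groupB, "molecular_system")) groupB$atoms else groupB
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  r <- cross_distances(as.matrix(a[, c("x", "y", "z")]), as.matrix(b[, c("x", "y", "z")]))
  check_singularity(r, a, b)
  bindfe_constants$coulomb * sum(outer(a$charge, b$charge) / r)
}

#' Lennard-Jones interaction energy between two atom groups
#'
#' 12-6 potential in the r_min/epsilon parameterisation,
#' `E = eps_ij ((rmin_ij/r)^12 - 2 (rmin_ij/r)^6)` with
#' `rmin_ij = R_i + R_j` (atomic `lj_radius` is r_min/2) and
#' `eps_ij = sqrt(eps_i eps_j)`; infinite cutoff.
#'
#' @inheritParams coulomb_interaction
#' @return kcal/mol.
#' @export
lj_interaction <- function(groupA, groupB) {
  a <- if (inherits(groupA, "molecular_system")) groupA$atoms else groupA
  b <- if (inherits(groupB, "molecular_system")) groupB$atoms else groupB
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  r <- cross_distances(as.matrix(a[, c("x", "y", "z")]), as.matrix(b[, c("x", "y", "z")]))
  check_singularity(r, a, b)
  rmin <- outer(a$lj_radius, b$lj_radius, "+")
  eps <- sqrt(outer(a$lj_epsilon, b$lj_epsilon))
  s6 <- (rmin / r)^6
  sum(eps * (s6 * s6 - 2 * s6))
}

#' Gas-phase binding energy of a complex frame
#'
#' Single-trajectory convention: receptor and ligand coordinates are taken
#' from the complex frame, so all intramolecular terms cancel and the
#' gas-phase binding energy equals the receptor-ligand cross-interaction.
#'
#' @param complex a `molecular_system` with role `"complex"`.
#' @param frame optional coordinate matrix overriding stored coordinates.
#' @return list of class `gas_phase_energy` with elements `el`, `vdw`,
#'   `total` (kcal/mol).
#' @export
gas_phase_binding <- function(complex, frame = NULL) {
  stopifnot(complex$role == "complex")
  if (!is.null(frame)) complex <- set_coords(complex, frame)
  rows <- partition_rows(complex)
  rec <- complex$atoms[rows$receptor, , drop = FALSE]
  lig <- complex$atoms[rows$ligand, , drop = FALSE]
  el <- coulomb_interaction(rec, lig)
  vdw <- lj_interaction(rec, lig)
  structure(list(el = el, vdw = vdw, total = el + vdw), class = "gas_phase_energy")
}

# Full nonbonded energy of one species including intramolecular pairs, with
# 1-2/1-3 exclusions from the bond graph (1-4 unscaled).  Used only by the
# single-trajectory identity check and by the differentiable energy model.
nonbonded_exclusions <- function(system) {
  n <- nrow(system$atoms)
  idx <- match(system$bonds, system$atoms$serial)
  b <- matrix(idx, ncol = 2)
  excl <- matrix(FALSE, n, n)
  if (nrow(b) > 0) {
    excl[b] <- TRUE; excl[b[, c(2, 1), drop = FALSE]] <- TRUE
    adj <- lapply(seq_len(n), function(i) c(b[b[, 1] == i, 2], b[b[, 2] == i, 1]))
    for (i in seq_len(n)) {
      for (j in adj[[i]]) {
        for (k in adj[[j]]) if (k != i) { excl[i, k] <- TRUE; excl[k, i] <- TRUE }
      }
    }
  }
  diag(excl) <- TRUE
  excl
}

#' Total nonbonded energy of one species (intramolecular pairs included)
#'
#' Coulomb + LJ over all atom pairs, excluding 1-2 and 1-3 pairs from the
#' bond graph (1-4 unscaled).  Exists mainly to verify the single-trajectory
#' identity `E(complex) - E(receptor) - E(ligand) = gas_phase_binding`.
#'
#' @param system a `molecular_system`.
#' @return list with `el`, `vdw`, `total` (kcal/mol).
#' @export
total_nonbonded <- function(system) {
  a <- system$atoms
  n <- nrow(a)
  if (n < 2) return(list(el = 0, vdw = 0, total = 0))
  xyz <- coords(system)
  r <- cross_distances(xyz, xyz)
  excl <- nonbonded_exclusions(system)
  mask <- upper.tri(r) & !excl
  if (any(r[mask] == 0)) stop("zero interatomic distance in nonbonded sum")
  qq <- outer(a$charge, a$charge)
  el <- bindfe_constants$coulomb * sum((qq / ifelse(r == 0, Inf, r))[mask])
  rmin <- outer(a$lj_radius, a$lj_radius, "+")
  eps <- sqrt(outer(a$lj_epsilon, a$lj_epsilon))
  s6 <- (rmin / ifelse(r == 0, Inf, r))^6
  vdw <- sum((eps * (s6 * s6 - 2 * s6))[mask])
  list(el = el, vdw = vdw, total = el + vdw)
}
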