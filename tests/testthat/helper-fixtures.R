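# Shared builders for small in-code fixtures.

toy_atoms <- function(n, xyz, charge = 0, lj_radius = 1.9, lj_epsilon = 0.1,
                      mass = 12, name = NULL, resid = "LIG", resno = NULL,
                      chain = "A") {
  if (is.null(name)) name <- paste0("C", seq_len(n))
  if (is.null(resno)) resno <- seq_len(n)
  data.frame(serial = seq_len(n), name = name, element = "C",
             resno = resno, resid = resid, chain = chain,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             charge = rep_len(charge, n), lj_radius = rep_len(lj_radius, n),
             lj_epsilon = rep_len(lj_epsilon, n), mass = rep_len(mass, n))
}

toy_system <- function(..., role = "ligand", bonds = NULL, partition = NULL) {
  molecular_system(toy_atoms(...), bonds = bonds, role = role,
                   partition = partition)
}

born_ion <- function(q = 1, radius = 2) {
  toy_system(1, matrix(0, 1, 3), charge = q, lj_radius = radius,
             lj_epsilon = 0.1, role = "receptor")
}

lj_diatomic <- function(sep = 3.8, eps = 0.3, radius = 1.9, masses = c(12, 16)) {
  at <- toy_atoms(2, cbind(c(0, sep), 0, 0), lj_radius = radius,
                  lj_epsilon = eps, mass = masses)
  molecular_system(at, role = "ligand")
}

bonded_diatomic <- function(sep = 4.1, masses = c(12, 16)) {
  at <- toy_atoms(2, cbind(c(0, sep), 0, 0), lj_epsilon = 0, mass = masses)
  molecular_system(at, bonds = matrix(c(1, 2), ncol = 2), role = "ligand")
}

# small rigid complex: two charged atoms facing each other
two_atom_complex <- function(sep = 5, qA = 1, qB = -1, eps = 0.1) {
  at <- toy_atoms(2, cbind(c(0, sep), 0, 0), charge = c(qA, qB),
                  lj_epsilon = eps, chain = c("R", "L"))
  molecular_system(at, role = "complex", partition = list(receptor = 1L, ligand = 2L))
}

rigid_fixture <- function(seed = 7, n_frames = 2, charge = 1) {
  fx <- build_complex(fixture_spec(seed = seed, ligand_net_charge = charge,
                                   fluctuation_sigma = 0, n_frames = n_frames,
                                   intermittent_bonds = list()))
  list(fixture = fx, ensemble = sample_ensemble(fx))
}

coarse_pb <- function(spacing = 0.8, padding = 6) {
  pb_settings(grid_spacing = spacing, grid_padding = padding)
}

rotate_translate <- function(xyz, angle = 0.37, shift = c(3, -2, 7)) {
  R <- matrix(c(cos(angle), -sin(angle), 0,
                sin(angle), cos(angle), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  sweep(xyz %*% t(R), 2, shift, "+")
}

# recompute the z-scored selection objective for an explicit subset
subset_obj_for_test <- function(idx, dec, occ) {
  enth <- dec$enthalpic_total
  mu <- mean(enth); sdv <- stats::sd(enth)
  o <- colMeans(occ * 1)
  osd <- apply(occ * 1, 2, stats::sd); osd[osd == 0] <- 1
  sum((c(mean(enth[idx]) - mu, stats::sd(enth[idx]) - sdv,
         colMeans(occ[idx, , drop = FALSE] * 1) - o) / c(sdv, sdv, osd))^2)
}
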