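# Implicit solvation: polar term by finite-difference Poisson-Boltzmann
# (compiled solver, see src/fdpb.cpp) and nonpolar term from
# solvent-accessible surface area (deterministic Shrake-Rupley sampling on a
# Fibonacci sphere lattice).

#' Poisson-Boltzmann solver settings
#'
#' @param grid_spacing grid spacing, A.
#' @param solute_dielectric,solvent_dielectric relative permittivities
#'   (defaults 1 and 80).
#' @param probe_radius solvent probe radius for SASA, A.
#' @param grid_padding clearance between the solute's cavity spheres and the
#'   grid boundary, A.
#' @param ionic_strength molar; 0 gives the Poisson limit.
#' @param temperature K (enters only the Debye screening length).
#' @param tol relative residual at which the iterative solver stops.
#' @param maxit iteration cap.
#' @param boundary_smoothing harmonic-mean dielectric smoothing on
#'   boundary-crossing grid edges (recommended; improves grid convergence).
#' @return list of class `pb_settings`.
#' @export
pb_settings <- function(grid_spacing = 0.5, solute_dielectric = 1.0,
                        solvent_dielectric = 80.0, probe_radius = 1.4,
                        grid_padding = 8.0, ionic_strength = 0,
                        temperature = 300, tol = 1e-6, maxit = 20000,
                        boundary_smoothing = TRUE) {
  stopifnot(grid_spacing > 0, solute_dielectric >= 1, solvent_dielectric >= 1,
            probe_radius >= 0, grid_padding > 0, ionic_strength >= 0)
  structure(list(grid_spacing = grid_spacing, solute_dielectric = solute_dielectric,
                 solvent_dielectric = solvent_dielectric, probe_radius = probe_radius,
                 grid_padding = grid_padding, ionic_strength = ionic_strength,
                 temperature = temperature, tol = tol, maxit = maxit,
                 boundary_smoothing = boundary_smoothing),
            class = "pb_settings")
}

debye_kappa2 <- function(settings) {
  if (settings$ionic_strength <= 0) return(0)
  # kappa^2 in A^-2: 8 pi k_coul n / (eps_out kB T), n in e^2 per A^3 per M
  8 * pi * bindfe_constants$coulomb * settings$ionic_strength * 6.02214076e-4 /
    (settings$solvent_dielectric * bindfe_constants$kB * settings$temperature)
}

#' Polar solvation energy by finite-difference Poisson-Boltzmann
#'
#' Reaction-field energy: grid electrostatic energy with the heterogeneous
#' dielectric (solute cavity in solvent) minus the energy of the same grid
#' with a uniform solute dielectric, which cancels the grid self-energy.
#' The dielectric boundary is the union of atom spheres at their
#' `lj_radius`; at zero ionic strength this solves the Poisson equation.
#'
#' @param system a `molecular_system`.
#' @param frame optional coordinate matrix.
#' @param settings a [pb_settings()] object.
#' @param origin_shift 3-vector added to the grid origin (grid-placement
#'   diagnostics).
#' @return kcal/mol (attributes `dims`, `iterations`).
#' @export
solve_pb <- function(system, frame = NULL, settings = pb_settings(),
                     origin_shift = c(0, 0, 0)) {
  if (is.null(frame)) frame <- coords(system)
  a <- system$atoms
  res <- fdpb_solve(frame, a$charge, a$lj_radius,
                    settings$grid_spacing, settings$grid_padding,
                    settings$solute_dielectric, settings$solvent_dielectric,
                    debye_kappa2(settings), settings$tol, settings$maxit,
                    settings$boundary_smoothing, as.numeric(origin_shift))
  structure(res$energy, dims = res$dims, iterations = res$iterations)
}

# deterministic, nearly uniform unit-sphere point set
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom's sphere of radius `lj_radius + probe_radius` is sampled on a
#' deterministic Fibonacci lattice; points buried inside any neighbour's
#' expanded sphere are excluded.  Exactly coincident atoms of equal radius
#' are deduplicated (only the first contributes surface).
#'
#' @param system a `molecular_system`.
#' @param frame optional coordinate matrix.
#' @param probe_radius probe radius, A.
#' @param n_points sample points per atom sphere.
#' @return numeric vector of per-atom areas (A^2) with attribute `total`.
#' @export
sasa <- function(system, frame = NULL, probe_radius = 1.4, n_points = 960) {
  if (is.null(frame)) frame <- coords(system)
  a <- system$atoms
  n <- nrow(a)
  rad <- a$lj_radius + probe_radius
  pts <- fibonacci_sphere(n_points)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    if (a$lj_radius[i] <= 0) next
    p <- sweep(pts * rad[i], 2, frame[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i || a$lj_radius[j] <= 0) next
      d2 <- sum((frame[i, ] - frame[j, ])^2)
      if (d2 < 1e-20) {                   # coincident atoms: first one wins
        if (rad[j] >= rad[i] && j < i) { exposed[] <- FALSE; break }
        next
      }
      if (d2 >= (rad[i] + rad[j])^2) next
      dj2 <- rowSums(sweep(p, 2, frame[j, ])^2)
      exposed <- exposed & (dj2 >= rad[j]^2)
      if (!any(exposed)) break
    }
    areas[i] <- 4 * pi * rad[i]^2 * sum(exposed) / n_points
  }
  structure(areas, total = sum(areas))
}

#' Nonpolar solvation term from surface area
#'
#' `gamma * SASA + offset`.  The default surface tension and offset are the
#' conventional companions of the PB setup used here; both are configurable.
#'
#' @param total_sasa total solvent-accessible surface area, A^2.
#' @param gamma surface tension, kcal/(mol A^2).
#' @param offset constant, kcal/mol.
#' @return kcal/mol.
#' @export
nonpolar_term <- function(total_sasa, gamma = 0.00542, offset = 0.92) {
  stopifnot(total_sasa >= 0)
  gamma * total_sasa + offset
}

#' Total solvation free energy of one species
#'
#' @param system a `molecular_system`.
#' @param frame optional coordinates.
#' @param settings [pb_settings()].
#' @param gamma,offset nonpolar parameters (see [nonpolar_term()]).
#' @return list of class `solvation_energy`: `polar`, `nonpolar`, `gamma`,
#'   `total` (kcal/mol), `sasa` (A^2).
#' @export
solvation_energy <- function(system, frame = NULL, settings = pb_settings(),
                             gamma = 0.00542, offset = 0.92) {
  polar <- as.numeric(solve_pb(system, frame, settings))
  area <- sasa(system, frame, probe_radius = settings$probe_radius)
  nonpolar <- nonpolar_term(attr(area, "total"), gamma, offset)
  structure(list(polar = polar, nonpolar = nonpolar, gamma = gamma,
                 total = polar + nonpolar, sasa = attr(area, "total")),
            class = "solvation_energy")
}

#' Solvation contribution to binding (single-trajectory convention)
#'
#' `G_solv(complex) - G_solv(receptor) - G_solv(ligand)` with receptor and
#' ligand coordinates shared with the complex frame.
#'
#' @inheritParams solvation_energy
#' @param complex a complex `molecular_system`.
#' @return list with `polar`, `nonpolar`, `total` differences (kcal/mol).
#' @export
binding_solvation <- function(complex, frame = NULL, settings = pb_settings(),
                              gamma = 0.00542, offset = 0.92) {
  stopifnot(complex$role == "complex")
  if (!is.null(frame)) complex <- set_coords(complex, frame)
  gc_ <- solvation_energy(complex, settings = settings, gamma = gamma, offset = offset)
  gr <- solvation_energy(extract_component(complex, "receptor"),
                         settings = settings, gamma = gamma, offset = offset)
  gl <- solvation_energy(extract_component(complex, "ligand"),
                         settings = settings, gamma = gamma, offset = offset)
  list(polar = gc_$polar - gr$polar - gl$polar,
       nonpolar = gc_$nonpolar - gr$nonpolar - gl$nonpolar,
       total = gc_$total - gr$total - gl$total)
}
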