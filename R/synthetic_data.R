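# Generator of toy receptor-hairpin complexes with stored ground truth.
#
# The fixture emulates the statistical structure the analysis assumes: a
# 15-residue hairpin ligand bound in a receptor groove, binding energy
# concentrated in a 4-residue "FxxA-like" hotspot (deep Lennard-Jones
# pocket contacts), a cationic ligand series against an anionic receptor
# patch, intermittent donor-acceptor hydrogen bonds realized as two-state
# telegraph processes, and harmonic positional fluctuation about the
# reference pose.  Residues are coarse (3-6 atoms) but follow PDB naming
# (N/CA/C backbone, CB/CG side chain) so every I/O and truncation path is
# exercised.

#' Specification of a synthetic receptor-hairpin fixture
#'
#' @param n_ligand_residues hairpin length (default 15).
#' @param hotspot_positions indices of the hotspot module (default 6:9,
#'   FxxA-like: PHE at the first position, ALA at the last, THR between).
#' @param ligand_net_charge net ligand charge in e (0-3); charge sites are
#'   lysine-like CB atoms at positions 12, 2, 14 (in that order).
#' @param intermittent_bonds list of bonds, each a list with
#'   `ligand_residue`, `ligand_atom`, `acceptor` (receptor residue label:
#'   `"ACC10"`-style, resolved at build time), `occupancy`, `d_on`, `d_off`
#'   (A).  Default: one serine-donor bond at position 10 with occupancy
#'   0.65.
#' @param fluctuation_sigma isotropic Gaussian positional fluctuation, A.
#' @param n_frames frames per sampled ensemble.
#' @param stride ps between frames.
#' @param telegraph_tau telegraph correlation time, frames (mean state
#'   dwell; gives the block-averaging tests real autocorrelation).
#' @param seed mandatory RNG seed.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_ligand_residues = 15, hotspot_positions = 6:9,
                         ligand_net_charge = 1, intermittent_bonds = NULL,
                         fluctuation_sigma = 0.1, n_frames = 50, stride = 6,
                         telegraph_tau = 10, seed) {
  if (missing(seed)) stop("fixture_spec requires a seed")
  n <- n_ligand_residues
  if (n < 6) stop("infeasible geometry: need at least 6 ligand residues")
  if (any(hotspot_positions < 1 | hotspot_positions > n) ||
      length(hotspot_positions) < 2)
    stop("infeasible geometry: hotspot positions outside the hairpin")
  if (ligand_net_charge < 0 || ligand_net_charge > 3)
    stop("ligand_net_charge must be in 0..3")
  charge_sites <- setdiff(c(12, 2, 14), hotspot_positions)
  charge_sites <- charge_sites[charge_sites <= n]
  if (length(charge_sites) < ligand_net_charge)
    stop("infeasible geometry: not enough charge sites for the requested net charge")
  if (is.null(intermittent_bonds)) {
    intermittent_bonds <- list(list(ligand_residue = min(10, n - 1), ligand_atom = "CG",
                                    occupancy = 0.65, d_on = 2.9, d_off = 5.0))
  }
  for (b in intermittent_bonds) {
    if (b$occupancy < 0 || b$occupancy > 1) stop("occupancies must be in [0,1]")
  }
  stopifnot(fluctuation_sigma >= 0, n_frames >= 1, telegraph_tau >= 1)
  structure(list(n_ligand_residues = n, hotspot_positions = sort(hotspot_positions),
                 ligand_net_charge = ligand_net_charge,
                 charge_sites = charge_sites[seq_len(ligand_net_charge)],
                 intermittent_bonds = intermittent_bonds,
                 fluctuation_sigma = fluctuation_sigma, n_frames = n_frames,
                 stride = stride, telegraph_tau = telegraph_tau, seed = seed),
            class = "fixture_spec")
}

# internal: coarse force-field parameter table of the fixture universe
fixture_param_table <- function() {
  p <- function(residue, atom, charge, r, e, m)
    data.frame(residue = residue, atom = atom, charge = charge,
               lj_radius = r, lj_epsilon = e, mass = m)
  rbind(
    p("SER", "N", -0.30, 1.824, 0.17, 14.007), p("SER", "CA", 0.10, 1.908, 0.1094, 12.011),
    p("SER", "C", 0.20, 1.908, 0.1094, 12.011), p("SER", "CB", 0.00, 1.908, 0.1094, 12.011),
    p("SER", "CG", 0.00, 1.908, 0.1094, 12.011),
    p("LYS", "N", -0.30, 1.824, 0.17, 14.007), p("LYS", "CA", 0.10, 1.908, 0.1094, 12.011),
    p("LYS", "C", 0.20, 1.908, 0.1094, 12.011), p("LYS", "CB", 1.00, 1.908, 0.1094, 12.011),
    p("LYS", "CG", 0.00, 1.908, 0.1094, 12.011),
    p("PHE", "N", -0.30, 1.824, 0.17, 14.007), p("PHE", "CA", 0.10, 1.908, 0.1094, 12.011),
    p("PHE", "C", 0.20, 1.908, 0.1094, 12.011), p("PHE", "CB", 0.00, 1.908, 0.1094, 12.011),
    p("PHE", "CG", 0.00, 1.908, 4.00, 12.011),
    p("THR", "N", -0.30, 1.824, 0.17, 14.007), p("THR", "CA", 0.10, 1.908, 0.1094, 12.011),
    p("THR", "C", 0.20, 1.908, 0.1094, 12.011), p("THR", "CB", 0.00, 1.908, 0.1094, 12.011),
    p("THR", "CG", 0.00, 1.908, 1.00, 12.011),
    p("ALA", "N", -0.30, 1.824, 0.17, 14.007), p("ALA", "CA", 0.10, 1.908, 0.1094, 12.011),
    p("ALA", "C", 0.20, 1.908, 0.1094, 12.011), p("ALA", "CB", 0.00, 1.908, 1.5625, 12.011),
    p("ALA", "HB1", 0.00, 1.487, 0.0157, 1.008),
    p("GLY", "N", -0.30, 1.824, 0.17, 14.007), p("GLY", "CA", 0.10, 1.908, 0.1094, 12.011),
    p("GLY", "C", 0.20, 1.908, 0.1094, 12.011), p("GLY", "HA2", 0.00, 1.387, 0.0157, 1.008),
    p("GRV", "CA", 0.00, 2.00, 0.15, 12.011),
    p("PKT", "CP", 0.00, 1.908, 4.00, 12.011),
    p("ASP", "OD1", -1.00, 1.6612, 0.21, 15.999),
    p("ACC", "OAC", 0.00, 1.6612, 0.21, 15.999)
  )
}

fixture_residue_center <- function(i, n) {
  s1 <- ceiling((n + 1) / 2)               # strand 1 length of the hairpin
  if (i <= s1) c(3.5 * (i - 1), 0, 0) else c(3.5 * (n - i), 4.5, 0)
}

# simple independent pair-sum oracle used for the stored ground truth; kept
# as explicit loops, deliberately not calling the mm_energetics functions
pair_energy_sum <- function(atomsA, atomsB) {
  el <- 0; vdw <- 0
  for (i in seq_len(nrow(atomsA))) {
    for (j in seq_len(nrow(atomsB))) {
      dx <- atomsA$x[i] - atomsB$x[j]; dy <- atomsA$y[i] - atomsB$y[j]
      dz <- atomsA$z[i] - atomsB$z[j]
      r <- sqrt(dx^2 + dy^2 + dz^2)
      el <- el + 332.0637 * atomsA$charge[i] * atomsB$charge[j] / r
      rm <- atomsA$lj_radius[i] + atomsB$lj_radius[j]
      ep <- sqrt(atomsA$lj_epsilon[i] * atomsB$lj_epsilon[j])
      s6 <- (rm / r)^6
      vdw <- vdw + ep * (s6^2 - 2 * s6)
    }
  }
  c(el = el, vdw = vdw)
}

#' Build a toy receptor-hairpin complex with stored ground truth
#'
#' Deterministic for a given spec.  Returns the complex, a parameter table
#' covering all its (residue, atom) pairs, and a ground-truth record with
#' analytic reference-pose interaction energies, per-residue side-chain
#' interaction energies (as probed by the truncation scan), target bond
#' occupancies, and the resolved intermittent-bond atom serials.
#'
#' @param spec a [fixture_spec()].
#' @return list of class `fixture` with elements `complex`
#'   (`molecular_system`), `params` (list as from [read_param_table()]),
#'   `truth`, `spec`.
#' @export
build_complex <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_ligand_residues
  hs <- spec$hotspot_positions
  seq_res <- rep("SER", n)
  seq_res[hs] <- "THR"
  seq_res[hs[1]] <- "PHE"
  seq_res[hs[length(hs)]] <- "ALA"
  seq_res[spec$charge_sites] <- "LYS"
  params <- fixture_param_table()
  pget <- function(res, atom) {
    r <- params[params$residue == res & params$atom == atom, ]
    if (nrow(r) == 0) stop("no fixture parameters for ", res, " ", atom)
    r
  }
  atoms <- NULL; bonds <- NULL
  serial <- 0L
  add_atom <- function(name, res, resno, chain, pos) {
    serial <<- serial + 1L
    pr <- pget(res, name)
    atoms <<- rbind(atoms, data.frame(serial = serial, name = name,
                                      element = substr(name, 1, 1),
                                      resno = resno, resid = res, chain = chain,
                                      x = pos[1], y = pos[2], z = pos[3],
                                      charge = pr$charge, lj_radius = pr$lj_radius,
                                      lj_epsilon = pr$lj_epsilon, mass = pr$mass))
    serial
  }
  add_bond <- function(a, b) bonds <<- rbind(bonds, c(a, b))

  # --- ligand hairpin ---
  prev_c <- NA
  cg_serial <- integer(n); cb_serial <- integer(n)
  for (i in seq_len(n)) {
    ctr <- fixture_residue_center(i, n)
    res <- seq_res[i]
    sn <- add_atom("N", res, i, "L", ctr + c(-1.2, 0.5, 0))
    sca <- add_atom("CA", res, i, "L", ctr)
    sc <- add_atom("C", res, i, "L", ctr + c(1.2, 0.5, 0))
    add_bond(sn, sca); add_bond(sca, sc)
    if (!is.na(prev_c)) add_bond(prev_c, sn)
    prev_c <- sc
    hotspot <- i %in% hs
    zdir <- if (hotspot) -1 else 1        # hotspot side chains face the groove
    if (res != "GLY") {
      scb <- add_atom("CB", res, i, "L", ctr + c(0, 0, zdir * 1.5))
      add_bond(sca, scb)
      cb_serial[i] <- scb
      if (res != "ALA") {
        scg <- add_atom("CG", res, i, "L", ctr + c(0, 0, zdir * 3.0))
        add_bond(scb, scg)
        cg_serial[i] <- scg
      }
    }
  }
  ligand_serials <- atoms$serial

  # --- receptor: groove wall, hotspot pockets, anionic patch, acceptors ---
  rmin_cc <- 1.908 + 1.908                # contact distance of the pockets
  s1_len <- ceiling((n + 1) / 2)
  for (i in seq_len(n)) {
    ctr <- fixture_residue_center(i, n)
    ydir <- if (i <= s1_len) -1 else 1    # groove wall flanks each strand outward
    add_atom("CA", "GRV", 100L + i, "R", ctr + c(0, ydir * 4.0, -5.0))
  }
  resno_r <- 100L + n
  for (i in hs) {
    ctr <- fixture_residue_center(i, n)
    depth <- if (seq_res[i] == "ALA") 1.5 else 3.0   # CB vs CG contact
    resno_r <- resno_r + 1L
    add_atom("CP", "PKT", resno_r, "R", ctr + c(0, 0, -depth - rmin_cc))
  }
  for (i in spec$charge_sites) {
    ctr <- fixture_residue_center(i, n)
    resno_r <- resno_r + 1L
    add_atom("OD1", "ASP", resno_r, "R", ctr + c(0, 0, -4.0))
  }
  bond_serials <- list()
  s1 <- ceiling((n + 1) / 2)
  for (b in spec$intermittent_bonds) {
    i <- b$ligand_residue
    ctr <- fixture_residue_center(i, n)
    ydir <- if (i <= s1) -1 else 1        # approach from the outside of the strand
    resno_r <- resno_r + 1L
    acc <- add_atom("OAC", "ACC", resno_r, "R", ctr + c(0, ydir * 3.2, 0.5))
    donor <- atoms$serial[atoms$resno == i & atoms$chain == "L" &
                          atoms$name == b$ligand_atom]
    if (length(donor) != 1)
      stop("infeasible bond request: no ", b$ligand_atom, " in ligand residue ", i)
    bond_serials[[length(bond_serials) + 1]] <-
      list(donor = donor, acceptor = acc, occupancy = b$occupancy,
           d_on = b$d_on, d_off = b$d_off)
  }
  receptor_serials <- setdiff(atoms$serial, ligand_serials)
  complex <- molecular_system(atoms, bonds, role = "complex",
                              partition = list(receptor = receptor_serials,
                                               ligand = ligand_serials))

  # --- ground truth by independent pair summation ---
  rec <- atoms[atoms$serial %in% receptor_serials, ]
  lig <- atoms[atoms$serial %in% ligand_serials, ]
  gas <- pair_energy_sum(rec, lig)
  side_truth <- do.call(rbind, lapply(seq_len(n), function(i) {
    res <- seq_res[i]
    mutation <- if (res == "ALA") "gly" else "ala"
    stem_name <- if (mutation == "gly") "CA" else "CB"
    resat <- lig[lig$resno == i, ]
    stem <- resat[resat$name == stem_name, ]
    removed <- if (mutation == "gly") {
      resat[!(resat$name %in% c("N", "CA", "C")), ]
    } else {
      resat[!(resat$name %in% c("N", "CA", "C", "CB")), ]
    }
    if (nrow(removed) == 0)
      return(data.frame(position = i, wild_type = res, mutation = mutation,
                        side_chain_energy = 0, ddG_gas = 0))
    gamma <- removed[1, ]                  # bonded neighbour of the stem
    u <- c(gamma$x - stem$x, gamma$y - stem$y, gamma$z - stem$z)
    u <- u / sqrt(sum(u^2))
    h <- stem
    h$x <- stem$x + 1.09 * u[1]; h$y <- stem$y + 1.09 * u[2]
    h$z <- stem$z + 1.09 * u[3]
    h$charge <- 0
    h$lj_radius <- if (mutation == "gly") 1.387 else 1.487
    h$lj_epsilon <- 0.0157
    e_rm <- pair_energy_sum(rec, removed)
    e_h <- pair_energy_sum(rec, h)
    # side_chain_energy: receptor interaction of the truncated atoms (minus
    # the replacement hydrogen's); ddG_gas: its sign-flipped value, i.e. the
    # gas-phase truncation ddG the scan should recover
    data.frame(position = i, wild_type = res, mutation = mutation,
               side_chain_energy = sum(e_rm) - sum(e_h),
               ddG_gas = sum(e_h) - sum(e_rm))
  }))
  el_per_site <- if (length(spec$charge_sites) > 0) {
    vapply(spec$charge_sites, function(i) {
      cb <- lig[lig$resno == i & lig$name == "CB", ]
      pair_energy_sum(rec, cb)[["el"]]
    }, numeric(1))
  } else numeric(0)
  truth <- list(gas_el = gas[["el"]], gas_vdw = gas[["vdw"]],
                gas_total = sum(gas),
                per_residue = side_truth,
                charge_site_el = el_per_site,
                bonds = bond_serials,
                net_ligand_charge = sum(lig$charge),
                sequence = seq_res)
  param_out <- params[paste(params$residue, params$atom) %in%
                      unique(c(paste(atoms$resid, atoms$name),
                               paste("ALA", "HB1"), paste("GLY", "HA2"))), ]
  structure(list(complex = complex,
                 params = list(params = param_out, bonds = bonds),
                 truth = truth, spec = spec),
            class = "fixture")
}

# telegraph state path with mean dwell tau and exact-count correction so the
# realized occupancy matches the target up to rounding (variance-controlled;
# see the methods vignette)
telegraph_states <- function(n, occupancy, tau) {
  if (occupancy <= 0) return(rep(FALSE, n))
  if (occupancy >= 1) return(rep(TRUE, n))
  p_on <- occupancy / tau
  p_off <- (1 - occupancy) / tau
  s <- logical(n)
  s[1] <- stats::runif(1) < occupancy
  if (n >= 2) {
    for (t in 2:n) {
      s[t] <- if (s[t - 1]) stats::runif(1) >= p_off else stats::runif(1) < p_on
    }
  }
  target <- round(n * occupancy)
  excess <- sum(s) - target
  if (excess > 0) {
    flip <- sample(which(s), excess)
    s[flip] <- FALSE
  } else if (excess < 0) {
    flip <- sample(which(!s), -excess)
    s[flip] <- TRUE
  }
  s
}

#' Sample a conformer ensemble from a fixture
#'
#' Frames are the reference pose plus independent isotropic Gaussian
#' displacements; each intermittent bond's donor is re-placed at its on/off
#' distance from the (displaced) acceptor following a two-state telegraph
#' process that realizes the target occupancy.
#'
#' @param fixture a `fixture` from [build_complex()].
#' @param n_frames,sigma,seed optional overrides of the spec values.
#' @return a `conformer_ensemble`; attribute `bond_states` is a logical
#'   matrix (frames x bonds) of the telegraph states.
#' @export
sample_ensemble <- function(fixture, n_frames = NULL, sigma = NULL, seed = NULL) {
  spec <- fixture$spec
  if (is.null(n_frames)) n_frames <- spec$n_frames
  if (is.null(sigma)) sigma <- spec$fluctuation_sigma
  if (is.null(seed)) seed <- spec$seed
  complex <- fixture$complex
  ref <- coords(complex)
  nat <- nrow(ref)
  set.seed(seed)
  bonds <- fixture$truth$bonds
  states <- if (length(bonds) > 0) {
    vapply(bonds, function(b) telegraph_states(n_frames, b$occupancy,
                                               spec$telegraph_tau),
           logical(n_frames))
  } else matrix(logical(0), nrow = n_frames, ncol = 0)
  if (n_frames == 1) states <- matrix(states, nrow = 1)
  drow <- vapply(bonds, function(b) match(b$donor, complex$atoms$serial), integer(1))
  arow <- vapply(bonds, function(b) match(b$acceptor, complex$atoms$serial), integer(1))
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    xyz <- ref + matrix(stats::rnorm(nat * 3, sd = sigma), nat, 3)
    for (bi in seq_along(bonds)) {
      d <- if (states[f, bi]) bonds[[bi]]$d_on else bonds[[bi]]$d_off
      u <- ref[drow[bi], ] - ref[arow[bi], ]
      u <- u / sqrt(sum(u^2))
      xyz[drow[bi], ] <- xyz[arow[bi], ] + d * u
    }
    frames[[f]] <- xyz
  }
  ens <- conformer_ensemble(complex, frames, stride = spec$stride)
  attr(ens, "bond_states") <- states
  ens
}

#' Emit synthetic high-level energy records for an ensemble
#'
#' Stand-ins for externally computed high-level (e.g. quantum-chemical)
#' gas-phase binding energies and forces, derived from the MM values.
#'
#' @param ensemble a `conformer_ensemble` of a complex.
#' @param mode `"mm_identity"`, `"mm_plus_offset"` or `"mm_plus_noise"`.
#' @param offset kcal/mol, for `mm_plus_offset`.
#' @param noise_sd kcal/mol, for `mm_plus_noise`.
#' @param seed RNG seed for the noise mode.
#' @param with_forces also emit per-atom forces for complex, receptor and
#'   ligand (analytic MM forces, perturbed consistently with the mode:
#'   constant energy offsets leave forces unchanged).
#' @param force_noise_sd kcal/(mol A) noise added per force component in
#'   `mm_plus_noise` mode.
#' @param ... passed to [energy_model()] for the force calculation.
#' @return a `highlevel_records`.
#' @export
emit_highlevel_records <- function(ensemble, mode = c("mm_identity", "mm_plus_offset",
                                                      "mm_plus_noise"),
                                   offset = 0, noise_sd = 0, seed = 1,
                                   with_forces = FALSE, force_noise_sd = 0, ...) {
  mode <- match.arg(mode)
  complex <- ensemble$topology
  set.seed(seed)
  e_mm <- vapply(seq_along(ensemble$frames), function(i) {
    gas_phase_binding(complex, ensemble$frames[[i]])$total
  }, numeric(1))
  e_out <- switch(mode,
    mm_identity = e_mm,
    mm_plus_offset = e_mm + offset,
    mm_plus_noise = e_mm + stats::rnorm(length(e_mm), sd = noise_sd))
  forces <- NULL
  if (with_forces) {
    rec <- extract_component(complex, "receptor")
    lig <- extract_component(complex, "ligand")
    rows <- partition_rows(complex)
    forces <- lapply(seq_along(ensemble$frames), function(i) {
      f <- ensemble$frames[[i]]
      fs <- list(complex = mm_forces(complex, f, ...),
                 receptor = mm_forces(rec, f[rows$receptor, , drop = FALSE], ...),
                 ligand = mm_forces(lig, f[rows$ligand, , drop = FALSE], ...))
      if (mode == "mm_plus_noise" && force_noise_sd > 0) {
        fs <- lapply(fs, function(m) m + matrix(stats::rnorm(length(m),
                                                             sd = force_noise_sd),
                                                nrow(m), 3))
      }
      fs
    })
    names(forces) <- as.character(ensemble$times)
  }
  highlevel_records(ensemble$times, e_out, forces)
}

# --- toy alchemical transformations with closed-form free energies --------

sample_observable <- function(n, energy, dvdl, x0, proposal_sd, T = 300,
                              burnin = 200, thin = 5) {
  x <- x0
  e <- energy(x)
  kT <- bindfe_constants$kB * T
  out <- numeric(n)
  total <- burnin + n * thin
  j <- 0
  for (t in seq_len(total)) {
    xp <- x + stats::rnorm(length(x), sd = proposal_sd)
    ep <- energy(xp)
    if (ep <= e || stats::runif(1) < exp(-(ep - e) / kT)) { x <- xp; e <- ep }
    if (t > burnin && (t - burnin) %% thin == 0) {
      j <- j + 1
      out[j] <- dvdl(x)
    }
  }
  out
}

#' Metropolis-sampled dV/dlambda tables for toy transformations
#'
#' Toy alchemical transformations with closed-form free-energy changes,
#' sampled with seeded Metropolis Monte Carlo at each quadrature node:
#' \describe{
#'   \item{harmonic_k}{1D oscillator with spring constant interpolated
#'     `k0 -> k1`; exact dG = (kT/2) ln(k1/k0).}
#'   \item{decharge / recharge}{1D oscillator with a linear field coupling
#'     `a(lambda) x`; decharge scales `a` from `c` to 0
#'     (dG = +c^2/(2 k)), recharge from 0 to `c` (dG = -c^2/(2 k)).}
#'   \item{softcore_appear}{3D particle in a harmonic restraint with an
#'     appearing soft-core LJ site at the origin; the reference dG is
#'     computed by deterministic radial quadrature of the partition
#'     functions.}
#' }
#'
#' @param transformation one of the above.
#' @param n_nodes Gauss-Legendre nodes.
#' @param n_per_node samples recorded per node.
#' @param seed RNG seed (node seeds derived deterministically).
#' @param T temperature, K.
#' @param k0,k1 spring constants, kcal/(mol A^2).
#' @param c_field field strength, kcal/(mol A).
#' @param rmin,eps soft-core LJ pair parameters.
#' @param sc a [softcore_params()] for `softcore_appear`.
#' @param thin Metropolis steps between recorded samples.
#' @return list with `stage` (a `ti_stage`; label decharge/recharge for the
#'   field transformations, vdw_softcore otherwise), `truth` (closed-form
#'   dG, kcal/mol).
#' @export
emit_ti_samples <- function(transformation = c("harmonic_k", "decharge", "recharge",
                                               "softcore_appear"),
                            n_nodes = 9, n_per_node = 500, seed = 1, T = 300,
                            k0 = 1, k1 = 4, c_field = 1, rmin = 3.8, eps = 0.5,
                            sc = softcore_params(direction = "appearing"),
                            thin = 5) {
  transformation <- match.arg(transformation)
  g <- gauss_nodes(n_nodes)
  kT <- bindfe_constants$kB * T
  samples <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) {
    lam <- g$nodes[i]
    set.seed(seed * 1000L + i)
    if (transformation == "harmonic_k") {
      klam <- k0 + lam * (k1 - k0)
      en <- function(x) 0.5 * klam * x^2
      dv <- function(x) 0.5 * (k1 - k0) * x^2
      samples[[i]] <- sample_observable(n_per_node, en, dv, 0,
                                        proposal_sd = sqrt(kT / klam), T = T,
                                        thin = thin)
    } else if (transformation %in% c("decharge", "recharge")) {
      a <- if (transformation == "decharge") (1 - lam) * c_field else lam * c_field
      dadl <- if (transformation == "decharge") -c_field else c_field
      en <- function(x) 0.5 * k0 * x^2 + a * x
      dv <- function(x) dadl * x
      samples[[i]] <- sample_observable(n_per_node, en, dv, -a / k0,
                                        proposal_sd = sqrt(kT / k0), T = T,
                                        thin = thin)
    } else {
      en <- function(x) {
        r <- sqrt(sum(x^2))
        0.5 * k0 * sum(x^2) + softcore_lj(r, lam, sc, rmin, eps)$energy
      }
      dv <- function(x) softcore_lj(sqrt(sum(x^2)), lam, sc, rmin, eps)$dvdl
      samples[[i]] <- sample_observable(n_per_node, en, dv, c(rmin, 0, 0),
                                        proposal_sd = sqrt(kT / k0), T = T,
                                        thin = thin)
    }
  }
  truth <- switch(transformation,
    harmonic_k = 0.5 * kT * log(k1 / k0),
    decharge = c_field^2 / (2 * k0),
    recharge = -c_field^2 / (2 * k0),
    softcore_appear = {
      zfun <- function(lam) {
        stats::integrate(function(r) {
          v <- 0.5 * k0 * r^2 + softcore_lj(r, lam, sc, rmin, eps)$energy
          4 * pi * r^2 * exp(-v / kT)
        }, 0, Inf, rel.tol = 1e-10)$value
      }
      -kT * log(zfun(1) / zfun(0))
    })
  label <- switch(transformation, decharge = "decharge", recharge = "recharge",
                  "vdw_softcore")
  list(stage = ti_stage(label, samples, nodes = g$nodes, weights = g$weights),
       truth = truth)
}

#' Emit a full three-stage toy mutation (decharge / soft-core vdW / recharge)
#'
#' A null mutation (`c_end = c_start`, identical LJ end states) has total
#' dG of exactly zero in the closed form.
#'
#' @param seed RNG seed.
#' @param c_start,c_end field strengths of the start and end states.
#' @param n_per_node samples per node.
#' @param ... passed to [emit_ti_samples()].
#' @return list with `stages` (list of three `ti_stage`s), `truth` (total).
#' @export
emit_three_stage <- function(seed = 1, c_start = 1, c_end = 1, n_per_node = 500,
                             ...) {
  s1 <- emit_ti_samples("decharge", seed = seed, c_field = c_start,
                        n_per_node = n_per_node, ...)
  s2 <- emit_ti_samples("softcore_appear", seed = seed + 1, eps = 0,
                        n_per_node = n_per_node, ...)
  s3 <- emit_ti_samples("recharge", seed = seed + 2, c_field = c_end,
                        n_per_node = n_per_node, ...)
  list(stages = list(s1$stage, s2$stage, s3$stage),
       truth = s1$truth + s2$truth + s3$truth)
}
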