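# Solute entropy change on binding from normal-mode analysis of minimized
# snapshots: ideal-gas translational (Sackur-Tetrode), rigid-rotor
# rotational, and quantum harmonic-oscillator vibrational entropies.

#' Minimize a frame under the configured energy model
#'
#' Conjugate gradients to a coarse gradient RMS, then quasi-Newton (BFGS)
#' refinement until the root-mean-square of the gradient elements is below
#' `tol`.  The returned energy is never above the starting energy.
#'
#' @param system a `molecular_system`.
#' @param frame starting coordinates (defaults to stored coordinates).
#' @param tol final gradient RMS tolerance, kcal/(mol A).
#' @param cg_tol gradient RMS at which conjugate gradients hand over.
#' @param max_cycles cap on refinement cycles (each up to 200 iterations).
#' @param ... passed to [energy_model()] (e.g. `gb = TRUE`).
#' @return list with `frame` (minimized coordinates), `energy`, `grms`,
#'   `converged`.
#' @export
minimize_frame <- function(system, frame = NULL, tol = 1e-4, cg_tol = 1e-2,
                           max_cycles = 60, ...) {
  if (is.null(frame)) frame <- coords(system)
  model <- energy_model(system, ...)
  n <- nrow(frame)
  fn <- function(p) model$energy(matrix(p, n, 3))
  gr <- function(p) as.vector(model$gradient(matrix(p, n, 3)))
  grms <- function(p) sqrt(mean(gr(p)^2))
  p <- as.vector(frame)
  if (grms(p) > cg_tol) {
    p <- stats::optim(p, fn, gr, method = "CG",
                      control = list(maxit = 500, reltol = 1e-12))$par
  }
  cycle <- 0
  while (grms(p) > tol && cycle < max_cycles) {
    res <- stats::optim(p, fn, gr, method = "BFGS",
                        control = list(maxit = 200, reltol = 1e-14))
    if (sum(abs(res$par - p)) == 0 && grms(p) > tol) break
    p <- res$par
    cycle <- cycle + 1
  }
  final_rms <- grms(p)
  if (final_rms > tol)
    stop(sprintf("minimization failed to converge: gradient RMS %.3e > tol %.3e",
                 final_rms, tol))
  list(frame = matrix(p, n, 3), energy = fn(p), grms = final_rms, converged = TRUE)
}

is_linear_geometry <- function(xyz, masses, tol = 1e-8) {
  if (nrow(xyz) <= 2) return(TRUE)
  com <- colSums(xyz * masses) / sum(masses)
  xc <- sweep(xyz, 2, com)
  inertia <- inertia_tensor(xc, masses)
  ev <- eigen(inertia, symmetric = TRUE, only.values = TRUE)$values
  min(ev) / max(ev) < tol
}

inertia_tensor <- function(xc, masses) {
  ix <- sum(masses * (xc[, 2]^2 + xc[, 3]^2))
  iy <- sum(masses * (xc[, 1]^2 + xc[, 3]^2))
  iz <- sum(masses * (xc[, 1]^2 + xc[, 2]^2))
  ixy <- -sum(masses * xc[, 1] * xc[, 2])
  ixz <- -sum(masses * xc[, 1] * xc[, 3])
  iyz <- -sum(masses * xc[, 2] * xc[, 3])
  matrix(c(ix, ixy, ixz, ixy, iy, iyz, ixz, iyz, iz), 3, 3)
}

#' Vibrational normal-mode frequencies of a minimized frame
#'
#' Builds the mass-weighted Hessian by central finite differences of the
#' analytic gradient, diagonalizes it, and removes the near-zero
#' translational/rotational modes (six for a nonlinear solute, five for a
#' linear one, three for a single atom).
#'
#' @param system a `molecular_system`.
#' @param frame minimized coordinates.
#' @param step finite-difference step, A.
#' @param zero_threshold modes with |frequency| below this (cm^-1) are
#'   treated as rigid-body modes.
#' @param ... passed to [energy_model()].
#' @return numeric vector of vibrational frequencies in cm^-1, increasing;
#'   attribute `all_frequencies` carries the full signed spectrum (negative
#'   entries flag imaginary modes).
#' @export
normal_modes <- function(system, frame = NULL, step = 1e-4, zero_threshold = 1.0, ...) {
  if (is.null(frame)) frame <- coords(system)
  model <- energy_model(system, ...)
  n <- nrow(frame)
  dim3 <- 3 * n
  H <- matrix(0, dim3, dim3)
  p0 <- as.vector(frame)
  for (k in seq_len(dim3)) {
    pp <- p0; pp[k] <- pp[k] + step
    pm <- p0; pm[k] <- pm[k] - step
    gp <- as.vector(model$gradient(matrix(pp, n, 3)))
    gm <- as.vector(model$gradient(matrix(pm, n, 3)))
    H[, k] <- (gp - gm) / (2 * step)
  }
  H <- (H + t(H)) / 2
  m3 <- rep(system$atoms$mass, times = 3)   # column-major coordinate flattening
  H <- H / sqrt(outer(m3, m3))
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values   # kcal/mol/A^2/amu
  omega2 <- ev * bindfe_constants$freq_conv                      # s^-2
  freq <- sign(omega2) * sqrt(abs(omega2)) / (2 * pi * bindfe_constants$c_cm)
  freq <- sort(freq)
  masses <- system$atoms$mass
  expected_zero <- if (n == 1) 3 else if (is_linear_geometry(frame, masses)) 5 else 6
  near_zero <- abs(freq) < zero_threshold
  if (sum(near_zero) > expected_zero)
    warning(sprintf("%d near-zero modes (expected %d): minimization may be incomplete",
                    sum(near_zero), expected_zero))
  vib <- freq[!near_zero]
  if (any(vib < 0))
    warning(sprintf("%d imaginary mode(s) dropped from the vibrational spectrum",
                    sum(vib < 0)))
  structure(vib[vib > 0], all_frequencies = freq)
}

# --- statistical-thermodynamic entropies, cal/(mol K) ----------------------

#' Ideal-gas translational entropy (Sackur-Tetrode)
#' @param mass total mass, amu.
#' @param T temperature, K.
#' @param pressure standard-state pressure, Pa (default 1 atm).
#' @return cal/(mol K)
#' @export
translational_entropy <- function(mass, T = 300, pressure = 101325) {
  cc <- bindfe_constants
  m <- mass * cc$amu_kg
  q <- (2 * pi * m * cc$kB_J * T / cc$h^2)^1.5 * (cc$kB_J * T / pressure)
  cc$R_cal * (log(q) + 2.5)
}

#' Rigid-rotor rotational entropy
#' @param xyz coordinates, A.
#' @param masses amu.
#' @param T kelvin.
#' @param sigma rotational symmetry number.
#' @return cal/(mol K); 0 for a single atom.
#' @export
rotational_entropy <- function(xyz, masses, T = 300, sigma = 1) {
  cc <- bindfe_constants
  if (nrow(xyz) == 1) return(0)
  com <- colSums(xyz * masses) / sum(masses)
  xc <- sweep(xyz, 2, com)
  inertia <- inertia_tensor(xc, masses) * cc$amu_kg * 1e-20   # kg m^2
  ev <- sort(eigen(inertia, symmetric = TRUE, only.values = TRUE)$values)
  if (is_linear_geometry(xyz, masses)) {
    I <- ev[3]
    q <- 8 * pi^2 * I * cc$kB_J * T / (sigma * cc$h^2)
    cc$R_cal * (log(q) + 1)
  } else {
    q <- sqrt(pi * prod(ev)) / sigma * (8 * pi^2 * cc$kB_J * T / cc$h^2)^1.5
    cc$R_cal * (log(q) + 1.5)
  }
}

#' Quantum harmonic-oscillator vibrational entropy
#' @param frequencies cm^-1 (positive).
#' @param T kelvin.
#' @return cal/(mol K)
#' @export
vibrational_entropy <- function(frequencies, T = 300) {
  cc <- bindfe_constants
  if (length(frequencies) == 0) return(0)
  theta <- cc$h * cc$c_cm * frequencies / cc$kB_J   # K
  x <- theta / T
  cc$R_cal * sum(x / (exp(x) - 1) - log(1 - exp(-x)))
}

species_entropy <- function(system, frame = NULL, T = 300, minimize = TRUE,
                            tol = 1e-4, ...) {
  if (nrow(system$atoms) == 0) stop("cannot compute entropy of an empty species")
  if (is.null(frame)) frame <- coords(system)
  if (minimize && nrow(system$atoms) > 1)
    frame <- minimize_frame(system, frame, tol = tol, ...)$frame
  freqs <- if (nrow(system$atoms) > 1) normal_modes(system, frame, ...) else numeric(0)
  s_t <- translational_entropy(sum(system$atoms$mass), T)
  s_r <- rotational_entropy(frame, system$atoms$mass, T)
  s_v <- vibrational_entropy(freqs, T)
  list(translational = s_t, rotational = s_r, vibrational = s_v,
       total = s_t + s_r + s_v)
}

#' Binding entropy from normal-mode analysis of minimized snapshots
#'
#' For each sampled snapshot the complex, receptor and ligand (coordinates
#' shared with the complex frame) are minimized and analysed; the entropy
#' change on binding is `S(complex) - S(receptor) - S(ligand)`, averaged
#' over snapshots.  Snapshots whose minimization fails are skipped with a
#' count; more than half skipped is an error.
#'
#' @param ensemble a `conformer_ensemble` of a complex.
#' @param stride sampling stride, ps (multiple of the frame stride).
#' @param T temperature, K.
#' @param tol minimization gradient RMS tolerance.
#' @param gb use the smooth implicit-solvent term during minimization.
#' @param ... passed to [energy_model()].
#' @return object of class `entropy_result`: per-component binding entropies
#'   (cal/(mol K)), `minus_T_delta_S` (kcal/mol at `T`), `n_snapshots`,
#'   `n_skipped`.
#' @export
binding_entropy <- function(ensemble, stride = NULL, T = 300, tol = 1e-4,
                            gb = TRUE, ...) {
  complex <- ensemble$topology
  stopifnot(complex$role == "complex")
  rows <- partition_rows(complex)
  if (length(rows$receptor) == 0 || length(rows$ligand) == 0)
    stop("cannot compute binding entropy with an empty receptor or ligand")
  sel <- select_frames(ensemble, stride)
  comps <- c("translational", "rotational", "vibrational", "total")
  acc <- matrix(0, 0, 4, dimnames = list(NULL, comps))
  skipped <- 0
  for (i in sel) {
    frame <- ensemble$frames[[i]]
    res <- tryCatch({
      sc <- species_entropy(set_coords(complex, frame), T = T, tol = tol, gb = gb, ...)
      rec <- extract_component(complex, "receptor", frame)
      lig <- extract_component(complex, "ligand", frame)
      sr <- species_entropy(rec, T = T, tol = tol, gb = gb, ...)
      sl <- species_entropy(lig, T = T, tol = tol, gb = gb, ...)
      vapply(comps, function(k) sc[[k]] - sr[[k]] - sl[[k]], numeric(1))
    }, error = function(e) NULL)
    if (is.null(res)) skipped <- skipped + 1 else acc <- rbind(acc, res)
  }
  if (skipped > length(sel) / 2)
    stop(sprintf("minimization failed for %d of %d snapshots", skipped, length(sel)))
  ds <- colMeans(acc)
  structure(list(translational = ds[["translational"]], rotational = ds[["rotational"]],
                 vibrational = ds[["vibrational"]], total = ds[["total"]],
                 minus_T_delta_S = -T * ds[["total"]] / 1000,
                 temperature = T, n_snapshots = nrow(acc), n_skipped = skipped),
            class = "entropy_result")
}

#' A zero-entropy placeholder (rigid-solute convention)
#'
#' Useful when assembling enthalpy-only binding free energies.
#' @param T temperature, K.
#' @return an `entropy_result` with all components zero.
#' @export
zero_entropy <- function(T = 300) {
  structure(list(translational = 0, rotational = 0, vibrational = 0, total = 0,
                 minus_T_delta_S = 0, temperature = T, n_snapshots = 0L,
                 n_skipped = 0L),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf(paste0("<entropy_result: dS trans %.2f, rot %.2f, vib %.2f, total %.2f",
                     " cal/(mol K); -T.dS = %.3f kcal/mol at %g K (%d snapshots)>\n"),
              x$translational, x$rotational, x$vibrational, x$total,
              x$minus_T_delta_S, x$temperature, x$n_snapshots))
  invisible(x)
}
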