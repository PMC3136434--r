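# Differentiable molecular-mechanics energy model with analytic gradient:
# nonbonded Coulomb + LJ (1-2/1-3 excluded, 1-4 unscaled), harmonic bond
# terms (reference lengths from the system's stored coordinates), and an
# optional smooth generalized-Born-style implicit-solvent term with fixed
# per-atom Born radii.  Used for snapshot minimization, normal modes and
# analytic MM forces.

#' Build a differentiable energy model for a system
#'
#' @param system a `molecular_system`; its stored coordinates define the
#'   reference bond lengths of the harmonic bond terms.
#' @param bond_k harmonic bond force constant, kcal/(mol A^2).
#' @param gb include the smooth implicit-solvent term (fixed Born radii equal
#'   to the atomic `lj_radius`; atoms with zero radius are skipped).
#' @param eps_solvent solvent dielectric of the implicit term.
#' @return list with functions `energy(xyz)` (kcal/mol) and `gradient(xyz)`
#'   (n x 3 matrix, kcal/(mol A)).
#' @export
energy_model <- function(system, bond_k = 300, gb = FALSE, eps_solvent = 80) {
  a <- system$atoms
  n <- nrow(a)
  excl <- nonbonded_exclusions(system)
  pair_mask <- upper.tri(matrix(0, n, n)) & !excl
  qq <- bindfe_constants$coulomb * outer(a$charge, a$charge)
  rmin <- outer(a$lj_radius, a$lj_radius, "+")
  eps <- sqrt(outer(a$lj_epsilon, a$lj_epsilon))
  bidx <- matrix(match(system$bonds, a$serial), ncol = 2)
  ref <- coords(system)
  if (nrow(bidx) > 0) {
    r0 <- sqrt(rowSums((ref[bidx[, 1], , drop = FALSE] - ref[bidx[, 2], , drop = FALSE])^2))
  } else r0 <- numeric(0)
  gb_scale <- if (gb) (1 - 1 / eps_solvent) else 0
  u_born <- outer(a$lj_radius, a$lj_radius)      # R_i R_j
  gb_ok <- u_born > 0
  gb_self <- if (gb) {
    keep <- a$lj_radius > 0
    -gb_scale * bindfe_constants$born * sum(a$charge[keep]^2 / a$lj_radius[keep])
  } else 0

  pair_terms <- function(xyz) {
    dx <- outer(xyz[, 1], xyz[, 1], "-")
    dy <- outer(xyz[, 2], xyz[, 2], "-")
    dz <- outer(xyz[, 3], xyz[, 3], "-")
    r <- sqrt(dx * dx + dy * dy + dz * dz)
    list(dx = dx, dy = dy, dz = dz, r = r)
  }

  energy <- function(xyz) {
    p <- pair_terms(xyz)
    r <- ifelse(p$r == 0, Inf, p$r)
    e <- 0
    if (n >= 2) {
      s6 <- (rmin / r)^6
      e <- sum((qq / r)[pair_mask]) + sum((eps * (s6 * s6 - 2 * s6))[pair_mask])
      if (gb) {
        f <- sqrt(p$r^2 + u_born * exp(-p$r^2 / (4 * u_born)))
        gbp <- upper.tri(f) & gb_ok
        e <- e - gb_scale * bindfe_constants$coulomb * sum((qq / bindfe_constants$coulomb / f)[gbp])
      }
    }
    if (nrow(bidx) > 0) {
      rb <- sqrt(rowSums((xyz[bidx[, 1], , drop = FALSE] - xyz[bidx[, 2], , drop = FALSE])^2))
      e <- e + 0.5 * bond_k * sum((rb - r0)^2)
    }
    e + gb_self
  }

  gradient <- function(xyz) {
    g <- matrix(0, n, 3)
    if (n >= 2) {
      p <- pair_terms(xyz)
      r <- ifelse(p$r == 0, Inf, p$r)
      # dE/dr for every (i,j); zero out excluded pairs and the diagonal
      s6 <- (rmin / r)^6
      dEdr <- -qq / r^2 - 12 * (eps / r) * (s6 * s6 - s6)
      if (gb) {
        ex <- exp(-p$r^2 / (4 * ifelse(gb_ok, u_born, 1)))
        f <- sqrt(p$r^2 + u_born * ex)
        dfdr <- ifelse(f > 0, p$r * (1 - ex / 4) / f, 0)
        dgb <- gb_scale * (qq / f^2) * dfdr
        dgb[!gb_ok] <- 0
        dEdr_gb <- dgb
      } else dEdr_gb <- 0
      w <- dEdr
      w[excl] <- 0
      w <- w + dEdr_gb * (!diag(n))          # GB has no 1-2/1-3 exclusion
      if (gb) w[!gb_ok] <- ifelse(excl[!gb_ok], 0, dEdr[!gb_ok])
      wr <- w / r
      g[, 1] <- rowSums(wr * p$dx)
      g[, 2] <- rowSums(wr * p$dy)
      g[, 3] <- rowSums(wr * p$dz)
    }
    if (nrow(bidx) > 0) {
      d <- xyz[bidx[, 1], , drop = FALSE] - xyz[bidx[, 2], , drop = FALSE]
      rb <- sqrt(rowSums(d * d))
      fb <- bond_k * (rb - r0) / ifelse(rb == 0, Inf, rb)
      for (b in seq_len(nrow(bidx))) {
        g[bidx[b, 1], ] <- g[bidx[b, 1], ] + fb[b] * d[b, ]
        g[bidx[b, 2], ] <- g[bidx[b, 2], ] - fb[b] * d[b, ]
      }
    }
    g
  }

  list(energy = energy, gradient = gradient, n_atoms = n,
       gb = gb, bond_k = bond_k, eps_solvent = eps_solvent)
}

#' Analytic MM forces on every atom of a species
#'
#' Negative gradient of the configured energy model, kcal/(mol A).
#'
#' @param system a `molecular_system`.
#' @param frame optional coordinate matrix (defaults to stored coordinates).
#' @param ... passed to [energy_model()].
#' @return n x 3 matrix of forces.
#' @export
mm_forces <- function(system, frame = NULL, ...) {
  if (is.null(frame)) frame <- coords(system)
  -energy_model(system, ...)$gradient(frame)
}
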