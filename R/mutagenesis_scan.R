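# Computational alanine and glycine scanning by geometric side-chain
# truncation on existing snapshots (no re-minimization, no resampling).
#
# Alanine mutants: every side-chain atom beyond C-beta is removed and the
# gamma atom is replaced by a hydrogen at the configured C-H length along
# the C-beta -> C-gamma bond.  Glycine mutants (for hotspot alanines)
# truncate at C-alpha in the same way.

BACKBONE_NAMES <- c("N", "CA", "C", "O", "H", "HN", "HA", "HA2", "HA3", "OXT")

default_cap_h <- function(template, serial, name, pos, charge = 0,
                          lj_radius = 1.387, lj_epsilon = 0.0157) {
  h <- template
  h$serial <- serial; h$name <- name; h$element <- "H"
  h$x <- pos[1]; h$y <- pos[2]; h$z <- pos[3]
  h$charge <- charge; h$lj_radius <- lj_radius; h$lj_epsilon <- lj_epsilon
  h$mass <- 1.008
  h
}

ligand_residue_atoms <- function(complex, residue) {
  rows <- partition_rows(complex)
  lig <- complex$atoms[rows$ligand, , drop = FALSE]
  res <- lig[lig$resno == residue, , drop = FALSE]
  if (nrow(res) == 0) stop("residue ", residue, " is not a ligand residue")
  res
}

truncate_side_chain <- function(complex, residue, stem_name, ch_length, h_name,
                                h_charge, h_lj_radius, h_lj_epsilon, new_resid) {
  res <- ligand_residue_atoms(complex, residue)
  if (res$resid[1] == "GLY")
    stop("glycine has no side chain to truncate at residue ", residue)
  stem <- res[res$name == stem_name, , drop = FALSE]
  if (nrow(stem) == 0)
    stop(sprintf("residue %d (%s) has no %s atom", residue, res$resid[1], stem_name))
  # atoms of this residue beyond the stem: side-chain atoms excluding the
  # stem itself and (for CB stems) the backbone
  side <- res[!(res$name %in% c(BACKBONE_NAMES, stem_name)), , drop = FALSE]
  if (stem_name == "CA") {
    # glycine truncation also removes CB and anything beyond
    side <- res[!(res$name %in% BACKBONE_NAMES), , drop = FALSE]
  }
  if (nrow(side) == 0)
    stop(sprintf("residue %d (%s) has no side-chain atoms beyond %s",
                 residue, res$resid[1], stem_name))
  # gamma-type atom: a removed atom bonded to the stem
  b <- complex$bonds
  nb <- c(b[b[, 1] == stem$serial, 2], b[b[, 2] == stem$serial, 1])
  gamma_serial <- intersect(nb, side$serial)
  if (length(gamma_serial) == 0)
    stop(sprintf("no atom bonded to %s to replace in residue %d", stem_name, residue))
  gamma <- complex$atoms[complex$atoms$serial == gamma_serial[1], , drop = FALSE]
  u <- c(gamma$x - stem$x, gamma$y - stem$y, gamma$z - stem$z)
  u <- u / sqrt(sum(u^2))
  hpos <- c(stem$x, stem$y, stem$z) + ch_length * u
  hrow <- default_cap_h(stem, max(complex$atoms$serial) + 1L, h_name, hpos,
                        h_charge, h_lj_radius, h_lj_epsilon)
  drop <- side$serial
  atoms <- complex$atoms[!(complex$atoms$serial %in% drop), , drop = FALSE]
  atoms$resid[atoms$resno == residue & atoms$serial %in% res$serial] <- new_resid
  atoms <- rbind(atoms, hrow)
  bonds <- complex$bonds[!(complex$bonds[, 1] %in% drop |
                           complex$bonds[, 2] %in% drop), , drop = FALSE]
  bonds <- rbind(bonds, c(stem$serial, hrow$serial))
  molecular_system(atoms, bonds, role = "complex",
                   partition = list(receptor = complex$partition$receptor,
                                    ligand = setdiff(atoms$serial,
                                                     complex$partition$receptor)))
}

#' Build an alanine mutant by side-chain truncation
#'
#' All side-chain atoms beyond C-beta are removed; one hydrogen is placed on
#' the C-beta -> C-gamma unit vector at `ch_length` and given alanine
#' H-beta-like parameters.  Backbone and receptor are untouched; coordinates
#' of all retained atoms are bit-identical to the input.
#'
#' @param complex a complex `molecular_system`.
#' @param residue ligand residue index.
#' @param frame optional coordinate matrix applied before truncation.
#' @param ch_length C-H placement length, A.
#' @param h_charge,h_lj_radius,h_lj_epsilon parameters of the placed
#'   hydrogen.
#' @return the mutant complex (with coordinates embedded).
#' @export
make_alanine_mutant <- function(complex, residue, frame = NULL, ch_length = 1.09,
                                h_charge = 0, h_lj_radius = 1.487,
                                h_lj_epsilon = 0.0157) {
  if (!is.null(frame)) complex <- set_coords(complex, frame)
  res <- ligand_residue_atoms(complex, residue)
  if (res$resid[1] == "ALA")
    stop("residue ", residue, " is already alanine; use make_glycine_mutant")
  truncate_side_chain(complex, residue, "CB", ch_length, "HB1",
                      h_charge, h_lj_radius, h_lj_epsilon, "ALA")
}

#' Build a glycine mutant by truncation at C-alpha
#'
#' @inheritParams make_alanine_mutant
#' @export
make_glycine_mutant <- function(complex, residue, frame = NULL, ch_length = 1.09,
                                h_charge = 0, h_lj_radius = 1.387,
                                h_lj_epsilon = 0.0157) {
  if (!is.null(frame)) complex <- set_coords(complex, frame)
  truncate_side_chain(complex, residue, "CA", ch_length, "HA2",
                      h_charge, h_lj_radius, h_lj_epsilon, "GLY")
}

species_solvation <- function(system, settings, gamma, offset) {
  list(polar = as.numeric(solve_pb(system, settings = settings)),
       nonpolar = nonpolar_term(attr(sasa(system,
                                          probe_radius = settings$probe_radius),
                                     "total"), gamma, offset))
}

frame_components <- function(complex, settings, gamma, offset, receptor_solv) {
  gas <- gas_phase_binding(complex)
  sc <- species_solvation(complex, settings, gamma, offset)
  sl <- species_solvation(extract_component(complex, "ligand"), settings, gamma, offset)
  c(el = gas$el, vdw = gas$vdw,
    polar = sc$polar - receptor_solv$polar - sl$polar,
    nonpolar = sc$nonpolar - receptor_solv$nonpolar - sl$nonpolar)
}

#' Computational alanine/glycine scan over an ensemble
#'
#' For each position, mutant and wild type are evaluated on otherwise
#' identical coordinates frame by frame; the enthalpic ddG (mutant minus
#' wild type) is averaged over frames.  With `mode = "auto"`, positions
#' whose wild type is alanine receive the glycine mutation (hotspot
#' convention); all others the alanine mutation.  The entropy term is
#' excluded: scan deltas are enthalpic.
#'
#' @param ensemble a `conformer_ensemble` of a complex.
#' @param positions ligand residue indices to scan (default all).
#' @param stride analysis stride, ps.
#' @param mode `"auto"`, `"ala"` or `"gly"`.
#' @param settings [pb_settings()].
#' @param gamma,offset nonpolar parameters.
#' @param ch_length C-H placement length, A.
#' @return data.frame of class `scan_result` with one row per position:
#'   `position`, `label` (01-15 style), `wild_type`, `mutation`, `ddG`,
#'   `d_el`, `d_vdw`, `d_polar`, `d_nonpolar` (kcal/mol), `n_snapshots`.
#' @export
residue_scan <- function(ensemble, positions = NULL, stride = NULL,
                         mode = c("auto", "ala", "gly"),
                         settings = pb_settings(), gamma = 0.00542,
                         offset = 0.92, ch_length = 1.09) {
  mode <- match.arg(mode)
  complex <- ensemble$topology
  stopifnot(complex$role == "complex")
  rows <- partition_rows(complex)
  lig <- complex$atoms[rows$ligand, , drop = FALSE]
  if (is.null(positions)) positions <- sort(unique(lig$resno))
  sel <- select_frames(ensemble, stride)
  comp_names <- c("el", "vdw", "polar", "nonpolar")
  acc <- lapply(positions, function(p) matrix(0, 0, 4, dimnames = list(NULL, comp_names)))
  names(acc) <- as.character(positions)
  wt_res <- vapply(positions, function(p) lig$resid[lig$resno == p][1], character(1))
  mut_kind <- vapply(seq_along(positions), function(i) {
    switch(mode, ala = "ala", gly = "gly",
           auto = if (wt_res[i] == "ALA") "gly" else "ala")
  }, character(1))
  for (fi in sel) {
    wt <- set_coords(complex, ensemble$frames[[fi]])
    rec_solv <- species_solvation(extract_component(wt, "receptor"),
                                  settings, gamma, offset)
    wt_comp <- frame_components(wt, settings, gamma, offset, rec_solv)
    for (i in seq_along(positions)) {
      p <- positions[i]
      if (mut_kind[i] == "ala" && wt_res[i] == "ALA") {
        acc[[i]] <- rbind(acc[[i]], c(el = 0, vdw = 0, polar = 0, nonpolar = 0))
        next
      }
      mut <- if (mut_kind[i] == "gly")
        make_glycine_mutant(wt, p, ch_length = ch_length)
      else
        make_alanine_mutant(wt, p, ch_length = ch_length)
      mut_comp <- frame_components(mut, settings, gamma, offset, rec_solv)
      acc[[i]] <- rbind(acc[[i]], mut_comp - wt_comp)
    }
  }
  out <- do.call(rbind, lapply(seq_along(positions), function(i) {
    m <- colMeans(acc[[i]])
    data.frame(position = positions[i],
               label = sprintf("%02d", positions[i]),
               wild_type = wt_res[i], mutation = mut_kind[i],
               ddG = sum(m), d_el = m[["el"]], d_vdw = m[["vdw"]],
               d_polar = m[["polar"]], d_nonpolar = m[["nonpolar"]],
               n_snapshots = nrow(acc[[i]]))
  }))
  out <- out[order(out$position), ]
  rownames(out) <- NULL
  class(out) <- c("scan_result", "data.frame")
  out
}
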