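# Core domain types: molecular systems, conformer ensembles, parameter tables,
# PDB I/O and ligand truncation.
#
# A molecular_system stores its atoms as a data.frame (one row per atom) with
# columns serial, name, element, resno, resid, chain, x, y, z, charge,
# lj_radius, lj_epsilon, mass.  Bonds are a two-column integer matrix of atom
# serials.  A complex additionally carries a receptor/ligand partition as two
# disjoint serial sets covering all atoms.

ATOM_COLS <- c("serial", "name", "element", "resno", "resid", "chain",
               "x", "y", "z", "charge", "lj_radius", "lj_epsilon", "mass")

#' Construct a molecular system
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`, `resno`
#'   (1-based residue index), `resid` (3-letter residue code), `chain`,
#'   `x`, `y`, `z` (A), `charge` (e), `lj_radius` (A, r_min/2 convention),
#'   `lj_epsilon` (kcal/mol), `mass` (amu).
#' @param bonds two-column integer matrix of bonded atom serial pairs.
#' @param role one of `"receptor"`, `"ligand"`, `"complex"`.
#' @param partition for `role = "complex"`, a list with integer vectors
#'   `receptor` and `ligand` of atom serials forming a disjoint exact cover.
#' @return An object of class `molecular_system`.
#' @export
molecular_system <- function(atoms, bonds = NULL, role = c("complex", "receptor", "ligand"),
                             partition = NULL) {
  role <- match.arg(role)
  stopifnot(is.data.frame(atoms))
  missing_cols <- setdiff(ATOM_COLS, names(atoms))
  if (length(missing_cols) > 0)
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  atoms <- atoms[, ATOM_COLS]
  rownames(atoms) <- NULL
  if (anyDuplicated(atoms$serial))
    stop("atom serials must be unique")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom positions must be finite")
  if (any(atoms$lj_radius < 0) || any(atoms$lj_epsilon < 0))
    stop("Lennard-Jones radius and well depth must be >= 0")
  if (any(atoms$mass <= 0))
    stop("atomic masses must be > 0")
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) > 0 && !all(bonds %in% atoms$serial))
    stop("bond list references unknown atom serials")
  if (role == "complex") {
    if (is.null(partition))
      stop("a complex requires a receptor/ligand partition")
    part <- lapply(partition[c("receptor", "ligand")], as.integer)
    both <- c(part$receptor, part$ligand)
    if (anyDuplicated(both) || !setequal(both, atoms$serial))
      stop("partition must be a disjoint exact cover of all atom serials")
    partition <- part
  } else {
    partition <- NULL
  }
  structure(list(atoms = atoms, bonds = bonds, role = role, partition = partition),
            class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  cat(sprintf("<molecular_system: %s, %d atoms, %d residues, %d bonds, net charge %+.3f e>\n",
              x$role, nrow(x$atoms), length(unique(paste(x$atoms$chain, x$atoms$resno))),
              nrow(x$bonds), net_charge(x)))
  invisible(x)
}

#' Net charge of a system
#'
#' Algebraic sum of the partial charges, in elementary charge units.
#'
#' @param system a `molecular_system` (or bare atoms data.frame).
#' @return numeric scalar, e.
#' @export
net_charge <- function(system) {
  atoms <- if (inherits(system, "molecular_system")) system$atoms else system
  if (nrow(atoms) == 0) return(0)
  sum(atoms$charge)
}

#' Construct a conformer ensemble
#'
#' Ordered snapshots of one topology.  `frames` is a list of n_atoms x 3
#' coordinate matrices; `times` are ps, strictly increasing.
#'
#' @param topology a `molecular_system`.
#' @param frames list of coordinate matrices (n_atoms x 3, A).
#' @param times numeric vector of frame times, ps; defaults to
#'   `stride * (1:n)`.
#' @param stride ps between stored frames (metadata).
#' @return An object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(topology, frames, times = NULL, stride = NULL) {
  stopifnot(inherits(topology, "molecular_system"), is.list(frames), length(frames) >= 1)
  n_at <- nrow(topology$atoms)
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == n_at && ncol(f) == 3, logical(1))
  if (!all(ok))
    stop("every frame must be an n_atoms x 3 coordinate matrix matching the topology")
  if (is.null(stride)) {
    stride <- if (!is.null(times) && length(times) > 1) diff(times)[1] else 1
  }
  if (is.null(times)) times <- stride * seq_along(frames)
  if (length(times) != length(frames))
    stop("times must match the number of frames")
  if (any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(topology = topology, frames = frames, times = as.numeric(times),
                 stride = stride),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("<conformer_ensemble: %d frames x %d atoms, t = %g..%g ps (stride %g ps)>\n",
              length(x$frames), nrow(x$topology$atoms),
              x$times[1], x$times[length(x$times)], x$stride))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a `conformer_ensemble`.
#' @return integer
#' @export
n_frames <- function(ensemble) length(ensemble$frames)

#' Coordinates of one system or frame
#'
#' @param system a `molecular_system`.
#' @return n_atoms x 3 matrix, A.
#' @export
coords <- function(system) {
  unname(as.matrix(system$atoms[, c("x", "y", "z")]))
}

#' Replace the coordinates of a system
#' @param system a `molecular_system`.
#' @param xyz n_atoms x 3 matrix.
#' @return the system with updated coordinates.
#' @export
set_coords <- function(system, xyz) {
  stopifnot(nrow(xyz) == nrow(system$atoms), ncol(xyz) == 3)
  system$atoms$x <- xyz[, 1]; system$atoms$y <- xyz[, 2]; system$atoms$z <- xyz[, 3]
  system
}

#' Extract the receptor or ligand component of a complex
#'
#' Single-trajectory convention: the component inherits the complex's
#' coordinates (optionally from a supplied frame).
#'
#' @param complex a `molecular_system` with `role = "complex"`.
#' @param which `"receptor"` or `"ligand"`.
#' @param frame optional coordinate matrix overriding the stored coordinates.
#' @return a `molecular_system` with the corresponding role.
#' @export
extract_component <- function(complex, which = c("receptor", "ligand"), frame = NULL) {
  which <- match.arg(which)
  stopifnot(inherits(complex, "molecular_system"), complex$role == "complex")
  if (!is.null(frame)) complex <- set_coords(complex, frame)
  keep <- complex$atoms$serial %in% complex$partition[[which]]
  atoms <- complex$atoms[keep, , drop = FALSE]
  sel <- complex$bonds[, 1] %in% atoms$serial & complex$bonds[, 2] %in% atoms$serial
  molecular_system(atoms, complex$bonds[sel, , drop = FALSE], role = which)
}

#' Row indices of the receptor/ligand atoms of a complex
#' @param complex a complex `molecular_system`.
#' @return list with integer vectors `receptor` and `ligand` (row indices).
#' @export
partition_rows <- function(complex) {
  stopifnot(complex$role == "complex")
  list(receptor = which(complex$atoms$serial %in% complex$partition$receptor),
       ligand   = which(complex$atoms$serial %in% complex$partition$ligand))
}

# ---------------------------------------------------------------------------
# Parameter tables

#' Read a per-atom parameter table
#'
#' Whitespace-delimited text with a header line
#' `residue atom charge lj_radius lj_epsilon mass`; an optional `[bonds]`
#' section lists bonded atom-serial pairs, one pair per line.  Both LF and
#' CRLF line endings are accepted.
#'
#' @param path file path.
#' @return list with data.frame `params` and integer matrix `bonds`.
#' @export
read_param_table <- function(path) {
  lines <- gsub("\r$", "", readLines(path, warn = FALSE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  bond_at <- which(lines == "[bonds]")
  if (length(bond_at) > 0) {
    bond_lines <- lines[(bond_at[1] + 1):length(lines)]
    lines <- lines[seq_len(bond_at[1] - 1)]
    bonds <- do.call(rbind, lapply(strsplit(bond_lines, "\\s+"),
                                   function(x) as.integer(x[1:2])))
  } else {
    bonds <- matrix(integer(0), ncol = 2)
  }
  tab <- utils::read.table(text = paste(lines, collapse = "\n"), header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("residue", "atom", "charge", "lj_radius", "lj_epsilon", "mass")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0)
    stop("parameter table is missing columns: ", paste(missing_cols, collapse = ", "))
  list(params = tab, bonds = bonds)
}

#' Write a parameter table
#' @param params data.frame as in [read_param_table()].
#' @param path output file.
#' @param bonds optional bond matrix appended as a `[bonds]` section.
#' @export
write_param_table <- function(params, path, bonds = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  utils::write.table(params, con, quote = FALSE, row.names = FALSE)
  if (!is.null(bonds) && nrow(bonds) > 0) {
    writeLines("[bonds]", con)
    utils::write.table(bonds, con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

lookup_params <- function(atoms, params) {
  key <- paste(atoms$resid, atoms$name)
  pkey <- paste(params$residue, params$atom)
  idx <- match(key, pkey)
  if (anyNA(idx)) {
    bad <- atoms[which(is.na(idx))[1], ]
    stop(sprintf("no parameters for residue/atom pair (\"%s\",\"%s\")",
                 bad$resid, bad$name))
  }
  atoms$charge     <- params$charge[idx]
  atoms$lj_radius  <- params$lj_radius[idx]
  atoms$lj_epsilon <- params$lj_epsilon[idx]
  atoms$mass       <- params$mass[idx]
  atoms
}

# ---------------------------------------------------------------------------
# PDB I/O (parsing delegated to bio3d)

# Pre-scan ATOM/HETATM records so malformed coordinate fields are reported
# with their line number, which bio3d does not do.
check_pdb_coords <- function(path) {
  lines <- gsub("\r$", "", readLines(path, warn = FALSE))
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    fields <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46), substr(lines[i], 47, 54))
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals))
      stop(sprintf("malformed coordinate field in PDB line %d: \"%s\"", i, lines[i]))
  }
  invisible(TRUE)
}

#' Read a (possibly multi-model) PDB file into package types
#'
#' Single-model files yield a `molecular_system`; files with several
#' `MODEL`/`ENDMDL` blocks yield a `conformer_ensemble` whose topology is the
#' first model.  Per-atom force-field parameters are joined from a parameter
#' table keyed on (residue name, atom name); a missing pair is an error
#' naming the pair.
#'
#' @param path PDB file.
#' @param parameters a parameter table as returned by [read_param_table()],
#'   or a path to one.
#' @param role role of the parsed system (`"complex"` requires `ligand_chain`).
#' @param ligand_chain for a complex, the chain id(s) forming the ligand;
#'   remaining chains form the receptor.
#' @param stride ps between models of a multi-model file (default 1).
#' @return `molecular_system` or `conformer_ensemble`.
#' @export
read_pdb <- function(path, parameters, role = c("complex", "receptor", "ligand"),
                     ligand_chain = NULL, stride = 1) {
  role <- match.arg(role)
  if (is.character(parameters)) parameters <- read_param_table(parameters)
  check_pdb_coords(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  atoms <- data.frame(serial = as.integer(at$eleno),
                      name = at$elety, element = at$elesy,
                      resno = as.integer(at$resno), resid = at$resid,
                      chain = ifelse(is.na(at$chain), "A", at$chain),
                      x = at$x, y = at$y, z = at$z,
                      charge = NA_real_, lj_radius = NA_real_,
                      lj_epsilon = NA_real_, mass = NA_real_,
                      stringsAsFactors = FALSE)
  atoms <- lookup_params(atoms, parameters$params)
  partition <- NULL
  if (role == "complex") {
    if (is.null(ligand_chain))
      stop("reading a complex requires ligand_chain")
    lig <- atoms$serial[atoms$chain %in% ligand_chain]
    if (length(lig) == 0) stop("no atoms on ligand chain(s) ", paste(ligand_chain, collapse = ","))
    partition <- list(receptor = setdiff(atoms$serial, lig), ligand = lig)
  }
  sys <- molecular_system(atoms, parameters$bonds, role = role, partition = partition)
  n_models <- nrow(pdb$xyz)
  if (is.null(n_models) || n_models <= 1) return(sys)
  frames <- lapply(seq_len(n_models), function(i) {
    matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)
  })
  sys <- set_coords(sys, frames[[1]])
  conformer_ensemble(sys, frames, stride = stride)
}

#' Write a system or ensemble to a PDB file
#'
#' @param x a `molecular_system` or `conformer_ensemble`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "conformer_ensemble")) {
    sys <- x$topology
    xyz <- do.call(rbind, lapply(x$frames, function(f) as.vector(t(f))))
  } else {
    sys <- x
    xyz <- matrix(as.vector(t(coords(sys))), nrow = 1)
  }
  a <- sys$atoms
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", nrow(a)),
                   eleno = a$serial, elety = a$name, resid = a$resid,
                   chain = a$chain, resno = a$resno, elesy = a$element)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Ligand truncation

#' Truncate the ligand of a complex to a residue range
#'
#' Removes ligand atoms whose residue index falls outside `keep`.  Severed
#' backbone bonds are capped with a hydrogen placed along the severed bond at
#' a standard length (`cap = "hydrogen"`), or left open (`cap = "none"`).
#' The receptor is untouched.
#'
#' @param system a complex `molecular_system`.
#' @param keep integer vector (range) of ligand residue indices to keep.
#' @param cap `"hydrogen"` (default) or `"none"`.
#' @param ch_length C-H cap bond length, A.
#' @return the truncated complex.
#' @export
truncate_ligand <- function(system, keep, cap = c("hydrogen", "none"), ch_length = 1.09) {
  cap <- match.arg(cap)
  stopifnot(system$role == "complex")
  rows <- partition_rows(system)
  lig <- system$atoms[rows$ligand, , drop = FALSE]
  lig_res <- sort(unique(lig$resno))
  keep <- intersect(as.integer(keep), lig_res)
  if (length(keep) == 0)
    stop("keep range has empty intersection with the ligand residues")
  drop_serials <- lig$serial[!(lig$resno %in% keep)]
  atoms <- system$atoms
  bonds <- system$bonds
  caps <- NULL
  if (cap == "hydrogen" && length(drop_serials) > 0) {
    severed <- bonds[xor(bonds[, 1] %in% drop_serials, bonds[, 2] %in% drop_serials), ,
                     drop = FALSE]
    if (nrow(severed) > 0) {
      next_serial <- max(atoms$serial) + 1L
      for (b in seq_len(nrow(severed))) {
        keep_s <- setdiff(severed[b, ], drop_serials)
        lost_s <- intersect(severed[b, ], drop_serials)
        ka <- atoms[atoms$serial == keep_s, ]
        la <- atoms[atoms$serial == lost_s, ]
        u <- c(la$x - ka$x, la$y - ka$y, la$z - ka$z)
        u <- u / sqrt(sum(u^2))
        hp <- c(ka$x, ka$y, ka$z) + ch_length * u
        hrow <- ka
        hrow$serial <- next_serial
        hrow$name <- "HC"; hrow$element <- "H"
        hrow$x <- hp[1]; hrow$y <- hp[2]; hrow$z <- hp[3]
        hrow$charge <- 0; hrow$lj_radius <- 1.387; hrow$lj_epsilon <- 0.0157
        hrow$mass <- 1.008
        caps <- rbind(caps, hrow)
        bonds <- rbind(bonds, c(keep_s, next_serial))
        next_serial <- next_serial + 1L
      }
    }
  }
  keep_mask <- !(atoms$serial %in% drop_serials)
  atoms <- rbind(atoms[keep_mask, , drop = FALSE], caps)
  bonds <- bonds[!(bonds[, 1] %in% drop_serials | bonds[, 2] %in% drop_serials), ,
                 drop = FALSE]
  new_lig <- setdiff(atoms$serial, system$partition$receptor)
  molecular_system(atoms, bonds, role = "complex",
                   partition = list(receptor = system$partition$receptor,
                                    ligand = new_lig))
}
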