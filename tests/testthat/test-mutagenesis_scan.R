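leucine_like_complex <- function() {
  # one receptor atom and one residue with a branched side chain
  at <- rbind(
    toy_atoms(1, matrix(c(0, 0, -6), 1, 3), name = "CP", resid = "PKT",
              resno = 101, chain = "R"),
    toy_atoms(6, cbind(c(-1.2, 0, 1.2, 0, 0, 0.8),
                       c(0.5, 0, 0.5, 0, 0.3, -0.4),
                       c(0, 0, 0, -1.5, -3.0, -4.0)),
              name = c("N", "CA", "C", "CB", "CG", "CD1"), resid = "LEU",
              resno = 1, chain = "L"))
  at$serial <- 1:7
  at <- rbind(at, toy_atoms(1, matrix(c(-0.8, -0.4, -4.0), 1, 3), name = "CD2",
                            resid = "LEU", resno = 1, chain = "L"))
  at$serial <- 1:8
  bonds <- matrix(c(2, 3, 3, 4, 3, 5, 5, 6, 6, 7, 6, 8), ncol = 2, byrow = TRUE)
  molecular_system(at, bonds, role = "complex",
                   partition = list(receptor = 1L, ligand = 2:8))
}

test_that("alanine truncation removes the side chain beyond C-beta and places one H", {
  cpx <- leucine_like_complex()
  mut <- make_alanine_mutant(cpx, 1)
  expect_equal(nrow(cpx$atoms) - nrow(mut$atoms), 2)  # CG,CD1,CD2 out, HB1 in
  expect_true("HB1" %in% mut$atoms$name)
  expect_false(any(c("CG", "CD1", "CD2") %in% mut$atoms$name))
  # H position: CB + 1.09 * unit(CG - CB)
  cb <- unlist(cpx$atoms[cpx$atoms$name == "CB", c("x", "y", "z")])
  cg <- unlist(cpx$atoms[cpx$atoms$name == "CG", c("x", "y", "z")])
  u <- (cg - cb) / sqrt(sum((cg - cb)^2))
  h <- unlist(mut$atoms[mut$atoms$name == "HB1", c("x", "y", "z")])
  expect_equal(unname(h), unname(cb + 1.09 * u), tolerance = 1e-9)
  # receptor and backbone coordinates bit-identical
  keep <- intersect(mut$atoms$serial, cpx$atoms$serial)
  expect_identical(mut$atoms[match(keep, mut$atoms$serial), c("x", "y", "z")],
                   cpx$atoms[match(keep, cpx$atoms$serial), c("x", "y", "z")])
})

test_that("glycine truncation applies only where it should", {
  fx <- build_complex(fixture_spec(seed = 31))
  ala_pos <- fx$truth$per_residue$position[fx$truth$per_residue$wild_type == "ALA"]
  mut <- make_glycine_mutant(fx$complex, ala_pos)
  # exactly one heavy atom (CB) removed, one HA2 added
  expect_equal(nrow(fx$complex$atoms), nrow(mut$atoms))
  expect_true("HA2" %in% mut$atoms$name[mut$atoms$resno == ala_pos])
  # collinearity of the placed hydrogen with the old CA->CB direction
  res <- fx$complex$atoms[fx$complex$atoms$resno == ala_pos &
                          fx$complex$atoms$chain == "L", ]
  ca <- unlist(res[res$name == "CA", c("x", "y", "z")])
  cb <- unlist(res[res$name == "CB", c("x", "y", "z")])
  h <- unlist(mut$atoms[mut$atoms$resno == ala_pos & mut$atoms$name == "HA2",
                        c("x", "y", "z")])
  cosang <- sum((h - ca) * (cb - ca)) /
    sqrt(sum((h - ca)^2) * sum((cb - ca)^2))
  expect_equal(acos(min(1, cosang)), 0, tolerance = 1e-6)
  # glycine target is an error, as is alanine under the alanine protocol
  gly_fx <- make_glycine_mutant(fx$complex, ala_pos)
  expect_error(make_alanine_mutant(fx$complex, ala_pos), "alanine")
  expect_error(make_glycine_mutant(gly_fx, ala_pos), "no side chain")
})

test_that("scan recovers the generator's hotspot energetics on a rigid fixture", {
  rf <- rigid_fixture(seed = 37, n_frames = 2)
  sc <- residue_scan(rf$ensemble, settings = coarse_pb())
  expect_equal(nrow(sc), 15)
  expect_equal(sc$position, 1:15)
  truth <- rf$fixture$truth$per_residue
  hot <- rf$fixture$spec$hotspot_positions
  for (p in hot) {
    expect_equal(sc$ddG[sc$position == p], truth$ddG_gas[truth$position == p],
                 tolerance = 0.35)      # PB/SA perturbation bound
  }
  # hotspot alanine receives the glycine mutation and loses a buried contact
  ala_pos <- truth$position[truth$wild_type == "ALA"]
  expect_equal(sc$mutation[sc$position == ala_pos], "gly")
  expect_gt(sc$ddG[sc$position == ala_pos], 0)
  # ddG equals the sum of its component deltas
  expect_equal(sc$ddG, sc$d_el + sc$d_vdw + sc$d_polar + sc$d_nonpolar,
               tolerance = 1e-9)
  # non-contacting residues with zero polar burial contribute ~ nothing
  # (positions flanking a charged site are excluded: truncating them changes
  # the dielectric cavity around the charge)
  sites <- rf$fixture$spec$charge_sites
  quiet <- setdiff(truth$position[truth$wild_type == "SER"],
                   c(10, sites - 1, sites + 1))
  expect_true(all(abs(sc$ddG[sc$position %in% quiet]) < 0.2))
})

test_that("two independent scan passes are identical", {
  rf <- rigid_fixture(seed = 41, n_frames = 2)
  s1 <- residue_scan(rf$ensemble, positions = c(6, 7), settings = coarse_pb())
  s2 <- residue_scan(rf$ensemble, positions = c(6, 7), settings = coarse_pb())
  expect_identical(s1, s2)
})

test_that("alanine and glycine scans are reported as distinct mutation types", {
  rf <- rigid_fixture(seed = 43, n_frames = 1)
  truth <- rf$fixture$truth$per_residue
  ala_pos <- truth$position[truth$wild_type == "ALA"]
  sc <- residue_scan(rf$ensemble, positions = c(6, ala_pos),
                     settings = coarse_pb())
  expect_setequal(sc$mutation, c("ala", "gly"))
})
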