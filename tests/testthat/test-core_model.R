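test_that("molecular_system enforces its invariants", {
  at <- toy_atoms(2, cbind(c(0, 3), 0, 0))
  expect_s3_class(molecular_system(at, role = "ligand"), "molecular_system")
  dup <- at; dup$serial <- c(1L, 1L)
  expect_error(molecular_system(dup, role = "ligand"), "unique")
  bad <- at; bad$mass[1] <- 0
  expect_error(molecular_system(bad, role = "ligand"), "mass")
  expect_error(molecular_system(at, role = "complex"), "partition")
  expect_error(molecular_system(at, role = "complex",
                                partition = list(receptor = 1L, ligand = 1L)),
               "disjoint")
})

test_that("net charge is the algebraic sum of partial charges", {
  at <- toy_atoms(2, cbind(c(0, 3), 0, 0), charge = c(0.5, -0.5))
  expect_equal(net_charge(molecular_system(at, role = "ligand")), 0)
  expect_equal(net_charge(at[0, ]), 0)
  fx <- build_complex(fixture_spec(seed = 1, ligand_net_charge = 2))
  expect_equal(net_charge(extract_component(fx$complex, "ligand")), 2)
})

test_that("PDB reading returns a system for one model and an ensemble for several", {
  fx <- build_complex(fixture_spec(seed = 3))
  single <- tempfile(fileext = ".pdb")
  write_pdb(fx$complex, single)
  sys <- read_pdb(single, fx$params, role = "complex", ligand_chain = "L")
  expect_s3_class(sys, "molecular_system")
  expect_equal(nrow(sys$atoms), nrow(fx$complex$atoms))

  ens <- sample_ensemble(fx, n_frames = 3)
  multi <- tempfile(fileext = ".pdb")
  write_pdb(ens, multi)
  ens2 <- read_pdb(multi, fx$params, role = "complex", ligand_chain = "L",
                   stride = fx$spec$stride)
  expect_s3_class(ens2, "conformer_ensemble")
  expect_equal(n_frames(ens2), 3)
})

test_that("PDB round trip preserves coordinates to 3 decimals and identities exactly", {
  fx <- build_complex(fixture_spec(seed = 5))
  f1 <- tempfile(fileext = ".pdb")
  write_pdb(fx$complex, f1)
  back <- read_pdb(f1, fx$params, role = "complex", ligand_chain = "L")
  expect_equal(coords(back), round(coords(fx$complex), 3), ignore_attr = TRUE)
  expect_identical(back$atoms$serial, fx$complex$atoms$serial)
  expect_identical(back$atoms$name, fx$complex$atoms$name)
  expect_identical(back$atoms$resid, fx$complex$atoms$resid)
  # second trip is the identity
  f2 <- tempfile(fileext = ".pdb")
  write_pdb(back, f2)
  again <- read_pdb(f2, fx$params, role = "complex", ligand_chain = "L")
  expect_equal(coords(again), coords(back))
})

test_that("missing parameters and malformed coordinates give named errors", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  XX  GLY A   1       1.500   0.000   0.000  1.00  0.00           C",
    "END"), pdb)
  params <- list(params = data.frame(residue = "GLY", atom = "CA", charge = 0,
                                     lj_radius = 1.9, lj_epsilon = 0.1, mass = 12),
                 bonds = matrix(integer(0), ncol = 2))
  expect_error(read_pdb(pdb, params, role = "ligand"), '"GLY","XX"')

  bad <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  GLY A   1       1.5x0   0.000   0.000  1.00  0.00           C",
    "END"), bad)
  expect_error(read_pdb(bad, params, role = "ligand"), "line 2")
})

test_that("parameter tables round trip through text with CRLF tolerance", {
  fx <- build_complex(fixture_spec(seed = 2))
  f <- tempfile(fileext = ".txt")
  write_param_table(fx$params$params, f, bonds = fx$params$bonds)
  back <- read_param_table(f)
  expect_equal(back$params$charge, fx$params$params$charge)
  expect_equal(back$bonds, matrix(as.integer(fx$params$bonds), ncol = 2))
  crlf <- tempfile(fileext = ".txt")
  writeLines(gsub("$", "\r", readLines(f)), crlf, sep = "\n")
  expect_equal(read_param_table(crlf)$params$mass, back$params$mass)
})

test_that("ligand truncation keeps the requested residues and caps severed bonds", {
  fx <- build_complex(fixture_spec(seed = 9))
  tr <- truncate_ligand(fx$complex, 1:8)
  lig <- extract_component(tr, "ligand")
  expect_setequal(unique(lig$atoms$resno), 1:8)
  # receptor untouched
  rec0 <- extract_component(fx$complex, "receptor")
  rec1 <- extract_component(tr, "receptor")
  expect_identical(rec0$atoms, rec1$atoms)
  # partition conservation
  expect_equal(nrow(tr$atoms),
               nrow(rec1$atoms) + nrow(lig$atoms))
  # hydrogen cap on the severed backbone bond
  expect_true("HC" %in% lig$atoms$name)
  # full range: identity (no severed bonds, so no caps either)
  full <- truncate_ligand(fx$complex, 1:15)
  expect_identical(full$atoms, fx$complex$atoms)
  expect_error(truncate_ligand(fx$complex, 90:99), "empty intersection")
})

test_that("conformer ensembles validate shape and time ordering", {
  sys <- lj_diatomic()
  f <- coords(sys)
  expect_error(conformer_ensemble(sys, list(f[1, , drop = FALSE])), "atom")
  expect_error(conformer_ensemble(sys, list(f, f), times = c(2, 1)),
               "strictly increasing")
  ens <- conformer_ensemble(sys, list(f, f + 0.1), times = c(6, 12))
  expect_equal(ens$stride, 6)
})
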