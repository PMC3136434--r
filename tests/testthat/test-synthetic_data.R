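test_that("fixture specs validate their geometry and parameters", {
  expect_error(fixture_spec(seed = 1, n_ligand_residues = 3), "at least 6")
  expect_error(fixture_spec(seed = 1, hotspot_positions = c(2, 99)), "hotspot")
  expect_error(fixture_spec(seed = 1, ligand_net_charge = 7), "0..3")
  expect_error(fixture_spec(), "seed")
  spec <- fixture_spec(seed = 1)
  expect_equal(spec$n_ligand_residues, 15)
  expect_equal(spec$hotspot_positions, 6:9)
})

test_that("built complexes have a valid partition and the requested charge", {
  for (m in 1:3) {
    fx <- build_complex(fixture_spec(seed = 5, ligand_net_charge = m))
    cpx <- fx$complex
    expect_equal(sort(c(cpx$partition$receptor, cpx$partition$ligand)),
                 sort(cpx$atoms$serial))
    lig <- extract_component(cpx, "ligand")
    expect_equal(length(unique(lig$atoms$resno)), 15)
    expect_equal(net_charge(lig), m)
    expect_equal(fx$truth$net_ligand_charge, m)
  }
})

test_that("stored ground truth is consistent with the MM energy path", {
  fx <- build_complex(fixture_spec(seed = 23, ligand_net_charge = 2))
  g <- gas_phase_binding(fx$complex)
  expect_equal(g$el, fx$truth$gas_el, tolerance = 1e-9)
  expect_equal(g$vdw, fx$truth$gas_vdw, tolerance = 1e-9)
  expect_equal(g$total, fx$truth$gas_total, tolerance = 1e-9)
  expect_equal(fx$truth$per_residue$ddG_gas,
               -fx$truth$per_residue$side_chain_energy, tolerance = 1e-12)
})

test_that("the charge series orders electrostatic binding strictly", {
  els <- vapply(1:3, function(m)
    build_complex(fixture_spec(seed = 2, ligand_net_charge = m))$truth$gas_el,
    numeric(1))
  expect_true(all(diff(els) < 0))
})

test_that("generation is exactly reproducible from (spec, seed)", {
  fx1 <- build_complex(fixture_spec(seed = 77, ligand_net_charge = 2))
  fx2 <- build_complex(fixture_spec(seed = 77, ligand_net_charge = 2))
  expect_identical(fx1, fx2)
  e1 <- sample_ensemble(fx1, n_frames = 25)
  e2 <- sample_ensemble(fx2, n_frames = 25)
  expect_identical(e1$frames, e2$frames)
  expect_identical(attr(e1, "bond_states"), attr(e2, "bond_states"))
  # different seed, different frames
  e3 <- sample_ensemble(fx1, n_frames = 25, seed = 78)
  expect_false(identical(e1$frames, e3$frames))
})

test_that("rigid specs give identical frames and strides follow the spec", {
  fx <- build_complex(fixture_spec(seed = 9, fluctuation_sigma = 0,
                                   intermittent_bonds = list(), n_frames = 5,
                                   stride = 12))
  ens <- sample_ensemble(fx)
  expect_equal(n_frames(ens), 5)
  expect_equal(ens$stride, 12)
  expect_equal(ens$times, 12 * (1:5))
  for (f in ens$frames) expect_equal(f, ens$frames[[1]])
})

test_that("high-level record modes behave as documented", {
  fx <- build_complex(fixture_spec(seed = 15, fluctuation_sigma = 0, n_frames = 60))
  ens <- sample_ensemble(fx)
  e_mm <- vapply(seq_len(60), function(i)
    gas_phase_binding(fx$complex, ens$frames[[i]])$total, numeric(1))
  rid <- emit_highlevel_records(ens, "mm_identity")
  expect_equal(rid$table$gas_binding_energy, e_mm, tolerance = 1e-12)
  roff <- emit_highlevel_records(ens, "mm_plus_offset", offset = 1.5)
  expect_equal(roff$table$gas_binding_energy, e_mm + 1.5, tolerance = 1e-12)
  rn <- emit_highlevel_records(ens, "mm_plus_noise", noise_sd = 0.3, seed = 4)
  shift <- mean(rn$table$gas_binding_energy - e_mm)
  expect_lt(abs(shift), 3 * 0.3 / sqrt(60))
})

test_that("toy TI emitters record the requested sampling and truths", {
  ti <- emit_ti_samples("harmonic_k", k0 = 2, k1 = 2, n_per_node = 40, seed = 6)
  expect_equal(ti$truth, 0)
  expect_true(all(vapply(ti$stage$samples, length, integer(1)) == 40))
  expect_true(all(vapply(ti$stage$samples, function(x) all(x == 0), logical(1))))
  kT <- bindfe_constants$kB * 300
  t4 <- emit_ti_samples("harmonic_k", k0 = 1, k1 = 4, n_per_node = 10, seed = 6)
  expect_equal(t4$truth, kT / 2 * log(4), tolerance = 1e-12)
  dch <- emit_ti_samples("decharge", c_field = 2, k0 = 1, n_per_node = 10, seed = 6)
  expect_equal(dch$truth, 2^2 / 2, tolerance = 1e-12)
  sc <- emit_ti_samples("softcore_appear", n_per_node = 10, seed = 6,
                        rmin = 3.8, eps = 0.3)
  expect_true(is.finite(sc$truth))
})
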