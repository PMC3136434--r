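test_that("Coulomb term reproduces the conversion constant and brute-force sums", {
  a <- toy_atoms(1, matrix(0, 1, 3), charge = 1)
  b <- toy_atoms(1, matrix(c(332.0637, 0, 0), 1, 3), charge = 1)
  expect_equal(coulomb_interaction(a, b), 1.0, tolerance = 1e-12)
  # neutral group
  b0 <- b; b0$charge <- 0
  expect_equal(coulomb_interaction(a, b0), 0)
  # 3x3 mixed-charge toy against explicit pair enumeration
  set.seed(21)
  ga <- toy_atoms(3, matrix(rnorm(9, sd = 3), 3, 3), charge = c(0.4, -1.1, 0.7))
  gb <- toy_atoms(3, matrix(rnorm(9, sd = 3) + 10, 3, 3), charge = c(-0.2, 0.9, 0.3))
  manual <- 0
  for (i in 1:3) for (j in 1:3) {
    r <- sqrt(sum((ga[i, c("x", "y", "z")] - gb[j, c("x", "y", "z")])^2))
    manual <- manual + 332.0637 * ga$charge[i] * gb$charge[j] / r
  }
  expect_equal(coulomb_interaction(ga, gb), manual, tolerance = 1e-12)
  # coincident atoms are a singularity error naming the pair
  expect_error(coulomb_interaction(ga, ga), "zero interatomic distance")
})

test_that("Lennard-Jones term has its analytic minimum and far-field decay", {
  a <- toy_atoms(1, matrix(0, 1, 3), lj_radius = 1.7, lj_epsilon = 0.2)
  b <- toy_atoms(1, matrix(c(1.7 + 2.1, 0, 0), 1, 3), lj_radius = 2.1,
                 lj_epsilon = 0.45)
  expect_equal(lj_interaction(a, b), -sqrt(0.2 * 0.45), tolerance = 1e-12)
  bfar <- b; bfar$x <- 1e4
  expect_lt(abs(lj_interaction(a, bfar)), 1e-12)
  # 4-atom toy against explicit enumeration
  set.seed(8)
  ga <- toy_atoms(2, matrix(rnorm(6, sd = 2), 2, 3), lj_radius = c(1.8, 2.0),
                  lj_epsilon = c(0.1, 0.3))
  gb <- toy_atoms(2, matrix(rnorm(6, sd = 2) + 8, 2, 3), lj_radius = c(1.6, 1.9),
                  lj_epsilon = c(0.2, 0.12))
  manual <- 0
  for (i in 1:2) for (j in 1:2) {
    r <- sqrt(sum((ga[i, c("x", "y", "z")] - gb[j, c("x", "y", "z")])^2))
    rm <- ga$lj_radius[i] + gb$lj_radius[j]
    ep <- sqrt(ga$lj_epsilon[i] * gb$lj_epsilon[j])
    manual <- manual + ep * ((rm / r)^12 - 2 * (rm / r)^6)
  }
  expect_equal(lj_interaction(ga, gb), manual, tolerance = 1e-12)
})

test_that("gas-phase binding is the receptor-ligand cross interaction", {
  cpx <- two_atom_complex()
  g <- gas_phase_binding(cpx)
  expect_equal(g$total, g$el + g$vdw, tolerance = 1e-9)
  # ghost ligand: all zero
  ghost <- cpx
  ghost$atoms$charge[2] <- 0; ghost$atoms$lj_epsilon[2] <- 0
  g0 <- gas_phase_binding(ghost)
  expect_equal(c(g0$el, g0$vdw, g0$total), c(0, 0, 0))
  # fixture ground truth stored by the generator
  fx <- build_complex(fixture_spec(seed = 4, ligand_net_charge = 3))
  gg <- gas_phase_binding(fx$complex)
  expect_equal(gg$el, fx$truth$gas_el, tolerance = 1e-9)
  expect_equal(gg$vdw, fx$truth$gas_vdw, tolerance = 1e-9)
  # decomposition identity
  rows <- partition_rows(fx$complex)
  expect_equal(gg$total,
               coulomb_interaction(fx$complex$atoms[rows$receptor, ],
                                   fx$complex$atoms[rows$ligand, ]) +
               lj_interaction(fx$complex$atoms[rows$receptor, ],
                              fx$complex$atoms[rows$ligand, ]),
               tolerance = 1e-12)
})

test_that("energies are invariant to rigid motion and label swap", {
  fx <- build_complex(fixture_spec(seed = 6))
  g0 <- gas_phase_binding(fx$complex)
  moved <- set_coords(fx$complex, rotate_translate(coords(fx$complex)))
  g1 <- gas_phase_binding(moved)
  expect_equal(g1$el, g0$el, tolerance = 1e-9)
  expect_equal(g1$vdw, g0$vdw, tolerance = 1e-9)
  swapped <- fx$complex
  swapped$partition <- list(receptor = fx$complex$partition$ligand,
                            ligand = fx$complex$partition$receptor)
  g2 <- gas_phase_binding(swapped)
  expect_equal(g2$total, g0$total, tolerance = 1e-12)
})

test_that("single-trajectory identity: full intramolecular terms cancel", {
  fx <- build_complex(fixture_spec(seed = 13, ligand_net_charge = 1))
  g <- gas_phase_binding(fx$complex)
  tc <- total_nonbonded(fx$complex)
  tr <- total_nonbonded(extract_component(fx$complex, "receptor"))
  tl <- total_nonbonded(extract_component(fx$complex, "ligand"))
  expect_equal(tc$total - tr$total - tl$total, g$total, tolerance = 1e-9)
})
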