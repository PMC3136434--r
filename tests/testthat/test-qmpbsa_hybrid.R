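test_that("power-law fit recovers exact generating parameters", {
  eps <- c(1, 2, 4, 8, 16)
  samp <- data.frame(solute_dielectric = eps, polar = -37.3 * eps^-1)
  f <- fit_polar_scaling(samp, target_dielectric = 4)
  expect_equal(f$exponent, -1, tolerance = 1e-8)
  expect_equal(f$amplitude, -37.3, tolerance = 1e-6)
  expect_lt(f$rms_residual, 1e-8)
  expect_equal(f$scale_factor, 4^-1, tolerance = 1e-8)
  # constant samples: exponent 0, scale factor 1
  const <- data.frame(solute_dielectric = eps, polar = rep(-5, 5))
  fc <- fit_polar_scaling(const, target_dielectric = 4)
  expect_equal(fc$exponent, 0, tolerance = 1e-12)
  expect_equal(fc$scale_factor, 1, tolerance = 1e-12)
  # preconditions
  expect_error(fit_polar_scaling(samp[1:2, ]), "3")
  mixed <- samp; mixed$polar[2] <- 5
  expect_error(fit_polar_scaling(mixed), "one sign")
})

test_that("hybrid assembly reduces to classical MM-PBSA under identity inputs", {
  rf <- rigid_fixture(seed = 47, n_frames = 4)
  dec <- snapshot_decomposition(rf$ensemble, settings = coarse_pb())
  classical <- binding_free_energy(dec)
  rec <- emit_highlevel_records(rf$ensemble, "mm_identity")
  hyb <- hybrid_binding_free_energy(dec, rec)
  expect_equal(hyb$delta_G, classical$delta_G, tolerance = 1e-9)
  # constant offset shifts dG by exactly the offset
  rec2 <- emit_highlevel_records(rf$ensemble, "mm_plus_offset", offset = -4.2)
  hyb2 <- hybrid_binding_free_energy(dec, rec2)
  expect_equal(hyb2$delta_G - classical$delta_G, -4.2, tolerance = 1e-9)
  # missing records are reported with their frame times
  expect_error(hybrid_binding_free_energy(dec,
                 highlevel_records(dec$frame_time[-1] ,
                                   rep(0, nrow(dec) - 1))),
               as.character(dec$frame_time[1]))
})

test_that("high-level records round trip through text tables", {
  rf <- rigid_fixture(seed = 53, n_frames = 3)
  rec <- emit_highlevel_records(rf$ensemble, "mm_identity", with_forces = TRUE)
  f1 <- tempfile(); f2 <- tempfile()
  write_highlevel_records(rec, f1, f2)
  back <- read_highlevel_records(f1, f2)
  expect_equal(back$table$gas_binding_energy, rec$table$gas_binding_energy,
               tolerance = 1e-9)
  expect_equal(back$forces[["6"]]$complex, rec$forces[["6"]]$complex,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("snapshot selection matches exhaustive enumeration and is monotone in k", {
  set.seed(59)
  fx <- build_complex(fixture_spec(seed = 59, fluctuation_sigma = 0.15,
                                   n_frames = 10))
  ens <- sample_ensemble(fx)
  dec <- snapshot_decomposition(ens, settings = coarse_pb())
  occ <- attr(ens, "bond_states")
  sel_ex <- select_representative_snapshots(dec, k = 2, hbond_indicators = occ)
  # brute force over all 45 pairs
  pairs <- utils::combn(10, 2)
  obj_brute <- apply(pairs, 2, function(p) {
    mu <- mean(dec$enthalpic_total); sdv <- stats::sd(dec$enthalpic_total)
    o <- colMeans(occ * 1)
    osd <- apply(occ * 1, 2, stats::sd); osd[osd == 0] <- 1
    sum((c(mean(dec$enthalpic_total[p]) - mu,
           stats::sd(dec$enthalpic_total[p]) - sdv,
           colMeans(occ[p, , drop = FALSE] * 1) - o) / c(sdv, sdv, osd))^2)
  })
  expect_equal(sort(sel_ex$extra), sort(pairs[, which.min(obj_brute)]))
  expect_equal(sel_ex$objective, min(obj_brute), tolerance = 1e-12)
  # greedy-with-swap agrees with exhaustive on this fixture
  sel_gr <- select_representative_snapshots(dec, k = 2, hbond_indicators = occ,
                                            exhaustive_limit = 1)
  expect_equal(sel_gr$extra, sel_ex$extra)
  # whole pool: objective zero
  sel_all <- select_representative_snapshots(dec, k = 10)
  expect_equal(sel_all$objective, 0, tolerance = 1e-12)
  # exhaustive optimum is no worse than any specific subset of the same size
  some <- utils::combn(10, 3)[, c(1, 40, 99)]
  best3 <- select_representative_snapshots(dec, k = 3,
                                           hbond_indicators = occ)$objective
  for (j in 1:3) {
    expect_lte(best3, subset_obj_for_test(some[, j], dec, occ))
  }
  expect_error(select_representative_snapshots(dec, k = 11), "pool")
})

test_that("a frame that alone matches the population mean is chosen at k = 1", {
  d <- data.frame(frame_time = 1:5, enthalpic_total = c(-3, -1, -2, -2.5, -1.5))
  # frame 3 equals the population mean (-2) exactly
  sel <- select_representative_snapshots(d, k = 1)
  expect_equal(sel$extra, 3)
})

test_that("force-error profiles are zero for identity records and localise perturbations", {
  rf <- rigid_fixture(seed = 61, n_frames = 2)
  rec <- emit_highlevel_records(rf$ensemble, "mm_identity", with_forces = TRUE)
  prof <- force_error_profile(rf$ensemble, rec)
  expect_true(all(prof$mean_abs_dF < 1e-9))
  # +1 kcal/(mol A) along x on one atom of the complex
  rec2 <- rec
  for (t in names(rec2$forces)) rec2$forces[[t]]$complex[5, 1] <-
      rec2$forces[[t]]$complex[5, 1] + 1
  prof2 <- force_error_profile(rf$ensemble, rec2)
  expect_equal(prof2$mean_abs_dF[5], 1.0, tolerance = 1e-9)
  expect_true(all(prof2$mean_abs_dF[-5] < 1e-9))
  # shape mismatch is an error
  rec3 <- rec
  rec3$forces[["6"]]$complex <- rec3$forces[["6"]]$complex[-1, ]
  expect_error(force_error_profile(rf$ensemble, rec3), "mismatch")
})

test_that("random force perturbations average to the expected magnitude", {
  rf0 <- build_complex(fixture_spec(seed = 67, fluctuation_sigma = 0, n_frames = 30))
  ens <- sample_ensemble(rf0)
  m <- 0.4
  rec <- emit_highlevel_records(ens, "mm_plus_noise", noise_sd = 0.1, seed = 71,
                                with_forces = TRUE, force_noise_sd = m)
  prof <- force_error_profile(ens, rec)
  # |dF| of a 3D isotropic Gaussian has mean m * sqrt(8/pi)
  expected <- m * sqrt(8 / pi)
  expect_equal(mean(prof$mean_abs_dF), expected, tolerance = 0.1)
})
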