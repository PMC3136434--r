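test_that("hydrogen-bond occupancy counts frames satisfying the criterion", {
  fx <- build_complex(fixture_spec(seed = 3, fluctuation_sigma = 0.05,
                                   n_frames = 20))
  ens <- sample_ensemble(fx)
  b <- fx$truth$bonds[[1]]
  spec <- hbond_spec(donor = b$donor, acceptor = b$acceptor)
  occ <- hbond_occupancy(ens, spec)
  # brute-force per-frame indicator count
  id <- match(b$donor, fx$complex$atoms$serial)
  ia <- match(b$acceptor, fx$complex$atoms$serial)
  manual <- mean(vapply(ens$frames, function(f)
    sqrt(sum((f[id, ] - f[ia, ])^2)) <= 3.5, logical(1)))
  expect_equal(occ$fraction, manual)
  # occupancy invariant to frame order
  perm <- sample(n_frames(ens))
  ens2 <- conformer_ensemble(fx$complex, ens$frames[perm], times = ens$times)
  expect_equal(hbond_occupancy(ens2, spec)$fraction, occ$fraction)
  expect_error(hbond_occupancy(ens, hbond_spec(donor = 9999, acceptor = b$acceptor)),
               "9999")
})

test_that("telegraph fixtures realize their target occupancy", {
  fx <- build_complex(fixture_spec(seed = 101, n_frames = 1000))
  ens <- sample_ensemble(fx)
  b <- fx$truth$bonds[[1]]
  occ <- hbond_occupancy(ens, hbond_spec(donor = b$donor, acceptor = b$acceptor))
  expect_equal(occ$fraction, 0.65, tolerance = 0.05)
  expect_true(all(occ$per_block >= 0 & occ$per_block <= 1))
})

test_that("the angular criterion distinguishes bent geometries", {
  # donor-H-acceptor: straight (180 deg) vs right angle (90 deg)
  at <- toy_atoms(3, cbind(c(0, 1, 2), 0, 0), name = c("D", "H", "A"))
  sys <- molecular_system(at, role = "ligand")
  straight <- coords(sys)
  bent <- straight; bent[3, ] <- c(1, 1, 0)
  ens <- conformer_ensemble(sys, list(straight, bent), times = c(1, 2))
  spec <- hbond_spec(donor = 1, acceptor = 3, hydrogen = 2,
                     distance_cutoff = 3.5, angle_cutoff = 120)
  expect_equal(hbond_indicator(ens, spec), c(TRUE, FALSE))
})

test_that("block averages partition the series and inflate correlated errors", {
  ba <- block_average(1:8, 4)
  expect_equal(ba$block_means, c(1.5, 3.5, 5.5, 7.5))
  expect_equal(block_average(rep(3, 20), 5)$se, 0)
  expect_error(block_average(1:3, 4), "shorter")
  # AR(1) series: block SE exceeds the naive (iid) SE
  set.seed(5)
  n <- 4000; phi <- 0.9
  x <- numeric(n); x[1] <- rnorm(1)
  for (i in 2:n) x[i] <- phi * x[i - 1] + rnorm(1)
  naive <- stats::sd(x) / sqrt(n)
  blocked <- block_average(x, 20)$se
  expect_gt(blocked, 2 * naive)
  # remainder folds into the last block
  ba2 <- block_average(1:10, 3)
  expect_equal(ba2$block_means, c(2, 5, 8.5))
})

test_that("distance distributions conserve counts and resolve two states", {
  fx <- build_complex(fixture_spec(seed = 7, fluctuation_sigma = 0, n_frames = 200))
  ens <- sample_ensemble(fx)
  b <- fx$truth$bonds[[1]]
  h <- distance_distribution(ens, c(b$donor, b$acceptor), bin_width = 0.1,
                             log_counts = TRUE)
  expect_equal(sum(h$counts), 200)
  occupied <- which(h$counts > 0)
  expect_equal(length(occupied), 2)            # bimodal: on and off states
  masses <- h$counts[occupied] / 200
  expect_equal(sort(masses), sort(c(0.35, 0.65)), tolerance = 0.05)
  expect_true(all(is.na(h$log_counts[h$counts == 0])))
  # rigid pair occupies a single bin
  at <- toy_atoms(2, cbind(c(0, 3), 0, 0))
  sys <- molecular_system(at, role = "ligand")
  ens2 <- conformer_ensemble(sys, list(coords(sys), coords(sys)), times = 1:2)
  h2 <- distance_distribution(ens2, c(1, 2))
  expect_equal(sum(h2$counts > 0), 1)
})

test_that("superposed RMSD removes rigid motion and measures real displacement", {
  fx <- build_complex(fixture_spec(seed = 11))
  ref <- coords(fx$complex)
  moved <- rotate_translate(ref)
  ens <- conformer_ensemble(fx$complex, list(ref, moved), times = 1:2)
  r <- backbone_rmsd(ens, reference = 1)
  expect_equal(r[1], 0, tolerance = 1e-9)
  expect_lt(r[2], 1e-9)
  # symmetric in frame and reference
  ens_rev <- conformer_ensemble(fx$complex, list(moved, ref), times = 1:2)
  expect_equal(backbone_rmsd(ens_rev, reference = 1)[2], r[2], tolerance = 1e-9)
  # all-atom displacement of magnitude d in random directions gives RMSD ~ d
  set.seed(3)
  d <- 0.8
  u <- matrix(rnorm(length(ref)), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  ens3 <- conformer_ensemble(fx$complex, list(ref, ref + d * u), times = 1:2)
  expect_equal(backbone_rmsd(ens3, reference = 1, selection = NULL)[2], d,
               tolerance = 0.15)
  expect_error(backbone_rmsd(ens, selection = "ZZ"), "empty")
})

test_that("the RMSD monitor flags excursions beyond its bound", {
  fx <- build_complex(fixture_spec(seed = 13))
  ref <- coords(fx$complex)
  sel <- which(fx$complex$atoms$name %in% c("N", "CA", "C"))
  big <- ref; big[sel, ] <- big[sel, ] + matrix(rnorm(length(sel) * 3, sd = 2),
                                                ncol = 3)
  ens <- conformer_ensemble(fx$complex, list(ref, big), times = 1:2)
  m <- rmsd_monitor(ens, reference = 1, bound = 2.0)
  expect_false(m$ok)
  m2 <- rmsd_monitor(conformer_ensemble(fx$complex, list(ref, ref), times = 1:2),
                     reference = 1, bound = 2.0)
  expect_true(m2$ok)
})
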