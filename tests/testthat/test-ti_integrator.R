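test_that("Gauss-Legendre rules on (0,1) satisfy their identities", {
  g1 <- gauss_nodes(1)
  expect_equal(g1$nodes, 0.5)
  expect_equal(g1$weights, 1)
  g9 <- gauss_nodes(9)
  expect_equal(sum(g9$weights), 1, tolerance = 1e-14)
  expect_equal(g9$nodes, 1 - rev(g9$nodes), tolerance = 1e-12)
  expect_error(gauss_nodes(0), ">= 1")
  # exactness up to degree 17 at n = 9
  errs <- vapply(0:17, function(p)
    abs(sum(g9$weights * g9$nodes^p) - 1 / (p + 1)), numeric(1))
  expect_true(all(errs <= 1e-10))
})

test_that("stage dG integrates constants and linear integrands exactly", {
  g <- gauss_nodes(9)
  const <- ti_stage("decharge", lapply(g$nodes, function(l) rep(2.5, 4)))
  r <- stage_delta_g(const)
  expect_equal(r$delta_g, 2.5, tolerance = 1e-12)
  expect_equal(r$se, 0)
  lin <- ti_stage("decharge", lapply(g$nodes, function(l) 1.2 + 3.4 * l))
  expect_equal(stage_delta_g(lin)$delta_g, 1.2 + 3.4 / 2, tolerance = 1e-12)
  empty <- ti_stage("decharge", c(lapply(g$nodes[-9], function(l) 1), list(numeric(0))))
  expect_error(stage_delta_g(empty), "lambda")
})

test_that("soft-core potential reduces to plain LJ and stays finite at r = 0", {
  p <- softcore_params(alpha = 0.5, power = 1, direction = "appearing")
  rmin <- 3.8; eps <- 0.5
  r <- c(2.5, 3.5, 3.8, 5.0)
  sc <- softcore_lj(r, lambda = 1, p, rmin, eps)
  lj <- eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
  expect_equal(sc$energy, lj, tolerance = 1e-12)
  expect_true(is.finite(softcore_lj(0, 0.5, p, rmin, eps)$energy))
  # disappearing direction couples at lambda = 0
  pd <- softcore_params(direction = "disappearing")
  expect_equal(softcore_lj(r, 0, pd, rmin, eps)$energy, lj, tolerance = 1e-12)
  # analytic dV/dlambda matches central differences
  h <- 1e-7
  for (lam in c(0.2, 0.43, 0.77)) {
    fd <- (softcore_lj(3.1, lam + h, p, rmin, eps)$energy -
           softcore_lj(3.1, lam - h, p, rmin, eps)$energy) / (2 * h)
    expect_equal(softcore_lj(3.1, lam, p, rmin, eps)$dvdl, fd,
                 tolerance = 1e-6)
  }
})

test_that("harmonic spring-constant change recovers its closed-form dG", {
  ti <- emit_ti_samples("harmonic_k", k0 = 1, k1 = 4, n_per_node = 800, seed = 2)
  r <- stage_delta_g(ti$stage)
  kT <- bindfe_constants$kB * 300
  expect_equal(ti$truth, kT / 2 * log(4), tolerance = 1e-12)
  expect_lt(abs(r$delta_g - ti$truth), 3 * r$se)
  # per-node convergence diagnostics are reported
  expect_true(all(c("half_diff", "se", "n") %in% names(r$nodes)))
  expect_equal(r$nodes$n, rep(800, 9))
})

test_that("three-stage totals combine stages with quadrature errors", {
  g <- gauss_nodes(3)
  mk <- function(label, value) ti_stage(label, lapply(g$nodes, function(l) value))
  zero <- three_stage_total(list(mk("decharge", 0), mk("vdw_softcore", 0),
                                 mk("recharge", 0)))
  expect_equal(zero$delta_g, 0)
  manual <- list(list(label = "decharge", delta_g = 1, se = 0.1),
                 list(label = "vdw_softcore", delta_g = 2, se = 0.2),
                 list(label = "recharge", delta_g = 3, se = 0.3))
  tot <- three_stage_total(manual)
  expect_equal(tot$delta_g, 6)
  expect_equal(tot$se, sqrt(0.01 + 0.04 + 0.09), tolerance = 1e-12)
  expect_error(three_stage_total(manual[c(1, 1, 2)]), "exactly")
})

test_that("a null mutation integrates to zero within its sampling error", {
  res <- emit_three_stage(seed = 11, c_start = 1, c_end = 1, n_per_node = 800)
  expect_equal(res$truth, 0, tolerance = 1e-12)
  tot <- three_stage_total(res$stages)
  expect_lt(abs(tot$delta_g), 3 * tot$se)
})

test_that("dV/dlambda tables round trip through text", {
  res <- emit_three_stage(seed = 13, n_per_node = 50)
  f <- tempfile()
  names(res$stages) <- vapply(res$stages, function(s) s$label, character(1))
  write_ti_samples(res$stages, f)
  back <- read_ti_samples(f)
  expect_setequal(names(back), c("decharge", "vdw_softcore", "recharge"))
  expect_equal(stage_delta_g(back$decharge)$delta_g,
               stage_delta_g(res$stages$decharge)$delta_g, tolerance = 1e-9)
})
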