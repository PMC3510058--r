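# Occupancy statistics, free-energy profiles, critical nucleus, CNT.

test_that("size_probability matches hand enumeration and weighting modes", {
  p20 <- partition_from_clusters(list(1:20), 20, 0)
  sp <- size_probability(list(p20))
  expect_equal(unname(sp$p[20]), 1)
  # two frames: {all monomers}, {one dimer + 18 monomers}
  f1 <- partition_from_clusters(list(), 20, 0)
  f2 <- partition_from_clusters(list(c(1, 2)), 20, 1)
  sp2 <- size_probability(list(f1, f2))
  # hand count: 20 + 18 = 38 monomer aggregates, 1 dimer aggregate
  expect_equal(unname(sp2$p[1:2]), c(38, 1) / 39)
  spp <- size_probability(list(f1, f2), weighting = "per_peptide")
  expect_equal(unname(spp$p[1:2]), c(38, 2) / 40)
  # identical runs give identical subset profiles
  sp3 <- size_probability(list(list(f1, f2), list(f1, f2)), subsets = 2)
  expect_equal(sp3$p_subsets[1, ], sp3$p_subsets[2, ])
  expect_error(size_probability(matrix(0L, 2, 20)), "empty")
})

test_that("free_energy_profile is -ln P shifted to zero", {
  flat <- free_energy_profile(rep(0.25, 4))
  expect_equal(flat$f, rep(0, 4))
  prof <- free_energy_profile(c(0.5, 0.25, 0.25))
  expect_equal(prof$f, c(0, log(2), log(2)))
  gap <- free_energy_profile(c(0.5, 0, 0.5))
  expect_true(is.na(gap$f[2]))
  expect_error(free_energy_profile(c(0.5, 0.4)), "normalized")
})

test_that("the F estimator converges with sample size (Boltzmann sampling)", {
  set.seed(101)
  f_true <- c(0, 1, 2, 1.2, 0.4)
  p_true <- exp(-f_true) / sum(exp(-f_true))
  err <- vapply(c(1e3, 1e5), function(m) {
    counts <- as.vector(rmultinom(1, m, p_true))
    fh <- -log(counts / m); fh <- fh - min(fh)
    max(abs(fh - f_true))
  }, 1.0)
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.05)
})

test_that("critical nucleus: argmax, plateau ranges, monotone flag", {
  mk <- function(f) {
    p <- exp(-f) / sum(exp(-f))
    free_energy_profile(p, coord = seq_along(f))
  }
  f <- c(0, 1, 2, 3, 4.5, 3.5, 2, 1, 0.5, 0.2)
  nuc <- critical_nucleus(mk(f))
  expect_false(nuc$no_nucleus)
  expect_equal(nuc$n_star, 5)
  # tie within tolerance reported as a range
  f2 <- c(0, 1, 2, 4.3, 4.5, 3, 2, 1, 0.5, 0.2)
  nuc2 <- critical_nucleus(mk(f2), tol = 0.5)
  expect_equal(nuc2$n_star, 5)
  expect_equal(nuc2$range, c(4, 5))
  # monotone profile: no nucleus
  mono <- critical_nucleus(mk(seq(0, 3, length.out = 8)))
  expect_true(mono$no_nucleus)
  # temperature label does not change the kBT-unit profile or the nucleus
  nuc_t <- critical_nucleus(free_energy_profile(exp(-f) / sum(exp(-f)),
                                                temperature = 280))
  expect_equal(nuc_t$n_star, nuc$n_star)
})

test_that("beta-residue profile reports the FIRST interior maximum", {
  # engineered profile: barrier at 26, deep well at 60, finite-size rise
  grid <- 0:80
  f <- 2.5 * exp(-((grid - 26) / 6)^2) - 2 * exp(-((grid - 60) / 8)^2)
  f[grid > 70] <- f[grid > 70] + 0.1 * (grid[grid > 70] - 70)   # boundary rise
  p <- exp(-f) / sum(exp(-f))
  counts <- rep(grid, times = pmax(1L, round(p * 2e5)))   # deterministic
  bfe <- beta_residue_free_energy(counts)
  expect_false(bfe$no_nucleus)
  expect_lt(abs(bfe$critical$count - 26), 4)      # first max, not the rise
  # histogram exactness on engineered fixed counts
  bfe2 <- beta_residue_free_energy(c(3, 3, 5, 5, 5, 9))
  expect_equal(bfe2$profile$counts[c(4, 6, 10)], c(2L, 3L, 1L))
  # uniform counts: flat, no nucleus
  bfe3 <- beta_residue_free_energy(rep(0:4, 100))
  expect_true(bfe3$no_nucleus)
})

test_that("CNT free energy: bulk/surface split and stationary point", {
  expect_equal(cnt_free_energy(8, 1, 2.5), 2.5 * 8^(2 / 3))   # S=1: surface only
  S <- 1.4; th <- 4
  ns <- cnt_nstar(S, th)
  g <- cnt_free_energy(1:1e4, S, th)
  expect_equal(which.max(g), round(ns), tolerance = 0.51)
  expect_lt(g[ceiling(ns) + 50] - g[ceiling(ns) + 49], 0)      # downhill beyond
  expect_error(cnt_free_energy(5, -1, 2), "positive")
  expect_error(cnt_nstar(0.9, 2), "S > 1")
})

test_that("cnt_fit recovers parameters and warns on small systems", {
  n <- 1:200
  f <- cnt_free_energy(n, 1.3, 3.2)
  p <- exp(-f) / sum(exp(-f))
  prof <- free_energy_profile(p, coord = n)
  fit <- cnt_fit(prof, small_system_max = 20)
  expect_equal(fit$S, 1.3, tolerance = 1e-4)
  expect_equal(fit$theta, 3.2, tolerance = 1e-4)
  expect_false(fit$degenerate)
  expect_null(fit$warning)
  # 20-monomer profile: mandatory warning
  n20 <- 1:20
  p20 <- exp(-cnt_free_energy(n20, 1.3, 3.2))
  prof20 <- free_energy_profile(p20 / sum(p20), coord = n20)
  expect_warning(fit20 <- cnt_fit(prof20), "small finite system")
  expect_false(is.null(fit20$warning))
  # flat profile flagged degenerate
  flat <- free_energy_profile(rep(1 / 6, 6))
  expect_true(cnt_fit(flat)$degenerate)
})
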