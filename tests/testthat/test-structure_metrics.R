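# Dihedrals, beta-state classification, DSSP-style H-bonds, contacts.

test_that("dihedral follows the IUPAC convention and handles degeneracy", {
  # planar trans zig-zag
  expect_equal(dihedral(c(0, 1, 0), c(1, 0, 0), c(2, 1, 0), c(3, 0, 0)), 180)
  # planar cis
  expect_equal(dihedral(c(0, 1, 0), c(1, 0, 0), c(2, 1, 0), c(1.5, 2, 0)), 0)
  # collinear -> flagged NA
  d <- dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_true(is.na(d))
  expect_equal(attr(d, "reason"), "degenerate")
})

test_that("dihedral is invariant under rigid motion (100 random rotations)", {
  set.seed(7)
  pts <- list(c(0.2, 1, 0.5), c(1, 0, 0), c(2, 1.3, 0), c(3, 0.1, 0.8))
  ref <- dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
  for (k in 1:100) {
    R <- oracle_rotation(); tr <- rnorm(3, sd = 10)
    mv <- lapply(pts, function(p) as.numeric(R %*% p + tr))
    expect_equal(dihedral(mv[[1]], mv[[2]], mv[[3]], mv[[4]]), ref,
                 tolerance = 1e-6 / abs(ref))
  }
})

test_that("beta windows classify canonical points and closed boundaries", {
  cr <- default_criteria()
  expect_true(residue_beta_state(-120, 130, cr))    # canonical beta
  expect_false(residue_beta_state(-60, -45, cr))    # alpha helix
  expect_true(residue_beta_state(150, 0, cr))       # exactly on window edges
  expect_true(residue_beta_state(-180, 180, cr))
  u <- residue_beta_state(NA, 130, cr)
  expect_false(as.logical(u))
  expect_equal(attr(u, "reason"), "undefined")
})

test_that("peptide beta state applies the >= 3 residue rule", {
  expect_true(peptide_beta_state(c(rep(TRUE, 3), rep(FALSE, 4))))
  expect_false(peptide_beta_state(c(rep(TRUE, 2), rep(FALSE, 5))))
  expect_true(peptide_beta_state(rep(TRUE, 7)))
  expect_true(peptide_beta_state(rep(FALSE, 7), min_count = 0))
})

test_that("hbond_energy matches the Kabsch-Sander form", {
  # ideal linear N-H...O=C geometry, r(N...O) = 2.9 A
  N <- c(0, 0, 0); H <- c(1.0, 0, 0); O <- c(2.9, 0, 0); C <- c(4.13, 0, 0)
  e <- hbond_energy(N, H, C, O)
  oracle <- 0.084 * 332 * (1 / 2.9 + 1 / (4.13 - 1) - 1 / (2.9 - 1) - 1 / 4.13)
  expect_equal(e, oracle, tolerance = 1e-12)
  expect_lt(e, -0.5)
  # distant pair: all 1/r terms vanish
  far <- hbond_energy(N, H, C + c(50, 0, 0), O + c(50, 0, 0))
  expect_lt(abs(far), 0.01)
  # rigid rotation invariance
  set.seed(3)
  R <- oracle_rotation()
  e2 <- hbond_energy(c(R %*% N), c(R %*% H), c(R %*% C), c(R %*% O))
  expect_equal(e2, e, tolerance = 1e-10)
  # clash
  expect_warning(ec <- hbond_energy(N, H, c(0.2, 0, 0), O), "clash")
  expect_identical(ec, Inf)
})

test_that("interstrand H-bonds: ideal sheets bond, distant/self do not", {
  sh <- fixture_sheet(2, "antiparallel")
  hb <- interstrand_hbonds(sh$frame, sh$topology, 1, 2)
  expect_gte(nrow(hb), 2)
  expect_true(all(hb$energy < -0.5))
  # union independent of scan order
  hb2 <- interstrand_hbonds(sh$frame, sh$topology, 2, 1)
  key <- function(h) sort(paste(h$donor_chain, h$donor_res,
                                h$acceptor_chain, h$acceptor_res))
  expect_identical(key(hb), key(hb2))
  expect_error(interstrand_hbonds(sh$frame, sh$topology, 1, 1), "differ")
  # two far-apart peptides
  topo2 <- topology("GNNQQNY", n_chains = 2)
  c1 <- sh$frame$coords[1:42, ]
  fr <- frame(rbind(c1, c1 + 60), 200, 0)
  expect_equal(nrow(interstrand_hbonds(fr, topo2, 1, 2)), 0)
})

test_that("side-chain contacts match a brute-force oracle", {
  set.seed(21)
  sh <- fixture_sheet(3)
  co <- sidechain_contacts(sh$frame, sh$topology, cutoff = 6.5)
  sc <- sh$topology$atoms[sh$topology$atoms$role == "SC", ]
  oracle <- oracle_contacts(sh$frame$coords[sc$atom, ], sc$chain, 6.5,
                            sh$frame$box_edge)
  expect_equal(as.integer(co), oracle)
  # boundary behaviour on a hand-built pair
  topo2 <- topology("GG", n_chains = 2)   # 2 chains x 2 residues
  base <- matrix(0, 24, 3)
  base[, 1] <- rep(seq(0, 5.75, by = 0.25), 1)[1:24]
  mk <- function(gap) {
    xyz <- base
    xyz[13:24, ] <- base[13:24, ] + matrix(rep(c(0, gap, 0), each = 12), 12)
    # isolate the SC beads: move non-SC atoms far away
    sc_rows <- which(topo2$atoms$role == "SC")
    xyz[setdiff(1:24, sc_rows), 3] <- 90
    xyz[sc_rows, 1] <- 0
    frame(xyz, 200, 0)
  }
  expect_equal(as.integer(sidechain_contacts(mk(6.4), topo2, 6.5)), 4)
  expect_equal(as.integer(sidechain_contacts(mk(6.6), topo2, 6.5)), 0)
  # intra-peptide pairs never count
  one <- topology("GNNQQNY")
  fro <- frame(matrix(rnorm(42 * 3), ncol = 3) + 50, 200, 0)
  expect_equal(as.integer(sidechain_contacts(fro, one, 10)), 0)
})

test_that("frame beta fraction equals the mean of residue flags", {
  sh <- fixture_sheet(2)
  rep_ <- beta_state_report(sh$frame, sh$topology)
  expect_equal(rep_$beta_fraction, mean(rep_$residue_flags$beta))
  expect_true(all(rep_$peptide_beta))
  # minimum-image invariance of the H-bond scan: shift one box length
  fr2 <- frame(sh$frame$coords + sh$frame$box_edge, sh$frame$box_edge, 0)
  hb1 <- interstrand_hbonds(sh$frame, sh$topology, 1, 2)
  hb2 <- interstrand_hbonds(fr2, sh$topology, 1, 2)
  expect_equal(nrow(hb1), nrow(hb2))
  expect_equal(sort(hb1$energy), sort(hb2$energy), tolerance = 1e-9)
})
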