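# System-level energy decomposition and analytic forces.

test_that("straight relaxed chain has zero bonded energy and nicks remove a zero term", {
  p <- model_params()
  sys <- straight_chain(8, p)
  e <- total_energy(sys$state, sys$topology, p)
  expect_equal(e$fene, 0, tolerance = 1e-9)
  expect_equal(e$bend, 0, tolerance = 1e-9)
  expect_equal(e$dihedral, 0, tolerance = 1e-9)
  # nicking a straight chain changes nothing
  nicked <- apply_nick(sys$topology, 4)
  expect_equal(total_energy(sys$state, nicked, p)$total, e$total, tolerance = 1e-12)
  # gap on a straight chain leaves bonded terms zero too
  gapped <- apply_gap(sys$topology, 3, params = p)
  eg <- total_energy(sys$state, gapped, p)
  expect_equal(eg$bend, 0, tolerance = 1e-9)
  expect_equal(eg$dihedral, 0, tolerance = 1e-9)
})

test_that("a close M-bead pair carries the sum of the WCA and DH pair energies", {
  p <- model_params()
  # two-unit chain stretched is unusable (bonded pair is excluded), so use the
  # 1-3 pair of a bent three-bead chain at distance 1.5
  topo <- chain_topology(3, circular = FALSE, params = p)
  # isoceles: beads 1 and 3 at distance 1.5, bonds of length 1
  h <- sqrt(1 - 0.75^2)
  m <- rbind(c(0, 0, 0), c(0.75, h, 0), c(1.5, 0, 0))
  fr <- supercoilr:::build_frames(m, FALSE)
  st <- conformation(rbind(m, fr$a, fr$p))
  e <- total_energy(st, topo, p)
  expect_equal(e$wca, wca_energy(1.5, p), tolerance = 1e-9)
  expect_equal(e$dh, dh_energy(1.5, -2, -2, p), tolerance = 1e-5)
})

test_that("forces equal the negative energy gradient everywhere, including at nicks, gaps and exemptions", {
  p <- model_params()
  sys <- small_circle(12, seed = 3, params = p)
  topo <- apply_nick(sys$topology, 2)
  topo <- apply_gap(topo, 6, params = p)
  topo <- enable_topoiii(topo)
  set.seed(4)
  st <- conformation(sys$state$positions +
                       matrix(rnorm(length(sys$state$positions), sd = 0.04), ncol = 3))
  f <- forces(st, topo, p)
  set.seed(9)
  beads <- sample(nrow(st$positions), 24, replace = TRUE)
  coords <- sample(3, 24, replace = TRUE)
  for (t in seq_along(beads)) {
    fd <- fd_force(st, topo, p, beads[t], coords[t])
    expect_equal(f[beads[t], coords[t]], fd, tolerance = 1e-4)
  }
  # translation invariance: total force vanishes
  expect_lt(max(abs(colSums(f))), 1e-10)
})

test_that("isolated beads beyond all cutoffs feel no force", {
  p <- model_params()
  topo <- chain_topology(2, circular = FALSE, params = p)
  m <- rbind(c(0, 0, 0), c(1, 0, 0))
  fr <- supercoilr:::build_frames(m, FALSE)
  st <- conformation(rbind(m, fr$a, fr$p))
  topo2 <- chain_topology(c(2), circular = FALSE, params = p)
  f <- forces(st, topo2, p)
  expect_lt(max(abs(f)), 1e-10)
})

test_that("energy errors name the overstretched bond", {
  p <- model_params()
  topo <- chain_topology(2, circular = FALSE, params = p)
  m <- rbind(c(0, 0, 0), c(1.7, 0, 0))
  fr <- supercoilr:::build_frames(m, FALSE)
  st <- conformation(rbind(m, fr$a, fr$p))
  expect_error(total_energy(st, topo, p), "FENE bond 1")
})
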