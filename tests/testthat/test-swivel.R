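# Active swivel, nick, gap and topoIII perturbations.

test_that("advance_swivel ramps the phase at 2 pi omega dt", {
  sw <- structure(list(junction = 0L, unit = 1, chain = 1, rate = 7e-4,
                       sign = 1, phase = 0), class = "sc_swivel")
  s1 <- advance_swivel(sw, 1)
  expect_equal(s1$phase, 2 * pi * 7e-4)
  s2 <- advance_swivel(sw, 1 / 7e-4)
  expect_equal(s2$accumulated_rotations, 1)
  sw0 <- sw; sw0$rate <- 0
  expect_equal(advance_swivel(sw0, 5)$phase, 0)
  expect_error(advance_swivel(sw, -1))
})

test_that("nicking a uniformly twisted circle releases exactly K_D(1 - cos dphi) per junction", {
  p <- model_params()
  sys <- small_circle(24, params = p)
  topo <- sys$topology
  # impose a uniform 0.1 rad twist strain by rotating every P offset
  st <- sys$state
  nm <- topo$n_m; nb <- nrow(topo$bonds)
  pos <- st$positions
  for (k in seq_len(nb)) {
    a <- topo$bonds[k, 1] + 1; b <- topo$bonds[k, 2] + 1
    t_hat <- pos[b, ] - pos[a, ]; t_hat <- t_hat / sqrt(sum(t_hat^2))
    u <- pos[nm + nb + k, ] - pos[nm + k, ]
    th <- 0.1 * (k - 1)
    rot <- u * cos(th) + supercoilr:::pracma_cross(t_hat, u) * sin(th) +
      t_hat * sum(t_hat * u) * (1 - cos(th))
    pos[nm + nb + k, ] <- pos[nm + k, ] + rot
  }
  st$positions <- pos
  e0 <- total_energy(st, topo, p)$dihedral
  nicked <- apply_nick(topo, 5)
  e1 <- total_energy(st, nicked, p)$dihedral
  # the four-point dihedral differs from the imposed transport rotation only
  # at second order in the polygon's bending angle
  expect_equal(e0 - e1, p$dihedral_constant * (1 - cos(0.1)), tolerance = 0.02)
})

test_that("gaps halve the local charge, soften bending and disable three dihedrals", {
  p <- model_params()
  sys <- small_circle(24, params = p)
  topo <- apply_gap(sys$topology, 10, params = p)
  beads <- 11:13 # 0-based units 10..12
  expect_equal(topo$charge[beads], rep(-1, 3))
  expect_equal(sum(topo$jun_enabled == 0), 3)
  expect_equal(sum(topo$angle_k == p$bend_constant_gap), 3)
  # DH pair energy with a duplex bead is half the duplex-duplex value
  expect_equal(dh_energy(1.5, -1, -2, p), dh_energy(1.5, -2, -2, p) / 2)
})

test_that("gap angles fluctuate more than duplex angles at equilibrium", {
  p <- model_params()
  sys <- small_circle(30, params = p)
  topo <- apply_gap(sys$topology, 12, params = p)
  s <- langevin_settings(n_steps = 6e4, params = p, seed = 8, obs_every = 0,
                         snapshot_every = 500)
  tr <- run_dynamics(sys$state, topo, p, s)
  ang_var <- function(snapshot, mid) {
    m <- m_positions(snapshot, topo)
    n <- nrow(m)
    im <- (mid - 1) %% n + 1; ip <- mid %% n + 1; i0 <- (mid - 2) %% n + 1
    u <- m[im, ] - m[i0, ]; v <- m[ip, ] - m[im, ]
    acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
  }
  snaps <- tr$snapshots[-seq_len(20)]
  th_gap <- vapply(snaps, ang_var, numeric(1), mid = 14) # inside the gap
  th_dup <- vapply(snaps, ang_var, numeric(1), mid = 29) # duplex region
  expect_gt(mean(th_gap^2), 2 * mean(th_dup^2))
})

test_that("topoIII mode exempts exactly the gap/duplex pairs and needs a gap", {
  p <- model_params()
  sys <- small_circle(20, params = p)
  expect_error(enable_topoiii(sys$topology), "no gap")
  topo <- apply_gap(sys$topology, 5, params = p)
  topo <- enable_topoiii(topo)
  expect_equal(topo$topoiii, 1L)
  n <- 20
  # 3 gap beads x (n - 3) others minus 2x2 bonded pairs at the gap borders
  expect_equal(supercoilr:::count_topoiii_exemptions(topo), 3 * (n - 3) - 2)
})

test_that("site collisions between swivels, nicks and gaps are rejected", {
  p <- model_params()
  sys <- small_circle(24, params = p)
  topo <- add_swivel(sys$topology, 0)
  expect_error(apply_nick(topo, 0), "active swivel")
  expect_error(apply_gap(topo, 23, params = p), "active swivel")
  nicked <- apply_nick(sys$topology, 3)
  expect_error(add_swivel(nicked, 3), "nicked")
})

test_that("a nicked circle under sustained swiveling reaches a bounded torsional plateau, an intact one does not", {
  p <- model_params()
  sys <- small_circle(32, params = p)
  run_one <- function(topo) {
    s <- langevin_settings(n_steps = 3e5, params = p, timestep = 0.002,
                           seed = 11, obs_every = 3000)
    run_dynamics(sys$state, topo, p, s)$observables
  }
  intact <- add_swivel(sys$topology, 0, rate = 1e-2)
  nickd <- apply_nick(add_swivel(sys$topology, 0, rate = 1e-2), 16)
  o1 <- run_one(intact)
  o2 <- run_one(nickd)
  # intact circle keeps absorbing linking: |Tw + Wr| grows to ~rotations
  lk1 <- abs(tail(o1$Tw_strain1 + o1$Wr1, 1))
  lk2 <- abs(tail(o2$Tw_strain1 + o2$Wr1, 1))
  expect_gt(lk1, 4)
  expect_lt(lk2, lk1 / 2)
  # and the nicked circle's torsional energy flattens: last two quarters agree
  n <- nrow(o2)
  q3 <- mean(o2$E_dih[seq(n %/% 2, 3 * n %/% 4)])
  q4 <- mean(o2$E_dih[seq(3 * n %/% 4, n)])
  expect_lt(abs(q4 - q3), 0.5 * max(q3, q4))
})
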