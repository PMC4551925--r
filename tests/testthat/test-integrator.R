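# Langevin velocity-Verlet: determinism, damping, diffusion, equipartition,
# NVE energy conservation.

test_that("identical seeds give bit-identical trajectories", {
  p <- model_params()
  sys <- small_circle(12, params = p)
  s <- langevin_settings(n_steps = 1500, params = p, seed = 42, obs_every = 500)
  t1 <- run_dynamics(sys$state, sys$topology, p, s)
  t2 <- run_dynamics(sys$state, sys$topology, p, s)
  expect_identical(t1$final_state$positions, t2$final_state$positions)
  expect_identical(t1$observables, t2$observables)
  s2 <- s; s2$seed <- 43
  t3 <- run_dynamics(sys$state, sys$topology, p, s2)
  expect_false(identical(t1$final_state$positions, t3$final_state$positions))
})

test_that("with friction but no noise the kinetic energy decays exponentially", {
  p <- model_params()
  sys <- straight_chain(3, p)
  st <- sys$state
  st$velocities[] <- 0
  st$velocities[seq_len(3), 1] <- 1 # push M beads along the chain axis
  st <- enforce_frame_constraints(st, sys$topology, p)
  s <- langevin_settings(n_steps = 1000, params = p, seed = 1, obs_every = 100,
                         kT = 0)
  tr <- run_dynamics(st, sys$topology, p, s)
  E <- tr$observables$E_kin
  t_end <- 1000 * p$timestep
  # kinetic energy decays at ~2 gamma_eff / m with gamma_eff between the
  # per-type drags (0.2 and 0.5 m/tau)
  rate <- -log(tail(E, 1) / E[1]) / (2 * t_end)
  expect_gt(rate, 0.2)
  expect_lt(rate, 0.8)
  # strictly monotone decay (no noise feeds energy back)
  expect_true(all(diff(E) < 0))
})

test_that("centre-of-mass diffusion obeys the Einstein relation", {
  p <- model_params()
  sys <- straight_chain(3, p)
  gamma_tot <- 3 * p$drag_M + 2 * p$drag_P + 2 * p$drag_A
  D_expect <- p$epsilon / gamma_tot
  set.seed(1)
  msd <- replicate(24, {
    s <- langevin_settings(n_steps = 4e4, params = p,
                           seed = sample.int(1e6, 1), obs_every = 4e4)
    tr <- run_dynamics(sys$state, sys$topology, p, s)
    com0 <- colMeans(sys$state$positions[1:3, ])
    com1 <- colMeans(tr$final_state$positions[1:3, ])
    sum((com1 - com0)^2)
  })
  t_tot <- 4e4 * p$timestep
  D_meas <- mean(msd) / (6 * t_tot)
  expect_equal(D_meas, D_expect, tolerance = 0.35)
})

test_that("without the thermostat total energy is conserved", {
  p <- model_params()
  sys <- small_circle(20, params = p)
  st <- sys$state
  set.seed(1)
  st$velocities <- matrix(rnorm(length(st$velocities), sd = 0.3), ncol = 3)
  st <- enforce_frame_constraints(st, sys$topology, p)
  s <- langevin_settings(n_steps = 1e4, params = p, seed = 1, obs_every = 200,
                         thermostat = FALSE)
  tr <- run_dynamics(st, sys$topology, p, s)
  E <- tr$observables$E_pot + tr$observables$E_kin
  expect_lt((max(E) - min(E)) / abs(mean(E)), 1e-3)
})

test_that("kinetic energy satisfies equipartition over the unconstrained degrees of freedom", {
  p <- model_params()
  sys <- small_circle(20, params = p)
  s <- langevin_settings(n_steps = 1e5, params = p, seed = 123, obs_every = 200)
  tr <- run_dynamics(sys$state, sys$topology, p, s)
  kin <- tr$observables$E_kin
  dof <- 4 * 20 # 3 per M bead + 1 torsional per frame
  expect_equal(mean(tail(kin, 400)) * 2 / dof, 1.0, tolerance = 0.05)
})

test_that("aborts on FENE overstretch carry diagnostics and the partial trajectory", {
  p <- model_params()
  sys <- straight_chain(4, p)
  st <- sys$state
  st$velocities[1, 1] <- -400 # slam the first bead away
  err <- tryCatch(
    run_dynamics(st, sys$topology, p,
                 langevin_settings(n_steps = 5000, params = p, seed = 1)),
    error = function(e) e)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "aborted")
  expect_s3_class(err$trajectory, "sc_trajectory")
})
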