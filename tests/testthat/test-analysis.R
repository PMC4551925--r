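# Estimators: rotational diffusion and persistence length.

test_that("the MSD estimator recovers the diffusion coefficient of a synthetic rotor", {
  # overdamped rotor: Brownian angle with known D = kT / gamma_r
  D_true <- 2.5
  dt <- 0.05
  # intermediate-lag MSD slopes trade efficiency for robustness to inertia
  # and internal modes, so the statistical precision is modest
  set.seed(42)
  series <- lapply(1:24, function(i) cumsum(rnorm(40000, sd = sqrt(2 * D_true * dt))))
  r <- rotational_diffusion_coefficient(series, dt)
  expect_equal(r$D, D_true, tolerance = 0.15)
  expect_false(r$flagged)
})

test_that("doubling all drags halves the measured rotational diffusion", {
  p1 <- model_params()
  p2 <- model_params(drag_M = 1.0, drag_P = 0.4, drag_A = 0.4, validate = FALSE)
  r1 <- measure_rotational_diffusion(p1, n_steps = 2e6, n_rep = 6, seed = 3)
  r2 <- measure_rotational_diffusion(p2, n_steps = 2e6, n_rep = 6, seed = 3)
  expect_equal(r2$D / r1$D, 0.5, tolerance = 0.25)
})

test_that("persistence length estimator is exact on synthetic worm-like chains", {
  # generate ideal discrete WLC tangents with K_b = 12 (lp ~ 11.5 bonds) and
  # feed them through the estimator as a fake trajectory
  K <- 12
  set.seed(8)
  n_bonds <- 79
  make_chain <- function() {
    t_hat <- matrix(0, n_bonds, 3)
    t_hat[1, ] <- c(0, 0, 1)
    for (k in 2:n_bonds) {
      # theta from density ~ sin(theta) exp(-K (1 - cos theta))
      repeat {
        ct <- 1 + log(runif(1)) / K # inverse CDF of exp(K ct) on [-1, 1], approx
        if (ct >= -1) break
      }
      st_ <- sqrt(1 - ct^2)
      phi <- runif(1, 0, 2 * pi)
      # rotate previous tangent by (theta, phi)
      tz <- t_hat[k - 1, ]
      e1 <- supercoilr:::pracma_cross(tz, c(1, 0, 0))
      if (sqrt(sum(e1^2)) < 1e-6) e1 <- supercoilr:::pracma_cross(tz, c(0, 1, 0))
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- supercoilr:::pracma_cross(tz, e1)
      t_hat[k, ] <- ct * tz + st_ * (cos(phi) * e1 + sin(phi) * e2)
    }
    apply(rbind(c(0, 0, 0), t_hat), 2, cumsum)
  }
  snaps <- replicate(300, make_chain(), simplify = FALSE)
  fake_topo <- list(chains = list(list(first = 0, n_units = n_bonds + 1,
                                       circular = FALSE)))
  fake <- list(snapshots = snaps, topology = fake_topo)
  class(fake) <- "sc_trajectory"
  r <- persistence_length(fake, model_params())
  lp_true <- -1 / log(1 / tanh(K) - 1 / K + 1 - 1) # coth K - 1/K
  lp_true <- -1 / log(1 / tanh(K) - 1 / K)
  expect_equal(r$Lp_sigma, lp_true, tolerance = 0.08)
  expect_false(r$flagged)
})

test_that("freely jointed chains have persistence length near one bond", {
  # uniform random tangents: mean cos ~ 0, lp below 2 bonds
  set.seed(2)
  n_bonds <- 40
  snaps <- replicate(200, {
    steps <- matrix(rnorm(3 * n_bonds), ncol = 3)
    steps <- steps / sqrt(rowSums(steps^2))
    apply(rbind(c(0, 0, 0), steps), 2, cumsum)
  }, simplify = FALSE)
  fake_topo <- list(chains = list(list(first = 0, n_units = n_bonds + 1,
                                       circular = FALSE)))
  fake <- list(snapshots = snaps, topology = fake_topo)
  class(fake) <- "sc_trajectory"
  r <- persistence_length(fake, model_params())
  expect_lt(r$Lp_sigma, 2)
})

test_that("bending-only chains approach the worm-like chain stiffness", {
  # simulate with charges and excluded volume off: lp should approach the
  # analytic discrete WLC value for the bending constant
  p <- model_params(charge_per_bead = -1e-12, sigma_ex = 0.2,
                    dihedral_constant = 1e-9, bend_constant = 10,
                    validate = FALSE)
  r <- measure_persistence_length(p, n_units = 40, n_rep = 4, n_steps = 6e5,
                                  warm_steps = 1.5e5, timestep = 0.004, seed = 4,
                                  snapshot_every = 2000)
  lp_expect <- -1 / log(1 / tanh(10) - 1 / 10)
  expect_equal(r$Lp_sigma, lp_expect, tolerance = 0.2)
})

test_that("bending-constant tuning errors on unreachable targets", {
  p <- model_params()
  expect_error(
    tune_bending_constant(target_lp_sigma = 0.2, params = p, lo = 1, hi = 2,
                          n_units = 20, n_steps = 5e4, seed = 1),
    "unreachable|bracket")
})
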