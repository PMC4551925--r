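# Writhe, twist, linking number and knot identification.

test_that("writhe: planar circle zero, mirror antisymmetry, projection-count agreement", {
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  circ <- cbind(cos(th), sin(th), 0)
  expect_lt(abs(writhe(circ)[1]), 1e-6)
  p <- model_params()
  sys <- small_circle(20, knot = "3_1", seed = 2, params = p)
  poly <- m_positions(sys$state, sys$topology)
  w <- writhe(poly)[1]
  mirror <- poly %*% diag(c(1, 1, -1))
  expect_equal(writhe(mirror)[1], -w, tolerance = 1e-10)
  w_mc <- writhe_by_projection(poly, n_proj = 500)
  expect_equal(w, w_mc, tolerance = 0.05)
})

test_that("writhe rejects degenerate segments", {
  poly <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_error(writhe(poly), "degenerate")
})

test_that("twist counts frame rotation in turns", {
  p <- model_params()
  # straight 3-bead chain, second frame rotated by +0.1 rad
  topo <- chain_topology(3, circular = FALSE, params = p)
  m <- cbind(0:2, 0, 0)
  a <- cbind(c(0.5, 1.5), 0, 0)
  pb <- rbind(c(0.5, 1, 0), c(1.5, cos(0.1), sin(0.1)))
  st <- conformation(rbind(m, a, pb))
  expect_equal(twist(st, topo, p), 0.1 / (2 * pi), tolerance = 1e-12)
  # uniform full turn over an n-unit circle
  sys <- small_circle(30, params = p)
  st2 <- sys$state
  nm <- 30; nb <- 30
  pos <- st2$positions
  for (k in seq_len(nb)) {
    aa <- sys$topology$bonds[k, 1] + 1; bb <- sys$topology$bonds[k, 2] + 1
    t_hat <- pos[bb, ] - pos[aa, ]; t_hat <- t_hat / sqrt(sum(t_hat^2))
    u <- pos[nm + nb + k, ] - pos[nm + k, ]
    th <- 2 * pi * (k - 1) / nb
    rot <- u * cos(th) + supercoilr:::pracma_cross(t_hat, u) * sin(th) +
      t_hat * sum(t_hat * u) * (1 - cos(th))
    pos[nm + nb + k, ] <- pos[nm + k, ] + rot
  }
  st2$positions <- pos
  expect_equal(abs(twist(st2, sys$topology, p)), 1, tolerance = 1e-6)
})

test_that("Gauss linking number is exact for torus links and zero for split circles", {
  p <- model_params()
  for (n_links in c(1, 3)) {
    spec <- scenario_spec(topology = "catenane", size_bp = 400, n_links = n_links,
                          seed = 3)
    cc <- build_catenane(spec, p)
    lk <- gauss_linking_number(m_positions(cc$state, cc$topology, 1),
                               m_positions(cc$state, cc$topology, 2))
    expect_equal(abs(lk), n_links)
  }
  th <- seq(0, 2 * pi, length.out = 31)[-31]
  c1 <- cbind(cos(th), sin(th), 0)
  c2 <- cbind(25 + cos(th), sin(th), 0)
  expect_identical(gauss_linking_number(c1, c2), 0L)
  expect_error(gauss_linking_number(c1, c2, closed_a = FALSE), "closed")
})

test_that("knot determinant identifies unknot, trefoil and 8_18, invariant over projections", {
  p <- model_params()
  expect_identical(knot_determinant(m_positions(small_circle(20)$state,
                                                small_circle(20)$topology)), 1L)
  s3 <- small_circle(25, knot = "3_1", seed = 2)
  expect_identical(knot_determinant(m_positions(s3$state, s3$topology)), 3L)
  s8 <- build_chain(scenario_spec(topology = "circle", size_bp = 1000,
                                  knot = "8_18", seed = 2), p)
  poly8 <- m_positions(s8$state, s8$topology)
  expect_identical(knot_determinant(poly8), 45L)
  # projection invariance: many independent projections must agree
  set.seed(77)
  expect_identical(knot_determinant(poly8, n_projections = 25), 45L)
})

test_that("the geometric determinants match the combinatorial braid-word oracle", {
  # trefoil as the closure of sigma1^3; 8_18 as the closure of (s1 s2^-1)^4
  expect_equal(braid_determinant(c(1, 1, 1), 2), 3)
  expect_equal(braid_determinant(rep(c(1, -2), 4), 3), 45)
  tri <- supercoilr:::braid_closure_curve(c(1, 1, 1), n_strands = 2)
  expect_identical(knot_determinant(tri), 3L)
  oct <- supercoilr:::braid_closure_curve(rep(c(1, -2), 4))
  expect_identical(knot_determinant(oct), 45L)
})

test_that("KMT reduction preserves the knot type while shrinking the polygon", {
  s3 <- small_circle(40, knot = "3_1", seed = 6)
  poly <- m_positions(s3$state, s3$topology)
  red <- supercoilr:::cpp_kmt(poly)
  expect_lt(nrow(red), nrow(poly))
  expect_identical(knot_determinant(red, reduce = FALSE),
                   knot_determinant(poly, reduce = FALSE))
})

test_that("Lk = Tw + Wr is an integer for closed frames and conserved by dynamics", {
  p <- model_params()
  for (knot in c("none", "3_1")) {
    sys <- small_circle(24, knot = knot, seed = 4, params = p)
    lk0 <- linking_number(sys$state, sys$topology, p)
    expect_equal(lk0, round(lk0), tolerance = 0.02)
    s <- langevin_settings(n_steps = 2e4, params = p, seed = 5, obs_every = 2e4)
    tr <- run_dynamics(sys$state, sys$topology, p, s)
    lk1 <- linking_number(tr$final_state, sys$topology, p)
    expect_equal(lk1, lk0, tolerance = 0.02)
  }
})
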