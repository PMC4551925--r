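# Builders: chains, knots, catenanes, thermalization.

test_that("bead counts follow the 8 bp per unit mapping", {
  p <- model_params()
  sys <- build_chain(scenario_spec(topology = "circle", size_bp = 3000), p)
  expect_equal(sys$topology$n_m, 375)
  expect_equal(nrow(sys$state$positions), 3 * 375)
  lin <- build_chain(scenario_spec(topology = "linear", size_bp = 80), p)
  expect_equal(lin$topology$n_m, 10)
  expect_equal(nrow(lin$state$positions), 10 + 2 * 9)
})

test_that("built chains satisfy geometry: unit bonds, exact frames, relaxed torsion", {
  p <- model_params()
  sys <- small_circle(40, knot = "3_1", seed = 3, params = p)
  m <- m_positions(sys$state, sys$topology)
  bonds <- rbind(m[-1, ], m[1, ]) - m
  bl <- sqrt(rowSums(bonds^2))
  expect_true(all(abs(bl - 1) < 0.05))
  expect_lt(max(constraint_residuals(sys$state, sys$topology)), 1e-9)
  # torsionally relaxed start: twist strain spread evenly, |Tw| < 1 turn
  expect_lt(abs(twist(sys$state, sys$topology, p)), 0.6)
})

test_that("requested knot types are realized and unknown ones rejected", {
  expect_identical(knot_determinant(m_positions(small_circle(30, "3_1", 2)$state,
                                                small_circle(30, "3_1", 2)$topology)), 3L)
  expect_error(build_chain(scenario_spec(topology = "circle", size_bp = 400,
                                         knot = "5_1")), "supported")
})

test_that("planar starting unknots have zero writhe and determinant 1", {
  sys <- small_circle(35)
  poly <- m_positions(sys$state, sys$topology)
  expect_lt(abs(writhe(poly)[1]), 1e-6)
  expect_identical(knot_determinant(poly), 1L)
})

test_that("linear chains can carry an interior pre-tied knot", {
  p <- model_params()
  lin <- build_chain(scenario_spec(topology = "linear", size_bp = 480,
                                   knot = "3_1", seed = 4), p)
  poly <- m_positions(lin$state, lin$topology)
  # close by the far-point construction and identify the trefoil
  closed <- supercoilr:::close_arc(poly, "ray")
  expect_identical(knot_determinant(closed), 3L)
})

test_that("catenanes get the requested interlinking and optional gaps", {
  p <- model_params()
  spec <- scenario_spec(topology = "catenane", size_bp = 400, n_links = 2,
                        gap = list(list(start = 10, chain = 1),
                                   list(start = 10, chain = 2)),
                        topoiii = TRUE, seed = 5)
  cc <- build_catenane(spec, p)
  expect_equal(length(cc$topology$chains), 2)
  expect_equal(abs(gauss_linking_number(m_positions(cc$state, cc$topology, 1),
                                        m_positions(cc$state, cc$topology, 2))), 2)
  expect_equal(length(cc$topology$gaps), 2)
  expect_equal(cc$topology$topoiii, 1L)
  expect_error(build_catenane(scenario_spec(topology = "catenane",
                                            size_bp = 400, n_links = 0)),
               "linking number")
})

test_that("thermalization equilibrates the energy and preserves the knot", {
  p <- model_params()
  sys <- small_circle(25, knot = "3_1", seed = 9, params = p)
  warmed <- thermalize(sys, n_steps = 4e4, params = p, seed = 10)
  expect_true(is.logical(attr(warmed, "equilibrated")))
  expect_identical(knot_determinant(m_positions(warmed$state, warmed$topology)), 3L)
  # swivels must stay off during thermalization
  topo_sw <- add_swivel(sys$topology, 0, rate = 1e-2)
  warmed2 <- thermalize(list(topology = topo_sw, state = sys$state),
                        n_steps = 2e4, params = p, seed = 11)
  expect_equal(warmed2$topology$jun_phase[warmed2$topology$swivels[[1]]$junction + 1], 0)
})

test_that("initial velocities carry k_BT/2 per unconstrained degree of freedom", {
  p <- model_params()
  sys <- build_chain(scenario_spec(topology = "circle", size_bp = 1600, seed = 12), p)
  ke <- 0.5 * sum(sys$state$velocities^2)
  n <- 200
  expect_equal(ke / (4 * n / 2), 1, tolerance = 0.3)
})
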