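# Unit conversions and the time-unit calibration chain.

test_that("viscosity scaling follows Stokes' law", {
  expect_equal(scale_diffusion_by_viscosity(6e7, 5000), 1.2e4)
  expect_equal(scale_diffusion_by_viscosity(6e7, 1), 6e7)
  expect_equal(scale_diffusion_by_viscosity(6e7, 15000), 4e3)
  expect_error(scale_diffusion_by_viscosity(6e7, 0.5))
})

test_that("tau calibration divides simulated by target diffusion", {
  expect_equal(calibrate_tau(1.6, 1.2e4), 1.6 / 1.2e4)
  expect_equal(signif(calibrate_tau(1.6, 1.2e4), 2), 1.3e-4)
  expect_equal(calibrate_tau(5, 5), 1)
  expect_equal(calibrate_tau(0.8, 1.2e4), calibrate_tau(1.6, 1.2e4) / 2)
})

test_that("swivel-rate conversion reproduces the physical gyrase speed", {
  tau <- calibrate_tau(1.6, 1.2e4)
  expect_equal(signif(swivel_rate_physical(7e-4, tau), 2), 5.2)
  expect_equal(swivel_rate_physical(7e-3, tau), 10 * swivel_rate_physical(7e-4, tau))
  expect_equal(swivel_rate_physical(0, tau), 0)
})

test_that("Bjerrum length converts to reduced units", {
  expect_equal(signif(bjerrum_in_sigma(0.71, 2.5), 2), 0.28)
  expect_equal(bjerrum_in_sigma(2.5, 2.5), 1)
  expect_equal(bjerrum_in_sigma(0.71, 5), bjerrum_in_sigma(0.71, 2.5) / 2)
})

test_that("base-pair counts map to repeat units", {
  expect_equal(size_in_beads(3000), 375)
  expect_equal(size_in_beads(1000), 125)
  expect_equal(size_in_beads(8), 1)
  expect_warning(size_in_beads(1001), "rounding")
})

test_that("round-trip conversions are identities", {
  tau <- calibrate_tau(1.6, 1.2e4)
  omega_phys <- swivel_rate_physical(7e-4, tau)
  expect_equal(omega_phys * tau, 7e-4, tolerance = 1e-12)
  lb <- bjerrum_in_sigma(0.71, 2.5)
  expect_equal(lb * 2.5, 0.71, tolerance = 1e-12)
})

test_that("the full chain reproduces the printed calibration end-to-end", {
  ch <- calibration_chain(D_sim = 1.6)
  val <- function(q) ch$value[ch$quantity == q]
  expect_equal(val("D_rot target"), 1.2e4)
  expect_equal(signif(val("tau"), 2), 1.3e-4)
  expect_equal(signif(val("swivel rate (physical)"), 2), 5.2)
  expect_equal(topoiii_substrate_time(100, 5), 20)
})
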