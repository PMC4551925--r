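# Scenario registry and artifact pipeline (at drastically reduced step counts;
# the physics of the full reduced-scale scenarios is exercised in the
# acceptance suite).

test_that("the registry lists the figure scenarios and rejects unknown names", {
  expect_true(all(c("fig1_linear_knot", "fig2_nicked_circle_antipodal",
                    "fig3a_90deg", "fig3c_8_18", "fig4_gap",
                    "fig5a_topoIII_unknot", "fig5b_topoIII_decatenate")
                  %in% scenario_names()))
  expect_error(run_scenario("fig9_nonexistent"), "unknown scenario")
})

test_that("a shortened scenario run writes the full artifact set", {
  outdir <- tempfile("scen")
  res <- run_scenario("fig2_nicked_circle_antipodal",
                      overrides = list(dynamics = list(n_steps = 4e4,
                                                       snapshot_every = 1e4,
                                                       obs_every = 2000,
                                                       thermalize_steps = 5e3)),
                      seed = 2, outdir = outdir)
  expect_true(file.exists(file.path(outdir, "trajectory.xyz")))
  expect_true(file.exists(file.path(outdir, "observables.tsv")))
  expect_true(file.exists(file.path(outdir, "summary.json")))
  expect_true(file.exists(file.path(outdir, "config.yaml")))
  expect_true(file.exists(file.path(outdir, "manifest.json")))
  smry <- jsonlite::read_json(file.path(outdir, "summary.json"))
  expect_equal(smry$scenario, "fig2_nicked_circle_antipodal")
  expect_gt(smry$rotations_injected, 0)
  expect_equal(smry$determinant_end[[1]], 3) # far too short to unknot
})

test_that("overrides switch topoIII off and the knot then survives", {
  res <- run_scenario("fig5a_topoIII_unknot",
                      overrides = list(topoIII = list(enabled = FALSE),
                                       dynamics = list(n_steps = 3e4,
                                                       snapshot_every = 1e4,
                                                       obs_every = 3000,
                                                       thermalize_steps = 5e3)),
                      seed = 3)
  expect_equal(res$topology$topoiii, 0L)
  expect_equal(res$summary$determinant_end[1], 3L)
})
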