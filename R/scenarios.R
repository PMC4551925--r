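# Named figure scenarios at reduced (desk) scale, and the pipeline that
# builds, thermalizes, runs, analyzes and writes artifacts.

#' @rdname run_scenario
#' @export
scenario_names <- function() names(scenario_registry)

# Reduced-scale study conditions. Circles are 1000 bp (125 repeat units), the
# size for which the model's fast active-swivel rate of 7e-3 rotations/tau is
# defined; runs use a 0.004 tau step (see the methods vignette for the
# stability analysis behind the desk-scale step).
scenario_registry <- list(
  fig1_linear_knot = list(
    scenario = list(topology = "linear", size_bp = 1000, knot = "3_1"),
    swivel = list(unit = 62, rate = 7e-3),
    dynamics = list(timestep = 0.004, n_steps = 8e5, snapshot_every = 2e4,
                    obs_every = 4000, thermalize_steps = 3e4)),
  fig2_nicked_circle_antipodal = list(
    scenario = list(topology = "circle", size_bp = 1000, knot = "3_1"),
    swivel = list(unit = 0, rate = 7e-3),
    nick = list(unit = 62),
    dynamics = list(timestep = 0.004, n_steps = 2e6, snapshot_every = 2.5e4,
                    obs_every = 8000, thermalize_steps = 3e4)),
  fig3a_90deg = list(
    scenario = list(topology = "circle", size_bp = 1000, knot = "3_1"),
    swivel = list(unit = 0, rate = 7e-3),
    nick = list(unit = 31),
    dynamics = list(timestep = 0.004, n_steps = 2e6, snapshot_every = 2.5e4,
                    obs_every = 8000, thermalize_steps = 3e4)),
  fig3c_8_18 = list(
    scenario = list(topology = "circle", size_bp = 1000, knot = "8_18"),
    swivel = list(unit = 0, rate = 7e-3),
    nick = list(unit = 62),
    dynamics = list(timestep = 0.004, n_steps = 2e6, snapshot_every = 2.5e4,
                    obs_every = 8000, thermalize_steps = 3e4)),
  fig4_gap = list(
    scenario = list(topology = "circle", size_bp = 1000, knot = "3_1"),
    swivel = list(unit = 0, rate = 7e-3),
    gap = list(start = 61),
    dynamics = list(timestep = 0.004, n_steps = 2e6, snapshot_every = 2.5e4,
                    obs_every = 8000, thermalize_steps = 3e4)),
  fig5a_topoIII_unknot = list(
    scenario = list(topology = "circle", size_bp = 1000, knot = "3_1"),
    swivel = list(unit = 0, rate = 7e-3),
    gap = list(start = 61),
    topoIII = list(enabled = TRUE),
    dynamics = list(timestep = 0.004, n_steps = 1.5e6, snapshot_every = 2e4,
                    obs_every = 6000, thermalize_steps = 3e4)),
  fig5b_topoIII_decatenate = list(
    scenario = list(topology = "catenane", size_bp = 1000, n_links = 2),
    swivel = list(list(unit = 0, rate = 7e-3, chain = 1),
                  list(unit = 0, rate = 7e-3, chain = 2)),
    gap = list(list(start = 61, chain = 1), list(start = 61, chain = 2)),
    topoIII = list(enabled = TRUE),
    dynamics = list(timestep = 0.004, n_steps = 1.5e6, snapshot_every = 2e4,
                    obs_every = 6000, thermalize_steps = 3e4)))

merge_overrides <- function(base, overrides) {
  for (nm in names(overrides)) {
    if (is.list(base[[nm]]) && is.list(overrides[[nm]]) &&
        !is.null(names(overrides[[nm]])))
      base[[nm]] <- modifyList(base[[nm]], overrides[[nm]])
    else base[[nm]] <- overrides[[nm]]
  }
  base
}

#' Run a named figure scenario at reduced scale
#'
#' Builds the configuration, thermalizes it with the motor off, runs the
#' production dynamics, analyzes the topology and (optionally) writes the
#' full artifact set (trajectory XYZ, observables TSV, knot-report TSV,
#' summary JSON, manifest) to `outdir`.
#'
#' Available scenarios: knotted linear DNA under arising supercoiling;
#' nicked knotted circles with antipodal and 90-degree site placements; an
#' 8_18 knot pushed to a nick; a gapped knotted circle; topoIII-mediated
#' unknotting and decatenation.
#'
#' @param name one of [scenario_names()].
#' @param overrides nested list merged over the scenario defaults (e.g.
#'   `list(topoIII = list(enabled = FALSE))`).
#' @param seed RNG seed for the whole pipeline.
#' @param outdir artifact directory, or `NULL` to skip writing.
#' @param params base [model_params()].
#' @return (invisibly) list with `trajectory`, `summary`, `topology`.
#' @export
run_scenario <- function(name, overrides = list(), seed = 1, outdir = NULL,
                         params = model_params()) {
  if (!name %in% names(scenario_registry))
    stop("unknown scenario '", name, "'; available: ",
         paste(scenario_names(), collapse = ", "))
  cfg <- merge_overrides(scenario_registry[[name]], overrides)
  t0 <- proc.time()[["elapsed"]]
  sc <- cfg$scenario
  spec <- scenario_spec(topology = sc$topology, size_bp = sc$size_bp,
                        knot = if (is.null(sc$knot)) "none" else sc$knot,
                        n_links = if (is.null(sc$n_links)) 2 else sc$n_links,
                        swivel = cfg$swivel, nick = cfg$nick, gap = cfg$gap,
                        topoiii = isTRUE(cfg$topoIII$enabled), seed = seed)
  sys <- build_chain(spec, params)
  dyn <- cfg$dynamics
  sys <- thermalize(sys, n_steps = dyn$thermalize_steps, params = params,
                    seed = seed + 1,
                    check_knot = sc$topology == "circle")
  settings <- langevin_settings(n_steps = dyn$n_steps, params = params,
                                timestep = dyn$timestep, seed = seed + 2,
                                snapshot_every = dyn$snapshot_every,
                                obs_every = dyn$obs_every)
  traj <- run_dynamics(sys$state, sys$topology, params, settings)
  summary <- summarize_scenario(name, traj, spec)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_trajectory_xyz(traj, file.path(outdir, "trajectory.xyz"))
    write_observables(traj, file.path(outdir, "observables.tsv"))
    if (!is.null(summary$trace))
      write.table(summary$trace, file.path(outdir, "knot_report.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary[setdiff(names(summary), "trace")],
                         file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    cfg_full <- cfg; cfg_full$seed <- seed
    yaml::write_yaml(cfg_full, file.path(outdir, "config.yaml"))
    write_manifest(structure(cfg_full, class = "sc_config"), seed,
                   dyn$n_steps, proc.time()[["elapsed"]] - t0,
                   file.path(outdir, "manifest.json"))
  }
  invisible(list(trajectory = traj, summary = summary,
                 topology = traj$topology))
}

summarize_scenario <- function(name, traj, spec) {
  topo <- traj$topology
  obs <- traj$observables
  out <- list(scenario = name,
              rotations_injected = tail(obs$rotations, 1))
  # endpoint topology per closed chain
  dets <- tryCatch(chain_determinants(traj$final_state, topo),
                   error = function(e) NA_integer_)
  out$determinant_end <- dets
  if ("Lk12" %in% names(obs)) {
    out$lk_series_end <- round(tail(obs$Lk12, 1))
    out$lk_abs_monotone <- !is.unsorted(rev(round(abs(obs$Lk12))))
  }
  # writhe plateau: last two quarters of |Wr| agree within 15%
  if ("Wr1" %in% names(obs)) {
    w <- abs(obs$Wr1); nq <- length(w)
    q3 <- mean(w[seq(floor(nq / 2) + 1, floor(3 * nq / 4))])
    q4 <- mean(w[seq(floor(3 * nq / 4) + 1, nq)])
    out$wr_plateau <- is.finite(q3) && is.finite(q4) &&
      abs(q4 - q3) <= 0.15 * max(q4, q3, 1e-9)
    out$wr_final = q4
  }
  # knot-to-site approach statistics
  site <- if (!is.null(spec$nick)) spec$nick$unit
  else if (!is.null(spec$gap) && !is.null(spec$gap$start)) spec$gap$start + 1
  else NULL
  if (!is.null(site) && spec$topology == "circle" &&
      !spec$knot %in% c("none", "unknot") && !is.na(dets[1]) && dets[1] > 1) {
    tr <- tryCatch(knot_position_trace(traj, site), error = function(e) NULL)
    if (!is.null(tr) && nrow(tr) >= 4) {
      out$trace <- tr
      out$approach <- attr(tr, "summary")
    }
  }
  out
}
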