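# Langevin velocity-Verlet driver and constraint projection.

#' Settings of a Langevin dynamics run
#'
#' The integrator is velocity Verlet with per-bead-type friction and a
#' fluctuation-dissipation-consistent random force (variance 2 gamma k_BT /
#' dt per Cartesian component per step). Rigid-frame constraints (axial bead
#' at the bond midpoint; periaxial offset of unit length, perpendicular to
#' the bond) are enforced after every step by an iterative symmetric
#' projection that preserves the torsional azimuth.
#'
#' @param n_steps number of integration steps.
#' @param params [model_params()]; supplies the default timestep.
#' @param timestep integration step, tau.
#' @param seed RNG seed of the run (recorded in the manifest; a run is fully
#'   reproducible from seed + configuration).
#' @param snapshot_every store a full conformation every this many steps
#'   (0 = only first and last).
#' @param obs_every log observables (energies, twist, writhe, swivel
#'   rotations) every this many steps.
#' @param thermostat couple to the Langevin bath; `FALSE` gives energy-
#'   conserving NVE dynamics (no friction, no noise).
#' @param kT bath temperature in epsilon; 0 with `thermostat = TRUE` gives
#'   pure friction (deterministic damping).
#' @param track_bond 0-based bond index whose periaxial azimuth is
#'   accumulated every step (for rotational-diffusion measurements);
#'   -1 disables.
#' @return an `sc_settings` list.
#' @export
langevin_settings <- function(n_steps = 1e4, params = model_params(),
                              timestep = params$timestep, seed = 1,
                              snapshot_every = 0L,
                              obs_every = max(1L, as.integer(n_steps / 500)),
                              thermostat = TRUE, track_bond = -1L,
                              kT = params$epsilon) {
  stopifnot(timestep > 0, n_steps >= 1)
  structure(list(timestep = timestep, n_steps = n_steps, seed = seed,
                 snap_every = as.integer(snapshot_every),
                 obs_every = as.integer(obs_every),
                 thermostat = thermostat, kT = kT,
                 track_bond = as.integer(track_bond)),
            class = "sc_settings")
}

topo_for_core <- function(topo) topo[c("n_m", "bonds", "junctions",
                                       "jun_enabled", "jun_phase",
                                       "jun_active", "jun_rate", "jun_sign",
                                       "angles", "angle_k", "charge", "gap",
                                       "topoiii", "topoiii_dh", "excl_pairs",
                                       "chains")]

#' Run Langevin dynamics
#'
#' Integrates the system for `settings$n_steps` steps, advancing active
#' swivel phases continuously, and returns the trajectory: snapshots,
#' an observables table (energies, twist, writhe, linking number for
#' two-chain systems, injected swivel rotations) and the final state.
#' Identical seed and inputs give an identical trajectory.
#'
#' @param state an `sc_state`.
#' @param topo an `sc_topology`.
#' @param params [model_params()].
#' @param settings [langevin_settings()].
#' @return an `sc_trajectory`.
#' @export
run_dynamics <- function(state, topo, params = model_params(),
                         settings = langevin_settings()) {
  res <- cpp_run(state$positions, state$velocities, topo_for_core(topo),
                 params_for_core(params), unclass(settings))
  obs <- as.data.frame(res$obs)
  obs$E_pot <- obs$E_fene + obs$E_wca + obs$E_dh + obs$E_bend + obs$E_dih
  nch <- length(topo$chains)
  for (c in seq_len(nch)) {
    obs[[paste0("Tw", c)]] <- res$tw[[c]]
    obs[[paste0("Tw_strain", c)]] <- res$tw_strain[[c]]
    obs[[paste0("Wr", c)]] <- res$wr[[c]]
  }
  if (nch == 2) obs$Lk12 <- res$lk12
  obs$time <- obs$step * settings$timestep
  topo$jun_phase <- res$phases
  for (i in seq_along(topo$swivels))
    topo$swivels[[i]]$phase <- res$phases[topo$swivels[[i]]$junction + 1]
  traj <- structure(list(
    observables = obs,
    snapshots = res$snapshots,
    snap_steps = res$snap_steps,
    final_state = conformation(res$positions, res$velocities),
    topology = topo, params = params, settings = settings,
    completed_steps = res$steps_done), class = "sc_trajectory")
  if (!isTRUE(res$ok)) {
    msg <- if (res$bad_bond > 0)
      sprintf("FENE bond %d overstretched at step %.0f", res$bad_bond, res$bad_step)
    else sprintf("non-finite coordinate for bead %d at step %.0f",
                 res$bad_bead, res$bad_step)
    cond <- simpleError(paste0("integration aborted: ", msg))
    cond$trajectory <- traj
    stop(cond)
  }
  traj
}

#' @export
print.sc_trajectory <- function(x, ...) {
  cat("Trajectory:", format(x$completed_steps, big.mark = ","), "steps,",
      length(x$snapshots), "snapshots,", nrow(x$observables), "observable rows\n")
  invisible(x)
}

#' Advance the system by one integration step
#'
#' One Langevin velocity-Verlet step including swivel-phase advance and
#' constraint projection. Mostly useful for inspection; long runs should use
#' [run_dynamics()].
#'
#' @inheritParams run_dynamics
#' @param seed RNG seed for the random force of this step.
#' @return `list(state =, topology =)` with updated positions, velocities
#'   and swivel phases.
#' @export
langevin_step <- function(state, topo, params = model_params(),
                          settings = langevin_settings(), seed = settings$seed) {
  s1 <- settings; s1$n_steps <- 1; s1$obs_every <- 0L; s1$snap_every <- 0L
  s1$seed <- seed
  traj <- run_dynamics(state, topo, params, s1)
  list(state = traj$final_state, topology = traj$topology)
}

#' Project a conformation back onto the rigid-frame constraint manifold
#'
#' Restores, for every bond: the axial bead to the bond midpoint, and the
#' periaxial offset to unit length and perpendicularity to the bond, by an
#' iterative symmetric projection over all involved beads; the torsional
#' azimuth of each frame is preserved. Velocity components along the
#' constrained directions are removed. Idempotent on already-valid states.
#'
#' @inheritParams run_dynamics
#' @return the projected `sc_state`.
#' @export
enforce_frame_constraints <- function(state, topo, params = model_params()) {
  res <- cpp_project_constraints(state$positions, state$velocities,
                                 topo_for_core(topo), params_for_core(params))
  conformation(res$positions, res$velocities)
}

#' Residuals of the rigid-frame constraints
#'
#' Maximum violations of the three frame constraints, useful for tests and
#' diagnostics.
#'
#' @inheritParams run_dynamics
#' @return named numeric: `midpoint`, `unit_length`, `perpendicular`.
#' @export
constraint_residuals <- function(state, topo) {
  pos <- state$positions
  nm <- topo$n_m; nb <- nrow(topo$bonds)
  a <- topo$bonds[, 1] + 1; b <- topo$bonds[, 2] + 1
  A <- pos[nm + seq_len(nb), , drop = FALSE]
  P <- pos[nm + nb + seq_len(nb), , drop = FALSE]
  mid <- (pos[a, , drop = FALSE] + pos[b, , drop = FALSE]) / 2
  r1 <- sqrt(rowSums((A - mid)^2))
  d <- P - A
  r2 <- abs(sqrt(rowSums(d^2)) - 1)
  m <- pos[b, , drop = FALSE] - pos[a, , drop = FALSE]
  r3 <- abs(rowSums(d * m)) / sqrt(rowSums(m^2))
  c(midpoint = max(r1), unit_length = max(r2), perpendicular = max(r3))
}

#' Total potential energy decomposed by term
#'
#' Sums the FENE, WCA, Debye-Hueckel, bending and dihedral contributions over
#' all bonds, pairs, angles and torsional frames, honouring nicks, gaps,
#' topoIII exemptions and bonded-pair exclusions.
#'
#' @inheritParams run_dynamics
#' @return named list `fene`, `wca`, `dh`, `bend`, `dihedral`, `total`
#'   (epsilon).
#' @export
total_energy <- function(state, topo, params = model_params()) {
  cpp_energy(state$positions, topo_for_core(topo), params_for_core(params))
}

#' Forces on every bead
#'
#' Analytic gradients of all potential terms (the exact negative gradient of
#' [total_energy()]), including the transmission of torsional-frame forces.
#'
#' @inheritParams run_dynamics
#' @return N x 3 matrix, epsilon/sigma.
#' @export
forces <- function(state, topo, params = model_params()) {
  cpp_forces(state$positions, topo_for_core(topo), params_for_core(params))
}
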