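# Configuration, trajectory and observables I/O.

bead_roles <- function(topo) {
  nb <- nrow(topo$bonds)
  c(rep("M", topo$n_m), rep("A", nb), rep("P", nb))
}

bead_chain_ids <- function(topo) {
  nb <- nrow(topo$bonds)
  mol_m <- integer(topo$n_m); mol_b <- integer(nb)
  for (c in seq_along(topo$chains)) {
    ch <- topo$chains[[c]]
    mol_m[ch$first + seq_len(ch$n_units)] <- c
    mol_b[ch$bond0 + seq_len(ch$nbonds)] <- c
  }
  c(mol_m, mol_b, mol_b)
}

#' Write one trajectory frame in extended-XYZ format
#'
#' One frame: bead-count line, a comment line carrying the step number and
#' the role legend, then one record per bead with its role tag (M/A/P) and
#' coordinates to six decimals.
#'
#' @param state an `sc_state` or position matrix.
#' @param topo the `sc_topology`.
#' @param step integration step of the frame.
#' @param sink open connection or file path (appended to).
#' @export
write_xyz_frame <- function(state, topo, step, sink) {
  pos <- if (is.matrix(state)) state else state$positions
  roles <- bead_roles(topo)
  con <- if (inherits(sink, "connection")) sink else {
    fc <- file(sink, open = "a"); on.exit(close(fc)); fc
  }
  writeLines(as.character(nrow(pos)), con)
  writeLines(sprintf("step=%d roles=M/A/P chains=%d", as.integer(step),
                     length(topo$chains)), con)
  writeLines(sprintf("%s %.6f %.6f %.6f", roles, pos[, 1], pos[, 2], pos[, 3]),
             con)
  invisible(NULL)
}

#' Write a whole trajectory to an extended-XYZ file
#'
#' @param traj an `sc_trajectory`.
#' @param path output file.
#' @export
write_trajectory_xyz <- function(traj, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_along(traj$snapshots))
    write_xyz_frame(traj$snapshots[[i]], traj$topology,
                    traj$snap_steps[i], con)
  invisible(path)
}

#' Read an extended-XYZ trajectory file
#'
#' @param path file written by [write_trajectory_xyz()].
#' @return list of frames, each `list(step =, roles =, positions =)`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    cm <- lines[i + 1]
    step <- as.integer(sub(".*step=([0-9]+).*", "\\1", cm))
    rec <- strsplit(lines[(i + 2):(i + 1 + n)], " +")
    roles <- vapply(rec, `[`, character(1), 1)
    pos <- t(vapply(rec, function(r) as.numeric(r[2:4]), numeric(3)))
    frames[[length(frames) + 1]] <- list(step = step, roles = roles,
                                         positions = pos)
    i <- i + 2 + n
  }
  frames
}

#' Write a PDB snapshot for molecular viewers
#'
#' Beads become atoms (element C; M/A/P in the atom-name field); each chain
#' of the topology becomes a PDB chain so catenanes display as two
#' molecules.
#'
#' @inheritParams write_xyz_frame
#' @param path output file.
#' @export
write_pdb_snapshot <- function(state, topo, path) {
  pos <- if (is.matrix(state)) state else state$positions
  roles <- bead_roles(topo)
  mols <- bead_chain_ids(topo)
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_len(nrow(pos))) {
    writeLines(sprintf(
      "ATOM  %5d  %-3s UNK %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      i, roles[i], LETTERS[mols[i]], i %% 10000,
      pos[i, 1], pos[i, 2], pos[i, 3]), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write / read the observables table
#'
#' Tab-separated, columns as produced by [run_dynamics()] (step, per-term
#' energies, kinetic energy, twist/writhe per chain, swivel rotations, ...).
#'
#' @param traj an `sc_trajectory` (or the observables data.frame itself).
#' @param path file path.
#' @export
write_observables <- function(traj, path) {
  df <- if (is.data.frame(traj)) traj else traj$observables
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observables
#' @export
read_observables <- function(path) {
  read.table(path, header = TRUE, sep = "\t")
}

# ---- run configuration ------------------------------------------------------

config_defaults <- function() {
  list(
    scenario = list(topology = NULL, size_bp = NULL, knot = "none",
                    n_links = 2),
    swivel = NULL, nick = NULL, gap = NULL,
    topoIII = list(enabled = FALSE, remove_dh = FALSE),
    params = as.list(unclass(model_params()))[
      setdiff(names(unclass(model_params())), "fene")],
    fene = model_params()$fene,
    dynamics = list(timestep = 0.001, n_steps = 1e5, snapshot_every = 0,
                    obs_every = 1000, thermalize_steps = 1e5),
    seed = 1,
    output = list(dir = NULL))
}

#' Read and validate a run configuration
#'
#' YAML file with stanzas `scenario` (required: `topology`, `size_bp`),
#' `swivel`, `nick`, `gap`, `topoIII`, `params`, `fene`, `dynamics`,
#' `output` and `seed`. All omitted parameters take the model defaults
#' ([model_params()]); unknown keys are rejected. All violations are
#' collected and reported together.
#'
#' @param path YAML file.
#' @return a validated `sc_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  validate_run_config(raw)
}

#' @rdname read_run_config
#' @param config a config list (as returned or about to be written).
#' @export
validate_run_config <- function(config) {
  defs <- config_defaults()
  errs <- character(0)
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown))
    errs <- c(errs, paste0("unknown stanza(s): ", paste(unknown, collapse = ", ")))
  for (st in intersect(names(config), names(defs))) {
    d <- defs[[st]]
    if (is.list(d) && !is.null(names(d)) && is.list(config[[st]])) {
      bad <- setdiff(names(config[[st]]), c(names(d), "unit", "start", "rate",
                                            "sign", "chain", "enabled",
                                            "remove_dh"))
      if (length(bad))
        errs <- c(errs, paste0("unknown key(s) in [", st, "]: ",
                               paste(bad, collapse = ", ")))
    }
  }
  sc <- config$scenario
  if (is.null(sc)) {
    errs <- c(errs, "missing required stanza [scenario]")
  } else {
    for (f in c("topology", "size_bp"))
      if (is.null(sc[[f]]))
        errs <- c(errs, paste0("missing required field scenario.", f))
    if (!is.null(sc$topology) &&
        !sc$topology %in% c("linear", "circle", "catenane"))
      errs <- c(errs, paste0("scenario.topology must be linear|circle|catenane, got ",
                             sc$topology))
    if (!is.null(sc$knot) && !sc$knot %in% supported_knots)
      errs <- c(errs, paste0("scenario.knot '", sc$knot, "' not supported (",
                             paste(supported_knots, collapse = ", "), ")"))
    if (!is.null(sc$size_bp) && any(sc$size_bp <= 0))
      errs <- c(errs, "scenario.size_bp must be positive")
  }
  dyn <- config$dynamics
  if (!is.null(dyn)) {
    if (!is.null(dyn$timestep) && dyn$timestep <= 0)
      errs <- c(errs, "dynamics.timestep must be > 0")
    if (!is.null(dyn$n_steps) && dyn$n_steps < 1)
      errs <- c(errs, "dynamics.n_steps must be >= 1")
  }
  if (length(errs))
    stop("invalid run configuration:\n  - ", paste(errs, collapse = "\n  - "))
  out <- modifyList(defs, config)
  class(out) <- "sc_config"
  out
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config)[!vapply(unclass(config), is.null, logical(1))],
                   path)
  invisible(path)
}

#' Write the run manifest
#'
#' Self-description of a run directory: configuration hash, seed, package
#' version, step count and wall time — together with the config file this
#' suffices to reproduce the run bit-identically.
#'
#' @param config the `sc_config` used.
#' @param seed the seed used.
#' @param n_steps steps integrated.
#' @param wall_s wall-clock seconds.
#' @param path output JSON path.
#' @export
write_manifest <- function(config, seed, n_steps, wall_s, path) {
  cfg_str <- yaml::as.yaml(unclass(config))
  manifest <- list(
    config_hash = sprintf("%08x", sum(utf8ToInt(cfg_str) *
                                        (seq_along(utf8ToInt(cfg_str)) %% 97 + 1)) %%
                            .Machine$integer.max),
    seed = seed,
    package_version = as.character(utils::packageVersion("supercoilr")),
    n_steps = n_steps,
    wall_seconds = wall_s,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
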