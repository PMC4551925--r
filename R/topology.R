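# Chain topology: connectivity, torsional frames and per-site annotations.
#
# Bead layout used throughout (and by the C++ core):
#   rows 1..n_m            main-chain (M) beads of all chains, concatenated
#   rows n_m+1..n_m+n_b    axial (A) beads, one per main-chain bond
#   rows n_m+n_b+1..N      periaxial (P) beads, one per bond
# All index fields stored in the topology are 0-based (C++ convention);
# user-facing arguments are 0-based repeat-unit indices as well.

make_topology <- function(n_units, circular, params = model_params()) {
  n_units <- as.integer(n_units)
  circular <- as.logical(circular)
  stopifnot(length(n_units) == length(circular),
            all(n_units >= ifelse(circular, 3L, 2L)))
  n_chain <- length(n_units)
  bonds <- NULL; junctions <- NULL; angles <- NULL
  chains <- vector("list", n_chain)
  first <- 0L; bond0 <- 0L; jun0 <- 0L
  for (c in seq_len(n_chain)) {
    n <- n_units[c]
    if (circular[c]) {
      b <- cbind(first + 0:(n - 1), first + c(1:(n - 1), 0))
      j <- cbind(bond0 + 0:(n - 1), bond0 + c(1:(n - 1), 0))
      a <- cbind(first + c(n - 1, 0:(n - 2)), first + 0:(n - 1),
                 first + c(1:(n - 1), 0))
    } else {
      b <- cbind(first + 0:(n - 2), first + 1:(n - 1))
      j <- if (n >= 3) cbind(bond0 + 0:(n - 3), bond0 + 1:(n - 2)) else
        matrix(integer(0), 0, 2)
      a <- if (n >= 3) cbind(first + 0:(n - 3), first + 1:(n - 2),
                             first + 2:(n - 1)) else matrix(integer(0), 0, 3)
    }
    chains[[c]] <- list(first = first, n_units = n, circular = circular[c],
                        bond0 = bond0, nbonds = nrow(b),
                        jun0 = jun0, njun = nrow(j))
    bonds <- rbind(bonds, b); junctions <- rbind(junctions, j)
    angles <- rbind(angles, a)
    first <- first + n; bond0 <- bond0 + nrow(b); jun0 <- jun0 + nrow(j)
  }
  nj <- nrow(junctions)
  topo <- list(
    n_m = first,
    bonds = bonds, junctions = junctions,
    jun_enabled = rep(1L, nj), jun_phase = rep(0, nj),
    jun_active = rep(0L, nj), jun_rate = rep(0, nj), jun_sign = rep(1, nj),
    angles = angles, angle_k = rep(params$bend_constant, nrow(angles)),
    charge = rep(params$charge_per_bead, first),
    gap = rep(0L, first),
    topoiii = 0L, topoiii_dh = 0L,
    excl_pairs = matrix(integer(0), 0, 2),
    chains = chains,
    nicks = integer(0), gaps = list(), swivels = list())
  class(topo) <- "sc_topology"
  topo
}

#' Build the connectivity of a torsional bead-spring chain
#'
#' Creates the topology of a single chain of `n_units` repeat units. Each
#' repeat unit contributes one main-chain (M) bead; each main-chain bond
#' carries an axial (A) bead at its midpoint and a periaxial (P) bead at unit
#' offset perpendicular to the bond, which together define the torsional
#' frame. A dihedral lock couples consecutive frames.
#'
#' @param n_units number of repeat units (1 unit = 8 bp).
#' @param circular closed (plasmid) or open (linear) chain.
#' @param params [model_params()]; supplies the default bending constant and
#'   bead charge stored per site.
#' @return An `sc_topology` object.
#' @seealso [apply_nick()], [apply_gap()], [add_swivel()], [enable_topoiii()]
#' @export
chain_topology <- function(n_units, circular = TRUE, params = model_params()) {
  make_topology(n_units, circular, params)
}

#' @export
print.sc_topology <- function(x, ...) {
  nch <- length(x$chains)
  cat("Chain topology:", nch, if (nch == 1) "chain," else "chains,",
      x$n_m, "repeat units total\n")
  for (c in seq_along(x$chains)) {
    ch <- x$chains[[c]]
    cat(sprintf("  chain %d: %d units, %s\n", c, ch$n_units,
                if (ch$circular) "circular" else "linear"))
  }
  if (length(x$nicks)) cat("  nicks at junctions:", paste(x$nicks, collapse = ", "), "\n")
  if (length(x$gaps)) cat("  gaps:", length(x$gaps), "\n")
  if (length(x$swivels)) {
    for (s in x$swivels)
      cat(sprintf("  active swivel at junction %d, rate %g rot/tau, sign %+d\n",
                  s$junction, s$rate, s$sign))
  }
  if (x$topoiii) cat("  topoIII passage mode enabled\n")
  invisible(x)
}

n_beads <- function(topo) topo$n_m + 2L * nrow(topo$bonds)

# junction whose middle vertex is M bead `unit` of chain `chain` (both 0-based
# unit indexing on the chain's own map). For circular chains junction j sits
# at vertex (j+1) mod n; for linear chains at vertex j+1.
junction_at_unit <- function(topo, unit, chain = 1) {
  ch <- topo$chains[[chain]]
  n <- ch$n_units
  if (unit < 0 || unit >= n) stop("unit index out of range [0, ", n - 1, "]")
  unit <- as.integer(unit)
  if (ch$circular) as.integer(ch$jun0 + (unit - 1L) %% n)
  else {
    if (unit < 1 || unit > n - 2) stop("linear chain has no torsional frame at terminal units")
    as.integer(ch$jun0 + unit - 1L)
  }
}

angle_at_unit <- function(topo, unit, chain = 1) {
  ch <- topo$chains[[chain]]
  mid <- ch$first + unit
  which(topo$angles[, 2] == mid) - 1L
}

#' Introduce a nick (passive swivel)
#'
#' A nick interrupts the dihedral lock between two consecutive repeat units,
#' so the flanking duplex segments can swivel freely about the chain axis and
#' torsional stress is dissipated there. All other interactions are
#' unchanged.
#'
#' @param topo an `sc_topology`.
#' @param unit 0-based repeat-unit index at which the lock is interrupted.
#' @param chain chain number (1-based) for multi-chain systems.
#' @return the modified topology.
#' @export
apply_nick <- function(topo, unit, chain = 1) {
  j <- junction_at_unit(topo, unit, chain)
  if (topo$jun_active[j + 1] == 1L)
    stop("junction ", j, " already carries an active swivel; ",
         "a site cannot be both nick and motor")
  topo$jun_enabled[j + 1] <- 0L
  topo$nicks <- sort(unique(c(topo$nicks, j)))
  topo
}

#' Introduce a single-stranded gap
#'
#' A gap spans three consecutive repeat units: the dihedral lock is removed
#' over that distance, the bead charge is reduced (ssDNA carries half the
#' linear charge density of duplex) and the local bending constant is lowered
#' to the single-strand value, making the region much more flexible.
#'
#' @inheritParams apply_nick
#' @param start_unit first of the three consecutive repeat units (0-based).
#' @param params [model_params()]; supplies `bend_constant_gap` and
#'   `gap_charge_factor`.
#' @return the modified topology.
#' @export
apply_gap <- function(topo, start_unit, chain = 1, params = model_params()) {
  ch <- topo$chains[[chain]]
  n <- ch$n_units
  units <- start_unit + 0:2
  if (!ch$circular && any(units > n - 1))
    stop("gap needs 3 consecutive units; chain too short past start_unit")
  units <- units %% n
  juns <- vapply(units, function(u) junction_at_unit(topo, u, chain), integer(1))
  if (any(topo$jun_active[juns + 1] == 1L))
    stop("gap overlaps an active swivel site")
  topo$jun_enabled[juns + 1] <- 0L
  beads <- ch$first + units
  topo$charge[beads + 1] <- topo$charge[beads + 1] * params$gap_charge_factor
  topo$gap[beads + 1] <- 1L
  for (u in units) {
    ai <- angle_at_unit(topo, u, chain)
    if (length(ai)) topo$angle_k[ai + 1] <- params$bend_constant_gap
  }
  topo$gaps <- c(topo$gaps, list(list(chain = chain, units = units,
                                      beads = beads, junctions = juns)))
  topo
}

#' Place an active swivel (gyrase-like torsional motor)
#'
#' The active swivel is one dihedral whose phase is ramped continuously
#' during the run at `rate` rotations per time unit, forcing the flanking
#' chain segments to rotate with respect to each other and thereby injecting
#' linking-number change, as DNA gyrase does. With `sign = +1` (default) the
#' injected supercoiling is negative (the measured Lk of the chain
#' decreases).
#'
#' @inheritParams apply_nick
#' @param rate swivel speed, rotations per tau.
#' @param sign +1 for negative supercoiling (gyrase), -1 for positive.
#' @return the modified topology.
#' @export
add_swivel <- function(topo, unit, rate = 7e-4, sign = 1, chain = 1) {
  j <- junction_at_unit(topo, unit, chain)
  if (topo$jun_enabled[j + 1] == 0L)
    stop("junction ", j, " is nicked or gapped; cannot place an active swivel there")
  topo$jun_active[j + 1] <- 1L
  topo$jun_rate[j + 1] <- rate
  topo$jun_sign[j + 1] <- sign
  sw <- structure(list(junction = j, unit = unit, chain = chain, rate = rate,
                       sign = sign, phase = topo$jun_phase[j + 1]),
                  class = "sc_swivel")
  topo$swivels <- c(topo$swivels, list(sw))
  topo
}

#' Advance an active swivel phase
#'
#' Ramps the swivel phase by `2 pi * rate * dt` (applied every integration
#' step inside [run_dynamics()]; this function is the same bookkeeping for a
#' standalone swivel record). `accumulated_rotations` is the total injected
#' |Delta Lk| for a closed, intact chain.
#'
#' @param swivel an `sc_swivel` record (see [add_swivel()]).
#' @param dt elapsed time, tau (> 0).
#' @return the swivel with updated `phase` and `accumulated_rotations`.
#' @export
advance_swivel <- function(swivel, dt) {
  stopifnot(dt > 0)
  swivel$phase <- swivel$phase + 2 * pi * swivel$rate * swivel$sign * dt
  swivel$accumulated_rotations <- abs(swivel$phase) / (2 * pi)
  swivel
}

#' Enable topoisomerase-III mediated passage at gaps
#'
#' Models topoIII action by removing the excluded-volume (WCA) interaction
#' between the beads of single-stranded gaps and the rest of the system, so
#' that supercoiling can drive duplex segments through the gap. The screened
#' electrostatic repulsion is kept by default (`remove_dh = FALSE`); chain
#' connectivity and bonded terms are never touched.
#'
#' @param topo an `sc_topology` that already carries at least one gap.
#' @param remove_dh also exempt gap/duplex pairs from Debye-Hueckel repulsion.
#' @return the modified topology.
#' @export
enable_topoiii <- function(topo, remove_dh = FALSE) {
  if (!length(topo$gaps))
    stop("no gap present; topoIII passage mode acts at single-stranded gaps")
  topo$topoiii <- 1L
  topo$topoiii_dh <- as.integer(remove_dh)
  topo
}

# number of (gap bead, non-gap bead) pairs exempted from WCA, net of pairs
# already excluded as bonded neighbours
count_topoiii_exemptions <- function(topo) {
  gap_beads <- which(topo$gap == 1L) - 1L
  other <- setdiff(0:(topo$n_m - 1L), gap_beads)
  bonded <- paste(pmin(topo$bonds[, 1], topo$bonds[, 2]),
                  pmax(topo$bonds[, 1], topo$bonds[, 2]))
  n <- 0L
  for (g in gap_beads)
    for (o in other)
      if (!(paste(min(g, o), max(g, o)) %in% bonded)) n <- n + 1L
  n
}
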