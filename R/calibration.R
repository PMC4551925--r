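# Reduced-unit <-> physical-unit conversions and the time-unit calibration.

#' Scale a diffusion coefficient by a viscosity factor
#'
#' Stokes' law: the diffusion coefficient is inversely proportional to the
#' viscosity of the medium. An 8 bp DNA segment has a rotational diffusion
#' coefficient of about 6e7 rad^2/s in water; intracellular viscosity can be
#' thousands of times higher.
#'
#' @param D_water diffusion coefficient in water (e.g. rad^2/s).
#' @param factor viscosity relative to water (>= 1).
#' @return scaled diffusion coefficient.
#' @export
scale_diffusion_by_viscosity <- function(D_water = 6e7, factor = 5000) {
  stopifnot(factor >= 1, D_water > 0)
  D_water / factor
}

#' Calibrate the physical duration of the reduced time unit
#'
#' Equates the simulated rotational diffusion coefficient of a repeat unit
#' (rad^2/tau) with its viscosity-scaled experimental value (rad^2/s):
#' tau = D_sim / D_target seconds.
#'
#' @param D_sim simulated rotational diffusion coefficient, rad^2/tau.
#' @param D_target physical target, rad^2/s.
#' @return tau in seconds (unrounded).
#' @export
calibrate_tau <- function(D_sim = 1.6, D_target = 1.2e4) {
  stopifnot(D_sim > 0, D_target > 0)
  D_sim / D_target
}

#' Convert a swivel rate from rotations/tau to rotations/second
#'
#' @param omega swivel speed, rotations per tau.
#' @param tau_s physical duration of tau, seconds.
#' @return rotations per second.
#' @export
swivel_rate_physical <- function(omega = 7e-4, tau_s = calibrate_tau()) {
  stopifnot(omega >= 0, tau_s > 0)
  omega / tau_s
}

#' Bjerrum length in reduced units
#'
#' @param l_B_nm Bjerrum length, nm (0.71 nm for aqueous solution).
#' @param sigma_nm bead diameter, nm.
#' @return l_B in sigma.
#' @export
bjerrum_in_sigma <- function(l_B_nm = 0.71, sigma_nm = 2.5) {
  stopifnot(l_B_nm > 0, sigma_nm > 0)
  l_B_nm / sigma_nm
}

#' DNA length in repeat units
#'
#' One repeat unit represents 8 bp.
#'
#' @param n_bp length in base pairs; warned and rounded when not a multiple
#'   of 8.
#' @param bp_per_bead base pairs per unit.
#' @return number of repeat units.
#' @export
size_in_beads <- function(n_bp, bp_per_bead = 8) {
  if (any(n_bp %% bp_per_bead != 0))
    warning("length not divisible by ", bp_per_bead, " bp; rounding")
  round(n_bp / bp_per_bead)
}

#' Time to create a topoIII substrate
#'
#' In simulated 3 kb plasmids on the order of a hundred axial rotations are
#' needed to push a knot to the nick; with gyrase inducing about 5 rotations
#' per second this sets the timescale for creating an unknotting substrate.
#'
#' @param rotations rotations needed to localize the knot at the nick.
#' @param rot_per_s gyrase swiveling speed, rotations per second.
#' @return time in seconds.
#' @export
topoiii_substrate_time <- function(rotations = 100, rot_per_s = 5) {
  rotations / rot_per_s
}

#' The full time-unit calibration chain
#'
#' Runs the complete conversion chain from the in-water rotational diffusion
#' coefficient of an 8 bp unit to the physical swivel speed: viscosity
#' scaling, tau calibration against the simulated rotational diffusion
#' coefficient, and swivel-rate conversion.
#'
#' @param D_sim simulated rotational diffusion coefficient, rad^2/tau (from
#'   [measure_rotational_diffusion()]).
#' @param D_water in-water rotational diffusion of an 8 bp fragment, rad^2/s.
#' @param viscosity_factor intracellular viscosity relative to water.
#' @param omega swivel speed in rotations per tau.
#' @return data.frame of the chain with columns `quantity`, `value`, `units`.
#' @export
calibration_chain <- function(D_sim = 1.6, D_water = 6e7,
                              viscosity_factor = 5000, omega = 7e-4) {
  D_target <- scale_diffusion_by_viscosity(D_water, viscosity_factor)
  tau <- calibrate_tau(D_sim, D_target)
  rps <- swivel_rate_physical(omega, tau)
  data.frame(
    quantity = c("D_rot in water", "viscosity factor", "D_rot target",
                 "D_rot simulated", "tau", "swivel rate (reduced)",
                 "swivel rate (physical)"),
    value = c(D_water, viscosity_factor, D_target, D_sim, tau, omega, rps),
    units = c("rad^2/s", "x water", "rad^2/s", "rad^2/tau", "s", "rot/tau",
              "rot/s"))
}
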