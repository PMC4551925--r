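#' Force-field and dynamics constants in reduced units
#'
#' Assembles the full parameter set of the model in reduced units
#' (length sigma, energy epsilon = k_BT, mass m, time tau). One bead
#' represents 8 bp of duplex DNA and sigma = 2.5 nm. Every value can be
#' overridden; the defaults are the standard parameterization of the model.
#'
#' @param sigma_nm physical length of one reduced unit, nm.
#' @param bp_per_bead base pairs per repeat unit.
#' @param epsilon energy unit, equal to k_BT (reduced).
#' @param mass bead mass m (reduced).
#' @param sigma_ex excluded-volume diameter of the WCA potential, sigma.
#'   The default 1.5 sigma (larger than the 1 sigma bond) closes the mesh of
#'   the chain against intersegmental passages.
#' @param charge_per_bead effective charge q per duplex bead (negative); -2
#'   corresponds to the non-neutralized charge of an 8 bp fragment at
#'   physiological ionic conditions.
#' @param bjerrum_length Bjerrum length l_B, sigma (0.71 nm = 0.28 sigma).
#' @param debye_kappa reciprocal Debye screening length kappa, 1/sigma.
#' @param dh_cutoff Debye-Hueckel interaction cutoff, sigma.
#' @param bend_constant bending constant K_b, epsilon. The default is the
#'   tuned value for which excluded volume, electrostatics and bending
#'   together give a persistence length of 50 nm (20 sigma); see
#'   [tune_bending_constant()].
#' @param dihedral_constant torsional lock constant K_D, epsilon.
#' @param fene list with `spring_constant` (epsilon/sigma^2), `max_extension`
#'   R0 (sigma) and `rest_length` r0 (sigma) of the shifted FENE bond. The
#'   exact published constants of the source model are not available; these
#'   are substitute values reproducing a stiff 1 sigma equilibrium bond.
#' @param drag_M,drag_P,drag_A per-bead-type hydrodynamic drags, m/tau. The
#'   defaults sum to the stated 0.9 m/tau per repeat unit.
#' @param timestep integration step, tau.
#' @param periaxial_offset distance of the P bead from the chain axis, sigma.
#' @param bend_constant_gap bending constant inside single-stranded gaps,
#'   epsilon; the default corresponds to an ssDNA persistence length of
#'   about 1.5 nm (0.6 sigma).
#' @param gap_charge_factor factor applied to the bead charge inside gaps
#'   (single-stranded DNA carries half the charge of duplex).
#' @param validate check invariants (positivity, drag budget).
#'
#' @return An object of class `sc_params`: a named list of all constants.
#' @examples
#' p <- model_params()
#' p$drag_M + p$drag_P + p$drag_A # 0.9 m/tau per repeat unit
#' @export
model_params <- function(sigma_nm = 2.5,
                         bp_per_bead = 8L,
                         epsilon = 1,
                         mass = 1,
                         sigma_ex = 1.5,
                         charge_per_bead = -2,
                         bjerrum_length = 0.28,
                         debye_kappa = 1 / 1.2,
                         dh_cutoff = 8,
                         bend_constant = 20.3,
                         dihedral_constant = 20,
                         fene = list(spring_constant = 30,
                                     max_extension = 0.5,
                                     rest_length = 1),
                         drag_M = 0.5,
                         drag_P = 0.2,
                         drag_A = 0.2,
                         timestep = 0.001,
                         periaxial_offset = 1,
                         bend_constant_gap = 0.6,
                         gap_charge_factor = 0.5,
                         validate = TRUE) {
  p <- list(sigma_nm = sigma_nm, bp_per_bead = as.integer(bp_per_bead),
            epsilon = epsilon, mass = mass, sigma_ex = sigma_ex,
            charge_per_bead = charge_per_bead,
            bjerrum_length = bjerrum_length, debye_kappa = debye_kappa,
            dh_cutoff = dh_cutoff, bend_constant = bend_constant,
            dihedral_constant = dihedral_constant, fene = fene,
            drag_M = drag_M, drag_P = drag_P, drag_A = drag_A,
            timestep = timestep, periaxial_offset = periaxial_offset,
            bend_constant_gap = bend_constant_gap,
            gap_charge_factor = gap_charge_factor)
  class(p) <- "sc_params"
  if (validate) validate_params(p)
  p
}

validate_params <- function(p) {
  pos <- c("sigma_nm", "epsilon", "mass", "sigma_ex", "bjerrum_length",
           "debye_kappa", "dh_cutoff", "bend_constant", "dihedral_constant",
           "timestep", "periaxial_offset", "bend_constant_gap")
  bad <- pos[vapply(pos, function(f) !is.numeric(p[[f]]) || p[[f]] <= 0, logical(1))]
  if (length(bad))
    stop("parameters must be strictly positive: ", paste(bad, collapse = ", "))
  if (p$charge_per_bead > 0)
    stop("charge_per_bead must be negative (DNA backbone charge) or zero")
  if (any(c(p$drag_M, p$drag_P, p$drag_A) < 0)) stop("drags must be >= 0")
  if (p$sigma_ex <= p$fene$rest_length)
    warning("sigma_ex <= bond rest length: intersegmental passages are no ",
            "longer sterically prevented")
  tot <- p$drag_M + p$drag_P + p$drag_A
  if (abs(tot - 0.9) > 1e-9)
    message("total drag per repeat unit is ", format(tot),
            " m/tau (standard parameterization uses 0.9)")
  invisible(p)
}

#' @export
print.sc_params <- function(x, ...) {
  cat("Model parameters (reduced units; sigma =", x$sigma_nm, "nm =",
      x$bp_per_bead, "bp)\n")
  cat(sprintf("  WCA sigma_ex %.2f | q %.1f | l_B %.2f | kappa %.3f | DH cutoff %.1f\n",
              x$sigma_ex, x$charge_per_bead, x$bjerrum_length, x$debye_kappa,
              x$dh_cutoff))
  cat(sprintf("  K_b %.2f | K_b(gap) %.2f | K_D %.1f | FENE K %.0f R0 %.2f r0 %.2f\n",
              x$bend_constant, x$bend_constant_gap, x$dihedral_constant,
              x$fene$spring_constant, x$fene$max_extension, x$fene$rest_length))
  cat(sprintf("  drags M/P/A %.2f/%.2f/%.2f m/tau | dt %.4f tau\n",
              x$drag_M, x$drag_P, x$drag_A, x$timestep))
  invisible(x)
}

# parameters in the flat list form expected by the C++ core
params_for_core <- function(p) {
  list(sigma_ex = p$sigma_ex, bjerrum_length = p$bjerrum_length,
       debye_kappa = p$debye_kappa, dh_cutoff = p$dh_cutoff,
       dihedral_constant = p$dihedral_constant,
       fene = p$fene, epsilon = p$epsilon,
       drag_M = p$drag_M, drag_P = p$drag_P, drag_A = p$drag_A,
       mass = p$mass)
}

#' Shifted FENE bond energy
#'
#' U(r) = -K R0^2/2 log(1 - ((r - r0)/R0)^2), minimum at the rest length r0.
#' The potential diverges as the extension approaches R0 on either side.
#'
#' @param r bond length(s), sigma.
#' @param params an [model_params()] object.
#' @return energy in epsilon.
#' @export
fene_energy <- function(r, params = model_params()) {
  f <- params$fene
  u <- (r - f$rest_length) / f$max_extension
  if (any(abs(u) >= 1))
    stop("bond extension beyond the FENE maximum extension R0 = ",
         f$max_extension, " sigma (bond length ", paste(format(r[abs(u) >= 1]),
         collapse = ", "), ")")
  -0.5 * f$spring_constant * f$max_extension^2 * log(1 - u^2)
}

#' WCA excluded-volume energy
#'
#' Shifted, cut, fully repulsive Weeks-Chandler-Andersen potential
#' 4 eps ((sigma_ex/r)^12 - (sigma_ex/r)^6 + 1/4) for r below the cutoff
#' 2^(1/6) sigma_ex, zero beyond.
#'
#' @param r center-to-center distance(s), sigma.
#' @inheritParams fene_energy
#' @return energy in epsilon.
#' @export
wca_energy <- function(r, params = model_params()) {
  if (any(r <= 0)) stop("distance must be positive")
  s6 <- (params$sigma_ex / r)^6
  e <- 4 * params$epsilon * (s6^2 - s6 + 0.25)
  e[r >= 2^(1 / 6) * params$sigma_ex] <- 0
  e
}

#' Debye-Hueckel screened electrostatic energy
#'
#' U(r) = eps l_B q_i q_j exp(-kappa r)/r for r at or below the cutoff,
#' zero beyond.
#'
#' @param r distance(s), sigma.
#' @param q_i,q_j bead charges.
#' @inheritParams fene_energy
#' @return energy in epsilon.
#' @export
dh_energy <- function(r, q_i = -2, q_j = -2, params = model_params()) {
  if (any(r <= 0)) stop("distance must be positive")
  e <- params$epsilon * params$bjerrum_length * q_i * q_j *
    exp(-params$debye_kappa * r) / r
  e[r > params$dh_cutoff] <- 0
  e
}

#' Bending energy
#'
#' U(theta) = K_b (1 - cos theta), with theta the deviation from collinearity
#' of two consecutive main-chain bonds (0 for a straight chain).
#'
#' @param theta bending angle(s), radians in `[0, pi]`; values outside are
#'   clamped with a warning.
#' @param K_b bending constant, epsilon.
#' @return energy in epsilon.
#' @export
bend_energy <- function(theta, K_b = model_params()$bend_constant) {
  if (any(theta < 0 | theta > pi)) {
    warning("bending angle outside [0, pi] clamped")
    theta <- pmin(pmax(theta, 0), pi)
  }
  K_b * (1 - cos(theta))
}

#' Torsional (dihedral) lock energy
#'
#' V(phi) = K_D (1 - cos(phi - p)): zero when the dihedral angle phi matches
#' the phase p, maximal (2 K_D) half a turn away. The phase is the handle by
#' which the active swivel injects rotation.
#'
#' @param phi dihedral angle(s), radians (any value; the difference is
#'   periodic).
#' @param p phase, radians.
#' @param K_D torsional constant, epsilon.
#' @return energy in epsilon.
#' @export
dihedral_energy <- function(phi, p = 0, K_D = model_params()$dihedral_constant) {
  K_D * (1 - cos(phi - p))
}
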