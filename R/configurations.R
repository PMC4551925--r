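# Starting configurations: curves, knots, catenanes, frames, thermalization.

#' Conformation (positions and velocities) of all beads
#'
#' @param positions N x 3 matrix, sigma units, in the bead layout
#'   M beads, then A beads, then P beads.
#' @param velocities N x 3 matrix, sigma/tau.
#' @return an `sc_state`.
#' @export
conformation <- function(positions, velocities = NULL) {
  if (is.null(velocities)) velocities <- matrix(0, nrow(positions), 3)
  stopifnot(ncol(positions) == 3, all(dim(positions) == dim(velocities)))
  structure(list(positions = positions, velocities = velocities),
            class = "sc_state")
}

#' @export
print.sc_state <- function(x, ...) {
  cat("Conformation:", nrow(x$positions), "beads\n")
  invisible(x)
}

# ---- parametric curves ------------------------------------------------------

circle_curve <- function(n, t) cbind(cos(t), sin(t), 0 * t)

# (p,q) torus knot; (2,3) is the trefoil
torus_knot_curve <- function(p, q, R = 2, a = 1) {
  function(t) cbind((R + a * cos(q * t)) * cos(p * t),
                    (R + a * cos(q * t)) * sin(p * t),
                    a * sin(q * t))
}

# closure of an n-strand annular braid given as a vector of generators
# (+k for sigma_k, -k for sigma_k^{-1}); returns a closed 3D polyline.
# Strands run around the annulus at radius levels; each braid letter swaps
# two adjacent levels inside one angular sector, with the over strand lifted
# to +h and the under strand pushed to -h.
braid_closure_curve <- function(word, n_strands = 3, R = 6, dr = 1, h = 0.8,
                                pts_per_sector = 12) {
  m <- length(word)
  # permutation check: follow strand levels around the annulus
  perm <- seq_len(n_strands)
  for (w in word) {
    k <- abs(w)
    i1 <- which(perm == k); i2 <- which(perm == k + 1)
    tmp <- perm[i1]; perm[i1] <- perm[i2]; perm[i2] <- tmp
  }
  # the closure is a single knot only if the permutation is an n-cycle
  cyc <- 1L; lvl <- perm[1L]
  while (lvl != 1L) { cyc <- cyc + 1L; lvl <- perm[lvl] }
  if (cyc != n_strands)
    stop("braid closure has ", n_strands - cyc + 1, " components; need a knot")
  # level occupied by the current pass before each sector
  pts <- NULL
  lvl <- 1L
  pass_needed <- n_strands
  for (pass in seq_len(pass_needed)) {
    for (s in seq_len(m)) {
      w <- word[s]; k <- abs(w)
      # every pass traverses the same angular sectors (the curve winds
      # n_strands times around the annulus)
      th0 <- 2 * pi * (s - 1) / m
      th1 <- 2 * pi * s / m
      tt <- seq(th0, th1, length.out = pts_per_sector + 1)[-(pts_per_sector + 1)]
      u <- (tt - th0) / (th1 - th0) # 0..1 across the sector
      involved <- lvl %in% c(k, k + 1)
      if (!involved) {
        rr <- rep(R + (lvl - (n_strands + 1) / 2) * dr, length(tt))
        zz <- rep(0, length(tt))
        new_lvl <- lvl
      } else {
        other <- if (lvl == k) k + 1L else k
        r0 <- R + (lvl - (n_strands + 1) / 2) * dr
        r1 <- R + (other - (n_strands + 1) / 2) * dr
        rr <- r0 + (r1 - r0) * (0.5 - 0.5 * cos(pi * u)) # smooth swap
        # over if: sigma_k (positive) takes the lower-numbered strand over
        over <- if (w > 0) lvl == k else lvl == k + 1
        zz <- (if (over) h else -h) * sin(pi * u)
        new_lvl <- other
      }
      pts <- rbind(pts, cbind(rr * cos(tt), rr * sin(tt), zz))
      lvl <- new_lvl
    }
  }
  pts
}

# two-component (2, 2n) torus link; component j in {0, 1}
torus_link_curves <- function(n_links, R = 3, a = 1.2) {
  lapply(0:1, function(j) {
    function(t) cbind((R + a * cos(n_links * t + pi * j)) * cos(t),
                      (R + a * cos(n_links * t + pi * j)) * sin(t),
                      a * sin(n_links * t + pi * j))
  })
}

# resample a closed polyline (or parametric function) to n vertices at equal
# arclength, then rescale so the mean bond length is `bond`
resample_curve <- function(curve, n, bond = 1, n_dense = NULL, closed = TRUE) {
  if (is.function(curve)) {
    if (is.null(n_dense)) n_dense <- max(2000, 20 * n)
    t <- seq(0, 2 * pi, length.out = n_dense + 1)[-(n_dense + 1)]
    pts <- curve(t)
  } else pts <- curve
  m <- nrow(pts)
  seg <- if (closed) rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE]) - pts
  else pts[-1, , drop = FALSE] - pts[-m, , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  total <- cum[length(cum)]
  want <- seq(0, total, length.out = n + 1)[seq_len(n)]
  out <- matrix(0, n, 3)
  j <- 1
  for (i in seq_len(n)) {
    while (cum[j + 1] < want[i] && j < length(len)) j <- j + 1
    f <- (want[i] - cum[j]) / len[j]
    p0 <- pts[j, ]
    p1 <- if (j == m) pts[1, ] else pts[(j %% m) + 1, ]
    out[i, ] <- p0 + f * (p1 - p0)
  }
  if (is.na(bond)) return(out)
  # rescale to the requested bond length
  segs <- rbind(out[-1, , drop = FALSE], out[1, , drop = FALSE]) - out
  if (!closed) segs <- segs[-n, , drop = FALSE]
  out * (bond / mean(sqrt(rowSums(segs^2))))
}

# ---- frames and full initial states ----------------------------------------

rodrigues <- function(v, axis, ca, sa) {
  v * ca + pracma_cross(axis, v) * sa + axis * sum(axis * v) * (1 - ca)
}
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# place A and P beads on a chain of M positions: A at bond midpoints, P at
# unit perpendicular offset, parallel-transported so every dihedral angle is
# zero; for closed chains the transport holonomy is spread evenly so all
# junction angles are equal (and near zero modulo 2 pi / n).
build_frames <- function(m_pos, circular) {
  n <- nrow(m_pos)
  nb <- if (circular) n else n - 1
  t_hat <- matrix(0, nb, 3)
  a_pos <- matrix(0, nb, 3)
  for (k in seq_len(nb)) {
    i <- k; j <- if (k == n) 1 else k + 1
    d <- m_pos[j, ] - m_pos[i, ]
    t_hat[k, ] <- d / sqrt(sum(d * d))
    a_pos[k, ] <- (m_pos[i, ] + m_pos[j, ]) / 2
  }
  u <- matrix(0, nb, 3)
  seed_v <- c(0, 0, 1)
  if (abs(sum(seed_v * t_hat[1, ])) > 0.9) seed_v <- c(0, 1, 0)
  u0 <- seed_v - sum(seed_v * t_hat[1, ]) * t_hat[1, ]
  u[1, ] <- u0 / sqrt(sum(u0 * u0))
  transport <- function(v, t1, t2) {
    ax <- pracma_cross(t1, t2)
    sa <- sqrt(sum(ax * ax)); ca <- sum(t1 * t2)
    if (sa < 1e-12) return(v)
    rodrigues(v, ax / sa, ca, sa)
  }
  if (nb >= 2)
    for (k in 2:nb) u[k, ] <- transport(u[k - 1, ], t_hat[k - 1, ], t_hat[k, ])
  if (circular) {
    # holonomy: transport the last frame back onto the first bond
    ub <- transport(u[nb, ], t_hat[nb, ], t_hat[1, ])
    alpha <- atan2(sum(pracma_cross(ub, u[1, ]) * t_hat[1, ]), sum(ub * u[1, ]))
    # spread the holonomy so every junction carries the same small twist
    for (k in seq_len(nb)) {
      th <- alpha * (k - 1) / nb
      u[k, ] <- rodrigues(u[k, ], t_hat[k, ], cos(th), sin(th))
    }
  }
  list(a = a_pos, p = a_pos + u)
}

maxwell_velocities <- function(n, kT, mass) {
  matrix(rnorm(3 * n, sd = sqrt(kT / mass)), n, 3)
}

# open-chain positions sampled from the discrete worm-like-chain ensemble of
# the bending potential K_b (1 - cos theta): bend cosines from the exact
# conditional density ~ exp(K cos theta), azimuths uniform. Starting an open
# chain inside its own bending ensemble removes the very slow relaxation of
# long-wavelength modes from a straight rod.
wlc_chain_positions <- function(n_units, K_b) {
  t_hat <- matrix(0, n_units - 1, 3)
  t_hat[1, ] <- c(1, 0, 0)
  if (n_units > 2) {
    for (k in 2:(n_units - 1)) {
      u <- runif(1)
      ct <- if (K_b > 1e-8) {
        1 + log(u + (1 - u) * exp(-2 * K_b)) / K_b
      } else 2 * u - 1
      st_ <- sqrt(max(0, 1 - ct^2))
      phi <- runif(1, 0, 2 * pi)
      tz <- t_hat[k - 1, ]
      e1 <- pracma_cross(tz, c(0, 0, 1))
      if (sqrt(sum(e1^2)) < 1e-6) e1 <- pracma_cross(tz, c(0, 1, 0))
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- pracma_cross(tz, e1)
      t_hat[k, ] <- ct * tz + st_ * (cos(phi) * e1 + sin(phi) * e2)
    }
  }
  apply(rbind(c(0, 0, 0), t_hat), 2, cumsum)
}

#' Scenario specification
#'
#' Collects the experimental design of one run: chain topology and size,
#' pre-tied knot, and placement of the active swivel, nick, gap and topoIII
#' mode on the circular map (0-based repeat-unit indices).
#'
#' @param topology `"linear"`, `"circle"` or `"catenane"`.
#' @param size_bp DNA length in base pairs (divisible by 8; one repeat unit
#'   per 8 bp). For catenanes, length of each of the two circles (recycled).
#' @param knot `"none"`, `"3_1"` (trefoil) or `"8_18"`.
#' @param n_links Gauss linking number of the catenane (torus link).
#' @param swivel `NULL` or `list(unit =, rate =, sign =)`.
#' @param nick `NULL` or `list(unit =)`.
#' @param gap `NULL` or `list(start =)` (first of three consecutive units);
#'   for catenanes a list of such lists (one per circle) is accepted.
#' @param topoiii enable topoIII passage mode at gaps.
#' @param seed RNG seed for initial velocities.
#' @return an `sc_scenario` list.
#' @export
scenario_spec <- function(topology = c("circle", "linear", "catenane"),
                          size_bp = 3000, knot = "none", n_links = 2,
                          swivel = NULL, nick = NULL, gap = NULL,
                          topoiii = FALSE, seed = 1) {
  topology <- match.arg(topology)
  if (any(size_bp %% 8 != 0)) {
    warning("size_bp not divisible by 8; rounding to whole repeat units")
    size_bp <- round(size_bp / 8) * 8
  }
  structure(list(topology = topology, size_bp = size_bp, knot = knot,
                 n_links = n_links, swivel = swivel, nick = nick, gap = gap,
                 topoiii = topoiii, seed = seed),
            class = "sc_scenario")
}

supported_knots <- c("none", "unknot", "3_1", "8_18")

knot_curve <- function(knot, n) {
  switch(knot,
         "none" = , "unknot" = resample_curve(function(t) circle_curve(n, t), n),
         "3_1" = resample_curve(torus_knot_curve(2, 3), n),
         "8_18" = resample_curve(braid_closure_curve(rep(c(1, -2), 4)), n),
         stop("unknown knot type '", knot, "'; supported: ",
              paste(supported_knots, collapse = ", ")))
}

#' Build an initial chain state
#'
#' Realizes the scenario as bead coordinates: the main chain follows a
#' regular circle, a line, or a parametric knotted curve (trefoil from the
#' (2,3) torus-knot equations; 8_18 from the closure of the alternating
#' 3-strand braid (s1 s2^-1)^4), resampled to 1 sigma bond length. Torsional
#' frames are parallel-transported so the chain starts torsionally relaxed,
#' and velocities are drawn from the Maxwell-Boltzmann distribution.
#'
#' @param spec an [scenario_spec()]; or a number, shorthand for a plain
#'   circle of that many base pairs.
#' @param params [model_params()].
#' @return `list(topology =, state =)`.
#' @export
build_chain <- function(spec, params = model_params()) {
  if (is.numeric(spec)) spec <- scenario_spec(size_bp = spec)
  if (spec$topology == "catenane") return(build_catenane(spec, params))
  n <- as.integer(spec$size_bp[1] / params$bp_per_bead)
  circular <- spec$topology == "circle"
  if (circular) {
    m_pos <- knot_curve(spec$knot, n)
  } else {
    if (spec$knot %in% c("none", "unknot")) {
      m_pos <- cbind(seq_len(n) - (n + 1) / 2, 0, 0)
    } else {
      # tie the knot in an open chain: take the knotted circle, open one bond
      # and extend straight tails along the end tangents so the knotted arc
      # stays interior
      core_n <- max(as.integer(0.7 * n), 12L)
      tail_n <- n - core_n
      closed <- knot_curve(spec$knot, core_n)
      t1 <- tail_n %/% 2; t2 <- tail_n - t1
      d1 <- closed[1, ] - closed[2, ]
      d2 <- closed[core_n, ] - closed[core_n - 1, ]
      d1 <- d1 / sqrt(sum(d1^2)); d2 <- d2 / sqrt(sum(d2^2))
      head_tail <- if (t1 > 0) t(sapply(t1:1, function(i) closed[1, ] + i * d1))
      else NULL
      foot_tail <- if (t2 > 0) t(sapply(1:t2, function(i) closed[core_n, ] + i * d2))
      else NULL
      m_pos <- rbind(head_tail, closed, foot_tail)
    }
  }
  topo <- make_topology(n, circular, params)
  fr <- build_frames(m_pos, circular)
  pos <- rbind(m_pos, fr$a, fr$p)
  set.seed(spec$seed %% .Machine$integer.max)
  vel <- maxwell_velocities(nrow(pos), params$epsilon, params$mass)
  st <- conformation(pos, vel)
  st <- enforce_frame_constraints(st, topo, params)
  topo <- place_sites(topo, spec, params)
  list(topology = topo, state = st)
}

place_sites <- function(topo, spec, params, chain = 1) {
  if (!is.null(spec$nick)) topo <- apply_nick(topo, spec$nick$unit, chain)
  if (!is.null(spec$gap)) {
    gaps <- if (!is.null(spec$gap$start)) list(spec$gap) else spec$gap
    for (g in gaps) topo <- apply_gap(topo, g$start, chain, params)
  }
  if (!is.null(spec$swivel)) {
    sw <- spec$swivel
    sws <- if (!is.null(sw$unit)) list(sw) else sw
    for (i in seq_along(sws)) {
      s <- sws[[i]]
      chg <- if (!is.null(s$chain)) s$chain else chain
      topo <- add_swivel(topo, s$unit,
                         rate = if (is.null(s$rate)) 7e-4 else s$rate,
                         sign = if (is.null(s$sign)) 1 else s$sign,
                         chain = chg)
    }
  }
  if (isTRUE(spec$topoiii)) topo <- enable_topoiii(topo)
  topo
}

#' Build a torus catenane of two circles
#'
#' Realizes two closed chains interlinked as a (2, 2n) torus link with Gauss
#' linking number n — the product topology of replication of a circular DNA.
#'
#' @inheritParams build_chain
#' @return `list(topology =, state =)`.
#' @export
build_catenane <- function(spec, params = model_params()) {
  if (spec$n_links < 1) stop("catenane requires linking number >= 1")
  sizes <- rep(spec$size_bp, length.out = 2)
  n <- as.integer(sizes / params$bp_per_bead)
  curves <- torus_link_curves(spec$n_links)
  # the two components must share one scale factor or the interlink geometry
  # is destroyed; pick it so the mean bond length over both circles is 1
  t1 <- seq(0, 2 * pi, length.out = max(2000, 20 * max(n)) + 1)
  t1 <- t1[-length(t1)]
  len <- function(p) sum(sqrt(rowSums((rbind(p[-1, ], p[1, ]) - p)^2)))
  s <- mean(c(n[1] / len(curves[[1]](t1)), n[2] / len(curves[[2]](t1))))
  m1 <- resample_curve(curves[[1]](t1) * s, n[1], bond = NA_real_)
  m2 <- resample_curve(curves[[2]](t1) * s, n[2], bond = NA_real_)
  topo <- make_topology(n, c(TRUE, TRUE), params)
  fr1 <- build_frames(m1, TRUE); fr2 <- build_frames(m2, TRUE)
  pos <- rbind(m1, m2, fr1$a, fr2$a, fr1$p, fr2$p)
  set.seed(spec$seed %% .Machine$integer.max)
  vel <- maxwell_velocities(nrow(pos), params$epsilon, params$mass)
  st <- conformation(pos, vel)
  st <- enforce_frame_constraints(st, topo, params)
  topo <- place_sites_catenane(topo, spec, params)
  list(topology = topo, state = st)
}

place_sites_catenane <- function(topo, spec, params) {
  if (!is.null(spec$gap)) {
    gaps <- if (!is.null(spec$gap$start)) list(modifyList(spec$gap, list(chain = 1))) else spec$gap
    for (g in gaps) {
      ch <- if (is.null(g$chain)) 1 else g$chain
      topo <- apply_gap(topo, g$start, ch, params)
    }
  }
  if (!is.null(spec$nick)) {
    nicks <- if (!is.null(spec$nick$unit)) list(spec$nick) else spec$nick
    for (nk in nicks) {
      ch <- if (is.null(nk$chain)) 1 else nk$chain
      topo <- apply_nick(topo, nk$unit, ch)
    }
  }
  if (!is.null(spec$swivel)) {
    sws <- if (!is.null(spec$swivel$unit)) list(spec$swivel) else spec$swivel
    for (s in sws) {
      ch <- if (is.null(s$chain)) 1 else s$chain
      topo <- add_swivel(topo, s$unit,
                         rate = if (is.null(s$rate)) 7e-4 else s$rate,
                         sign = if (is.null(s$sign)) 1 else s$sign, chain = ch)
    }
  }
  if (isTRUE(spec$topoiii)) topo <- enable_topoiii(topo)
  topo
}

#' Thermalize a built configuration
#'
#' Runs Langevin dynamics with all active swivels switched off, checks that
#' the potential energy has become stationary (the running means of the last
#' two quarters agree within 2%) and verifies that no strand passage has
#' occurred (knot determinant of every closed chain unchanged).
#'
#' @param system `list(topology, state)` from [build_chain()].
#' @param n_steps number of integration steps.
#' @param params [model_params()].
#' @param seed RNG seed.
#' @param check_knot verify the knot type is preserved (error if not).
#' @return the system with an updated state and attributes `equilibrated`
#'   (logical) and `energy_trace`.
#' @export
thermalize <- function(system, n_steps = 1e5, params = model_params(),
                       seed = 1, check_knot = TRUE) {
  topo <- system$topology
  det0 <- if (check_knot) chain_determinants(system$state, topo) else NULL
  quiet <- topo
  quiet$jun_active[] <- 0L
  settings <- langevin_settings(n_steps = n_steps, params = params,
                                seed = seed,
                                obs_every = max(1L, as.integer(n_steps / 200)),
                                snapshot_every = 0L)
  traj <- run_dynamics(system$state, quiet, params, settings)
  pe <- rowSums(traj$observables[, c("E_fene", "E_wca", "E_dh", "E_bend", "E_dih")])
  nq <- length(pe)
  q3 <- pe[seq(floor(nq / 2) + 1, floor(3 * nq / 4))]
  q4 <- pe[seq(floor(3 * nq / 4) + 1, nq)]
  equil <- abs(mean(q4) - mean(q3)) <= 0.02 * abs(mean(pe[-seq_len(nq %/% 2)]))
  st <- traj$final_state
  if (check_knot) {
    det1 <- chain_determinants(st, topo)
    if (!identical(det0, det1))
      stop("knot type changed during thermalization (strand passage): ",
           paste(det0, collapse = ","), " -> ", paste(det1, collapse = ","))
  }
  out <- list(topology = topo, state = st)
  attr(out, "equilibrated") <- equil
  attr(out, "energy_trace") <- pe
  out
}

chain_determinants <- function(state, topo) {
  vapply(seq_along(topo$chains), function(c) {
    ch <- topo$chains[[c]]
    if (!ch$circular) return(NA_integer_)
    knot_determinant(m_positions(state, topo, c))
  }, integer(1))
}

#' Extract the main-chain polygon of one chain
#'
#' @param state an `sc_state` (or a snapshot matrix).
#' @param topo the `sc_topology`.
#' @param chain chain number.
#' @return matrix of M-bead coordinates in chain order.
#' @export
m_positions <- function(state, topo, chain = 1) {
  pos <- if (is.matrix(state)) state else state$positions
  ch <- topo$chains[[chain]]
  pos[ch$first + seq_len(ch$n_units), , drop = FALSE]
}
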