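# Topological and polymer observables: linking number, writhe, twist, knot
# identification and localization, rotational diffusion, persistence length.

#' Gauss linking number of two closed curves
#'
#' Discrete Gauss double integral (exact per-segment-pair solid angles) over
#' all segment pairs, rounded to the nearest integer.
#'
#' @param curve_a,curve_b matrices of vertex coordinates of closed polygons.
#' @param closed_a,closed_b both curves must be closed; passing `FALSE`
#'   raises an error (the linking number of open curves is undefined).
#' @return integer linking number (sign follows curve orientations).
#' @export
gauss_linking_number <- function(curve_a, curve_b,
                                 closed_a = TRUE, closed_b = TRUE) {
  if (!closed_a || !closed_b)
    stop("linking number requires closed curves")
  raw <- cpp_linking(as.matrix(curve_a), as.matrix(curve_b))
  lk <- round(raw)
  if (abs(raw - lk) > 1e-4)
    warning("Gauss integral ", format(raw), " is not close to an integer; ",
            "curves may touch")
  as.integer(lk)
}

#' Writhe of a space curve
#'
#' Exact discrete Gauss self-integral (per-segment-pair solid angle closed
#' form). For open curves the plain double sum over segment pairs is
#' reported and flagged via the `closed` attribute.
#'
#' @param curve matrix of vertex coordinates.
#' @param closed treat the polygon as closed.
#' @return numeric writhe; attribute `closed` records the closure flag.
#' @export
writhe <- function(curve, closed = TRUE) {
  w <- cpp_writhe(as.matrix(curve), closed)
  attr(w, "closed") <- closed
  w
}

#' Twist of the periaxial ribbon
#'
#' Sum over junctions of the rotation of the periaxial offset relative to
#' parallel transport across the vertex, in turns. Nicked and gapped frames
#' are included geometrically. With `relative_to_phase = TRUE` each
#' junction's current phase (the active swivel's ramped phase) is
#' subtracted, giving the elastic twist of the DNA itself; together with the
#' writhe this is the measured linking number whose change tracks the
#' rotations injected by the motor.
#'
#' @param state an `sc_state` (or snapshot matrix).
#' @param topo an `sc_topology`.
#' @param params [model_params()].
#' @param relative_to_phase subtract junction phases (motor strain
#'   convention).
#' @return numeric vector, one twist (in turns) per chain.
#' @export
twist <- function(state, topo, params = model_params(),
                  relative_to_phase = FALSE) {
  pos <- if (is.matrix(state)) state else state$positions
  cpp_twist(pos, topo_for_core(topo), params_for_core(params),
            as.integer(relative_to_phase))
}

#' Measured linking number (Tw + Wr) of each closed chain
#'
#' @inheritParams twist
#' @return numeric vector of Tw + Wr per chain (geometric twist by default).
#' @export
linking_number <- function(state, topo, params = model_params(),
                           relative_to_phase = FALSE) {
  tw <- twist(state, topo, params, relative_to_phase)
  wr <- vapply(seq_along(topo$chains), function(c) {
    ch <- topo$chains[[c]]
    cpp_writhe(m_positions(state, topo, c), ch$circular)
  }, numeric(1))
  tw + wr
}

# ---- knot identification ----------------------------------------------------

random_rotation <- function() {
  repeat {
    q <- rnorm(4)
    n <- sqrt(sum(q^2))
    if (n > 1e-8) break
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# |det| of the (m-1)x(m-1) minor of an integer matrix, computed modulo a
# prime by Gaussian elimination; exact for values below p/2
det_mod <- function(M, p) {
  m <- nrow(M)
  if (m <= 1) return(1)
  A <- M[-m, -m, drop = FALSE] %% p
  n <- nrow(A)
  det <- 1
  for (k in seq_len(n)) {
    piv <- which(A[k:n, k] != 0)
    if (!length(piv)) return(0)
    piv <- piv[1] + k - 1
    if (piv != k) {
      tmp <- A[k, ]; A[k, ] <- A[piv, ]; A[piv, ] <- tmp
      det <- (p - det) %% p
    }
    det <- (det * A[k, k]) %% p
    inv <- mod_inv(A[k, k], p)
    if (k < n) {
      for (r in (k + 1):n) {
        if (A[r, k] != 0) {
          f <- (A[r, k] * inv) %% p
          A[r, ] <- (A[r, ] - f * A[k, ]) %% p
        }
      }
    }
  }
  det
}

mod_inv <- function(a, p) {
  # Fermat: a^(p-2) mod p by fast exponentiation (doubles are exact here)
  e <- p - 2
  r <- 1; b <- a %% p
  while (e > 0) {
    if (e %% 2 == 1) r <- (r * b) %% p
    b <- (b * b) %% p
    e <- e %/% 2
  }
  r
}

# knot determinant of one generic planar diagram given by cpp_diagram output
diagram_determinant <- function(cr) {
  m <- nrow(cr)
  if (m == 0) return(1L)
  # passages along the curve: each crossing contributes two, ordered by
  # (edge, parameter); arcs are the runs between under-passages
  pass <- rbind(
    data.frame(edge = cr[, 1], t = cr[, 2], crossing = seq_len(m), over = cr[, 5] == 1),
    data.frame(edge = cr[, 3], t = cr[, 4], crossing = seq_len(m), over = cr[, 5] == 0))
  pass <- pass[order(pass$edge, pass$t), ]
  k <- nrow(pass)
  under_idx <- which(!pass$over)
  # arc id for each passage: arcs break after each under-passage
  arc_of_pass <- integer(k)
  arc <- 1L
  for (i in seq_len(k)) {
    arc_of_pass[i] <- arc
    if (!pass$over[i]) arc <- arc + 1L
  }
  n_arcs <- arc - 1L
  # the curve is closed: the final partial arc is the same as the first
  arc_of_pass[arc_of_pass == arc] <- 1L
  if (n_arcs != m) return(NA_integer_) # inconsistent diagram
  # coloring matrix: per crossing, 2 * over - under_in - under_out
  A <- matrix(0, m, n_arcs)
  for (cx in seq_len(m)) {
    rows <- which(pass$crossing == cx)
    over_arc <- arc_of_pass[rows[pass$over[rows]]]
    up <- rows[!pass$over[rows]]
    arc_in <- arc_of_pass[up]
    arc_out <- if (arc_in == n_arcs) 1L else arc_in + 1L
    A[cx, over_arc] <- A[cx, over_arc] + 2
    A[cx, arc_in] <- A[cx, arc_in] - 1
    A[cx, arc_out] <- A[cx, arc_out] - 1
  }
  p1 <- 46337; p2 <- 46327
  d1 <- det_mod(A, p1); d2 <- det_mod(A, p2)
  v1 <- min(d1, p1 - d1); v2 <- min(d2, p2 - d2)
  if (v1 != v2) return(NA_integer_)
  as.integer(v1)
}

#' Knot determinant |Delta(-1)| of a closed curve
#'
#' Identifies the knot type of a closed polygon through the determinant of
#' the knot (the Alexander polynomial evaluated at -1): 1 for the unknot, 3
#' for the trefoil, 45 for 8_18. The polygon is first simplified by
#' passage-free vertex elision (KMT reduction), then projected along random
#' directions; each generic projection yields a diagram whose Fox-coloring
#' matrix determinant is computed exactly in modular arithmetic. The value
#' is projection-invariant; projections are retried when degenerate and
#' cross-checked for agreement.
#'
#' @param curve matrix of vertex coordinates of a closed polygon.
#' @param n_projections number of independent projections that must agree.
#' @param max_retry maximum projection attempts.
#' @param reduce apply KMT chain reduction first (recommended).
#' @return integer determinant.
#' @export
knot_determinant <- function(curve, n_projections = 2, max_retry = 25,
                             reduce = TRUE) {
  poly <- as.matrix(curve)
  if (reduce) poly <- cpp_kmt(poly)
  if (nrow(poly) <= 3) return(1L)
  vals <- integer(0)
  tries <- 0
  while (length(vals) < n_projections && tries < max_retry) {
    tries <- tries + 1
    rot <- random_rotation()
    dg <- cpp_diagram(poly %*% t(rot))
    if (!isTRUE(dg$ok)) next
    d <- diagram_determinant(dg$crossings)
    if (is.na(d)) next
    vals <- c(vals, d)
  }
  if (length(vals) < n_projections)
    stop("no generic projection found after ", max_retry, " attempts")
  if (length(unique(vals)) != 1)
    stop("projections disagree on the knot determinant: ",
         paste(vals, collapse = ", "))
  vals[1]
}

# ---- knot core localization -------------------------------------------------

# close an open arc: either join the endpoints directly, or send both
# endpoints radially out to a far point ("ray" closure)
close_arc <- function(arc, method = c("ray", "direct"), far_scale = 100) {
  method <- match.arg(method)
  if (method == "direct") return(arc)
  ctr <- colMeans(arc)
  n <- nrow(arc)
  mid <- (arc[1, ] + arc[n, ]) / 2
  dirv <- mid - ctr
  nv <- sqrt(sum(dirv^2))
  if (nv < 1e-8) dirv <- c(0, 0, 1) else dirv <- dirv / nv
  span <- max(sqrt(rowSums(sweep(arc, 2, ctr)^2)))
  far <- ctr + dirv * far_scale * max(span, 1)
  rbind(arc, far)
}

arc_indices <- function(s, e, n) {
  # inclusive arc from s to e walking forward on a circle of n vertices (0-based)
  if (s <= e) s:e else c(s:(n - 1), 0:e)
}

#' Locate the knotted core of a closed curve
#'
#' Finds a short contiguous arc that carries the knot: starting from the
#' full chain, vertices are trimmed from both ends (two-pointer shrink) as
#' long as the closed-up arc keeps the full chain's knot determinant; the
#' complementary arc must close to an unknot. Because localization depends
#' on where the circle is cut and how arcs are closed, several starting cuts
#' are tried and the shortest core kept (ties broken by smaller start
#' index). Arc closure follows the far-point ray construction by default.
#'
#' @param curve closed polygon (matrix).
#' @param sites optional integer vector of 0-based repeat-unit indices of
#'   nicks/gaps; if given, the contour distance from the core midpoint to
#'   the nearest site is reported.
#' @param closure closure method for sub-arcs ("ray" or "direct").
#' @param n_cuts number of starting cut positions tried.
#' @return a `knot_report` list: `determinant`, `core_start`, `core_end`
#'   (0-based, inclusive, forward arc), `core_length_units`,
#'   `distance_to_site`, `unknotted`.
#' @export
locate_knot_core <- function(curve, sites = NULL, closure = "ray",
                             n_cuts = 6) {
  poly <- as.matrix(curve)
  n <- nrow(poly)
  full_det <- knot_determinant(poly)
  rep0 <- list(determinant = full_det, core_start = NA_integer_,
               core_end = NA_integer_, core_length_units = 0L,
               distance_to_site = NA_real_, unknotted = full_det == 1)
  class(rep0) <- "knot_report"
  if (full_det == 1) return(rep0)
  arc_det <- function(s, e) {
    idx <- arc_indices(s, e, n)
    if (length(idx) < 5) return(1L)
    knot_determinant(close_arc(poly[idx + 1, , drop = FALSE], closure))
  }
  best <- NULL
  for (cut in as.integer(seq(0, n - 1, length.out = n_cuts + 1)[seq_len(n_cuts)])) {
    s <- (cut + 1L) %% n; e <- cut
    # shrink alternately from both ends while the arc still holds the knot
    repeat {
      moved <- FALSE
      if ((e - s) %% n > 5 && arc_det((s + 1L) %% n, e) == full_det) {
        s <- (s + 1L) %% n; moved <- TRUE
      }
      if ((e - s) %% n > 5 && arc_det(s, (e - 1L + n) %% n) == full_det) {
        e <- (e - 1L + n) %% n; moved <- TRUE
      }
      if (!moved) break
    }
    len <- ((e - s) %% n) + 1L
    cand <- list(s = s, e = e, len = len)
    if (is.null(best) || cand$len < best$len ||
        (cand$len == best$len && cand$s < best$s)) best <- cand
  }
  mid <- (best$s + ((best$e - best$s) %% n) %/% 2) %% n
  dist <- NA_real_
  if (!is.null(sites) && length(sites)) {
    d <- abs(sites - mid)
    dist <- min(pmin(d, n - d))
  }
  out <- list(determinant = full_det, core_start = best$s, core_end = best$e,
              core_length_units = best$len, distance_to_site = dist,
              unknotted = FALSE)
  class(out) <- "knot_report"
  out
}

#' @export
print.knot_report <- function(x, ...) {
  if (x$unknotted) {
    cat("Unknotted (determinant 1)\n")
  } else {
    cat(sprintf("Knot determinant %d; core units %d..%d (length %d)",
                x$determinant, x$core_start, x$core_end, x$core_length_units))
    if (!is.na(x$distance_to_site))
      cat(sprintf("; contour distance to nearest site %.0f", x$distance_to_site))
    cat("\n")
  }
  invisible(x)
}

#' Knot position along a trajectory
#'
#' For each stored snapshot, localizes the knot core and reports its contour
#' distance (repeat units, along the circular map) to a site of interest
#' (typically the nick or gap). If the chain unknots during the trajectory
#' the series is truncated there and flagged.
#'
#' @param traj an `sc_trajectory` of a knotted circular chain.
#' @param site_unit 0-based repeat-unit index of the nick/gap site.
#' @param chain chain number.
#' @param every analyze every `every`-th snapshot.
#' @return data.frame with `step`, `time`, `distance`, `core_length`,
#'   `determinant`; attributes `truncated` (logical) and `summary` (initial
#'   and final quartile means and least-squares slope of distance vs time).
#' @export
knot_position_trace <- function(traj, site_unit, chain = 1, every = 1L) {
  idx <- seq(1, length(traj$snapshots), by = every)
  rows <- list()
  truncated <- FALSE
  for (i in idx) {
    poly <- m_positions(traj$snapshots[[i]], traj$topology, chain)
    rep <- locate_knot_core(poly, sites = site_unit)
    if (rep$unknotted) { truncated <- TRUE; break }
    rows[[length(rows) + 1]] <-
      data.frame(step = traj$snap_steps[i],
                 time = traj$snap_steps[i] * traj$settings$timestep,
                 distance = rep$distance_to_site,
                 core_length = rep$core_length_units,
                 determinant = rep$determinant)
  }
  df <- do.call(rbind, rows)
  attr(df, "truncated") <- truncated
  if (!is.null(df) && nrow(df) >= 4) {
    nq <- nrow(df)
    q1 <- df$distance[seq_len(ceiling(nq / 4))]
    q4 <- df$distance[seq(floor(3 * nq / 4) + 1, nq)]
    fit <- lm(distance ~ time, data = df)
    slope <- unname(coef(fit)[2])
    # the distance series is autocorrelated and, while the knot is
    # delocalized, dominated by localization ambiguity; a parametric slope
    # error would be far too small. The null scale is taken from circular
    # shifts of the same series, which preserve its full correlation
    # structure while destroying any real time trend.
    slope_shift <- function(k) {
      d <- df$distance[((seq_len(nq) - 1 + k) %% nq) + 1]
      unname(coef(lm(d ~ df$time))[2])
    }
    null_slopes <- vapply(seq_len(nq - 1), slope_shift, numeric(1))
    attr(df, "summary") <- list(initial_quartile_mean = mean(q1),
                                final_quartile_mean = mean(q4),
                                slope = slope,
                                slope_se = stats::sd(null_slopes))
  }
  df
}

# ---- dynamics-derived polymer observables -----------------------------------

#' Rotational diffusion coefficient from a cumulative angle series
#'
#' D_rot = slope of the mean-squared cumulative rotation angle versus time,
#' divided by 2 (one rotational degree of freedom about the chain axis). The
#' MSD is averaged over all time origins. Because the angular velocity
#' decorrelates over m/gamma (a few tau), the MSD approaches its asymptote
#' 2 D t - const from below; the slope is therefore fitted with a free
#' intercept over intermediate lags (0.6% to 6% of the series length),
#' past the inertial regime but short enough for many independent
#' intervals.
#'
#' @param angle cumulative (unwrapped) rotation angle series in rad, or a
#'   list of replicate series.
#' @param dt time between successive samples, tau.
#' @param lag_min smallest lag used in the fit, in samples; supply it when
#'   the rotor has inertia (several times m/gamma over `dt`) so the fit
#'   stays clear of the ballistic regime. Default: series length / 160.
#' @return list `D` (rad^2/tau), `se` (between-replicate standard error when
#'   replicates are given), `flagged` (TRUE when the relative CI exceeds
#'   20%).
#' @export
rotational_diffusion_coefficient <- function(angle, dt, lag_min = NULL) {
  series <- if (is.list(angle)) angle else list(angle)
  one <- function(a) {
    n <- length(a)
    # window: past the inertial regime but short in absolute terms, so long
    # series contribute many independent intervals instead of longer lags
    lo <- if (is.null(lag_min)) max(4, n %/% 160) else max(4, round(lag_min))
    hi <- min(n %/% 3, max(2 * lo, 1000))
    if (hi <= lo + 8) hi <- lo + 8
    lags <- unique(round(seq(lo, hi, length.out = 24)))
    msd <- vapply(lags, function(L) mean((a[(L + 1):n] - a[1:(n - L)])^2),
                  numeric(1))
    t <- lags * dt
    unname(coef(lm(msd ~ t))[2]) / 2
  }
  Ds <- vapply(series, one, numeric(1))
  D <- mean(Ds)
  se <- if (length(Ds) > 1) sd(Ds) / sqrt(length(Ds)) else NA_real_
  flagged <- !is.na(se) && (2 * se) > 0.2 * abs(D)
  list(D = D, se = se, replicates = Ds, flagged = flagged)
}

#' Measure the repeat-unit rotational diffusion coefficient by simulation
#'
#' Simulates the minimal torsionally coherent DNA fragment — four main-chain
#' beads carrying three locked torsional frames — and tracks the cumulative
#' azimuthal rotation of the interior frame about the local chain axis. An
#' isolated repeat unit embedded in torsionally continuous DNA spins
#' together with its locked neighbours, so the fragment's collective axial
#' rotation is the model's repeat-unit rotational mobility; the expected
#' scale is k_BT divided by the summed periaxial azimuthal drag.
#'
#' @param params [model_params()].
#' @param n_frames number of torsional frames in the fragment.
#' @param n_steps integration steps per replicate.
#' @param n_rep number of independent replicates.
#' @param seed base RNG seed.
#' @return as [rotational_diffusion_coefficient()], plus `n_frames`.
#' @export
measure_rotational_diffusion <- function(params = model_params(),
                                         n_frames = 3, n_steps = 1.2e6,
                                         n_rep = 10, seed = 1) {
  n_units <- n_frames + 1L
  series <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    spec <- scenario_spec(topology = "linear", size_bp = n_units * 8,
                          seed = seed + 7 * r)
    sys <- build_chain(spec, params)
    st <- langevin_settings(n_steps = n_steps, params = params,
                            seed = seed + 7 * r,
                            obs_every = 50L, snapshot_every = 0L,
                            track_bond = as.integer((n_units - 1L) %/% 2))
    traj <- run_dynamics(sys$state, sys$topology, params, st)
    series[[r]] <- traj$observables$azimuth
  }
  dt_sample <- 50 * params$timestep
  # stay several angular-velocity correlation times m/gamma_P clear of the
  # ballistic regime
  lag_min <- ceiling(5 * (params$mass / params$drag_P) / dt_sample)
  out <- rotational_diffusion_coefficient(series, dt = dt_sample,
                                          lag_min = lag_min)
  out$n_frames <- n_frames
  out
}

#' Persistence length from tangent-vector correlations
#'
#' Computes the mean cosine of the angle between bond vectors separated by
#' contour distance s over the stored snapshots of an open-chain trajectory
#' and fits exp(-s/L_p). Sampling should cover at least ~200 decorrelated
#' frames for a stable fit.
#'
#' @param traj an `sc_trajectory` of an open chain (or list of trajectories,
#'   pooled).
#' @param params [model_params()] (for the nm conversion).
#' @param s_max largest contour separation used in the fit; default half the
#'   chain or 2.5 times the running L_p estimate, whichever is smaller.
#' @param discard_frac fraction of initial snapshots discarded as
#'   equilibration.
#' @return list `Lp_sigma`, `Lp_nm`, `r_squared`, `ci_sigma` (95% from the
#'   fit), `flagged` (non-exponential decay, R^2 < 0.9), `correlation`
#'   (data.frame s, mean_cos).
#' @export
persistence_length <- function(traj, params = model_params(), s_max = NULL,
                               discard_frac = 0.2) {
  trajs <- if (inherits(traj, "sc_trajectory")) list(traj) else traj
  acc <- NULL
  for (tr in trajs) {
    topo <- tr$topology
    n_snap <- length(tr$snapshots)
    use <- seq(max(1, ceiling(discard_frac * n_snap)), n_snap)
    for (i in use) {
      m <- m_positions(tr$snapshots[[i]], topo, 1)
      t_vec <- diff(m)
      t_hat <- t_vec / sqrt(rowSums(t_vec^2))
      nbv <- nrow(t_hat)
      smax_here <- nbv - 1
      cs <- lapply(seq_len(smax_here), function(s) {
        rowSums(t_hat[1:(nbv - s), , drop = FALSE] *
                t_hat[(1 + s):nbv, , drop = FALSE])
      })
      sums <- vapply(cs, sum, numeric(1))
      cnts <- vapply(cs, length, numeric(1))
      if (is.null(acc)) acc <- list(s = sums, n = cnts)
      else { acc$s <- acc$s + sums; acc$n <- acc$n + cnts }
    }
  }
  corr <- acc$s / acc$n
  s <- seq_along(corr)
  # first estimate from short range, then restrict the fit window; the fit is
  # weighted by pair counts since long-separation correlations are noisy
  lp0 <- -1 / coef(lm(log(pmax(corr[1:min(8, length(corr))], 1e-6)) ~
                        s[1:min(8, length(corr))]))[2]
  if (is.null(s_max))
    s_max <- max(4, min(floor(length(corr) * 0.6), round(2 * lp0)))
  # restrict to separations where the correlation is well above its noise
  # floor: the log transform biases the slope down where C(s) is noisy
  keep <- s <= s_max & corr > 0.2
  if (sum(keep) < 3) keep <- s <= s_max & corr > 0.05
  if (sum(keep) < 3) {
    # correlations decay below the noise floor within a bond or two: the
    # chain is at (or below) the freely jointed limit
    lp <- -1 / log(max(corr[1], 1e-6))
    return(list(Lp_sigma = lp, Lp_nm = lp * params$sigma_nm,
                r_squared = NA_real_, ci_sigma = NA_real_, flagged = TRUE,
                correlation = data.frame(s = s, mean_cos = corr, n = acc$n)))
  }
  fit <- lm(log(corr[keep]) ~ s[keep], weights = acc$n[keep])
  lp <- -1 / unname(coef(fit)[2])
  r2 <- summary(fit)$r.squared
  se_slope <- summary(fit)$coefficients[2, 2]
  ci <- lp^2 * 1.96 * se_slope # delta method on 1/slope
  list(Lp_sigma = lp, Lp_nm = lp * params$sigma_nm, r_squared = r2,
       ci_sigma = ci, flagged = r2 < 0.9,
       correlation = data.frame(s = s, mean_cos = corr, n = acc$n))
}

#' Equilibrate open chains and measure the persistence length
#'
#' Convenience wrapper: builds `n_rep` independent open chains, equilibrates
#' each, runs sampling trajectories and fits the pooled tangent correlation
#' decay. Bending modes at wavelengths near L_p relax slowly, so several
#' independent replicate chains give a far more stable estimate than one
#' long trajectory.
#'
#' @param params [model_params()].
#' @param n_units chain length in repeat units.
#' @param n_rep independent replicate chains (pooled).
#' @param n_steps sampling steps per replicate.
#' @param warm_steps equilibration steps per replicate.
#' @param s_max largest contour separation in the fit. The default 12 keeps
#'   the fit inside the strictly exponential, well-sampled part of the
#'   decay; larger separations are dominated by slowly relaxing global
#'   bending modes and add noise, not information.
#' @param timestep integration step used for sampling.
#' @param seed RNG seed.
#' @param snapshot_every frames cadence.
#' @return as [persistence_length()].
#' @export
measure_persistence_length <- function(params = model_params(), n_units = 80,
                                       n_rep = 4, n_steps = 1e6,
                                       warm_steps = max(2e5, n_steps %/% 4),
                                       timestep = 0.004,
                                       seed = 1, snapshot_every = 2000,
                                       s_max = 12) {
  trajs <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    sd <- seed + 101 * (r - 1)
    spec <- scenario_spec(topology = "linear", size_bp = n_units * 8, seed = sd)
    sys <- build_chain(spec, params)
    # stiff chains start from an in-ensemble worm-like-chain conformation:
    # long-wavelength bending modes relax far too slowly from a rod and
    # would leave seed-dependent stiffness memory in the sample. Flexible
    # chains (K_b < 8) relax quickly and keep the rod start, since strongly
    # bent random conformations would carry steric overlaps.
    if (params$bend_constant >= 8) {
      set.seed(sd %% .Machine$integer.max)
      m_pos <- wlc_chain_positions(n_units, params$bend_constant)
      fr <- build_frames(m_pos, FALSE)
      st0 <- conformation(rbind(m_pos, fr$a, fr$p),
                          maxwell_velocities(nrow(m_pos) * 3 - 2,
                                             params$epsilon, params$mass))
      sys$state <- enforce_frame_constraints(st0, sys$topology, params)
    }
    warm <- langevin_settings(n_steps = warm_steps, params = params,
                              timestep = timestep, seed = sd,
                              obs_every = as.integer(max(1, warm_steps / 20)))
    tr0 <- run_dynamics(sys$state, sys$topology, params, warm)
    st <- langevin_settings(n_steps = n_steps, params = params,
                            timestep = timestep, seed = sd + 1,
                            obs_every = as.integer(n_steps / 20),
                            snapshot_every = as.integer(snapshot_every))
    trajs[[r]] <- run_dynamics(tr0$final_state, sys$topology, params, st)
  }
  persistence_length(trajs, params, s_max = s_max, discard_frac = 0)
}

#' Tune the bending constant to a target persistence length
#'
#' The chain's stiffness results from the cumulative action of excluded
#' volume, electrostatic repulsion and the bending potential, so K_b must be
#' adjusted by simulation. Bisection over K_b; each evaluation equilibrates
#' an open chain and measures L_p. Monotonicity of L_p in K_b makes the
#' bracket valid.
#'
#' @param target_lp_sigma target persistence length, sigma.
#' @param params base [model_params()].
#' @param lo,hi bracket for K_b, epsilon.
#' @param tol acceptable relative deviation of the measured L_p.
#' @param n_units,n_steps,timestep sampling configuration per evaluation.
#' @param seed RNG seed.
#' @param max_iter bisection iterations.
#' @return list `K_b`, `Lp_sigma`, `scan` (data.frame of all evaluations).
#' @export
tune_bending_constant <- function(target_lp_sigma = 20,
                                  params = model_params(), lo = 1, hi = 40,
                                  tol = 0.1, n_units = 60, n_steps = 1.2e6,
                                  timestep = 0.004, seed = 1, max_iter = 8) {
  eval_lp <- function(K) {
    p <- params; p$bend_constant <- K
    measure_persistence_length(p, n_units = n_units, n_steps = n_steps,
                               timestep = timestep, seed = seed,
                               snapshot_every = max(500, n_steps %/% 400))$Lp_sigma
  }
  scan <- data.frame(K_b = numeric(0), Lp_sigma = numeric(0))
  note <- function(K, L) scan <<- rbind(scan, data.frame(K_b = K, Lp_sigma = L))
  L_lo <- eval_lp(lo); note(lo, L_lo)
  if (L_lo > target_lp_sigma)
    stop("target persistence length ", target_lp_sigma, " sigma is below the ",
         "bare-chain value ", format(L_lo), " sigma at K_b = ", lo,
         "; unreachable (scan table attached)")
  L_hi <- eval_lp(hi); note(hi, L_hi)
  if (L_hi < target_lp_sigma)
    stop("bracket failure: L_p(", hi, ") = ", format(L_hi),
         " sigma below target; increase hi (scan table attached)")
  K <- NA; L <- NA
  for (it in seq_len(max_iter)) {
    K <- 0.5 * (lo + hi)
    L <- eval_lp(K); note(K, L)
    if (abs(L - target_lp_sigma) <= tol * target_lp_sigma) break
    if (L < target_lp_sigma) lo <- K else hi <- K
  }
  list(K_b = K, Lp_sigma = L, scan = scan)
}
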