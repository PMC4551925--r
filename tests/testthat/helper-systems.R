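# Small systems and oracles shared across tests.

tiny_params <- function(...) model_params(...)

# straight linear chain of n units along x, exact frames
straight_chain <- function(n, params = model_params()) {
  build_chain(scenario_spec(topology = "linear", size_bp = n * 8, seed = 42),
              params)
}

small_circle <- function(n, knot = "none", seed = 7, params = model_params()) {
  build_chain(scenario_spec(topology = "circle", size_bp = n * 8, knot = knot,
                            seed = seed), params)
}

# central finite difference of the total energy for selected coordinates
fd_force <- function(state, topo, params, bead, coord, h = 1e-6) {
  xp <- state$positions; xm <- state$positions
  xp[bead, coord] <- xp[bead, coord] + h
  xm[bead, coord] <- xm[bead, coord] - h
  ep <- total_energy(conformation(xp), topo, params)$total
  em <- total_energy(conformation(xm), topo, params)$total
  -(ep - em) / (2 * h)
}

# independent writhe oracle: signed crossings averaged over projections
writhe_by_projection <- function(poly, n_proj = 400, seed = 1) {
  set.seed(seed)
  n <- nrow(poly)
  tot <- 0
  for (q in seq_len(n_proj)) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    P <- poly %*% Q
    s <- 0
    for (i in 1:n) {
      i2 <- i %% n + 1
      for (j in i:n) {
        j2 <- j %% n + 1
        if (j == i || j2 == i || j == i2) next
        x1 <- P[i, 1]; y1 <- P[i, 2]; x2 <- P[i2, 1]; y2 <- P[i2, 2]
        x3 <- P[j, 1]; y3 <- P[j, 2]; x4 <- P[j2, 1]; y4 <- P[j2, 2]
        den <- (x2 - x1) * (y4 - y3) - (y2 - y1) * (x4 - x3)
        if (abs(den) < 1e-12) next
        t <- ((x3 - x1) * (y4 - y3) - (y3 - y1) * (x4 - x3)) / den
        u <- ((x3 - x1) * (y2 - y1) - (y3 - y1) * (x2 - x1)) / den
        if (t <= 0 || t >= 1 || u <= 0 || u >= 1) next
        z1 <- P[i, 3] + t * (P[i2, 3] - P[i, 3])
        z2 <- P[j, 3] + u * (P[j2, 3] - P[j, 3])
        cz <- (x2 - x1) * (y4 - y3) - (y2 - y1) * (x4 - x3)
        s <- s + if (z1 > z2) sign(cz) else -sign(cz)
      }
    }
    tot <- tot + s
  }
  tot / n_proj
}

# combinatorial knot-determinant oracle straight from a braid word: builds the
# diagram's Fox-coloring matrix from strand bookkeeping, no 3D geometry
braid_determinant <- function(word, n_strands) {
  m <- length(word)
  # arcs: each strand position carries a current arc id; a new arc starts
  # after every under-passage
  arc_at <- seq_len(n_strands)
  next_arc <- n_strands + 1L
  rows <- list()
  for (w in word) {
    k <- abs(w)
    over_first <- w > 0 # sigma_k: strand at position k crosses over
    a_lower <- arc_at[k]; a_upper <- arc_at[k + 1]
    if (over_first) {
      over <- a_lower; under_in <- a_upper; under_out <- next_arc
    } else {
      over <- a_upper; under_in <- a_lower; under_out <- next_arc
    }
    next_arc <- next_arc + 1L
    rows[[length(rows) + 1]] <- c(over = over, u_in = under_in, u_out = under_out)
    # after the crossing the strands swap positions
    if (over_first) {
      arc_at[k] <- under_out; arc_at[k + 1] <- over
    } else {
      arc_at[k] <- over; arc_at[k + 1] <- under_out
    }
  }
  # closure: identify the final arc at each position with the initial one
  alias <- seq_len(next_arc - 1L)
  for (pos in seq_len(n_strands)) alias[arc_at[pos]] <- pos
  resolve <- function(a) { while (alias[a] != a) a <- alias[a]; a }
  ids <- sort(unique(vapply(seq_len(next_arc - 1L), resolve, integer(1))))
  col_of <- function(a) match(resolve(a), ids)
  A <- matrix(0, length(rows), length(ids))
  for (r in seq_along(rows)) {
    cr <- rows[[r]]
    A[r, col_of(cr["over"])] <- A[r, col_of(cr["over"])] + 2
    A[r, col_of(cr["u_in"])] <- A[r, col_of(cr["u_in"])] - 1
    A[r, col_of(cr["u_out"])] <- A[r, col_of(cr["u_out"])] - 1
  }
  abs(round(det(A[-1, -1, drop = FALSE])))
}
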