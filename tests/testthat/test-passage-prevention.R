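# The enlarged excluded volume (sigma_ex = 1.5 sigma > 1 sigma bonds) closes
# the mesh of the chain: segments cannot be driven through each other.

test_that("two chain segments driven together by a strong constant force do not pass", {
  p <- model_params()
  # chain A along x at z = 0; chain B along y at z = 1.6, pushed down onto A
  topoA <- chain_topology(10, circular = FALSE, params = p)
  mA <- cbind(seq(-4.5, 4.5), 0, 0)
  mB <- cbind(0, seq(-4.5, 4.5), 1.6)
  topo <- supercoilr:::make_topology(c(10, 10), c(FALSE, FALSE), p)
  frA <- supercoilr:::build_frames(mA, FALSE)
  frB <- supercoilr:::build_frames(mB, FALSE)
  pos <- rbind(mA, mB, frA$a, frB$a, frA$p, frB$p)
  st <- conformation(pos)
  s <- langevin_settings(n_steps = 4e4, params = p, timestep = 0.002, seed = 3,
                         obs_every = 0, snapshot_every = 5000)
  # +5 eps/sigma downward on every B bead, upward on every A bead
  s$ext_idx <- as.integer(c(0:9, 10:19))
  s$ext_force <- rbind(matrix(rep(c(0, 0, 5), each = 10), ncol = 3),
                       matrix(rep(c(0, 0, -5), each = 10), ncol = 3))
  tr <- run_dynamics(st, topo, p, s)
  # test closure: close each segment through a large detour on its own side;
  # if B had passed through A the closures' linking number would change
  closure <- function(m, lift) {
    n <- nrow(m)
    far1 <- m[n, ] + c(0, 0, lift)
    far2 <- m[1, ] + c(0, 0, lift)
    rbind(m, far1, far2)
  }
  lk <- function(snapshot) {
    mAx <- m_positions(snapshot, topo, 1)
    mBx <- m_positions(snapshot, topo, 2)
    gauss_linking_number(closure(mAx, -40), closure(mBx, 40))
  }
  expect_identical(lk(st$positions), 0L)
  for (i in seq_along(tr$snapshots)) expect_identical(lk(tr$snapshots[[i]]), 0L)
  # the drive produced genuine hard contact at some point (the chains are
  # eventually free to slip around each other, but never through)
  min_dist <- vapply(tr$snapshots, function(sn) {
    a <- m_positions(sn, topo, 1); b <- m_positions(sn, topo, 2)
    min(sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)))
  }, numeric(1))
  expect_lt(min(min_dist), 1.8)
})
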