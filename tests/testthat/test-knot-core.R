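# Knot-core localization.

# a tight trefoil spliced into a large circle: the core is known to sit in
# the small knotted arc
tied_trefoil_polygon <- function(n_loop = 90) {
  tref <- supercoilr:::resample_curve(supercoilr:::torus_knot_curve(2, 3), 24)
  # open the knot between vertex 1 and 24 and splice in a big planar detour
  a <- tref[1, ]; b <- tref[24, ]
  ctr <- colMeans(tref)
  dirv <- (a + b) / 2 - ctr
  dirv <- dirv / sqrt(sum(dirv^2))
  far <- ctr + dirv * 30
  # detour: arc through far point, perpendicular spread
  perp <- supercoilr:::pracma_cross(dirv, c(0, 0, 1))
  if (sqrt(sum(perp^2)) < 1e-6) perp <- supercoilr:::pracma_cross(dirv, c(0, 1, 0))
  perp <- perp / sqrt(sum(perp^2))
  t <- seq(0, 1, length.out = n_loop)
  detour <- t(sapply(t, function(u) {
    base <- (1 - u) * b + u * a
    lift <- sin(pi * u) * 28
    base + dirv * lift + perp * 6 * sin(2 * pi * u)
  }))
  rbind(tref, detour[-c(1, n_loop), ])
}

test_that("a tight trefoil tied into a long circle is localized to a short core", {
  poly <- tied_trefoil_polygon()
  expect_identical(knot_determinant(poly), 3L)
  set.seed(3)
  rep <- locate_knot_core(poly)
  expect_false(rep$unknotted)
  expect_equal(rep$determinant, 3L)
  expect_lte(rep$core_length_units, 30)
  # the core must overlap the knotted arc (vertices 0..23 in 0-based terms)
  idx <- supercoilr:::arc_indices(rep$core_start, rep$core_end, nrow(poly))
  expect_gt(length(intersect(idx, 0:23)), 10)
})

test_that("unknots yield an empty core report", {
  sys <- small_circle(30)
  rep <- locate_knot_core(m_positions(sys$state, sys$topology))
  expect_true(rep$unknotted)
  expect_identical(rep$core_length_units, 0L)
})

test_that("localization is stable under halving the curve resolution", {
  poly <- tied_trefoil_polygon()
  n <- nrow(poly)
  set.seed(5)
  r1 <- locate_knot_core(poly)
  half <- poly[seq(1, n, by = 2), ]
  r2 <- locate_knot_core(half)
  mid1 <- (r1$core_start + ((r1$core_end - r1$core_start) %% n) %/% 2) %% n
  n2 <- nrow(half)
  mid2 <- (r2$core_start + ((r2$core_end - r2$core_start) %% n2) %/% 2) %% n2
  # compare on the full-resolution index scale
  expect_lt(abs(mid1 - 2 * mid2), 2 * 5 + 1)
})

test_that("contour distance to sites is measured along the circular map", {
  poly <- tied_trefoil_polygon()
  set.seed(7)
  rep <- locate_knot_core(poly, sites = c(5L))
  expect_false(is.na(rep$distance_to_site))
  n <- nrow(poly)
  expect_lte(rep$distance_to_site, n / 2)
})
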