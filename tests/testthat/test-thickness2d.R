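test_that("thickness field honours footprint values and decays in the patch", {
  bp <- default_bilayer()
  fp <- wedge_footprint(U = -0.9)
  fld <- solve_thickness_field(bp, fp, h = 0.15, margin = 6.5)
  # prescribed immersion on footprint cells
  xy <- cbind(rep(fld$x, length(fld$y)), rep(fld$y, each = length(fld$x)))
  im <- footprint_immersion(fp, xy)
  inside <- !is.na(im)
  expect_equal(as.vector(fld$u)[inside], im[inside], tolerance = 1e-9)
  # far field decays to the relaxed state; the pinned-height field decays
  # at rate 0.66/nm, so at >= 6.3 nm from the wedge the honest envelope is
  # |U| exp(-0.66 * 6.3) ~ 1.4e-2 nm
  far <- abs(xy[, 1]) > 1.5 + 6.3 | abs(xy[, 2]) > 0.6 + 6.3
  expect_lt(max(abs(as.vector(fld$u)[far])), 5e-3)
  expect_gt(fld$energy, 0)
  expect_error(solve_thickness_field(bp, fp, h = 0.3), "resolve")
})

test_that("field and energy scale exactly with the immersion amplitude", {
  bp <- default_bilayer()
  f1 <- solve_thickness_field(bp, wedge_footprint(U = -0.45), h = 0.15,
                              margin = 3)
  f2 <- solve_thickness_field(bp, wedge_footprint(U = -0.9), h = 0.15,
                              margin = 3)
  expect_equal(2 * f1$u, f2$u, tolerance = 1e-9)
  expect_equal(4 * f1$energy, f2$energy, tolerance = 1e-9)
})

test_that("mid-length transect of a long wedge matches the 1D pinned solution", {
  bp <- default_bilayer()
  L <- 13
  fld <- solve_thickness_field(bp, wedge_footprint(-0.9, L = L), h = 0.15,
                               margin = 5)
  tr <- field_transect(fld, x0 = 0)
  pp <- pinned_thickness_profile(bp, deep_wedge())
  sel <- tr$y > 0.6 & tr$y < 4.5
  u2d <- tr$u[sel]; u1d <- pp$u(tr$y[sel] - 0.6)
  expect_lt(max(abs(u2d - u1d)) / max(abs(u1d)), 0.05)
  expect_lt(abs(tr$energy_per_length - 2 * pp$energy_per_length) /
              (2 * pp$energy_per_length), 0.10)
})

test_that("pair interaction energies converge under grid refinement", {
  bp <- default_bilayer()
  int_at <- function(h) {
    f1 <- solve_thickness_field(bp, wedge_footprint(-0.9), h = h, margin = 4)
    f2 <- solve_thickness_field(bp, wedge_footprint(-0.9, center = c(0, 2.0)),
                                h = h, margin = 4)
    fj <- solve_thickness_field(bp, list(wedge_footprint(-0.9),
                                         wedge_footprint(-0.9, center = c(0, 2.0))),
                                h = h, margin = 4)
    fj$energy - f1$energy - f2$energy
  }
  e1 <- int_at(0.15); e2 <- int_at(0.075)
  expect_lt(abs(e1 - e2) / abs(e2), 0.05)
  expect_lt(e1, 0)     # face-on deep pair is attractive
})

test_that("pair-potential tables behave like the physics they tabulate", {
  tab <- test_h0_table()
  # attractive face-on well at intermediate gaps
  expect_lt(min(pair_potential(tab, 0, c(1.6, 1.8, 2.2), 0)), 0)
  # far pose is zero, overlapping pose is hardcore
  expect_identical(pair_potential(tab, 0, 20, 0), 0)
  expect_identical(pair_potential(tab, 0, 1.0, 0), Inf)
  # mirror symmetry of the lookup
  set.seed(11)
  q <- cbind(runif(50, -8, 8), runif(50, -8, 8), runif(50, -6, 6))
  expect_equal(pair_potential(tab, q[, 1], q[, 2], q[, 3]),
               pair_potential(tab, -q[, 1], q[, 2], -q[, 3]))
  expect_equal(pair_potential(tab, q[, 1], q[, 2], q[, 3]),
               pair_potential(tab, q[, 1], -q[, 2], -q[, 3]))
  # tip-to-tip is weaker than face-on at the same outline gap
  gap <- 1.0
  face <- pair_potential(tab, 0, 1.2 + gap, 0)
  tip <- pair_potential(tab, 3 + gap, 0, 0)
  expect_lt(abs(tip), abs(face))
  # energy at the largest tabulated separations is essentially zero
  xm <- max(tab$dx); ym <- max(tab$dy)
  expect_lt(max(abs(pair_potential(tab, c(xm, 0, xm), c(0, ym, ym), 0))), 1e-2)
})

test_that("thickness-mediated interactions are approximately pairwise additive", {
  bp <- default_bilayer()
  # collinear face-on triple at moderate gaps
  fps <- list(wedge_footprint(-0.9, center = c(0, 0)),
              wedge_footprint(-0.9, center = c(0, 2.1)),
              wedge_footprint(-0.9, center = c(0, 4.2)))
  ad <- additivity_check(bp, fps, h = 0.15, margin = 4)
  expect_lt(abs(ad$triple_energy - ad$pairwise_sum) / abs(ad$pairwise_sum), 0.2)
  # widely separated triple: both measures vanish
  far <- list(wedge_footprint(-0.9, center = c(0, 0)),
              wedge_footprint(-0.9, center = c(0, 12)),
              wedge_footprint(-0.9, center = c(12, 6)))
  ad2 <- additivity_check(bp, far, h = 0.15, margin = 4)
  expect_lt(abs(ad2$triple_energy), 0.05)
  expect_lt(abs(ad2$pairwise_sum), 0.05)
  # two far, one near: the triple is dominated by the close pair
  mix <- list(wedge_footprint(-0.9, center = c(0, 0)),
              wedge_footprint(-0.9, center = c(0, 2.0)),
              wedge_footprint(-0.9, center = c(14, 0)))
  ad3 <- additivity_check(bp, mix, h = 0.15, margin = 4)
  expect_equal(ad3$triple_energy, ad3$pair_energies[1], tolerance = 0.05)
  expect_error(additivity_check(bp, list(fps[[1]], fps[[1]], fps[[2]])),
               "overlap")
})
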