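test_that("pair profiles satisfy the imposed boundary conditions", {
  bp <- default_bilayer()
  for (tau in c(0, 0.05)) {
    b <- bilayer_params(tau = tau)
    wa <- wedge_params(U = -0.9)
    wb <- wedge_params(U = -0.4)                 # asymmetric pair
    pr <- solve_pair_profile(b, wa, wb, d = 3.2)
    s <- pr$s
    f0 <- profile_eval(pr, c(-s, s))
    f1 <- profile_eval(pr, c(-s, s), deriv = 1)
    expect_equal(f0$u, c(wa$U, wb$U), tolerance = 1e-9)
    expect_equal(f1$u, c(wa$slope_u, -wb$slope_u), tolerance = 1e-9)
    expect_equal(f1$h, c(wa$slope_h, -wb$slope_h), tolerance = 1e-9)
    expect_equal(f0$h[1], 0, tolerance = 1e-9)   # reference level
  }
})

test_that("conjugate pairing keeps the evaluated fields real", {
  pr <- solve_pair_profile(default_bilayer(), deep_wedge(), deep_wedge(), d = 2.5)
  r <- seq(-pr$s, pr$s, length.out = 31)
  raw <- wedgelat:::.profile_fields(pr, r, 0)
  expect_lt(max(abs(Im(raw$ubar))), 1e-10)
  expect_lt(max(abs(Im(raw$h))), 1e-10)
})

test_that("a symmetric pair has zero midpoint thickness slope", {
  pr <- solve_pair_profile(default_bilayer(), deep_wedge(), deep_wedge(), d = 3)
  expect_equal(profile_eval(pr, 0, deriv = 1)$u, 0, tolerance = 1e-10)
  expect_equal(pr$delta, 0, tolerance = 1e-9)    # mirror symmetry
})

test_that("isolated profiles decay to the unperturbed state", {
  pr <- solve_isolated_profile(default_bilayer(), deep_wedge())
  ls <- decay_constants(default_bilayer())$lambda_s
  # the thickness field decays on 2*lambda_s (the real part of sqrt(nu)),
  # so the honest envelope at distance r is |U| exp(-r / (2 lambda_s))
  expect_lt(abs(profile_eval(pr, 10 * ls)$u), 2 * 0.9 * exp(-5))
  expect_lt(abs(profile_eval(pr, 16 * ls)$u), 1e-3 * 0.9)
  expect_lt(abs(profile_eval(pr, 40)$u), 1e-12)
})

test_that("an unperturbed wedge produces a flat zero-energy profile", {
  w0 <- wedge_params(U = 0, slope_h = 0, slope_u = 0)
  pr <- solve_isolated_profile(default_bilayer(), w0)
  r <- seq(0, 10, length.out = 21)
  expect_lt(max(abs(profile_eval(pr, r)$u)), 1e-12)
  expect_equal(profile_energy(pr), 0, tolerance = 1e-12)
  pr2 <- solve_pair_profile(default_bilayer(), w0, w0, d = 3)
  expect_equal(profile_energy(pr2), 0, tolerance = 1e-12)
})

test_that("wedges may not overlap", {
  expect_error(solve_pair_profile(default_bilayer(), deep_wedge(), deep_wedge(),
                                  d = 1.1), "overlap")
  expect_error(interaction_curve(default_bilayer(), deep_wedge(),
                                 d_grid = c(1.0, 3)), "2\\*r0")
})

test_that("boundary-term energy equals direct quadrature on random draws", {
  draws <- make_fixture("param_draws", seed = 42L, n_draws = 100L)
  for (i in seq_len(nrow(draws))) {
    b <- bilayer_params(K_b = draws$K_b[i], K_t = draws$K_t[i],
                        a = draws$a[i], tau = draws$tau[i])
    w <- wedge_params(U = draws$U[i])
    pr <- solve_pair_profile(b, w, w, d = draws$d[i])
    expect_lt(abs(profile_energy(pr) - profile_energy_quadrature(pr)), 1e-6)
  }
  # and on the semi-infinite exterior
  for (tau in c(0, 0.03)) {
    pr <- solve_isolated_profile(bilayer_params(tau = tau), deep_wedge())
    expect_lt(abs(profile_energy(pr) - profile_energy_quadrature(pr)), 1e-5)
  }
})

test_that("shallow-state repulsion matches its closed form", {
  # with U = 0 and zero thickness slope the interaction is a pure
  # bending-frustration term, K_b L tan(9 deg)^2 / (d/2 - r0)
  d <- c(1.5, 2, 3, 5, 10, 40)
  expect_equal(gint_at(d, U = 0), shallow_closed_form(d), tolerance = 1e-8)
})

test_that("interaction curve is symmetric under swapping the wedges", {
  bp <- default_bilayer()
  wa <- wedge_params(U = -0.9); wb <- wedge_params(U = -0.3)
  d <- c(1.5, 2.2, 4)
  expect_equal(interaction_curve(bp, wa, wb, d)$g_int,
               interaction_curve(bp, wb, wa, d)$g_int, tolerance = 1e-10)
})

test_that("the far field is the slow bending tail plus a decayed thickness part", {
  # the thickness (u+) sector decays exponentially on 2*lambda_s; what is
  # left at large separation is exactly the closed-form 1/(d/2 - r0) bending
  # frustration of the mirrored contact slopes
  expect_equal(gint_at(40), shallow_closed_form(40), tolerance = 1e-4)
  expect_lt(abs(gint_at(40)), 0.1)
  # and it vanishes in the limit
  expect_lt(abs(gint_at(200)), abs(gint_at(40)) / 4)
})

test_that("deep wedges have an attractive well, shallow wedges never do", {
  de <- dimerization_energy(default_bilayer(), deep_wedge())
  expect_true(de$attractive)
  expect_gt(de$energy, 10)
  expect_equal(de$d_star, 1.78, tolerance = 0.05)
  d0 <- dimerization_energy(default_bilayer(), shallow_wedge())
  expect_false(d0$attractive)
  expect_gt(d0$energy, 0)        # contact cost is a positive penalty
})

test_that("dimerization strengthens with immersion depth", {
  gains <- vapply(seq(-0.5, -0.9, by = -0.1), function(U)
    dimerization_energy(default_bilayer(), wedge_params(U = U))$energy, 0)
  expect_true(all(diff(gains) > 0))
})

test_that("tension weakens dimerization at experimentally visible tensions", {
  gains <- vapply(c(0.2, 0.5, 1, 2), function(tau)
    dimerization_energy(bilayer_params(tau = tau), deep_wedge())$energy, 0)
  expect_true(all(diff(gains) < 0))
  g0 <- dimerization_energy(default_bilayer(), deep_wedge())$energy
  expect_lt(gains[4], g0)
  # shallow-state curves shift far less than the deep-state gain does
  shallow_shift <- abs(gint_at(2, U = 0, tau = 2) - gint_at(2, U = 0))
  expect_lt(shallow_shift, abs(gains[4] - g0))
})

test_that("the tensionless solution is the small-tension limit", {
  # the isolated-wedge reference carries a tension tail whose energy scales
  # as sqrt(K_b * tau), so the approach to tau = 0 follows a sqrt(tau) law
  g0 <- gint_at(2)
  d8 <- abs(gint_at(2, tau = 1e-8) - g0)
  d6 <- abs(gint_at(2, tau = 1e-6) - g0)
  expect_lt(d8, 1e-4)
  expect_equal(d6 / d8, 10, tolerance = 0.25)     # sqrt(100) scaling
})

test_that("critical immersion depth is stable under grid refinement", {
  bp <- default_bilayer()
  uc <- critical_immersion_depth(bp, deep_wedge())
  uc2 <- critical_immersion_depth(bp, deep_wedge(), d_step = 0.0125)
  expect_lt(abs(uc - uc2), 2e-3)
  expect_error(critical_immersion_depth(bp, deep_wedge(),
                                        U_bracket = c(-0.2, -0.1)), "sign change")
})

test_that("h-pinned 1D profile meets its contact conditions and decays", {
  pp <- pinned_thickness_profile(default_bilayer(), deep_wedge())
  expect_equal(pp$u(0), -0.9, tolerance = 1e-10)
  expect_equal(pp$u(0, deriv = 1), 0, tolerance = 1e-10)
  expect_lt(abs(pp$u(15)), 1e-4)
  expect_gt(pp$energy_per_length, 0)
})
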