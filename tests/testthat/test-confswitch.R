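test_that("state energies follow the two-state bookkeeping", {
  cm <- conformational_model(epsilon_d = 1.7)
  expect_equal(state_base_energy(cm, 0, 0), 0)
  expect_equal(state_base_energy(cm, 0, 1), 1.7)
  expect_equal(state_base_energy(cm, 1, 1), 3.4)
  # deep-deep interaction equals the symmetric deep-pair curve
  d <- c(1.5, 1.8, 2.5, 6)
  expect_equal(state_interaction(cm, 1, 1, d), gint_at(d), tolerance = 1e-9)
  # mixed state decays at large separation; shallow state repels everywhere
  expect_lt(abs(state_interaction(cm, 0, 1, 39)), 0.1)
  expect_true(all(state_interaction(cm, 0, 0, seq(1.5, 12, by = 0.5)) > 0))
  expect_error(state_interaction(cm, 1, 1, 1.0), "hardcore")
})

test_that("Boltzmann weights have the dilute-limit and error behaviour", {
  cm <- conformational_model(epsilon_d = 2)
  # c -> 0: z -> exp(-G_non)
  expect_equal(boltzmann_weight(cm, 0, 0, 1e-12), 1, tolerance = 1e-6)
  expect_equal(boltzmann_weight(cm, 0, 1, 1e-12), exp(-2), tolerance = 1e-5)
  # z(0,1) = z(1,0) by construction
  expect_identical(boltzmann_weight(cm, 0, 1, 1e-4),
                   boltzmann_weight(cm, 1, 0, 1e-4))
  # deep-deep weight overtakes shallow-shallow at high concentration when
  # the dimerization gain exceeds 2 epsilon_d
  expect_gt(boltzmann_weight(cm, 1, 1, 1e-3), boltzmann_weight(cm, 0, 0, 1e-3))
  # unphysically high c is a named range error
  expect_error(boltzmann_weight(cm, 0, 0, 0.05), "0\\.05")
})

test_that("deep-state probability has its closed-form dilute limit and grows with c", {
  cm <- conformational_model(epsilon_d = 2)
  expect_equal(deep_state_probability(cm, 1e-9), 1 / (1 + exp(2))^2,
               tolerance = 1e-2)
  cm0 <- conformational_model(epsilon_d = 0)
  expect_equal(deep_state_probability(cm0, 1e-9), 0.25, tolerance = 1e-2)
  cs <- 10^seq(-6, -3, length.out = 8)
  pd <- vapply(cs, function(cc) deep_state_probability(cm, cc), 0)
  expect_true(all(diff(pd) > 0))
  expect_true(all(pd >= 0 & pd <= 1))
})

test_that("the interaction cutoff matters only at the percent level", {
  # the algebraic 1/d bending tail of the repulsive states keeps a small
  # cutoff sensitivity in the spatial integrals; the attractive well that
  # drives the switch is fully contained well inside 40 nm
  cm40 <- conformational_model(epsilon_d = 2, r_c = 40)
  cm80 <- conformational_model(epsilon_d = 2, r_c = 80)
  for (cc in c(1e-5, 1e-4)) {
    expect_lt(abs(deep_state_probability(cm40, cc) -
                  deep_state_probability(cm80, cc)), 0.01)
  }
})

test_that("the phase diagram shows a concerted switch", {
  cm <- conformational_model(epsilon_d = 0)
  pd <- phase_diagram(cm, c_grid = 10^seq(-6, -3, length.out = 15),
                      eps_grid = seq(0, 3, by = 0.5))
  expect_true(all(pd$P_d >= 0 & pd$P_d <= 1, na.rm = TRUE))
  # P_d crosses 1/2 at most once along each concentration row
  for (j in seq_along(pd$eps_grid)) {
    p <- pd$P_d[, j]
    expect_lte(sum(diff(p >= 0.5) != 0, na.rm = TRUE), 1)
  }
  # the zero-bias row never drops below the dilute-limit value 1/4
  expect_true(all(pd$P_d[, 1] >= 0.25 - 1e-9, na.rm = TRUE))
  # a P_d = 1/2 crossing exists at positive epsilon_d: the concerted switch
  expect_true(any(!is.na(pd$contour$c_half[pd$contour$epsilon_d > 0])))
})
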