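test_that("parameter constructors validate their inputs", {
  expect_s3_class(bilayer_params(), "bilayer_params")
  expect_error(bilayer_params(K_b = -1), "K_b")
  expect_error(bilayer_params(K_t = 0), "K_t")
  expect_error(bilayer_params(a = 0), "'a'")
  expect_error(bilayer_params(tau = -0.1), "tau")
  expect_error(wedge_params(U = -0.9, r0 = 0), "r0")
  expect_error(wedge_params(U = -0.9, L = -3), "L")
})

test_that("decay constants reproduce the characteristic length scales", {
  dc <- decay_constants(default_bilayer())
  # lambda_s = (K_b a^2 / (8 K_t))^(1/4) = (1/6)^(1/4) for the defaults
  expect_equal(dc$lambda_s, (1 / 6)^0.25, tolerance = 1e-12)
  expect_true(is.infinite(dc$lambda_t))
  # at zero tension the inverse square decay lengths are purely imaginary
  # complex conjugates
  expect_equal(Re(dc$nu_plus), 0)
  expect_equal(dc$nu_minus, Conj(dc$nu_plus))
  # chosen roots admit decaying branches
  expect_true(all(Re(c(sqrt(dc$nu_plus), sqrt(dc$nu_minus))) >= 0))

  dc2 <- decay_constants(bilayer_params(tau = 0.05))
  expect_equal(dc2$lambda_t, sqrt(20 / 0.05), tolerance = 1e-12)  # 20 nm
  expect_equal(dc2$nu_minus, Conj(dc2$nu_plus))
})
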