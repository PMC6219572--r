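test_that("configurations validate, fill defaults and round-trip", {
  cfg <- as_run_config(list())
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$bilayer$K_b, 20)
  expect_equal(cfg$wedge$slope_h, -tan(9 * pi / 180))
  expect_error(as_run_config(list(bogus = 1)), "bogus")
  expect_error(as_run_config(list(bilayer = list(K_b = 20, typo = 2))), "typo")
  expect_error(as_run_config(list(bilayer = list(K_t = -60))), "K_t")
  expect_error(as_run_config(list(scenario = "nope")), "scenario")

  tmp <- withr::local_tempdir()
  y <- file.path(tmp, "cfg.yaml"); j <- file.path(tmp, "cfg.json")
  cfg$seed <- 17L
  save_config(cfg, y); save_config(cfg, j)
  expect_equal(load_config(y)$seed, 17L)
  expect_equal(load_config(j)$bilayer, cfg$bilayer)
  expect_equal(load_config(y)$wedge, cfg$wedge)
})

test_that("scenario runs write numeric CSVs plus a metadata sidecar, reproducibly", {
  tmp <- withr::local_tempdir()
  cfg <- as_run_config(list(scenario = "potential-curve",
                            curve = list(d_min = 1.3, d_max = 4, d_step = 0.1)))
  run_scenario(cfg, file.path(tmp, "a"))
  run_scenario(cfg, file.path(tmp, "b"))
  fa <- file.path(tmp, "a", "potential_curve.csv")
  expect_true(file.exists(fa))
  expect_true(file.exists(file.path(tmp, "a", "metadata.json")))
  da <- utils::read.csv(fa)
  expect_named(da, c("d_nm", "G_int_kBT"))
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(file.path(tmp, "b", "potential_curve.csv"), "raw",
                           file.size(fa)))
  meta <- jsonlite::read_json(file.path(tmp, "a", "metadata.json"))
  expect_equal(meta$config$bilayer$K_b, 20)
  expect_equal(meta$seed, 1)
})

test_that("fixtures are deterministic, overlap-free and density-limited", {
  a <- make_fixture("random_config", seed = 9L, n = 8L, box = 50)
  b <- make_fixture("random_config", seed = 9L, n = 8L, box = 50)
  expect_identical(a$poses, b$poses)
  sh <- a$shape
  expect_false(wedgelat:::mc_any_overlap(a$poses, a$box, sh,
                                         wedgelat:::.empty_table(sh$h0),
                                         list(on = FALSE, eps = 0, rm = 1)))
  expect_error(make_fixture("random_config", seed = 1L, n = 40L, box = 25),
               "density")
  expect_error(make_fixture("no-such-kind"), "unknown fixture")
  draws <- make_fixture("param_draws", seed = 3L, n_draws = 10L)
  expect_equal(nrow(draws), 10L)
  expect_true(all(draws$K_b > 0 & draws$K_t > 0 & draws$tau >= 0))
})
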