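test_that("the rigid N-BAR shape is a sane protein model", {
  sh <- nbar_shape()
  # the two H0 footprints of one protein never overlap each other
  f <- sh$capsules[nrow(sh$capsules) - 1:0, ]
  d <- wedgelat:::.segment_distance(f[1, 1:2], f[1, 3:4], f[2, 1:2], f[2, 3:4])
  expect_gt(d, 2 * sh$h0$r0)
  # outer normals are unit vectors perpendicular to the H0 axes
  for (a in 1:2) {
    expect_equal(sum(sh$h0_outer[a, ]^2), 1, tolerance = 1e-12)
    axis <- c(cos(sh$h0_frames[a, 3]), sin(sh$h0_frames[a, 3]))
    expect_equal(sum(sh$h0_outer[a, ] * axis), 0, tolerance = 1e-12)
  }
})

test_that("BAR pair potential matches its closed form", {
  # facing side-by-side at the minimum distance: full well depth
  expect_equal(bar_pair_potential(10, pi / 2, pi / 2), -10)
  # collinear orientations switch off the attractive term entirely
  expect_equal(bar_pair_potential(10, 0, 0), 10 * (1 - 0))
  expect_equal(bar_pair_potential(20, pi / 2, pi / 2),
               10 * ((1 / 2)^12 - 2 * (1 / 2)^6))
  expect_lt(abs(bar_pair_potential(1e3, pi / 2, pi / 2)), 1e-10)
  expect_gt(bar_pair_potential(2, pi / 2, pi / 2), 1e4)   # r^-12 wall
  expect_error(bar_pair_potential(0, 0, 0), "positive")
  # angles are taken modulo pi
  expect_equal(bar_pair_potential(12, pi / 2 + pi, pi / 2),
               bar_pair_potential(12, pi / 2, pi / 2))
})

test_that("total energy respects locality, periodicity and rigid motions", {
  tab <- test_h0_table()
  sh <- nbar_shape()
  expect_equal(total_energy(nbar_config(cbind(30, 30, 0), 60, sh), tab), 0)
  far <- nbar_config(rbind(c(10, 10, 0), c(40, 40, 1)), 60, sh)
  expect_equal(total_energy(far, tab), 0)
  dp <- make_fixture("dimer_pair")
  e0 <- total_energy(dp, tab)
  expect_lt(e0, -10)
  # periodic image shift
  shifted <- dp; shifted$poses[2, 1] <- shifted$poses[2, 1] + dp$box
  expect_equal(total_energy(shifted, tab), e0, tolerance = 1e-12)
  # rigid translation and rotation of the whole configuration
  tr <- dp; tr$poses[, 1] <- (tr$poses[, 1] + 7.3) %% tr$box
  tr$poses[, 2] <- (tr$poses[, 2] + 3.1) %% tr$box
  expect_equal(total_energy(tr, tab), e0, tolerance = 1e-9)
  rot <- dp
  phi <- 0.7; cphi <- cos(phi); sphi <- sin(phi); ctr <- c(40, 40)
  xy <- sweep(rot$poses[, 1:2], 2, ctr)
  rot$poses[, 1] <- ctr[1] + cphi * xy[, 1] - sphi * xy[, 2]
  rot$poses[, 2] <- ctr[2] + sphi * xy[, 1] + cphi * xy[, 2]
  rot$poses[, 3] <- rot$poses[, 3] + phi
  expect_equal(total_energy(rot, tab), e0, tolerance = 1e-9)
  # overlap is infinite
  ov <- nbar_config(rbind(c(30, 30, 0), c(31, 30, 0)), 60, sh)
  expect_identical(total_energy(ov, tab), Inf)
})

test_that("R and C++ table lookups agree everywhere", {
  tab <- test_h0_table()
  set.seed(5)
  q <- cbind(runif(300, -9, 9), runif(300, -9, 9), runif(300, -7, 7))
  rv <- pair_potential(tab, q[, 1], q[, 2], q[, 3])
  cv <- wedgelat:::mc_pair_lookup(wedgelat:::.table_payload(tab),
                                  q[, 1], q[, 2], q[, 3])
  expect_identical(is.infinite(rv), is.infinite(cv))
  fin <- is.finite(rv)
  expect_equal(rv[fin], cv[fin], tolerance = 1e-12)
})

test_that("Metropolis dynamics is deterministic and non-increasing at T = 0", {
  tab <- test_h0_table()
  cfg <- make_fixture("random_config", n = 8L, box = 45, seed = 3L)
  set.seed(99)
  r1 <- metropolis_sweep(cfg, tab, T = 0, n_steps = 400,
                         schedule = anneal_schedule(n_hot = 1, n_cool = 0,
                                                    record_every = 20))
  expect_true(all(diff(r1$trace$energy) <= 1e-9))
  set.seed(99)
  r2 <- metropolis_sweep(cfg, tab, T = 0, n_steps = 400,
                         schedule = anneal_schedule(n_hot = 1, n_cool = 0,
                                                    record_every = 20))
  expect_identical(r1$config$poses, r2$config$poses)
  expect_identical(r1$trace$energy, r2$trace$energy)
})

test_that("annealing with interactions disabled keeps an empty energy surface", {
  sh <- nbar_shape()
  tab0 <- wedgelat:::.empty_table(sh$h0)
  cfg <- make_fixture("random_config", n = 6L, box = 45, seed = 7L)
  set.seed(7)
  out <- anneal(cfg, tab0, schedule = anneal_schedule(n_hot = 200, n_cool = 200))
  expect_equal(out$energy, 0)
  expect_false(wedgelat:::mc_any_overlap(out$config$poses, out$config$box, sh,
                                         tab0, list(on = FALSE, eps = 0, rm = 1)))
})

test_that("annealing lowers the energy of interacting configurations", {
  tab <- test_h0_table()
  for (s in 1:3) {
    cfg <- make_fixture("random_config", n = 10L, box = 50, seed = s)
    e0 <- total_energy(cfg, tab)
    set.seed(1000 + s)
    out <- anneal(cfg, tab, schedule = anneal_schedule(n_hot = 2e4, n_cool = 1e4))
    expect_lte(out$energy, e0)
  }
})

test_that("chain statistics recognise hand-built dimers and chains", {
  iso <- make_fixture("random_config", n = 4L, box = 120, seed = 2L)
  cs0 <- chain_statistics(iso)
  # far-apart proteins: no dimers, all chains of length 1
  if (cs0$n_dimers == 0) expect_true(all(cs0$chain_lengths == 1))
  dp <- make_fixture("dimer_pair")
  cs <- chain_statistics(dp)
  expect_equal(cs$n_dimers, 1L)
  expect_equal(sort(cs$chain_lengths), 2L)
  expect_lt(abs(cs$dimers$alignment - pi), pi / 36)   # antiparallel
  expect_true(cs$dimers$outer_outer)
  ch <- chain_statistics(make_fixture("chain", n = 5L))
  expect_equal(cs_len <- max(ch$chain_lengths), 5L)
  expect_equal(ch$n_dimers, 4L)
  expect_true(all(abs(ch$dimers$alignment - pi) < pi / 36))
})
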