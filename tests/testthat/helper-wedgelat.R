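# Shared fixtures for the test suite.  The H0 pair-potential table used by
# the Monte Carlo tests is expensive (a few minutes of sparse solves), so it
# is built lazily once per test run and memoised.

.test_cache <- new.env(parent = emptyenv())

default_bilayer <- function(tau = 0) bilayer_params(tau = tau)
deep_wedge <- function() wedge_params(U = -0.9)
shallow_wedge <- function() wedge_params(U = 0)

# interaction energy at one separation through the public curve API
gint_at <- function(d, U = -0.9, tau = 0) {
  w <- wedge_params(U = U)
  interaction_curve(bilayer_params(tau = tau), w, w, d_grid = d)$g_int
}

# closed-form shallow-state repulsion: with U = 0 and zero u+ contact slope
# the thickness field vanishes identically and the height field is the
# energy-minimising cubic between mirrored contact slopes, giving
# G_int(d) = K_b * L * tan(9 deg)^2 / (d/2 - r0) exactly at zero tension
shallow_closed_form <- function(d, K_b = 20, L = 3, r0 = 0.6) {
  K_b * L * tan(9 * pi / 180)^2 / (d / 2 - r0)
}

test_h0_table <- function() {
  if (is.null(.test_cache$tab)) {
    .test_cache$tab <- pair_potential_table(
      bilayer_params(), wedge_params(U = -0.9),
      dx = c(0, 1.5, 3, 4.5, 6, 8, 11),
      dy = c(0, 1.3, 1.6, 2.0, 2.4, 3, 4, 5.5, 7, 10),
      dtheta = c(0, pi / 4, pi / 2, 3 * pi / 4),
      h = 0.15, margin = 4)
  }
  .test_cache$tab
}

# memoised scaled-down H0-only anneal (shared between acceptance blocks)
anneal_h0_only <- function(seed) {
  key <- paste0("anneal", seed)
  if (is.null(.test_cache[[key]])) {
    cfg <- random_nbar_config(16, box = 60, seed = seed)
    set.seed(100 + seed)
    .test_cache[[key]] <- anneal(cfg, test_h0_table(),
                                 schedule = anneal_schedule(n_hot = 1e5,
                                                            n_cool = 5e4))
  }
  .test_cache[[key]]
}
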