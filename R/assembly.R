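# Rigid-body model of an N-BAR protein and the simulated-annealing Monte
# Carlo machinery acting on configurations of such proteins in a periodic
# box.  The compute kernels live in src/mc_engine.cpp; everything here is
# geometry construction, thin wrappers and analysis.

#' Rigid two-dimensional model of an N-BAR protein
#'
#' Builds the rigid in-plane geometry used by the Monte Carlo module: a
#' crescent BAR backbone (an arc of capsules whose end-to-end span matches
#' the BAR pair-potential minimum distance) with one H0 wedge footprint
#' attached beyond each tip, directed along the local arc tangent.  The
#' steric outline is the union of the backbone and H0 capsules.  All
#' dimensions are parameters; the defaults give a crescent of 10 nm span
#' with 3 nm H0 helices.
#'
#' @param arc_span End-to-end (chord) length of the BAR arc (nm).
#' @param arc_half_angle Half opening angle of the arc (radians).
#' @param bar_radius Capsule radius of the backbone (nm).
#' @param n_arc Number of capsules approximating the arc.
#' @param h0 A [wedge_params()] describing the H0 helices.
#' @param h0_gap Gap between the arc tip circle and the start of the H0
#'   footprint (nm).  Negative values let the helix lie partly alongside the
#'   scaffold tip, as in N-BAR structures where the H0 helices emerge at the
#'   distal ends of the scaffold; the default places the H0 center 0.9 nm
#'   beyond the tip, which puts the scaffold centers of an H0-dimerised
#'   protein pair at the distance where the scaffold pair potential
#'   discriminates between the two dimer architectures.
#'
#' @return An object of class `nbar_shape` with elements `capsules` (matrix
#'   `x1, y1, x2, y2, r` in the body frame), `h0_frames` (2 x 3 matrix:
#'   center x, y and axis angle of each H0 footprint), `h0_outer` (2 x 2
#'   matrix of unit normals pointing to the outer side of each H0, away from
#'   the arc center) and the generating parameters.
#' @examples
#' sh <- nbar_shape()
#' nrow(sh$capsules)
#' @export
nbar_shape <- function(arc_span = 10, arc_half_angle = 60 * pi / 180,
                       bar_radius = 1.0, n_arc = 5L,
                       h0 = wedge_params(U = -0.9), h0_gap = -0.6) {
  stopifnot(arc_span > 0, arc_half_angle > 0, arc_half_angle < pi / 2,
            bar_radius > 0, n_arc >= 2L, inherits(h0, "wedge_params"))
  R <- arc_span / (2 * sin(arc_half_angle))
  cc <- c(0, R * cos(arc_half_angle))           # arc center (concave side +y)
  t <- seq(-arc_half_angle, arc_half_angle, length.out = n_arc + 1L)
  pts <- cbind(cc[1] + R * sin(t), cc[2] - R * cos(t))
  caps <- cbind(pts[-nrow(pts), , drop = FALSE], pts[-1, , drop = FALSE],
                bar_radius)
  # H0 helices along the tip tangents, protruding beyond the tips
  tanR <- c(cos(arc_half_angle), sin(arc_half_angle))
  tanL <- c(-cos(arc_half_angle), sin(arc_half_angle))
  tipR <- c(arc_span / 2, 0); tipL <- c(-arc_span / 2, 0)
  ext <- h0_gap + h0$L / 2
  cR <- tipR + ext * tanR
  cL <- tipL + ext * tanL
  phiR <- arc_half_angle
  phiL <- pi - arc_half_angle
  hc <- h0$L / 2 - h0$r0
  h0_caps <- rbind(
    c(cR - hc * tanR, cR + hc * tanR, h0$r0),
    c(cL - hc * tanL, cL + hc * tanL, h0$r0))
  capsules <- rbind(caps, h0_caps)
  colnames(capsules) <- c("x1", "y1", "x2", "y2", "r")
  h0_frames <- rbind(c(cR, phiR), c(cL, phiL))
  colnames(h0_frames) <- c("cx", "cy", "phi")
  h0_outer <- rbind(c(sin(arc_half_angle), -cos(arc_half_angle)),
                    c(-sin(arc_half_angle), -cos(arc_half_angle)))
  structure(list(capsules = capsules, h0_frames = h0_frames,
                 h0_outer = h0_outer, arc_span = arc_span,
                 arc_half_angle = arc_half_angle, bar_radius = bar_radius,
                 h0 = h0, h0_gap = h0_gap),
            class = "nbar_shape")
}

#' @exportS3Method base::print
print.nbar_shape <- function(x, ...) {
  cat(sprintf("N-BAR shape: %g nm crescent (half angle %.1f deg), %d capsules, H0 L = %g nm\n",
              x$arc_span, x$arc_half_angle * 180 / pi, nrow(x$capsules), x$h0$L))
  invisible(x)
}

#' Configuration of N-BAR proteins in a periodic box
#'
#' @param poses Numeric matrix with one row per protein: center `x`, `y`
#'   (nm) and orientation `theta` (radians).
#' @param box Periodic square box side (nm).
#' @param shape An [nbar_shape()].
#' @param seed Optional integer recording the RNG seed the configuration was
#'   generated from.
#'
#' @return An object of class `nbar_config`.
#' @export
nbar_config <- function(poses, box, shape = nbar_shape(), seed = NULL) {
  poses <- as.matrix(poses)
  stopifnot(ncol(poses) == 3L, is.numeric(poses), box > 0,
            inherits(shape, "nbar_shape"))
  poses[, 1:2] <- poses[, 1:2] %% box
  colnames(poses) <- c("x", "y", "theta")
  structure(list(poses = poses, box = box, shape = shape, seed = seed),
            class = "nbar_config")
}

#' @exportS3Method base::print
print.nbar_config <- function(x, ...) {
  cat(sprintf("N-BAR configuration: %d proteins in a %g nm periodic box\n",
              nrow(x$poses), x$box))
  invisible(x)
}

#' @exportS3Method
plot.nbar_config <- function(x, ...) {
  graphics::plot(NA, xlim = c(0, x$box), ylim = c(0, x$box), asp = 1,
                 xlab = "x (nm)", ylab = "y (nm)", ...)
  caps <- x$shape$capsules
  for (i in seq_len(nrow(x$poses))) {
    p <- x$poses[i, ]
    ct <- cos(p[3]); st <- sin(p[3])
    for (q in seq_len(nrow(caps))) {
      e <- caps[q, ]
      p1 <- c(p[1] + ct * e[1] - st * e[2], p[2] + st * e[1] + ct * e[2])
      p2 <- c(p[1] + ct * e[3] - st * e[4], p[2] + st * e[3] + ct * e[4])
      graphics::segments(p1[1], p1[2], p2[1], p2[2], lwd = e[5] * 6,
                         lend = 1, col = if (q > nrow(caps) - 2) "steelblue" else "grey40")
    }
  }
  invisible(x)
}

#' Random overlap-free configuration of N-BAR proteins
#'
#' Rejection-samples uniformly random poses until no two steric outlines
#' overlap (minimum-image convention).  Deterministic given the seed.
#'
#' @param n Number of proteins.
#' @param box Periodic box side (nm).
#' @param shape An [nbar_shape()].
#' @param seed Integer RNG seed.
#' @param max_tries Placement attempts per protein before giving up.
#'
#' @return An [nbar_config()].
#' @export
random_nbar_config <- function(n, box = 60, shape = nbar_shape(), seed = 1L,
                               max_tries = 500L) {
  stopifnot(n >= 1L, box > 0)
  set.seed(seed)
  dummy <- .empty_table(shape$h0)
  poses <- matrix(NA_real_, 0L, 3L)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (k in seq_len(max_tries)) {
      cand <- c(stats::runif(2, 0, box), stats::runif(1, -pi, pi))
      trial <- rbind(poses, cand)
      if (!mc_any_overlap(trial, box, shape, dummy,
                          list(on = FALSE, eps = 0, rm = 1))) {
        poses <- trial; placed <- TRUE; break
      }
    }
    if (!placed)
      stop(sprintf("could not place protein %d without overlap after %d tries: density too high",
                   i, max_tries), call. = FALSE)
  }
  nbar_config(poses, box, shape, seed = seed)
}

# minimal zero table (sterics only); used where only overlap tests are needed
.empty_table <- function(wedge) {
  list(dx = c(0, 1), dy = c(0, 1), dtheta = c(0, pi / 2),
       E = array(0, c(2, 2, 2)),
       wedge = list(L = wedge$L, r0 = wedge$r0))
}

# convert a pair_potential_table (or a ready list) for the C++ kernels
.table_payload <- function(h0_table) {
  if (inherits(h0_table, "pair_potential_table"))
    list(dx = h0_table$dx, dy = h0_table$dy, dtheta = h0_table$dtheta,
         E = h0_table$E,
         wedge = list(L = h0_table$wedge$L, r0 = h0_table$wedge$r0))
  else h0_table
}

#' Modified Lennard-Jones pair potential between BAR domains
#'
#' Evaluates the anisotropic BAR-BAR pair potential
#' `eps * ((r_m/r)^12 - 2 (r_m/r)^6 (1 - |2 theta1 - pi|/(2 pi) -
#' |2 theta2 - pi|/(2 pi)))`, where `r` is the center-to-center distance and
#' `theta1`, `theta2` are the BAR orientations relative to the line joining
#' the centers, taken modulo `pi`.  Two BAR domains facing each other
#' side-by-side (`theta1 = theta2 = pi/2`) at `r = r_m` sit at the minimum
#' `-eps`.
#'
#' @param r Center-to-center distance (nm), positive.
#' @param theta1,theta2 Orientation angles (radians); reduced modulo `pi`.
#' @param eps Well depth (k_BT).
#' @param r_m Minimum-energy distance (nm).
#'
#' @return Energy (k_BT), vectorised over the inputs.
#' @examples
#' bar_pair_potential(10, pi / 2, pi / 2)   # -10 k_BT at the minimum
#' @export
bar_pair_potential <- function(r, theta1, theta2, eps = 10, r_m = 10) {
  if (any(r <= 0)) stop("'r' must be positive (diverges at r = 0)", call. = FALSE)
  t1 <- theta1 %% pi; t2 <- theta2 %% pi
  q6 <- (r_m / r)^6
  ang <- 1 - abs(2 * t1 - pi) / (2 * pi) - abs(2 * t2 - pi) / (2 * pi)
  eps * (q6^2 - 2 * q6 * ang)
}

#' Total interaction energy of a configuration
#'
#' Sums the tabulated H0-H0 wedge interaction over all inter-protein H0
#' pairs (four per protein pair; intra-protein pairs are rigid and excluded)
#' and, optionally, the BAR pair potential over protein centers, using
#' minimum-image distances.  Returns `Inf` when any two steric outlines
#' overlap.
#'
#' @param config An [nbar_config()].
#' @param h0_table A [pair_potential_table()] for the H0 wedges.
#' @param bar_on Include the BAR pair potential?
#' @param bar_eps,bar_rm BAR potential parameters (k_BT, nm).
#'
#' @return Total energy (k_BT).
#' @export
total_energy <- function(config, h0_table, bar_on = FALSE,
                         bar_eps = 10, bar_rm = 10) {
  stopifnot(inherits(config, "nbar_config"))
  mc_total_energy(config$poses, config$box, config$shape,
                  .table_payload(h0_table),
                  list(on = isTRUE(bar_on), eps = bar_eps, rm = bar_rm))
}

#' Annealing schedule for the Monte Carlo module
#'
#' One Monte Carlo step performs, for every protein in a freshly shuffled
#' order, one displacement trial and one rotation trial, accepted by the
#' Metropolis rule with energies in units of k_B T_rm.  A run holds the
#' temperature at `T_hot` for `n_hot` steps, then cools linearly to zero
#' over `n_cool` steps.  The full-scale protocol is `1e7` hot plus `5e6`
#' cooling steps; scaled-down runs pass smaller values explicitly.
#'
#' @param n_hot Steps at constant temperature `T_hot`.
#' @param n_cool Steps of linear cooling to zero temperature.
#' @param T_hot Hot-phase temperature (units of T_rm).
#' @param delta_r Maximum displacement per trial (nm).
#' @param delta_theta Maximum rotation per trial (radians).
#' @param record_every Record the energy trace every this many steps.
#'
#' @return An object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(n_hot = 1e7, n_cool = 5e6, T_hot = 2,
                            delta_r = 0.1, delta_theta = pi / 180,
                            record_every = max(1, floor((n_hot + n_cool) / 200))) {
  stopifnot(n_hot >= 0, n_cool >= 0, n_hot + n_cool >= 1, T_hot >= 0,
            delta_r > 0, delta_theta > 0)
  structure(list(n_hot = n_hot, n_cool = n_cool, T_hot = T_hot,
                 delta_r = delta_r, delta_theta = delta_theta,
                 record_every = record_every),
            class = "anneal_schedule")
}

#' Metropolis sweeps at fixed temperature
#'
#' @param config An [nbar_config()].
#' @param h0_table A [pair_potential_table()].
#' @param T Temperature in units of T_rm (`T = 0` accepts only downhill
#'   moves).
#' @param n_steps Number of Monte Carlo steps (one displacement and one
#'   rotation trial per protein per step).
#' @param schedule An [anneal_schedule()] supplying trial sizes.
#' @inheritParams total_energy
#'
#' @return A list with the updated `config` and a data frame `trace`
#'   (`step`, `T`, `energy`).
#' @export
metropolis_sweep <- function(config, h0_table, T, n_steps,
                             schedule = anneal_schedule(),
                             bar_on = FALSE, bar_eps = 10, bar_rm = 10) {
  stopifnot(inherits(config, "nbar_config"), T >= 0, n_steps >= 1)
  res <- mc_sweep(config$poses, config$box, config$shape,
                  .table_payload(h0_table),
                  list(on = isTRUE(bar_on), eps = bar_eps, rm = bar_rm),
                  T, n_steps, schedule$delta_r, schedule$delta_theta,
                  schedule$record_every)
  out <- config
  out$poses <- res$poses
  colnames(out$poses) <- c("x", "y", "theta")
  list(config = out, trace = res$trace, energy = res$energy)
}

#' Simulated annealing of an N-BAR configuration
#'
#' Runs the hot phase followed by linear cooling to zero temperature and
#' returns the final (low-energy) configuration together with the sampled
#' energy trace.
#'
#' @param config0 Initial [nbar_config()] (e.g. from
#'   [random_nbar_config()]).
#' @inheritParams metropolis_sweep
#'
#' @return A list with `config` (final), `energy` (final total energy,
#'   k_BT) and `trace` (data frame `step`, `T`, `energy`).
#' @examples
#' \donttest{
#' # small sterics-only run: remains overlap-free at zero energy
#' cfg <- random_nbar_config(4, box = 60, seed = 2)
#' tab <- wedgelat:::.empty_table(cfg$shape$h0)
#' out <- anneal(cfg, tab, schedule = anneal_schedule(n_hot = 50, n_cool = 50))
#' out$energy
#' }
#' @export
anneal <- function(config0, h0_table, bar_on = FALSE,
                   schedule = anneal_schedule(), bar_eps = 10, bar_rm = 10) {
  stopifnot(inherits(config0, "nbar_config"),
            inherits(schedule, "anneal_schedule"))
  res <- mc_run(config0$poses, config0$box, config0$shape,
                .table_payload(h0_table),
                list(on = isTRUE(bar_on), eps = bar_eps, rm = bar_rm),
                schedule$n_hot, schedule$n_cool, schedule$T_hot,
                schedule$delta_r, schedule$delta_theta,
                schedule$record_every)
  out <- config0
  out$poses <- res$poses
  colnames(out$poses) <- c("x", "y", "theta")
  list(config = out, energy = res$energy, trace = res$trace)
}

# world-frame H0 footprint frames of every protein:
# one row per (protein, helix): x, y, phi, outer normal nx, ny
.h0_world <- function(config) {
  poses <- config$poses; sh <- config$shape
  out <- matrix(NA_real_, 2L * nrow(poses), 6L)
  colnames(out) <- c("protein", "x", "y", "phi", "nx", "ny")
  for (i in seq_len(nrow(poses))) {
    ct <- cos(poses[i, 3]); st <- sin(poses[i, 3])
    for (a in 1:2) {
      f <- sh$h0_frames[a, ]
      nrm <- sh$h0_outer[a, ]
      out[2L * (i - 1L) + a, ] <- c(
        i,
        poses[i, 1] + ct * f[1] - st * f[2],
        poses[i, 2] + st * f[1] + ct * f[2],
        poses[i, 3] + f[3],
        ct * nrm[1] - st * nrm[2],
        st * nrm[1] + ct * nrm[2])
    }
  }
  out
}

#' Dimer and chain statistics of an N-BAR configuration
#'
#' Identifies H0 dimers as inter-protein H0 pairs whose footprint centers
#' lie within a distance gate and whose axes are aligned (parallel or
#' antiparallel) within an angle gate, partitions the proteins into chains
#' (connected components of the dimer relation), and reports the
#' distribution of alignment angles and the dimer architecture (which side
#' of each helix faces its partner).
#'
#' @param config An [nbar_config()].
#' @param gate_dist Maximum H0 center separation of a dimer (nm).
#' @param gate_angle Maximum deviation of the axis alignment from parallel
#'   or antiparallel (radians).
#'
#' @return An object of class `chain_stats`: a list with `n_dimers`,
#'   `dimers` (data frame of paired helix indices, separations, alignment
#'   angles in `[0, pi]` and logical `outer_outer` architecture), `chains`
#'   (integer membership vector over proteins), `chain_lengths` and
#'   `chain_length_table`.
#' @export
chain_statistics <- function(config, gate_dist = 2.5, gate_angle = pi / 6) {
  stopifnot(inherits(config, "nbar_config"), gate_dist > 0, gate_angle > 0)
  h0 <- .h0_world(config)
  n <- nrow(config$poses); box <- config$box
  m <- nrow(h0)
  pairs <- list()
  for (p in seq_len(m - 1L)) for (q in (p + 1L):m) {
    if (h0[p, 1] == h0[q, 1]) next     # intra-protein
    dx <- h0[q, 2] - h0[p, 2]; dy <- h0[q, 3] - h0[p, 3]
    dx <- dx - box * round(dx / box); dy <- dy - box * round(dy / box)
    sep <- sqrt(dx^2 + dy^2)
    if (sep > gate_dist) next
    ali <- acos(pmin(pmax(cos(h0[p, 4] - h0[q, 4]), -1), 1))   # [0, pi]
    if (min(ali, pi - ali) > gate_angle) next
    oo <- (dx * h0[p, 5] + dy * h0[p, 6]) > 0 &&
          (-dx * h0[q, 5] - dy * h0[q, 6]) > 0
    pairs[[length(pairs) + 1L]] <-
      data.frame(helix_a = p, helix_b = q,
                 protein_a = as.integer(h0[p, 1]), protein_b = as.integer(h0[q, 1]),
                 separation = sep, alignment = ali, outer_outer = oo)
  }
  dimers <- if (length(pairs)) do.call(rbind, pairs)
            else data.frame(helix_a = integer(), helix_b = integer(),
                            protein_a = integer(), protein_b = integer(),
                            separation = numeric(), alignment = numeric(),
                            outer_outer = logical())
  # connected components over proteins (union-find)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(dimers))) {
    ra <- find(dimers$protein_a[k]); rb <- find(dimers$protein_b[k])
    if (ra != rb) parent[ra] <- rb
  }
  comp <- vapply(seq_len(n), find, integer(1))
  comp <- match(comp, unique(comp))
  lens <- as.integer(table(comp))
  structure(list(n_dimers = nrow(dimers), dimers = dimers, chains = comp,
                 chain_lengths = lens,
                 chain_length_table = table(factor(lens, levels = seq_len(n)))),
            class = "chain_stats")
}

#' @exportS3Method base::print
print.chain_stats <- function(x, ...) {
  cat(sprintf("Chain statistics: %d H0 dimer(s), %d chain(s), longest chain %d\n",
              x$n_dimers, length(x$chain_lengths), max(x$chain_lengths)))
  if (x$n_dimers > 0)
    cat(sprintf("  median alignment angle: %.1f deg (antiparallel = 180)\n",
                stats::median(x$dimers$alignment) * 180 / pi))
  invisible(x)
}
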