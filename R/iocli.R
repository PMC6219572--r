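# Configuration schema, scenario dispatch, result serialization and fixture
# generation.  Configs are YAML or JSON with one block per parameter group;
# unknown keys are rejected so typos never silently fall back to defaults.
# Every output directory receives the numeric results as CSV plus a JSON
# sidecar with the fully resolved configuration and seed.

.schema <- list(
  scenario = c("potential-curve", "critical-depth", "field-2d", "pair-table",
               "anneal", "phase-diagram"),
  blocks = list(
    bilayer = c("K_b", "K_t", "a", "tau"),
    wedge = c("U", "L", "r0", "slope_h", "slope_u"),
    wedge_b = c("U", "L", "r0", "slope_h", "slope_u"),
    curve = c("d_min", "d_max", "d_step"),
    ucrit = c("U_lo", "U_hi", "tol"),
    field2d = c("h", "margin"),
    pairtable = c("dx", "dy", "n_theta", "h", "margin"),
    anneal = c("n", "box", "n_hot", "n_cool", "T_hot", "delta_r",
               "delta_theta", "bar_on", "bar_eps", "bar_rm"),
    phase = c("c_min", "c_max", "n_c", "eps_min", "eps_max", "n_eps", "r_c")
  ))

.default_config <- function() {
  list(scenario = "potential-curve",
       seed = 1L,
       bilayer = list(K_b = 20, K_t = 60, a = 2.0, tau = 0),
       wedge = list(U = -0.9, L = 3, r0 = 0.6,
                    slope_h = -tan(9 * pi / 180), slope_u = 0),
       wedge_b = NULL,
       curve = list(d_min = 1.25, d_max = 10, d_step = 0.05),
       ucrit = list(U_lo = -0.9, U_hi = -0.1, tol = 1e-3),
       field2d = list(h = 0.15, margin = 5),
       pairtable = list(dx = c(0, 1, 2, 3, 4, 5, 6, 8),
                        dy = c(0, 1.3, 1.6, 2, 2.4, 3, 4, 5, 6.5, 8),
                        n_theta = 4L, h = 0.15, margin = 5),
       anneal = list(n = 16L, box = 60, n_hot = 1e5, n_cool = 5e4, T_hot = 2,
                     delta_r = 0.1, delta_theta = pi / 180,
                     bar_on = FALSE, bar_eps = 10, bar_rm = 10),
       phase = list(c_min = 1e-6, c_max = 2.5e-3, n_c = 25L,
                    eps_min = 0, eps_max = 4, n_eps = 17L, r_c = 40),
       format_version = "1")
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration file (chosen by extension), validates
#' it against the scenario schema -- unknown keys are rejected with the
#' offending field named -- and fills every missing value with the package
#' default (the standard bilayer and wedge parameter set).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#'
#' @return A fully resolved configuration (class `run_config`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  as_run_config(raw)
}

#' @rdname load_config
#' @param x A named list with (a subset of) the configuration fields.
#' @export
as_run_config <- function(x) {
  stopifnot(is.list(x))
  cfg <- .default_config()
  top_known <- c("scenario", "seed", names(.schema$blocks), "format_version")
  unknown <- setdiff(names(x), top_known)
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in intersect(names(x), c("scenario", "seed", "format_version")))
    cfg[[nm]] <- x[[nm]]
  if (!cfg$scenario %in% .schema$scenario)
    stop("unknown scenario '", cfg$scenario, "'; must be one of: ",
         paste(.schema$scenario, collapse = ", "), call. = FALSE)
  for (blk in names(.schema$blocks)) {
    if (is.null(x[[blk]])) next
    unknown <- setdiff(names(x[[blk]]), .schema$blocks[[blk]])
    if (length(unknown))
      stop(sprintf("unknown field(s) in block '%s': %s", blk,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    if (blk == "wedge_b" && is.null(cfg$wedge_b)) cfg$wedge_b <- cfg$wedge
    for (nm in names(x[[blk]])) cfg[[blk]][[nm]] <- x[[blk]][[nm]]
  }
  # validation with named errors via the constructors
  bp <- do.call(bilayer_params, cfg$bilayer)
  do.call(wedge_params, cfg$wedge)
  if (!is.null(cfg$wedge_b)) do.call(wedge_params, cfg$wedge_b)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' @exportS3Method base::print
print.run_config <- function(x, ...) {
  cat(sprintf("Run configuration: scenario '%s', seed %d\n", x$scenario, x$seed))
  invisible(x)
}

#' Save a configuration
#'
#' @param config A `run_config`.
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$wedge_b <- x$wedge_b   # keep NULL as absent
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  else yaml::write_yaml(x, path, precision = 12L)
  invisible(path)
}

.write_sidecar <- function(dir, config, extra = list()) {
  meta <- c(list(config = unclass(config),
                 package = "wedgelat",
                 version = as.character(utils::packageVersion("wedgelat")),
                 seed = config$seed),
            extra)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
}

#' Run a configured scenario and write its results
#'
#' Dispatches a validated configuration to the owning module and writes the
#' numeric results (CSV with unit-suffixed headers, JSON-lines trajectory
#' for annealing runs) plus a `metadata.json` sidecar carrying the resolved
#' configuration and seed.  Identical configuration and seed give
#' byte-identical numeric outputs.
#'
#' @param config A `run_config` from [load_config()] or [as_run_config()].
#' @param out_dir Output directory (created if missing).
#' @param seed Optional override of the configured seed.
#'
#' @return Character vector of the files written, invisibly.
#' @export
run_scenario <- function(config, out_dir, seed = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  bp <- do.call(bilayer_params, config$bilayer)
  wa <- do.call(wedge_params, config$wedge)
  wb <- if (is.null(config$wedge_b)) wa else do.call(wedge_params, config$wedge_b)
  files <- character()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  extra <- list()
  switch(config$scenario,
    "potential-curve" = {
      cv <- config$curve
      ic <- interaction_curve(bp, wa, wb,
                              d_grid = seq(cv$d_min, cv$d_max, by = cv$d_step))
      wr(data.frame(d_nm = ic$d, G_int_kBT = ic$g_int), "potential_curve.csv")
    },
    "critical-depth" = {
      uc <- critical_immersion_depth(bp, wa,
                                     U_bracket = c(config$ucrit$U_lo, config$ucrit$U_hi),
                                     tol = config$ucrit$tol)
      wr(data.frame(U_c_nm = uc), "critical_depth.csv")
      extra$U_c_nm <- uc
    },
    "field-2d" = {
      fp <- wedge_footprint(wa$U, wa$L, wa$r0)
      fld <- solve_thickness_field(bp, fp, h = config$field2d$h,
                                   margin = config$field2d$margin)
      grid <- expand.grid(x_nm = fld$x, y_nm = fld$y)
      wr(cbind(grid, u_nm = as.vector(fld$u)), "thickness_field.csv")
      extra$energy_kBT <- fld$energy
    },
    "pair-table" = {
      pt <- config$pairtable
      tab <- pair_potential_table(bp, wa, dx = pt$dx, dy = pt$dy,
                                  dtheta = seq(0, pi, length.out = pt$n_theta + 1L)[seq_len(pt$n_theta)],
                                  h = pt$h, margin = pt$margin)
      grid <- expand.grid(dx_nm = tab$dx, dy_nm = tab$dy, dtheta_rad = tab$dtheta)
      wr(cbind(grid, E_kBT = as.vector(tab$E)), "pair_table.csv")
    },
    "anneal" = {
      an <- config$anneal
      sh <- nbar_shape(h0 = wa)
      tabcfg <- config$pairtable
      tab <- pair_potential_table(bp, wa, dx = tabcfg$dx, dy = tabcfg$dy,
                                  dtheta = seq(0, pi, length.out = tabcfg$n_theta + 1L)[seq_len(tabcfg$n_theta)],
                                  h = tabcfg$h, margin = tabcfg$margin)
      cfg0 <- random_nbar_config(an$n, an$box, sh, seed = config$seed)
      sched <- anneal_schedule(n_hot = an$n_hot, n_cool = an$n_cool,
                               T_hot = an$T_hot, delta_r = an$delta_r,
                               delta_theta = an$delta_theta)
      out <- anneal(cfg0, tab, bar_on = an$bar_on, schedule = sched,
                    bar_eps = an$bar_eps, bar_rm = an$bar_rm)
      wr(data.frame(id = seq_len(an$n),
                    x_nm = out$config$poses[, 1],
                    y_nm = out$config$poses[, 2],
                    theta_rad = out$config$poses[, 3]), "final_state.csv")
      traj <- file.path(out_dir, "trajectory.jsonl")
      con <- file(traj, "w")
      for (i in seq_len(nrow(out$trace)))
        writeLines(jsonlite::toJSON(as.list(out$trace[i, ]), auto_unbox = TRUE,
                                    digits = NA), con)
      close(con)
      files <- c(files, traj)
      extra$final_energy_kBT <- out$energy
    },
    "phase-diagram" = {
      ph <- config$phase
      cm <- conformational_model(epsilon_d = 0, bilayer = bp,
                                 wedge_shallow = wedge_params(U = 0, L = wa$L, r0 = wa$r0,
                                                              slope_h = wa$slope_h, slope_u = wa$slope_u),
                                 wedge_deep = wa, r_c = ph$r_c)
      pd <- phase_diagram(cm,
                          c_grid = 10^seq(log10(ph$c_min), log10(ph$c_max),
                                          length.out = ph$n_c),
                          eps_grid = seq(ph$eps_min, ph$eps_max,
                                         length.out = ph$n_eps))
      grid <- expand.grid(c_per_nm2 = pd$c_grid, epsilon_d_kBT = pd$eps_grid)
      wr(cbind(grid, P_d = as.vector(pd$P_d)), "phase_diagram.csv")
      wr(data.frame(epsilon_d_kBT = pd$contour$epsilon_d,
                    c_half_per_nm2 = pd$contour$c_half), "contour.csv")
    },
    stop("unhandled scenario", call. = FALSE))
  .write_sidecar(out_dir, config, extra)
  invisible(c(files, file.path(out_dir, "metadata.json")))
}

#' Deterministic fixtures for tests and examples
#'
#' @param kind One of `"random_config"` (overlap-free random N-BAR
#'   configuration), `"dimer_pair"` (two proteins hand-placed with one
#'   antiparallel H0 dimer), `"chain"` (a hand-built tip-to-tail chain of
#'   four proteins) or `"param_draws"` (random bilayer/wedge parameter sets
#'   for solver property tests).
#' @param seed Integer seed; identical seeds give identical fixtures.
#' @param ... Options per kind: `n`, `box`, `shape` for `"random_config"`;
#'   `n_draws` for `"param_draws"`.
#'
#' @return The fixture: an [nbar_config()] or a data frame of parameter
#'   draws.
#' @export
make_fixture <- function(kind, seed = 1L, ...) {
  opts <- list(...)
  switch(kind,
    "random_config" = {
      n <- opts$n %||% 16L
      box <- opts$box %||% 60
      shape <- opts$shape %||% nbar_shape()
      random_nbar_config(n, box, shape, seed = seed)
    },
    "dimer_pair" = {
      shape <- opts$shape %||% nbar_shape()
      sep <- opts$separation %||% 1.9
      # an antiparallel H0 dimer pairs the right H0 of one protein with the
      # right H0 of a pi-rotated partner (axis angles alpha and alpha + pi),
      # side by side along the outer normal (outer-outer architecture)
      f <- shape$h0_frames[1, 1:2]
      nrm <- shape$h0_outer[1, ]
      c1 <- c(30, 30)
      h1 <- c1 + f
      h2 <- h1 + sep * nrm
      c2 <- h2 + f                           # rot(f, pi) = -f
      nbar_config(rbind(c(c1, 0), c(c2, pi)), box = opts$box %||% 80,
                  shape = shape, seed = seed)
    },
    "chain" = {
      shape <- opts$shape %||% nbar_shape()
      n <- opts$n %||% 4L
      sep <- opts$separation %||% 1.9
      rot <- function(v, t) c(cos(t) * v[1] - sin(t) * v[2],
                              sin(t) * v[1] + cos(t) * v[2])
      poses <- matrix(NA_real_, n, 3L)
      c_cur <- c(20, 60); th <- 0
      poses[1, ] <- c(c_cur, th)
      for (i in seq_len(n - 1L)) {
        # alternate links: right-with-right, then left-with-left helices
        k <- if (abs(sin(th / 2)) < 0.5) 1L else 2L   # th = 0 -> right, pi -> left
        h_here <- c_cur + rot(shape$h0_frames[k, 1:2], th)
        nrm <- rot(shape$h0_outer[k, ], th)
        th_next <- (th + pi) %% (2 * pi)
        h_next <- h_here + sep * nrm
        c_next <- h_next - rot(shape$h0_frames[k, 1:2], th_next)
        poses[i + 1L, ] <- c(c_next, th_next)
        c_cur <- c_next; th <- th_next
      }
      nbar_config(poses, box = opts$box %||% 120, shape = shape, seed = seed)
    },
    "param_draws" = {
      set.seed(seed)
      n <- opts$n_draws %||% 100L
      data.frame(K_b = stats::runif(n, 10, 40),
                 K_t = stats::runif(n, 30, 90),
                 a = stats::runif(n, 1.5, 2.5),
                 tau = stats::rexp(n, rate = 20) * (stats::runif(n) < 0.5),
                 U = stats::runif(n, -1.2, 0.2),
                 d = stats::runif(n, 1.4, 12))
    },
    stop("unknown fixture kind: ", kind, call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
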