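# Finite-difference minimisation of the leaflet thickness deformation energy
# over a 2D membrane patch around stadium footprints, with the height field
# held flat (h+ = 0).  The solver works in the shifted thickness variable
# ubar = u+ + tau*a/K_t, for which the discrete energy is the pure quadratic
#   E = Delta^2 * sum_membrane 1/2 { (K_b/2)(lap ubar)^2 + (K_t/2)(ubar/a)^2
#                                    + (tau/2)|grad ubar|^2 },
# already measured relative to the tension-relaxed background.  Dirichlet
# data: ubar = immersion profile + tau*a/K_t over the footprints, ubar = 0 in
# a two-cell clamped band at the patch edge.  The minimiser solves one sparse
# SPD system (13-point bilaplacian stencil via lap' lap).

# 5-point Laplacian of an nx x ny grid with zero-Dirichlet padding
.grid_laplacian <- function(nx, ny, h) {
  n <- nx * ny
  idx <- matrix(seq_len(n), nx, ny)
  ii <- c(seq_len(n), rep(NA_integer_, 4L * n)); jj <- ii; vv <- numeric(5L * n)
  ii <- jj <- vv <- NULL
  centre <- seq_len(n)
  pieces_i <- list(centre); pieces_j <- list(centre)
  pieces_v <- list(rep(-4, n))
  shift <- function(di, dj) {
    i0 <- seq_len(nx); j0 <- seq_len(ny)
    ival <- i0 + di; jshift <- j0 + dj
    keep_i <- ival >= 1 & ival <= nx
    keep_j <- jshift >= 1 & jshift <= ny
    from <- as.vector(idx[i0[keep_i], j0[keep_j], drop = FALSE])
    to <- as.vector(idx[ival[keep_i], jshift[keep_j], drop = FALSE])
    list(from = from, to = to)
  }
  for (s in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    sh <- shift(s[1], s[2])
    pieces_i <- c(pieces_i, list(sh$from))
    pieces_j <- c(pieces_j, list(sh$to))
    pieces_v <- c(pieces_v, list(rep(1, length(sh$from))))
  }
  Matrix::sparseMatrix(i = unlist(pieces_i), j = unlist(pieces_j),
                       x = unlist(pieces_v) / h^2, dims = c(n, n))
}

# forward-difference operators (edges as rows)
.grid_gradient <- function(nx, ny, h) {
  n <- nx * ny
  idx <- matrix(seq_len(n), nx, ny)
  fx <- as.vector(idx[seq_len(nx - 1), ]); tx <- as.vector(idx[2:nx, ])
  fy <- as.vector(idx[, seq_len(ny - 1)]); ty <- as.vector(idx[, 2:ny])
  Gx <- Matrix::sparseMatrix(i = rep(seq_along(fx), 2), j = c(fx, tx),
                             x = c(rep(-1, length(fx)), rep(1, length(fx))) / h,
                             dims = c(length(fx), n))
  Gy <- Matrix::sparseMatrix(i = rep(seq_along(fy), 2), j = c(fy, ty),
                             x = c(rep(-1, length(fy)), rep(1, length(fy))) / h,
                             dims = c(length(fy), n))
  list(Gx = Gx, Gy = Gy, fx = fx, tx = tx, fy = fy, ty = ty)
}

#' Leaflet thickness field around wedge footprints
#'
#' Minimises the thickness deformation energy (height field pinned flat) on a
#' regular grid over a rectangular membrane patch containing one or more
#' stadium footprints.  The immersion profile of each footprint is imposed as
#' Dirichlet data over the cells it covers (a plateau, which also pins the
#' normal slope at the footprint edge to zero at the discretisation scale),
#' the patch edge is clamped to the relaxed state, and the unique minimiser
#' of the convex discrete energy is found by one sparse linear solve.
#'
#' @param bilayer A [bilayer_params()] object.
#' @param footprints A [wedge_footprint()] or list of them.
#' @param h Grid spacing (nm).  Must resolve the cap radius with at least 4
#'   cells.
#' @param margin Width of undisturbed membrane kept around the footprints'
#'   bounding box (nm).  Defaults to 10 decay lengths.
#' @param patch Optional explicit patch `list(xlim =, ylim =)` (nm),
#'   overriding the automatic bounding box.  Patch limits are snapped to the
#'   global grid lattice so identical footprints discretise identically
#'   regardless of patch placement.
#'
#' @return An object of class `thickness_field`: grid vectors `x`, `y`,
#'   matrix `u` of thickness deformations (nm, `u+` convention), logical
#'   `mask` of footprint-covered cells, the background-subtracted `energy`
#'   (k_BT) and the inputs.
#' @examples
#' \donttest{
#' fp <- wedge_footprint(U = -0.9)
#' fld <- solve_thickness_field(bilayer_params(), fp, h = 0.2, margin = 5)
#' fld$energy
#' }
#' @export
solve_thickness_field <- function(bilayer, footprints, h = 0.15,
                                  margin = 10 * decay_constants(bilayer)$lambda_s,
                                  patch = NULL) {
  stopifnot(inherits(bilayer, "bilayer_params"))
  if (inherits(footprints, "wedge_footprint")) footprints <- list(footprints)
  if (length(footprints) == 0L) stop("need at least zero-area patch: supply 'patch'")
  r0min <- min(vapply(footprints, function(f) f$r0, 0))
  if (h > r0min / 4 + 1e-12)
    stop(sprintf("grid spacing h = %g does not resolve r0 = %g (need >= 4 cells)",
                 h, r0min), call. = FALSE)
  if (is.null(patch)) {
    box <- sapply(footprints, function(f) {
      e <- f$L / 2
      c(f$center[1] - e, f$center[1] + e, f$center[2] - e, f$center[2] + e)
    })
    patch <- list(xlim = c(min(box[1, ]) - margin, max(box[2, ]) + margin),
                  ylim = c(min(box[3, ]) - margin, max(box[4, ]) + margin))
  }
  # snap to the global lattice so footprint discretisation is translation
  # independent up to whole cells
  x0 <- floor(patch$xlim[1] / h) * h
  y0 <- floor(patch$ylim[1] / h) * h
  x <- seq(x0, patch$xlim[2] + h / 2, by = h)
  y <- seq(y0, patch$ylim[2] + h / 2, by = h)
  nx <- length(x); ny <- length(y)
  n <- nx * ny
  xy <- cbind(rep(x, times = ny), rep(y, each = nx))

  off <- bilayer$tau * bilayer$a / bilayer$K_t
  fixed_val <- rep(NA_real_, n)
  mask <- rep(FALSE, n)
  for (fp in footprints) {
    im <- footprint_immersion(fp, xy)
    inside <- !is.na(im)
    if (any(inside & mask)) stop("footprints overlap", call. = FALSE)
    mask <- mask | inside
    fixed_val[inside] <- im[inside] + off   # ubar on the footprint
  }
  ix <- rep(seq_len(nx), times = ny); iy <- rep(seq_len(ny), each = nx)
  edge <- ix <= 2L | ix >= nx - 1L | iy <= 2L | iy >= ny - 1L
  if (any(mask & edge)) stop("footprints must lie inside the patch", call. = FALSE)
  fixed_val[edge & !mask] <- 0
  fixed <- !is.na(fixed_val)

  lap <- .grid_laplacian(nx, ny, h)
  memb <- !mask                      # energy lives on the membrane only
  # clamped contact: the curvature energy also counts the ring of footprint
  # cells whose stencil reaches the membrane, which penalises any jump of the
  # normal slope across the footprint edge (the plateau pins it to zero)
  mm <- matrix(memb, nx, ny)
  nbr_memb <- matrix(FALSE, nx, ny)
  nbr_memb[-nx, ] <- nbr_memb[-nx, ] | mm[-1, ]
  nbr_memb[-1, ] <- nbr_memb[-1, ] | mm[-nx, ]
  nbr_memb[, -ny] <- nbr_memb[, -ny] | mm[, -1]
  nbr_memb[, -1] <- nbr_memb[, -1] | mm[, -ny]
  curv <- memb | (mask & as.vector(nbr_memb))
  Dm <- Matrix::Diagonal(n, x = as.numeric(curv))
  Q <- (bilayer$K_b / 2) * Matrix::crossprod(lap, Dm %*% lap) +
    Matrix::Diagonal(n, x = as.numeric(memb) * bilayer$K_t / (2 * bilayer$a^2))
  if (bilayer$tau > 0) {
    gr <- .grid_gradient(nx, ny, h)
    wx <- as.numeric(memb[gr$fx] & memb[gr$tx])
    wy <- as.numeric(memb[gr$fy] & memb[gr$ty])
    Q <- Q + (bilayer$tau / 2) *
      (Matrix::crossprod(gr$Gx, Matrix::Diagonal(length(wx), wx) %*% gr$Gx) +
       Matrix::crossprod(gr$Gy, Matrix::Diagonal(length(wy), wy) %*% gr$Gy))
  }
  Q <- h^2 * Q

  v <- numeric(n)
  v[fixed] <- fixed_val[fixed]
  free <- !fixed
  if (any(free)) {
    rhs <- -(Q[free, fixed, drop = FALSE] %*% v[fixed])
    sol <- tryCatch(
      Matrix::solve(Q[free, free], rhs),
      error = function(e) stop("thickness solver failed: ", conditionMessage(e),
                               call. = FALSE))
    v[free] <- as.numeric(sol)
  }
  energy <- as.numeric(0.5 * sum(v * as.numeric(Q %*% v)))
  structure(list(x = x, y = y, u = matrix(v - off, nx, ny),
                 mask = matrix(mask, nx, ny), energy = energy,
                 h = h, bilayer = bilayer, footprints = footprints),
            class = "thickness_field")
}

#' @exportS3Method base::print
print.thickness_field <- function(x, ...) {
  cat(sprintf("Thickness field: %d x %d grid (h = %g nm), %d footprint(s)\n",
              length(x$x), length(x$y), x$h, length(x$footprints)))
  cat(sprintf("  energy = %.6g k_BT, min u+ = %.4g nm\n", x$energy, min(x$u)))
  invisible(x)
}

#' @exportS3Method
plot.thickness_field <- function(x, ...) {
  graphics::image(x$x, x$y, x$u, asp = 1, xlab = "x (nm)", ylab = "y (nm)",
                  col = grDevices::hcl.colors(64, "Blue-Red 3", rev = TRUE), ...)
  for (fp in x$footprints) graphics::lines(footprint_outline(fp))
  invisible(x)
}

# interaction energy of a set of footprints: joint field energy minus the
# isolated field energy of each footprint solved in the *same* patch, so
# both the footprint discretisation error and the patch-edge truncation
# error cancel exactly
.field_interaction <- function(bilayer, footprints, h, margin) {
  joint <- solve_thickness_field(bilayer, footprints, h = h, margin = margin)
  patch <- list(xlim = range(joint$x), ylim = range(joint$y))
  singles <- vapply(footprints, function(fp)
    solve_thickness_field(bilayer, list(fp), h = h, patch = patch)$energy,
    numeric(1))
  list(interaction = joint$energy - sum(singles),
       joint = joint$energy, singles = singles)
}

#' Transect of a thickness field across a wedge axis
#'
#' Extracts the field along a grid column `x = x0` (perpendicular to an
#' axis-aligned footprint) together with the one-dimensional energy density
#' integrated across the transect.  At the mid-length of a long footprint
#' this is directly comparable to the analytic h+-pinned 1D solution from
#' [pinned_thickness_profile()].
#'
#' @param field A `thickness_field`.
#' @param x0 Transect position (nm); the nearest grid column is used.
#'
#' @return A list with `y`, `u` (field values along the transect), `mask`
#'   (footprint cells) and `energy_per_length` (k_BT/nm, both sides,
#'   curvature counted on membrane cells plus the clamped contact ring).
#' @export
field_transect <- function(field, x0 = 0) {
  stopifnot(inherits(field, "thickness_field"))
  ix <- which.min(abs(field$x - x0))
  u <- field$u[ix, ]; msk <- field$mask[ix, ]
  hh <- field$h; ny <- length(u)
  K_b <- field$bilayer$K_b; K_t <- field$bilayer$K_t; a <- field$bilayer$a
  d2 <- c(NA, diff(diff(u)), NA) / hh^2
  memb <- !msk
  ring <- msk & (c(memb[-1], FALSE) | c(FALSE, memb[-ny]))
  # counting both terms on the contact ring approximates the half-cell strip
  # of membrane hidden by the staircase boundary
  dens <- 0.5 * (K_b / 2 * d2^2 + K_t / (2 * a^2) * u^2)
  sel <- (memb | ring) & is.finite(dens)
  list(y = field$y, u = u, mask = msk,
       energy_per_length = hh * sum(dens[sel]))
}

#' Directional pair-potential table for two wedge footprints
#'
#' Tabulates the bilayer-thickness-mediated interaction energy of two
#' identical wedges over a grid of relative poses: the second wedge's center
#' offset `(dx, dy)` in the first wedge's frame and relative orientation
#' `dtheta`.  Each entry is the joint two-footprint field energy minus the
#' two isolated references; overlapping poses are flagged infinite (hardcore)
#' and poses whose outline gap exceeds `far_cut` are set to zero without a
#' solve.  The stadium's two mirror symmetries are exploited: the table
#' stores `dx >= 0`, `dy >= 0` and queries map onto it.
#'
#' @param bilayer A [bilayer_params()] object.
#' @param wedge A [wedge_params()] object (geometry and immersion depth).
#' @param dx,dy Non-negative offset grids (nm), strictly increasing from 0.
#' @param dtheta Relative orientation grid (radians), covering `[0, pi)`
#'   uniformly (the stadium is 2-fold symmetric).
#' @param h,margin Discretisation of the underlying field solves; see
#'   [solve_thickness_field()].
#' @param far_cut Outline gap (nm) beyond which the interaction is recorded
#'   as exactly zero.
#'
#' @return An object of class `pair_potential_table` with the grids, the
#'   energy array `E[dx, dy, dtheta]` (`Inf` on hardcore poses) and the
#'   generating parameters.  Query it with [pair_potential()].
#' @seealso [pair_potential()], [anneal()]
#' @export
pair_potential_table <- function(bilayer, wedge,
                                 dx = c(0, 1, 2, 3, 4, 5, 6, 8, 11),
                                 dy = c(0, 1.3, 1.6, 2, 2.4, 3, 4, 5, 6.5, 10),
                                 dtheta = seq(0, pi, length.out = 5L)[1:4],
                                 h = 0.15, margin = 4, far_cut = 7) {
  stopifnot(inherits(bilayer, "bilayer_params"), inherits(wedge, "wedge_params"))
  if (any(dx < 0) || any(dy < 0) || is.unsorted(dx, strictly = TRUE) ||
      is.unsorted(dy, strictly = TRUE))
    stop("'dx' and 'dy' must be strictly increasing and non-negative",
         call. = FALSE)
  fp0 <- wedge_footprint(wedge$U, wedge$L, wedge$r0)
  E <- array(NA_real_, dim = c(length(dx), length(dy), length(dtheta)))
  for (k in seq_along(dtheta)) for (j in seq_along(dy)) for (i in seq_along(dx)) {
    fp1 <- fp0
    fp2 <- wedge_footprint(wedge$U, wedge$L, wedge$r0,
                           center = c(dx[i], dy[j]), theta = dtheta[k])
    gap <- .segment_distance(.footprint_segment(fp1)[1, ], .footprint_segment(fp1)[2, ],
                             .footprint_segment(fp2)[1, ], .footprint_segment(fp2)[2, ]) -
      2 * wedge$r0
    # gaps below one grid cell are not resolvable: hardcore
    if (footprints_overlap(fp1, fp2) || gap < h) { E[i, j, k] <- Inf; next }
    if (gap > far_cut) { E[i, j, k] <- 0; next }
    E[i, j, k] <- .field_interaction(bilayer, list(fp1, fp2), h, margin)$interaction
  }
  structure(list(dx = dx, dy = dy, dtheta = dtheta, E = E,
                 bilayer = bilayer, wedge = wedge, h = h, margin = margin,
                 far_cut = far_cut),
            class = "pair_potential_table")
}

#' @exportS3Method base::print
print.pair_potential_table <- function(x, ...) {
  fin <- x$E[is.finite(x$E)]
  cat(sprintf("H0 pair-potential table: %d x %d x %d poses (U = %g nm)\n",
              length(x$dx), length(x$dy), length(x$dtheta), x$wedge$U))
  cat(sprintf("  energy range [%.3g, %.3g] k_BT, %d hardcore poses\n",
              min(fin), max(fin), sum(is.infinite(x$E))))
  invisible(x)
}

#' Interpolated wedge pair potential
#'
#' Looks up the tabulated interaction energy at an arbitrary relative pose,
#' applying the stadium mirror symmetries
#' `E(dx, dy, dth) = E(-dx, dy, -dth) = E(dx, -dy, -dth)` and orientation
#' periodicity `pi`, multilinear interpolation in `(|dx|, |dy|)`,
#' periodic-linear interpolation in `dtheta`, zero beyond the tabulated
#' range, and `Inf` for overlapping outlines.
#'
#' @param table A [pair_potential_table()].
#' @param dx,dy Offset of the second wedge center in the first wedge's frame
#'   (nm); vectors of equal length.
#' @param dtheta Relative orientation (radians).
#'
#' @return Numeric vector of energies (k_BT).
#' @export
pair_potential <- function(table, dx, dy, dtheta) {
  stopifnot(inherits(table, "pair_potential_table"))
  n <- max(length(dx), length(dy), length(dtheta))
  dx <- rep_len(dx, n); dy <- rep_len(dy, n); dtheta <- rep_len(dtheta, n)
  vapply(seq_len(n), function(i)
    .pair_potential_one(table, dx[i], dy[i], dtheta[i]), numeric(1))
}

.pair_potential_one <- function(tab, dx, dy, dth) {
  # hardcore from exact geometry, never interpolated
  fp1 <- wedge_footprint(tab$wedge$U, tab$wedge$L, tab$wedge$r0)
  fp2 <- wedge_footprint(tab$wedge$U, tab$wedge$L, tab$wedge$r0,
                         center = c(dx, dy), theta = dth)
  if (footprints_overlap(fp1, fp2)) return(Inf)
  # mirror symmetries onto the stored quadrant
  if (dx < 0) { dx <- -dx; dth <- -dth }
  if (dy < 0) { dy <- -dy; dth <- -dth }
  dth <- dth %% pi
  if (dx > max(tab$dx) || dy > max(tab$dy)) return(0)
  li <- function(grid, v) {
    j <- findInterval(v, grid, all.inside = TRUE)
    w <- (v - grid[j]) / (grid[j + 1] - grid[j])
    list(j = j, w = min(max(w, 0), 1))
  }
  ax <- li(tab$dx, dx); ay <- li(tab$dy, dy)
  nth <- length(tab$dtheta)
  step <- pi / nth
  k0 <- floor(dth / step) %% nth
  wt <- dth / step - floor(dth / step)
  k1 <- (k0 + 1) %% nth
  val_th <- function(k) {
    e <- tab$E[ax$j + (0:1), ay$j + (0:1), k + 1L]
    # a hardcore corner dominates only if the query sits on top of it
    if (any(is.infinite(e))) e[is.infinite(e)] <- max(e[is.finite(e)], 0)
    (1 - ax$w) * ((1 - ay$w) * e[1, 1] + ay$w * e[1, 2]) +
      ax$w * ((1 - ay$w) * e[2, 1] + ay$w * e[2, 2])
  }
  (1 - wt) * val_th(k0) + wt * val_th(k1)
}

#' Pairwise additivity of wedge interactions
#'
#' Computes the interaction energy of three footprints (triple field energy
#' minus the three isolated references) and the sum of the three pair
#' interaction energies, to quantify how close the thickness-mediated
#' interactions are to pairwise additive.
#'
#' @param bilayer A [bilayer_params()] object.
#' @param footprints A list of three pairwise non-overlapping
#'   [wedge_footprint()]s.
#' @inheritParams solve_thickness_field
#'
#' @return A list with `triple_energy`, `pairwise_sum` and the individual
#'   `pair_energies` (k_BT).
#' @export
additivity_check <- function(bilayer, footprints, h = 0.15, margin = 4) {
  stopifnot(length(footprints) == 3L)
  for (i in 1:2) for (j in (i + 1):3)
    if (footprints_overlap(footprints[[i]], footprints[[j]]))
      stop("footprints overlap", call. = FALSE)
  triple <- .field_interaction(bilayer, footprints, h, margin)
  pairs <- combn(3L, 2L)
  pe <- apply(pairs, 2L, function(ij)
    .field_interaction(bilayer, footprints[ij], h, margin)$interaction)
  list(triple_energy = triple$interaction, pairwise_sum = sum(pe),
       pair_energies = pe)
}
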