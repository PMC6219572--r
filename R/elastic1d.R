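# Analytic solution of the 1D Euler-Lagrange problem for leaflet height and
# thickness deformations around one or two parallel wedges, and the
# bilayer-mediated interaction potential derived from it.
#
# Fields: u+ (leaflet thickness deformation) and h+ (leaflet height), with the
# lower leaflet undeformed.  The thickness field is solved in the shifted
# variable ubar = u+ + tau*a/K_t, whose general solution is a sum of four
# complex exponentials exp(+-sqrt(nu_pm) r); the height field is
# h+ = ubar/2 + (solution of K_b w'''' = tau w'').  For the latter we use the
# limit-stable basis {1, r, C(r), S(r)} with
#   C(r) = lambda_t^2 (cosh(r/lambda_t) - 1)  ->  r^2/2   as tau -> 0,
#   S(r) = lambda_t^3 (sinh(r/lambda_t) - r/lambda_t)  ->  r^3/6,
# which is well conditioned for every tau >= 0 and reduces exactly to the
# cubic polynomial basis of the tensionless biharmonic equation.

# ---- basis machinery (internal) ------------------------------------------

# rows of the ubar exponential basis at position r; exponentials are anchored
# at the nearest end of the span [-s, s] so their modulus never exceeds 1
.ubar_basis <- function(dc, r, s, deriv) {
  k <- dc$k
  anchor <- ifelse(Re(k) >= 0, s, -s)
  k^deriv * exp(k * (r - anchor))
}

# rows of the extra h+ basis {1, r, C(r), S(r)}
.hext_basis <- function(dc, r, s, deriv) {
  lt <- dc$lambda_t
  if (is.infinite(lt)) {
    C <- c(r^2 / 2, r, 1, 0)[deriv + 1]
    S <- c(r^3 / 6, r^2 / 2, r, 1)[deriv + 1]
  } else {
    x <- r / lt
    C <- switch(deriv + 1,
                lt^2 * (cosh(x) - 1), lt * sinh(x), cosh(x), sinh(x) / lt)
    S <- switch(deriv + 1,
                lt^3 * (sinh(x) - x), lt^2 * (cosh(x) - 1), lt * sinh(x), cosh(x))
  }
  as.complex(c(if (deriv == 0) 1 else 0,
               if (deriv == 0) r else if (deriv == 1) 1 else 0,
               C, S))
}

# semi-infinite h+ extra basis {1, g(r)} with g = lambda_t (1 - exp(-r/lambda_t))
# -> r as tau -> 0; bounded at infinity for tau > 0, linear far tilt at tau = 0
.hsemi_basis <- function(dc, r, deriv) {
  lt <- dc$lambda_t
  g <- if (is.infinite(lt)) c(r, 1, 0, 0)[deriv + 1]
       else if (deriv == 0) lt * (1 - exp(-r / lt))
       else (-1)^(deriv + 1) * lt^(1 - deriv) * exp(-r / lt)
  as.complex(c(if (deriv == 0) 1 else 0, g))
}

# complex field values (ubar and h and derivatives 0..3) at positions r
.profile_fields <- function(profile, r, deriv) {
  dc <- profile$dc
  if (profile$region == "interior") {
    ub <- vapply(r, function(ri)
      sum(profile$coef[1:4] * .ubar_basis(dc, ri, profile$s, deriv)), complex(1))
    hx <- vapply(r, function(ri)
      sum(profile$coef[5:8] * .hext_basis(dc, ri, profile$s, deriv)), complex(1))
  } else {
    kdec <- profile$kdec
    ub <- vapply(r, function(ri)
      sum(profile$coef[1:2] * kdec^deriv * exp(kdec * ri)), complex(1))
    hx <- vapply(r, function(ri)
      sum(profile$coef[3:4] * .hsemi_basis(dc, ri, deriv)), complex(1))
  }
  list(ubar = ub, h = 0.5 * ub + hx)
}

# ---- profile solvers ------------------------------------------------------

#' Analytic deformation profile between two parallel wedges
#'
#' Solves the one-dimensional Euler-Lagrange boundary-value problem for the
#' lipid bilayer region separating two parallel wedges whose axes are a
#' distance `d` apart.  The boundary conditions are applied at the wedge
#' edges `r = -(d/2 - r0)` and `r = +(d/2 - r0)`: the thickness deformation
#' equals each wedge's immersion depth, and the contact slopes of `u+` and
#' `h+` are imposed along the outward normal of each wedge.  The reference
#' level of `h+` is fixed to zero at the left wedge edge; the relative height
#' of the two wedges is chosen to minimise the elastic energy (zero vertical
#' force on the wedges) unless `delta` is given explicitly.
#'
#' @param bilayer A [bilayer_params()] object.
#' @param wedge_a,wedge_b [wedge_params()] objects for the left and right
#'   wedge; their immersion depths may differ (asymmetric pair).
#' @param d Axis-to-axis wedge separation (nm).  Must exceed `2 * r0`
#'   (non-overlapping wedges).
#' @param delta Height of the right wedge edge relative to the left
#'   (`h+` difference, nm), or `NULL` (default) to minimise the energy over
#'   the height difference.
#'
#' @return An object of class `deformation_profile` (region `"interior"`,
#'   local coordinate `r` spanning `[-s, s]` with `s = d/2 - r0`).  Evaluate
#'   it with [profile_eval()] or [predict.deformation_profile()].
#' @seealso [solve_isolated_profile()], [profile_energy()]
#' @examples
#' bp <- bilayer_params()
#' w <- wedge_params(U = -0.9)
#' pr <- solve_pair_profile(bp, w, w, d = 3)
#' profile_eval(pr, 0)   # midspan deformation
#' @export
solve_pair_profile <- function(bilayer, wedge_a, wedge_b, d, delta = NULL) {
  stopifnot(inherits(bilayer, "bilayer_params"),
            inherits(wedge_a, "wedge_params"), inherits(wedge_b, "wedge_params"))
  if (wedge_a$r0 != wedge_b$r0)
    stop("wedges must share the same radius 'r0'", call. = FALSE)
  r0 <- wedge_a$r0
  if (!is.finite(d) || d <= 2 * r0)
    stop(sprintf("wedges overlap: need d > 2*r0 = %g nm (got d = %g)", 2 * r0, d),
         call. = FALSE)
  if (is.null(delta)) {
    en <- .pair_energy_coefs(bilayer, wedge_a, wedge_b, d)
    delta <- en$delta_opt
  }
  .solve_pair_at(bilayer, wedge_a, wedge_b, d, delta)
}

# raw interior solve at a fixed height difference delta
.solve_pair_at <- function(bilayer, wedge_a, wedge_b, d, delta) {
  r0 <- wedge_a$r0
  s <- (d - 2 * r0) / 2
  dc <- decay_constants(bilayer)
  off <- bilayer$tau * bilayer$a / bilayer$K_t
  M <- matrix(0i, 8, 8)
  rhs <- complex(8)
  row <- function(r, deriv, field) {
    v <- complex(8)
    ub <- .ubar_basis(dc, r, s, deriv)
    if (field == "u") v[1:4] <- ub
    else { v[1:4] <- 0.5 * ub; v[5:8] <- .hext_basis(dc, r, s, deriv) }
    v
  }
  M[1, ] <- row(-s, 0, "u"); rhs[1] <- wedge_a$U + off
  M[2, ] <- row(-s, 1, "u"); rhs[2] <- wedge_a$slope_u
  M[3, ] <- row(-s, 1, "h"); rhs[3] <- wedge_a$slope_h
  M[4, ] <- row(-s, 0, "h"); rhs[4] <- 0
  M[5, ] <- row(+s, 0, "u"); rhs[5] <- wedge_b$U + off
  M[6, ] <- row(+s, 1, "u"); rhs[6] <- -wedge_b$slope_u
  M[7, ] <- row(+s, 1, "h"); rhs[7] <- -wedge_b$slope_h
  M[8, ] <- row(+s, 0, "h"); rhs[8] <- delta
  coef <- tryCatch(solve(M, rhs), error = function(e)
    stop(sprintf("degenerate parameters: interior system singular at d = %g (%s)",
                 d, conditionMessage(e)), call. = FALSE))
  structure(list(region = "interior", coef = coef, dc = dc, s = s, d = d,
                 delta = delta, offset = off, bilayer = bilayer,
                 wedges = list(a = wedge_a, b = wedge_b)),
            class = "deformation_profile")
}

#' Analytic deformation profile outside an isolated wedge
#'
#' Solves the semi-infinite exterior problem on one side of a single wedge:
#' only decaying branches of the thickness field are kept, so `u+` relaxes to
#' the tension-set background far from the wedge.  At zero tension the height
#' field keeps a linear far tilt (free of elastic cost); at finite tension it
#' decays to a constant over the tension length.  Doubling the energy of this
#' profile gives the per-wedge reference used in the large-separation limit
#' of the interaction potential.
#'
#' @inheritParams solve_pair_profile
#' @param wedge A [wedge_params()] object.
#'
#' @return A `deformation_profile` (region `"exterior"`, local coordinate
#'   `r >= 0` measured outward from the wedge edge).
#' @examples
#' pr <- solve_isolated_profile(bilayer_params(), wedge_params(U = -0.9))
#' profile_eval(pr, c(0, 2, 8))$u
#' @export
solve_isolated_profile <- function(bilayer, wedge) {
  stopifnot(inherits(bilayer, "bilayer_params"), inherits(wedge, "wedge_params"))
  dc <- decay_constants(bilayer)
  off <- bilayer$tau * bilayer$a / bilayer$K_t
  kdec <- c(-sqrt(dc$nu_plus), -sqrt(dc$nu_minus))
  M <- matrix(0i, 3, 3)
  M[1, ] <- c(1, 1, 0)
  M[2, ] <- c(kdec, 0)
  M[3, ] <- c(0.5 * kdec, .hsemi_basis(dc, 0, 1)[2])
  rhs <- c(wedge$U + off, wedge$slope_u, wedge$slope_h)
  coef3 <- tryCatch(solve(M, rhs), error = function(e)
    stop("degenerate parameters: exterior system singular", call. = FALSE))
  structure(list(region = "exterior", coef = c(coef3[1:2], 0i, coef3[3]),
                 kdec = kdec, dc = dc, s = 0, offset = off,
                 bilayer = bilayer, wedges = list(a = wedge)),
            class = "deformation_profile")
}

#' Evaluate a solved deformation profile
#'
#' @param profile A `deformation_profile` from [solve_pair_profile()] or
#'   [solve_isolated_profile()].
#' @param r Positions (nm) in the profile's local coordinate (interior:
#'   `[-s, s]` between the wedge edges; exterior: `r >= 0` outward from the
#'   edge).
#' @param deriv Derivative order, 0 to 3.
#'
#' @return A list with numeric vectors `u` and `h`: the (derivatives of the)
#'   leaflet thickness deformation and height fields.  The complex basis
#'   coefficients occur in conjugate pairs, so the fields are real; the
#'   residual imaginary part is dropped.
#' @export
profile_eval <- function(profile, r, deriv = 0) {
  stopifnot(inherits(profile, "deformation_profile"),
            deriv %in% 0:3)
  f <- .profile_fields(profile, r, deriv)
  u <- Re(f$ubar)
  if (deriv == 0) u <- u - profile$offset
  list(u = u, h = Re(f$h))
}

#' @describeIn profile_eval `predict` method returning a data frame with
#'   columns `r`, `u`, `h`.
#' @param object A `deformation_profile`.
#' @param ... Unused.
#' @exportS3Method
predict.deformation_profile <- function(object, r, deriv = 0, ...) {
  f <- profile_eval(object, r, deriv)
  data.frame(r = r, u = f$u, h = f$h)
}

#' @exportS3Method base::print
print.deformation_profile <- function(x, ...) {
  if (x$region == "interior")
    cat(sprintf("Interior deformation profile: d = %g nm (span %g nm), delta = %.4g nm\n",
                x$d, 2 * x$s, x$delta))
  else
    cat("Semi-infinite exterior deformation profile (isolated wedge)\n")
  invisible(x)
}

# ---- energies -------------------------------------------------------------

# the total-derivative bracket of the on-shell energy density, evaluated at r
.phi_at <- function(profile, r) {
  d0 <- .profile_fields(profile, r, 0)
  d1 <- .profile_fields(profile, r, 1)
  d2 <- .profile_fields(profile, r, 2)
  d3 <- .profile_fields(profile, r, 3)
  h0 <- Re(d0$h); h1 <- Re(d1$h); h2 <- Re(d2$h); h3 <- Re(d3$h)
  u0 <- Re(d0$ubar); u1 <- Re(d1$ubar); u2 <- Re(d2$ubar); u3 <- Re(d3$ubar)
  K_b <- profile$bilayer$K_b; tau <- profile$bilayer$tau
  K_b / 2 * (h1 * h2 - h0 * h3 - 0.5 * h1 * u2 + 0.5 * h0 * u3 +
             0.5 * u1 * u2 - 0.5 * u0 * u3 + 0.5 * u0 * h3 - 0.5 * u1 * h2) +
    tau / 2 * (h0 * h1 - 0.5 * h0 * u1 + 0.5 * u0 * u1 - 0.5 * u0 * h1)
}

#' Elastic energy of a solved profile (boundary-term form)
#'
#' Evaluates the on-shell elastic energy of a solved deformation profile from
#' the total-derivative (boundary-term) form of the energy functional: the
#' integrand collapses to the difference of a bracket of field derivatives at
#' the region ends.  The constant background energy density of the
#' tension-relaxed bilayer, `-tau^2/(4 K_t)` per unit area, is excluded; it
#' cancels in every interaction quantity.
#'
#' @param profile A solved `deformation_profile`.
#' @param bilayer Bilayer parameters; defaults to those stored in the
#'   profile.
#' @param L Wedge length (nm) scaling the 1D energy density to an energy;
#'   defaults to the length of the profile's first wedge.
#'
#' @return Energy in k_BT.
#' @seealso [profile_energy_quadrature()] for the independent direct
#'   quadrature of the energy density.
#' @export
profile_energy <- function(profile, bilayer = profile$bilayer,
                           L = profile$wedges[[1]]$L) {
  stopifnot(inherits(profile, "deformation_profile"))
  if (profile$region == "interior")
    L * (.phi_at(profile, profile$s) - .phi_at(profile, -profile$s))
  else
    -L * .phi_at(profile, 0)   # bracket vanishes at infinity
}

#' Elastic energy of a solved profile (direct quadrature)
#'
#' Integrates the energy density of the deformation functional over the
#' profile's region by adaptive quadrature, with the same background
#' subtraction convention as [profile_energy()].  This is a deliberately
#' independent route to the same number and serves as the oracle for the
#' boundary-term evaluation.
#'
#' @inheritParams profile_energy
#' @param rel.tol Relative tolerance passed to [stats::integrate()].
#'
#' @return Energy in k_BT.
#' @export
profile_energy_quadrature <- function(profile, bilayer = profile$bilayer,
                                      L = profile$wedges[[1]]$L,
                                      rel.tol = 1e-12) {
  stopifnot(inherits(profile, "deformation_profile"))
  K_b <- bilayer$K_b; K_t <- bilayer$K_t; a <- bilayer$a; tau <- bilayer$tau
  dens <- function(r) {
    vapply(r, function(ri) {
      d1 <- .profile_fields(profile, ri, 1)
      d2 <- .profile_fields(profile, ri, 2)
      d0 <- .profile_fields(profile, ri, 0)
      h1 <- Re(d1$h); h2 <- Re(d2$h)
      u0 <- Re(d0$ubar) - profile$offset
      u1 <- Re(d1$ubar); u2 <- Re(d2$ubar)
      0.5 * (K_b * (h2^2 - h2 * u2 + 0.5 * u2^2) + K_t / 2 * (u0 / a)^2 +
             tau * u0 / a + tau * (h1^2 - h1 * u1 + 0.5 * u1^2)) +
        tau^2 / (4 * K_t)
    }, numeric(1))
  }
  if (profile$region == "interior") {
    L * stats::integrate(dens, -profile$s, profile$s,
                         rel.tol = rel.tol, subdivisions = 2000L)$value
  } else {
    # exponential tails are negligible far beyond the slowest decay length
    rmax <- 40 * max(profile$dc$lambda_s,
                     if (is.finite(profile$dc$lambda_t)) 0 else 0)
    if (is.finite(profile$dc$lambda_t)) rmax <- max(rmax, 20 * profile$dc$lambda_t)
    L * stats::integrate(dens, 0, rmax,
                         rel.tol = rel.tol, subdivisions = 5000L)$value
  }
}

# interior energy as a quadratic in the wedge height difference delta:
# E(delta) = e0 + a1 delta + a2 delta^2, minimised analytically
.pair_energy_coefs <- function(bilayer, wedge_a, wedge_b, d) {
  L <- wedge_a$L
  Eat <- function(delta) {
    p <- .solve_pair_at(bilayer, wedge_a, wedge_b, d, delta)
    L * (.phi_at(p, p$s) - .phi_at(p, -p$s))
  }
  e0 <- Eat(0); ep <- Eat(1); em <- Eat(-1)
  a2 <- (ep + em - 2 * e0) / 2
  a1 <- (ep - em) / 2
  if (a2 > 0) {
    delta_opt <- -a1 / (2 * a2)
    emin <- e0 - a1^2 / (4 * a2)
  } else {                      # flat or concave direction: keep level wedges
    delta_opt <- 0
    emin <- e0
  }
  list(e0 = e0, a1 = a1, a2 = a2, delta_opt = delta_opt, energy = emin)
}

# height-minimised interior energy minus the isolated-wedge reference
.interaction_energy <- function(bilayer, wedge_a, wedge_b, d,
                                e_ref = NULL) {
  if (is.null(e_ref)) e_ref <- .isolated_reference(bilayer, wedge_a, wedge_b)
  .pair_energy_coefs(bilayer, wedge_a, wedge_b, d)$energy - e_ref
}

# reference energy G_0 = lim_{d->inf} G(d): one semi-infinite exterior per
# wedge on the facing side (closed form, no large-d extrapolation)
.isolated_reference <- function(bilayer, wedge_a, wedge_b) {
  ea <- profile_energy(solve_isolated_profile(bilayer, wedge_a))
  eb <- if (identical(wedge_a, wedge_b)) ea
        else profile_energy(solve_isolated_profile(bilayer, wedge_b))
  ea + eb
}

# ---- interaction potential ------------------------------------------------

#' Bilayer-mediated interaction potential between two parallel wedges
#'
#' Computes `G_int(d) = G(d) - G_0` on a grid of axis-to-axis separations,
#' where `G(d)` is the height-minimised elastic energy of the bilayer region
#' between the wedges and `G_0 = lim_{d -> Inf} G(d)` is the isolated-wedge
#' reference (twice the semi-infinite exterior energy for a symmetric pair).
#' Negative values are favourable.
#'
#' @inheritParams solve_pair_profile
#' @param d_grid Separations (nm); each must exceed `2 * r0`.
#'
#' @return An object of class `interaction_curve`: a data frame with columns
#'   `d` (nm) and `g_int` (k_BT), carrying the bilayer and wedge parameters
#'   as attributes.
#' @examples
#' bp <- bilayer_params()
#' wd <- wedge_params(U = -0.9)
#' ic <- interaction_curve(bp, wd, wd, d_grid = seq(1.3, 8, by = 0.1))
#' print(ic)
#' @export
interaction_curve <- function(bilayer, wedge_a, wedge_b = wedge_a, d_grid) {
  stopifnot(inherits(bilayer, "bilayer_params"),
            inherits(wedge_a, "wedge_params"), inherits(wedge_b, "wedge_params"),
            is.numeric(d_grid), length(d_grid) >= 1L)
  r0 <- wedge_a$r0
  if (any(d_grid <= 2 * r0))
    stop(sprintf("all separations must exceed 2*r0 = %g nm", 2 * r0),
         call. = FALSE)
  e_ref <- .isolated_reference(bilayer, wedge_a, wedge_b)
  g <- vapply(d_grid, function(d)
    .interaction_energy(bilayer, wedge_a, wedge_b, d, e_ref), numeric(1))
  structure(data.frame(d = d_grid, g_int = g),
            bilayer = bilayer, wedge_a = wedge_a, wedge_b = wedge_b,
            class = c("interaction_curve", "data.frame"))
}

#' @exportS3Method base::print
print.interaction_curve <- function(x, ...) {
  wa <- attr(x, "wedge_a"); wb <- attr(x, "wedge_b")
  cat(sprintf("Wedge-wedge interaction potential, U = (%g, %g) nm, tau = %g k_BT/nm^2\n",
              wa$U, wb$U, attr(x, "bilayer")$tau))
  i <- which.min(x$g_int)
  cat(sprintf("  %d separations in [%g, %g] nm; min G_int = %.4g k_BT at d = %g nm\n",
              nrow(x), min(x$d), max(x$d), x$g_int[i], x$d[i]))
  invisible(x)
}

#' @exportS3Method
plot.interaction_curve <- function(x, ...) {
  graphics::plot(x$d, x$g_int, type = "l",
                 xlab = "axis-to-axis separation d (nm)",
                 ylab = expression(G[int] ~ (k[B] * T)), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

# fine grid + golden-section refinement of min_d G_int on [d_lo, d_hi]
.gint_minimum <- function(bilayer, wedge_a, wedge_b, d_lo, d_hi, step = 0.025) {
  e_ref <- .isolated_reference(bilayer, wedge_a, wedge_b)
  f <- function(d) .interaction_energy(bilayer, wedge_a, wedge_b, d, e_ref)
  ds <- seq(d_lo, d_hi, by = step)
  if (ds[length(ds)] < d_hi) ds <- c(ds, d_hi)
  g <- vapply(ds, f, numeric(1))
  i <- which.min(g)
  lo <- ds[max(1L, i - 1L)]; hi <- ds[min(length(ds), i + 1L)]
  if (hi > lo) {
    opt <- stats::optimize(f, c(lo, hi), tol = 1e-6)
    if (opt$objective < g[i]) return(list(d_star = opt$minimum, g_min = opt$objective))
  }
  list(d_star = ds[i], g_min = g[i])
}

#' Dimerization energy of a wedge pair
#'
#' Locates the minimum of the interaction potential `G_int(d)` over a bracket
#' of separations.  When the minimum is negative (a favourable well), the
#' dimerization energy is its magnitude, the energy gained by bringing the
#' wedges to their optimal separation `d_star`.  When the potential is
#' repulsive throughout, the wedges have no bound state; the function then
#' reports the contact cost, the minimum of `G_int` over the dimer-contact
#' window `[2*r0, 2 nm]`, which is the least energy penalty incurred by
#' holding the pair at dimer-like separations.
#'
#' @inheritParams solve_pair_profile
#' @param d_min,d_max Search bracket for the separation (nm);
#'   `d_min` must be at least `2 * r0`.
#'
#' @return A list with fields `energy` (k_BT: the gain, positive, when the
#'   well exists; otherwise the positive contact cost), `d_star` (nm),
#'   `g_min` (the signed minimum of `G_int` over the bracket) and
#'   `attractive` (logical).
#' @examples
#' de <- dimerization_energy(bilayer_params(), wedge_params(U = -0.9))
#' de$energy   # > 10 k_BT for the deep state at zero tension
#' de$d_star
#' @export
dimerization_energy <- function(bilayer, wedge_a, wedge_b = wedge_a,
                                d_min = 2 * wedge_a$r0 + 0.05, d_max = 10) {
  r0 <- wedge_a$r0
  if (d_min < 2 * r0)
    stop(sprintf("'d_min' must be at least 2*r0 = %g nm", 2 * r0), call. = FALSE)
  if (d_max <= d_min) stop("empty separation bracket", call. = FALSE)
  m <- .gint_minimum(bilayer, wedge_a, wedge_b, max(d_min, 2 * r0 + 1e-3), d_max)
  if (m$g_min < 0) {
    list(energy = -m$g_min, d_star = m$d_star, g_min = m$g_min, attractive = TRUE)
  } else {
    mc <- .gint_minimum(bilayer, wedge_a, wedge_b, 2 * r0 + 0.05,
                        min(2.0, d_max))
    list(energy = mc$g_min, d_star = mc$d_star, g_min = m$g_min,
         attractive = FALSE)
  }
}

#' Critical immersion depth for the onset of wedge attraction
#'
#' Finds, by bisection, the immersion depth `U_c` at which the minimum over
#' separation of the interaction potential changes sign: wedges shallower
#' than `U_c` repel at every separation, deeper wedges develop a favourable
#' well at intermediate separations.
#'
#' @inheritParams solve_pair_profile
#' @param wedge_template A [wedge_params()] object supplying geometry and
#'   contact slopes; its `U` is overridden during the search.
#' @param U_bracket Length-2 bracket of immersion depths (nm) containing the
#'   sign change of `min_d G_int`.
#' @param tol Bisection tolerance on `U` (nm).
#' @param d_range Separation bracket (nm) over which the minimum of `G_int`
#'   is taken.
#' @param d_step Grid step (nm) of the separation scan.
#'
#' @return The critical immersion depth `U_c` (nm).
#' @examples
#' \donttest{
#' critical_immersion_depth(bilayer_params(), wedge_params(U = -0.9))
#' }
#' @export
critical_immersion_depth <- function(bilayer, wedge_template,
                                     U_bracket = c(-0.9, -0.1), tol = 1e-3,
                                     d_range = c(2 * wedge_template$r0 + 0.05, 10),
                                     d_step = 0.025) {
  stopifnot(length(U_bracket) == 2L)
  phi <- function(U) {
    w <- wedge_params(U = U, L = wedge_template$L, r0 = wedge_template$r0,
                      slope_h = wedge_template$slope_h,
                      slope_u = wedge_template$slope_u)
    .gint_minimum(bilayer, w, w, d_range[1], d_range[2], step = d_step)$g_min
  }
  lo <- min(U_bracket); hi <- max(U_bracket)   # lo: deep (attract), hi: shallow
  flo <- phi(lo); fhi <- phi(hi)
  if (sign(flo) == sign(fhi))
    stop("no sign change of min_d G_int inside 'U_bracket'", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sign(phi(mid)) == sign(flo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# ---- h+-pinned thickness profile (1D reference for the 2D solver) ---------

#' One-dimensional thickness profile with the height field pinned
#'
#' Solves the exterior thickness deformation next to a single long wedge for
#' the reduced functional in which the leaflet height field is held flat
#' (`h+ = 0`), the regime computed by the two-dimensional solver.  Used as
#' the analytic reference for mid-length transects of
#' [solve_thickness_field()].
#'
#' @inheritParams solve_isolated_profile
#'
#' @return A list with `u`, a function `u(r, deriv = 0)` of the outward
#'   distance from the wedge edge, `energy_per_length` (k_BT/nm, one side,
#'   background-subtracted) and the complex decay roots `k`.
#' @export
pinned_thickness_profile <- function(bilayer, wedge) {
  stopifnot(inherits(bilayer, "bilayer_params"), inherits(wedge, "wedge_params"))
  K_b <- bilayer$K_b; K_t <- bilayer$K_t; a <- bilayer$a; tau <- bilayer$tau
  # K_b ubar'''' - tau ubar'' + (K_t/a^2) ubar = 0
  disc <- sqrt(as.complex(tau^2 - 4 * K_b * K_t / a^2))
  nu <- c((tau + disc) / (2 * K_b), (tau - disc) / (2 * K_b))
  kdec <- -sqrt(nu)                     # Re < 0: decaying branches
  off <- tau * a / K_t
  M <- rbind(c(1, 1), kdec)
  coef <- solve(M, c(wedge$U + off, wedge$slope_u))
  ufun <- function(r, deriv = 0) {
    v <- vapply(r, function(ri) sum(coef * kdec^deriv * exp(kdec * ri)), complex(1))
    out <- Re(v)
    if (deriv == 0) out <- out - off
    out
  }
  dens <- function(r) {
    u0 <- ufun(r, 0); u1 <- ufun(r, 1); u2 <- ufun(r, 2)
    0.5 * (K_b / 2 * u2^2 + K_t / 2 * (u0 / a)^2 + tau * u0 / a +
           tau / 2 * u1^2) + tau^2 / (4 * K_t)
  }
  rmax <- 30 / abs(Re(kdec[1]))
  epl <- stats::integrate(dens, 0, rmax, rel.tol = 1e-10,
                          subdivisions = 2000L)$value
  list(u = ufun, energy_per_length = epl, k = kdec)
}
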