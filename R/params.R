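#' Elastic material constants of the lipid bilayer
#'
#' Bundles the four material constants of the leaflet elasticity model:
#' bending rigidity, thickness deformation modulus, unperturbed monolayer
#' hydrophobic thickness and membrane tension.  The defaults are the standard
#' parameter set for phospholipid bilayers used throughout the package.
#'
#' @param K_b Bending rigidity of the bilayer (k_BT).  Must be positive.
#' @param K_t Thickness deformation modulus (k_BT/nm^2).  Must be positive.
#' @param a Unperturbed monolayer hydrophobic thickness (nm).  Must be
#'   positive.
#' @param tau Membrane tension (k_BT/nm^2).  Must be non-negative; `tau = 0`
#'   is the tensionless reference case.
#'
#' @return An object of class `bilayer_params`.
#' @examples
#' bilayer_params()
#' bilayer_params(tau = 0.05)
#' @export
bilayer_params <- function(K_b = 20, K_t = 60, a = 2.0, tau = 0) {
  stopifnot(is.numeric(K_b), length(K_b) == 1L, is.finite(K_b),
            is.numeric(K_t), length(K_t) == 1L, is.finite(K_t),
            is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(tau), length(tau) == 1L, is.finite(tau))
  if (K_b <= 0) stop("'K_b' must be positive", call. = FALSE)
  if (K_t <= 0) stop("'K_t' must be positive", call. = FALSE)
  if (a <= 0) stop("'a' must be positive", call. = FALSE)
  if (tau < 0) stop("'tau' must be non-negative", call. = FALSE)
  structure(list(K_b = K_b, K_t = K_t, a = a, tau = tau),
            class = "bilayer_params")
}

#' @exportS3Method base::print
print.bilayer_params <- function(x, ...) {
  cat("Bilayer elastic parameters\n")
  cat(sprintf("  K_b = %g k_BT   K_t = %g k_BT/nm^2   a = %g nm   tau = %g k_BT/nm^2\n",
              x$K_b, x$K_t, x$a, x$tau))
  invisible(x)
}

#' Geometry and contact conditions of an amphipathic wedge
#'
#' Describes a single membrane-inserted amphipathic helix ("wedge"): its
#' immersion depth, in-plane dimensions and the contact slopes imposed on the
#' leaflet height and thickness fields at the bilayer--wedge interface.  The
#' slopes are measured along the outward normal pointing from the wedge into
#' the surrounding membrane; the wedge cross-section is mirror symmetric, so
#' the same slope applies on both sides.
#'
#' @param U Immersion depth (nm).  Non-positive by convention: `0` is the
#'   shallow (surface-level) state, `-0.9` the deep state of N-BAR H0
#'   helices.
#' @param L Wedge length along the helix axis (nm).
#' @param r0 Wedge radius (nm); half the in-plane width of the wedge
#'   cross-section.
#' @param slope_h Contact slope of the leaflet height field h+ at the
#'   bilayer--wedge interface (dimensionless, along the outward normal).
#' @param slope_u Contact slope of the leaflet thickness deformation field u+
#'   at the interface (dimensionless, along the outward normal).
#'
#' @return An object of class `wedge_params`.
#' @examples
#' wedge_params(U = -0.9)       # deep immersion state
#' wedge_params(U = 0)          # shallow state, contact slopes retained
#' @export
wedge_params <- function(U, L = 3, r0 = 0.6,
                         slope_h = -tan(9 * pi / 180), slope_u = 0) {
  stopifnot(is.numeric(U), length(U) == 1L, is.finite(U),
            is.numeric(L), length(L) == 1L, is.finite(L),
            is.numeric(r0), length(r0) == 1L, is.finite(r0),
            is.numeric(slope_h), length(slope_h) == 1L, is.finite(slope_h),
            is.numeric(slope_u), length(slope_u) == 1L, is.finite(slope_u))
  if (r0 <= 0) stop("'r0' must be positive", call. = FALSE)
  if (L <= 0) stop("'L' must be positive", call. = FALSE)
  structure(list(U = U, L = L, r0 = r0, slope_h = slope_h, slope_u = slope_u),
            class = "wedge_params")
}

#' @exportS3Method base::print
print.wedge_params <- function(x, ...) {
  cat(sprintf("Wedge: U = %g nm, L = %g nm, r0 = %g nm, slopes (h, u) = (%.4f, %.4f)\n",
              x$U, x$L, x$r0, x$slope_h, x$slope_u))
  invisible(x)
}

#' Characteristic decay constants of leaflet deformations
#'
#' Computes the tension length `lambda_t = sqrt(K_b/tau)` (infinite at zero
#' tension), the thickness-deformation length
#' `lambda_s = (K_b a^2 / (8 K_t))^(1/4)`, and the inverse square decay
#' lengths
#' `nu_pm = (lambda_t^-2 +- sqrt(lambda_t^-4 - lambda_s^-4)) / 2`
#' of the thickness field.  Whenever `lambda_t^-4 < lambda_s^-4` (always at
#' `tau = 0`) the two roots are complex conjugates and the thickness
#' deformation decays with an oscillatory profile.
#'
#' @param bilayer A [bilayer_params()] object.
#'
#' @return An object of class `decay_constants` with fields `lambda_t`
#'   (nm, `Inf` at zero tension), `lambda_s` (nm), `nu_plus`, `nu_minus`
#'   (complex, 1/nm^2) and `k`, the four complex roots
#'   `c(sqrt(nu_plus), -sqrt(nu_plus), sqrt(nu_minus), -sqrt(nu_minus))`
#'   used by the analytic solver.
#' @examples
#' dc <- decay_constants(bilayer_params())
#' dc$lambda_s   # (1/6)^(1/4) for the default parameter set
#' @export
decay_constants <- function(bilayer) {
  stopifnot(inherits(bilayer, "bilayer_params"))
  ls <- (bilayer$K_b * bilayer$a^2 / (8 * bilayer$K_t))^0.25
  if (bilayer$tau == 0) {
    lt <- Inf
    nu_p <- 1i / (2 * ls^2)
    nu_m <- -1i / (2 * ls^2)
  } else {
    lt <- sqrt(bilayer$K_b / bilayer$tau)
    disc <- sqrt(as.complex(lt^-4 - ls^-4))
    nu_p <- 0.5 * (lt^-2 + disc)
    nu_m <- 0.5 * (lt^-2 - disc)
  }
  k <- c(sqrt(nu_p), -sqrt(nu_p), sqrt(nu_m), -sqrt(nu_m))
  structure(list(lambda_t = lt, lambda_s = ls,
                 nu_plus = nu_p, nu_minus = nu_m, k = k),
            class = "decay_constants")
}

#' @exportS3Method base::print
print.decay_constants <- function(x, ...) {
  cat(sprintf("Decay constants: lambda_t = %s nm, lambda_s = %.6g nm\n",
              if (is.infinite(x$lambda_t)) "Inf" else sprintf("%.6g", x$lambda_t),
              x$lambda_s))
  cat(sprintf("  nu_plus  = %.6g%+.6gi 1/nm^2\n", Re(x$nu_plus), Im(x$nu_plus)))
  cat(sprintf("  nu_minus = %.6g%+.6gi 1/nm^2\n", Re(x$nu_minus), Im(x$nu_minus)))
  invisible(x)
}
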