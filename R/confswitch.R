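# Pair statistical mechanics of the concerted shallow-to-deep conformational
# switch.  A pair of membrane-bound proteins carries conformation variables
# s1, s2 in {0, 1} (shallow / deep wedging); the non-interacting energy is
# G_non = (s1 + s2) * epsilon_d and the separation-dependent part is the
# bilayer-mediated interaction potential of the 1D module with the immersion
# depths mapped from the states.  Boltzmann weights are sampled over the
# separation via the Mayer f-function.

#' Two-state conformational model of a protein pair
#'
#' @param epsilon_d Energy difference (k_BT) between the deep and shallow
#'   single-protein conformations at infinite separation.
#' @param bilayer A [bilayer_params()] object.
#' @param wedge_shallow,wedge_deep [wedge_params()] objects for the two
#'   conformations (defaults: immersion 0 and -0.9 nm, shared contact
#'   slopes).
#' @param r_c Long-range cutoff of the pair interaction (nm).
#'
#' @return An object of class `conformational_model`.  The pair interaction
#'   is isotropic in the axis-to-axis separation `r`, helices face-on;
#'   `r_min = 2 r0` is the hardcore contact.
#' @examples
#' cm <- conformational_model(epsilon_d = 2)
#' deep_state_probability(cm, c = 1e-4)
#' @export
conformational_model <- function(epsilon_d, bilayer = bilayer_params(),
                                 wedge_shallow = wedge_params(U = 0),
                                 wedge_deep = wedge_params(U = -0.9),
                                 r_c = 40) {
  stopifnot(is.numeric(epsilon_d), length(epsilon_d) == 1L,
            inherits(bilayer, "bilayer_params"),
            inherits(wedge_shallow, "wedge_params"),
            inherits(wedge_deep, "wedge_params"))
  r_min <- 2 * wedge_deep$r0
  if (r_min >= r_c) stop("'r_c' must exceed the contact separation 2*r0",
                         call. = FALSE)
  structure(list(epsilon_d = epsilon_d, bilayer = bilayer,
                 wedges = list(wedge_shallow, wedge_deep),
                 r_min = r_min, r_c = r_c,
                 cache = new.env(parent = emptyenv())),
            class = "conformational_model")
}

#' @exportS3Method base::print
print.conformational_model <- function(x, ...) {
  cat(sprintf("Conformational switch model: epsilon_d = %g k_BT, U = (%g, %g) nm, r_c = %g nm\n",
              x$epsilon_d, x$wedges[[1]]$U, x$wedges[[2]]$U, x$r_c))
  invisible(x)
}

#' State-dependent pair interaction energy
#'
#' `G_int(s1, s2, r)` from the analytic 1D solver with the immersion depths
#' of the two conformations; the mixed state uses the asymmetric-pair
#' solution with the same contact slopes on both wedges.
#'
#' @param model A [conformational_model()].
#' @param s1,s2 Conformation states, 0 (shallow) or 1 (deep).
#' @param r Axis-to-axis separations (nm), each at least `r_min`.
#'
#' @return Energies (k_BT), vectorised over `r`.
#' @export
state_interaction <- function(model, s1, s2, r) {
  stopifnot(inherits(model, "conformational_model"),
            s1 %in% 0:1, s2 %in% 0:1)
  if (any(r < model$r_min))
    stop(sprintf("separation below hardcore contact r_min = %g nm", model$r_min),
         call. = FALSE)
  wa <- model$wedges[[s1 + 1L]]
  wb <- model$wedges[[s2 + 1L]]
  e_ref <- .isolated_reference(model$bilayer, wa, wb)
  vapply(r, function(ri) {
    if (ri <= model$r_min + 1e-9) return(Inf)
    .interaction_energy(model$bilayer, wa, wb, ri, e_ref)
  }, numeric(1))
}

#' Non-interacting pair energy
#'
#' `G_non(s1, s2) = (s1 + s2) * epsilon_d`, with the shallow-shallow state
#' as the zero of energy.
#'
#' @inheritParams state_interaction
#' @return Energy (k_BT).
#' @export
state_base_energy <- function(model, s1, s2) {
  stopifnot(s1 %in% 0:1, s2 %in% 0:1)
  (s1 + s2) * model$epsilon_d
}

# spatial Mayer integral I(s1, s2) = pi * int_{r_min}^{r_c} f12(r) r dr,
# f12 = exp(-G_int) - 1; split at the potential minimum to resolve the deep
# attractive well; cached per state pair
.mayer_integral <- function(model, s1, s2, rel.tol = 1e-6) {
  key <- paste0("I", min(s1, s2), max(s1, s2))
  if (!is.null(model$cache[[key]])) return(model$cache[[key]])
  wa <- model$wedges[[min(s1, s2) + 1L]]
  wb <- model$wedges[[max(s1, s2) + 1L]]
  e_ref <- .isolated_reference(model$bilayer, wa, wb)
  integrand <- function(r) {
    vapply(r, function(ri) {
      g <- if (ri <= model$r_min + 1e-9) Inf
           else .interaction_energy(model$bilayer, wa, wb, ri, e_ref)
      (exp(-g) - 1) * ri
    }, numeric(1))
  }
  m <- .gint_minimum(model$bilayer, wa, wb, model$r_min + 0.05,
                     min(10, model$r_c))
  split <- min(max(m$d_star, model$r_min + 0.1), model$r_c - 0.1)
  I <- pi * (stats::integrate(integrand, model$r_min, split,
                              rel.tol = rel.tol, subdivisions = 500L)$value +
             stats::integrate(integrand, split, model$r_c,
                              rel.tol = rel.tol, subdivisions = 500L)$value)
  model$cache[[key]] <- I
  I
}

#' Boltzmann weight of a conformational state pair
#'
#' `z(s1, s2) = exp(-G_non) * (1 + c * pi * int_{2 r0}^{r_c} f12(r) r dr)`
#' with the Mayer function `f12 = exp(-G_int) - 1`, sampling the pair
#' separation at surface concentration `c`.
#'
#' @inheritParams state_interaction
#' @param c Concentration of membrane-bound proteins (1/nm^2), positive.
#'
#' @return Dimensionless weight (positive).
#' @export
boltzmann_weight <- function(model, s1, s2, c) {
  stopifnot(inherits(model, "conformational_model"), c > 0)
  bracket <- 1 + c * .mayer_integral(model, s1, s2)
  if (bracket <= 0)
    stop(sprintf("Boltzmann weight bracket non-positive at c = %g 1/nm^2 for state (%d, %d): concentration outside the dilute-pair regime",
                 c, s1, s2), call. = FALSE)
  exp(-state_base_energy(model, s1, s2)) * bracket
}

#' Probability of the jointly deep conformational state
#'
#' `P_d = z(1,1) / (z(0,0) + 2 z(0,1) + z(1,1))`: the probability that both
#' proteins of the pair are in the deep-immersion conformation.  In the
#' dilute limit `c -> 0` this reduces to `1 / (1 + exp(epsilon_d))^2`.
#'
#' @inheritParams boltzmann_weight
#' @return Probability in `[0, 1]`.
#' @export
deep_state_probability <- function(model, c) {
  z00 <- boltzmann_weight(model, 0, 0, c)
  z01 <- boltzmann_weight(model, 0, 1, c)
  z11 <- boltzmann_weight(model, 1, 1, c)
  z11 / (z00 + 2 * z01 + z11)
}

#' Deep-state phase diagram over concentration and conformational bias
#'
#' Evaluates `P_d` over the product grid of concentrations and single-protein
#' energy differences and extracts the `P_d = 1/2` contour by linear
#' interpolation along the concentration axis.  The spatial Mayer integrals
#' do not depend on `epsilon_d` or `c`, so they are computed once.
#'
#' @param model A [conformational_model()] (its `epsilon_d` is overridden by
#'   `eps_grid`).
#' @param c_grid Concentrations (1/nm^2), positive, increasing.  The
#'   dilute-pair expansion underlying the Boltzmann weights breaks down when
#'   `c` approaches `-1/I` for the most repulsive state pair (about
#'   3e-3 1/nm^2 with default parameters); grid points beyond that are
#'   reported as `NA`.
#' @param eps_grid Energy differences `epsilon_d` (k_BT).
#'
#' @return An object of class `phase_diagram`: list with `c_grid`,
#'   `eps_grid`, matrix `P_d` (`length(c_grid)` x `length(eps_grid)`) and
#'   `contour`, a data frame of the `P_d = 1/2` crossing concentration per
#'   `epsilon_d` (NA where no crossing occurs in range).
#' @export
phase_diagram <- function(model, c_grid = 10^seq(-6, log10(2.5e-3), length.out = 25),
                          eps_grid = seq(0, 4, by = 0.25)) {
  stopifnot(inherits(model, "conformational_model"),
            length(c_grid) >= 1L, all(c_grid > 0), length(eps_grid) >= 1L)
  I00 <- .mayer_integral(model, 0, 0)
  I01 <- .mayer_integral(model, 0, 1)
  I11 <- .mayer_integral(model, 1, 1)
  P <- matrix(NA_real_, length(c_grid), length(eps_grid))
  for (j in seq_along(eps_grid)) {
    e <- eps_grid[j]
    for (i in seq_along(c_grid)) {
      cc <- c_grid[i]
      b00 <- 1 + cc * I00; b01 <- 1 + cc * I01; b11 <- 1 + cc * I11
      if (min(b00, b01, b11) <= 0) next      # outside dilute-pair regime
      z00 <- b00; z01 <- exp(-e) * b01; z11 <- exp(-2 * e) * b11
      P[i, j] <- z11 / (z00 + 2 * z01 + z11)
    }
  }
  contour <- data.frame(epsilon_d = eps_grid, c_half = NA_real_)
  for (j in seq_along(eps_grid)) {
    p <- P[, j]
    ok <- which(!is.na(p))
    cross <- ok[which(diff(p[ok] >= 0.5) != 0)]
    if (length(cross)) {
      i <- cross[1]
      i2 <- ok[which(ok == i) + 1L]
      w <- (0.5 - p[i]) / (p[i2] - p[i])
      # interpolate in log-concentration
      contour$c_half[j] <- exp((1 - w) * log(c_grid[i]) + w * log(c_grid[i2]))
    } else if (all(p[ok] >= 0.5)) contour$c_half[j] <- c_grid[ok[1]]
  }
  structure(list(c_grid = c_grid, eps_grid = eps_grid, P_d = P,
                 contour = contour, model = model),
            class = "phase_diagram")
}

#' @exportS3Method base::print
print.phase_diagram <- function(x, ...) {
  cat(sprintf("Deep-state phase diagram: %d concentrations x %d epsilon_d values\n",
              length(x$c_grid), length(x$eps_grid)))
  cat(sprintf("  P_d range [%.3g, %.3g]; P_d = 1/2 contour defined for %d epsilon values\n",
              min(x$P_d, na.rm = TRUE), max(x$P_d, na.rm = TRUE),
              sum(!is.na(x$contour$c_half))))
  invisible(x)
}

#' @exportS3Method
plot.phase_diagram <- function(x, ...) {
  graphics::image(log10(x$c_grid), x$eps_grid, x$P_d,
                  xlab = expression(log[10] ~ c ~ (nm^-2)),
                  ylab = expression(epsilon[d] ~ (k[B] * T)),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  ok <- !is.na(x$contour$c_half)
  if (any(ok))
    graphics::lines(log10(x$contour$c_half[ok]), x$contour$epsilon_d[ok],
                    lty = 2, lwd = 2)
  invisible(x)
}
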