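# Stadium-shaped wedge footprints for the 2D thickness solver: a rectangle of
# length L - 2*r0 capped by semicircles of radius r0, carrying an immersion
# profile that is constant U on the straight sides and tapers linearly in arc
# length to 0 at the two cap centers.

#' Stadium footprint of a membrane-inserted wedge
#'
#' Builds the in-plane footprint of a wedge for the two-dimensional thickness
#' solver: a stadium (rectangle capped by semicircles of radius `r0`, total
#' length `L` along the axis) at a given pose.  The immersion profile along
#' the outline is `U` on the straight sides and tapers linearly in arc length
#' across each rounded tip, reaching 0 at the tip centers, so the imposed
#' leaflet compression fades out at the helix ends.
#'
#' @param U Immersion depth on the straight sides (nm, typically negative).
#' @param L Total footprint length along the axis (nm); must exceed `2 * r0`.
#' @param r0 Cap (wedge) radius (nm).
#' @param center Footprint center `c(x, y)` (nm).
#' @param theta Axis orientation (radians).
#'
#' @return An object of class `wedge_footprint`.
#' @examples
#' fp <- wedge_footprint(U = -0.9)
#' footprint_perimeter(fp)           # 2*(L - 2*r0) + 2*pi*r0
#' footprint_immersion(fp, cbind(0, 0.6))   # side midpoint: U
#' @export
wedge_footprint <- function(U, L = 3, r0 = 0.6, center = c(0, 0), theta = 0) {
  stopifnot(is.numeric(U), length(U) == 1L,
            is.numeric(center), length(center) == 2L,
            is.numeric(theta), length(theta) == 1L)
  if (r0 <= 0) stop("'r0' must be positive", call. = FALSE)
  if (L <= 2 * r0) stop("degenerate footprint: need L > 2*r0", call. = FALSE)
  structure(list(U = U, L = L, r0 = r0,
                 center = as.numeric(center), theta = theta,
                 half_core = L / 2 - r0),
            class = "wedge_footprint")
}

#' @exportS3Method base::print
print.wedge_footprint <- function(x, ...) {
  cat(sprintf("Stadium footprint: U = %g nm, L = %g nm, r0 = %g nm, center (%.2f, %.2f) nm, theta = %.3f rad\n",
              x$U, x$L, x$r0, x$center[1], x$center[2], x$theta))
  invisible(x)
}

# world -> body coordinates, n x 2
.to_body <- function(fp, xy) {
  dx <- xy[, 1] - fp$center[1]
  dy <- xy[, 2] - fp$center[2]
  ct <- cos(fp$theta); st <- sin(fp$theta)
  cbind(ct * dx + st * dy, -st * dx + ct * dy)
}

#' Membership and immersion profile of a footprint
#'
#' `footprint_contains()` tests which points lie inside the stadium outline;
#' `footprint_immersion()` returns the immersion value assigned to points of
#' the footprint (the Dirichlet data of the 2D solver): `U` over the
#' rectangular core and a linear-in-arc-length taper to 0 across the caps,
#' extended continuously into the interior.  Points outside the footprint get
#' `NA`.
#'
#' @param fp A [wedge_footprint()].
#' @param xy A two-column matrix of positions (nm).
#'
#' @return Logical vector, resp. numeric vector of immersion values (nm).
#' @export
footprint_contains <- function(fp, xy) {
  b <- .to_body(fp, xy)
  xc <- pmin(pmax(b[, 1], -fp$half_core), fp$half_core)
  (b[, 1] - xc)^2 + b[, 2]^2 <= fp$r0^2 + 1e-12
}

#' @rdname footprint_contains
#' @export
footprint_immersion <- function(fp, xy) {
  b <- .to_body(fp, xy)
  inside <- footprint_contains(fp, xy)
  # angular position along the cap, 0 at the side-cap junction,
  # pi/2 at the tip center; linear taper in arc length r0 * phi
  xexc <- pmax(abs(b[, 1]) - fp$half_core, 0)
  phi <- atan2(xexc, abs(b[, 2]))
  val <- fp$U * (1 - 2 * phi / pi)
  val[!inside] <- NA_real_
  val
}

#' Outline of a stadium footprint
#'
#' @param fp A [wedge_footprint()].
#' @param n Number of points per semicircular cap.
#' @return A closed two-column matrix of outline points (nm, world frame).
#' @export
footprint_outline <- function(fp, n = 40L) {
  hc <- fp$half_core; r0 <- fp$r0
  t1 <- seq(-pi / 2, pi / 2, length.out = n)        # right cap
  t2 <- seq(pi / 2, 3 * pi / 2, length.out = n)     # left cap
  pts <- rbind(cbind(hc + r0 * cos(t1), r0 * sin(t1)),
               cbind(-hc + r0 * cos(t2), r0 * sin(t2)))
  ct <- cos(fp$theta); st <- sin(fp$theta)
  out <- cbind(fp$center[1] + ct * pts[, 1] - st * pts[, 2],
               fp$center[2] + st * pts[, 1] + ct * pts[, 2])
  rbind(out, out[1, , drop = FALSE])
}

#' @rdname footprint_outline
#' @export
footprint_perimeter <- function(fp) 2 * (fp$L - 2 * fp$r0) + 2 * pi * fp$r0

# capsule segment endpoints of the stadium, world frame
.footprint_segment <- function(fp) {
  ct <- cos(fp$theta); st <- sin(fp$theta)
  e <- fp$half_core
  cbind(fp$center[1] + c(-e, e) * ct, fp$center[2] + c(-e, e) * st)
}

# minimum distance between two segments p1-p2 and q1-q2
.segment_distance <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1; r <- p1 - q1
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a <= 1e-14 && e <= 1e-14) return(sqrt(sum(r * r)))
  if (a <= 1e-14) { s <- 0; t <- min(max(f / e, 0), 1) }
  else {
    c_ <- sum(d1 * r)
    if (e <= 1e-14) { t <- 0; s <- min(max(-c_ / a, 0), 1) }
    else {
      b <- sum(d1 * d2); den <- a * e - b * b
      s <- if (den > 1e-14) min(max((b * f - c_ * e) / den, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-c_ / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - c_) / a, 0), 1) }
    }
  }
  cp <- p1 + s * d1; cq <- q1 + t * d2
  sqrt(sum((cp - cq)^2))
}

#' Do two stadium footprints overlap?
#'
#' Exact test via the distance between the core segments of the two stadiums
#' (a stadium is the set of points within `r0` of its core segment).
#'
#' @param fp_a,fp_b [wedge_footprint()] objects.
#' @return `TRUE` if the outlines overlap.
#' @export
footprints_overlap <- function(fp_a, fp_b) {
  sa <- .footprint_segment(fp_a); sb <- .footprint_segment(fp_b)
  .segment_distance(sa[1, ], sa[2, ], sb[1, ], sb[2, ]) < fp_a$r0 + fp_b$r0
}
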