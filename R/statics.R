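# Zipper statics: equilibrium configurations, energies and forces of
# two-axon zippers.
#
# Geometry convention: A and B are the fixed endpoints of the two free
# segments, C the fixed endpoint of the zippered segment, V the mobile
# zipper vertex. The zipper axis is the unit vector from V toward C; the
# zipper angles alpha1 (between VA and the extension of the axis beyond V)
# and alpha2 (between VB and the same extension) sum to the full zipper
# angle beta. Angles are stored in radians internally and exposed in
# degrees.

#' Zipper geometry
#'
#' Container for the instantaneous geometry of a two-axon zipper: fixed
#' points `A`, `B` (free-segment endpoints), `C` (zippered-segment endpoint)
#' and the mobile vertex `V`. Coordinates in micrometres.
#'
#' @param A,B,C,V Numeric length-2 vectors `(x, y)` in um.
#' @return An object of class `zipper_geometry`.
#' @export
zipper_geometry <- function(A, B, C, V) {
  pts <- list(A = A, B = B, C = C, V = V)
  for (nm in names(pts)) {
    p <- pts[[nm]]
    if (!is.numeric(p) || length(p) != 2 || anyNA(p)) {
      stop("point ", nm, " must be a numeric (x, y) pair", call. = FALSE)
    }
  }
  for (nm in c("A", "B", "C")) {
    if (vnorm(pts[[nm]] - V) < 1e-9) {
      stop("degenerate geometry: vertex coincides with ", nm, call. = FALSE)
    }
  }
  structure(pts, class = "zipper_geometry")
}

#' Zipper mechanics
#'
#' Effective tensions of the two axons and the axon-axon adhesion strength.
#' The effective tension combines axial tensile energy per unit length with
#' axon-substrate adhesion energy per unit length; the adhesion strength `S`
#' is the axon-axon adhesion energy per unit length of the zippered segment.
#' All in nN (equivalently nJ/m).
#'
#' @param T1 Effective tension of the first axon (nN).
#' @param T2 Effective tension of the second axon (nN); defaults to `T1`.
#' @param S Axon-axon adhesion strength (nN).
#' @return An object of class `zipper_mechanics`.
#' @export
zipper_mechanics <- function(T1, T2 = T1, S) {
  if (T1 <= 0 || T2 <= 0) stop("tensions must be positive", call. = FALSE)
  if (S < 0) stop("adhesion strength must be non-negative", call. = FALSE)
  structure(list(T1 = T1, T2 = T2, S = S), class = "zipper_mechanics")
}

full_zippering <- function() {
  structure(NA_real_, state = "full_zippering")
}

#' Test for the full-zippering state
#'
#' Equilibrium solvers return this first-class state (rather than throwing)
#' when the adhesion is strong enough that no static equilibrium with an
#' open zipper angle exists and the vertex would run into the fixed point of
#' the zippered segment.
#'
#' @param x A return value of one of the equilibrium functions.
#' @return `TRUE` if `x` flags full zippering.
#' @export
is_full_zippering <- function(x) {
  identical(attr(x, "state"), "full_zippering")
}

#' Equilibrium zipper angle of a symmetric zipper
#'
#' For equal tensions the force balance along the zippered segment reads
#' `S = 2 T (1 - cos(beta/2))`, giving the equilibrium full zipper angle
#' `beta = 2 acos(1 - S / (2 T))`. A symmetric equilibrium with
#' `beta < 180` degrees exists iff `S < 2 T`; for `S > 2 T` the
#' full-zippering state is returned (see [is_full_zippering()]).
#'
#' @param tension Effective axon tension T (nN).
#' @param adhesion Axon-axon adhesion strength S (nN).
#' @return Equilibrium angle beta in degrees, or the full-zippering state.
#' @seealso [adhesion_from_angle()] for the inverse relation.
#' @export
equilibrium_angle_symmetric <- function(tension, adhesion) {
  if (tension <= 0) stop("tension must be positive", call. = FALSE)
  if (adhesion < 0) stop("adhesion must be non-negative", call. = FALSE)
  if (adhesion > 2 * tension) {
    return(full_zippering())
  }
  rad2deg(2 * acos(1 - adhesion / (2 * tension)))
}

#' Adhesion strength from an equilibrium angle
#'
#' Inverse of [equilibrium_angle_symmetric()]:
#' `S = 2 T (1 - cos(beta/2))` for `beta` in `[0, 180]` degrees.
#'
#' @param tension Effective axon tension T (nN).
#' @param beta Equilibrium full zipper angle (degrees).
#' @return Adhesion strength S (nN), in `[0, 2T]`.
#' @export
adhesion_from_angle <- function(tension, beta) {
  if (tension <= 0) stop("tension must be positive", call. = FALSE)
  if (any(beta < 0 | beta > 180)) {
    stop("angle must lie in [0, 180] degrees", call. = FALSE)
  }
  2 * tension * (1 - cos(deg2rad(beta) / 2))
}

#' Equilibrium angles of an asymmetric zipper
#'
#' Solves the static force balance at the vertex for unequal tensions:
#' along the zippered segment
#' `-(T1 + T2 - S) + T1 cos(alpha1) + T2 cos(alpha2) = 0`
#' and transverse to it `T1 sin(alpha1) = T2 sin(alpha2)`.
#' The transverse condition is used to express `alpha2` in terms of
#' `alpha1`, and the longitudinal residual is solved by bracketed root
#' finding on `alpha1` in (0, 90) degrees, which is deterministic and
#' guaranteed to converge. The equilibrium so defined is the (stable)
#' energy minimum of the configuration energy.
#'
#' @param T1,T2 Effective tensions (nN).
#' @param S Adhesion strength (nN).
#' @param tol Root-finding tolerance on the angle (radians).
#' @return Named vector `c(alpha1, alpha2)` in degrees, or the
#'   full-zippering state when no solution with both angles below 90
#'   degrees exists.
#' @export
equilibrium_angles_asymmetric <- function(T1, T2, S, tol = 1e-12) {
  if (T1 <= 0 || T2 <= 0) stop("tensions must be positive", call. = FALSE)
  if (S < 0) stop("adhesion must be non-negative", call. = FALSE)
  if (S == 0) {
    return(c(alpha1 = 0, alpha2 = 0))
  }
  # alpha2(alpha1) from the transverse balance; alpha1 limited so that
  # sin(alpha2) <= 1
  a1_max <- if (T1 > T2) asin(T2 / T1) else pi / 2
  f <- function(a1) {
    a2 <- asin(pmin(1, T1 * sin(a1) / T2))
    T1 * cos(a1) + T2 * cos(a2) - (T1 + T2 - S)
  }
  lo <- 1e-14
  hi <- a1_max - 1e-14
  if (f(hi) > 0) {
    return(full_zippering())
  }
  a1 <- stats::uniroot(f, c(lo, hi), tol = tol)$root
  a2 <- asin(min(1, T1 * sin(a1) / T2))
  structure(c(alpha1 = rad2deg(a1), alpha2 = rad2deg(a2)),
            residuals = c(longitudinal = f(a1),
                          transverse = T1 * sin(a1) - T2 * sin(a2)))
}

#' Configuration energy of a zipper
#'
#' Total tension/adhesion energy of the configuration,
#' `E = T1 (|VA| + |VC|) + T2 (|VB| + |VC|) - S |VC|`,
#' in internal units nN um (1 nN um = 1e-15 J). Tensions are treated as
#' constants independent of length (no Hookean elasticity within a
#' configuration) and bending energy is neglected.
#'
#' @param geom A [zipper_geometry()].
#' @param mech A [zipper_mechanics()].
#' @return Energy (nN um).
#' @export
config_energy <- function(geom, mech) {
  la <- vnorm(geom$A - geom$V)
  lb <- vnorm(geom$B - geom$V)
  lc <- vnorm(geom$C - geom$V)
  if (min(la, lb, lc) < 1e-9) {
    stop("degenerate geometry: zero-length segment", call. = FALSE)
  }
  mech$T1 * (la + lc) + mech$T2 * (lb + lc) - mech$S * lc
}

#' Conservative force on the zipper vertex
#'
#' Minus the gradient of [config_energy()] with respect to the vertex
#' position: `F = T1 a + T2 b + (T1 + T2 - S) c`, where `a`, `b`, `c` are
#' the unit vectors from V toward A, B and C. The last term contains the
#' adhesion contribution `-S c`, a force of magnitude S anti-parallel to
#' the zippered segment (pulling the vertex toward longer zippered length).
#'
#' @inheritParams config_energy
#' @return Numeric length-2 force vector (nN).
#' @export
vertex_force <- function(geom, mech) {
  a <- unit_vec(geom$V, geom$A)
  b <- unit_vec(geom$V, geom$B)
  cc <- unit_vec(geom$V, geom$C)
  mech$T1 * a + mech$T2 * b + (mech$T1 + mech$T2 - mech$S) * cc
}

#' Zipper angles of a geometry
#'
#' Angles between the free segments and the extension of the zipper axis
#' beyond the vertex. `beta = alpha1 + alpha2` is the full zipper angle.
#'
#' @inheritParams config_energy
#' @return Named vector `c(alpha1, alpha2, beta)` in degrees.
#' @export
zipper_angles_of <- function(geom) {
  axis_ext <- -unit_vec(geom$V, geom$C) # extension of zippered segment
  a <- unit_vec(geom$V, geom$A)
  b <- unit_vec(geom$V, geom$B)
  a1 <- acos(pmin(1, pmax(-1, sum(a * axis_ext))))
  a2 <- acos(pmin(1, pmax(-1, sum(b * axis_ext))))
  c(alpha1 = rad2deg(a1), alpha2 = rad2deg(a2), beta = rad2deg(a1 + a2))
}

#' Locate the equilibrium vertex position
#'
#' Minimizes the configuration energy over the vertex position by
#' derivative-based quasi-Newton descent (analytic gradient equal to minus
#' [vertex_force()]), started from a midpoint heuristic, then polished by
#' Newton iteration on the force residual. At the returned point the force
#' residual is below `tol` and the energy is a strict local minimum.
#'
#' Two boundary outcomes are flagged instead of an interior point: if the
#' adhesion is too weak to sustain a zippered wedge in this geometry, the
#' minimum sits at `V = C` (zero zippered length, straight-line
#' configuration) and `C` is returned with attribute `state =
#' "zero_zipper"`; if the adhesion drives the vertex to a straight
#' `A-V-B` configuration (zipper angle 180 degrees), the full-zippering
#' state is returned.
#'
#' @param A,B,C Fixed points (um); must not be collinear-degenerate.
#' @param mech A [zipper_mechanics()].
#' @param tol Force-residual tolerance (nN).
#' @return Numeric length-2 equilibrium vertex position `V*`, or the
#'   full-zippering state.
#' @export
find_equilibrium_vertex <- function(A, B, C, mech, tol = 1e-9) {
  cross <- (B[1] - A[1]) * (C[2] - A[2]) - (B[2] - A[2]) * (C[1] - A[1])
  if (abs(cross) < 1e-9) {
    stop("fixed points are collinear-degenerate", call. = FALSE)
  }
  mid <- (A + B) / 2
  v0 <- mid + 0.5 * (C - mid)
  dist_c <- function(v) vnorm(v - C)
  en <- function(v) {
    if (min(dist_c(v), vnorm(v - A), vnorm(v - B)) < 1e-6) {
      return(Inf)
    }
    config_energy(zipper_geometry(A, B, C, v), mech)
  }
  gr <- function(v) {
    if (min(vnorm(v - A), vnorm(v - B), vnorm(v - C)) < 1e-6) {
      return(c(0, 0)) # fn is Inf here; let the line search backtrack
    }
    -vertex_force(zipper_geometry(A, B, C, v), mech)
  }
  opt <- stats::optim(v0, en, gr, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 500))
  v <- opt$par
  scale <- vnorm(A - C) + vnorm(B - C)
  if (dist_c(v) < 1e-3 * scale) {
    # adhesion too weak for the geometry: the minimum sits at V = C, a
    # straight-line configuration with zero zippered length
    return(structure(C, state = "zero_zipper"))
  }
  if (zipper_angles_of(zipper_geometry(A, B, C, v))[["beta"]] > 179.5) {
    return(full_zippering())
  }
  # Newton polish on F(v) = 0 with finite-difference Jacobian
  h <- 1e-6
  for (i in 1:50) {
    f0 <- vertex_force(zipper_geometry(A, B, C, v), mech)
    if (vnorm(f0) < tol) break
    jx <- (vertex_force(zipper_geometry(A, B, C, v + c(h, 0)), mech) - f0) / h
    jy <- (vertex_force(zipper_geometry(A, B, C, v + c(0, h)), mech) - f0) / h
    J <- cbind(jx, jy)
    step <- tryCatch(solve(J, -f0), error = function(e) NULL)
    if (is.null(step)) break
    if (vnorm(step) > 0.1 * scale) step <- step * (0.1 * scale) / vnorm(step)
    v <- v + step
    if (dist_c(v) < 1e-3 * scale) {
      return(structure(C, state = "zero_zipper"))
    }
  }
  if (vnorm(vertex_force(zipper_geometry(A, B, C, v), mech)) > tol) {
    stop("equilibrium search did not converge", call. = FALSE)
  }
  v
}

#' Mean interior angle of a regular loop and loop stability
#'
#' A closed loop of `n` zippered segments has mean vertex angle
#' `(n - 2) * 180 / n` degrees (60 for a triangle, 90 for a rectangle).
#' A loop shrinks when the equilibrium zipper angle exceeds the current
#' angles at its vertices (all vertices advance synchronously), expands
#' when it is smaller, and is marginally stable at equality.
#'
#' @param n_sides Number of sides of the loop (>= 3).
#' @return Mean angle in degrees.
#' @export
loop_mean_angle <- function(n_sides) {
  if (n_sides < 3) stop("a loop needs at least 3 sides", call. = FALSE)
  (n_sides - 2) * 180 / n_sides
}

#' @rdname loop_mean_angle
#' @param current Current mean zipper angle at the loop vertices (degrees).
#' @param beta_eq Equilibrium zipper angle for the loop's axons (degrees).
#' @return `"shrink"`, `"expand"` or `"stable"`.
#' @export
classify_loop <- function(current, beta_eq) {
  if (beta_eq > current) "shrink" else if (beta_eq < current) "expand" else "stable"
}

#' Adhesion energy per unit membrane area
#'
#' Converts the adhesion force S (energy per unit zippered length) into an
#' adhesion energy per unit membrane area, assuming a fraction `f` of the
#' circumference of an axon of diameter `d` participates in the contact:
#' `density = S / (f * pi * d)`.
#'
#' @param S Adhesion force (pN).
#' @param d Axon diameter (um).
#' @param f Fraction of the circumference in contact, in (0, 1).
#' @return Energy density in J/um^2.
#' @export
adhesion_energy_density <- function(S, d, f) {
  if (f <= 0 || f >= 1) stop("contact fraction must lie in (0, 1)", call. = FALSE)
  if (S < 0 || d <= 0) stop("S must be >= 0 and d > 0", call. = FALSE)
  # pN/um = 1e-12 N / 1e-6 m = 1e-6 J/m^2 = 1e-18 J/um^2
  S / (f * pi * d) * 1e-18
}

#' Tension increase from axon stretch
#'
#' Linear-spring estimate of the tension increase produced by stretching an
#' axon: `delta_T = k * delta_L`, with `k` the axon elongation stiffness.
#'
#' @param stiffness Axon spring constant (pN/um).
#' @param stretch Imposed stretch (um).
#' @return Tension increase (pN).
#' @export
stretch_tension_increase <- function(stiffness, stretch) {
  if (stiffness < 0 || stretch < 0) stop("arguments must be non-negative", call. = FALSE)
  stiffness * stretch
}
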