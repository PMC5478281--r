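# Zipper dynamics: overdamped motion of the zipper vertex on the
# tension/adhesion energy landscape, F_v = H(x, y) u, where H is the
# (anisotropic, geometry-dependent) vertex friction tensor assembled from
# three dissipation mechanisms:
#   * elongation viscosity of the axons (strain-rate friction, eta_elong),
#   * vertex-localized friction acting along the zipper axis (eta_Z),
#   * substrate friction distributed along the segments (eta_par, eta_perp),
#     integrated with a linear velocity profile (zero at the fixed point,
#     vertex velocity at V) via the Rayleigh dissipation formalism.

#' Friction parameters
#'
#' The four dissipation constants selecting the dynamic regime.
#'
#' @param eta_elong Elongation viscosity (nN s): viscous axial stress is
#'   `eta_elong * Ldot / L` per axon, with L the axon's total free length.
#' @param eta_Z Vertex-localized friction constant (nN s / um;
#'   1 nN s / um = 1e-3 N s / m). Acts along the zipper axis only.
#' @param eta_par,eta_perp Substrate friction densities (Pa s) for element
#'   velocity components parallel and transverse to the segment.
#' @return An object of class `friction_params`.
#' @export
friction_params <- function(eta_elong = 0, eta_Z = 0,
                            eta_par = 0, eta_perp = 0) {
  vals <- c(eta_elong, eta_Z, eta_par, eta_perp)
  if (any(vals < 0)) stop("friction constants must be non-negative", call. = FALSE)
  if (all(vals == 0)) {
    stop("at least one friction constant must be positive", call. = FALSE)
  }
  structure(list(eta_elong = eta_elong, eta_Z = eta_Z,
                 eta_par = eta_par, eta_perp = eta_perp),
            class = "friction_params")
}

#' Zippering velocity of a symmetric zipper
#'
#' Closed-form equation of motion for a mirror-symmetric zipper with the
#' zippered segment along the advancing axis:
#' `ydot = (S - 2 T (1 - cos(beta/2))) /
#'         (2 eta_elong (cos(beta/2) - 1)^2 / L + eta_Z)`.
#' The sign of `ydot` equals the sign of the force imbalance
#' `S - 2T(1 - cos(beta/2))`; it vanishes exactly at the static
#' equilibrium angle.
#'
#' @param tension Effective tension T of each axon (nN).
#' @param adhesion Adhesion strength S (nN).
#' @param beta Current full zipper angle (degrees).
#' @param L Total free length of each axon (um).
#' @param eta_elong Elongation viscosity (nN s).
#' @param eta_Z Vertex friction (nN s / um).
#' @return Zippering velocity ydot (um/s); positive means advancing.
#' @export
symmetric_velocity <- function(tension, adhesion, beta, L,
                               eta_elong = 0, eta_Z = 0) {
  if (eta_elong == 0 && eta_Z == 0) {
    stop("undefined friction: eta_elong and eta_Z both zero", call. = FALSE)
  }
  ch <- cos(deg2rad(beta) / 2)
  denom <- 2 * eta_elong * (ch - 1)^2 / L + eta_Z
  (adhesion - 2 * tension * (1 - ch)) / denom
}

#' Assemble the vertex friction tensor
#'
#' Builds the 2x2 symmetric positive semidefinite friction tensor H such
#' that the conservative vertex force balances `H u` at vertex velocity
#' `u`. Contributions:
#' \itemize{
#'   \item vertex-localized: `eta_Z * c ct` with `c` the unit vector along
#'     the zipper axis (geometry-independent direction, rank 1);
#'   \item elongation: `(eta_elong / L1) (a + c)(a + c)t +
#'     (eta_elong / L2) (b + c)(b + c)t`, from the strain-rate force in
#'     each axon (`a`, `b`, `c` unit vectors from V toward A, B, C; L1, L2
#'     the total free lengths including the zippered segment);
#'   \item substrate: for each of the three segments, a linear velocity
#'     profile (zero at the fixed point, `u` at the vertex) integrates to
#'     `(len / 3) * (eta_par tt t + eta_perp (I - t tt))` with `t` the
#'     segment tangent; Pa s are converted to nN s / um^2 internally.
#' }
#'
#' @param geom A [zipper_geometry()].
#' @param friction A [friction_params()].
#' @return 2x2 symmetric matrix (nN s / um).
#' @export
assemble_friction_tensor <- function(geom, friction) {
  a <- unit_vec(geom$V, geom$A)
  b <- unit_vec(geom$V, geom$B)
  cc <- unit_vec(geom$V, geom$C)
  la <- vnorm(geom$A - geom$V)
  lb <- vnorm(geom$B - geom$V)
  lc <- vnorm(geom$C - geom$V)
  H <- matrix(0, 2, 2)
  if (friction$eta_Z > 0) {
    H <- H + friction$eta_Z * tcrossprod(cc)
  }
  if (friction$eta_elong > 0) {
    v1 <- a + cc
    v2 <- b + cc
    H <- H + friction$eta_elong / (la + lc) * tcrossprod(v1) +
      friction$eta_elong / (lb + lc) * tcrossprod(v2)
  }
  if (friction$eta_par > 0 || friction$eta_perp > 0) {
    ep <- friction$eta_par * az_units$nNs_um2_per_Pas
    et <- friction$eta_perp * az_units$nNs_um2_per_Pas
    I2 <- diag(2)
    for (seg in list(list(t = a, len = la), list(t = b, len = lb),
                     list(t = cc, len = lc))) {
      P <- tcrossprod(seg$t)
      H <- H + seg$len / 3 * (ep * P + et * (I2 - P))
    }
  }
  (H + t(H)) / 2
}

interp_protocol <- function(protocol, tt) {
  g <- function(col) {
    stats::approx(protocol$time, protocol[[col]], xout = tt, rule = 2)$y
  }
  zipper_mechanics(T1 = g("T1"), T2 = g("T2"), S = g("S"))
}

#' Simulate the overdamped motion of a zipper vertex
#'
#' Integrates `u = H^{-1} F_v` with an explicit adaptive step: the step is
#' rejected and `dt` halved whenever the configuration energy increases
#' while the mechanics are constant (the energy is a Lyapunov function of
#' the overdamped dynamics). Fixed points A, B, C are immobile and the
#' tensions are constant unless a protocol prescribes otherwise.
#'
#' When only `eta_Z` is positive the tensor is singular transverse to the
#' zipper axis; a small substrate friction of 1 Pa s is then added
#' automatically as regularization.
#'
#' @param geom Initial [zipper_geometry()].
#' @param mech A [zipper_mechanics()]; ignored if `protocol` is given.
#' @param friction A [friction_params()].
#' @param protocol Optional data frame with columns `time`, `T1`, `T2`,
#'   `S`; values are interpolated piecewise-linearly and held constant
#'   beyond the last row.
#' @param dt Base time step (s).
#' @param t_end End time (s).
#' @param stop_speed Convergence threshold on the vertex speed (um/s);
#'   integration stops early once the protocol (if any) has ended, the
#'   speed falls below this value and the force residual is below
#'   `force_tol`.
#' @param force_tol Convergence threshold on the force residual (nN).
#'   Once the mechanics are constant the step size is allowed to grow
#'   (energy-guarded), so convergence to this residual is cheap even for
#'   slow substrate-dominated dynamics.
#' @param record_every Record every n-th accepted step.
#' @return A data frame of class `vertex_trajectory` with columns `t`, `x`,
#'   `y`, `ux`, `uy`, `beta_deg`, `energy`, `zip_len`, and attributes
#'   `terminal` (one of `"converged"`, `"fully_zippered"`, `"detached"`,
#'   `"time_end"`) and `geom0`.
#' @export
simulate_zipper <- function(geom, mech = NULL, friction,
                            protocol = NULL, dt = 0.1, t_end = 600,
                            stop_speed = 1e-5, force_tol = 1e-8,
                            record_every = 1L) {
  if (is.null(mech) && is.null(protocol)) {
    stop("either mech or protocol must be supplied", call. = FALSE)
  }
  # without substrate friction the tensor can be singular (eta_Z only)
  # or arbitrarily ill-conditioned (eta_elong only, when the two strain
  # directions align); add a small 1 Pa s substrate term as regularization
  fr <- friction
  if (fr$eta_par == 0 && fr$eta_perp == 0) {
    fr <- friction_params(eta_elong = fr$eta_elong, eta_Z = fr$eta_Z,
                          eta_par = 1, eta_perp = 1)
  }
  A <- geom$A; B <- geom$B; C <- geom$C; V <- geom$V
  scale <- vnorm(A - C) + vnorm(B - C)
  proto_end <- if (is.null(protocol)) 0 else max(protocol$time)
  mech_at <- function(tt) {
    if (is.null(protocol)) mech else interp_protocol(protocol, tt)
  }
  tt <- 0
  dt_grow <- dt
  terminal <- "time_end"
  nmax <- ceiling(t_end / dt) * 4L + 16L
  rec <- matrix(NA_real_, nrow = min(nmax, 2e6), ncol = 8)
  colnames(rec) <- c("t", "x", "y", "ux", "uy", "beta_deg", "energy", "zip_len")
  k <- 0L
  step_i <- 0L
  push <- function(u, m) {
    g <- zipper_geometry(A, B, C, V)
    k <<- k + 1L
    if (k > nrow(rec)) rec <<- rbind(rec, matrix(NA_real_, nrow(rec), 8))
    rec[k, ] <<- c(tt, V[1], V[2], u[1], u[2],
                   zipper_angles_of(g)[["beta"]], config_energy(g, m),
                   vnorm(V - C))
  }
  m <- mech_at(0)
  push(c(0, 0), m)
  while (tt < t_end) {
    m <- mech_at(tt)
    g <- zipper_geometry(A, B, C, V)
    f <- vertex_force(g, m)
    H <- assemble_friction_tensor(g, fr)
    u <- solve(H, f)
    spd <- vnorm(u)
    if (spd < stop_speed && tt >= proto_end) {
      # the overdamped flow converges to the unique nearby minimum; the
      # residual motion is below any measurable displacement, so finish
      # with a Newton snap onto the exact equilibrium
      vstar <- tryCatch(find_equilibrium_vertex(A, B, C, m, tol = force_tol),
                        error = function(e) NULL)
      if (!is.null(vstar) && !is_full_zippering(vstar) &&
          is.null(attr(vstar, "state")) && vnorm(vstar - V) < 0.05) {
        V <- vstar
      }
      terminal <- "converged"
      push(u, m)
      break
    }
    mech_const <- is.null(protocol) || tt >= proto_end
    # cap displacement per step for stability; once the mechanics are
    # constant the (energy-guarded) step may grow geometrically
    dt_base <- if (mech_const) dt_grow else dt
    dt_cur <- min(dt_base, t_end - tt, if (spd > 0) 0.2 / spd else dt_base)
    e0 <- config_energy(g, m)
    f0n <- vnorm(f)
    halved <- FALSE
    repeat {
      Vp <- V + u * dt_cur
      ok <- TRUE
      if (vnorm(Vp - C) < 1e-6 * scale) {
        V <- Vp
        terminal <- "detached" # zippered length exhausted: axons separate
        break
      }
      gp <- zipper_geometry(A, B, C, Vp)
      ep <- config_energy(gp, m)
      if (mech_const && ep > e0 + 1e-12 * abs(e0)) {
        dt_cur <- dt_cur / 2
        halved <- TRUE
        if (dt_cur < 1e-9) { # cannot make progress downhill
          ok <- FALSE
          terminal <- "converged"
          break
        }
        next
      }
      V <- Vp
      break
    }
    if (mech_const) {
      dt_grow <- if (halved) max(dt, dt_cur) else min(dt_grow * 1.5, 1e4 * dt)
    }
    if (terminal == "detached") {
      tt <- tt + dt_cur
      push(u, m)
      break
    }
    if (!isTRUE(ok)) { # energy-guard stall: snap to the minimum if close
      vstar <- tryCatch(find_equilibrium_vertex(A, B, C, m, tol = force_tol),
                        error = function(e) NULL)
      if (!is.null(vstar) && !is_full_zippering(vstar) &&
          is.null(attr(vstar, "state")) && vnorm(vstar - V) < 0.05) {
        V <- vstar
      }
      push(u, m)
      break
    }
    tt <- tt + dt_cur
    step_i <- step_i + 1L
    if (vnorm(V - C) < 0.01 * scale) {
      terminal <- "detached"
      push(u, m)
      break
    }
    bet <- zipper_angles_of(zipper_geometry(A, B, C, V))[["beta"]]
    if (bet >= 179.9) {
      terminal <- "fully_zippered"
      push(u, m)
      break
    }
    if (step_i %% record_every == 0L || tt >= t_end) push(u, m)
  }
  out <- as.data.frame(rec[seq_len(k), , drop = FALSE])
  attr(out, "terminal") <- terminal
  attr(out, "geom0") <- geom
  attr(out, "friction") <- fr
  class(out) <- c("vertex_trajectory", class(out))
  out
}

gauss_kernel <- function(dt_grid, half_width) {
  w <- exp(-dt_grid^2 / (2 * half_width^2))
  w / sum(w)
}

#' Fit zippering velocity against the angle term
#'
#' Ordinary least squares of the smoothed zippering velocity `u_Z` (time
#' derivative of the zippered length) against `1 - cos(beta/2)`. The angle
#' series is smoothed with a Gaussian kernel of the given half-width and
#' the velocity is obtained by convolving the zippered-length series with
#' the derivative of the same kernel. Under vertex-dominated friction the
#' symmetric equation of motion predicts slope `-2 T / eta_Z` and
#' intercept `S / eta_Z`; with appreciable elongation viscosity the
#' relation is curved and the reported R^2 drops accordingly (the model
#' mismatch is reported, not corrected).
#'
#' @param traj A `vertex_trajectory` (or any data frame with columns `t`,
#'   `zip_len`, `beta_deg`).
#' @param half_width Gaussian smoothing half-width (s).
#' @return List with `slope`, `intercept`, `r_squared`, and the smoothed
#'   series (`phi` = 1 - cos(beta/2), `velocity`).
#' @export
fit_velocity_vs_angle <- function(traj, half_width = 10) {
  t_raw <- traj$t
  if (length(t_raw) < 10) stop("need at least 10 samples", call. = FALSE)
  dt <- stats::median(diff(t_raw))
  tg <- seq(min(t_raw), max(t_raw), by = dt)
  z <- stats::approx(t_raw, traj$zip_len, xout = tg)$y
  b <- stats::approx(t_raw, traj$beta_deg, xout = tg)$y
  n <- length(tg)
  hw_n <- max(1L, round(half_width / dt))
  idx <- seq(-3L * hw_n, 3L * hw_n)
  g <- gauss_kernel(idx * dt, half_width)
  dg <- -(idx * dt) / half_width^2 * g # derivative of the Gaussian kernel
  interior <- seq(3L * hw_n + 1L, n - 3L * hw_n)
  if (length(interior) < 10) stop("need at least 10 samples after smoothing", call. = FALSE)
  b_s <- vapply(interior, function(i) sum(g * b[i + idx]), numeric(1))
  # (z * g)'(t): convolution with the kernel derivative
  u_s <- vapply(interior, function(i) -sum(dg * z[i + idx]), numeric(1))
  phi <- 1 - cos(deg2rad(b_s) / 2)
  if (stats::var(phi) < 1e-18) {
    stop("degenerate abscissa: no variance in the angle term", call. = FALSE)
  }
  fit <- stats::lm(u_s ~ phi)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       phi = phi, velocity = u_s)
}

#' Adhesion-to-tension ratio from a velocity-angle fit
#'
#' Under vertex-dominated friction the linear fit of `u_Z` against
#' `1 - cos(beta/2)` has slope `-2T/eta_Z` and intercept `S/eta_Z`, so
#' `S / T = 2 |intercept / slope|`.
#'
#' @param slope Fitted slope (um/s); must be negative.
#' @param intercept Fitted intercept (um/s).
#' @return Dimensionless ratio S/T.
#' @export
infer_st_ratio <- function(slope, intercept) {
  if (slope >= 0) stop("unphysical fit: slope must be negative", call. = FALSE)
  2 * abs(intercept / slope)
}

#' Vertex friction constant from a velocity-angle fit
#'
#' `eta_Z = 2 T / |slope|`.
#'
#' @param slope Fitted slope (um/s); must be negative.
#' @param tension Axon tension T (nN).
#' @return `eta_Z` in nN s / um (multiply by 1e-3 for N s / m).
#' @export
infer_eta_z <- function(slope, tension) {
  if (slope >= 0) stop("unphysical fit: slope must be negative", call. = FALSE)
  2 * tension / abs(slope)
}

#' Rate of energy dissipation at a moving vertex
#'
#' `P = eta_Z * u^2`, reported in J/min.
#'
#' @param eta_Z Vertex friction constant (nN s / um).
#' @param u Vertex speed (um/min).
#' @return Dissipated power (J/min).
#' @export
dissipation_rate <- function(eta_Z, u) {
  if (eta_Z < 0) stop("eta_Z must be non-negative", call. = FALSE)
  u_s <- u / az_units$s_per_min # um/s
  p_int <- eta_Z * u_s^2 # nN um / s
  p_int * az_units$J_per_nN_um * az_units$s_per_min
}
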