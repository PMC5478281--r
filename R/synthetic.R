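# Seeded synthetic-data generators. These emulate the statistical
# structure of the microscopy and probe recordings that the analysis
# modules consume: lognormal single-axon tensions, equilibrium zipper
# angles with measurement noise, BFP force staircases with angle and
# bead-tracking noise, and coarsening/stable/de-coarsening sequences of
# segmented planar networks. One seeded PRNG stream per generator call;
# identical spec gives identical output.

#' Generator specification
#'
#' @param seed Integer seed for the generator's PRNG stream.
#' @param scenario Scenario preset name (generator-specific).
#' @param ... Parameter overrides stored alongside.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L, scenario = "default", ...) {
  structure(list(seed = as.integer(seed), scenario = scenario,
                 overrides = list(...)),
            class = "generator_spec")
}

spec_par <- function(spec, name, default) {
  spec$overrides[[name]] %||% default
}

#' Generate tension and equilibrium-angle samples
#'
#' Tensions are drawn from a lognormal with the requested mean and sd
#' (default: the measured single-axon population, mean 0.68 nN, sd
#' 0.25 nN). Equilibrium angles are generated by drawing further tensions
#' from the same law, mapping each through the symmetric equilibrium
#' condition with the planted adhesion `S`, and adding Gaussian
#' measurement noise. Default sample sizes (7 tensions, 34 angle
#' measurements) mirror the experimental study; both scale.
#'
#' @param spec A [generator_spec()]. Recognized overrides: `n_tension`,
#'   `n_angle`, `T_mean`, `T_sd`, `S`, `angle_noise_sd` (deg).
#' @return List with `tensions` (nN), `angles` (deg), `S` (the planted
#'   adhesion, nN) and `spec`.
#' @export
gen_tension_and_angle_samples <- function(spec = generator_spec()) {
  set.seed(spec$seed)
  n_t <- spec_par(spec, "n_tension", 7L)
  n_a <- spec_par(spec, "n_angle", 34L)
  T_mean <- spec_par(spec, "T_mean", 0.68)
  T_sd <- spec_par(spec, "T_sd", 0.25)
  S <- spec_par(spec, "S", 0.17)
  noise <- spec_par(spec, "angle_noise_sd", 3)
  par <- lognormal_from_moments(T_mean, T_sd)
  tensions <- stats::rlnorm(n_t, par$meanlog, par$sdlog)
  t_ang <- stats::rlnorm(n_a, par$meanlog, par$sdlog)
  t_ang <- pmax(t_ang, S / 2 + 1e-6) # stay on the open-zipper branch
  beta <- rad2deg(2 * acos(1 - S / (2 * t_ang)))
  beta <- beta + stats::rnorm(n_a, 0, noise)
  beta <- pmin(179.9, pmax(0.1, beta))
  list(tensions = tensions, angles = beta, S = S, spec = spec)
}

#' Generate a synthetic BFP recording
#'
#' A staircase of pulling plateaux: the pipette is stepped to increasing
#' deflection angles (up to ~5 degrees, where the bead typically detaches)
#' and held; at each plateau the transverse probe force balances the
#' tension projection `2 T sin(delta)` plus a calibration offset. Noise
#' model: per-frame deflection-angle noise (default sd 0.5 deg) and probe
#' force noise equal to the stiffness times the bead-tracking error
#' (default sd 0.02 um within the documented 10-50 nm band; see the
#' methods vignette for the choice).
#'
#' @param spec A [generator_spec()].
#' @param T_true Planted axon tension (pN).
#' @param k Probe stiffness (pN/um).
#' @param n_plateaux Number of plateaux (>= 3).
#' @param plateau_duration,ramp_duration Seconds per plateau / ramp.
#' @param fps Frame rate (default 65).
#' @param angle_noise_sd Deflection noise per frame (deg).
#' @param tracking_noise Bead tracking error (um).
#' @param phi Pipette-axon angle (deg).
#' @param intercept Calibration offset of the transverse force (pN).
#' @param k_error_sd Relative error of the assumed probe stiffness
#'   (default 0.14, the method's stated calibration uncertainty); drawn
#'   once per recording, it scales every reported force.
#' @return A [bfp_recording()] with attribute `truth` (list with the
#'   planted tension and plateau schedule).
#' @export
gen_bfp_recording <- function(spec = generator_spec(), T_true = 680, k = 200,
                              n_plateaux = 5, plateau_duration = 6,
                              ramp_duration = 1, fps = 65,
                              angle_noise_sd = 0.5, tracking_noise = 0.02,
                              phi = 90, intercept = 15, k_error_sd = 0.14) {
  set.seed(spec$seed)
  k_factor <- 1 + stats::rnorm(1, 0, k_error_sd)
  if (n_plateaux < 3) stop("need at least 3 plateaux", call. = FALSE)
  delta_levels <- seq(1, 5, length.out = n_plateaux)
  # piecewise schedule: ramp to level, hold
  t_knots <- c(0)
  d_knots <- c(0)
  for (i in seq_len(n_plateaux)) {
    t_knots <- c(t_knots, t_knots[length(t_knots)] + ramp_duration,
                 t_knots[length(t_knots)] + ramp_duration + plateau_duration)
    d_knots <- c(d_knots, delta_levels[i], delta_levels[i])
  }
  tt <- seq(0, max(t_knots), by = 1 / fps)
  delta_true <- stats::approx(t_knots, d_knots, xout = tt)$y
  f_perp_true <- 2 * T_true * sin(deg2rad(delta_true)) + intercept
  force <- k_factor * f_perp_true / sin(deg2rad(phi)) +
    stats::rnorm(length(tt), 0, k * tracking_noise)
  delta_obs <- delta_true + stats::rnorm(length(tt), 0, angle_noise_sd)
  delta_obs <- pmin(89.9, pmax(-89.9, delta_obs))
  rec <- bfp_recording(tt, force, delta_obs, phi)
  plateau_sched <- data.frame(
    level = delta_levels,
    t_start = t_knots[seq(2, length(t_knots) - 1, by = 2)],
    t_end = t_knots[seq(3, length(t_knots), by = 2)]
  )
  attr(rec, "truth") <- list(T_true = T_true, intercept = intercept,
                             plateaux = plateau_sched, k = k,
                             k_factor = k_factor)
  rec
}

# ---- synthetic network sequences ----------------------------------------

# Internal state of one symmetric zipper motif: fixed anchor C0, axis
# direction, zippered length z (vertex at C0 + z * axis), arm budget a0
# (free arm length is a0 - z), full angle beta set per frame.
motif_polylines <- function(m, beta_deg) {
  axis <- m$axis
  V <- m$C0 + m$z * axis
  half <- deg2rad(beta_deg) / 2
  rot <- function(v, th) c(cos(th) * v[1] - sin(th) * v[2],
                           sin(th) * v[1] + cos(th) * v[2])
  arm <- m$a0 - m$z
  A <- V + arm * rot(axis, half)
  B <- V + arm * rot(axis, -half)
  list(rbind(A, V), rbind(B, V), rbind(V, m$C0))
}

triangle_polylines <- function(tr, beta_deg = 60) {
  ths <- tr$orient + c(0, 2, 4) * pi / 3
  corners <- t(vapply(ths, function(th) tr$center + tr$s * c(cos(th), sin(th)),
                      numeric(2)))
  if (tr$collapsed) {
    # the collapsed loop is now a single fascicle zipper junction: two
    # free arms separated by the planted equilibrium angle, the zippered
    # arm opposite their bisector
    half <- deg2rad(beta_deg) / 2
    dirs <- list(c(cos(tr$orient + half), sin(tr$orient + half)),
                 c(cos(tr$orient - half), sin(tr$orient - half)),
                 c(cos(tr$orient + pi), sin(tr$orient + pi)))
    return(lapply(dirs, function(dirv) {
      rbind(tr$center + tr$arm * dirv, tr$center)
    }))
  }
  sides <- lapply(seq_len(3), function(i) {
    rbind(corners[i, ], corners[if (i == 3) 1 else i + 1, ])
  })
  arms <- lapply(seq_len(3), function(i) {
    dirv <- c(cos(ths[i]), sin(ths[i]))
    rbind(corners[i, ] + tr$arm * dirv, corners[i, ])
  })
  c(sides, arms)
}

#' Generate a coarsening (or stable / de-coarsening) network sequence
#'
#' Builds a field of independent symmetric zipper motifs, a few triangular
#' loops and axon crossings, and evolves them over time with the
#' separation of time scales observed in developing networks: individual
#' zippering events are minutes-long transients during which the vertex
#' advances at an approximately constant speed in the observed band
#' (0.3-2 um/min, the near-constant-velocity regime of the equation of
#' motion under gradual forcing), while the angle population tracks the
#' quasi-static equilibrium law for fascicle parameters rescaled with the
#' running mean fascicle size `n(t) = L(0) / L(t)`.
#'
#' Scenario presets: `"coarsening"` (zippering events dominate; total
#' length decays by ~20 percent over 3 h and triangular loops shrink and
#' collapse, each collapse removing two junctions), `"stable"` (no events;
#' angles sit exactly on the planted equilibrium law), `"decoarsen"`
#' (after the onset time, un-zippering events lengthen the network;
#' entangled motifs - default fraction 28 percent - are blocked from
#' receding).
#'
#' @param spec A [generator_spec()] with `scenario` one of `"coarsening"`,
#'   `"stable"`, `"decoarsen"`. Recognized overrides: `n_motifs`,
#'   `n_triangles`, `n_crossings`, `duration_min`, `cadence_min`,
#'   `T_mean`, `T_sd`, `S`, `event_rate` (events per motif per min),
#'   `entangled_fraction`, `onset_min` (decoarsen).
#' @return List of [network_frame()] objects (one per frame) with
#'   attribute `manifest`: planted parameters, per-motif base tensions,
#'   the event table with planted speeds, and the per-frame zippered
#'   lengths and angles.
#' @export
gen_network_sequence <- function(spec = generator_spec(scenario = "coarsening")) {
  set.seed(spec$seed)
  scen <- spec$scenario
  if (!scen %in% c("coarsening", "stable", "decoarsen")) {
    stop("unknown scenario: ", scen, call. = FALSE)
  }
  n_m <- spec_par(spec, "n_motifs", 32L)
  n_tr <- spec_par(spec, "n_triangles", if (scen == "coarsening") 3L else 0L)
  n_cr <- spec_par(spec, "n_crossings", 4L)
  dur <- spec_par(spec, "duration_min", 180)
  cad <- spec_par(spec, "cadence_min", 1)
  T_mean <- spec_par(spec, "T_mean", 0.68)
  T_sd <- spec_par(spec, "T_sd", 0.25)
  S0 <- spec_par(spec, "S", 0.17)
  ev_rate <- spec_par(spec, "event_rate", 1 / 70)
  ent_frac <- spec_par(spec, "entangled_fraction", 0.28)
  onset <- spec_par(spec, "onset_min", 60)

  par <- lognormal_from_moments(T_mean, T_sd)
  # motif layout on a jittered grid, spacing large enough that motifs
  # never snap together
  ncol_grid <- ceiling(sqrt(n_m))
  centers <- t(vapply(seq_len(n_m) - 1L, function(i) {
    c((i %% ncol_grid) * 70, (i %/% ncol_grid) * 70) + stats::runif(2, -8, 8)
  }, numeric(2)))
  motifs <- lapply(seq_len(n_m), function(i) {
    th <- stats::runif(1, 0, 2 * pi)
    list(C0 = centers[i, ], axis = c(cos(th), sin(th)),
         a0 = stats::runif(1, 22, 28), z = stats::runif(1, 4, 8),
         T_base = pmax(S0 / 2 + 0.05, stats::rlnorm(1, par$meanlog, par$sdlog)),
         S_base = S0,
         entangled = stats::runif(1) < ent_frac)
  })
  # per-motif event table: start, duration, speed (um/min), direction
  events <- NULL
  if (scen != "stable") {
    for (i in seq_len(n_m)) {
      t0 <- if (scen == "decoarsen") onset else 0
      tt <- t0 + stats::rexp(1, ev_rate)
      while (tt < dur) {
        dd <- stats::runif(1, 3, 6)
        sp <- stats::runif(1, 0.35, 1.9)
        events <- rbind(events, data.frame(
          motif = i, t_start = floor(tt), duration = round(dd), speed = sp,
          direction = if (scen == "coarsening") 1 else -1))
        tt <- tt + dd + stats::rexp(1, ev_rate)
      }
    }
  }
  triangles <- lapply(seq_len(n_tr), function(j) {
    list(center = c(-90, (j - 1) * 90) + stats::runif(2, -5, 5),
         orient = stats::runif(1, 0, 2 * pi),
         s = stats::runif(1, 7, 10), arm = 10,
         shrink_rate = stats::runif(1, 0.35, 1.0) / sqrt(3), # corner speed in band
         T_base = pmax(S0 / 2 + 0.05, stats::rlnorm(1, par$meanlog, par$sdlog)),
         collapsed = FALSE)
  })
  crossings <- lapply(seq_len(n_cr), function(j) {
    ctr <- c(220 + 40 * ((j - 1) %% 2), 40 + 80 * ((j - 1) %/% 2))
    th1 <- stats::runif(1, 0, pi)
    th2 <- th1 + stats::runif(1, pi / 3, 2 * pi / 3)
    lapply(c(th1, th2), function(th) {
      d <- c(cos(th), sin(th))
      m <- rbind(ctr - 15 * d, ctr + 15 * d)
      attr(m, "kind") <- "crossing"
      m
    })
  })

  frame_times <- seq(0, dur, by = cad)
  minutes <- seq_len(max(1, round(dur))) # event integration at 1-min steps
  # integrate zippered lengths minute by minute
  zmat <- matrix(NA_real_, nrow = n_m, ncol = length(frame_times))
  z_cur <- vapply(motifs, function(m) m$z, numeric(1))
  a0 <- vapply(motifs, function(m) m$a0, numeric(1))
  ent <- vapply(motifs, function(m) m$entangled, logical(1))
  smat <- matrix(NA_real_, nrow = n_tr, ncol = length(frame_times))
  s_cur <- vapply(triangles, function(tr) tr$s, numeric(1))
  collapsed <- rep(FALSE, n_tr)
  col_frame <- rep(NA_integer_, n_tr)
  fi <- 1L
  record <- function(minute_now) {
    while (fi <= length(frame_times) && frame_times[fi] <= minute_now + 1e-9) {
      zmat[, fi] <<- z_cur
      if (n_tr) smat[, fi] <<- s_cur
      fi <<- fi + 1L
    }
  }
  record(0)
  for (mn in minutes) {
    if (!is.null(events)) {
      act <- events[events$t_start < mn & (events$t_start + events$duration) >= mn, ]
      if (nrow(act)) {
        for (r in seq_len(nrow(act))) {
          i <- act$motif[r]
          dz <- act$speed[r] * act$direction[r]
          if (dz < 0 && ent[i]) next # entangled zippers cannot recede
          z_cur[i] <- min(max(z_cur[i] + dz, 1), 0.75 * a0[i])
        }
      }
    }
    if (n_tr && scen == "coarsening") {
      for (j in seq_len(n_tr)) {
        if (collapsed[j]) next
        s_cur[j] <- s_cur[j] - triangles[[j]]$shrink_rate
        if (s_cur[j] < 2) {
          collapsed[j] <- TRUE
          s_cur[j] <- 0
        }
      }
    }
    record(mn)
  }
  # frame-wise total length (motifs: 2*(a0 - z) + z = 2 a0 - z)
  tri_len <- function(s, collapsed) {
    if (collapsed) 3 * 10 else 3 * sqrt(3) * s + 3 * 10
  }
  frames <- vector("list", length(frame_times))
  L0 <- NULL
  angmat <- matrix(NA_real_, nrow = n_m, ncol = length(frame_times))
  for (f in seq_along(frame_times)) {
    z <- zmat[, f]
    L_mot <- sum(2 * a0 - z)
    L_tri <- if (n_tr) sum(vapply(seq_len(n_tr), function(j) {
      tri_len(smat[j, f], smat[j, f] <= 0)
    }, numeric(1))) else 0
    L_cross <- 30 * 2 * n_cr
    L_tot <- L_mot + L_tri + L_cross
    if (is.null(L0)) L0 <- L_tot
    n_fas <- max(1, L0 / L_tot)
    pls <- list()
    for (i in seq_len(n_m)) {
      Ti <- n_fas * motifs[[i]]$T_base
      Si <- sqrt(n_fas) * motifs[[i]]$S_base
      beta <- equilibrium_angle_symmetric(Ti, Si)
      if (is_full_zippering(beta)) beta <- 179
      angmat[i, f] <- beta
      m <- motifs[[i]]
      m$z <- z[i]
      pls <- c(pls, motif_polylines(m, beta))
    }
    if (n_tr) {
      for (j in seq_len(n_tr)) {
        tr <- triangles[[j]]
        tr$s <- max(smat[j, f], 0)
        tr$collapsed <- smat[j, f] <= 0
        bt <- equilibrium_angle_symmetric(n_fas * tr$T_base,
                                          sqrt(n_fas) * S0)
        if (is_full_zippering(bt)) bt <- 179
        pls <- c(pls, triangle_polylines(tr, beta_deg = bt))
      }
    }
    for (cr in crossings) pls <- c(pls, cr)
    frames[[f]] <- network_frame(pls, timestamp = frame_times[f],
                                 snap_tol = 0.5)
  }
  attr(frames, "manifest") <- list(
    spec = spec, scenario = scen,
    T_base = vapply(motifs, function(m) m$T_base, numeric(1)),
    S = S0, entangled = ent, events = events,
    frame_times = frame_times, zip_lengths = zmat, angles = angmat,
    triangle_sides = if (n_tr) smat else NULL)
  frames
}
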