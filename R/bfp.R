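# Biomembrane Force Probe (BFP) analysis. A red blood cell aspirated in a
# micropipette acts as a calibrated linear spring loading a bead attached
# to an axon. Holding the pipette fixed produces force plateaux; the
# per-plateau averages of the transverse probe force and of sin(delta)
# (delta = axon deflection angle) fall on a line of slope 2T, giving the
# axon tension T.

#' BFP probe and its spring constant
#'
#' Probe geometry and aspiration pressure. Within the working range the
#' aspirated red blood cell behaves as a linear spring of stiffness
#' `k = Rp dP pi (1 - rp) / (ln(4 / (rp rc)) - (1 - rp/4 - 3 rp^2/8 + rc^2))`
#' where `rp = Rp/R0` and `rc = Rc/R0` are the pipette and bead-contact
#' radii scaled by the unstrained aspirated cell radius. The grouping of
#' the logarithm's argument follows the reading under which the documented
#' probe parameter ranges produce stiffnesses in the stated working band
#' (about 100-400 pN/um); see the methods vignette.
#'
#' @param Rp Internal pipette radius (um), 0 < Rp < R0.
#' @param Rc Radius of the cell-bead contact (um), 0 < Rc < R0.
#' @param R0 Radius of the unstrained aspirated cell (um).
#' @param dP Aspiration pressure (Pa).
#' @return An object of class `bfp_probe` with the derived stiffness `k`
#'   (pN/um).
#' @export
bfp_probe <- function(Rp, Rc, R0, dP) {
  if (!(Rp > 0 && Rp < R0)) stop("require 0 < Rp < R0", call. = FALSE)
  if (!(Rc > 0 && Rc < R0)) stop("require 0 < Rc < R0", call. = FALSE)
  if (dP <= 0) stop("aspiration pressure must be positive", call. = FALSE)
  p <- structure(list(Rp = Rp, Rc = Rc, R0 = R0, dP = dP,
                      rp = Rp / R0, rc = Rc / R0),
                 class = "bfp_probe")
  p$k <- probe_stiffness(p)
  p
}

#' @rdname bfp_probe
#' @param probe A `bfp_probe`.
#' @return `probe_stiffness`: the spring constant k (pN/um), strictly
#'   linear in `dP`.
#' @export
probe_stiffness <- function(probe) {
  rp <- probe$rp
  rc <- probe$rc
  denom <- log(4 / (rp * rc)) - (1 - rp / 4 - 3 * rp^2 / 8 + rc^2)
  if (denom <= 0) stop("invalid probe geometry: non-positive denominator", call. = FALSE)
  # Rp [um] * dP [Pa] = 1e-6 N/m = pN/um, so the units come out directly
  probe$Rp * probe$dP * pi * (1 - rp) / denom
}

#' BFP recording
#'
#' Time series of the probe force and the axon deflection geometry.
#' `delta` is the axon deflection angle in degrees, signed: negative
#' values correspond to deflection by pushing. `phi` is the angle between
#' the pipette axis and the axon (degrees); the transverse probe force is
#' `force * sin(phi)`.
#'
#' @param time Frame times (s), strictly increasing.
#' @param force Probe force (pN).
#' @param delta Deflection angle (degrees), |delta| < 90.
#' @param phi Pipette-axon angle (degrees); recycled if scalar.
#' @return A data frame of class `bfp_recording`.
#' @export
bfp_recording <- function(time, force, delta, phi = 90) {
  if (is.unsorted(time, strictly = TRUE)) {
    stop("time must be strictly increasing", call. = FALSE)
  }
  if (any(abs(delta) >= 90)) stop("|delta| must be < 90 degrees", call. = FALSE)
  out <- data.frame(time = time, force = force, delta = delta,
                    phi = rep_len(phi, length(time)))
  class(out) <- c("bfp_recording", class(out))
  out
}

rolling_sd <- function(x, w) {
  n <- length(x)
  half <- w %/% 2
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  cnt <- hi - lo + 1
  m <- (cs[hi + 1] - cs[lo]) / cnt
  v <- (cs2[hi + 1] - cs2[lo]) / cnt - m^2
  sqrt(pmax(0, v) * cnt / pmax(1, cnt - 1))
}

#' Detect force plateaux in a BFP recording
#'
#' Flags the frames whose windowed force standard deviation falls below a
#' threshold and returns the disjoint, ordered runs longer than the
#' minimal duration. These are the intervals during which the pipette was
#' held fixed.
#'
#' Because the rolling window straddles the plateau edges, the raw
#' below-threshold runs under-cover each plateau by about half a window on
#' each side; a second pass therefore expands every run outward, frame by
#' frame, while the force stays consistent with the plateau mean (within
#' three noise standard deviations, with a short run of consecutive
#' outliers required to stop), never crossing the midpoint of the gap to
#' the neighbouring run.
#'
#' @param rec A [bfp_recording()].
#' @param window Rolling window (s) for the force standard deviation.
#' @param sd_threshold Plateau threshold on the windowed sd (pN).
#' @param min_duration Minimal plateau duration (s).
#' @return Data frame with one row per plateau: `start`, `end` (frame
#'   indices), `t_start`, `t_end`, `duration` (s). May have zero rows.
#' @export
detect_plateaux <- function(rec, window = 2, sd_threshold = 5,
                            min_duration = 3) {
  dt <- stats::median(diff(rec$time))
  if ((max(rec$time) - min(rec$time)) <= min_duration) {
    stop("recording shorter than min_duration", call. = FALSE)
  }
  w <- max(3L, round(window / dt))
  s <- rolling_sd(rec$force, w)
  flat <- s < sd_threshold
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(start = starts[keep], end = ends[keep])
  out <- out[out$end - out$start + 1L >= w, , drop = FALSE]
  if (nrow(out)) out <- expand_plateaux(rec$force, out, s)
  if (nrow(out)) {
    out$t_start <- rec$time[out$start]
    out$t_end <- rec$time[out$end]
    out$duration <- out$t_end - out$t_start
    out <- out[out$duration >= min_duration, , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out$t_start <- out$t_end <- out$duration <- numeric(0)
  }
  out
}

# Grow each detected run outward while the force remains consistent with
# the run's plateau level. A stop requires `m_stop` consecutive frames
# deviating by more than 3 noise sd, which makes the expansion robust to
# single-frame outliers; those trailing outliers are then trimmed off.
expand_plateaux <- function(force, runs, wsd, m_stop = 5L) {
  n <- length(force)
  runs <- runs[order(runs$start), , drop = FALSE]
  nr <- nrow(runs)
  for (i in seq_len(nr)) {
    idx <- runs$start[i]:runs$end[i]
    mu <- stats::median(force[idx])
    noise <- max(1e-9, stats::median(wsd[idx]))
    thr <- 3 * noise
    lo_lim <- if (i == 1) 1L else floor((runs$end[i - 1] + runs$start[i]) / 2) + 1L
    hi_lim <- if (i == nr) n else floor((runs$end[i] + runs$start[i + 1]) / 2)
    grow <- function(pos, step, lim) {
      bad <- 0L
      while ((step > 0 && pos < lim) || (step < 0 && pos > lim)) {
        nxt <- pos + step
        if (abs(force[nxt] - mu) > thr) {
          bad <- bad + 1L
          if (bad >= m_stop) return(pos - step * m_stop)
        } else {
          bad <- 0L
        }
        pos <- nxt
      }
      pos - step * bad
    }
    runs$start[i] <- grow(runs$start[i], -1L, lo_lim)
    runs$end[i] <- grow(runs$end[i], 1L, hi_lim)
  }
  runs
}

#' Axon tension from plateau regression
#'
#' Summarizes each plateau by the means of `sin(delta)` and of the
#' transverse probe force `F sin(phi)`, then fits the transverse force
#' against `sin(delta)` by ordinary least squares with a free intercept.
#' The slope equals `2 T`; a non-zero intercept absorbs the calibration
#' offset of the unstrained probe length and does not affect the tension.
#' Pushing plateaux (mean `delta < 0`) are excluded by default.
#'
#' The reported uncertainty `T_sd` combines the regression slope standard
#' deviation with the systematic probe-stiffness calibration error (the
#' dominant stated uncertainty of the method, about 14 percent relative,
#' which scales every force and hence the fitted tension):
#' `T_sd^2 = (slope_sd/2)^2 + (k_uncertainty * T)^2`.
#'
#' @param rec A [bfp_recording()].
#' @param plateaux Output of [detect_plateaux()]; computed if missing.
#' @param exclude_pushing Drop plateaux with mean delta < 0 (default TRUE).
#' @param k_uncertainty Relative probe-stiffness calibration uncertainty
#'   folded into `T_sd` (default 0.14; set 0 for the bare regression sd).
#' @param ... Passed on to [detect_plateaux()] when `plateaux` is missing.
#' @return An object of class `tension_estimate`: list with `T_mean` and
#'   `T_sd` (pN), `slope`, `intercept`, `slope_sd`, `r_squared`, and the
#'   per-plateau summary table `plateaux`.
#' @export
fit_tension <- function(rec, plateaux = NULL, exclude_pushing = TRUE,
                        k_uncertainty = 0.14, ...) {
  if (is.null(plateaux)) plateaux <- detect_plateaux(rec, ...)
  if (nrow(plateaux) < 3) {
    stop("insufficient data: need at least 3 plateaux", call. = FALSE)
  }
  summ <- do.call(rbind, lapply(seq_len(nrow(plateaux)), function(i) {
    idx <- plateaux$start[i]:plateaux$end[i]
    sind <- sin(deg2rad(rec$delta[idx]))
    fperp <- rec$force[idx] * sin(deg2rad(rec$phi[idx]))
    data.frame(plateau = i,
               mean_sin_delta = mean(sind), sd_sin_delta = stats::sd(sind),
               mean_f_perp = mean(fperp), sd_f_perp = stats::sd(fperp),
               mean_delta = mean(rec$delta[idx]))
  }))
  if (exclude_pushing) summ <- summ[summ$mean_delta >= 0, , drop = FALSE]
  if (nrow(summ) < 3) {
    stop("insufficient data: need at least 3 pulling plateaux", call. = FALSE)
  }
  if (stats::var(summ$mean_sin_delta) < 1e-16) {
    stop("no variance in sin(delta) across plateaux", call. = FALSE)
  }
  fit <- stats::lm(mean_f_perp ~ mean_sin_delta, data = summ)
  sl <- stats::coef(fit)[["mean_sin_delta"]]
  sl_sd <- summary(fit)$coefficients["mean_sin_delta", "Std. Error"]
  t_sd <- sqrt((sl_sd / 2)^2 + (k_uncertainty * sl / 2)^2)
  structure(list(T_mean = sl / 2, T_sd = t_sd, slope = sl,
                 slope_sd = sl_sd,
                 intercept = stats::coef(fit)[["(Intercept)"]],
                 r_squared = summary(fit)$r.squared, plateaux = summ),
            class = "tension_estimate")
}

#' @export
print.tension_estimate <- function(x, ...) {
  cat(sprintf("BFP tension estimate: T = %.0f +/- %.0f pN (R^2 = %.3f, %d plateaux)\n",
              x$T_mean, x$T_sd, x$r_squared, nrow(x$plateaux)))
  invisible(x)
}

#' Population tension distribution from per-axon fits
#'
#' Represents each tension fit by a Normal distribution with the fitted
#' mean and standard deviation, sums the densities with equal weights and
#' normalizes the sum on a reporting grid (default 1 pN spacing).
#'
#' @param T_means Fitted tensions (pN), one per axon.
#' @param T_sds Fit standard deviations (pN), all positive.
#' @param grid Optional tension grid (pN); defaults to 1 pN spacing on
#'   `[0, max(T) + 5 max(sd)]`.
#' @return An [empirical_pdf()] over tension (pN).
#' @export
population_tension_pdf <- function(T_means, T_sds, grid = NULL) {
  if (length(T_means) < 1) stop("need at least one estimate", call. = FALSE)
  if (length(T_sds) != length(T_means)) stop("length mismatch", call. = FALSE)
  if (any(T_sds <= 0)) stop("all sigma must be positive", call. = FALSE)
  if (is.null(grid)) grid <- seq(0, max(T_means) + 5 * max(T_sds), by = 1)
  dens <- rowMeans(vapply(seq_along(T_means),
                          function(j) stats::dnorm(grid, T_means[j], T_sds[j]),
                          numeric(length(grid))))
  empirical_pdf(grid, dens, variable = "tension", units = "pN")
}
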