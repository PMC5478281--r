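# Distribution machinery: kernel density estimation, the change-of-variables
# transform from tension to equilibrium zipper angle, the two adhesion
# estimation procedures (best-match and joint screening), fascicle scaling
# and the crossing-probability CDF.

#' Empirical probability density on a grid
#'
#' The common currency of the tension/angle/adhesion inference: a density
#' sampled on a strictly increasing grid, normalized by trapezoidal
#' quadrature. A point mass that leaves the support during a transform
#' (full zippering) is carried in the `atom` attribute and accounted for in
#' the normalization.
#'
#' @param grid Strictly increasing numeric grid.
#' @param density Non-negative density values on the grid.
#' @param variable,units Metadata strings.
#' @param atom Probability mass outside the grid support (default 0).
#' @param normalize Rescale so that integral + atom = 1 (default TRUE).
#' @return An object of class `empirical_pdf`.
#' @export
empirical_pdf <- function(grid, density, variable = "x", units = "",
                          atom = 0, normalize = TRUE) {
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing", call. = FALSE)
  }
  if (length(density) != length(grid)) stop("length mismatch", call. = FALSE)
  if (any(density < -1e-12)) stop("density must be non-negative", call. = FALSE)
  density <- pmax(0, density)
  tot <- trapz(grid, density)
  if (normalize) {
    if (tot <= 0 && atom <= 0) stop("zero total mass", call. = FALSE)
    if (tot > 0) density <- density * (1 - atom) / tot
  }
  structure(list(grid = grid, density = density, variable = variable,
                 units = units, atom = atom),
            class = "empirical_pdf")
}

#' @export
print.empirical_pdf <- function(x, ...) {
  cat(sprintf("empirical_pdf of %s [%s]: %d grid points on [%g, %g]",
              x$variable, x$units, length(x$grid), min(x$grid), max(x$grid)))
  if (x$atom > 1e-12) cat(sprintf(", atom mass %.3g", x$atom))
  cat("\n")
  invisible(x)
}

pdf_cdf <- function(p) {
  n <- length(p$grid)
  cumsum(c(0, (p$grid[-1] - p$grid[-n]) * (p$density[-1] + p$density[-n]) / 2))
}

#' Summary statistics of an empirical PDF
#'
#' `pdf_mean` is the trapezoidal first moment; `pdf_quantile` and
#' `pdf_median` invert the piecewise-linear CDF by interpolation;
#' `pdf_iqr` returns the 25 and 75 percent quantiles.
#'
#' @param p An [empirical_pdf()].
#' @return Numeric value(s) on the grid scale.
#' @export
pdf_mean <- function(p) trapz(p$grid, p$grid * p$density) / trapz(p$grid, p$density)

#' @rdname pdf_mean
#' @param probs Quantile levels in (0, 1), relative to the on-grid mass.
#' @export
pdf_quantile <- function(p, probs) {
  cdf <- pdf_cdf(p)
  tot <- cdf[length(cdf)]
  keep <- !duplicated(cdf)
  stats::approx(cdf[keep] / tot, p$grid[keep], xout = probs, ties = "ordered")$y
}

#' @rdname pdf_mean
#' @export
pdf_median <- function(p) pdf_quantile(p, 0.5)

#' @rdname pdf_mean
#' @export
pdf_iqr <- function(p) pdf_quantile(p, c(0.25, 0.75))

#' @rdname pdf_mean
#' @export
pdf_mode <- function(p) p$grid[which.max(p$density)]

#' Gaussian kernel density estimate on a grid
#'
#' Convolves the sample with a Gaussian kernel and normalizes on the
#' requested grid. Bandwidth defaults to Silverman's rule on the raw
#' samples.
#'
#' @param samples Numeric sample (>= 2 values).
#' @param bandwidth Kernel standard deviation; Silverman default.
#' @param grid Evaluation grid; defaults to the sample range padded by 4
#'   bandwidths, 512 points.
#' @param variable,units Metadata strings.
#' @return An [empirical_pdf()].
#' @export
kde <- function(samples, bandwidth = NULL, grid = NULL,
                variable = "x", units = "") {
  if (length(samples) < 2) stop("need at least 2 samples", call. = FALSE)
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(samples)
  if (bandwidth <= 0) stop("bandwidth must be positive", call. = FALSE)
  if (is.null(grid)) {
    grid <- seq(min(samples) - 4 * bandwidth, max(samples) + 4 * bandwidth,
                length.out = 512)
  }
  dens <- rowMeans(vapply(samples, function(s) stats::dnorm(grid, s, bandwidth),
                          numeric(length(grid))))
  empirical_pdf(grid, dens, variable = variable, units = units)
}

#' Transform a tension distribution into an angle distribution
#'
#' Change of variables through the symmetric equilibrium condition
#' `S = 2 T (1 - cos(beta/2))`. Writing `Phi = 1 - cos(beta/2)`, the
#' equilibrium tension at angle beta is `T(beta) = S / (2 Phi)` and
#' `q(beta) = p(T(beta)) |dT/dbeta| =
#'   p(S / (2 Phi)) (S / 4) sqrt(2 - Phi) / Phi^(3/2)`
#' (per radian; the returned density is per degree). The map is monotone
#' decreasing in T: larger tension gives a smaller equilibrium angle, so
#' the median of `q` is the angle at the median of `p`. Any tension mass
#' below `S/2` corresponds to full zippering (beta > 180) and is reported
#' as the `atom` of the result rather than silently dropped.
#'
#' @param p_T An [empirical_pdf()] of tension (nN).
#' @param S Adhesion strength (nN), positive.
#' @param grid_deg Angle grid in degrees on (0, 180); default 0.05 degree
#'   spacing.
#' @return An [empirical_pdf()] of the zipper angle (degrees).
#' @export
transform_tension_to_angle <- function(p_T, S,
                                       grid_deg = seq(0.05, 179.95, by = 0.05)) {
  if (S <= 0) stop("S must be positive", call. = FALSE)
  phi <- 1 - cos(deg2rad(grid_deg) / 2)
  t_of_beta <- S / (2 * phi)
  p_at <- stats::approx(p_T$grid, p_T$density, xout = t_of_beta,
                        yleft = 0, yright = 0, rule = 2)$y
  p_at[t_of_beta < min(p_T$grid) | t_of_beta > max(p_T$grid)] <- 0
  q_rad <- p_at * (S / 4) * sqrt(2 - phi) / phi^1.5
  q_deg <- q_rad * pi / 180
  # tension mass below S/2 maps beyond beta = 180: full-zippering atom
  below <- p_T$grid < S / 2
  atom <- if (any(below)) {
    idx <- which(below)
    if (length(idx) > 1) trapz(p_T$grid[idx], p_T$density[idx]) else 0
  } else 0
  empirical_pdf(grid_deg, q_deg, variable = "zipper angle", units = "deg",
                atom = atom)
}

#' Best-match estimate of the adhesion strength
#'
#' Screens a grid of adhesion values, transforms the tension distribution
#' to an angle distribution for each, and returns the value maximizing the
#' Pearson correlation with the observed angle distribution evaluated on
#' its grid.
#'
#' @param p_T An [empirical_pdf()] of tension (nN).
#' @param q_obs An [empirical_pdf()] of observed equilibrium angles (deg).
#' @param S_grid Candidate adhesion values (nN); defaults to a 1 pN grid
#'   on (0, 2 x 5th percentile of the tension distribution].
#' @return List with `S` (nN), `r` (Pearson correlation at the optimum)
#'   and the full `profile` data frame. A nearly flat correlation profile
#'   triggers an ambiguity warning.
#' @export
match_adhesion <- function(p_T, q_obs, S_grid = NULL) {
  if (is.null(S_grid)) {
    s_max <- 2 * pdf_quantile(p_T, 0.05)
    S_grid <- seq(0.001, s_max, by = 0.001)
  }
  rs <- vapply(S_grid, function(S) {
    q <- transform_tension_to_angle(p_T, S, grid_deg = q_obs$grid)
    suppressWarnings(stats::cor(q$density, q_obs$density))
  }, numeric(1))
  rs[is.na(rs)] <- -Inf
  best <- which.max(rs)
  if (max(rs) - stats::median(rs[is.finite(rs)]) < 1e-3) {
    warning("flat correlation profile: adhesion estimate is ambiguous")
  }
  list(S = S_grid[best], r = rs[best],
       profile = data.frame(S = S_grid, r = rs))
}

#' Adhesion distribution by joint screening
#'
#' Treats the tension and the equilibrium angle as independent random
#' variables, forms their product joint density, maps every (T, beta) cell
#' to `S = 2 T (1 - cos(beta/2))` and integrates the joint probability
#' into S bins (default 1 pN). Because real tensions and angles are
#' partially dependent, the spread of the result is an upper bound on the
#' spread of S.
#'
#' @param p_T An [empirical_pdf()] of tension (nN).
#' @param q_beta An [empirical_pdf()] of equilibrium angles (deg).
#' @param bin S bin width (nN); default 0.001 (1 pN).
#' @return List with `pdf` (an [empirical_pdf()] of S in nN), `median` and
#'   `iqr` (nN), and metadata noting the independence assumption.
#' @export
joint_screening <- function(p_T, q_beta, bin = 0.001) {
  tg <- p_T$grid
  wt <- p_T$density * trap_weights(tg)
  bg <- q_beta$grid
  nb <- length(bg)
  wb <- q_beta$density * trap_weights(bg)
  phi <- 1 - cos(deg2rad(bg) / 2)
  s_max <- 2 * max(tg) * max(phi)
  nbin <- ceiling(s_max / bin) + 1L
  acc <- numeric(nbin)
  for (j in seq_len(nb)) {
    if (wb[j] <= 0) next
    k <- pmin(nbin, floor(2 * tg * phi[j] / bin) + 1L)
    acc <- acc + wb[j] * as.numeric(tapply_sum(wt, k, nbin))
  }
  centers <- (seq_len(nbin) - 0.5) * bin
  total <- sum(acc)
  pdf <- empirical_pdf(centers, acc / (total * bin), variable = "adhesion S",
                       units = "nN")
  list(pdf = pdf, median = pdf_median(pdf), iqr = pdf_iqr(pdf),
       assumption = "tension and angle treated as mutually independent")
}

trap_weights <- function(x) {
  n <- length(x)
  d <- diff(x)
  if (n == 2) return(c(d / 2, d / 2))
  c(d[1] / 2, (d[-1] + d[-(n - 1)]) / 2, d[n - 1] / 2)
}

tapply_sum <- function(w, k, nbin) {
  out <- numeric(nbin)
  s <- rowsum(w, k)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Lognormal parameters from mean and standard deviation
#'
#' Closed-form moment inversion: `sdlog^2 = log(1 + (sd/mean)^2)`,
#' `meanlog = log(mean) - sdlog^2 / 2`. The returned parameters reproduce
#' the requested moments exactly.
#'
#' @param mean,sd Target mean and standard deviation (both positive).
#' @return List with `meanlog`, `sdlog`, and the implied `median`
#'   (`mean / sqrt(1 + (sd/mean)^2)`).
#' @export
lognormal_from_moments <- function(mean, sd) {
  if (mean <= 0 || sd < 0) stop("mean must be > 0 and sd >= 0", call. = FALSE)
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2),
       median = mean / sqrt(1 + (sd / mean)^2))
}

#' @rdname lognormal_from_moments
#' @param grid Tension grid (nN); defaults to 1 pN spacing covering the
#'   bulk of the distribution.
#' @return `lognormal_pdf`: an [empirical_pdf()] of the lognormal with the
#'   requested moments.
#' @export
lognormal_pdf <- function(mean, sd, grid = NULL) {
  par <- lognormal_from_moments(mean, sd)
  if (is.null(grid)) grid <- seq(0.001, mean + 12 * max(sd, mean / 10), by = 0.001)
  dens <- stats::dlnorm(grid, par$meanlog, par$sdlog)
  empirical_pdf(grid, dens, variable = "tension", units = "nN")
}

#' Fascicle parameters and their scaling with fascicle size
#'
#' A fascicle of `n` axons with independent per-axon tensions has mean
#' tension scaling linearly with `n` and tension standard deviation
#' scaling with `sqrt(n)`; its adhesion to a like fascicle scales with the
#' contact surface, i.e. `sqrt(n)` for an approximately circular
#' cross-section. Note that scaling all three parameters by a common
#' linear factor would leave the transformed angle distribution exactly
#' unchanged (the equilibrium condition is scale invariant), so the
#' square-root exponents are what produces the predicted angle shift.
#'
#' @param T_mean Mean single-axon tension (nN).
#' @param T_sd Tension standard deviation (nN).
#' @param S Adhesion strength (nN).
#' @param n Fascicle size (>= 1; real-valued for mean sizes).
#' @return An object of class `fascicle_params`.
#' @export
fascicle_params <- function(T_mean, T_sd, S, n = 1) {
  if (T_mean <= 0 || T_sd <= 0 || S <= 0) stop("parameters must be positive", call. = FALSE)
  if (n < 1) stop("fascicle size must be >= 1", call. = FALSE)
  structure(list(T_mean = T_mean, T_sd = T_sd, S = S, n = n),
            class = "fascicle_params")
}

#' @rdname fascicle_params
#' @param base A `fascicle_params` at the single-axon baseline.
#' @export
fascicle_scale <- function(base, n) {
  if (n < 1) stop("fascicle size must be >= 1", call. = FALSE)
  fascicle_params(T_mean = n * base$T_mean, T_sd = sqrt(n) * base$T_sd,
                  S = sqrt(n) * base$S, n = n * base$n)
}

fascicle_angle_pdf <- function(fp, grid = NULL) {
  p <- lognormal_pdf(fp$T_mean, fp$T_sd, grid = grid)
  transform_tension_to_angle(p, fp$S)
}

#' Median-angle shift under fascicle coarsening
#'
#' Difference between the median equilibrium zipper angle predicted for
#' the single-axon baseline and for the baseline rescaled to mean fascicle
#' size `n` (lognormal tension distribution in both cases). Positive when
#' coarsening lowers the median angle.
#'
#' @param base A [fascicle_params()] baseline.
#' @param n Mean fascicle size (>= 1).
#' @return Shift in degrees.
#' @export
median_angle_shift <- function(base, n) {
  m0 <- pdf_median(fascicle_angle_pdf(base))
  m1 <- pdf_median(fascicle_angle_pdf(fascicle_scale(base, n)))
  m0 - m1
}

#' Crossing probability at an incidence angle
#'
#' The probability that two axons meeting at incidence angle `beta_inc`
#' cross rather than zipper equals the probability that their equilibrium
#' zipper angle is below the incidence angle, i.e. the CDF of the
#' equilibrium-angle distribution evaluated at `beta_inc`.
#'
#' @param q_beta An [empirical_pdf()] of equilibrium angles (deg).
#' @param beta_inc Incidence angle(s), degrees in `[0, 180]`.
#' @return CDF value(s) in `[0, 1]`, monotone in `beta_inc`.
#' @export
crossing_probability <- function(q_beta, beta_inc) {
  if (any(beta_inc < 0 | beta_inc > 180)) {
    stop("incidence angle must lie in [0, 180] degrees", call. = FALSE)
  }
  cdf <- pdf_cdf(q_beta)
  tot <- cdf[length(cdf)]
  vapply(beta_inc, function(b) {
    if (b <= min(q_beta$grid)) return(0)
    if (b >= max(q_beta$grid)) return(1)
    stats::approx(q_beta$grid, cdf / tot, xout = b)$y
  }, numeric(1))
}

#' Fascicle-size ratio from total network length
#'
#' Mean fascicle size scales inversely with the total network length per
#' unit area, so over a fixed field of view
#' `n_after / n_before = L_before / L_after`.
#'
#' @param L_before,L_after Total network lengths (um), positive.
#' @return The fascicle-size ratio.
#' @export
rescale_factor_from_length <- function(L_before, L_after) {
  if (L_before <= 0 || L_after <= 0) stop("lengths must be positive", call. = FALSE)
  L_before / L_after
}
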