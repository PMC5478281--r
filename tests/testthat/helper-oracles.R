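# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: energies are re-typed from the definition, the
# symmetric equation of motion is re-integrated directly, and
# distributions are pushed forward by Monte Carlo sampling.

# Configuration energy re-typed from its definition (not config_energy()).
oracle_energy <- function(A, B, C, V, T1, T2, S) {
  len <- function(p, q) sqrt(sum((p - q)^2))
  T1 * (len(V, A) + len(V, C)) + T2 * (len(V, B) + len(V, C)) - S * len(V, C)
}

# Central-difference gradient of the oracle energy.
oracle_force <- function(A, B, C, V, T1, T2, S, h = 1e-6) {
  gx <- (oracle_energy(A, B, C, V + c(h, 0), T1, T2, S) -
           oracle_energy(A, B, C, V - c(h, 0), T1, T2, S)) / (2 * h)
  gy <- (oracle_energy(A, B, C, V + c(0, h), T1, T2, S) -
           oracle_energy(A, B, C, V - c(0, h), T1, T2, S)) / (2 * h)
  -c(gx, gy)
}

# Equilibrium of a mirror-symmetric zipper by 1-D minimization of the
# oracle energy over the vertex position on the symmetry axis.
oracle_symmetric_equilibrium_angle <- function(T, S, w = 20, h = 30, cb = -30) {
  A <- c(-w, h); B <- c(w, h); C <- c(0, cb)
  en <- function(y) oracle_energy(A, B, C, c(0, y), T, T, S)
  y_star <- stats::optimize(en, c(cb + 0.01, h - 0.01), tol = 1e-12)$minimum
  2 * atan2(w, h - y_star) * 180 / pi
}

# Direct Euler integration of the symmetric equation of motion for a
# mirror geometry (half-width w, free ends at height h, zipper anchor at
# cb); returns a data frame usable by fit_velocity_vs_angle().
oracle_integrate_symmetric <- function(T, S, eta_elong, eta_Z,
                                       w = 20, h = 30, cb = -30,
                                       y0 = 25, dt = 0.5, n = 3000) {
  y <- y0
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    beta <- 2 * atan2(w, h - y) * 180 / pi
    L <- sqrt(w^2 + (h - y)^2) + (y - cb)
    v <- symmetric_velocity(T, S, beta, L, eta_elong, eta_Z)
    out[i, ] <- c((i - 1) * dt, y - cb, beta)
    y <- y + v * dt
  }
  stats::setNames(as.data.frame(out), c("t", "zip_len", "beta_deg"))
}

expect_close <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol),
              label = sprintf("|%s - %s| <= %s",
                              paste(signif(object, 8), collapse = ","),
                              paste(signif(expected, 8), collapse = ","),
                              format(tol)))
}
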