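test_that("symmetric zippering velocity has the right sign, zero and value", {
  beta_eq <- equilibrium_angle_symmetric(1, 0.2)
  expect_close(symmetric_velocity(1, 0.2, beta_eq, 50, 3000, 1), 0, tol = 1e-12)

  # frozen value re-derived symbolically in the oracle helper form
  ch <- cos(80 / 2 * pi / 180)
  v_expect <- (0.2 - 2 * (1 - ch)) / (2 * 3000 * (ch - 1)^2 / 50 + 1)
  expect_close(symmetric_velocity(1, 0.2, 80, 50, 3000, 1), v_expect, tol = 1e-12)

  # with eta_elong = 0 the velocity is affine in (1 - cos(beta/2))
  betas <- seq(20, 140, by = 10)
  phi <- 1 - cos(betas / 2 * pi / 180)
  v <- vapply(betas, function(b) symmetric_velocity(1, 0.2, b, 50, 0, 2),
              numeric(1))
  fit <- lm(v ~ phi)
  expect_close(unname(coef(fit)[2]), -2 * 1 / 2, tol = 1e-10)
  expect_close(unname(coef(fit)[1]), 0.2 / 2, tol = 1e-10)

  expect_error(symmetric_velocity(1, 0.2, 80, 50, 0, 0), "friction")
})

test_that("friction tensor: structure, covariance, and dissipation equivalence", {
  g <- zipper_geometry(c(-20, 30), c(25, 28), c(2, -35), c(1, 2))

  # vertex-localized contribution is rank 1 along the zipper axis
  Hz <- assemble_friction_tensor(g, friction_params(eta_Z = 2))
  cc <- (g$C - g$V) / sqrt(sum((g$C - g$V)^2))
  expect_close(max(abs(Hz - 2 * tcrossprod(cc))), 0, tol = 1e-12)
  expect_close(det(Hz), 0, tol = 1e-12)

  # substrate-only: per-segment dissipation integrates to eta * len / 3,
  # cross-checked against numerical quadrature of the linear profile
  fr_s <- friction_params(eta_par = 150, eta_perp = 150)
  Hs <- assemble_friction_tensor(g, fr_s)
  eta_int <- 150 * az_units$nNs_um2_per_Pas
  len_tot <- sum(sqrt(colSums((cbind(g$A, g$B, g$C) - g$V)^2)))
  expect_close(max(abs(Hs - eta_int * len_tot / 3 * diag(2))), 0, tol = 1e-12)

  u <- c(0.013, -0.007)
  for (fr in list(fr_s, friction_params(eta_par = 80, eta_perp = 240))) {
    H <- assemble_friction_tensor(g, fr)
    # quadrature oracle: v(l) = (l/len) u along each segment
    ep <- fr$eta_par * az_units$nNs_um2_per_Pas
    et <- fr$eta_perp * az_units$nNs_um2_per_Pas
    diss <- 0
    for (P in list(g$A, g$B, g$C)) {
      len <- sqrt(sum((P - g$V)^2))
      tv <- (P - g$V) / len
      ls <- seq(0, len, length.out = 20001)
      sc <- ls / len
      vpar <- sc * sum(u * tv)
      vperp2 <- sc^2 * sum(u^2) - vpar^2
      integrand <- ep * vpar^2 + et * vperp2
      diss <- diss + sum((integrand[-1] + integrand[-length(ls)]) / 2 * diff(ls))
    }
    expect_lt(abs(sum(u * (H %*% u)) - diss) / diss, 1e-4)
  }

  # elongation contribution dissipates eta/L * Ldot^2 per axon
  fr_e <- friction_params(eta_elong = 1000)
  He <- assemble_friction_tensor(g, fr_e)
  h <- 1e-7
  l1 <- function(v) sqrt(sum((g$A - v)^2)) + sqrt(sum((g$C - v)^2))
  l2 <- function(v) sqrt(sum((g$B - v)^2)) + sqrt(sum((g$C - v)^2))
  l1dot <- (l1(g$V + u * h) - l1(g$V - u * h)) / (2 * h)
  l2dot <- (l2(g$V + u * h) - l2(g$V - u * h)) / (2 * h)
  diss_e <- 1000 * (l1dot^2 / l1(g$V) + l2dot^2 / l2(g$V))
  expect_lt(abs(sum(u * (He %*% u)) - diss_e) / diss_e, 1e-5)

  # frame covariance under rotation by 30 degrees
  th <- pi / 6
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  fr_all <- friction_params(eta_elong = 500, eta_Z = 1.5,
                            eta_par = 100, eta_perp = 50)
  H1 <- assemble_friction_tensor(g, fr_all)
  g_rot <- zipper_geometry(c(R %*% g$A), c(R %*% g$B), c(R %*% g$C),
                           c(R %*% g$V))
  H2 <- assemble_friction_tensor(g_rot, fr_all)
  expect_close(max(abs(H2 - R %*% H1 %*% t(R))), 0, tol = 1e-10)

  # symmetric PSD
  ev <- eigen(H1, symmetric = TRUE)$values
  expect_true(all(ev >= -1e-12))
  expect_error(friction_params(), "at least one")
})

test_that("overdamped simulation: Lyapunov energy, regime-independent endpoint, terminal states", {
  A <- c(-30, 40); B <- c(30, 40); C <- c(0, -40)
  m0 <- zipper_mechanics(1, 1, 0.2)
  m1 <- zipper_mechanics(1, 1.5, 0.2)
  V0 <- find_equilibrium_vertex(A, B, C, m0)

  # start at equilibrium: stationary
  tr0 <- simulate_zipper(zipper_geometry(A, B, C, V0), mech = m0,
                         friction = friction_params(eta_Z = 1), t_end = 50)
  expect_lt(max(abs(tr0$x - V0[1])), 1e-6)
  expect_lt(max(abs(tr0$y - V0[2])), 1e-6)

  ends <- list()
  for (fr in list(friction_params(eta_Z = 1),
                  friction_params(eta_par = 200, eta_perp = 200),
                  friction_params(eta_elong = 3000))) {
    tr <- simulate_zipper(zipper_geometry(A, B, C, V0), mech = m1,
                          friction = fr, dt = 0.1, t_end = 50000)
    expect_true(all(diff(tr$energy) <= 1e-9)) # Lyapunov property
    vend <- c(tail(tr$x, 1), tail(tr$y, 1))
    res <- sqrt(sum(vertex_force(zipper_geometry(A, B, C, vend), m1)^2))
    expect_lt(res, 1e-6) # equilibrium residual independent of regime
    ends[[length(ends) + 1]] <- vend
  }
  # paths differ but the endpoints agree
  expect_lt(max(abs(ends[[1]] - ends[[2]])), 1e-4)
  expect_lt(max(abs(ends[[1]] - ends[[3]])), 1e-4)

  # strong adhesion drives the vertex into C: fully zippered terminal state
  trz <- simulate_zipper(zipper_geometry(A, B, C, c(0, 0)),
                         mech = zipper_mechanics(0.4, 0.4, 1.0),
                         friction = friction_params(eta_Z = 1),
                         dt = 0.1, t_end = 20000)
  expect_identical(attr(trz, "terminal"), "fully_zippered")
})

test_that("mirror-symmetric general simulation reproduces the 1-D equation of motion", {
  As <- c(-20, 30); Bs <- c(20, 30); Cs <- c(0, -30)
  ms <- zipper_mechanics(0.8, 0.8, 0.3)
  frs <- friction_params(eta_elong = 500, eta_Z = 2)
  tr <- simulate_zipper(zipper_geometry(As, Bs, Cs, c(0, 10)), mech = ms,
                        friction = frs, dt = 0.05, t_end = 2000)
  expect_lt(max(abs(tr$x)), 1e-9) # symmetry is preserved
  y <- 10
  for (i in seq_len(nrow(tr) - 1)) {
    beta <- 2 * atan2(20, 30 - y) * 180 / pi
    L <- sqrt(20^2 + (30 - y)^2) + (y + 30)
    v <- symmetric_velocity(0.8, 0.3, beta, L, 500, 2)
    y <- y + v * (tr$t[i + 1] - tr$t[i])
  }
  expect_lt(abs(y - tail(tr$y, 1)), 0.1)
})

test_that("perturbation protocols: lateral-first path under vertex friction, constant speed under ramps", {
  A <- c(-30, 40); B <- c(30, 40); C <- c(0, -40)
  V0 <- find_equilibrium_vertex(A, B, C, zipper_mechanics(1, 1, 0.2))

  # abrupt tension step with dominant vertex friction: fast lateral
  # equilibration, then motion parallel to the zippered segment
  proto <- data.frame(time = c(0, 5), T1 = c(1, 1), T2 = c(1, 1.5),
                      S = c(0.2, 0.2))
  tr <- simulate_zipper(zipper_geometry(A, B, C, V0),
                        friction = friction_params(eta_Z = 1),
                        protocol = proto, dt = 0.1, t_end = 2000)
  early <- tr[tr$t <= 30, ]
  late <- tr[tr$t > 100, ]
  expect_gt(diff(range(early$x)), 0.7 * diff(range(tr$x))) # lateral motion happens early
  expect_gt(diff(range(late$y)), 5 * diff(range(late$x)))  # then along the zipper axis

  # gradual 500 s ramp: approximately constant vertex speed during the ramp
  proto_g <- data.frame(time = c(0, 500), T1 = c(1, 1), T2 = c(1, 1.5),
                        S = c(0.2, 0.2))
  for (fr in list(friction_params(eta_Z = 1),
                  friction_params(eta_par = 200, eta_perp = 200))) {
    trg <- simulate_zipper(zipper_geometry(A, B, C, V0), friction = fr,
                           protocol = proto_g, dt = 0.5, t_end = 700)
    mid <- trg[trg$t > 100 & trg$t < 450, ]
    spd <- sqrt(mid$ux^2 + mid$uy^2)
    expect_lt(stats::sd(spd) / mean(spd), 0.35)
  }
})

test_that("velocity-angle fit recovers planted parameters and flags model mismatch", {
  # noise-free vertex-friction trajectory: slope -2T/etaZ, intercept S/etaZ
  traj <- oracle_integrate_symmetric(T = 1, S = 0.2, eta_elong = 0, eta_Z = 1)
  f <- fit_velocity_vs_angle(traj, half_width = 2)
  expect_close(f$slope, -2, tol = 0.01 * 2)       # within 1 percent
  expect_close(f$intercept, 0.2, tol = 0.01 * 0.2)
  expect_close(infer_st_ratio(f$slope, f$intercept), 0.2, tol = 0.004)
  expect_close(infer_eta_z(f$slope, 1), 1, tol = 0.02)

  # exactly affine velocity-angle data: R^2 = 1 up to smoothing edge effects
  tl <- seq(0, 99, by = 1)
  phi_t <- 0.05 + 0.0005 * tl              # u = 0.1 - 2 * phi
  z <- 30 + 0.1 * tl - 2 * (0.05 * tl + 0.00025 * tl^2)
  betas <- 2 * acos(1 - phi_t) * 180 / pi
  f2 <- fit_velocity_vs_angle(data.frame(t = tl, zip_len = z, beta_deg = betas),
                              half_width = 2)
  expect_gt(f2$r_squared, 0.999)
  expect_close(f2$slope, -2, tol = 0.05)

  # appreciable elongation viscosity bends the relation: R^2 visibly below 1
  traj3 <- oracle_integrate_symmetric(T = 1, S = 0.2, eta_elong = 4000,
                                      eta_Z = 0.2, n = 1500)
  f3 <- fit_velocity_vs_angle(traj3, half_width = 5)
  expect_lt(f3$r_squared, 0.999)

  expect_error(fit_velocity_vs_angle(data.frame(t = 1:50, zip_len = 1:50,
                                                beta_deg = rep(40, 50)),
                                     half_width = 2), "abscissa")
})

test_that("ratio and friction-constant inference reproduce the printed fit arithmetic", {
  expect_equal(round(infer_st_ratio(-4.1692, 0.0825), 2), 0.04)
  expect_equal(infer_st_ratio(-2, 0), 0)
  expect_error(infer_st_ratio(1, 0.1), "slope")

  eta <- infer_eta_z(-4.1692, 2) # nN s / um
  expect_equal(round(log10(eta * az_units$Nsm_per_nNs_um)), -3) # ~1e-3 N s/m

  expect_equal(dissipation_rate(1, 0), 0)
  expect_close(dissipation_rate(1, 2) / dissipation_rate(1, 1), 4, tol = 1e-12)
  expect_equal(floor(log10(dissipation_rate(1, 1))), -17)
})
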