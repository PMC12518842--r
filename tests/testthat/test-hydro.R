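# Bead-model hydrodynamics, the hydrodynamic function, and the colloidal
# diffusion relations.

kT_pe <- function(env) 1.380649e-23 * env$temperature /
  (env$viscosity * 1e-3) * 1e18 / pi

test_that("single bead reproduces the Stokes formulas to 1e-10", {
  env <- water_env()
  a <- 2.3
  m <- bead_model(matrix(0, 1, 3), 1, "Fc", c(0, 0, 0))
  h <- rpy_rigid_body_tensor(m, a, env)
  expect_equal(h$D_t, kT_pe(env) / (6 * a), tolerance = 1e-10)
  expect_equal(h$D_r0, kT_pe(env) / (8 * a^3), tolerance = 1e-10)
  expect_true(all(eigen(h$diffusion_matrix)$values > 0))
})

test_that("touching-dimer tensor matches the closed-form RPY values", {
  env <- water_env()
  a <- 1
  m <- bead_model(rbind(c(0, 0, 0), c(0, 0, 2 * a)), c(1, 1), c("Fc", "Fc"),
                  c(0, 0, a))
  h <- rpy_rigid_body_tensor(m, a, env)
  # independent closed form: rigid translation friction = 2/(self + cross)
  # with the axial/perpendicular RPY eigenvalues at r = 2a
  b_ax <- 5 / (48 * a)
  b_pp <- 7 / (96 * a)
  D_ax <- kT_pe(env) * (1 / (6 * a) + b_ax) / 2
  D_pp <- kT_pe(env) * (1 / (6 * a) + b_pp) / 2
  expect_equal(h$center, c(0, 0, a), tolerance = 1e-9)
  Dtt <- h$diffusion_matrix[1:3, 1:3]
  expect_equal(Dtt[3, 3], D_ax, tolerance = 1e-9)
  expect_equal(Dtt[1, 1], D_pp, tolerance = 1e-9)
  expect_equal(h$D_t, (D_ax + 2 * D_pp) / 3, tolerance = 1e-9)
})

test_that("shell-model sphere converges to the Stokes translation", {
  env <- water_env()
  R <- 5
  th <- seq(0, pi, length.out = 20)
  pts <- NULL
  for (t in th) {
    nphi <- max(1, round(2 * pi * sin(t) * 19 / pi))
    for (p in (seq_len(nphi) - 0.5) * 2 * pi / nphi)
      pts <- rbind(pts, R * c(sin(t) * cos(p), sin(t) * sin(p), cos(t)))
  }
  m <- bead_model(pts, rep(1, nrow(pts)), rep("Fc", nrow(pts)), c(0, 0, 0))
  h <- rpy_rigid_body_tensor(m, 0.5 * pi * R / 19, env)
  expect_equal(h$D_t, kT_pe(env) / (6 * R), tolerance = 0.05)
})

test_that("rigid-body D0(Q): point limit, Q->0 limit, positivity, BD oracle", {
  env <- water_env()
  one <- bead_model(matrix(0, 1, 3), 1, "Fc", c(0, 0, 0))
  h1 <- rpy_rigid_body_tensor(one, 1.5, env)
  dq1 <- rigid_body_DQ(one, h1, c(0.3, 1, 2))
  expect_equal(dq1$D0, rep(h1$D_t, 3), tolerance = 1e-10)
  # Q -> 0 limit: on a symmetric body (scattering centroid = centre of
  # diffusion) the plateau is exactly D_t
  eq <- 2 * rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0), c(-0.5, -sqrt(3) / 2, 0))
  msym <- bead_model(eq, rep(1, 3), rep("Fc", 3), c(0, 0, 0))
  hsym <- rpy_rigid_body_tensor(msym, 0.6, env)
  expect_equal(rigid_body_DQ(msym, hsym, 1e-3)$D0, hsym$D_t, tolerance = 1e-3)
  pos <- rbind(c(2, 0, 0), c(-1, 1.5, 0), c(-1, -1.5, 0.8))
  m <- bead_model(pos, c(1, 1.3, 0.8), rep("Fc", 3), colMeans(pos))
  h <- rpy_rigid_body_tensor(m, 0.6, env)
  dq <- rigid_body_DQ(m, h, c(1e-3, 0.4, 1.0, 1.8))
  expect_true(all(dq$Dr >= -1e-12))
  # Brownian-dynamics first-cumulant oracle (seeded)
  set.seed(123)
  L <- t(chol(h$diffusion_matrix))
  posc <- sweep(m$positions, 2, h$center)
  b <- m$contrasts
  ns <- 15000; dt <- 0.02
  dX <- sqrt(2 * dt) * (L %*% matrix(rnorm(6 * ns), 6, ns))
  w <- t(dX[4:6, ]); th <- sqrt(rowSums(w^2)); what <- w / th
  ct <- cos(th); st <- sin(th)
  rot <- lapply(1:3, function(k) {
    r <- posc[k, ]
    wr <- cbind(what[, 2] * r[3] - what[, 3] * r[2],
                what[, 3] * r[1] - what[, 1] * r[3],
                what[, 1] * r[2] - what[, 2] * r[1])
    ct * matrix(r, ns, 3, byrow = TRUE) + st * wr +
      (1 - ct) * drop(what %*% r) * what + t(dX[1:3, ])
  })
  U <- fibonacci_sphere(101)
  for (q in c(0.4, 1.4)) {
    num <- 0; den <- 0; vals <- numeric(0)
    for (mdx in seq_len(nrow(U))) {
      u <- U[mdx, ]
      rho0 <- sum(b * exp(1i * q * drop(posc %*% u)))
      rho1 <- b[1] * exp(1i * q * drop(rot[[1]] %*% u)) +
              b[2] * exp(1i * q * drop(rot[[2]] %*% u)) +
              b[3] * exp(1i * q * drop(rot[[3]] %*% u))
      v <- Re(rho1 * Conj(rho0))
      num <- num + mean(v); den <- den + Mod(rho0)^2
      vals <- c(vals, v)
    }
    D_bd <- -log(num / den) / (q^2 * dt)
    se <- stats::sd(vals) / sqrt(length(vals)) / (den / nrow(U)) / (q^2 * dt)
    D_pkg <- rigid_body_DQ(m, h, q, n_orientations = 453)$D0
    expect_lt(abs(D_pkg - D_bd), 3 * se)
  }
})

test_that("hydrodynamic function: dilute limit, no-structure limit, shape", {
  Qg <- seq(0.05, 3, length.out = 25)
  R <- 4
  vol <- 4 * pi * R^3 / 3
  # consistent dilute system: S from the same tiny volume fraction
  Sd <- structure_factor(sq_params(model = "hard_sphere_PY", radius = R,
                                   volume_fraction = 1e-4), Qg)
  Hd <- delta_gamma_H(Sd, R, 1e-4 / vol, Qg)
  expect_lt(max(abs(Hd$H - 1)), 1e-3)
  # S = 1: distinct part vanishes, H constant at the self part
  S1 <- structure_factor(sq_params(model = "unity"), Qg)
  H1 <- delta_gamma_H(S1, R, 0.2 / vol, Qg)
  expect_lt(max(abs(H1$Hd)), 1e-10)
  expect_equal(H1$H, rep(attr(H1, "self_part"), 25))
  # moderate phi PY: H similar in shape to S but weaker; H/S > 1 at low Q
  S <- structure_factor(sq_params(model = "hard_sphere_PY", radius = R,
                                  volume_fraction = 0.2), Qg)
  H <- delta_gamma_H(S, R, 0.2 / vol, Qg)
  expect_equal(attr(H, "Phi_HI"), 0.2, tolerance = 1e-12)
  expect_true(all(H$H > 0))
  expect_gt(H$H[1] / S$I[1], 1)
  expect_lt(H$H[1], 1)
  # high-Q limit approaches the self part
  expect_equal(H$H[25], attr(H, "self_part"), tolerance = 0.02)
})

test_that("delta-gamma quadratures converge and the self part decreases", {
  Qg <- seq(0.1, 2.5, length.out = 15)
  R <- 4; vol <- 4 * pi * R^3 / 3
  S <- structure_factor(sq_params(model = "hard_sphere_PY", radius = R,
                                  volume_fraction = 0.2), Qg)
  H <- delta_gamma_H(S, R, 0.2 / vol, Qg)
  Hfine <- delta_gamma_H(S, R, 0.2 / vol, Qg, n_x = 480, n_mu = 64,
                         x_max = 160)
  expect_lt(max(abs(Hfine$H - H$H) / abs(H$H)), 1e-3)
  # independent high-resolution quadrature of the self part
  phi <- 0.2
  gam <- igdyn:::.sgamma_scale(phi, nodes = 40000L, tmax = 1000)
  t <- (seq_len(40000L) - 0.5) * 1000 / 40000L
  wq <- igdyn:::.sinc(t)^2
  self_hr <- sum(wq / (1 + phi * gam * wq)) / sum(wq)
  expect_equal(attr(H, "self_part"), self_hr, tolerance = 1e-3)
  # strict decrease of the self part with volume fraction
  selfs <- vapply(seq(0.02, 0.5, by = 0.04), function(p) {
    Sx <- structure_factor(sq_params(model = "hard_sphere_PY", radius = R,
                                     volume_fraction = p), Qg[1:2])
    attr(delta_gamma_H(Sx, R, p / vol, Qg[1:2]), "self_part")
  }, numeric(1))
  expect_true(all(diff(selfs) < 0))
  expect_error(delta_gamma_H(S, R, 0.8 / vol, Qg), "out of range")
})

test_that("rotational hindrance evaluates the crowding polynomial", {
  expect_equal(rotational_hindrance(0), 1)
  expect_equal(rotational_hindrance(0.1), 1 - 0.0631 - 0.00726)
  expect_equal(rotational_hindrance(0.3), 1 - 0.631 * 0.3 - 0.726 * 0.09)
  expect_error(rotational_hindrance(0.7), "out of")
})

test_that("Stokes-Einstein conversions and temperature rescaling", {
  env <- environment_conditions(298.15, 1.095, "custom")
  expect_equal(stokes_einstein_radius(0.0368, env), 5.4, tolerance = 0.02)
  D <- stokes_einstein_D(stokes_einstein_radius(0.04, env), env)
  expect_equal(D, 0.04, tolerance = 1e-12)
  env2 <- environment_conditions(298.15, 2 * 1.095, "custom")
  expect_equal(stokes_einstein_radius(0.04, env2),
               stokes_einstein_radius(0.04, env) / 2, tolerance = 1e-12)
  # rescaling: identity, monotonicity, inverse
  expect_equal(temperature_rescale(0.03, 298.15, 298.15), 0.03)
  expect_gt(temperature_rescale(0.02, 283.15, 298.15), 0.02)
  back <- temperature_rescale(temperature_rescale(0.02, 283.15, 298.15),
                              298.15, 283.15)
  expect_equal(back, 0.02, tolerance = 1e-12)
  expect_error(temperature_rescale(0.02, 250, 298.15), "range")
  expect_equal(solvent_viscosity(298.15, "D2O"), 1.095, tolerance = 0.002)
  expect_equal(solvent_viscosity(298.15, "H2O"), 0.890, tolerance = 0.002)
})

test_that("virial fit of collective diffusion recovers D_0 and k_D", {
  conc <- c(5, 10, 15, 20, 25)
  D0 <- 0.0368; kD <- 0.004
  D <- D0 * (1 + kD * conc)
  f <- suppressWarnings(interaction_expansion_fit(conc, D))  # exact fit
  expect_equal(f$D_0, D0, tolerance = 1e-10)
  expect_equal(f$k_D, kD, tolerance = 1e-8)
  # zero-slope data: slope consistent with zero
  set.seed(5)
  Dz <- D0 * (1 + 0.005 * rnorm(5))
  fz <- interaction_expansion_fit(conc, Dz, sigma = rep(0.005 * D0, 5))
  expect_lt(abs(fz$k_D), 2 * fz$k_D_err + 1e-4)
  # noisy recovery within 3 sigma (seeded)
  set.seed(11)
  Dn <- D * (1 + 0.02 * rnorm(5))
  fn <- interaction_expansion_fit(conc, Dn, sigma = 0.02 * D)
  expect_lt(abs(fn$D_0 - D0), 3 * fn$D_0_err)
  expect_error(interaction_expansion_fit(c(5, 5, 5), c(1, 1, 1)), "degenerate")
})

test_that("hard-sphere self-diffusion model curves are physical", {
  sd <- self_diffusion_models(seq(0, 0.45, by = 0.01))
  expect_equal(unlist(sd[1, -1]), c(short_virial = 1, long_virial = 1,
                                    short_TO = 1, long_TO = 1))
  expect_true(all(sd$long_virial <= sd$short_virial))
  expect_true(all(sd$long_TO <= sd$short_TO))
  for (col in names(sd)[-1]) expect_true(all(diff(sd[[col]]) < 0))
  expect_error(self_diffusion_models(0.6), "phi")
})
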