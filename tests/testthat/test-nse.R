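# Coherent mode form factors, the composite two-timescale ISF, cumulant
# analysis and the slow-diffusion decomposition.

test_that("mode form factor reproduces closed forms and rejects mismatches", {
  one <- bead_model(matrix(0, 1, 3), 1, "Fab_l", c(-2, 0, 0))
  # displacement u along one axis: orientation average gives Q^2 u^2 / 3
  for (u in c(1, 2.5)) {
    md <- displacement_mode(matrix(c(u, 0, 0), 1, 3), "attack", "Fab_l")
    Pa <- mode_form_factor(one, md, c(0.5, 1.2), 1153)$P_alpha
    expect_equal(Pa, c(0.5, 1.2)^2 * u^2 / 3, tolerance = 1e-3)
  }
  zero <- displacement_mode(matrix(0, 1, 3), "attack", "Fab_l")
  expect_equal(mode_form_factor(one, zero, c(0.5, 1))$P_alpha, c(0, 0))
  ym <- ymodel_small()
  expect_error(mode_form_factor(ym, zero, 1), "bead count")
})

test_that("Gaussian-ensemble averaging validates P_alpha at second order", {
  # Ensemble form factor over Gaussian mode amplitudes g ~ N(0, a^2):
  # <|rho|^2> = P + a^2 (P_alpha - P_DW) + O(a^4), with the Debye-Waller
  # cross term P_DW; all terms in one orientation-quadrature convention.
  ym <- fixture("pa_model", function() build_synthetic_ymodel(2.5, 3, 12L, seed = 3))
  for (kind in c("attack", "search_in_plane", "fragment_rotation")) {
    mode <- make_displacement_mode(ym, kind, "Fab_l")
    U <- fibonacci_sphere(151)
    b <- ym$contrasts; d <- mode$vectors
    Qg <- c(0.6, 1.2)
    terms <- lapply(Qg, function(q) {
      P <- 0; Pa <- 0; Pdw <- 0
      for (m in seq_len(nrow(U))) {
        u <- U[m, ]
        ph <- b * exp(1i * q * drop(ym$positions %*% u))
        w <- q * drop(d %*% u)
        P <- P + Mod(sum(ph))^2
        Pa <- Pa + Mod(sum(ph * w))^2
        Pdw <- Pdw + Re(sum(outer(Conj(ph), ph) * 0.5 * outer(w^2, w^2, "+")))
      }
      c(P, Pa, Pdw) / nrow(U)
    })
    # package path agrees with the quadrature above
    Pa_pkg <- mode_form_factor(ym, mode, Qg, 151)$P_alpha
    expect_equal(Pa_pkg, vapply(terms, `[`, numeric(1), 2), tolerance = 1e-10)
    # exact Gaussian ensemble (deterministic integral over g)
    gauss <- function(q, a) {
      tot <- 0
      for (m in seq_len(nrow(U))) {
        u <- U[m, ]
        ph <- b * exp(1i * q * drop(ym$positions %*% u))
        w <- q * drop(d %*% u)
        tot <- tot + Re(sum(outer(Conj(ph), ph) *
                              exp(-a^2 * outer(w, w, "-")^2 / 2)))
      }
      tot / nrow(U)
    }
    err <- vapply(c(0.1, 0.2), function(a) {
      max(abs(vapply(seq_along(Qg), function(i) {
        gauss(Qg[i], a) - (terms[[i]][1] + a^2 * (terms[[i]][2] - terms[[i]][3]))
      }, numeric(1))))
    }, numeric(1))
    # remainder is fourth order: doubling a grows the error ~16x
    expect_lt(err[1], 1e-2 * terms[[1]][1])
    expect_gt(err[2] / err[1], 8)
  }
})

test_that("Monte-Carlo Gaussian ensemble matches P + a^2(P_alpha - P_DW)", {
  ym <- fixture("pa_model", function() build_synthetic_ymodel(2.5, 3, 12L, seed = 3))
  mode <- make_displacement_mode(ym, "attack", "Fab_m")
  U <- fibonacci_sphere(76)
  b <- ym$contrasts
  a <- 0.3
  q <- 0.9
  set.seed(77)
  g <- rnorm(6000, 0, a)
  ph0 <- exp(1i * q * (U %*% t(ym$positions)))   # dirs x N
  w <- q * (U %*% t(mode$vectors))
  samples <- vapply(seq_along(g), function(s) {
    rho <- (ph0 * exp(1i * g[s] * w)) %*% b
    mean(Mod(rho)^2)
  }, numeric(1))
  P <- mean(Mod(ph0 %*% b)^2)
  Pa <- mean(Mod((ph0 * w) %*% b)^2)
  Pdw <- mean(vapply(seq_len(nrow(U)), function(m) {
    ph <- b * ph0[m, ]
    Re(sum(outer(Conj(ph), ph) * 0.5 * outer(w[m, ]^2, w[m, ]^2, "+")))
  }, numeric(1)))
  se <- stats::sd(samples) / sqrt(length(samples))
  expect_lt(abs(mean(samples) - (P + a^2 * (Pa - Pdw))), 3 * se + 1e-9)
})

test_that("relaxation amplitude and mode diffusion follow the closed forms", {
  ms <- modeset_attack_full()
  ms0 <- ms
  ms0$amplitude <- 0
  expect_equal(relaxation_amplitude(ms0)$A, rep(0, length(ms$Q)))
  A <- relaxation_amplitude(ms)
  expect_true(all(A$A >= 0 & A$A < 1))
  # a^2 sum P_alpha = P at a point gives A = 1/2 (arithmetic identity)
  fake <- structure(list(Q = 1, P = 2, P_alpha_sum = 2, amplitude = 1,
                         lambda = 10), class = "mode_set")
  expect_equal(relaxation_amplitude(fake)$A, 0.5)
  expect_equal(mode_diffusion(fake)$D_m, 0.5 / (10 * 1^2))
  # single-bead translation mode: A = (a^2 Q^2/3)/(1 + a^2 Q^2/3),
  # D_m -> a^2/(3 lambda) at small Q
  one <- bead_model(matrix(0, 1, 3), 1, "Fab_l", c(-2, 0, 0))
  md <- displacement_mode(matrix(c(1, 0, 0), 1, 3), "attack", "Fab_l")
  mst <- mode_set(one, list(md), c(0.05, 0.5, 1), amplitude = 0.8,
                  lambda = 20, n_orientations = 1153)
  Ath <- 0.8^2 * c(0.05, 0.5, 1)^2 / 3 / (1 + 0.8^2 * c(0.05, 0.5, 1)^2 / 3)
  expect_equal(relaxation_amplitude(mst)$A, Ath, tolerance = 1e-3)
  expect_equal(mode_diffusion(mst)$D_m[1], 0.8^2 / (3 * 20), tolerance = 1e-3)
})

test_that("attack pattern peaks near the fragment-distance scale and below
           the fragment-rotation pattern", {
  dm_a <- mode_diffusion(modeset_attack_full())
  dm_r <- mode_diffusion(modeset_fragrot_full())
  peak_a <- dm_a$Q[which.max(dm_a$D_m)]
  peak_r <- dm_r$Q[which.max(dm_r$D_m)]
  expect_gt(peak_a, 0.4)
  expect_lt(peak_a, 0.8)
  expect_gt(peak_r, peak_a)   # rotation probes the smaller fragment scale
})

test_that("composite ISF: limits and the initial-slope identity", {
  Qs <- c(0.4, 1.0)
  A <- data.frame(Q = Qs, A = c(0.3, 0.5))
  D <- c(0.03, 0.035)
  lam <- 40
  tg <- seq(0, 100, length.out = 11)
  sp <- composite_isf(A, lam, D, tg)
  expect_equal(sp$isf[sp$t == 0], c(1, 1))
  expect_true(all(tapply(sp$isf, sp$Q, function(v) all(diff(v) < 0))))
  # A = 0 reduces to a pure exponential
  sp0 <- composite_isf(data.frame(Q = Qs, A = 0), lam, D, tg)
  expect_equal(sp0$isf, exp(-rep(Qs, each = 11)^2 * rep(D, each = 11) *
                              rep(tg, 2)), tolerance = 1e-12)
  # numerical log-derivative at t -> 0 equals -Q^2 (D + A/(lambda Q^2))
  h <- 1e-5
  sph <- composite_isf(A, lam, D, c(0, h))
  slope <- log(sph$isf[sph$t == h]) / h
  expect_equal(slope, -Qs^2 * (D + A$A / (lam * Qs^2)), tolerance = 1e-4)
})

test_that("cumulant analysis: exponential input, initial slope, bounding", {
  Qs <- c(0.5, 1.1)
  tg <- seq(0, 15, length.out = 12)
  D <- c(0.04, 0.03)
  single <- composite_isf(data.frame(Q = Qs, A = 0), 10, D, tg)
  cf <- cumulant_fit(single, t_max = 15)
  expect_equal(cf$D_cum, D, tolerance = 1e-8)
  expect_equal(cf$k, c(0, 0), tolerance = 1e-8)
  # composite input with t_max -> 0 recovers the analytic initial slope
  A <- data.frame(Q = Qs, A = c(0.25, 0.45))
  fine <- composite_isf(A, 40, D, seq(0, 0.4, length.out = 15))
  cf2 <- cumulant_fit(fine, t_max = 0.4)
  expect_equal(cf2$D_cum, D + A$A / (40 * Qs^2), tolerance = 1e-5)
  # biexponential: large-window cumulant lies between the two rates
  t2 <- seq(0, 60, length.out = 30)
  bi <- nse_spectrum(rep(1, 30), t2, 0.5 * exp(-0.01 * t2) + 0.5 * exp(-0.05 * t2))
  cb <- cumulant_fit(bi, t_max = 60)
  expect_gt(cb$D_cum, 0.01)
  expect_lt(cb$D_cum, 0.05)
  expect_error(cumulant_fit(single, t_max = 1e-9), "fewer than 3")
})

test_that("global composite fit recovers exact and noisy truths", {
  ms <- modeset_fit()
  Qs <- nse_Q
  Ds <- nse_D
  g0 <- gen_nse(ms, 1.0, 40, Ds, Qs, noise_frac = 0, seed = 2)
  f0 <- fit_composite(g0$spectrum, ms)
  expect_lt(abs(f0$u_f - 1), 1e-6)
  expect_lt(abs(f0$lambda - 40), 1e-4)
  expect_lt(max(abs(f0$D_slow$D_slow - Ds)), 1e-8)
  # 3% noise: 3-sigma recovery
  g1 <- gen_nse(ms, 1.0, 40, Ds, Qs, noise_frac = 0.03, seed = 7)
  f1 <- fit_composite(g1$spectrum, ms)
  expect_lt(abs(f1$u_f - 1), 3 * f1$u_f_err)
  expect_lt(abs(f1$lambda - 40), 3 * f1$lambda_err)
  expect_true(all(abs(f1$D_slow$D_slow - Ds) < 3 * f1$D_slow$sigma))
  # null amplitude: fitted u_f consistent with zero
  gn <- gen_nse(ms, 0, 40, Ds, Qs, noise_frac = 0.02, seed = 3)
  fn <- fit_composite(gn$spectrum, ms)
  expect_lt(fn$u_f, 2 * max(fn$u_f_err, 0.02))
  # per-Q independent variant returns a per-Q table
  fq <- fit_composite(g0$spectrum, ms, share = FALSE)
  expect_equal(fq$per_Q$D_slow, Ds, tolerance = 1e-6)
})

test_that("composite fit is unbiased with ~68% coverage over replicates", {
  ms <- modeset_fit()
  Qs <- nse_Q
  Ds <- nse_D
  est <- matrix(NA_real_, 100, 4)  # u_f, err, lambda, err
  for (r in 1:100) {
    g <- gen_nse(ms, 1.0, 40, Ds, Qs, noise_frac = 0.03, seed = 1000 + r)
    f <- fit_composite(g$spectrum, ms)
    est[r, ] <- c(f$u_f, f$u_f_err, f$lambda, f$lambda_err)
  }
  expect_lt(abs(mean(est[, 1]) - 1), stats::sd(est[, 1]))       # bias < 1 sd
  expect_lt(abs(mean(est[, 3]) - 40), stats::sd(est[, 3]))
  cov_u <- mean(abs(est[, 1] - 1) < est[, 2])
  expect_gt(cov_u, 0.5); expect_lt(cov_u, 0.85)
  within3 <- mean(abs(est[, 1] - 1) < 3 * est[, 2] &
                    abs(est[, 3] - 40) < 3 * est[, 4])
  expect_gte(within3, 0.95)
})

test_that("slow-diffusion decomposition recovers the generating parameters", {
  env <- environment_conditions()
  ym <- fixture("dec_model", function() build_synthetic_ymodel(4.2, 4.6, 20L, seed = 8))
  h <- rpy_rigid_body_tensor(ym, 1.2, env)
  Rh <- stokes_einstein_radius(h$D_t, env)
  Qs <- seq(0.2, 1.8, length.out = 12)
  Qgrid <- seq(0.1, 2.2, length.out = 40)
  frs <- c("Fc", "Fab_l", "Fab_m")
  search <- mode_set(ym, c(
    lapply(frs, function(f) make_displacement_mode(ym, "search_in_plane", f)),
    lapply(frs, function(f) make_displacement_mode(ym, "search_out_of_plane", f))),
    Qgrid, n_orientations = 301)
  fragrot <- mode_set(ym, lapply(frs, function(f)
    make_displacement_mode(ym, "fragment_rotation", f)), Qgrid,
    n_orientations = 301)
  n <- 50 / 148000 * 0.602214076
  S <- structure_factor(sq_params(model = "hard_sphere_PY", radius = 5.4,
                                  volume_fraction = n * 4 * pi * 5.4^3 / 3), Qgrid)
  truth <- c(f_c = 0.75, f_r = 1.0, u_m = 1.0, u_r = 0.8)
  H <- delta_gamma_H(S, truth[["f_c"]] * Rh, n, Qs)
  Sn <- approx(S$Q, S$I, xout = Qs, rule = 2)$y
  DQ <- rigid_body_DQ(ym, h, Qs)
  dmv <- function(ms, u) {
    r <- approx(ms$Q, ms$P_alpha_sum / ms$P, xout = Qs, rule = 2)$y
    u^2 * r / (1 + u^2 * r) / (200 * Qs^2)
  }
  D_true <- h$D_t * H$H / Sn +
    truth[["f_r"]] * rotational_hindrance(attr(H, "Phi_HI")) * DQ$Dr +
    dmv(search, truth[["u_m"]]) + dmv(fragrot, truth[["u_r"]])
  set.seed(3)
  dec <- decompose_slow(data.frame(Q = Qs,
                                   D_slow = D_true * (1 + 0.01 * rnorm(12)),
                                   sigma = 0.01 * D_true),
                        h, ym, S, search, fragrot, n, Rh)
  fit <- attr(dec, "fit")
  expect_true(all(abs(fit$par - truth) < 3 * fit$errors))
  # reassembled components equal the fitted model curve exactly
  expect_lt(max(abs(dec$D_t + dec$D_r + dec$D_m_search + dec$D_m_fragrot -
                      dec$D_model)), 1e-12)
  expect_true(all(dec$D_t > 0 & dec$D_r >= 0 &
                    dec$D_m_search >= 0 & dec$D_m_fragrot >= 0))
  # null internal dynamics: D_slow = D_t alone, amplitudes fitted to zero
  H0 <- delta_gamma_H(S, 0.75 * Rh, n, Qs)
  D_null <- h$D_t * H0$H / Sn
  dec0 <- decompose_slow(data.frame(Q = Qs, D_slow = D_null,
                                    sigma = 1e-4 * D_null),
                         h, ym, S, search, fragrot, n, Rh,
                         start = c(f_c = 0.8, f_r = 0.1, u_m = 0.1, u_r = 0.1))
  f0 <- attr(dec0, "fit")
  expect_lt(f0$par[["u_m"]], 0.1)
  expect_lt(f0$par[["u_r"]], 0.1)
  expect_lt(f0$par[["f_r"]] * max(abs(dec0$D_r)), 0.02 * min(D_null))
})
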