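# Seeded synthetic-data generators with ground-truth sidecars: SAXS
# concentration series, NSE spectra, DLS correlation decays and PFG-NMR echo
# attenuations.  Every generator records its full parameter set so the
# corresponding fit operation can be validated by round trip.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

#' Ground-truth record of a synthetic data set
#'
#' @param seed Seed used.
#' @param ... Named generating parameters.
#' @return Object of class `ground_truth` (a list).
#' @export
ground_truth <- function(seed, ...) {
  structure(c(list(seed = seed), list(...)), class = "ground_truth")
}

#' Write a ground-truth sidecar as JSON
#'
#' @param truth A [ground_truth()].
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

#' Synthetic SAXS concentration series
#'
#' Generates \eqn{I(Q,c) = c/M_w \, P(Q) \, S'(Q,c)} for each concentration,
#' with multiplicative Gaussian counting noise of fractional level
#' `noise_frac` (the `sigma` column is set accordingly).  `S'` uses the
#' amplitude-asymmetry correction \eqn{S' = 1 + \beta (S - 1)}.
#'
#' @param model A [bead_model()].
#' @param sq_list List of [sq_params()] (one per concentration).
#' @param concentrations mg/ml (> 0).
#' @param Q_grid Wavevector grid (nm^-1).
#' @param M_w Molecular weight (kDa).
#' @param noise_frac Fractional noise level (0 = exact).
#' @param seed Integer seed.
#' @param n_orientations Directions for beta(Q).
#' @return List with `curves` (list of [scattering_curve()]) and `truth`
#'   (a [ground_truth()]).
#' @export
gen_saxs_series <- function(model, sq_list, concentrations, Q_grid,
                            M_w = 148, noise_frac = 0.01, seed = 1L,
                            n_orientations = 453L) {
  stopifnot(all(concentrations > 0), length(sq_list) == length(concentrations))
  P <- form_factor(model, Q_grid)
  beta <- amplitude_asymmetry(model, Q_grid, n_orientations)
  .with_seed(seed, {
    curves <- lapply(seq_along(concentrations), function(i) {
      S <- structure_factor(sq_list[[i]], Q_grid)
      Sp <- effective_structure_factor(S, beta)
      I0 <- concentrations[i] / M_w * P$I * Sp$I
      sig <- pmax(noise_frac * abs(I0), 1e-12 * max(I0))
      I <- if (noise_frac > 0) I0 * (1 + noise_frac * stats::rnorm(length(I0))) else I0
      scattering_curve(Q_grid, I, if (noise_frac > 0) sig else NULL,
                       concentration = concentrations[i])
    })
    truth <- ground_truth(seed, concentrations = concentrations, M_w = M_w,
                          noise_frac = noise_frac,
                          sq = lapply(sq_list, unclass),
                          P = list(Q = Q_grid, I = P$I))
    list(curves = curves, truth = truth)
  })
}

#' Extrapolate a concentration series to infinite dilution
#'
#' Estimates the form factor from concentration-scaled intensities
#' \eqn{M_w I(Q,c)/c} by extrapolating to c = 0, either linearly per Q point
#' (default) or with a single global linear factor.
#'
#' @param curves List of [scattering_curve()]s with concentration attributes.
#' @param M_w Molecular weight (kDa).
#' @param c_max Use only concentrations at or below this (mg/ml); the linear
#'   regime of weak interactions.
#' @param method `"per_Q"` or `"global"`.
#' @return A [scattering_curve()] estimating P(Q).
#' @export
extrapolate_form_factor <- function(curves, M_w = 148, c_max = 25,
                                    method = c("per_Q", "global")) {
  method <- match.arg(method)
  conc <- vapply(curves, function(x) attr(x, "concentration"), numeric(1))
  keep <- which(conc <= c_max)
  if (length(keep) < 2) stop("need >= 2 concentrations at or below c_max")
  Q <- curves[[keep[1]]]$Q
  scaled <- vapply(keep, function(i) M_w * curves[[i]]$I / conc[i],
                   numeric(length(Q)))
  cs <- conc[keep]
  if (method == "per_Q") {
    P <- vapply(seq_along(Q), function(j) {
      stats::coef(stats::lm(scaled[j, ] ~ cs))[[1]]
    }, numeric(1))
  } else {
    # single multiplicative interaction slope shared by all Q
    f <- function(s) {
      pred <- outer(rowMeans(scaled), 1 + s * (cs - mean(cs)))
      sum((scaled - pred)^2)
    }
    s <- stats::optimize(f, c(-0.1, 0.1))$minimum
    P <- rowMeans(scaled) * (1 + s * (0 - mean(cs)))
  }
  scattering_curve(Q, P)
}

#' Synthetic NSE spectrum from the composite two-timescale model
#'
#' Evaluates the composite ISF for a mode set with amplitude `u_f` and fast
#' relaxation time `lambda` on top of `D_slow(Q)` and adds multiplicative
#' Gaussian noise.  Default time grids emulate spin-echo ranges (maximum
#' Fourier times of order 100-300 ns).
#'
#' @param modeset A [mode_set()] (grid must cover `Q`).
#' @param u_f Common rms displacement (nm).
#' @param lambda Fast relaxation time (ns).
#' @param D_slow Numeric vector per Q (nm^2/ns), or function of Q.
#' @param Q Wavevectors (nm^-1).
#' @param t_grids List of time grids (ns) per Q, or a single grid.
#' @param noise_frac Fractional noise level.
#' @param seed Integer seed.
#' @return List with `spectrum` (an [nse_spectrum()]) and `truth`.
#' @export
gen_nse <- function(modeset, u_f, lambda, D_slow, Q,
                    t_grids = c(0, 10^seq(log10(0.5), log10(150),
                                          length.out = 24)),
                    noise_frac = 0.03, seed = 1L) {
  if (is.function(D_slow)) D_slow <- D_slow(Q)
  stopifnot(length(D_slow) == length(Q), lambda > 0, u_f >= 0)
  if (!is.list(t_grids)) t_grids <- rep(list(t_grids), length(Q))
  ratio <- stats::approx(modeset$Q, modeset$P_alpha_sum / modeset$P,
                         xout = Q, rule = 2)$y
  A <- u_f^2 * ratio / (1 + u_f^2 * ratio)
  .with_seed(seed, {
    rows <- lapply(seq_along(Q), function(i) {
      t <- t_grids[[i]]
      isf0 <- ((1 - A[i]) + A[i] * exp(-t / lambda)) *
        exp(-Q[i]^2 * D_slow[i] * t)
      sig <- pmax(noise_frac * abs(isf0), 1e-12)
      isf <- if (noise_frac > 0)
        isf0 * (1 + noise_frac * stats::rnorm(length(t))) else isf0
      data.frame(Q = Q[i], t = t, isf = isf,
                 sigma = if (noise_frac > 0) sig else NA_real_)
    })
    df <- do.call(rbind, rows)
    truth <- ground_truth(seed, u_f = u_f, lambda = lambda,
                          D_slow = as.numeric(D_slow), Q = Q, A = A,
                          noise_frac = noise_frac)
    list(spectrum = nse_spectrum(df$Q, df$t, df$isf, df$sigma), truth = truth)
  })
}

#' Synthetic DLS intensity correlation decay
#'
#' Siegert-form \eqn{g_2(t) - 1 = \beta_{coh} e^{-2 Q^2 D_c t}} with
#' additive Gaussian noise.  At the standard backscattering wavevector
#' `Q = 0.026` nm^-1 and protein-scale `D_c`, relaxation times are tens of
#' microseconds.
#'
#' @param D_c Collective diffusion coefficient (nm^2/ns, > 0).
#' @param Q Wavevector (nm^-1).
#' @param beta_coh Coherence factor.
#' @param t_grid Lag times (ns).
#' @param noise Additive noise level.
#' @param seed Integer seed.
#' @return List with `curve` (data frame `t`, `g2m1`, `sigma`) and `truth`.
#' @export
gen_dls <- function(D_c, Q = 0.026, beta_coh = 0.95,
                    t_grid = 10^seq(2, 5.7, length.out = 60),
                    noise = 0.002, seed = 1L) {
  stopifnot(D_c > 0)
  .with_seed(seed, {
    g0 <- beta_coh * exp(-2 * Q^2 * D_c * t_grid)
    g <- if (noise > 0) g0 + noise * stats::rnorm(length(t_grid)) else g0
    truth <- ground_truth(seed, D_c = D_c, Q = Q, beta_coh = beta_coh,
                          noise = noise)
    list(curve = data.frame(t = t_grid, g2m1 = g,
                            sigma = if (noise > 0) noise else NA_real_),
         truth = truth)
  })
}

#' Synthetic PFG-NMR echo attenuation
#'
#' Stejskal-Tanner attenuation
#' \eqn{E(g) = \exp(-(\gamma g \delta)^2 D (\Delta - \delta/3))} for a
#' stimulated-echo gradient sequence (gradient pulse length `delta`,
#' diffusion time `Delta`).
#'
#' @param D_s Self-diffusion coefficient (nm^2/ns, > 0).
#' @param gradients Gradient strengths (T/m).
#' @param delta Gradient pulse length (ms).
#' @param Delta Diffusion time (ms).
#' @param gamma Gyromagnetic ratio (rad s^-1 T^-1), default 1H.
#' @param noise Additive Gaussian noise level.
#' @param seed Integer seed.
#' @return List with `curve` (data frame `g`, `E`, `b`, `sigma`; `b` in
#'   s/m^2) and `truth`.
#' @export
gen_pfg <- function(D_s, gradients = seq(0, 4, length.out = 20), delta = 2,
                    Delta = 20, gamma = 2.6752218744e8, noise = 0.01,
                    seed = 1L) {
  stopifnot(D_s > 0, delta > 0, Delta > delta / 3)
  b <- (gamma * gradients * delta * 1e-3)^2 * (Delta - delta / 3) * 1e-3
  D_SI <- D_s * 1e-9   # nm^2/ns -> m^2/s
  .with_seed(seed, {
    E0 <- exp(-b * D_SI)
    E <- if (noise > 0) E0 + noise * stats::rnorm(length(E0)) else E0
    truth <- ground_truth(seed, D_s = D_s, delta_ms = delta, Delta_ms = Delta,
                          gamma = gamma, noise = noise)
    list(curve = data.frame(g = gradients, E = E, b = b,
                            sigma = if (noise > 0) noise else NA_real_),
         truth = truth)
  })
}

#' Fit a single-exponential DLS decay (first cumulant)
#'
#' @param curve Data frame `t`, `g2m1` (and optional `sigma`).
#' @param Q Wavevector (nm^-1).
#' @return List with `D_c`, `D_c_err`, `beta_coh`.
#' @export
fit_dls <- function(curve, Q = 0.026) {
  keep <- curve$g2m1 > 0
  df <- curve[keep, ]
  w <- if (is.null(df$sigma) || all(is.na(df$sigma))) (df$g2m1)^2
       else (df$g2m1 / df$sigma)^2
  fit <- stats::lm(log(g2m1) ~ t, data = df, weights = w)
  cf <- summary(fit)$coefficients
  list(D_c = -cf[2, 1] / (2 * Q^2), D_c_err = cf[2, 2] / (2 * Q^2),
       beta_coh = exp(cf[1, 1]))
}

#' Fit a Stejskal-Tanner echo attenuation
#'
#' @param curve Data frame `b` (s/m^2), `E` (and optional `sigma`).
#' @return List with `D_s` (nm^2/ns) and `D_s_err`.
#' @export
fit_pfg <- function(curve) {
  df <- curve[curve$E > 0, ]
  w <- if (is.null(df$sigma) || all(is.na(df$sigma))) df$E^2
       else (df$E / df$sigma)^2
  fit <- stats::lm(log(E) ~ b, data = df, weights = w)
  cf <- summary(fit)$coefficients
  list(D_s = -cf[2, 1] * 1e9, D_s_err = cf[2, 2] * 1e9)
}
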