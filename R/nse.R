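# Dynamic models for NSE: coherent mode form factors, relaxation amplitudes,
# the composite two-timescale intermediate scattering function, mode
# diffusion contributions, cumulant analysis and the decomposition of the
# slow diffusion coefficient.

#' Coherent mode form factor P_alpha(Q)
#'
#' \deqn{P_\alpha(Q) = \langle \sum_{kl} b_k b_l e^{iQ(r_k - r_l)}
#'   (Q\cdot d_k^\alpha)(Q\cdot d_l^\alpha) \rangle}
#' averaged over a deterministic Fibonacci direction set; real and equal to
#' \eqn{\langle |\sum_k b_k e^{iQ\hat u r_k} (Q\hat u \cdot d_k)|^2\rangle}
#' by construction.  Units: nm^-2 per (unit contrast)^2 when `d` is the
#' unit-rmsd field, so that `a^2 P_alpha` with `a` in nm is commensurate
#' with `P`.
#'
#' @param model A [bead_model()].
#' @param mode A [displacement_mode()] for the same bead count.
#' @param Q_grid Wavevector grid (nm^-1).
#' @param n_orientations Directions for the orientation average.
#' @return Data frame `Q`, `P_alpha`.
#' @export
mode_form_factor <- function(model, mode, Q_grid, n_orientations = 1153L) {
  if (nrow(mode$vectors) != nrow(model$positions))
    stop("mode and model bead counts differ")
  U <- fibonacci_sphere(n_orientations)
  pos <- model$positions
  b <- model$contrasts
  proj <- U %*% t(mode$vectors)   # n_dir x N: (u . d_k)
  Pa <- vapply(Q_grid, function(q) {
    E <- exp(1i * q * (U %*% t(pos)))
    amp <- rowSums(E * matrix(b, nrow(U), length(b), byrow = TRUE) * (q * proj))
    mean(Mod(amp)^2)
  }, numeric(1))
  data.frame(Q = Q_grid, P_alpha = Pa)
}

#' Set of displacement modes with common amplitude and relaxation time
#'
#' Precomputes the summed mode form factor \eqn{\sum_\alpha P_\alpha(Q)} and
#' the static form factor on a common Q grid, for use in relaxation
#' amplitudes, mode diffusion and the composite ISF.
#'
#' @param model A [bead_model()].
#' @param modes List of [displacement_mode()]s.
#' @param Q_grid Wavevector grid (nm^-1).
#' @param amplitude Common rms displacement scale a (nm).
#' @param lambda Common relaxation time (ns, > 0).
#' @param n_orientations Orientation-average directions.
#' @return Object of class `mode_set` with `Q`, `P`, `P_alpha_sum`,
#'   `amplitude`, `lambda`.
#' @export
mode_set <- function(model, modes, Q_grid, amplitude = 1, lambda = 200,
                     n_orientations = 1153L) {
  stopifnot(amplitude >= 0, lambda > 0, length(modes) >= 1)
  Pa <- rowSums(vapply(modes, function(m)
    mode_form_factor(model, m, Q_grid, n_orientations)$P_alpha,
    numeric(length(Q_grid))))
  P <- form_factor(model, Q_grid)$I
  structure(list(Q = Q_grid, P = P, P_alpha_sum = Pa, amplitude = amplitude,
                 lambda = lambda, kinds = vapply(modes, `[[`, "", "kind")),
            class = "mode_set")
}

.amp_curve <- function(ms, a = ms$amplitude) {
  a^2 * ms$P_alpha_sum / (ms$P + a^2 * ms$P_alpha_sum)
}

#' Relaxation amplitude A(Q) of a mode set
#'
#' \eqn{A(Q) = a^2 \sum_\alpha P_\alpha / (P + a^2 \sum_\alpha P_\alpha)},
#' in [0, 1), vanishing as a -> 0.
#'
#' @param modeset A [mode_set()].
#' @param P Optional [scattering_curve()] with the static form factor on the
#'   mode set's grid (defaults to the precomputed one).
#' @return Data frame `Q`, `A`.
#' @export
relaxation_amplitude <- function(modeset, P = NULL) {
  if (!is.null(P)) {
    if (length(P$Q) != length(modeset$Q) || max(abs(P$Q - modeset$Q)) > 1e-9)
      stop("curves are not on a common Q grid")
    modeset$P <- P$I
  }
  data.frame(Q = modeset$Q, A = .amp_curve(modeset))
}

#' Composite two-timescale intermediate scattering function
#'
#' \deqn{I(Q,t)/I(Q,0) = ((1 - A(Q)) + A(Q) e^{-t/\lambda})
#'   e^{-Q^2 D_{slow}(Q) t},}
#' a fast internal-mode relaxation of amplitude A on top of slow diffusion.
#'
#' @param A Data frame `Q`, `A` (amplitudes per Q).
#' @param lambda Fast relaxation time (ns, > 0).
#' @param D_slow Numeric vector of slow diffusion coefficients per Q
#'   (nm^2/ns), matching `A$Q`.
#' @param t_grid Fourier times (ns).
#' @return An [nse_spectrum()].
#' @export
composite_isf <- function(A, lambda, D_slow, t_grid) {
  stopifnot(lambda > 0, length(D_slow) == nrow(A))
  g <- expand.grid(t = t_grid, Q = A$Q)
  Av <- rep(A$A, each = length(t_grid))
  Dv <- rep(D_slow, each = length(t_grid))
  isf <- ((1 - Av) + Av * exp(-g$t / lambda)) * exp(-g$Q^2 * Dv * g$t)
  nse_spectrum(g$Q, g$t, isf)
}

#' Mode contribution to the effective diffusion coefficient
#'
#' \deqn{D_m(Q) = \frac{a^2}{\lambda}\frac{\sum_\alpha P_\alpha(Q)}
#'   {Q^2 [P(Q) + a^2 \sum_\alpha P_\alpha(Q)]} = \frac{A(Q)}{\lambda Q^2},}
#' in nm^2/ns for a in nm, lambda in ns, Q in nm^-1.
#'
#' @param modeset A [mode_set()].
#' @param P Optional static form factor curve (see [relaxation_amplitude()]).
#' @return Data frame `Q`, `D_m`.
#' @export
mode_diffusion <- function(modeset, P = NULL) {
  A <- relaxation_amplitude(modeset, P)
  data.frame(Q = A$Q, D_m = A$A / (modeset$lambda * A$Q^2))
}

#' Cumulant analysis of an NSE spectrum
#'
#' Per-Q weighted fit of \eqn{\ln I(Q,t) = \ln A - Q^2 D t + k t^2 / 2} for
#' \eqn{t \le t_{max}}, the model-free short-time effective diffusion
#' coefficient.
#'
#' @param spectrum An [nse_spectrum()].
#' @param t_max Fit window (ns).
#' @return Data frame `Q`, `D_cum` (nm^2/ns), `k`, `n_points`.
#' @export
cumulant_fit <- function(spectrum, t_max = 20) {
  out <- lapply(split(as.data.frame(spectrum), spectrum$Q), function(df) {
    df <- df[df$t <= t_max & df$isf > 0, ]
    if (nrow(df) < 3) stop("fewer than 3 points with t <= t_max at Q = ", df$Q[1])
    w <- if (all(is.na(df$sigma))) rep(1, nrow(df)) else (df$isf / df$sigma)^2
    fit <- stats::lm(log(isf) ~ t + I(t^2 / 2), data = df, weights = w)
    cf <- stats::coef(fit)
    data.frame(Q = df$Q[1], D_cum = -cf[["t"]] / df$Q[1]^2,
               k = cf[["I(t^2/2)"]], n_points = nrow(df))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$Q), ]
}

#' Global fit of the composite ISF to an NSE spectrum
#'
#' Fits all Q values simultaneously with a shared rms displacement `u_f`
#' (the mode amplitude, since mode fields are unit-rmsd normalised) and a
#' shared fast relaxation time `lambda`, plus an independent `D_slow(Q)` per
#' Q.  Setting `share = FALSE` instead fits (u_f, lambda, D_slow)
#' independently per Q.
#'
#' @param spectrum An [nse_spectrum()] (>= 2 Q values, >= 5 times each for
#'   the shared fit).
#' @param modeset A [mode_set()] whose grid covers the spectrum's Q values
#'   (interpolated as needed).
#' @param start Optional named start values `u_f`, `lambda`.
#' @param share Share (u_f, lambda) across Q (default) or fit per Q.
#' @return List with `u_f`, `lambda`, `D_slow` (data frame per Q with
#'   errors), and `fit` (a `fit_result`).
#' @export
fit_composite <- function(spectrum, modeset, start = c(u_f = 0.5, lambda = 30),
                          share = TRUE) {
  sp <- as.data.frame(spectrum)
  Qs <- sort(unique(sp$Q))
  if (share && length(Qs) < 2) stop("shared fit needs >= 2 Q values")
  if (min(table(sp$Q)) < 5) stop("need >= 5 time points per Q")
  ratio <- stats::approx(modeset$Q, modeset$P_alpha_sum / modeset$P,
                         xout = Qs, rule = 2)$y
  sig <- if (all(is.na(sp$sigma))) rep(1, nrow(sp)) else sp$sigma
  qidx <- match(sp$Q, Qs)
  model_resid <- function(p) {
    a <- p[["u_f"]]; lam <- p[["lambda"]]
    A <- a^2 * ratio / (1 + a^2 * ratio)
    D <- p[paste0("D", seq_along(Qs))]
    isf <- ((1 - A[qidx]) + A[qidx] * exp(-sp$t / lam)) *
      exp(-sp$Q^2 * D[qidx] * sp$t)
    (isf - sp$isf) / sig
  }
  if (share) {
    # start D from the tail slope of each Q
    D0 <- vapply(Qs, function(q) {
      df <- sp[sp$Q == q & sp$isf > 0, ]
      max(1e-4, -stats::coef(stats::lm(log(isf) ~ t, df))[2] / q^2)
    }, numeric(1))
    p0 <- c(start, stats::setNames(D0, paste0("D", seq_along(Qs))))
    lower <- c(u_f = 0, lambda = 1e-3, stats::setNames(rep(0, length(Qs)),
                                                       paste0("D", seq_along(Qs))))
    upper <- c(u_f = 50, lambda = 1e4, stats::setNames(rep(10, length(Qs)),
                                                       paste0("D", seq_along(Qs))))
    fit <- least_squares_fit(model_resid, start = p0, lower = lower, upper = upper)
    if (!fit$converged) stop("composite fit did not converge; chi^2_red = ",
                             signif(fit$chisq_red, 4))
    at_bound <- fit$par <= lower + 1e-10 | fit$par >= upper - 1e-10
    Didx <- grep("^D", names(fit$par))
    list(u_f = unname(fit$par["u_f"]), lambda = unname(fit$par["lambda"]),
         u_f_err = unname(fit$errors["u_f"]),
         lambda_err = unname(fit$errors["lambda"]),
         D_slow = data.frame(Q = Qs, D_slow = unname(fit$par[Didx]),
                             sigma = unname(fit$errors[Didx])),
         at_bound = names(fit$par)[at_bound], fit = fit)
  } else {
    rows <- lapply(seq_along(Qs), function(i) {
      sel <- sp$Q == Qs[i]
      rfun <- function(p) {
        A <- p[["u_f"]]^2 * ratio[i] / (1 + p[["u_f"]]^2 * ratio[i])
        isf <- ((1 - A) + A * exp(-sp$t[sel] / p[["lambda"]])) *
          exp(-Qs[i]^2 * p[["D"]] * sp$t[sel])
        (isf - sp$isf[sel]) / sig[sel]
      }
      df <- sp[sel & sp$isf > 0, ]
      D0 <- max(1e-4, -stats::coef(stats::lm(log(isf) ~ t, df))[2] / Qs[i]^2)
      f <- least_squares_fit(rfun, start = c(start, D = D0),
                             lower = c(u_f = 0, lambda = 1e-3, D = 0),
                             upper = c(u_f = 50, lambda = 1e4, D = 10))
      data.frame(Q = Qs[i], u_f = f$par[["u_f"]], lambda = f$par[["lambda"]],
                 D_slow = f$par[["D"]], u_f_err = f$errors[["u_f"]],
                 lambda_err = f$errors[["lambda"]], sigma = f$errors[["D"]])
    })
    list(per_Q = do.call(rbind, rows))
  }
}

#' Decomposition of the slow diffusion coefficient
#'
#' Fits the additive model
#' \deqn{D_{slow}(Q) = D_0 H(Q)/S(Q) + f_r\,h(\Phi_{HI})\,D_r(Q)
#'   + D_{m,search}(Q; u_m) + D_{m,fragrot}(Q; u_r)}
#' with free parameters `f_c` (through \eqn{R_{HI} = f_c R_h} inside the
#' hydrodynamic function), `f_r`, and the rms displacements `u_m`, `u_r` of
#' the summed "search" motions and fragment rotations (both with the fixed
#' slow relaxation time `lambda_fixed`).  \eqn{h(\Phi)} is the rotational
#' hindrance polynomial.  Emits a warning when any parameter pair is
#' correlated above 0.95 (at low concentration the search-mode and
#' whole-body-rotation patterns are nearly degenerate).
#'
#' @param D_slow Data frame `Q`, `D_slow` and optionally `sigma` (nm^2/ns).
#' @param hydro A `rigid_body_hydro` (supplies `D_t` = D_0 and, with
#'   `model`, the rotational curve).
#' @param model A [bead_model()].
#' @param S A [scattering_curve()] with S(Q) covering the fit range.
#' @param search_modeset,fragrot_modeset [mode_set()]s for the summed search
#'   motions and fragment rotations.
#' @param number_density Particle number density (nm^-3).
#' @param R_h Dilute-limit hydrodynamic radius (nm).
#' @param lambda_fixed Relaxation time of both slow mode sets (ns).
#' @param start,lower,upper Start values and box bounds for
#'   `c(f_c, f_r, u_m, u_r)`.
#' @return Object of class `diffusion_decomposition`: data frame of per-Q
#'   components (`D_t`, `D_r`, `D_m_search`, `D_m_fragrot`, `D_model`) with
#'   the fit, parameters and 1-sigma errors as attributes.
#' @export
decompose_slow <- function(D_slow, hydro, model, S, search_modeset,
                           fragrot_modeset, number_density, R_h,
                           lambda_fixed = 200,
                           start = c(f_c = 0.8, f_r = 0.8, u_m = 1, u_r = 1),
                           lower = c(f_c = 0.3, f_r = 0, u_m = 0, u_r = 0),
                           upper = c(f_c = 1.5, f_r = 2, u_m = 6, u_r = 6)) {
  Qs <- D_slow$Q
  sig <- if (is.null(D_slow$sigma) || all(is.na(D_slow$sigma)))
    rep(1, length(Qs)) else D_slow$sigma
  Svals <- stats::approx(S$Q, S$I, xout = Qs, rule = 2)$y
  Dr_rigid <- rigid_body_DQ(model, hydro, Qs)$Dr
  dm <- function(ms, u) {
    r <- stats::approx(ms$Q, ms$P_alpha_sum / ms$P, xout = Qs, rule = 2)$y
    u^2 * r / (1 + u^2 * r) / (lambda_fixed * Qs^2)
  }
  components <- function(p) {
    H <- delta_gamma_H(S, R_HI = p[["f_c"]] * R_h, number_density, Qs)
    phi <- attr(H, "Phi_HI")
    Dt <- hydro$D_t * H$H / Svals
    Dr <- p[["f_r"]] * rotational_hindrance(phi) * Dr_rigid
    list(Dt = Dt, Dr = Dr, Dms = dm(search_modeset, p[["u_m"]]),
         Dmr = dm(fragrot_modeset, p[["u_r"]]), phi = phi, H = H)
  }
  resid_fn <- function(p) {
    cmp <- components(p)
    (cmp$Dt + cmp$Dr + cmp$Dms + cmp$Dmr - D_slow$D_slow) / sig
  }
  fit <- least_squares_fit(resid_fn, start = start, lower = lower, upper = upper)
  if (!fit$converged) stop("decomposition fit did not converge")
  hi <- abs(fit$cor[upper.tri(fit$cor)]) > 0.95
  if (any(hi, na.rm = TRUE))
    warning("parameter correlation above 0.95: components are nearly degenerate")
  cmp <- components(fit$par)
  out <- data.frame(Q = Qs, D_slow = D_slow$D_slow, sigma = sig,
                    D_t = cmp$Dt, D_r = cmp$Dr, D_m_search = cmp$Dms,
                    D_m_fragrot = cmp$Dmr,
                    D_model = cmp$Dt + cmp$Dr + cmp$Dms + cmp$Dmr)
  attr(out, "fit") <- fit
  attr(out, "Phi_HI") <- cmp$phi
  attr(out, "self_part") <- attr(cmp$H, "self_part")
  attr(out, "lambda_fixed") <- lambda_fixed
  class(out) <- c("diffusion_decomposition", "data.frame")
  out
}
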