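# Ornstein-Uhlenbeck model of harmonically bound fragment motion: coherent
# ISF, parameter fitting, entropic-spring estimates and force-unit
# conversion.

#' Ornstein-Uhlenbeck fragment parameters
#'
#' Overdamped Brownian motion of a fragment in a harmonic potential: total
#' force constant `k_f` (g ps^-2 mol^-1) and total friction `xi`
#' (kg ps^-1 mol^-1) per fragment.  With the constraint that the effective
#' potential force and the friction force balance, the relaxation time is
#' `lambda = xi / k_f` (ns in these units) and the equilibrium rms
#' displacement follows from equipartition, `u_f = sqrt(kT / k_f)` (nm).
#'
#' @param k_f Force constant (g ps^-2 mol^-1, > 0).
#' @param xi Friction (kg ps^-1 mol^-1, > 0).
#' @param temperature K.
#' @return Object of class `ou_params` with derived `lambda` (ns) and
#'   `u_f` (nm).
#' @export
ou_params <- function(k_f, xi, temperature = 298.15) {
  stopifnot(k_f > 0, xi > 0)
  kT <- kT_molar(temperature)
  structure(list(k_f = k_f, xi = xi, temperature = temperature,
                 lambda = xi / k_f, u_f = sqrt(kT / k_f),
                 Gamma = xi), class = "ou_params")
}

#' @export
print.ou_params <- function(x, ...) {
  cat(sprintf("ou_params: k_f = %.4g g/ps^2/mol, xi = %.4g kg/ps/mol,",
              x$k_f, x$xi),
      sprintf("lambda = %.4g ns, u_f = %.4g nm\n", x$lambda, x$u_f))
  invisible(x)
}

#' Coherent ISF of Ornstein-Uhlenbeck fragment motion
#'
#' Evaluates, orientation-averaged over a Fibonacci direction set,
#' \deqn{I_{OU}(Q,t) = \langle \sum_{kl} b_k b_l e^{iQ(R_k - R_l)}
#'   f_{kl}(Q,\infty) f'_{kl}(Q,t) \rangle}
#' with the Debye-Waller-like factor
#' \eqn{f_{kl}(\infty) = \exp(-\frac12\sum_j[(d_{jk}Q)^2 + (d_{jl}Q)^2])},
#' displacements \eqn{d_{jk} = \sqrt{kT/k_j}\,\hat e_{jk}}, and time part
#' \eqn{f'_{kl}(t) = \exp(\sum_j (v_{jk}Q)(v_{jl}Q) e^{-t/\lambda_j})} with
#' \eqn{v_{jk} = \sqrt{kT/(\lambda_j\Gamma_j)}\,\hat b_{jk}}.  Under the
#' balance constraint \eqn{k_j = \lambda_j \Gamma_j} (enforced here),
#' \eqn{d = v} and the t = 0 value equals the Gaussian-ensemble static form
#' factor; the t -> infinity plateau is the Debye-Waller-suppressed static
#' term.
#'
#' @param model A [bead_model()].
#' @param attack_modes List of [displacement_mode()]s (one per fragment);
#'   the per-bead unit direction fields define \eqn{\hat e_{jk}}.
#' @param params An [ou_params()] (shared by all modes).
#' @param Q Wavevectors (nm^-1).
#' @param t_grid Times (ns).
#' @param n_orientations Orientation-average directions.
#' @return An [nse_spectrum()] normalised to the t = 0 value, with
#'   attributes `I0` and `plateau` (per Q, unnormalised).
#' @export
ou_isf <- function(model, attack_modes, params, Q, t_grid,
                   n_orientations = 229L) {
  stopifnot(inherits(params, "ou_params"), all(t_grid >= 0))
  Q <- sort(unique(Q))
  kT <- kT_molar(params$temperature)
  amp <- sqrt(kT / params$k_f)           # nm, = sqrt(kT/(lambda Gamma))
  lam <- params$lambda
  U <- fibonacci_sphere(n_orientations)
  pos <- model$positions
  b <- model$contrasts
  N <- length(b)
  # unit direction field per mode (zero rows stay zero)
  E <- lapply(attack_modes, function(m) {
    v <- m$vectors
    nr <- sqrt(rowSums(v^2))
    v[nr > 0, ] <- v[nr > 0, ] / nr[nr > 0]
    v
  })
  tgrid <- sort(unique(t_grid))
  res <- lapply(Q, function(q) {
    acc <- numeric(length(tgrid)); acc_inf <- 0; acc0 <- 0
    for (m in seq_len(n_orientations)) {
      u <- U[m, ]
      w <- vapply(E, function(e) amp * q * drop(e %*% u), numeric(N)) # N x J
      C <- tcrossprod(w)                  # C_kl = sum_j (d_jk Q)(d_jl Q)
      if (max(diag(C)) > 350)
        stop("exponent overflow: Q * u_f too large for the OU Gaussian model")
      g <- exp(-0.5 * diag(C))
      ph <- exp(1i * q * drop(pos %*% u))
      mvec <- b * g * ph
      M0 <- Re(mvec %*% Conj(t(mvec)))    # static x Debye-Waller weights
      acc_inf <- acc_inf + sum(M0)
      for (it in seq_along(tgrid))
        acc[it] <- acc[it] + sum(M0 * exp(C * exp(-tgrid[it] / lam)))
      acc0 <- acc0 + sum(M0 * exp(C))
    }
    list(isf = acc / acc0, I0 = acc0 / n_orientations,
         plateau = acc_inf / acc0)
  })
  spec <- nse_spectrum(rep(Q, each = length(tgrid)),
                       rep(tgrid, length(Q)),
                       unlist(lapply(res, `[[`, "isf")))
  attr(spec, "I0") <- vapply(res, `[[`, numeric(1), "I0")
  attr(spec, "plateau") <- vapply(res, `[[`, numeric(1), "plateau")
  spec
}

#' Fit Ornstein-Uhlenbeck parameters to an NSE spectrum
#'
#' Fits the fast relaxation of a spectrum with the OU coherent ISF (times an
#' optional slow-diffusion factor \eqn{e^{-Q^2 D_{slow} t}}), either in the
#' mechanical parameterisation `(k_f, xi)` or in the observable
#' parameterisation `(u_f, lambda)` (converted internally via
#' \eqn{k_f = kT/u_f^2}, \eqn{\xi = k_f \lambda}).  Reports both sets with
#' 1-sigma errors propagated from the fitted pair.
#'
#' @param spectrum An [nse_spectrum()] resolving the fast window.
#' @param model,attack_modes As in [ou_isf()].
#' @param D_slow Slow diffusion coefficient(s) per Q (nm^2/ns), fixed.
#' @param start Named start values for the chosen parameterisation.
#' @param parameterisation `"force"` (k_f, xi) or `"displacement"`
#'   (u_f, lambda).
#' @param temperature K.
#' @param n_orientations Orientation-average directions.
#' @return List with `params` (an [ou_params()]), `u_f`, `lambda`, errors,
#'   and `fit`.
#' @export
fit_ou <- function(spectrum, model, attack_modes, D_slow = 0,
                   start = NULL,
                   parameterisation = c("force", "displacement"),
                   temperature = 298.15, n_orientations = 121L) {
  parameterisation <- match.arg(parameterisation)
  kT <- kT_molar(temperature)
  sp <- as.data.frame(spectrum)
  Qs <- sort(unique(sp$Q))
  if (length(D_slow) == 1) D_slow <- rep(D_slow, length(Qs))
  sig <- if (all(is.na(sp$sigma))) rep(1, nrow(sp)) else sp$sigma
  to_mech <- function(p) {
    if (parameterisation == "force") c(k_f = p[[1]], xi = p[[2]])
    else c(k_f = kT / p[[1]]^2, xi = kT / p[[1]]^2 * p[[2]])
  }
  resid_fn <- function(p) {
    mech <- to_mech(p)
    op <- ou_params(mech[["k_f"]], mech[["xi"]], temperature)
    pred <- tryCatch({
      unlist(lapply(seq_along(Qs), function(i) {
        tq <- sp$t[sp$Q == Qs[i]]
        s <- ou_isf(model, attack_modes, op, Qs[i], tq, n_orientations)
        s$isf * exp(-Qs[i]^2 * D_slow[i] * tq)
      }))
    }, error = function(e) NULL)  # e.g. Gaussian-exponent overflow
    if (is.null(pred)) return(rep(1e4, nrow(sp)))
    (pred - sp$isf) / sig
  }
  if (is.null(start))
    start <- if (parameterisation == "force") c(k_f = 2, xi = 70)
             else c(u_f = 1, lambda = 35)
  lower <- if (parameterisation == "force") c(k_f = 1e-3, xi = 1e-3)
           else c(u_f = 1e-3, lambda = 1e-2)
  upper <- if (parameterisation == "force") c(k_f = 1e3, xi = 1e4)
           else c(u_f = 20, lambda = 1e4)
  fit <- least_squares_fit(resid_fn, start = start, lower = lower, upper = upper)
  if (!fit$converged) stop("OU fit did not converge")
  mech <- to_mech(fit$par)
  op <- ou_params(mech[["k_f"]], mech[["xi"]], temperature)
  # first-order error propagation between parameterisations
  if (parameterisation == "force") {
    k_err <- fit$errors[["k_f"]]; xi_err <- fit$errors[["xi"]]
    u_err <- 0.5 * op$u_f / op$k_f * k_err
    l_err <- op$lambda * sqrt((xi_err / op$xi)^2 + (k_err / op$k_f)^2)
  } else {
    u_err <- fit$errors[["u_f"]]; l_err <- fit$errors[["lambda"]]
    k_err <- 2 * op$k_f / op$u_f * u_err
    xi_err <- op$xi * sqrt((k_err / op$k_f)^2 + (l_err / op$lambda)^2)
  }
  amplitude_zero <- op$u_f < 2 * u_err
  list(params = op, u_f = op$u_f, lambda = op$lambda,
       k_f_err = k_err, xi_err = xi_err, u_f_err = u_err, lambda_err = l_err,
       amplitude_consistent_with_zero = amplitude_zero, fit = fit)
}

#' Entropic spring constant of a Gaussian linker chain
#'
#' Three-dimensional Gaussian-chain restoring constant
#' \eqn{k = 3 k_B T / (N b^2)} in molar mechanical units, for a linker of
#' `N` segments of length `b`.  (The one-dimensional form \eqn{kT/(Nb^2)}
#' underestimates the restoring force of an isotropic tether by a factor 3;
#' the 3D form matches the per-fragment force-constant scale of the hinge
#' linker.)
#'
#' @param N_segments Number of Kuhn segments (> 0).
#' @param b_segment Segment length (nm).
#' @param temperature K.
#' @return Spring constant in g ps^-2 mol^-1.
#' @export
entropic_spring_constant <- function(N_segments, b_segment = 0.38,
                                     temperature = 298.15) {
  stopifnot(N_segments > 0, b_segment > 0, temperature > 0)
  3 * kT_molar(temperature) / (N_segments * b_segment^2)
}

# 1 g ps^-2 mol^-1 in pN/nm (via Avogadro's constant)
.force_unit_factor <- 1e24 / .NA  # = 1.66054

#' Convert force constants between molar and single-molecule units
#'
#' 1 g ps^-2 mol^-1 = 1.66 pN/nm.
#'
#' @param value Numeric value(s).
#' @param from,to `"g_ps2_mol"` or `"pN_nm"`.
#' @return Converted value(s).
#' @export
force_unit_convert <- function(value, from = c("g_ps2_mol", "pN_nm"),
                               to = c("pN_nm", "g_ps2_mol")) {
  from <- match.arg(from); to <- match.arg(to)
  if (from == to) return(value)
  if (from == "g_ps2_mol") value * .force_unit_factor
  else value / .force_unit_factor
}
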