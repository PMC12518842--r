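# Colloidal hydrodynamics: rigid-body bead-model diffusion tensors,
# Q-dependent rigid-body diffusion, the delta-gamma-type hydrodynamic
# function, rotational hindrance, Stokes-Einstein conversions, temperature
# rescaling and hard-sphere self-diffusion model curves.

#' Solvent / temperature conditions
#'
#' @param temperature Temperature (K).
#' @param viscosity Solvent viscosity (mPa s).  If `NULL`, taken from the
#'   empirical correlation for the chosen solvent at `temperature`.
#' @param solvent `"D2O"`, `"H2O"` or `"custom"`.
#' @return Object of class `environment_conditions`.
#' @export
environment_conditions <- function(temperature = 298.15, viscosity = NULL,
                                   solvent = c("D2O", "H2O", "custom")) {
  solvent <- match.arg(solvent)
  if (is.null(viscosity)) {
    if (solvent == "custom") stop("custom solvent requires explicit viscosity")
    viscosity <- solvent_viscosity(temperature, solvent)
  }
  stopifnot(temperature > 0, viscosity > 0)
  structure(list(temperature = temperature, viscosity = viscosity,
                 solvent = solvent), class = "environment_conditions")
}

#' Solvent viscosity correlation (5-45 degrees C)
#'
#' H2O from the Vogel correlation
#' \eqn{\eta = 0.02414 \cdot 10^{247.8/(T-140)}} mPa s; D2O from the same
#' correlation times an empirical quadratic isotope ratio anchored at
#' 1.095 mPa s / 25 degrees C.
#'
#' @param temperature K.
#' @param solvent `"D2O"` or `"H2O"`.
#' @return Viscosity in mPa s.
#' @export
solvent_viscosity <- function(temperature, solvent = c("D2O", "H2O")) {
  solvent <- match.arg(solvent)
  if (any(temperature < 278.15 - 1e-9 | temperature > 318.15 + 1e-9))
    stop("temperature outside the 5-45 degrees C correlation range")
  eta_h2o <- 0.02414 * 10^(247.8 / (temperature - 140))
  if (solvent == "H2O") return(eta_h2o)
  dT <- temperature - 298.15
  ratio <- 1.2296 - 2.73e-3 * dT + 6.69e-5 * dT^2
  eta_h2o * ratio
}

#' Rigid-body diffusion tensor of a bead model (Rotne-Prager-Yamakawa)
#'
#' Builds the 3N x 3N RPY translational mobility supermatrix
#' (overlap-corrected), inverts it to bead-level frictions, projects onto
#' rigid-body translation + rotation, adds the per-bead rotational friction
#' \eqn{8\pi\eta a^3}, and inverts the resulting 6 x 6 friction matrix to the
#' diffusion matrix (times kT), referenced to the centre of diffusion (the
#' point where the translation-rotation coupling is symmetric, removing the
#' reference-point ambiguity).
#'
#' @param model A [bead_model()].
#' @param bead_radius Hydrodynamic bead radius (nm).
#' @param env An [environment_conditions()].
#' @return Object of class `rigid_body_hydro` with elements
#'   `diffusion_matrix` (6 x 6; translation block nm^2/ns, rotation block
#'   1/ns), `D_t` (nm^2/ns), `D_r0` (1/ns) and `center` (nm).
#' @export
rpy_rigid_body_tensor <- function(model, bead_radius,
                                  env = environment_conditions()) {
  stopifnot(bead_radius > 0)
  pos <- model$positions
  N <- nrow(pos)
  a <- bead_radius
  # kT/(pi eta) in nm^3/ns
  kT_pe <- .kT_over_eta(env$temperature, env$viscosity) / pi
  M <- matrix(0, 3 * N, 3 * N)
  for (i in seq_len(N)) {
    M[3 * i - 2:0, 3 * i - 2:0] <- diag(3) / (6 * a)
    if (i < N) for (j in (i + 1):N) {
      rij <- pos[j, ] - pos[i, ]
      r <- sqrt(sum(rij^2))
      if (r < 1e-9) stop("exact bead-centre overlap between beads ", i, " and ", j)
      e <- rij / r
      ee <- tcrossprod(e)
      B <- if (r >= 2 * a) {
        (1 / (8 * r)) * ((1 + 2 * a^2 / (3 * r^2)) * diag(3) +
                         (1 - 2 * a^2 / r^2) * ee)
      } else {
        (1 / (6 * a)) * ((1 - 9 * r / (32 * a)) * diag(3) +
                         (3 * r / (32 * a)) * ee)
      }
      M[3 * i - 2:0, 3 * j - 2:0] <- B
      M[3 * j - 2:0, 3 * i - 2:0] <- B
    }
  }
  Z <- tryCatch(solve(M), error = function(e)
    stop("singular RPY supermatrix: ", conditionMessage(e)))
  # 6x6 friction at the origin; A_i = skew(r_i)
  Att <- matrix(0, 3, 3); Atr <- matrix(0, 3, 3); Arr <- matrix(0, 3, 3)
  Art <- matrix(0, 3, 3)
  Ai <- lapply(seq_len(N), function(i) .skew(pos[i, ]))
  for (i in seq_len(N)) for (j in seq_len(N)) {
    Zij <- Z[3 * i - 2:0, 3 * j - 2:0]
    Att <- Att + Zij
    Atr <- Atr - Zij %*% Ai[[j]]
    Art <- Art + Ai[[i]] %*% Zij
    Arr <- Arr - Ai[[i]] %*% Zij %*% Ai[[j]]
  }
  # each bead co-rotates with the body: per-bead spin friction 8 pi eta a^3
  Arr <- Arr + diag(3) * (8 * a^3) * N
  Xi <- rbind(cbind(Att, Atr), cbind(Art, Arr))
  Xi <- (Xi + t(Xi)) / 2
  Dmat <- kT_pe * solve(Xi)   # friction entries are in units of pi*eta
  # shift to the centre of diffusion: solve linear system for s such that
  # the coupling block D_tr(s) = D_tr(0) - skew(s) D_rr is symmetric
  Dtr <- Dmat[1:3, 4:6]; Drr <- Dmat[4:6, 4:6]
  asym <- function(Mx) c(Mx[3, 2] - Mx[2, 3], Mx[1, 3] - Mx[3, 1],
                         Mx[2, 1] - Mx[1, 2])
  Amat <- vapply(1:3, function(k) {
    ek <- numeric(3); ek[k] <- 1
    asym(.skew(ek) %*% Drr)
  }, numeric(3))
  s <- tryCatch(solve(Amat, asym(Dtr)), error = function(e) c(0, 0, 0))
  Tmap <- rbind(cbind(diag(3), -.skew(s)), cbind(matrix(0, 3, 3), diag(3)))
  Dcd <- Tmap %*% Dmat %*% t(Tmap)
  Dcd <- (Dcd + t(Dcd)) / 2
  structure(list(diffusion_matrix = Dcd,
                 D_t = sum(diag(Dcd[1:3, 1:3])) / 3,
                 D_r0 = sum(diag(Dcd[4:6, 4:6])) / 3,
                 center = s), class = "rigid_body_hydro")
}

#' @export
print.rigid_body_hydro <- function(x, ...) {
  cat("rigid_body_hydro: D_t =", signif(x$D_t, 4), "nm^2/ns, D_r0 =",
      signif(x$D_r0, 5), "1/ns\n")
  invisible(x)
}

#' Q-dependent rigid-body diffusion coefficient D_0(Q)
#'
#' First-cumulant effective diffusion of a rigid scatterer including coupled
#' translation and rotation,
#' \deqn{D_0(Q) = \frac{1}{Q^2 P(Q)} \left\langle \rho(Q)
#'   (Q, Q \times r_k) D (Q, Q \times r_l) \rho^*(Q) \right\rangle,}
#' orientation-averaged over a deterministic Fibonacci direction set.  Bead
#' positions are referenced to the tensor's centre of diffusion.  The Q -> 0
#' limit is the translational coefficient `D_t`; the rotational contribution
#' is `D_0(Q) - D_t >= 0`.
#'
#' @param model A [bead_model()].
#' @param hydro A `rigid_body_hydro` for the same geometry.
#' @param Q_grid Wavevector grid (nm^-1).
#' @param n_orientations Directions for the orientation average.
#' @return Data frame with columns `Q`, `D0` (nm^2/ns) and `Dr`
#'   (`= D0 - D_t`).
#' @export
rigid_body_DQ <- function(model, hydro, Q_grid, n_orientations = 453L) {
  U <- fibonacci_sphere(n_orientations)
  pos <- sweep(model$positions, 2, hydro$center)
  b <- model$contrasts
  Dm <- hydro$diffusion_matrix
  N <- nrow(pos)
  D0 <- vapply(Q_grid, function(q) {
    num <- 0; den <- 0
    for (m in seq_len(n_orientations)) {
      u <- U[m, ]
      ph <- exp(1i * q * drop(pos %*% u))
      qxr <- q * cbind(u[2] * pos[, 3] - u[3] * pos[, 2],
                       u[3] * pos[, 1] - u[1] * pos[, 3],
                       u[1] * pos[, 2] - u[2] * pos[, 1])
      Avec <- cbind(matrix(q * u, N, 3, byrow = TRUE), qxr)  # N x 6
      s <- crossprod(Avec, b * ph)                            # 6 x 1 complex
      num <- num + Re(Conj(t(s)) %*% Dm %*% s)
      den <- den + sum(Mod(sum(b * ph))^2)
    }
    num / (q^2 * den)
  }, numeric(1))
  data.frame(Q = Q_grid, D0 = D0, Dr = D0 - hydro$D_t)
}

# --- delta-gamma-type hydrodynamic function ------------------------------

# short-time self-diffusion of hard spheres used to calibrate the
# microstructure weight: D_s^s/D_0 = 2(1-phi)/(2+3phi)
.Ds_hard_sphere <- function(phi) 2 * (1 - phi) / (2 + 3 * phi)

# gamma(phi) such that the Eq.-13-type quadrature with
# S_gamma(x|phi) = gamma * sinc^2(x) reproduces .Ds_hard_sphere(phi)
.sgamma_scale <- function(phi, nodes = 4000L, tmax = 300) {
  if (phi <= 0) return(0)
  t <- (seq_len(nodes) - 0.5) * tmax / nodes
  w <- .sinc(t)^2
  target <- .Ds_hard_sphere(phi)
  # normalised by the zero-coupling quadrature so the dilute limit is exact
  f <- function(g) sum(w / (1 + phi * g * w)) / sum(w) - target
  stats::uniroot(f, c(1e-10, 1e6), tol = 1e-12)$root
}

#' Hydrodynamic function H(Q) (delta-gamma-type scheme)
#'
#' Computes \eqn{H(Q) = H_d(Q) + D_s^s/D_0} for spheres of hydrodynamic
#' interaction radius `R_HI` at number density `n`:
#' the self part from the quadrature
#' \eqn{D_s^s/D_0 = (2/\pi)\int_0^\infty dt\, \mathrm{sinc}^2(t)
#' [1 + \Phi_{HI} S_\gamma(t)]^{-1}} and the distinct part from the double
#' integral
#' \eqn{H_d(Q) = \frac{3}{2\pi}\int_0^\infty dx\,
#' \frac{\sin^2 x}{x^2 [1+\Phi_{HI} S_\gamma(x)]}
#' \int_{-1}^{1} d\mu (1-\mu^2) (S(|\vec Q - \vec k|) - 1)}
#' with \eqn{x = R_{HI} k}.  The microstructure weight
#' \eqn{S_\gamma(x|\Phi)} is a separable calibrated form (see the methods
#' vignette): its amplitude is fixed per volume fraction so the self part
#' reproduces the hard-sphere short-time self-diffusion closed form
#' \eqn{2(1-\Phi)/(2+3\Phi)}; it vanishes in the dilute limit, giving
#' \eqn{H \to 1}.  The structure factor is extended by \eqn{S \to 1} beyond
#' its data range.
#'
#' @param S A [scattering_curve()] holding S(Q).
#' @param R_HI Hydrodynamic interaction radius (nm).
#' @param number_density Particle number density (nm^-3).
#' @param Q_grid Output wavevector grid (nm^-1).
#' @param n_x,n_mu Quadrature nodes for the radial and angular integrals.
#' @param x_max Radial cutoff in units of R_HI k.
#' @return Object of class `hydrodynamic_function`: data frame `Q`, `H`,
#'   `Hd`, with attributes `self_part`, `R_HI`, `Phi_HI`.
#' @export
delta_gamma_H <- function(S, R_HI, number_density, Q_grid,
                          n_x = 240L, n_mu = 32L, x_max = 80) {
  stopifnot(R_HI > 0, number_density >= 0)
  phi <- number_density * 4 * pi * R_HI^3 / 3
  if (phi >= 0.64) stop("Phi_HI out of range: ", signif(phi, 3))
  Sfun <- stats::approxfun(S$Q, S$I, rule = 2)
  gam <- .sgamma_scale(phi)
  # self part: quadrature normalised by its zero-coupling value, so the
  # dilute limit is exactly 1
  t <- (seq_len(4000L) - 0.5) * 300 / 4000L
  wts <- .sinc(t)^2
  self_part <- if (phi == 0) 1 else
    sum(wts / (1 + phi * gam * wts)) / sum(wts)
  # distinct part: Gauss-Legendre in x and mu
  gx <- pracma::gaussLegendre(n_x, 0, x_max)
  gm <- pracma::gaussLegendre(n_mu, -1, 1)
  wx <- .sinc(gx$x)^2 / (1 + phi * gam * .sinc(gx$x)^2)
  k <- gx$x / R_HI
  Hd <- vapply(Q_grid, function(q) {
    inner <- vapply(seq_along(k), function(i) {
      qprime <- sqrt(pmax(q^2 + k[i]^2 - 2 * q * k[i] * gm$x, 0))
      sum(gm$w * (1 - gm$x^2) * (Sfun(qprime) - 1))
    }, numeric(1))
    (3 / (2 * pi)) * sum(gx$w * wx * inner)
  }, numeric(1))
  out <- data.frame(Q = Q_grid, H = Hd + self_part, Hd = Hd)
  attr(out, "self_part") <- self_part
  attr(out, "R_HI") <- R_HI
  attr(out, "Phi_HI") <- phi
  class(out) <- c("hydrodynamic_function", "data.frame")
  out
}

#' Rotational hindrance factor
#'
#' Reduction of rotational diffusion by hydrodynamic crowding,
#' \eqn{1 - 0.631\,\Phi_{HI} - 0.726\,\Phi_{HI}^2}.
#'
#' @param phi_HI Hydrodynamic volume fraction, in [0, 0.64).
#' @return Numeric factor.
#' @export
rotational_hindrance <- function(phi_HI) {
  if (any(phi_HI < 0 | phi_HI >= 0.64)) stop("Phi_HI out of [0, 0.64)")
  1 - 0.631 * phi_HI - 0.726 * phi_HI^2
}

#' Stokes-Einstein conversions
#'
#' \eqn{R_h = kT / (6 \pi \eta D_0)} and its inverse.
#'
#' @param D0 Translational diffusion coefficient (nm^2/ns).
#' @param env An [environment_conditions()].
#' @return Hydrodynamic radius in nm.
#' @export
stokes_einstein_radius <- function(D0, env = environment_conditions()) {
  stopifnot(D0 > 0)
  .kT_over_eta(env$temperature, env$viscosity) / (6 * pi * D0)
}

#' @rdname stokes_einstein_radius
#' @param R_h Hydrodynamic radius (nm).
#' @export
stokes_einstein_D <- function(R_h, env = environment_conditions()) {
  stopifnot(R_h > 0)
  .kT_over_eta(env$temperature, env$viscosity) / (6 * pi * R_h)
}

#' Rescale a diffusion coefficient to a reference temperature
#'
#' \eqn{D_{ref} = D \cdot (T_{ref}/T) \cdot \eta(T)/\eta(T_{ref})} using the
#' solvent viscosity correlation (valid 5-45 degrees C).
#'
#' @param D Measured diffusion coefficient.
#' @param T_meas,T_ref Measurement and reference temperatures (K).
#' @param solvent `"D2O"` or `"H2O"`.
#' @return Rescaled coefficient.
#' @export
temperature_rescale <- function(D, T_meas, T_ref = 298.15, solvent = "D2O") {
  D * (T_ref / T_meas) *
    (solvent_viscosity(T_meas, solvent) / solvent_viscosity(T_ref, solvent))
}

#' Virial fit of collective diffusion vs concentration
#'
#' Weighted linear fit of \eqn{D_c(c) = D_0 (1 + k_D c)}; returns the
#' infinite-dilution coefficient and the interaction parameter with 1-sigma
#' errors.
#'
#' @param concentration Concentrations (mg/ml), >= 3 values.
#' @param D_c Measured collective diffusion coefficients (nm^2/ns).
#' @param sigma Optional 1-sigma errors of `D_c`.
#' @return List with `D_0`, `k_D`, `D_0_err`, `k_D_err` and the underlying
#'   `lm` fit.
#' @export
interaction_expansion_fit <- function(concentration, D_c, sigma = NULL) {
  stopifnot(length(concentration) >= 3, length(D_c) == length(concentration))
  if (length(unique(concentration)) < 2) stop("degenerate design: need >= 2 distinct concentrations")
  w <- if (is.null(sigma)) NULL else 1 / sigma^2
  fit <- stats::lm(D_c ~ concentration, weights = w)
  cf <- summary(fit)$coefficients
  D0 <- cf[1, 1]; slope <- cf[2, 1]
  kD <- slope / D0
  # error propagation for the ratio (ignoring intercept-slope covariance term
  # beyond first order)
  V <- stats::vcov(fit)
  kD_err <- abs(kD) * sqrt(V[2, 2] / slope^2 + V[1, 1] / D0^2 -
                             2 * V[1, 2] / (slope * D0))
  list(D_0 = D0, k_D = kD, D_0_err = cf[1, 2], k_D_err = kD_err, fit = fit)
}

#' Hard-sphere short- and long-time self-diffusion model curves
#'
#' Closed-form hard-sphere models linking short- and long-time self-diffusion
#' to volume fraction: a virial-type short-time form
#' \eqn{1 - 1.73\Phi + 0.88\Phi^2} with the cage-relaxation factorisation
#' \eqn{D^l_s = D^s_s / (1 + 2\Phi g(\sigma;\Phi))} (Percus-Yevick contact
#' value), and the Tokuyama-Oppenheim short-time form with its long-time
#' extension.  All curves equal 1 at \eqn{\Phi = 0} and the long-time curve
#' lies below its short-time counterpart.
#'
#' @param phi Volume-fraction grid in [0, 0.5].
#' @return Data frame `phi`, `short_virial`, `long_virial`, `short_TO`,
#'   `long_TO`.
#' @export
self_diffusion_models <- function(phi) {
  if (any(phi < 0 | phi > 0.5)) stop("phi out of [0, 0.5]")
  short_v <- 1 - 1.73 * phi + 0.88 * phi^2
  g_contact <- (1 + phi / 2) / (1 - phi)^2
  long_v <- short_v / (1 + 2 * phi * g_contact)
  b <- sqrt(9 * phi / 8); c2 <- 11 * phi / 16
  Hto <- 2 * b^2 / (1 - b) - c2 / (1 + 2 * c2) -
    b * c2 * (2 + c2) / ((1 + c2) * (1 - b + c2))
  short_to <- 1 / (1 + Hto)
  phi0 <- (4 / 3)^3 / (7 * log(3) - 8 * log(2) + 2)
  long_to <- short_to / (1 + 2 * short_to * (phi / phi0) * (1 - phi / phi0)^(-2))
  data.frame(phi = phi, short_virial = short_v, long_virial = long_v,
             short_TO = short_to, long_TO = long_to)
}
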