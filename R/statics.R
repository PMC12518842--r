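# Static scattering: form factor, amplitude asymmetry, structure factors,
# SAXS intensity assembly and configuration refinement.

#' Orientation-averaged form factor by exact Debye summation
#'
#' \eqn{P(Q) = \sum_{kl} b_k b_l \, \mathrm{sinc}(Q r_{kl})}; exact (no
#' orientational sampling), with \eqn{P(0) = (\sum_k b_k)^2}.
#'
#' @param model A [bead_model()].
#' @param Q_grid Wavevector grid (nm^-1, ascending, > 0).
#' @return A [scattering_curve()] with `I = P(Q)`.
#' @export
form_factor <- function(model, Q_grid) {
  stopifnot(all(Q_grid > 0), all(diff(Q_grid) > 0))
  D <- as.matrix(stats::dist(model$positions))
  W <- tcrossprod(model$contrasts)
  P <- vapply(Q_grid, function(q) sum(W * .sinc(q * D)), numeric(1))
  scattering_curve(Q_grid, P)
}

# complex scattering amplitudes rho(Q u) for all directions (rows of U)
.amplitudes <- function(model, Q, U, origin = NULL) {
  if (is.null(origin)) {
    w <- model$contrasts
    origin <- colSums(model$positions * w) / sum(w)
  }
  pos <- sweep(model$positions, 2, origin)
  phase <- Q * (U %*% t(pos))            # n_dir x N
  exp(1i * phase) %*% model$contrasts    # n_dir x 1 complex
}

#' Scattering-amplitude asymmetry factor beta(Q)
#'
#' \eqn{\beta(Q) = |\langle\rho(Q)\rangle|^2 / \langle|\rho(Q)|^2\rangle},
#' the decoupling-approximation factor that converts the interparticle
#' structure factor of an anisotropic particle into its apparent form
#' \eqn{S'(Q)}.  Orientation averages use a deterministic Fibonacci-sphere
#' direction set; amplitudes are referenced to the contrast-weighted centroid.
#' \eqn{\beta \in [0, 1]} with \eqn{\beta(0) = 1}.
#'
#' @param model A [bead_model()].
#' @param Q_grid Wavevector grid (nm^-1).
#' @param n_orientations Number of quadrature directions (>= 2).
#' @return Data frame with columns `Q`, `beta`.
#' @export
amplitude_asymmetry <- function(model, Q_grid, n_orientations = 1153L) {
  stopifnot(n_orientations >= 2)
  U <- fibonacci_sphere(n_orientations)
  beta <- vapply(Q_grid, function(q) {
    if (q == 0) return(1)
    rho <- .amplitudes(model, q, U)
    Mod(mean(rho))^2 / mean(Mod(rho)^2)
  }, numeric(1))
  data.frame(Q = Q_grid, beta = pmin(1, beta))
}

#' Interaction parameters for colloidal structure factors
#'
#' @param model One of `"unity"`, `"hard_sphere_PY"`, `"RMSA"`, `"tabulated"`.
#' @param radius Effective interaction radius (nm).
#' @param volume_fraction Volume fraction (0 to < 0.64).
#' @param charge Effective charge (e), used by RMSA.
#' @param ionic_strength Ionic strength (mM), used by RMSA.
#' @param density_basis `"protein"` or `"fragment"`; see
#'   [sq_params_from_concentration()].
#' @param bjerrum Bjerrum length (nm), default 0.714 (water-like solvent,
#'   25 degrees C).
#' @return Object of class `sq_params`.
#' @export
sq_params <- function(model = c("unity", "hard_sphere_PY", "RMSA", "tabulated"),
                      radius = 1, volume_fraction = 0, charge = 0,
                      ionic_strength = 50, density_basis = c("protein", "fragment"),
                      bjerrum = 0.714) {
  model <- match.arg(model)
  density_basis <- match.arg(density_basis)
  stopifnot(radius > 0, volume_fraction >= 0, volume_fraction < 0.64,
            ionic_strength >= 0)
  structure(list(model = model, radius = radius,
                 volume_fraction = volume_fraction, charge = charge,
                 ionic_strength = ionic_strength, density_basis = density_basis,
                 bjerrum = bjerrum), class = "sq_params")
}

#' Structure-factor parameters from a mass concentration
#'
#' Converts a protein concentration to the volume fraction entering the
#' structure factor.  With `density_basis = "fragment"` the number density is
#' tripled (and the per-unit molecular weight correspondingly divided),
#' implementing the crossover from whole-protein to fragment-level
#' interactions seen above ~33 mg/ml, where the bounding spheres of
#' neighbouring antibodies touch.
#'
#' @param concentration mg/ml.
#' @param M_w Molecular weight of the whole protein (kDa).
#' @param radius Effective interaction radius (nm).
#' @param density_basis `"protein"` or `"fragment"`.
#' @inheritParams sq_params
#' @param ... Passed to [sq_params()].
#' @return An `sq_params` object with attribute `number_density` (nm^-3).
#' @export
sq_params_from_concentration <- function(concentration, M_w = 148,
                                         radius = 5.4,
                                         density_basis = c("protein", "fragment"),
                                         ...) {
  density_basis <- match.arg(density_basis)
  n <- .number_density(concentration, M_w)
  if (density_basis == "fragment") n <- 3 * n
  p <- sq_params(radius = radius, volume_fraction = n * 4 * pi * radius^3 / 3,
                 density_basis = density_basis, ...)
  attr(p, "number_density") <- n
  p
}

# analytic Percus-Yevick structure factor for hard spheres (Wertheim)
.py_sq <- function(Q, radius, phi) {
  if (phi == 0) return(rep(1, length(Q)))
  sigma <- 2 * radius
  s <- Q * sigma
  a <- (1 + 2 * phi)^2 / (1 - phi)^4
  b <- -6 * phi * (1 + phi / 2)^2 / (1 - phi)^4
  g <- phi * a / 2
  nc <- numeric(length(s))
  small <- s < 0.05
  if (any(!small)) {
    x <- s[!small]
    nc[!small] <- -24 * phi * (
      a * (sin(x) - x * cos(x)) / x^3 +
      b * (2 * x * sin(x) + (2 - x^2) * cos(x) - 2) / x^4 +
      g * (-x^4 * cos(x) + 4 * ((3 * x^2 - 6) * cos(x) +
           (x^3 - 6 * x) * sin(x) + 6)) / x^6)
  }
  if (any(small)) {
    # series limit: n c(q->0) = -24 phi (a/3 + b/4 + g/6) + O(s^2)
    x <- s[small]
    nc[small] <- -24 * phi * ((a / 3 + b / 4 + g / 6) -
      x^2 * (a / 30 + b / 36 + g / 48))
  }
  1 / (1 - nc)
}

#' Colloidal structure factor S(Q)
#'
#' Computes the interparticle structure factor for the selected interaction
#' model: `"unity"` (no interactions), `"hard_sphere_PY"` (analytic
#' Percus-Yevick solution), `"RMSA"` (rescaled mean-spherical approximation
#' for a screened-Coulomb hard core, solved numerically with the
#' effective-core rescaling applied when the contact value turns negative),
#' or `"tabulated"` (interpolation of a supplied curve, extended by
#' \eqn{S \to 1} beyond its range).
#'
#' @param params An [sq_params()].
#' @param Q_grid Wavevector grid (nm^-1).
#' @param tabulated_curve A [scattering_curve()] holding S(Q); required for
#'   `model = "tabulated"`.
#' @return A [scattering_curve()] with `I = S(Q)`.
#' @export
structure_factor <- function(params, Q_grid, tabulated_curve = NULL) {
  stopifnot(inherits(params, "sq_params"))
  S <- switch(params$model,
    unity = rep(1, length(Q_grid)),
    hard_sphere_PY = .py_sq(Q_grid, params$radius, params$volume_fraction),
    RMSA = .rmsa_sq(Q_grid, params),
    tabulated = {
      if (is.null(tabulated_curve)) stop("tabulated model requires a curve")
      stats::approx(tabulated_curve$Q, tabulated_curve$I, xout = Q_grid,
                    rule = 2)$y
    })
  scattering_curve(Q_grid, S)
}

#' Apparent structure factor of an anisotropic particle
#'
#' \eqn{S'(Q) = 1 + \beta(Q)\,(S(Q) - 1)}.
#'
#' @param S A [scattering_curve()] holding S(Q).
#' @param beta Data frame with columns `Q`, `beta` on the same grid.
#' @return A [scattering_curve()] with `I = S'(Q)`.
#' @export
effective_structure_factor <- function(S, beta) {
  if (length(S$Q) != length(beta$Q) || max(abs(S$Q - beta$Q)) > 1e-9)
    stop("curves are not on a common Q grid")
  scattering_curve(S$Q, 1 + beta$beta * (S$I - 1))
}

#' Assemble an absolute-scale SAXS intensity
#'
#' \eqn{I(Q, c) = c / M_w \; P(Q) \; S'(Q, c)}.
#'
#' @param model A [bead_model()] (form factor is computed on the `S'` grid).
#' @param Sprime A [scattering_curve()] holding S'(Q).
#' @param concentration mg/ml (> 0).
#' @param M_w Molecular weight (kDa, > 0).
#' @return A [scattering_curve()].
#' @export
saxs_intensity <- function(model, Sprime, concentration, M_w) {
  stopifnot(concentration > 0, M_w > 0)
  P <- form_factor(model, Sprime$Q)
  scattering_curve(Sprime$Q, concentration / M_w * P$I * Sprime$I,
                   concentration = concentration)
}

#' Refine the fragment configuration against a target form factor
#'
#' Global differential-evolution search over a chosen subset of
#' configuration parameters, followed by local Levenberg-Marquardt
#' refinement, minimising the reduced chi^2 of the model form factor against
#' the target curve.  Weights are 1/sigma^2; if the target has no
#' uncertainties a Poisson-like sigma = sqrt(I) (floor-clamped) is used.
#' Configuration changes are visible mainly at Q > 0.7 nm^-1, so the target
#' should cover that range.
#'
#' @param initial A [bead_model()], the starting configuration.
#' @param target A [scattering_curve()] (the form factor to match).
#' @param lower,upper Named numeric vectors of bounds for the free
#'   parameters; names use `<field>.<fragment>` for per-fragment entries,
#'   e.g. `c(in_plane.Fab_l = -1, radial.Fab_l = -2)`.
#' @param seed Integer seed for the global search.
#' @param maxiter_de Differential-evolution generations.
#' @return List with elements `params` (a [configuration_params()]),
#'   `model` (refined [bead_model()]) and `fit` (a `fit_result`).
#' @export
refine_configuration <- function(initial, target, lower, upper, seed = 1L,
                                 maxiter_de = 40L) {
  stopifnot(length(lower) == length(upper), !is.null(names(lower)))
  nm <- names(lower)
  sigma <- target$sigma
  if (all(is.na(sigma))) sigma <- pmax(sqrt(pmax(target$I, 0)), 1e-6 * max(target$I))
  to_config <- function(x) {
    names(x) <- nm
    fields <- list(in_plane = numeric(), out_plane = numeric(),
                   radial = numeric(), fc_bend = 0, linker_scale = 1)
    for (i in seq_along(x)) {
      parts <- strsplit(nm[i], ".", fixed = TRUE)[[1]]
      if (parts[1] %in% c("in_plane", "out_plane", "radial")) {
        v <- fields[[parts[1]]]; v[parts[2]] <- x[i]; fields[[parts[1]]] <- v
      } else if (parts[1] == "fc_bend") fields$fc_bend <- x[i]
      else if (parts[1] == "linker_scale") fields$linker_scale <- x[i]
      else stop("unknown parameter name: ", nm[i])
    }
    do.call(configuration_params, fields)
  }
  resid_fn <- function(x) {
    m <- apply_configuration(initial, to_config(x))
    P <- form_factor(m, target$Q)
    r <- (P$I - target$I) / sigma
    if (!all(is.finite(r))) stop("non-finite chi^2 during refinement")
    r
  }
  fit <- global_search(resid_fn, lower = lower, upper = upper, seed = seed,
                       maxiter = maxiter_de, polish = TRUE)
  at_bound <- fit$par <= lower + 1e-8 | fit$par >= upper - 1e-8
  if (any(at_bound)) fit$at_bound <- nm[at_bound]
  params <- to_config(fit$par)
  list(params = params, model = apply_configuration(initial, params), fit = fit)
}
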