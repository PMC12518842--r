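# Physical constants and unit helpers.
#
# Package-wide unit conventions: lengths in nm, times in ns, wavevectors in
# nm^-1, diffusion in nm^2/ns, viscosity in mPa*s, temperature in K,
# concentration in mg/ml.  Only the Ornstein-Uhlenbeck layer uses molar
# mechanical units (force constants g ps^-2 mol^-1, friction kg ps^-1 mol^-1).

.kB <- 1.380649e-23      # J/K
.NA <- 6.02214076e23     # 1/mol
.Rgas <- .kB * .NA       # J/mol/K

#' Thermal energy in molar mechanical units
#'
#' Returns \eqn{k_B T} expressed in g nm^2 ps^-2 mol^-1, the natural unit for
#' fragment force constants in g ps^-2 mol^-1 paired with displacements in nm.
#'
#' @param temperature Temperature in K.
#' @return Numeric scalar, g nm^2 ps^-2 mol^-1.
#' @export
kT_molar <- function(temperature) {
  stopifnot(temperature > 0)
  # 1 J/mol = 1e-3 g nm^2 ps^-2 mol^-1
  .Rgas * temperature * 1e-3
}

# kT / eta in nm^3/ns for T in K and eta in mPa*s
.kT_over_eta <- function(temperature, eta_mPas) {
  .kB * temperature / (eta_mPas * 1e-3) * 1e18
}

#' Deterministic Fibonacci-sphere direction set
#'
#' Generates `n` quasi-uniform unit vectors used for orientation averages of
#' scattering amplitudes.  The set is deterministic (no RNG) and includes
#' directions spread symmetrically over the sphere, so real parts of
#' orientation averages converge much faster than Monte-Carlo at equal cost.
#'
#' @param n Number of directions (>= 2).
#' @return `n x 3` matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n = 1153L) {
  stopifnot(n >= 2)
  i <- seq_len(n) - 0.5
  golden <- (1 + sqrt(5)) / 2
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- 2 * pi * i / golden
  cbind(r * cos(phi), r * sin(phi), z)
}

# sin(x)/x with the x -> 0 limit
.sinc <- function(x) {
  out <- rep(1, length(x))
  nz <- abs(x) > 1e-8
  out[nz] <- sin(x[nz]) / x[nz]
  out
}

# rotation matrix about unit axis by angle (Rodrigues)
.rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# skew matrix S such that S %*% v == r x v
.skew <- function(r) {
  matrix(c(0, r[3], -r[2], -r[3], 0, r[1], r[2], -r[1], 0), 3, 3)
}

# number density (nm^-3) from concentration (mg/ml) and molecular weight (kDa)
.number_density <- function(concentration, M_w_kDa) {
  concentration / (M_w_kDa * 1000) * 0.602214076
}
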