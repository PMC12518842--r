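# Curve and spectrum containers with plain-text I/O.

#' Static scattering curve
#'
#' @param Q Wavevector grid (nm^-1), strictly increasing and positive.
#' @param I Intensity (arbitrary units).
#' @param sigma Optional 1-sigma uncertainties (same units as `I`).
#' @param concentration Optional concentration (mg/ml).
#' @param temperature Optional temperature (degrees C).
#' @return Object of class `scattering_curve` (a data.frame).
#' @export
scattering_curve <- function(Q, I, sigma = NULL, concentration = NA_real_,
                             temperature = NA_real_) {
  stopifnot(length(Q) == length(I), all(Q > 0), all(diff(Q) > 0))
  if (!is.null(sigma)) {
    stopifnot(length(sigma) == length(Q))
    if (any(sigma <= 0, na.rm = TRUE)) stop("sigma must be positive")
  }
  out <- data.frame(Q = Q, I = I,
                    sigma = if (is.null(sigma)) NA_real_ else sigma)
  attr(out, "concentration") <- concentration
  attr(out, "temperature") <- temperature
  class(out) <- c("scattering_curve", "data.frame")
  out
}

.check_grid <- function(a, b, tol = 1e-9) {
  if (length(a$Q) != length(b$Q) || max(abs(a$Q - b$Q)) > tol)
    stop("curves are not on a common Q grid")
  invisible(TRUE)
}

#' Read / write a scattering curve as 3-column text with JSON sidecar
#'
#' Whitespace/CSV-compatible columns `Q I sigma`; metadata (concentration,
#' temperature, units) in `<path>.json`.
#'
#' @param curve A [scattering_curve()].
#' @param path File path.
#' @return `read_curve` returns a [scattering_curve()].
#' @export
write_curve <- function(curve, path) {
  utils::write.table(data.frame(Q = curve$Q, I = curve$I, sigma = curve$sigma),
                     path, row.names = FALSE, quote = FALSE)
  meta <- list(concentration_mg_ml = attr(curve, "concentration"),
               temperature_C = attr(curve, "temperature"),
               units = list(Q = "nm^-1", I = "a.u."))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  df <- utils::read.table(path, header = TRUE)
  conc <- NA_real_; temp <- NA_real_
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    conc <- meta$concentration_mg_ml %||% NA_real_
    temp <- meta$temperature_C %||% NA_real_
  }
  sig <- if (all(is.na(df$sigma))) NULL else df$sigma
  scattering_curve(df$Q, df$I, sig, concentration = conc, temperature = temp)
}

#' Normalised NSE spectrum on a (Q, t) grid
#'
#' Long-format container of the normalised coherent intermediate scattering
#' function I(Q,t)/I(Q,0).
#'
#' @param Q,t,isf,sigma Vectors of equal length: wavevector (nm^-1), Fourier
#'   time (ns, >= 0), normalised ISF and its 1-sigma uncertainty.
#' @return Object of class `nse_spectrum` (a data.frame).
#' @export
nse_spectrum <- function(Q, t, isf, sigma = NA_real_) {
  stopifnot(length(Q) == length(t), length(t) == length(isf), all(Q > 0),
            all(t >= 0))
  out <- data.frame(Q = Q, t = t, isf = isf, sigma = sigma)
  out <- out[order(out$Q, out$t), ]
  rownames(out) <- NULL
  # normalisation sanity: value at the earliest time should be ~1
  for (q in unique(out$Q)) {
    i0 <- which(out$Q == q)[1]
    if (out$t[i0] == 0 && is.finite(out$isf[i0]) &&
        abs(out$isf[i0] - 1) > 0.25)
      warning("ISF(t=0) deviates strongly from 1 at Q = ", q)
  }
  class(out) <- c("nse_spectrum", "data.frame")
  out
}

#' Read / write an NSE spectrum as long-format CSV
#'
#' Columns `Q,t,isf,sigma` (nm^-1, ns).
#'
#' @param spec An [nse_spectrum()].
#' @param path File path.
#' @export
write_nse <- function(spec, path) {
  utils::write.csv(as.data.frame(spec), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_nse
#' @export
read_nse <- function(path) {
  df <- utils::read.csv(path)
  nse_spectrum(df$Q, df$t, df$isf, df$sigma)
}

#' Logarithmic Q-binning of a measured curve
#'
#' Optional pre-processing step: averages points into bins equally spaced in
#' log(Q), propagating uncertainties as standard errors of the weighted mean.
#'
#' @param curve A [scattering_curve()].
#' @param n_bins Number of log-spaced bins.
#' @return A [scattering_curve()].
#' @export
q_log_bin <- function(curve, n_bins = 100L) {
  edges <- exp(seq(log(min(curve$Q)), log(max(curve$Q)), length.out = n_bins + 1))
  idx <- findInterval(curve$Q, edges, rightmost.closed = TRUE)
  w <- if (all(is.na(curve$sigma))) rep(1, nrow(curve)) else 1 / curve$sigma^2
  agg <- function(v) vapply(split(seq_along(idx), idx), function(i)
    sum(v[i] * w[i]) / sum(w[i]), numeric(1))
  Q <- agg(curve$Q); I <- agg(curve$I)
  s <- vapply(split(seq_along(idx), idx), function(i) sqrt(1 / sum(w[i])), numeric(1))
  keep <- is.finite(Q)
  scattering_curve(Q[keep], I[keep],
                   if (all(is.na(curve$sigma))) NULL else s[keep],
                   concentration = attr(curve, "concentration"),
                   temperature = attr(curve, "temperature"))
}
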