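# Shared fitting engine: weighted least squares with Levenberg-Marquardt
# refinement, a seeded differential-evolution global search, and a common
# fit-result container with covariance-based 1-sigma errors.

#' Fit result container
#'
#' @param par Named parameter estimates.
#' @param errors 1-sigma errors (covariance-based, scaled by reduced chi^2).
#' @param chisq_red Reduced chi^2.
#' @param cov,cor Covariance and correlation matrices.
#' @param converged Logical convergence flag.
#' @param n_eval Number of objective evaluations.
#' @param seed Seed used (NA for deterministic fits).
#' @return Object of class `fit_result`.
#' @export
fit_result <- function(par, errors, chisq_red, cov, cor, converged,
                       n_eval = NA_integer_, seed = NA_integer_) {
  structure(list(par = par, errors = errors, chisq_red = chisq_red,
                 cov = cov, cor = cor, converged = converged,
                 n_eval = n_eval, seed = seed), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result (", if (x$converged) "converged" else "NOT converged",
      "), chi^2_red =", signif(x$chisq_red, 4), "\n")
  print(data.frame(value = x$par, error = x$errors))
  invisible(x)
}

#' @export
as.data.frame.fit_result <- function(x, ...) {
  data.frame(parameter = names(x$par), value = unname(x$par),
             error = unname(x$errors))
}

.cov_from_lm <- function(lmfit, n_resid) {
  p <- length(lmfit$par)
  dof <- max(n_resid - p, 1)
  chisq_red <- lmfit$deviance / dof
  # nls.lm's hessian slot holds J'J; cov = chisq_red (J'J)^-1
  H <- lmfit$hessian
  cov <- tryCatch(solve(H) * chisq_red, error = function(e) {
    sv <- svd(H)
    d <- ifelse(sv$d > max(sv$d) * 1e-12, 1 / sv$d, 0)
    (sv$v %*% (d * t(sv$u))) * chisq_red
  })
  list(chisq_red = chisq_red, cov = cov)
}

#' Weighted least-squares fit with Levenberg-Marquardt refinement
#'
#' Minimises \eqn{\sum_i w_i (f(x)_i - y_i)^2} from a given start, with box
#' bounds, returning covariance-based 1-sigma errors scaled by the reduced
#' chi^2 (the common convention when only relative weights are trusted).
#'
#' @param model_fn Function of the parameter vector.  If `data` is `NULL` it
#'   must return residuals directly; otherwise it returns predicted values to
#'   be compared with `data`.
#' @param data Observed values, or `NULL`.
#' @param weights Optional weights (1/sigma^2); default 1.
#' @param start Named start vector (finite, within bounds).
#' @param lower,upper Box bounds.
#' @param control Passed to [minpack.lm::nls.lm.control()].
#' @return A [fit_result()].
#' @export
least_squares_fit <- function(model_fn, data = NULL, weights = NULL, start,
                              lower = rep(-Inf, length(start)),
                              upper = rep(Inf, length(start)),
                              control = minpack.lm::nls.lm.control(maxiter = 200)) {
  stopifnot(all(is.finite(start)), all(start >= lower), all(start <= upper))
  n_eval <- 0L
  resid_fn <- function(p) {
    n_eval <<- n_eval + 1L
    r <- if (is.null(data)) model_fn(p) else model_fn(p) - data
    if (!is.null(weights)) r <- r * sqrt(weights)
    r
  }
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn, lower = lower,
                            upper = upper, control = control)
  n <- length(fit$fvec)
  cc <- .cov_from_lm(fit, n)
  errs <- sqrt(pmax(diag(cc$cov), 0))
  corm <- cc$cov / outer(errs, errs)
  diag(corm) <- 1
  par <- stats::setNames(fit$par, names(start))
  fit_result(par, stats::setNames(errs, names(start)), cc$chisq_red, cc$cov,
             corm, converged = fit$info %in% 1:4, n_eval = n_eval)
}

#' Seeded differential-evolution global search with local polish
#'
#' Classic rand/1/bin differential evolution inside finite box bounds,
#' deterministic for a given seed, followed (optionally) by a
#' Levenberg-Marquardt polish from the best member.  The objective is the
#' weighted residual sum of squares of `model_fn`.
#'
#' @param model_fn Function of the parameter vector.  With `data = NULL`
#'   returns residuals; otherwise predicted values.
#' @inheritParams least_squares_fit
#' @param seed Integer seed.
#' @param popsize Population size (default 15 per dimension).
#' @param maxiter Number of generations.
#' @param F_de,CR Differential weight and crossover probability.
#' @param polish Run a local refinement from the best member.
#' @return A [fit_result()] with element `par` at the optimum; the population
#'   best objective per generation is attached as attribute `trace`.
#' @export
global_search <- function(model_fn, data = NULL, weights = NULL, lower, upper,
                          seed = 1L, popsize = NULL, maxiter = 60L,
                          F_de = 0.8, CR = 0.9, polish = TRUE) {
  stopifnot(all(is.finite(lower)), all(is.finite(upper)), all(upper > lower))
  d <- length(lower)
  if (is.null(popsize)) popsize <- max(15L * d, 15L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  n_eval <- 0L
  obj <- function(p) {
    n_eval <<- n_eval + 1L
    r <- if (is.null(data)) model_fn(p) else model_fn(p) - data
    if (!is.null(weights)) r <- r * sqrt(weights)
    s <- sum(r^2)
    if (!is.finite(s)) Inf else s
  }
  pop <- matrix(stats::runif(popsize * d, lower, upper), popsize, d, byrow = TRUE)
  cost <- apply(pop, 1, obj)
  trace <- numeric(maxiter)
  for (gen in seq_len(maxiter)) {
    for (i in seq_len(popsize)) {
      idx <- sample(setdiff(seq_len(popsize), i), 3)
      mutant <- pop[idx[1], ] + F_de * (pop[idx[2], ] - pop[idx[3], ])
      mutant <- pmin(pmax(mutant, lower), upper)  # projection
      cross <- stats::runif(d) < CR
      cross[sample.int(d, 1)] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      ct <- obj(trial)
      if (ct <= cost[i]) { pop[i, ] <- trial; cost[i] <- ct }
    }
    trace[gen] <- min(cost)
  }
  best <- pop[which.min(cost), ]
  names(best) <- names(lower)
  if (polish) {
    out <- least_squares_fit(model_fn, data = data, weights = weights,
                             start = best, lower = lower, upper = upper)
    out$n_eval <- out$n_eval + n_eval
    out$seed <- seed
  } else {
    p <- length(best)
    out <- fit_result(best, rep(NA_real_, p), min(cost) / max(1, p),
                      matrix(NA, p, p), matrix(NA, p, p), TRUE,
                      n_eval = n_eval, seed = seed)
  }
  attr(out, "trace") <- trace
  out
}
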