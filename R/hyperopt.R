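# Empirical-Bayes fitting of the shared hyperparameters.
#
# Small-sample proteomics data cannot support per-protein hyperparameters,
# so (mu0, alpha, beta, kappa, phi) are shared across all proteins and
# chosen to maximize the dataset-level marginal likelihood: the log of the
# product over proteins of the two-component mixture
#   p_H1,i * ML_H1,i + (1 - p_H1,i) * ML_H0,i
# with p_H1,i from the protein's missing-value frequencies. tau0 is pinned
# to 0 (up- and down-regulation equally likely a priori).

#' Dataset-level log marginal likelihood
#'
#' @param x an [intensity_matrix()], normally [standardize()]d first.
#' @param hp a [hyperparams()].
#' @param form prior form, see [prior_h1()].
#' @return scalar: sum over proteins of the log two-component mixture
#'   marginal.
#' @export
total_log_marginal <- function(x, hp, form = c("polynomial", "exponential")) {
  ev <- protein_evidence(x, hp, form)
  # log(p e^{L1} + (1-p) e^{L0}) via log-sum-exp; handles p in {0, 1}
  a <- log(ev$prior_h1) + ev$log_ml_h1
  b <- log1p(-ev$prior_h1) + ev$log_ml_h0
  m <- pmax(a, b)
  m[!is.finite(m)] <- pmin(a, b)[!is.finite(m)]  # both -Inf cannot occur
  sum(m + log(exp(a - m) + exp(b - m)))
}

#' Default box bounds for hyperparameter fitting
#'
#' Diffuse-but-proper boxes appropriate for standardized (unit-scale) data.
#' @return named list with elements \code{lower} and \code{upper}.
#' @export
default_bounds <- function() {
  list(lower = c(mu0 = -5, alpha = 0.5, beta = 0.01, kappa = 0.01, phi = 0.01),
       upper = c(mu0 = 5, alpha = 50, beta = 50, kappa = 100, phi = 100))
}

#' Fit the shared hyperparameters by marginal-likelihood maximization
#'
#' Maximizes [total_log_marginal()] over (mu0, alpha, beta, kappa, phi)
#' within box bounds using L-BFGS-B; tau0 is fixed at 0. Deterministic
#' given data and starting point. If the optimizer ever returns a point
#' worse than the start, the start is kept (monotone-improvement contract).
#'
#' @param x an [intensity_matrix()]; fitted on standardized data in the
#'   main pipeline.
#' @param form prior form, see [prior_h1()].
#' @param init starting [hyperparams()] (default: unit-scale neutral point
#'   mu0=0, alpha=2, beta=1, kappa=1, phi=1).
#' @param bounds list with \code{lower}/\code{upper} named vectors over
#'   (mu0, alpha, beta, kappa, phi); default [default_bounds()].
#' @param multi_start number of additional seeded random restarts (0 = off,
#'   the default, for strict determinism); best point wins.
#' @param seed seed for the restarts (ignored when \code{multi_start = 0}).
#' @return object of class \code{fit_result}: list with
#'   \code{hyperparams}, \code{objective_value}, \code{initial_value},
#'   \code{converged}, \code{n_iterations}.
#' @export
fit_hyperparameters <- function(x, form = c("polynomial", "exponential"),
                                init = hyperparams(), bounds = default_bounds(),
                                multi_start = 0L, seed = 1L) {
  stopifnot(inherits(x, "intensity_matrix"), inherits(init, "hyperparams"))
  form <- match.arg(form)
  lower <- bounds$lower; upper <- bounds$upper
  obj <- function(par) {
    hp <- hyperparams(mu0 = par[1], alpha = par[2], beta = par[3],
                      tau0 = 0, kappa = par[4], phi = par[5])
    val <- total_log_marginal(x, hp, form)
    if (!is.finite(val)) return(1e10)
    -val
  }
  starts <- list(pmin(pmax(c(init$mu0, init$alpha, init$beta, init$kappa,
                             init$phi), lower), upper))
  if (multi_start > 0) {
    rs <- .with_seed(seed, replicate(multi_start,
      lower + stats::runif(5) * (upper - lower), simplify = FALSE))
    starts <- c(starts, rs)
  }
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) list(par = p0, value = obj(p0), convergence = 1L,
                               counts = c(0L, 0L)))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  init_val <- -obj(starts[[1]])
  opt_val <- -best$value
  par <- best$par
  converged <- isTRUE(best$convergence == 0)
  if (opt_val < init_val) {   # never accept a deterioration
    par <- starts[[1]]
    opt_val <- init_val
    converged <- FALSE
    warning("optimizer failed to improve on the starting point; keeping it")
  }
  structure(list(
    hyperparams = hyperparams(mu0 = par[1], alpha = par[2], beta = par[3],
                              tau0 = 0, kappa = par[4], phi = par[5]),
    objective_value = opt_val,
    initial_value = init_val,
    converged = converged,
    n_iterations = unname(best$counts[1])),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: objective %.4f (from %.4f), converged: %s\n",
              x$objective_value, x$initial_value, x$converged))
  print(x$hyperparams)
  invisible(x)
}

# evaluate expr under a temporary RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
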