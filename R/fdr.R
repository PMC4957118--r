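# Bayesian FDR: the expected fraction of nulls among called proteins is
# the average posterior probability of H0 within the call set; the
# threshold is chosen as the most permissive one keeping that expectation
# under the target level.

#' Expected Bayesian false discovery rate at a posterior threshold
#'
#' \deqn{\widehat{FDR}(p_{th}) = \frac{\sum_i (1 - p_i)\,I[p_i \ge p_{th}]}
#'   {c + \sum_i I[p_i \ge p_{th}]}}
#' where \eqn{p_i} are posterior probabilities of differential expression
#' and \eqn{c \ge 0} is an offset stabilizing the denominator.
#'
#' @param posteriors numeric vector of posterior probabilities in \[0, 1\].
#' @param p_th threshold probability; proteins with \eqn{p_i \ge p_{th}}
#'   are called (inclusive).
#' @param c non-negative offset; with \code{c = 0} and an empty call set
#'   the FDR is undefined and \code{NA} is returned with a warning.
#' @return expected FDR in \[0, 1\], or \code{NA} when undefined.
#' @export
expected_fdr <- function(posteriors, p_th, c = 0) {
  if (length(posteriors) == 0) stop("empty posterior list")
  if (any(posteriors < 0 | posteriors > 1)) stop("posteriors must be in [0, 1]")
  if (c < 0) stop("offset c must be non-negative")
  called <- posteriors >= p_th
  k <- sum(called)
  if (k == 0) {
    if (c == 0) {
      warning("no protein called and c = 0: expected FDR undefined")
      return(NA_real_)
    }
    return(0)
  }
  sum(1 - posteriors[called]) / (c + k)
}

#' Select the posterior threshold controlling the Bayesian FDR
#'
#' Scans the exact step points of the expected-FDR curve (the sorted unique
#' posterior values - the curve only changes there) and returns the
#' smallest threshold whose expected FDR is at or below the target level,
#' i.e. the largest call set compatible with the bound.
#'
#' @inheritParams expected_fdr
#' @param alpha_level target FDR in (0, 1).
#' @return object of class \code{fdr_curve}: list with \code{thresholds}
#'   (ascending candidate grid), \code{expected_fdr} (matched values),
#'   \code{offset_c}, \code{alpha_level}, \code{selected_threshold}
#'   (\code{NA} when no threshold attains the bound) and \code{n_called}.
#' @export
select_threshold <- function(posteriors, alpha_level = 0.05, c = 0) {
  if (length(posteriors) == 0) stop("empty posterior list")
  if (alpha_level <= 0 || alpha_level >= 1) stop("alpha_level must be in (0, 1)")
  grid <- sort(unique(posteriors))
  efdr <- vapply(grid, function(t) {
    suppressWarnings(expected_fdr(posteriors, t, c))
  }, numeric(1))
  ok <- which(!is.na(efdr) & efdr <= alpha_level)
  sel <- if (length(ok)) grid[min(ok)] else NA_real_
  structure(list(thresholds = grid, expected_fdr = efdr,
                 offset_c = c, alpha_level = alpha_level,
                 selected_threshold = sel,
                 n_called = if (is.na(sel)) 0L else sum(posteriors >= sel)),
            class = "fdr_curve")
}

#' @export
print.fdr_curve <- function(x, ...) {
  if (is.na(x$selected_threshold)) {
    cat(sprintf("fdr_curve: no threshold attains FDR <= %g; 0 calls\n",
                x$alpha_level))
  } else {
    cat(sprintf("fdr_curve: threshold %.6g at FDR <= %g; %d call(s)\n",
                x$selected_threshold, x$alpha_level, x$n_called))
  }
  invisible(x)
}
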