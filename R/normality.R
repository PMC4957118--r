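# Advisory normality screening of the observed intensities, per protein
# and group. The model assumes Normal log intensities; the screen reports
# how much of the data is compatible with that, it never gates the
# analysis. KS and Shapiro-Wilk delegate to stats; Lilliefors and
# Anderson-Darling (composite null, parameters estimated) are implemented
# from the standard published p-value approximations since no packaged
# implementation is available here.

#' Lilliefors test for normality
#'
#' KS statistic against the Normal with estimated mean and sd; p-value by
#' the Dallal-Wilkinson (1986) approximation, switching to the Stephens
#' polynomial form when it exceeds 0.1.
#'
#' @param x numeric vector, n >= 4.
#' @return list with \code{statistic} and \code{p.value}.
#' @export
lilliefors_test <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 4) stop("need at least 4 observations")
  p <- stats::pnorm((x - mean(x)) / stats::sd(x))
  dplus <- max(seq_len(n) / n - p)
  dminus <- max(p - (seq_len(n) - 1) / n)
  k <- max(dplus, dminus)
  if (n <= 100) { kd <- k; nd <- n } else { kd <- k * (n / 100)^0.49; nd <- 100 }
  pv <- exp(-7.01256 * kd^2 * (nd + 2.78019) +
              2.99587 * kd * sqrt(nd + 2.78019) - 0.122119 +
              0.974598 / sqrt(nd) + 1.67997 / nd)
  if (pv > 0.1) {
    kk <- (sqrt(n) - 0.01 + 0.85 / sqrt(n)) * k
    pv <- if (kk <= 0.302) 1
      else if (kk <= 0.5) 2.76773 - 19.828315 * kk + 80.709644 * kk^2 -
        138.55152 * kk^3 + 81.218052 * kk^4
      else if (kk <= 0.9) -4.901232 + 40.662806 * kk - 97.490286 * kk^2 +
        94.029866 * kk^3 - 32.355711 * kk^4
      else if (kk <= 1.31) 6.198765 - 19.558097 * kk + 23.186922 * kk^2 -
        12.234627 * kk^3 + 2.423045 * kk^4
      else 0
  }
  list(statistic = k, p.value = min(max(pv, 0), 1))
}

#' Anderson-Darling test for normality
#'
#' Composite-null A-squared with the Stephens small-sample adjustment
#' \eqn{A^{*2} = A^2 (1 + 0.75/n + 2.25/n^2)} and the matching piecewise
#' exponential p-value approximation.
#'
#' @param x numeric vector, n >= 4 (larger recommended).
#' @return list with \code{statistic} and \code{p.value}.
#' @export
anderson_darling_test <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 4) stop("need at least 4 observations")
  p <- stats::pnorm((x - mean(x)) / stats::sd(x))
  p <- pmin(pmax(p, .Machine$double.xmin), 1 - 1e-16)
  i <- seq_len(n)
  a2 <- -n - mean((2 * i - 1) * (log(p) + log(1 - rev(p))))
  z <- a2 * (1 + 0.75 / n + 2.25 / n^2)
  pv <- if (z >= 0.6) exp(1.2937 - 5.709 * z + 0.0186 * z^2)
    else if (z >= 0.34) exp(0.9177 - 4.279 * z - 1.38 * z^2)
    else if (z > 0.2) 1 - exp(-8.318 + 42.796 * z - 59.938 * z^2)
    else 1 - exp(-13.436 + 101.14 * z - 223.73 * z^2)
  list(statistic = a2, p.value = min(max(pv, 0), 1))
}

#' Screen a dataset for normality, per protein and group
#'
#' Runs the selected tests on every (protein, group) cell with at least
#' \code{min_obs} observed values and reports, per test, the fraction of
#' tested cells where normality is NOT rejected at \code{alpha}. Advisory
#' only - the screen never gates the analysis.
#'
#' @param x an [intensity_matrix()].
#' @param tests subset of \code{c("KS", "Lilliefors", "ShapiroWilk",
#'   "AndersonDarling")}.
#' @param alpha rejection level (default 0.05).
#' @param min_obs minimum observed values per cell (default 4).
#' @return list of class \code{normality_screen}: \code{fraction_normal}
#'   (named per test; \code{NA} when no cell qualified), \code{p_values}
#'   (cells x tests data.frame), \code{n_tested}, \code{n_skipped}.
#' @export
normality_screen <- function(x, tests = c("KS", "Lilliefors", "ShapiroWilk",
                                          "AndersonDarling"),
                             alpha = 0.05, min_obs = 4) {
  stopifnot(inherits(x, "intensity_matrix"))
  tests <- match.arg(tests, several.ok = TRUE)
  runner <- list(
    KS = function(v) suppressWarnings(
      stats::ks.test(v, "pnorm", mean(v), stats::sd(v))$p.value),
    Lilliefors = function(v) lilliefors_test(v)$p.value,
    ShapiroWilk = function(v) stats::shapiro.test(v)$p.value,
    AndersonDarling = function(v) anderson_darling_test(v)$p.value)
  cells <- list()
  for (grp in c("CTRL", "TRT")) {
    sel <- x$groups == grp
    for (i in seq_len(nrow(x$values))) {
      v <- x$values[i, sel][x$observed[i, sel]]
      cells[[length(cells) + 1]] <- list(id = rownames(x$values)[i],
                                         group = grp, values = v)
    }
  }
  eligible <- vapply(cells, function(cl)
    length(cl$values) >= min_obs && stats::sd(cl$values) > 0, logical(1))
  pmat <- t(vapply(cells[eligible], function(cl) {
    vapply(tests, function(tn) {
      tryCatch(runner[[tn]](cl$values), error = function(e) NA_real_)
    }, numeric(1))
  }, stats::setNames(numeric(length(tests)), tests)))
  if (!sum(eligible)) pmat <- matrix(numeric(0), 0, length(tests),
                                     dimnames = list(NULL, tests))
  frac <- vapply(tests, function(tn) {
    p <- pmat[, tn]
    if (!length(p) || all(is.na(p))) NA_real_ else mean(p >= alpha, na.rm = TRUE)
  }, numeric(1))
  meta <- do.call(rbind, lapply(cells[eligible], function(cl)
    data.frame(id = cl$id, group = cl$group, stringsAsFactors = FALSE)))
  structure(list(
    fraction_normal = frac,
    p_values = if (sum(eligible)) cbind(meta, as.data.frame(pmat)) else NULL,
    n_tested = sum(eligible),
    n_skipped = sum(!eligible)),
    class = "normality_screen")
}

#' @export
print.normality_screen <- function(x, ...) {
  cat(sprintf("normality screen: %d cell(s) tested, %d skipped (< min_obs)\n",
              x$n_tested, x$n_skipped))
  for (tn in names(x$fraction_normal))
    cat(sprintf("  %-16s %s\n", tn,
                if (is.na(x$fraction_normal[tn])) "skipped"
                else sprintf("%.4f not rejecting normality",
                             x$fraction_normal[tn])))
  invisible(x)
}
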