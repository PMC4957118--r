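# Comparator methods for the benchmark: three missing-value imputation
# schemes (KNN across proteins, iterative PCA with known-data regression or
# trimmed-scores regression) and five two-sample tests scored as 1 - p for
# AUROC ranking.

#' Comparator method specification
#'
#' @param test one of \code{"t"}, \code{"wilcoxon_rank_sum"},
#'   \code{"kruskal_wallis"}, \code{"kolmogorov_smirnov"},
#'   \code{"permutation"}.
#' @param imputation one of \code{"none"}, \code{"knn"}, \code{"pca_kdr"},
#'   \code{"pca_tsr"}. With \code{"none"}, missing entries are treated as
#'   0, the simplest historical convention.
#' @param k neighbours for KNN (>= 1).
#' @param ncomp principal components for the PCA schemes.
#' @param n_perm permutations for the permutation test (>= 100).
#' @return object of class \code{method_spec}.
#' @export
method_spec <- function(test = c("t", "wilcoxon_rank_sum", "kruskal_wallis",
                                 "kolmogorov_smirnov", "permutation"),
                        imputation = c("none", "knn", "pca_kdr", "pca_tsr"),
                        k = 10L, ncomp = 2L, n_perm = 1000L) {
  test <- match.arg(test)
  imputation <- match.arg(imputation)
  if (test == "permutation" && n_perm < 100) stop("n_perm must be >= 100")
  if (imputation == "knn" && k < 1) stop("k must be >= 1")
  structure(list(test = test, imputation = imputation, k = as.integer(k),
                 ncomp = as.integer(ncomp), n_perm = as.integer(n_perm)),
            class = "method_spec")
}

#' Impute missing intensities
#'
#' Completes the matrix; observed entries are never altered.
#' \describe{
#'   \item{knn}{For each missing entry, the average of that sample's values
#'     over the \code{k} nearest proteins (Euclidean distance over
#'     co-observed samples, normalized by their number) that are observed in
#'     that sample. Proteins with no observed values fall back to the global
#'     observed mean (with a warning).}
#'   \item{pca_kdr / pca_tsr}{Iterative PCA model-based imputation: fill
#'     with column means, fit a rank-\code{ncomp} PCA, re-estimate each
#'     row's missing part from its observed part by known-data regression
#'     (conditional mean under the rank-a covariance) or trimmed-scores
#'     regression (through the score space), iterate to convergence.}
#' }
#'
#' @param x an [intensity_matrix()].
#' @param method \code{"knn"}, \code{"pca_kdr"} or \code{"pca_tsr"}.
#' @param k neighbours for KNN.
#' @param ncomp components for the PCA schemes.
#' @param tol,maxit convergence control for the iterative PCA schemes.
#' @return a complete \code{intensity_matrix} (all entries observed).
#' @export
impute <- function(x, method = c("knn", "pca_kdr", "pca_tsr"), k = 10L,
                   ncomp = 2L, tol = 1e-6, maxit = 200L) {
  stopifnot(inherits(x, "intensity_matrix"))
  method <- match.arg(method)
  if (all(x$observed)) return(x)
  filled <- switch(method,
    knn = .impute_knn(x$values, x$observed, k),
    pca_kdr = .impute_pca(x$values, x$observed, ncomp, tol, maxit, "kdr"),
    pca_tsr = .impute_pca(x$values, x$observed, ncomp, tol, maxit, "tsr"))
  out <- x
  out$values <- filled
  out$observed[] <- TRUE
  out
}

.impute_knn <- function(v, obs, k) {
  w <- obs * 1
  x0 <- v * w
  a <- tcrossprod(x0)
  b <- tcrossprod(x0^2, w)
  n_co <- tcrossprod(w)
  d2 <- (b + t(b) - 2 * a) / n_co          # mean squared diff, NaN if no overlap
  d2[n_co == 0] <- Inf
  diag(d2) <- Inf
  gmean <- mean(v[obs])
  rows <- which(rowSums(!obs) > 0)
  all_missing <- rowSums(obs) == 0
  if (any(all_missing))
    warning(sum(all_missing), " protein(s) fully missing; imputed with the",
            " global observed mean")
  for (i in rows) {
    if (all_missing[i]) { v[i, !obs[i, ]] <- gmean; next }
    ord <- order(d2[i, ])
    for (j in which(!obs[i, ])) {
      cand <- ord[obs[ord, j] & is.finite(d2[i, ord])]
      v[i, j] <- if (length(cand)) mean(v[cand[seq_len(min(k, length(cand)))], j])
                 else gmean
    }
  }
  v
}

.impute_pca <- function(v, obs, ncomp, tol, maxit, variant) {
  n <- nrow(v); p <- ncol(v)
  a <- min(ncomp, n - 1, p)
  miss <- !obs
  cmean <- colSums(v * obs) / pmax(colSums(obs), 1)
  x <- v
  x[miss] <- matrix(cmean, n, p, byrow = TRUE)[miss]
  all_missing <- rowSums(obs) == 0
  if (any(all_missing))
    warning(sum(all_missing), " protein(s) fully missing; held at the",
            " column means")
  converged <- FALSE
  for (it in seq_len(maxit)) {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    sv <- svd(xc, nu = 0, nv = a)
    pl <- sv$v                                   # p x a loadings
    s_full <- crossprod(xc) / (n - 1)
    lam <- (sv$d[seq_len(a)]^2) / (n - 1)
    s_a <- pl %*% (lam * t(pl))                  # rank-a covariance
    xnew <- x
    for (i in which(rowSums(miss) > 0 & !all_missing)) {
      m <- miss[i, ]; o <- !m
      z_o <- xc[i, o]
      est <- if (variant == "kdr") {
        s_a[m, o, drop = FALSE] %*% MASS::ginv(s_a[o, o, drop = FALSE]) %*% z_o
      } else {
        l_o <- pl[o, , drop = FALSE]
        s_oo <- s_full[o, o, drop = FALSE]
        s_a[m, o, drop = FALSE] %*% l_o %*%
          MASS::ginv(t(l_o) %*% s_oo %*% l_o) %*% t(l_o) %*% z_o
      }
      xnew[i, m] <- est + mu[m]
    }
    delta <- max(abs(xnew[miss] - x[miss]), 0)
    x <- xnew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("iterative PCA imputation did not converge in ", maxit,
            " iterations; returning last iterate")
  x[obs] <- v[obs]
  x
}

#' Score proteins with a classical two-sample test
#'
#' Applies one of five tests per protein and returns \code{1 - p} so that
#' larger scores mean more evidence of differential abundance (shared
#' orientation with the Bayesian posterior for AUROC). The matrix should be
#' complete (post-imputation); if missing entries remain they are treated
#' as 0. Constant proteins score 0 rather than erroring.
#'
#' The permutation test uses the difference of group means with seeded
#' label permutations and the add-one convention p = (1 + #extreme)/(B+1);
#' when the group sizes admit at most 10^4 distinct assignments it
#' enumerates them exhaustively instead.
#'
#' @param x an [intensity_matrix()].
#' @param test test name, see [method_spec()].
#' @param n_perm permutation count.
#' @param seed seed for the permutation test.
#' @return numeric vector of per-protein scores in \[0, 1\].
#' @export
test_per_protein <- function(x, test = c("t", "wilcoxon_rank_sum",
                                         "kruskal_wallis",
                                         "kolmogorov_smirnov", "permutation"),
                             n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(x, "intensity_matrix"))
  test <- match.arg(test)
  v <- x$values                     # sentinel 0 already in place for missing
  trt <- x$groups == "TRT"
  if (test == "permutation") return(.perm_scores(v, trt, n_perm, seed))
  pvals <- apply(v, 1, function(row) {
    a <- row[!trt]; b <- row[trt]
    if (stats::sd(row) == 0) return(1)          # constant protein: no evidence
    p <- tryCatch(suppressWarnings(switch(test,
      t = stats::t.test(a, b, var.equal = TRUE)$p.value,
      wilcoxon_rank_sum = stats::wilcox.test(a, b, exact = FALSE)$p.value,
      kruskal_wallis = stats::kruskal.test(list(a, b))$p.value,
      kolmogorov_smirnov = stats::ks.test(a, b)$p.value)),
      error = function(e) 1)
    if (!is.finite(p)) 1 else p
  })
  1 - pvals
}

.perm_scores <- function(v, trt, n_perm, seed) {
  n <- length(trt); nt <- sum(trt)
  t_obs <- rowMeans(v[, trt, drop = FALSE]) - rowMeans(v[, !trt, drop = FALSE])
  n_distinct <- choose(n, nt)
  if (n_distinct <= 1e4) {
    combos <- utils::combn(n, nt)
    stat_of <- function(idx) {
      sel <- logical(n); sel[idx] <- TRUE
      rowMeans(v[, sel, drop = FALSE]) - rowMeans(v[, !sel, drop = FALSE])
    }
    stats_mat <- apply(combos, 2, stat_of)      # proteins x permutations
    if (is.null(dim(stats_mat))) stats_mat <- matrix(stats_mat, nrow = nrow(v))
    p <- rowMeans(abs(stats_mat) >= abs(t_obs) - 1e-12)
  } else {
    perms <- .with_seed(seed, replicate(n_perm, sample.int(n)))
    exceed <- integer(nrow(v))
    for (b in seq_len(n_perm)) {
      sel <- logical(n); sel[perms[seq_len(nt), b]] <- TRUE
      tb <- rowMeans(v[, sel, drop = FALSE]) - rowMeans(v[, !sel, drop = FALSE])
      exceed <- exceed + (abs(tb) >= abs(t_obs) - 1e-12)
    }
    p <- (1 + exceed) / (n_perm + 1)
  }
  constant <- apply(v, 1, function(r) stats::sd(r) == 0)
  p[constant] <- 1
  1 - p
}
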