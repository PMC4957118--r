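# AUROC scoring against ground truth and aggregation of the replicate
# benchmark.

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' positive outranks a randomly chosen negative, with tied score pairs
#' contributing one half. Identical (to numerical precision) to
#' trapezoidal integration of the ROC curve with thresholds placed between
#' distinct score values.
#'
#' @param scores per-protein ranking scores (higher = more evidence).
#' @param labels 0/1 (or logical) ground-truth differential indicators.
#' @return AUROC in \[0, 1\]; \code{NA} with a warning when only one class
#'   is present.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warning("AUROC undefined: single-class truth")
    return(NA_real_)
  }
  r <- rank(scores)                      # midranks handle ties with 1/2 credit
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# internal second route: explicit trapezoidal ROC integration (kept as the
# dual implementation the test suite cross-checks against Mann-Whitney)
.auroc_trapezoid <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n0, 0)
  tpr <- c(0, tpr, 1); fpr <- c(0, fpr, 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Score a dataset with one method
#'
#' Dispatches either the Bayesian pipeline (standardize, fit, posterior)
#' or a comparator [method_spec()] (impute, test) and returns per-protein
#' ranking scores.
#'
#' @param dataset a \code{sim_dataset} (or any list with a
#'   \code{$matrix} [intensity_matrix()]).
#' @param method either a [method_spec()] or a list
#'   \code{list(bayes = "polynomial"/"exponential")} selecting the Bayesian
#'   method with that prior form.
#' @param seed seed forwarded to seeded components (permutation test).
#' @return numeric score vector, one per protein.
#' @export
score_dataset <- function(dataset, method, seed = 1L) {
  x <- dataset$matrix
  if (!is.null(method$bayes)) {
    std <- suppressWarnings(standardize(x))
    fit <- fit_hyperparameters(std, form = method$bayes)
    ev <- protein_evidence(std, fit$hyperparams, form = method$bayes)
    return(ev$posterior_h1)
  }
  stopifnot(inherits(method, "method_spec"))
  xin <- if (method$imputation == "none") x
         else suppressWarnings(impute(x, method$imputation, k = method$k,
                                      ncomp = method$ncomp))
  test_per_protein(xin, method$test, n_perm = method$n_perm, seed = seed)
}

.method_label <- function(method) {
  if (!is.null(method$bayes)) return(paste0("bayes_", method$bayes))
  if (method$imputation == "none") method$test
  else paste(method$test, method$imputation, sep = "+")
}

#' Run the simulation benchmark
#'
#' Applies every method to every dataset of the grid, computes AUROC
#' against each dataset's ground truth, and aggregates mean and sd per
#' design cell. Per-dataset seeds come from the grid, so any cell is
#' recomputable in isolation. A method failing on a dataset is recorded as
#' \code{NA} with a warning and the run continues.
#'
#' @param grid a design data.frame from [generate_benchmark_grid()].
#' @param methods named list of methods ([method_spec()]s and/or
#'   \code{list(bayes = form)} entries); names become method labels,
#'   defaults derived otherwise.
#' @param verbose print progress lines.
#' @return list of class \code{benchmark_summary}: \code{summary}
#'   (mean/sd AUROC per cell x method), \code{results} (per-dataset
#'   AUROCs).
#' @export
run_benchmark <- function(grid, methods, verbose = FALSE) {
  if (is.null(names(methods)) || any(names(methods) == ""))
    names(methods) <- vapply(methods, .method_label, character(1))
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cfg <- simulation_config(family = g$family, n_proteins = g$n_proteins,
                             n_per_group = g$n_per_group, sigma = g$sigma,
                             missing_fraction = g$missing_fraction,
                             seed = g$seed)
    ds <- suppressWarnings(simulate_dataset(cfg))
    aucs <- vapply(names(methods), function(mn) {
      tryCatch(auroc(score_dataset(ds, methods[[mn]], seed = g$seed),
                     ds$truth$lambda),
               error = function(e) {
                 warning("method '", mn, "' failed on dataset row ", i, ": ",
                         conditionMessage(e))
                 NA_real_
               })
    }, numeric(1))
    res[[i]] <- data.frame(g, method = names(methods), auroc = unname(aucs),
                           row.names = NULL, stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("[%d/%d] %s sigma=%g miss=%g n=%d rep=%d done",
                      i, nrow(grid), g$family, g$sigma, g$missing_fraction,
                      g$n_per_group, g$replicate))
  }
  results <- do.call(rbind, res)
  key <- c("family", "sigma", "missing_fraction", "n_per_group", "method")
  agg <- stats::aggregate(results$auroc, results[key], function(a)
    c(mean = mean(a, na.rm = TRUE),
      sd = if (sum(!is.na(a)) > 1) stats::sd(a, na.rm = TRUE) else NA_real_,
      n = sum(!is.na(a))))
  summary <- cbind(agg[key], mean_auroc = agg$x[, "mean"],
                   sd_auroc = agg$x[, "sd"], n_replicates = agg$x[, "n"])
  structure(list(summary = summary, results = results),
            class = "benchmark_summary")
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat("benchmark_summary over", nrow(x$results), "dataset x method runs\n")
  print(x$summary, digits = 3)
  invisible(x)
}
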