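# Delimited-text readers/writers and the end-to-end analysis pipeline.

#' Read a wide intensity table
#'
#' Expects rectangular delimited text: first column protein ids, header row
#' of sample names. Missing-value encoding is explicit and mandatory - no
#' silent guessing on real data. Intensities are assumed to be on the log
#' scale already unless a transform is requested; transforms apply to
#' observed entries only.
#'
#' @param path file path (TSV by default).
#' @param group_map named character vector mapping every sample name to
#'   \code{"CTRL"} or \code{"TRT"}, or a path to a two-column (sample,
#'   group) delimited file without header.
#' @param missing_encoding how missing values are written: \code{"NA"},
#'   \code{"blank"} (empty cell), \code{"zero"}, or any custom sentinel
#'   string.
#' @param log_transform \code{"none"}, \code{"log2"}, \code{"log10"} or
#'   \code{"ln"}.
#' @param sep field separator (default tab).
#' @return an [intensity_matrix()].
#' @export
read_intensity_table <- function(path, group_map,
                                 missing_encoding = c("NA", "blank", "zero"),
                                 log_transform = c("none", "log2", "log10", "ln"),
                                 sep = "\t") {
  if (length(missing_encoding) > 1) missing_encoding <- missing_encoding[1]
  log_transform <- match.arg(log_transform)
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", comment.char = "",
                           quote = "\"", na.strings = NULL)
  if (ncol(raw) < 2) stop("expected protein ids plus at least one sample column")
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop("duplicate protein ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cells <- as.matrix(raw[, -1, drop = FALSE])
  samples <- colnames(cells)
  if (is.character(group_map) && length(group_map) == 1 && is.null(names(group_map))) {
    gm <- utils::read.table(group_map, header = FALSE, sep = sep,
                            colClasses = "character")
    group_map <- stats::setNames(gm[[2]], gm[[1]])
  }
  unmapped <- setdiff(samples, names(group_map))
  if (length(unmapped))
    stop("samples missing from group map: ", paste(unmapped, collapse = ", "))
  groups <- unname(group_map[samples])

  is_missing <- switch(missing_encoding,
    "NA" = cells == "NA" | is.na(cells),
    blank = trimws(cells) == "",
    zero = suppressWarnings(as.numeric(cells)) == 0 & !is.na(suppressWarnings(as.numeric(cells))),
    cells == missing_encoding)
  is_missing <- matrix(is_missing %in% TRUE, nrow(cells), ncol(cells))
  num <- suppressWarnings(as.numeric(cells))
  bad <- which(is.na(num) & !is_missing, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell not matching the missing encoding at row %d (%s), column '%s'",
                 bad[1, 1], ids[bad[1, 1]], samples[bad[1, 2]]))
  vals <- matrix(num, nrow(cells), ncol(cells),
                 dimnames = list(ids, samples))
  vals[is_missing] <- 0
  obs <- !is_missing
  if (log_transform != "none") {
    f <- switch(log_transform, log2 = log2, log10 = log10, ln = log)
    vals[obs] <- f(vals[obs])
    if (any(!is.finite(vals[obs])))
      stop("log transform produced non-finite values (non-positive intensities?)")
  }
  intensity_matrix(vals, observed = obs, groups = groups)
}

#' Write an intensity matrix as TSV
#'
#' Inverse of [read_intensity_table()]: round-trips values, mask and
#' column order losslessly (missing entries written per the encoding).
#'
#' @param x an [intensity_matrix()].
#' @param path output path.
#' @param missing_encoding \code{"NA"}, \code{"blank"}, \code{"zero"} or a
#'   custom sentinel.
#' @export
write_intensity_table <- function(x, path, missing_encoding = "NA") {
  stopifnot(inherits(x, "intensity_matrix"))
  out <- matrix(sprintf("%.17g", x$values), nrow(x$values),
                dimnames = dimnames(x$values))
  sent <- switch(missing_encoding, "NA" = "NA", blank = "", zero = "0",
                 missing_encoding)
  out[!x$observed] <- sent
  df <- data.frame(protein = rownames(x$values), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Full Bayesian differential-abundance analysis
#'
#' The end-to-end pipeline: per-protein standardization, empirical-Bayes
#' hyperparameter fitting, posterior probabilities of differential
#' expression, and Bayesian FDR thresholding.
#'
#' @param x an [intensity_matrix()].
#' @param form prior form, see [prior_h1()].
#' @param fdr_level target Bayesian FDR in (0, 1).
#' @param offset_c FDR denominator offset (default 0).
#' @param init,bounds forwarded to [fit_hyperparameters()].
#' @return list of class \code{bmsdiff_result}: \code{table} (per-protein
#'   results, original order, with a logical \code{called} column),
#'   \code{fit} (the [fit_hyperparameters()] result), \code{fdr} (the
#'   [select_threshold()] curve), \code{form}.
#' @examples
#' ds <- simulate_dataset(simulation_config(n_proteins = 50, seed = 7,
#'                                          missing_fraction = 0.2))
#' res <- differential_abundance(ds$matrix, fdr_level = 0.05)
#' head(res$table)
#' @export
differential_abundance <- function(x, form = c("polynomial", "exponential"),
                                   fdr_level = 0.05, offset_c = 0,
                                   init = hyperparams(),
                                   bounds = default_bounds()) {
  stopifnot(inherits(x, "intensity_matrix"))
  form <- match.arg(form)
  std <- suppressWarnings(standardize(x))
  fit <- fit_hyperparameters(std, form = form, init = init, bounds = bounds)
  ev <- protein_evidence(std, fit$hyperparams, form = form)
  fdr <- select_threshold(ev$posterior_h1, alpha_level = fdr_level, c = offset_c)
  ev$called <- if (is.na(fdr$selected_threshold)) FALSE
               else ev$posterior_h1 >= fdr$selected_threshold
  structure(list(table = ev, fit = fit, fdr = fdr, form = form),
            class = "bmsdiff_result")
}

#' @export
print.bmsdiff_result <- function(x, ...) {
  cat(sprintf("differential abundance (%s prior): %d of %d proteins called\n",
              x$form, sum(x$table$called), nrow(x$table)))
  print(x$fit)
  print(x$fdr)
  invisible(x)
}
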