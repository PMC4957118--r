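#' Protein intensity matrix with explicit missingness
#'
#' The central container of the package: a proteins-by-samples grid of
#' log-scale intensities, a logical mask of which entries were actually
#' observed, and a two-group sample annotation (\code{"CTRL"} vs
#' \code{"TRT"}). Missing entries carry a sentinel value (0 by convention,
#' mirroring detection-limit censored MS output) but all downstream code
#' consults the mask, never the sentinel.
#'
#' @param values numeric matrix, proteins in rows, samples in columns.
#'   Rownames (protein ids) and colnames (sample names) are kept if present,
#'   otherwise generated.
#' @param observed logical matrix of the same shape, \code{TRUE} where the
#'   intensity was observed. Defaults to \code{!is.na(values)}.
#' @param groups character/factor of length \code{ncol(values)} assigning
#'   every sample to \code{"CTRL"} or \code{"TRT"}.
#' @return an object of class \code{intensity_matrix}: a list with elements
#'   \code{values}, \code{observed}, \code{groups}.
#' @examples
#' m <- matrix(rnorm(12, 15), 3, 4)
#' im <- intensity_matrix(m, groups = c("CTRL", "CTRL", "TRT", "TRT"))
#' @export
intensity_matrix <- function(values, observed = NULL, groups) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(observed)) observed <- !is.na(values)
  observed <- as.matrix(observed)
  if (!is.logical(observed) || !identical(dim(observed), dim(values)))
    stop("'observed' must be a logical matrix with the same shape as 'values'")
  groups <- as.character(groups)
  if (length(groups) != ncol(values))
    stop("'groups' must assign every sample (one entry per column)")
  bad <- setdiff(unique(groups), c("CTRL", "TRT"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (use 'CTRL' / 'TRT')")
  if (!all(c("CTRL", "TRT") %in% groups))
    stop("both groups (CTRL and TRT) must be non-empty")
  if (any(!is.finite(values[observed])))
    stop("observed entries must be finite")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%d", seq_len(nrow(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate protein ids")
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%d", seq_len(ncol(values)))
  values[!observed] <- 0
  dimnames(observed) <- dimnames(values)
  structure(list(values = values, observed = observed, groups = groups),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf(
    "intensity_matrix: %d proteins x %d samples (%d CTRL, %d TRT), %.1f%% missing\n",
    nrow(x$values), ncol(x$values),
    sum(x$groups == "CTRL"), sum(x$groups == "TRT"),
    100 * mean(!x$observed)))
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' Standardize each protein to zero mean and unit variance
#'
#' Centres and scales the observed entries of every protein, pooling both
#' groups (the between-group shift is the signal the model detects and is
#' preserved relative to the pooled spread). Sample standard deviation uses
#' the n-1 denominator. Proteins with fewer than two observed values are
#' left untouched; proteins with zero variance are centred only. Both cases
#' raise a warning and are reported in the \code{"flagged"} attribute.
#'
#' @param x an [intensity_matrix()].
#' @return a standardized \code{intensity_matrix} with an added attribute
#'   \code{flagged}: integer indices of proteins that could not be fully
#'   standardized.
#' @export
standardize <- function(x) {
  stopifnot(inherits(x, "intensity_matrix"))
  v <- x$values
  obs <- x$observed
  n_obs <- rowSums(obs)
  w <- ifelse(obs, 1, NA_real_)
  mu <- rowMeans(v * w, na.rm = TRUE)
  mu[n_obs == 0] <- 0
  cen <- v - mu
  ss <- rowSums((cen * w)^2, na.rm = TRUE)
  sdv <- ifelse(n_obs >= 2, sqrt(ss / pmax(n_obs - 1, 1)), NA_real_)
  too_few <- n_obs < 2
  zero_var <- !too_few & (sdv < .Machine$double.eps^0.5)
  scale_by <- ifelse(too_few | zero_var, 1, sdv)
  out <- cen / scale_by
  out[too_few, ] <- v[too_few, ]   # left unstandardized entirely
  out[!obs] <- 0
  flagged <- which(too_few | zero_var)
  if (length(flagged))
    warning(length(flagged), " protein(s) with <2 observed values or zero",
            " variance were not (fully) standardized")
  res <- x
  res$values <- out
  attr(res, "flagged") <- flagged
  res
}
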