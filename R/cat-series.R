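#' Categorical series
#'
#' The elementary unit all information measures consume: a vector of integer
#' category codes (1-based, dense in `1:n_levels`) plus the level count.
#' Arbitrary input vectors (numeric, character, logical, factor) are encoded
#' by their distinct observed values; unobserved factor levels are dropped so
#' that empirical frequencies are always positive for every retained level.
#'
#' @param x a vector of observations (any atomic type or factor).
#' @return An object of class `cat_series` with fields `codes` (integer,
#'   values in `1:n_levels`) and `n_levels`.
#' @examples
#' s <- cat_series(c("a", "b", "a"))
#' s$n_levels
#' entropy(s)
#' @export
cat_series <- function(x) {
  if (length(x) == 0L) {
    stop("cat_series: input must contain at least one observation", call. = FALSE)
  }
  if (anyNA(x)) {
    stop("cat_series: missing values are not allowed; impute or drop rows first",
         call. = FALSE)
  }
  if (inherits(x, "cat_series")) return(x)
  codes <- match(x, sort(unique(x)))
  new_cat_series(as.integer(codes), length(unique(codes)))
}

# internal constructor: codes already dense 1..n_levels
new_cat_series <- function(codes, n_levels) {
  structure(list(codes = codes, n_levels = as.integer(n_levels)),
            class = "cat_series")
}

#' @export
print.cat_series <- function(x, ...) {
  cat(sprintf("<cat_series> %d obs, %d levels\n", length(x$codes), x$n_levels))
  invisible(x)
}

#' @export
length.cat_series <- function(x) length(x$codes)

as_cat_series <- function(x) {
  if (inherits(x, "cat_series")) x else cat_series(x)
}

#' Discretization settings
#'
#' Controls how continuous columns are converted to categories before
#' information estimation. Columns with at most `continuity_threshold - 1`
#' distinct values are treated as already categorical and passed through
#' unchanged; all others are cut at equal-frequency (quantile) boundaries
#' taken over the distinct values, so identical inputs can never straddle a
#' bin boundary.
#'
#' @param n_bins number of quantile bins for continuous columns (>= 2).
#' @param continuity_threshold minimum number of distinct values for a column
#'   to be considered continuous.
#' @return An object of class `discretization_spec`.
#' @export
discretization_spec <- function(n_bins = 5L, continuity_threshold = 21L) {
  n_bins <- as.integer(n_bins)
  continuity_threshold <- as.integer(continuity_threshold)
  if (is.na(n_bins) || n_bins < 2L) {
    stop("discretization_spec: n_bins must be an integer >= 2", call. = FALSE)
  }
  if (is.na(continuity_threshold) || continuity_threshold < 1L) {
    stop("discretization_spec: continuity_threshold must be >= 1", call. = FALSE)
  }
  structure(list(n_bins = n_bins, continuity_threshold = continuity_threshold),
            class = "discretization_spec")
}

#' Equal-frequency discretization of a numeric column
#'
#' Bins a numeric vector at quantile boundaries computed over its *distinct*
#' values, which makes the mapping deterministic and keeps tied observations
#' in a single bin. Columns with fewer distinct values than the continuity
#' threshold are passed through as categorical without binning.
#'
#' @param column numeric vector, all values finite.
#' @param spec a [discretization_spec()].
#' @return A [cat_series()] with at most `n_bins` levels (continuous input) or
#'   one level per distinct value (categorical passthrough).
#' @examples
#' discretize_equal_frequency(1:10, discretization_spec(n_bins = 2,
#'                                                      continuity_threshold = 1))
#' @export
discretize_equal_frequency <- function(column, spec = discretization_spec()) {
  if (length(column) == 0L) {
    stop("discretize_equal_frequency: empty column", call. = FALSE)
  }
  if (!is.numeric(column)) {
    stop("discretize_equal_frequency: column must be numeric", call. = FALSE)
  }
  if (any(!is.finite(column))) {
    stop("discretize_equal_frequency: non-finite values present; clean the column first",
         call. = FALSE)
  }
  distinct <- sort(unique(column))
  if (length(distinct) < spec$continuity_threshold) {
    return(new_cat_series(match(column, distinct), length(distinct)))
  }
  # interior boundaries from quantiles of the distinct values: ties stay together
  probs <- seq_len(spec$n_bins - 1L) / spec$n_bins
  cuts <- unique(stats::quantile(distinct, probs = probs, type = 7, names = FALSE))
  codes <- findInterval(column, cuts, left.open = TRUE) + 1L
  # re-densify in case some bin is empty
  lev <- sort(unique(codes))
  new_cat_series(match(codes, lev), length(lev))
}
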