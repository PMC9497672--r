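#' Encoded dataset: predictors plus class column
#'
#' The unit every selection method consumes: an ordered, named collection of
#' discretized predictor columns and one categorical class column, all of the
#' same length. Construct directly from pre-encoded columns, or from a data
#' frame via [as_dataset_table()] / [read_csv_dataset()], which discretize
#' continuous columns first.
#'
#' @param features named list of [cat_series()] (or coercible vectors).
#' @param class_column a [cat_series()] (or coercible vector) of class labels.
#' @return An object of class `dataset_table` with fields `features`,
#'   `class_column`, `n_obs`.
#' @export
dataset_table <- function(features, class_column) {
  if (length(features) == 0L) {
    stop("dataset_table: need at least one feature", call. = FALSE)
  }
  if (is.null(names(features)) || any(names(features) == "") ||
      anyDuplicated(names(features))) {
    stop("dataset_table: features must have unique non-empty names", call. = FALSE)
  }
  features <- lapply(features, as_cat_series)
  class_column <- as_cat_series(class_column)
  n_obs <- length(class_column$codes)
  bad <- vapply(features, function(s) length(s$codes) != n_obs, logical(1))
  if (any(bad)) {
    stop(sprintf("dataset_table: features %s differ in length from the class column",
                 paste(names(features)[bad], collapse = ", ")), call. = FALSE)
  }
  structure(list(features = features, class_column = class_column, n_obs = n_obs),
            class = "dataset_table")
}

#' @export
print.dataset_table <- function(x, ...) {
  cat(sprintf("<dataset_table> %d obs, %d features, %d classes\n",
              x$n_obs, length(x$features), x$class_column$n_levels))
  invisible(x)
}

n_features <- function(data) length(data$features)

feature_names <- function(data) names(data$features)

#' Encode a data frame as a dataset_table
#'
#' Numeric columns that look continuous (at least `continuity_threshold`
#' distinct values) are binned at equal-frequency boundaries; everything else
#' is passed through as categorical.
#'
#' @param df a data frame with no missing values.
#' @param target_column name of the class column in `df`.
#' @param discretization a [discretization_spec()].
#' @return A [dataset_table()].
#' @export
as_dataset_table <- function(df, target_column,
                             discretization = discretization_spec()) {
  if (!target_column %in% names(df)) {
    stop(sprintf("as_dataset_table: target column '%s' not found", target_column),
         call. = FALSE)
  }
  na_cols <- names(df)[vapply(df, anyNA, logical(1))]
  if (length(na_cols) > 0L) {
    stop(sprintf("as_dataset_table: missing values in column(s): %s",
                 paste(na_cols, collapse = ", ")), call. = FALSE)
  }
  feats <- df[setdiff(names(df), target_column)]
  encoded <- lapply(feats, function(col) {
    if (is.numeric(col)) discretize_equal_frequency(col, discretization)
    else cat_series(col)
  })
  dataset_table(encoded, cat_series(df[[target_column]]))
}

#' Read a delimited dataset from disk
#'
#' Reads a header-ed CSV, checks for missing values, encodes categorical
#' columns and discretizes continuous ones.
#'
#' @param path path to a CSV file with a header row.
#' @param target_column name of the class column.
#' @param discretization a [discretization_spec()].
#' @return A [dataset_table()].
#' @export
read_csv_dataset <- function(path, target_column,
                             discretization = discretization_spec()) {
  if (!file.exists(path)) {
    stop(sprintf("read_csv_dataset: no such file: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_dataset_table(df, target_column, discretization)
}
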