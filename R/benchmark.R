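# Classifier benchmark harness: selection-size grid x method x four
# classifier families, scored by stratified cross-validated accuracy so the
# comparison of selectors is not tied to any single downstream model.

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

fit_predict_family <- function(family, Xtr, ytr, Xte) {
  switch(family,
    knn = as.character(class::knn(Xtr, Xte, cl = ytr)),
    nb = {
      fit <- e1071::naiveBayes(Xtr, ytr)
      as.character(stats::predict(fit, Xte))
    },
    svm = {
      fit <- e1071::svm(Xtr, ytr, kernel = "linear", scale = FALSE)
      as.character(stats::predict(fit, Xte))
    },
    lda = {
      fit <- MASS::lda(Xtr, grouping = ytr)
      as.character(stats::predict(fit, Xte)$class)
    },
    stop(sprintf("unknown classifier family '%s'", family), call. = FALSE))
}

#' Cross-validated accuracy of a feature subset
#'
#' Scores a candidate subset with four off-the-shelf classifier families —
#' nearest neighbour, naive Bayes, linear support vector machine, and linear
#' discriminant analysis, all at default hyperparameters — under stratified
#' k-fold cross-validation with a fixed seed, and reports the per-family and
#' mean accuracies. Using several families decouples the comparison of
#' selectors from any one model's inductive bias. A family that fails on a
#' fold (e.g. a within-class-constant predictor breaking the discriminant
#' fit) scores `NA` for that fold and is averaged over the folds it
#' completed.
#'
#' @param data a [dataset_table()].
#' @param subset integer indices of the features to evaluate.
#' @param families classifier families, a subset of
#'   `c("knn", "nb", "svm", "lda")`.
#' @param cv_folds number of folds (>= 2); every class must have at least
#'   `cv_folds` observations.
#' @param seed seed controlling the fold assignment.
#' @return A list: `accuracy` (named per-family), `mean_accuracy`,
#'   `cv_folds`, `seed`, `subset`.
#' @export
evaluate_subset <- function(data, subset,
                            families = c("knn", "nb", "svm", "lda"),
                            cv_folds = 5L, seed = 1L) {
  stopifnot(inherits(data, "dataset_table"))
  subset <- as.integer(subset)
  if (length(subset) == 0L || any(subset < 1L | subset > n_features(data))) {
    stop("evaluate_subset: subset must be non-empty feature indices", call. = FALSE)
  }
  if (cv_folds < 2L) stop("evaluate_subset: cv_folds must be >= 2", call. = FALSE)
  y <- factor(data$class_column$codes)
  small <- table(y) < cv_folds
  if (any(small)) {
    stop(sprintf(paste0("evaluate_subset: class(es) %s have fewer than %d ",
                        "observations; reduce cv_folds or merge classes"),
                 paste(names(small)[small], collapse = ", "), cv_folds),
         call. = FALSE)
  }
  X <- vapply(data$features[subset], function(f) as.numeric(f$codes),
              numeric(data$n_obs))
  X <- matrix(X, nrow = data$n_obs,
              dimnames = list(NULL, feature_names(data)[subset]))
  # one seeded RNG scope covers fold assignment AND classifier-internal
  # randomness (e.g. nearest-neighbour tie-breaks), so results are
  # reproducible and the caller's RNG stream is untouched
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  fold <- stratified_folds(y, cv_folds)
  acc <- matrix(NA_real_, nrow = cv_folds, ncol = length(families),
                dimnames = list(NULL, families))
  for (f in seq_len(cv_folds)) {
    te <- fold == f
    Xtr <- X[!te, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    ytr <- droplevels(y[!te])
    for (fam in families) {
      pred <- tryCatch(
        suppressWarnings(fit_predict_family(fam, Xtr, ytr, Xte)),
        error = function(e) NULL)
      if (!is.null(pred)) acc[f, fam] <- mean(pred == as.character(y[te]))
    }
  }
  per_family <- colMeans(acc, na.rm = TRUE)
  per_family[is.nan(per_family)] <- NA_real_
  list(accuracy = per_family,
       mean_accuracy = mean(per_family, na.rm = TRUE),
       cv_folds = cv_folds, seed = seed, subset = subset)
}

#' Run the full method x selection-size benchmark grid
#'
#' For every method and every selection size P, selects a subset and scores
#' it with [evaluate_subset()] under identical folds and seed, so cells are
#' directly comparable. Failures of individual methods are recorded per cell
#' and the grid continues.
#'
#' @param data a [dataset_table()].
#' @param methods character vector of method names (`"mitn"` plus any of the
#'   greedy criteria).
#' @param P_grid selection sizes; `max(P_grid)` must not exceed the number
#'   of features.
#' @param families,cv_folds,seed passed to [evaluate_subset()].
#' @param beta MIFS-U penalty scale (if `"mifs-u"` is among the methods).
#' @param config a [milp_config()] for the network selector; its achieved
#'   gap is recorded per cell.
#' @return An object of class `benchmark_result`: `cells` (one row per
#'   method / P / classifier), `means` (one row per method / P), `errors`,
#'   and the configuration metadata.
#' @export
run_grid <- function(data, methods, P_grid,
                     families = c("knn", "nb", "svm", "lda"),
                     cv_folds = 5L, seed = 1L, beta = NULL,
                     config = milp_config()) {
  stopifnot(inherits(data, "dataset_table"))
  P_grid <- as.integer(P_grid)
  if (max(P_grid) > n_features(data)) {
    stop("run_grid: max(P_grid) exceeds the number of features", call. = FALSE)
  }
  cells <- list(); means <- list(); errors <- list()
  for (method in methods) {
    for (P in P_grid) {
      sel <- tryCatch(select_features(data, method, P, beta = beta,
                                      config = config),
                      error = function(e) e)
      if (inherits(sel, "error")) {
        errors[[length(errors) + 1L]] <-
          data.frame(method = method, P = P, error = conditionMessage(sel))
        next
      }
      ev <- evaluate_subset(data, sel$indices, families, cv_folds, seed)
      gap <- if (inherits(sel$result, "selection_result"))
        sel$result$achieved_gap else NA_real_
      cells[[length(cells) + 1L]] <-
        data.frame(method = sel$method, P = P, classifier = families,
                   accuracy = unname(ev$accuracy))
      means[[length(means) + 1L]] <-
        data.frame(method = sel$method, P = P,
                   mean_accuracy = ev$mean_accuracy, achieved_gap = gap,
                   subset = paste(sel$names, collapse = ";"))
    }
  }
  structure(list(
    cells = do.call(rbind, cells),
    means = do.call(rbind, means),
    errors = if (length(errors)) do.call(rbind, errors) else NULL,
    meta = list(families = families, cv_folds = cv_folds, seed = seed,
                beta = beta, mip_gap = config$mip_gap,
                of_ratio = data$n_obs / n_features(data),
                hyperparameters = "library defaults")
  ), class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d cells, %d method/P combinations\n",
              NROW(x$cells), NROW(x$means)))
  print(x$means)
  invisible(x)
}

#' Rank methods within each benchmark cell
#'
#' Rank 1 is the most accurate method within every (classifier, P) cell;
#' tied methods share the better rank.
#'
#' @param result a `benchmark_result` covering at least two methods.
#' @return Data frame with columns `method`, `P`, `classifier`, `accuracy`,
#'   `rank`.
#' @export
rank_methods <- function(result) {
  stopifnot(inherits(result, "benchmark_result"))
  cells <- result$cells
  if (length(unique(cells$method)) < 2L) {
    stop("rank_methods: need at least two methods", call. = FALSE)
  }
  cells$rank <- stats::ave(cells$accuracy,
                           interaction(cells$P, cells$classifier),
                           FUN = function(a) rank(-a, ties.method = "min"))
  cells
}

#' Write benchmark results to disk
#'
#' Tidy CSV of the per-cell accuracies plus a JSON summary of the per-method
#' means and metadata.
#'
#' @param result a `benchmark_result`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return Invisibly, a list of the paths written.
#' @export
write_benchmark <- function(result, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(result, "benchmark_result"))
  if (!is.null(csv_path)) utils::write.csv(result$cells, csv_path,
                                           row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(means = result$means, meta = result$meta,
                              errors = result$errors),
                         json_path, digits = NA, auto_unbox = TRUE,
                         dataframe = "rows")
  }
  invisible(list(csv = csv_path, json = json_path))
}
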