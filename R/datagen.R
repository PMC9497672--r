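#' Parameters of the planted-structure generator
#'
#' Describes a synthetic classification dataset with three kinds of
#' predictors: *informative* features drawn class-conditionally (Gaussian
#' with class means `class_signal` pooled standard deviations apart),
#' *redundant* features that are noisy copies of informative ones, and
#' *noise* features independent of the class. This mirrors the structure
#' filter selectors must disentangle in real tabular data: relevance,
#' near-collinearity, and irrelevance.
#'
#' @param n_informative,n_redundant,n_noise feature counts (informative +
#'   redundant + noise >= 1).
#' @param n_obs number of observations (at least `10 * n_classes`).
#' @param n_classes number of class labels (balanced).
#' @param class_signal separation of adjacent class means, in units of the
#'   within-class standard deviation. The default 2 gives strongly but not
#'   perfectly informative single features.
#' @param redundancy_noise standard deviation of the perturbation added to a
#'   redundant copy. The default 0.5 keeps about 80% of the parent's
#'   variance, emulating near-collinear measured covariates.
#' @param seed integer seed; the whole table is a deterministic function of
#'   the spec.
#' @return An object of class `planted_spec`.
#' @export
planted_spec <- function(n_informative = 5L, n_redundant = 5L, n_noise = 40L,
                         n_obs = 500L, n_classes = 2L, class_signal = 2,
                         redundancy_noise = 0.5, seed = 1L) {
  counts <- c(n_informative, n_redundant, n_noise)
  if (any(counts < 0) || sum(counts) < 1L) {
    stop("planted_spec: feature counts must be >= 0 and sum to >= 1", call. = FALSE)
  }
  if (n_redundant > 0L && n_informative < 1L) {
    stop("planted_spec: redundant features need at least one informative parent",
         call. = FALSE)
  }
  if (n_classes < 2L) stop("planted_spec: need at least 2 classes", call. = FALSE)
  if (n_obs < 10L * n_classes) {
    stop("planted_spec: n_obs must be at least 10 * n_classes", call. = FALSE)
  }
  if (class_signal < 0 || redundancy_noise < 0) {
    stop("planted_spec: class_signal and redundancy_noise must be >= 0",
         call. = FALSE)
  }
  structure(list(n_informative = as.integer(n_informative),
                 n_redundant = as.integer(n_redundant),
                 n_noise = as.integer(n_noise),
                 n_obs = as.integer(n_obs), n_classes = as.integer(n_classes),
                 class_signal = class_signal,
                 redundancy_noise = redundancy_noise, seed = as.integer(seed)),
            class = "planted_spec")
}

#' Generate a dataset with planted informative, redundant and noise features
#'
#' Draws a balanced-class table per the spec and returns both the raw
#' continuous columns and the encoded [dataset_table()] (continuous columns
#' binned at equal-frequency boundaries). The ground-truth role of every
#' feature is returned for recovery scoring.
#'
#' @param spec a [planted_spec()].
#' @param discretization a [discretization_spec()].
#' @return An object of class `planted_dataset`: `data` (a
#'   [dataset_table()]), `raw` (data frame incl. the `class` column),
#'   `roles` (character vector: `"informative"`, `"redundant"`, `"noise"`),
#'   `parents` (for redundant features, the name of the informative parent),
#'   `spec`.
#' @export
generate_planted_dataset <- function(spec, discretization = discretization_spec()) {
  stopifnot(inherits(spec, "planted_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)
  n <- spec$n_obs
  cls <- sample(rep_len(seq_len(spec$n_classes), n))
  centered <- cls - (spec$n_classes + 1) / 2
  cols <- list(); roles <- character(0); parents <- character(0)
  inf_raw <- list()
  for (i in seq_len(spec$n_informative)) {
    x <- spec$class_signal * centered + stats::rnorm(n)
    nm <- sprintf("inf%d", i)
    cols[[nm]] <- x; inf_raw[[i]] <- x
    roles <- c(roles, "informative"); parents <- c(parents, NA_character_)
  }
  for (j in seq_len(spec$n_redundant)) {
    parent <- ((j - 1L) %% spec$n_informative) + 1L
    nm <- sprintf("red%d", j)
    cols[[nm]] <- inf_raw[[parent]] + stats::rnorm(n, sd = spec$redundancy_noise)
    roles <- c(roles, "redundant")
    parents <- c(parents, sprintf("inf%d", parent))
  }
  for (j in seq_len(spec$n_noise)) {
    cols[[sprintf("noise%d", j)]] <- stats::rnorm(n)
    roles <- c(roles, "noise"); parents <- c(parents, NA_character_)
  }
  raw <- as.data.frame(cols)
  names(roles) <- names(parents) <- names(raw)
  raw$class <- cls
  structure(list(data = as_dataset_table(raw, "class", discretization),
                 raw = raw, roles = roles, parents = parents, spec = spec),
            class = "planted_dataset")
}

#' @export
print.planted_dataset <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<planted_dataset> %d obs, %d classes; %d informative + %d redundant + %d noise (seed %d)\n",
              s$n_obs, s$n_classes, s$n_informative, s$n_redundant, s$n_noise,
              s$seed))
  invisible(x)
}

#' Write the raw columns of a planted dataset to CSV
#'
#' @param planted a `planted_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_planted_csv <- function(planted, path) {
  stopifnot(inherits(planted, "planted_dataset"))
  utils::write.csv(planted$raw, path, row.names = FALSE)
  invisible(path)
}
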