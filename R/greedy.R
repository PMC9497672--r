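#' The greedy forward criteria
#'
#' Every classical MI-based greedy forward selector fits one template: at
#' each step pick the unselected feature f maximizing
#' `J(f) = I(C; f) - beta * sum_{fi in SEL} g(f, fi, C)`, where `beta` is a
#' scale rule (a constant, or `1/|SEL|`-type) and `g` a redundancy /
#' complementarity term. This constructor returns one such (beta, g) pair by
#' name:
#'
#' | name     | beta      | g(f, fi, C)                              |
#' |----------|-----------|------------------------------------------|
#' | MIFS-U   | user      | `I(fi;C)/H(fi) * I(f;fi)`                |
#' | IGFS     | -1/\|SEL\|| `I(f; C,fi)`                             |
#' | CIFE     | 1         | `I(fi; C,f)`                             |
#' | MRMD     | 1/\|SEL\| | `I(f;fi) - I(f;C|fi)`                    |
#' | MRI      | 1         | `2 I(f;fi;C) - I(f;C) - I(fi;C)`         |
#' | mRMR     | 1/\|SEL\| | `I(f;fi)`                                |
#' | SPEC-CMI | -1        | `I(f;C|fi)`                              |
#'
#' Joint terms such as `I(f; C,fi)` are evaluated through the joint variable
#' of C and fi; the interaction term uses the convention of
#' [interaction_information()]. For MIFS-U a constant `beta` must be given;
#' a selected feature with zero entropy contributes 0 to its penalty (it
#' carries no information at all).
#'
#' @param name criterion name (case-insensitive, `"mifs-u"`, `"igfs"`,
#'   `"cife"`, `"mrmd"`, `"mri"`, `"mrmr"`, `"spec-cmi"`).
#' @param beta penalty scale for MIFS-U; ignored (with a warning) otherwise.
#' @return An object of class `greedy_criterion`.
#' @export
greedy_criterion <- function(name, beta = NULL) {
  key <- tolower(gsub("[^a-z]", "", tolower(name)))
  known <- c(mifsu = "MIFS-U", igfs = "IGFS", cife = "CIFE", mrmd = "MRMD",
             mri = "MRI", mrmr = "mRMR", speccmi = "SPEC-CMI")
  if (!key %in% names(known)) {
    stop(sprintf("greedy_criterion: unknown criterion '%s' (known: %s)",
                 name, paste(known, collapse = ", ")), call. = FALSE)
  }
  canonical <- known[[key]]
  if (canonical == "MIFS-U") {
    if (is.null(beta)) {
      stop("greedy_criterion: MIFS-U requires a numeric beta", call. = FALSE)
    }
  } else if (!is.null(beta)) {
    warning(sprintf("beta is ignored for %s (its scale rule is fixed)", canonical))
  }
  beta_rule <- switch(canonical,
    "MIFS-U"   = function(n_sel) beta,
    "IGFS"     = function(n_sel) -1 / n_sel,
    "CIFE"     = function(n_sel) 1,
    "MRMD"     = function(n_sel) 1 / n_sel,
    "MRI"      = function(n_sel) 1,
    "mRMR"     = function(n_sel) 1 / n_sel,
    "SPEC-CMI" = function(n_sel) -1)
  structure(list(name = canonical, beta = beta, beta_rule = beta_rule),
            class = "greedy_criterion")
}

# per-dataset memo of the information terms the criteria reuse
new_score_cache <- function(data, base = 2) {
  e <- new.env(parent = emptyenv())
  e$data <- data
  e$base <- base
  n <- n_features(data)
  e$rel <- vapply(data$features,
                  function(f) mutual_information(f, data$class_column, base = base),
                  numeric(1))                      # I(fi; C)
  e$H <- vapply(data$features, entropy, numeric(1), base = base)
  e$memo <- new.env(parent = emptyenv())
  e
}

cached <- function(cache, key, expr) {
  if (is.null(cache$memo[[key]])) cache$memo[[key]] <- force(expr)
  cache$memo[[key]]
}

# g(f, fi, C) for one selected feature fi, per criterion
g_term <- function(criterion, f, fi, cache) {
  d <- cache$data; base <- cache$base
  ff <- d$features[[f]]; fs <- d$features[[fi]]; C <- d$class_column
  pair <- function(tag, i, j) paste(tag, i, j, sep = ":")
  mi_ffi <- function() cached(cache, pair("mi", min(f, fi), max(f, fi)),
                              mutual_information(ff, fs, base = base))
  switch(criterion$name,
    "MIFS-U" = if (cache$H[fi] <= 0) 0 else
      cache$rel[fi] / cache$H[fi] * mi_ffi(),
    "IGFS" = cached(cache, pair("jmi", f, fi),
                    mutual_information(ff, joint_variable(C, fs), base = base)),
    "CIFE" = cached(cache, pair("jmi", fi, f),
                    mutual_information(fs, joint_variable(C, ff), base = base)),
    "MRMD" = mi_ffi() - cached(cache, pair("cmi", f, fi),
                               conditional_mutual_information(ff, C, fs, base = base)),
    "MRI" = 2 * cached(cache, pair("ii", min(f, fi), max(f, fi)),
                       interaction_information(ff, fs, C, base = base)) -
            cache$rel[f] - cache$rel[fi],
    "mRMR" = mi_ffi(),
    "SPEC-CMI" = cached(cache, pair("cmi", f, fi),
                        conditional_mutual_information(ff, C, fs, base = base)))
}

#' Score one candidate feature under a greedy criterion
#'
#' Evaluates `J(f) = I(C; f) - beta(|SEL|) * sum_{fi in SEL} g(f, fi, C)`.
#' With an empty selected set the penalty sum is empty and every criterion
#' reduces to the relevance `I(C; f)`.
#'
#' @param f index of the candidate feature (must not be in `SEL`).
#' @param SEL integer indices of the already-selected features.
#' @param data a [dataset_table()].
#' @param criterion a [greedy_criterion()].
#' @param cache internal memo from a running [greedy_select()]; omit for
#'   one-off use.
#' @param base logarithm base for the information terms.
#' @return The criterion value, in the units of `base`.
#' @export
criterion_score <- function(f, SEL, data, criterion, cache = NULL, base = 2) {
  stopifnot(inherits(criterion, "greedy_criterion"))
  if (f %in% SEL) stop("criterion_score: f is already selected", call. = FALSE)
  if (is.null(cache)) cache <- new_score_cache(data, base = base)
  if (length(SEL) == 0L) return(cache$rel[[f]])
  penalty <- sum(vapply(SEL, function(fi) g_term(criterion, f, fi, cache),
                        numeric(1)))
  cache$rel[[f]] - criterion$beta_rule(length(SEL)) * penalty
}

#' Greedy forward feature selection
#'
#' The generic incremental engine: starting from an empty set, repeatedly
#' add the unselected feature with the highest criterion score (ties go to
#' the smallest index). Every candidate is re-scored at every step, so
#' selecting m of n features costs exactly `(2n - m + 1) m / 2` criterion
#' evaluations (see [evaluation_count()]), and the first j picks of a run of
#' length m coincide with a full run of length j.
#'
#' @param data a [dataset_table()].
#' @param m number of features to select.
#' @param criterion a [greedy_criterion()].
#' @param base logarithm base for the information terms.
#' @return An object of class `greedy_trace`: `selected_order` (indices, in
#'   pick order), `selected_names`, `scores` (criterion value at each pick),
#'   `evaluations` (total criterion evaluations), `criterion`.
#' @export
greedy_select <- function(data, m, criterion, base = 2) {
  stopifnot(inherits(data, "dataset_table"), inherits(criterion, "greedy_criterion"))
  n <- n_features(data)
  m <- as.integer(m)
  if (is.na(m) || m < 1L || m > n) {
    stop(sprintf("greedy_select: m must be in [1, %d]", n), call. = FALSE)
  }
  warn_constant_features(data)
  cache <- new_score_cache(data, base = base)
  SEL <- integer(0)
  scores <- numeric(0)
  evals <- 0L
  while (length(SEL) < m) {
    candidates <- setdiff(seq_len(n), SEL)
    J <- vapply(candidates,
                function(f) criterion_score(f, SEL, data, criterion, cache, base),
                numeric(1))
    evals <- evals + length(candidates)
    pick <- candidates[which.max(J)]       # first maximum = smallest index
    SEL <- c(SEL, pick)
    scores <- c(scores, max(J))
  }
  structure(list(selected_order = SEL,
                 selected_names = feature_names(data)[SEL],
                 scores = scores, evaluations = evals,
                 criterion = criterion$name, beta = criterion$beta),
            class = "greedy_trace")
}

#' @export
print.greedy_trace <- function(x, ...) {
  cat(sprintf("<greedy_trace> %s: %d features in %d evaluations\n",
              x$criterion, length(x$selected_order), x$evaluations))
  cat("  order:", paste(x$selected_names, collapse = " > "), "\n")
  invisible(x)
}

warn_constant_features <- function(data) {
  const <- vapply(data$features, function(f) f$n_levels == 1L, logical(1))
  if (any(const)) {
    warning(sprintf("constant feature(s) carry no information: %s",
                    paste(feature_names(data)[const], collapse = ", ")),
            call. = FALSE)
  }
  invisible(const)
}

#' Criterion evaluations needed by greedy forward search
#'
#' Selecting m of n features greedily scores n candidates at the first step,
#' n - 1 at the second, and so on: `n + (n-1) + ... + (n-m+1) =
#' (2n - m + 1) m / 2` evaluations in total, against `choose(n, m)` subsets
#' for the exhaustive search it replaces.
#'
#' @param n total number of features.
#' @param m number selected.
#' @return Integer evaluation count.
#' @examples
#' evaluation_count(10, 3)  # 27
#' @export
evaluation_count <- function(n, m) {
  n <- as.integer(n); m <- as.integer(m)
  if (is.na(n) || is.na(m) || m < 1L || n < 1L || m > n) {
    stop("evaluation_count: need 1 <= m <= n", call. = FALSE)
  }
  as.integer((2L * n - m + 1L) * m / 2L)
}
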