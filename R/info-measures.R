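#' Shannon entropy of a categorical series
#'
#' Plug-in (maximum-likelihood) estimate from the empirical category
#' frequencies, in bits. Cells with zero probability contribute nothing
#' (0 log 0 := 0).
#'
#' @param s a [cat_series()] or coercible vector.
#' @param base logarithm base; 2 (bits, the default) or any base > 1.
#'   Selection methods are invariant to the base because every criterion
#'   scales uniformly with it.
#' @return Entropy in bits, in `[0, log2(n_levels)]`.
#' @examples
#' entropy(cat_series(c(0, 1)))        # 1 bit
#' entropy(cat_series(c(0, 0, 0, 1)))  # 0.811 bits
#' @export
entropy <- function(s, base = 2) {
  s <- as_cat_series(s)
  p <- tabulate(s$codes, nbins = s$n_levels) / length(s$codes)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

check_equal_length <- function(..., what) {
  lens <- vapply(list(...), function(s) length(s$codes), integer(1))
  if (length(unique(lens)) != 1L) {
    stop(sprintf("%s: series lengths differ (%s)", what,
                 paste(lens, collapse = ", ")), call. = FALSE)
  }
}

#' Joint variable of two categorical series
#'
#' Pairs the two series row-wise and assigns one code per *observed* (a, b)
#' combination, so the entropy of the result equals the joint entropy of the
#' inputs. Used to evaluate joint-information terms such as I(f; C,fi).
#'
#' @param a,b [cat_series()] objects (or coercible) of equal length.
#' @return A [cat_series()] over the observed pairs.
#' @export
joint_variable <- function(a, b) {
  a <- as_cat_series(a); b <- as_cat_series(b)
  check_equal_length(a, b, what = "joint_variable")
  key <- (a$codes - 1L) * b$n_levels + b$codes
  lev <- sort(unique(key))
  new_cat_series(match(key, lev), length(lev))
}

joint_all <- function(ss) Reduce(joint_variable, ss)

#' Joint entropy of one or more categorical series
#'
#' Entropy of the tuple-valued variable obtained by aligning the series
#' row-wise, in bits. Satisfies the chain rule
#' `H(X, Y) = H(Y) + H(X | Y)`.
#'
#' @param ss a list of [cat_series()] objects of equal length (a single
#'   series is also accepted).
#' @param base logarithm base (see [entropy()]).
#' @return Joint entropy in bits.
#' @export
joint_entropy <- function(ss, base = 2) {
  if (inherits(ss, "cat_series")) ss <- list(ss)
  if (length(ss) == 0L) stop("joint_entropy: need at least one series", call. = FALSE)
  ss <- lapply(ss, as_cat_series)
  do.call(check_equal_length, c(ss, list(what = "joint_entropy")))
  entropy(joint_all(ss), base = base)
}

#' Conditional entropy H(X | Y)
#'
#' `H(X | Y) = H(X, Y) - H(Y)`, in bits; always within `[0, H(X)]`.
#'
#' @param x,y [cat_series()] objects of equal length.
#' @param base logarithm base (see [entropy()]).
#' @return Conditional entropy in bits.
#' @export
conditional_entropy <- function(x, y, base = 2) {
  x <- as_cat_series(x); y <- as_cat_series(y)
  check_equal_length(x, y, what = "conditional_entropy")
  joint_entropy(list(x, y), base = base) - entropy(y, base = base)
}

#' Mutual information I(X; Y)
#'
#' `I(X; Y) = H(X) - H(X | Y)`, in bits; symmetric and non-negative, bounded
#' by `min(H(X), H(Y))`.
#'
#' @param x,y [cat_series()] objects of equal length.
#' @param base logarithm base (see [entropy()]).
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y, base = 2) {
  x <- as_cat_series(x); y <- as_cat_series(y)
  check_equal_length(x, y, what = "mutual_information")
  entropy(x, base = base) + entropy(y, base = base) -
    joint_entropy(list(x, y), base = base)
}

#' Conditional mutual information I(X; Y | Z)
#'
#' `I(X; Y | Z) = H(X | Z) - H(X | Y, Z)`, in bits; non-negative.
#'
#' @param x,y,z [cat_series()] objects of equal length.
#' @param base logarithm base (see [entropy()]).
#' @return Conditional mutual information in bits.
#' @export
conditional_mutual_information <- function(x, y, z, base = 2) {
  x <- as_cat_series(x); y <- as_cat_series(y); z <- as_cat_series(z)
  check_equal_length(x, y, z, what = "conditional_mutual_information")
  conditional_entropy(x, z, base = base) -
    conditional_entropy(x, joint_variable(y, z), base = base)
}

#' Interaction information I(X; Y; Z)
#'
#' Three-way information under the convention
#' `I(X; Y; Z) = I(X; Y) - I(X; Y | Z)`: positive values indicate redundancy
#' among the three variables, negative values synergy (the XOR triple gives
#' -1 bit). Symmetric under any permutation of its arguments.
#'
#' @param x,y,z [cat_series()] objects of equal length.
#' @param base logarithm base (see [entropy()]).
#' @return Interaction information in bits (may be negative).
#' @export
interaction_information <- function(x, y, z, base = 2) {
  x <- as_cat_series(x); y <- as_cat_series(y); z <- as_cat_series(z)
  check_equal_length(x, y, z, what = "interaction_information")
  mutual_information(x, y, base = base) -
    conditional_mutual_information(x, y, z, base = base)
}
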