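#' Build the MI transfer network
#'
#' Computes the symmetric matrix `U` of pairwise mutual information between
#' predictors (zero diagonal) — the arc capacities of the transfer network —
#' and the supply vector `b` with `b[i] = I(f_i; C)`, the class information
#' injected at node i. The "infinite" capacity of the arcs into the sink is
#' replaced by the finite `big_M = sum(b)` (total flow into the sink can
#' never exceed total supply), keeping every coefficient finite for the
#' solver.
#'
#' @param data a [dataset_table()].
#' @return An object of class `mi_network` with fields `U` (n x n, bits),
#'   `b` (length n, bits), `names`, `big_M`.
#' @export
build_network <- function(data) {
  stopifnot(inherits(data, "dataset_table"))
  n <- n_features(data)
  feats <- data$features
  U <- matrix(0, n, n, dimnames = list(names(feats), names(feats)))
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        U[i, j] <- U[j, i] <- mutual_information(feats[[i]], feats[[j]])
      }
    }
  }
  b <- vapply(feats, function(f) mutual_information(f, data$class_column),
              numeric(1))
  big_M <- sum(b)
  if (big_M <= 0) big_M <- 1
  structure(list(U = U, b = b, names = names(feats), big_M = big_M),
            class = "mi_network")
}

#' Construct an MI transfer network from raw components
#'
#' Mostly useful for tests and for feeding the solver in isolation from any
#' dataset; validates the network invariants.
#'
#' @param U symmetric non-negative matrix of pairwise MI (bits), zero diagonal.
#' @param b non-negative supply vector, `b[i] = I(f_i; C)` in bits.
#' @param names optional feature labels.
#' @param big_M finite stand-in for the unbounded sink-arc capacity;
#'   defaults to `max(sum(b), 1)`.
#' @return An `mi_network`.
#' @export
mi_network <- function(U, b, names = NULL, big_M = NULL) {
  U <- as.matrix(U)
  n <- length(b)
  if (!all(dim(U) == c(n, n))) stop("mi_network: U must be n x n", call. = FALSE)
  if (any(U < 0) || any(b < 0)) stop("mi_network: U and b must be non-negative",
                                     call. = FALSE)
  if (max(abs(U - t(U))) > 1e-9) stop("mi_network: U must be symmetric", call. = FALSE)
  diag(U) <- 0
  if (is.null(names)) names <- paste0("f", seq_len(n))
  if (is.null(big_M)) big_M <- max(sum(b), 1)
  if (big_M < sum(b) * (1 - 1e-12)) {
    stop("mi_network: big_M must be at least sum(b)", call. = FALSE)
  }
  dimnames(U) <- list(names, names)
  structure(list(U = U, b = stats::setNames(as.numeric(b), names),
                 names = names, big_M = big_M),
            class = "mi_network")
}

#' @export
print.mi_network <- function(x, ...) {
  cat(sprintf("<mi_network> %d feature nodes, total supply %.4f bits\n",
              length(x$b), sum(x$b)))
  invisible(x)
}

#' Per-terminal upper bounds on sink flow
#'
#' For each candidate terminal i, bounds the flow it can deliver into the
#' sink when P features are selected: its own supply plus either the top
#' (P - 1) arc capacities into it or the top (P - 1) other supplies,
#' whichever total is smaller. The candidate set for the companions is taken
#' as all other features, a precomputable superset relaxation of the
#' unselected set (a superset can only raise the maxima, so validity is
#' preserved). These bounds shrink the feasible region of the selection
#' model and prune its search.
#'
#' @param network an `mi_network`.
#' @param P selection size, `1 <= P <= n`.
#' @return An object of class `bound_vector`: fields `k` (length n, bits)
#'   and `P`.
#' @export
compute_upper_bounds <- function(network, P) {
  stopifnot(inherits(network, "mi_network"))
  n <- length(network$b)
  P <- as.integer(P)
  if (is.na(P) || P < 1L || P > n) {
    stop(sprintf("compute_upper_bounds: P must be in [1, %d]", n), call. = FALSE)
  }
  top_sum <- function(v, r) if (r <= 0L || length(v) == 0L) 0 else
    sum(sort(v, decreasing = TRUE)[seq_len(min(r, length(v)))])
  k <- vapply(seq_len(n), function(i) {
    cap_in <- network$U[-i, i]
    min(network$b[i] + top_sum(cap_in, P - 1L),
        network$b[i] + top_sum(network$b[-i], P - 1L))
  }, numeric(1))
  structure(list(k = stats::setNames(k, network$names), P = P),
            class = "bound_vector")
}

#' Write / read an MI transfer network as JSON
#'
#' Round-trippable plain-text serialization (names, U, b, big_M) so a network
#' can be archived or handed to the solver without the originating dataset.
#'
#' @param network an `mi_network`.
#' @param path output file path.
#' @return `write_network_json` returns `path` invisibly;
#'   `read_network_json` returns an `mi_network`.
#' @export
write_network_json <- function(network, path) {
  stopifnot(inherits(network, "mi_network"))
  payload <- list(names = network$names,
                  U = unname(network$U),
                  b = unname(network$b),
                  big_M = network$big_M)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  mi_network(U = payload$U, b = payload$b, names = payload$names,
             big_M = payload$big_M)
}
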