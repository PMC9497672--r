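#' Solver configuration
#'
#' @param mip_gap relative optimality-gap tolerance at which branch-and-bound
#'   may stop (default 0.05, i.e. the incumbent is within 5% of the best
#'   remaining bound). Use 0 for proven optimality.
#' @param time_limit_seconds wall-clock limit; the best incumbent found so
#'   far is returned with status `"time_limit"` when exceeded.
#' @param seed accepted for interface uniformity; the solver itself is
#'   deterministic.
#' @return An object of class `milp_config`.
#' @export
milp_config <- function(mip_gap = 0.05, time_limit_seconds = Inf, seed = NULL) {
  if (mip_gap < 0) stop("milp_config: mip_gap must be >= 0", call. = FALSE)
  structure(list(mip_gap = mip_gap, time_limit_seconds = time_limit_seconds,
                 seed = seed), class = "milp_config")
}

#' Build the selection MILP
#'
#' Assembles the gated maximum-flow model over an MI transfer network:
#' continuous arc flows `x_ij` (feature to feature), `x_iD` (to the dummy
#' node absorbing undelivered supply) and `x_iT` (to the sink), binary
#' selection indicators `y_i` and terminal indicators `v_i`. The objective
#' maximizes total flow into the sink subject to
#' \itemize{
#'   \item (C1) `sum(y) = P` and (C2) `sum(v) = 1`, with (C3) `v_i <= y_i`:
#'     exactly P features are selected and exactly one of them is the
#'     terminal;
#'   \item (C4) flow balance `sum_j x_ij + x_iD + x_iT - sum_j x_ji = b_i`
#'     at every feature node;
#'   \item (C5) `x_ij <= U_ij y_i` and `x_ij <= U_ij y_j`: information moves
#'     only between selected features, never exceeding the pairwise MI;
#'   \item (C6) `x_iT <= big_M v_i`: only the terminal reaches the sink;
#'   \item (C7) `x_iT <= k_i`: the precomputed per-terminal bound.
#' }
#' The dummy and sink nodes have no outgoing arcs.
#'
#' @param network an `mi_network` from [build_network()] or [mi_network()].
#' @param P number of features to select.
#' @param bounds a `bound_vector` from [compute_upper_bounds()] for the same
#'   `P`; computed automatically if omitted.
#' @return An object of class `mitn_model` with the model data and the
#'   variable/constraint dimensions (`n_vars`, `n_constraints`).
#' @export
build_model <- function(network, P, bounds = NULL) {
  stopifnot(inherits(network, "mi_network"))
  n <- length(network$b)
  P <- as.integer(P)
  if (is.na(P) || P < 1L || P > n) {
    stop(sprintf("build_model: P must be in [1, %d]", n), call. = FALSE)
  }
  if (is.null(bounds)) bounds <- compute_upper_bounds(network, P)
  if (!inherits(bounds, "bound_vector") || length(bounds$k) != n) {
    stop("build_model: bounds do not match the network", call. = FALSE)
  }
  if (bounds$P != P) {
    stop("build_model: bounds were computed for a different P", call. = FALSE)
  }
  structure(list(
    network = network, P = P, k = bounds$k,
    n_vars = n * (n - 1L) + 3L * n + n,              # x_ff, x_D, x_T, y + v
    n_constraints = 2L + n + n + 2L * n * (n - 1L) + n + n
  ), class = "mitn_model")
}

#' @export
print.mitn_model <- function(x, ...) {
  cat(sprintf("<mitn_model> n = %d features, P = %d; %d variables, %d constraints\n",
              length(x$network$b), x$P, x$n_vars, x$n_constraints))
  invisible(x)
}

# heuristic completion of a partial selection: fill with the undecided
# features that can hand the terminal the most information directly
complete_heuristic <- function(network, t, inc, und, r) {
  if (r > 0L) {
    score <- pmin(network$b[und], network$U[und, t])
    inc <- c(inc, und[order(-score, und)][seq_len(r)])
  }
  inc
}

top_sum_num <- function(v, r) {
  if (r <= 0L || length(v) == 0L) return(0)
  sum(sort(v, decreasing = TRUE)[seq_len(min(r, length(v)))])
}

#' Solve the selection MILP by branch-and-bound
#'
#' Best-first branch-and-bound over the binary variables. At any node of the
#' search tree the terminal is fixed and features are partitioned into
#' included / excluded / undecided; the relaxation bound is the minimum of
#' (i) the terminal's supply plus the largest attainable direct-arc
#' capacities into it, (ii) the largest attainable total supply, and (iii)
#' the max-flow value of the network restricted to the non-excluded features
#' — valid because once the binaries are fixed the model is exactly a
#' maximum-flow linear program. The search stops when the best open bound is
#' within the configured relative gap of the incumbent.
#'
#' @param model a `mitn_model` from [build_model()].
#' @param config a [milp_config()].
#' @return An object of class `selection_result`: `selected` (indices),
#'   `selected_names`, `terminal`, `flow` (arc table with columns `from`,
#'   `to`, `flow`; `"D"` and `"T"` denote the dummy and sink nodes),
#'   `objective` (bits into the sink), `achieved_gap`, `status` (one of
#'   `"optimal"`, `"gap_reached"`, `"time_limit"`), `P`, `nodes_explored`.
#' @export
solve_model <- function(model, config = milp_config()) {
  stopifnot(inherits(model, "mitn_model"))
  if (!inherits(config, "milp_config")) stop("solve_model: config must be a milp_config",
                                             call. = FALSE)
  network <- model$network
  n <- length(network$b)
  P <- model$P
  k <- model$k
  gap <- config$mip_gap
  t_start <- Sys.time()
  cap_T <- function(t) min(k[t], network$big_M)
  tol <- 1e-12

  # incumbent: greedy-by-supply subset, best terminal inside it
  S0 <- order(-network$b, seq_len(n))[seq_len(P)]
  best <- list(value = -Inf, S = NULL, t = NULL)
  for (t in S0) {
    v <- solver_flow(network, S0, t, cap_T(t))$value
    if (v > best$value + tol) best <- list(value = v, S = sort(S0), t = t)
  }

  # node store: one root per terminal
  nodes <- vector("list", 64L)
  bounds_q <- rep(-Inf, 64L)
  n_nodes <- 0L
  pruned_ub <- -Inf   # largest bound of any subtree discarded under the gap
  push <- function(node) {
    n_nodes <<- n_nodes + 1L
    if (n_nodes > length(nodes)) {
      length(nodes) <<- 2L * length(nodes)
      bounds_q <<- c(bounds_q, rep(-Inf, length(bounds_q)))
    }
    nodes[[n_nodes]] <<- node
    bounds_q[n_nodes] <<- node$bound
  }

  node_bound <- function(t, inc, excl, lb) {
    und <- setdiff(which(!excl), inc)
    r <- P - length(inc)
    if (length(und) < r) return(NULL)
    others <- setdiff(inc, t)
    cheap <- min(
      network$b[t] + sum(network$U[others, t]) + top_sum_num(network$U[und, t], r),
      sum(network$b[inc]) + top_sum_num(network$b[und], r),
      k[t])
    if (cheap <= lb * (1 + gap) + tol) return(list(bound = cheap, skip = TRUE))
    avail <- which(!excl)
    fb <- solver_flow(network, avail, t, cap_T(t))$value
    list(bound = min(cheap, fb), skip = FALSE, und = und, r = r)
  }

  explored <- 0L
  for (t in order(-k, seq_len(n))) {
    excl <- rep(FALSE, n)
    nb <- node_bound(t, t, excl, best$value)
    if (is.null(nb)) next
    if (nb$skip) { pruned_ub <- max(pruned_ub, nb$bound); next }
    push(list(t = t, inc = t, excl = excl, bound = nb$bound))
  }

  status <- "optimal"
  final_ub <- best$value
  while (n_nodes > 0L) {
    if (is.finite(config$time_limit_seconds) &&
        as.numeric(difftime(Sys.time(), t_start, units = "secs")) >
        config$time_limit_seconds) {
      status <- "time_limit"
      final_ub <- max(best$value, pruned_ub, max(bounds_q[seq_len(n_nodes)]))
      break
    }
    i_top <- which.max(bounds_q[seq_len(n_nodes)])
    node <- nodes[[i_top]]
    top_bound <- bounds_q[i_top]
    nodes[[i_top]] <- nodes[[n_nodes]]
    bounds_q[i_top] <- bounds_q[n_nodes]
    bounds_q[n_nodes] <- -Inf
    n_nodes <- n_nodes - 1L
    if (top_bound <= best$value * (1 + gap) + tol) {
      # the largest open bound is within the gap: done
      final_ub <- max(best$value, top_bound, pruned_ub)
      status <- if (final_ub <= best$value + 1e-9) "optimal" else "gap_reached"
      break
    }
    explored <- explored + 1L
    t <- node$t
    und <- setdiff(which(!node$excl), node$inc)
    r <- P - length(node$inc)
    # heuristic dive keeps the incumbent honest early
    Sh <- complete_heuristic(network, t, node$inc, und, r)
    vh <- solver_flow(network, Sh, t, cap_T(t))$value
    if (vh > best$value + tol) best <- list(value = vh, S = sort(Sh), t = t)
    # branch on the undecided feature with the largest direct value to t
    score <- pmin(network$b[und], network$U[und, t]) + 1e-9 * network$b[und]
    j <- und[order(-score, und)][1L]
    for (take in c(TRUE, FALSE)) {
      inc2 <- node$inc; excl2 <- node$excl
      if (take) inc2 <- c(inc2, j) else excl2[j] <- TRUE
      if (length(inc2) == P) {
        v <- solver_flow(network, inc2, t, cap_T(t))$value
        if (v > best$value + tol) best <- list(value = v, S = sort(inc2), t = t)
        next
      }
      nb <- node_bound(t, inc2, excl2, best$value)
      if (is.null(nb)) next
      if (nb$skip) { pruned_ub <- max(pruned_ub, nb$bound); next }
      push(list(t = t, inc = inc2, excl = excl2, bound = nb$bound))
    }
  }
  if (n_nodes == 0L && status == "optimal") {
    final_ub <- max(best$value, pruned_ub)
    if (final_ub > best$value + 1e-9) status <- "gap_reached"
  }

  res <- as_selection_result(network, best$S, best$t, cap_T(best$t), P)
  res$achieved_gap <- if (best$value > 0) max(0, (final_ub - best$value) / best$value)
                      else 0
  res$status <- status
  res$nodes_explored <- explored
  res
}

# package a (subset, terminal) pair as a full selection_result, with the
# per-arc flows recovered from the solver-route max flow
as_selection_result <- function(network, S, t, cap_T, P) {
  sf <- solver_flow(network, S, t, cap_T, flows = TRUE)
  nm <- network$names
  m <- length(S)
  ed <- sf$edges
  lab <- c("S", nm[S], "T")
  from <- lab[ed$from]; to <- lab[ed$to]
  ff <- from != "S" & to != "T"
  flow <- data.frame(from = from[ff], to = to[ff], flow = ed$flow[ff],
                     stringsAsFactors = FALSE)
  # terminal -> sink arc
  it <- which(to == "T")
  flow <- rbind(flow, data.frame(from = nm[t], to = "T", flow = ed$flow[it]))
  # undelivered supply drains to the dummy node; unselected nodes send all of it
  drained <- stats::setNames(network$b, nm)
  src <- ed$from == 1L
  drained[nm[S]] <- network$b[S] - ed$flow[src][match(seq_len(m), ed$to[src] - 1L)]
  flow <- rbind(flow, data.frame(from = nm, to = "D",
                                 flow = pmax(unname(drained), 0)))
  structure(list(
    selected = sort(S), selected_names = nm[sort(S)], terminal = t,
    terminal_name = nm[t], flow = flow, objective = sf$value,
    achieved_gap = 0, status = "optimal", P = P
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> P = %d, objective = %.6f bits, status = %s (gap %.4f)\n",
              x$P, x$objective, x$status, x$achieved_gap))
  cat("  selected:", paste(x$selected_names, collapse = ", "), "\n")
  cat("  terminal:", x$terminal_name, "\n")
  invisible(x)
}

#' Check a selection result against the model constraints
#'
#' Re-derives every constraint of the selection MILP on the returned
#' incumbent — cardinalities, terminal membership, non-negativity, flow
#' balance at each feature node, and all capacity constraints — and reports
#' each violation found. Report-only: never throws.
#'
#' @param result a `selection_result`.
#' @param network the `mi_network` it was solved on.
#' @param P the selection size used.
#' @param tol numeric tolerance for the balance and capacity checks.
#' @return Character vector of violation messages (empty when valid), with
#'   class `mitn_validation`.
#' @export
validate_solution <- function(result, network, P, tol = 1e-6) {
  v <- character(0)
  nm <- network$names
  n <- length(nm)
  if (length(result$selected) != P) {
    v <- c(v, sprintf("cardinality: |selected| = %d, expected P = %d",
                      length(result$selected), P))
  }
  if (length(result$terminal) != 1L) {
    v <- c(v, "terminal: exactly one terminal required")
  } else if (!result$terminal %in% result$selected) {
    v <- c(v, "terminal gating: terminal is not a selected feature (v_i <= y_i)")
  }
  fl <- result$flow
  if (any(fl$flow < -tol)) v <- c(v, "non-negativity: negative arc flow present")
  k <- compute_upper_bounds(network, P)$k
  ysel <- nm %in% nm[result$selected]
  for (a in which(fl$from != "D" & fl$to != "D" & fl$to != "T")) {
    i <- match(fl$from[a], nm); j <- match(fl$to[a], nm)
    capv <- network$U[i, j] * min(ysel[i], ysel[j])
    if (fl$flow[a] > capv + tol) {
      v <- c(v, sprintf("capacity: x[%s,%s] = %.6g exceeds U*y = %.6g",
                        fl$from[a], fl$to[a], fl$flow[a], capv))
    }
  }
  for (a in which(fl$to == "T")) {
    i <- match(fl$from[a], nm)
    gate <- if (length(result$terminal) == 1L && i == result$terminal)
      network$big_M else 0
    if (fl$flow[a] > gate + tol) {
      v <- c(v, sprintf("sink gating: x[%s,T] = %.6g but node is not the terminal",
                        fl$from[a], fl$flow[a]))
    }
    if (fl$flow[a] > k[i] + tol) {
      v <- c(v, sprintf("sink bound: x[%s,T] = %.6g exceeds k = %.6g",
                        fl$from[a], fl$flow[a], k[i]))
    }
  }
  outfl <- infl <- stats::setNames(rep(0, n), nm)
  for (a in seq_len(nrow(fl))) {
    if (fl$from[a] %in% nm) outfl[fl$from[a]] <- outfl[fl$from[a]] + fl$flow[a]
    if (fl$to[a] %in% nm) infl[fl$to[a]] <- infl[fl$to[a]] + fl$flow[a]
  }
  bal <- outfl - infl - network$b
  for (i in which(abs(bal) > tol)) {
    v <- c(v, sprintf("balance: node %s off by %.6g (outflow - inflow - b)",
                      nm[i], bal[i]))
  }
  structure(v, class = "mitn_validation")
}

#' @export
print.mitn_validation <- function(x, ...) {
  if (length(x) == 0L) cat("valid: no constraint violations\n")
  else cat(sprintf("%d violation(s):\n%s\n", length(x),
                   paste(" -", unclass(x), collapse = "\n")))
  invisible(x)
}

#' Exhaustive oracle for the selection model
#'
#' Enumerates every P-subset and every terminal choice inside it, solves each
#' induced maximum-flow problem with a self-contained augmenting-path
#' algorithm (independent of the branch-and-bound route), and returns the
#' global optimum. Ties are broken by lexicographically smallest subset, then
#' smallest terminal index. Intended for verification on small instances.
#'
#' @param network an `mi_network`.
#' @param P selection size.
#' @param cap refuse instances with more than this many subsets.
#' @return A `selection_result` with status `"optimal"`, gap 0, and an extra
#'   field `per_terminal`: the best achievable sink flow for each choice of
#'   terminal node (useful for auditing the per-terminal bounds).
#' @export
exhaustive_oracle <- function(network, P, cap = 20000) {
  stopifnot(inherits(network, "mi_network"))
  n <- length(network$b)
  P <- as.integer(P)
  if (is.na(P) || P < 1L || P > n) {
    stop(sprintf("exhaustive_oracle: P must be in [1, %d]", n), call. = FALSE)
  }
  if (choose(n, P) > cap) {
    stop(sprintf(paste0("exhaustive_oracle: %d subsets exceed the cap of %d; ",
                        "reduce n or P (or raise cap)"),
                 choose(n, P), cap), call. = FALSE)
  }
  k <- compute_upper_bounds(network, P)$k
  subsets <- utils::combn(n, P)
  best_v <- -Inf; best_S <- NULL; best_t <- NULL
  per_terminal <- stats::setNames(rep(-Inf, n), network$names)
  for (s in seq_len(ncol(subsets))) {
    S <- subsets[, s]
    for (t in S) {
      # uncapped sink arc; every unit of sink flow crosses that single arc,
      # so the k-capped model value is simply min(v_unc, k_t)
      v_unc <- oracle_flow(network, S, t, network$big_M)$value
      if (v_unc > per_terminal[t]) per_terminal[t] <- v_unc
      v <- min(v_unc, k[t])
      if (v > best_v + 1e-12) { best_v <- v; best_S <- S; best_t <- t }
    }
  }
  res <- as_selection_result(network, best_S, best_t,
                             min(k[best_t], network$big_M), P)
  # report the oracle's own objective (Edmonds-Karp route)
  res$objective <- best_v
  res$per_terminal <- per_terminal
  res
}
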