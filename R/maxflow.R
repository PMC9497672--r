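# Flow subproblems induced by a candidate selection.
#
# Once the binary selection (subset S, terminal t) is fixed, the selection
# model reduces to a pure maximum-flow problem: a super-source feeds each
# selected node its supply b_j, selected features exchange flow along arcs of
# capacity U_jm (both directions), and only the terminal forwards into the
# sink, capped by min(k_t, big_M). Two independent evaluators are kept on
# purpose: the branch-and-bound solver uses igraph's max_flow, while the
# exhaustive oracle uses a self-contained Edmonds-Karp so that
# oracle-vs-solver agreement is a genuine cross-check.

# Edmonds-Karp on a dense capacity matrix (node 1 = source, node n = sink).
# Pure R; intended for the small graphs the oracle enumerates.
ek_max_flow <- function(cap, tol = 1e-12) {
  n <- nrow(cap)
  resid <- cap
  value <- 0
  repeat {
    # BFS for a shortest augmenting path in the residual graph
    parent <- integer(n)
    parent[1L] <- -1L
    queue <- 1L; head <- 1L
    while (head <= length(queue) && parent[n] == 0L) {
      u <- queue[head]; head <- head + 1L
      nxt <- which(resid[u, ] > tol & parent == 0L)
      nxt <- nxt[nxt != 1L]
      if (length(nxt) > 0L) {
        parent[nxt] <- u
        queue <- c(queue, nxt)
      }
    }
    if (parent[n] == 0L) break
    # bottleneck along the path
    aug <- Inf
    v <- n
    while (v != 1L) {
      u <- parent[v]
      aug <- min(aug, resid[u, v])
      v <- u
    }
    v <- n
    while (v != 1L) {
      u <- parent[v]
      resid[u, v] <- resid[u, v] - aug
      resid[v, u] <- resid[v, u] + aug
      v <- u
    }
    value <- value + aug
  }
  list(value = value, flow = pmax(cap - resid, 0))
}

# Capacity matrix for subset S with terminal t (t must be in S).
# Node order: source, S (in given order), sink.
subset_capacity <- function(network, S, t, cap_T) {
  m <- length(S)
  cap <- matrix(0, m + 2L, m + 2L)
  cap[1L, 1L + seq_len(m)] <- network$b[S]
  if (m > 1) cap[1L + seq_len(m), 1L + seq_len(m)] <- network$U[S, S, drop = FALSE]
  cap[1L + match(t, S), m + 2L] <- cap_T
  cap
}

# Oracle-route evaluation of one (S, t) candidate: Edmonds-Karp.
oracle_flow <- function(network, S, t, cap_T) {
  ek_max_flow(subset_capacity(network, S, t, cap_T))
}

# Solver-route evaluation of one (S, t) candidate: igraph max_flow.
# Returns the optimal sink flow and, if flows = TRUE, the per-arc flows.
solver_flow <- function(network, S, t, cap_T, flows = FALSE) {
  m <- length(S)
  # edge list: source (vertex 1) -> features (2..m+1), feature pairs both
  # directions, terminal -> sink (m+2)
  from <- rep(1L, m); to <- 1L + seq_len(m); capv <- unname(network$b[S])
  if (m > 1) {
    pr <- utils::combn(m, 2L)
    uu <- network$U[S, S, drop = FALSE][t(pr)]
    keep <- uu > 0
    if (any(keep)) {
      i <- pr[1L, keep] + 1L; j <- pr[2L, keep] + 1L; u <- uu[keep]
      from <- c(from, i, j); to <- c(to, j, i); capv <- c(capv, u, u)
    }
  }
  from <- c(from, 1L + match(t, S)); to <- c(to, m + 2L)
  capv <- c(capv, cap_T)
  g <- igraph::make_graph(rbind(from, to), n = m + 2L, directed = TRUE)
  mf <- igraph::max_flow(g, source = 1L, target = m + 2L, capacity = capv)
  if (!flows) return(list(value = mf$value))
  list(value = mf$value,
       edges = data.frame(from = from, to = to, capacity = capv,
                          flow = pmax(as.numeric(mf$flow), 0)))
}
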