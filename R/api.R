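#' Select P features with the MI-transfer-network MILP
#'
#' Convenience front-end: builds the MI transfer network from the data,
#' precomputes the per-terminal bounds, assembles the gated maximum-flow
#' model and solves it by branch-and-bound.
#'
#' @param data a [dataset_table()].
#' @param P number of features to select.
#' @param config a [milp_config()].
#' @return A `selection_result` (see [solve_model()]).
#' @examples
#' d <- generate_planted_dataset(planted_spec(n_informative = 2, n_redundant = 0,
#'                                            n_noise = 3, n_obs = 120, seed = 7))
#' mitn_select(d$data, P = 2, config = milp_config(mip_gap = 0))
#' @export
mitn_select <- function(data, P, config = milp_config()) {
  stopifnot(inherits(data, "dataset_table"))
  network <- build_network(data)
  bounds <- compute_upper_bounds(network, P)
  model <- build_model(network, P, bounds)
  solve_model(model, config)
}

#' Select features by any method in the package
#'
#' Uniform dispatcher over the network selector (`"mitn"`) and the seven
#' greedy criteria; used by the benchmark harness and the command line.
#'
#' @param data a [dataset_table()].
#' @param method `"mitn"` or a greedy criterion name
#'   (see [greedy_criterion()]).
#' @param m number of features to select.
#' @param beta MIFS-U penalty scale (required for `"mifs-u"`).
#' @param config a [milp_config()] (used by `"mitn"` only).
#' @return A list with `indices`, `names`, `method`, and the full `result`
#'   object (`selection_result` or `greedy_trace`).
#' @export
select_features <- function(data, method, m, beta = NULL,
                            config = milp_config()) {
  method_key <- tolower(method)
  if (method_key %in% c("mitn", "mitn-ilp", "mitnilp")) {
    res <- mitn_select(data, m, config)
    return(list(indices = res$selected, names = res$selected_names,
                method = "MITN-ILP", result = res))
  }
  crit <- greedy_criterion(method, beta = beta)
  tr <- greedy_select(data, m, crit)
  list(indices = sort(tr$selected_order),
       names = feature_names(data)[sort(tr$selected_order)],
       method = crit$name, result = tr)
}
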