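# Debug-oriented exports: the assembled model as an LP-format file and a
# selection result as JSON.

#' Write the selection MILP in LP file format
#'
#' Emits the full model — objective, cardinality, gating, balance and
#' capacity constraints, binaries — in CPLEX LP text format so it can be
#' inspected or fed to any external LP/MILP tool.
#'
#' @param model a `mitn_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lp <- function(model, path) {
  stopifnot(inherits(model, "mitn_model"))
  network <- model$network
  n <- length(network$b)
  idx <- seq_len(n)
  xff <- function(i, j) sprintf("x_%d_%d", i, j)
  lines <- c("\\ MI transfer network selection model", "Maximize",
             paste(" obj:", paste(sprintf("xT_%d", idx), collapse = " + ")),
             "Subject To",
             paste0(" card_y: ", paste(sprintf("y_%d", idx), collapse = " + "),
                    " = ", model$P),
             paste0(" card_v: ", paste(sprintf("v_%d", idx), collapse = " + "),
                    " = 1"),
             sprintf(" gate_v_%d: v_%d - y_%d <= 0", idx, idx, idx))
  for (i in idx) {
    out_terms <- c(vapply(setdiff(idx, i), function(j) xff(i, j), character(1)),
                   sprintf("xD_%d", i), sprintf("xT_%d", i))
    in_terms <- vapply(setdiff(idx, i), function(j) xff(j, i), character(1))
    lines <- c(lines, paste0(" bal_", i, ": ",
                             paste(out_terms, collapse = " + "),
                             paste0(" - ", in_terms, collapse = ""),
                             " = ", format(network$b[i], digits = 17)))
  }
  for (i in idx) for (j in setdiff(idx, i)) {
    u <- format(network$U[i, j], digits = 17)
    lines <- c(lines,
               sprintf(" cap_%d_%d_a: %s - %s y_%d <= 0", i, j, xff(i, j), u, i),
               sprintf(" cap_%d_%d_b: %s - %s y_%d <= 0", i, j, xff(i, j), u, j))
  }
  lines <- c(lines,
             sprintf(" sink_gate_%d: xT_%d - %s v_%d <= 0", idx, idx,
                     format(network$big_M, digits = 17), idx),
             sprintf(" sink_bound_%d: xT_%d <= %s", idx, idx,
                     vapply(model$k, format, character(1), digits = 17)),
             "Binaries",
             paste("", paste(c(sprintf("y_%d", idx), sprintf("v_%d", idx)),
                             collapse = " ")),
             "End")
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a selection result to JSON
#'
#' @param result a `selection_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  payload <- list(
    selected = result$selected_names,
    selected_indices = result$selected,
    terminal = result$terminal_name,
    objective_bits = result$objective,
    achieved_gap = result$achieved_gap,
    status = result$status,
    P = result$P,
    flows = result$flow[result$flow$flow > 1e-12, ]
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  invisible(path)
}
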