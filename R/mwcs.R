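#' Find the maximum-weight connected subgraph (active module)
#'
#' Finds a connected node set maximizing the sum of node scores. Exact
#' mode uses a branch-and-bound search (positive-component contraction,
#' non-positive leaf pruning, reachable-positive-weight bound) and
#' guarantees optimality; heuristic mode grows a connected set greedily
#' with two-step lookahead and is certified connected but possibly
#' suboptimal. When every score is negative the single best-scoring node
#' is returned (a non-empty report is always produced). Connectivity of
#' the returned set is re-verified independently of the solver.
#'
#' @param net igraph network whose vertices all carry a finite `score`.
#' @param mode `"exact"` or `"heuristic"`.
#' @param max_exact_nodes Refuse exact mode beyond this size.
#' @return An `mwcs_solution`: list with `node_keys` (sorted character),
#'   `total_score`, `solver_status`, `replicate_index` (NA here).
#' @export
solve_mwcs <- function(net, mode = c("exact", "heuristic"),
                       max_exact_nodes = 30000L) {
  mode <- match.arg(mode)
  score <- igraph::V(net)$score
  if (is.null(score) || any(!is.finite(score))) {
    abort("every node must carry a finite score",
          class = "metamodule_data_error")
  }
  n <- igraph::vcount(net)
  if (mode == "exact" && n > max_exact_nodes) {
    abort(sprintf("exact mode refused for %d nodes (> %d); use mode = 'heuristic'",
                  n, max_exact_nodes), class = "metamodule_solver_error")
  }
  # canonical vertex order = sorted node keys, for deterministic tie-breaks
  ord <- order(igraph::V(net)$name)
  net_s <- igraph::permute(net, order(ord))
  keys <- igraph::V(net_s)$name
  w <- igraph::V(net_s)$score
  el <- igraph::as_edgelist(net_s, names = FALSE)

  if (mode == "exact") {
    res <- .mwcs_solve_cpp(n, matrix(as.integer(el - 1L), ncol = 2), w)
    sel <- res$nodes
    total <- res$score
    status <- "optimal"
  } else {
    sel <- greedy_mwcs(net_s, w)
    total <- sum(w[sel])
    status <- "heuristic"
  }
  sub <- igraph::induced_subgraph(net_s, sel)
  if (igraph::vcount(sub) > 0 && !igraph::is_connected(sub)) {
    abort("solver returned a disconnected node set", # nocov
          class = "metamodule_solver_error")         # nocov
  }
  if (abs(total - sum(w[sel])) > 1e-6) {
    abort("solver score does not match recomputed member sum", # nocov
          class = "metamodule_solver_error")                   # nocov
  }
  structure(list(node_keys = sort(keys[sel]), total_score = sum(w[sel]),
                 solver_status = status, replicate_index = NA_integer_),
            class = "mwcs_solution")
}

# greedy connected growth with two-step lookahead over frontier nodes
greedy_mwcs <- function(net, w) {
  n <- length(w)
  adj <- igraph::as_adj_list(net, mode = "all")
  adj <- purrr::map(adj, as.integer)
  start <- which.max(w)
  sel <- rep(FALSE, n)
  sel[start] <- TRUE
  repeat {
    frontier <- setdiff(unique(unlist(adj[sel])), which(sel))
    if (length(frontier) == 0) break
    gain1 <- w[frontier]
    gain2 <- purrr::map_dbl(frontier, function(v) {
      nb <- setdiff(adj[[v]], which(sel))
      w[v] + if (length(nb) > 0) max(c(0, w[nb])) else 0
    })
    pick <- frontier[which.max(pmax(gain1, gain2))]
    if (max(pmax(gain1, gain2)) <= 0) break
    sel[pick] <- TRUE
  }
  which(sel)
}

#' @export
print.mwcs_solution <- function(x, ...) {
  cat(sprintf("Active module: %d node(s), total score %.4f [%s]\n",
              length(x$node_keys), x$total_score, x$solver_status))
  cat(" ", paste(head(x$node_keys, 12), collapse = ", "),
      if (length(x$node_keys) > 12) "..." else "", "\n")
  invisible(x)
}

#' @export
glance.mwcs_solution <- function(x, ...) {
  tibble::tibble(n_nodes = length(x$node_keys), total_score = x$total_score,
                 solver_status = x$solver_status,
                 replicate_index = x$replicate_index)
}

#' @export
tidy.mwcs_solution <- function(x, ...) {
  tibble::tibble(node = x$node_keys)
}
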