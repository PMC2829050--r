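#' Impute scores for unmeasured nodes
#'
#' Unmeasured metabolites are assumed unchanged under the null, so their
#' p-values are drawn from Uniform(0, 1) and converted to scores with the
#' mixture fit obtained from the measured p-values. This samples the joint
#' null distribution of unmeasured abundances rather than asserting
#' certainty that they did not change, and lets an unmeasured node enter
#' a module when it bridges high-scoring measured neighbours.
#'
#' @param net igraph network with scores on measured nodes (NA elsewhere).
#' @param fit A `bum_fit` carrying tau (from the measured p-values).
#' @param tau Threshold override.
#' @return Fully scored network (every node has a finite `score`).
#' @export
impute_unmeasured <- function(net, fit, tau = fit$tau) {
  score <- igraph::V(net)$score
  if (is.null(score)) score <- rep(NA_real_, igraph::vcount(net))
  miss <- which(is.na(score))
  if (length(miss) > 0) {
    p <- runif(length(miss))
    score[miss] <- score_pvalue(p, fit, tau)
  }
  igraph::V(net)$score <- score
  net
}

#' Repeated randomized module searches
#'
#' Runs `n_replicates` independent active-module searches. Each replicate
#' re-draws the uniform p-values of unmeasured nodes (and, when ambiguity
#' groups are given, re-assigns each shared peak's score to one uniformly
#' chosen candidate node, the other candidates reverting to unmeasured)
#' and solves for the optimal module. Replicate seeds are
#' `base_seed + replicate_index`, so any replicate can be reproduced in
#' isolation.
#'
#' @param net Network with scores on measured nodes.
#' @param fit,tau Mixture fit and threshold from the measured p-values.
#' @param n_replicates Number of searches (default 100).
#' @param base_seed Integer seed.
#' @param mode Solver mode, see [solve_mwcs()].
#' @param ambiguity_groups Optional list of character vectors of node
#'   keys; each group's candidates must all be flagged measured in `net`
#'   (carrying the shared peak's score).
#' @return List of `mwcs_solution` objects with `replicate_index` set.
#'   Failed replicates are dropped with a warning.
#' @export
run_replicates <- function(net, fit, tau = fit$tau, n_replicates = 100L,
                           base_seed = 1L, mode = "exact",
                           ambiguity_groups = NULL) {
  keys <- igraph::V(net)$name
  base_score <- igraph::V(net)$score
  solutions <- purrr::map(seq_len(n_replicates), function(i) {
    set.seed(base_seed + i)
    score <- base_score
    if (!is.null(ambiguity_groups)) {
      for (g in ambiguity_groups) {
        idx <- match(g, keys)
        if (any(is.na(idx)) || any(is.na(base_score[idx]))) {
          abort("ambiguity group candidates must be measured nodes of the network",
                class = "metamodule_data_error")
        }
        keep <- sample.int(length(idx), 1L)
        score[idx[-keep]] <- NA_real_
      }
    }
    igraph::V(net)$score <- score
    sol <- tryCatch(solve_mwcs(impute_unmeasured(net, fit, tau), mode = mode),
                    error = function(e) e)
    if (inherits(sol, "error")) return(sol)
    sol$replicate_index <- i
    sol
  })
  failed <- purrr::map_lgl(solutions, inherits, "error")
  if (any(failed)) {
    warn(sprintf("%d of %d replicates failed and were excluded",
                 sum(failed), n_replicates))
  }
  solutions[!failed]
}

#' Aggregate replicate solutions into an Active Module Group
#'
#' The relative frequency of each node over the replicate solutions is
#' computed; nodes at or above the frequency threshold form the AMG.
#'
#' @param solutions List of `mwcs_solution`.
#' @param threshold Relative frequency cutoff (default 0.20).
#' @return An `amg` object: list with `frequencies` (tibble node /
#'   frequency over all nodes ever selected), `selected` (character),
#'   `threshold`, `n_solutions`.
#' @export
build_amg <- function(solutions, threshold = 0.20) {
  if (length(solutions) == 0) {
    abort("need at least one solution", class = "metamodule_data_error")
  }
  freq <- tibble::tibble(node = unlist(purrr::map(solutions, "node_keys"))) |>
    dplyr::count(.data$node) |>
    dplyr::mutate(frequency = .data$n / length(solutions)) |>
    dplyr::select("node", "frequency") |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$node)
  structure(list(frequencies = freq,
                 selected = sort(freq$node[freq$frequency >= threshold]),
                 threshold = threshold, n_solutions = length(solutions)),
            class = "amg")
}

#' @export
print.amg <- function(x, ...) {
  cat(sprintf("Active Module Group: %d node(s) at frequency >= %.2f over %d solutions\n",
              length(x$selected), x$threshold, x$n_solutions))
  invisible(x)
}

#' @export
tidy.amg <- function(x, ...) {
  x$frequencies |> dplyr::mutate(selected = .data$node %in% x$selected)
}

#' @export
glance.amg <- function(x, ...) {
  tibble::tibble(n_selected = length(x$selected), threshold = x$threshold,
                 n_solutions = x$n_solutions)
}
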