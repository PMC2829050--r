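#' Default promiscuous / buffered metabolite exclusion list
#'
#' Twenty-eight currency and buffered metabolites (cofactors, inorganic
#' ions, water) whose ubiquity would create non-specific bridges between
#' otherwise unrelated parts of the network. They are removed from
#' reactions before edge formation unless a reaction is explicitly
#' exempted (e.g. nucleotide biosynthesis/catabolism, where nucleotides
#' are the primary reactants and products).
#' @export
promiscuous_metabolites <- c(
  "UMP", "UDP", "UTP", "FAD", "FADH2", "Na", "K", "SO4", "NH4", "CO2",
  "Pi", "O2", "PPi", "H2O", "H", "OH", "ATP", "ADP", "AMP", "CTP",
  "CDP", "CMP", "NAD", "NADH", "NADP", "NADPH", "H2O2", "HCO3")

node_key <- function(metabolite, compartment) {
  sprintf("%s[%s]", metabolite, compartment)
}

participant_keys <- function(df) node_key(df$metabolite, df$compartment)

#' Build the unipartite metabolite reaction network
#'
#' Projects a compartmented reaction table onto an undirected graph whose
#' nodes are compartment-split metabolites (`met[compartment]`). Two edge
#' rules apply per reaction: every reactant is joined to every product
#' (tag `reactant_product`), and, for each catalyst, all substrates
#' (reactants and products, pooled across every reaction of that
#' catalyst) are joined into a clique (tag `shared_substrate`).
#' Promiscuous metabolites are dropped from reactions before edge
#' formation, except in reactions listed in `exempt_reactions`.
#' Reversibility is ignored: the projection is undirected.
#'
#' @param reactions Tibble from [read_reaction_table()].
#' @param promiscuous Metabolite identifiers to exclude.
#' @param exempt_reactions Reaction ids whose promiscuous participants are
#'   kept (nucleotide-primary carve-out).
#' @return An igraph object with vertex attributes `name` (node key),
#'   `metabolite`, `compartment`, `measured` and edge attributes
#'   `reactant_product`, `shared_substrate`, `reactions`, `catalysts`.
#' @export
build_mrn <- function(reactions, promiscuous = promiscuous_metabolites,
                      exempt_reactions = character()) {
  filt <- reactions |>
    dplyr::mutate(exempt = .data$reaction_id %in% exempt_reactions,
                  reactants = purrr::map2(.data$reactants, .data$exempt,
                    ~ if (.y) .x else dplyr::filter(.x, !.data$metabolite %in% promiscuous)),
                  products = purrr::map2(.data$products, .data$exempt,
                    ~ if (.y) .x else dplyr::filter(.x, !.data$metabolite %in% promiscuous)))
  gone <- purrr::map2_lgl(filt$reactants, filt$products,
                          ~ nrow(.x) == 0 && nrow(.y) == 0)
  if (any(gone)) {
    warn(sprintf("reaction(s) with all participants promiscuous contribute nothing: %s",
                 paste(filt$reaction_id[gone], collapse = ", ")))
  }

  node_tab <- dplyr::bind_rows(
    purrr::map2_dfr(filt$reactants, filt$reaction_id, ~ dplyr::mutate(.x, reaction_id = .y)),
    purrr::map2_dfr(filt$products, filt$reaction_id, ~ dplyr::mutate(.x, reaction_id = .y))
  ) |>
    dplyr::mutate(key = node_key(.data$metabolite, .data$compartment))

  rp_edges <- purrr::pmap_dfr(
    list(filt$reactants, filt$products, filt$reaction_id),
    function(r, p, id) {
      if (nrow(r) == 0 || nrow(p) == 0) return(NULL)
      tidyr::expand_grid(a = participant_keys(r), b = participant_keys(p)) |>
        dplyr::filter(.data$a != .data$b) |>
        dplyr::mutate(reaction = id, catalyst = NA_character_, tag = "reactant_product")
    })

  cat_tab <- filt |>
    dplyr::select("reaction_id", "catalysts", "reactants", "products") |>
    tidyr::unnest_longer("catalysts", values_to = "catalyst") |>
    dplyr::filter(!is.na(.data$catalyst), .data$catalyst != "")
  ss_edges <- cat_tab |>
    dplyr::group_by(.data$catalyst) |>
    dplyr::group_modify(function(d, key) {
      subs <- sort(unique(c(unlist(purrr::map(d$reactants, participant_keys)),
                            unlist(purrr::map(d$products, participant_keys)))))
      if (length(subs) < 2) return(tibble::tibble())
      pairs <- t(utils::combn(subs, 2))
      tibble::tibble(a = pairs[, 1], b = pairs[, 2],
                     reaction = paste(sort(unique(d$reaction_id)), collapse = ","),
                     tag = "shared_substrate")
    }) |>
    dplyr::ungroup()

  edges <- dplyr::bind_rows(rp_edges, ss_edges)
  if (nrow(edges) == 0) {
    edge_tab <- tibble::tibble(from = character(), to = character(),
                               reactant_product = logical(),
                               shared_substrate = logical(),
                               reactions = character(), catalysts = character())
  } else {
    edge_tab <- edges |>
      dplyr::mutate(from = pmin(.data$a, .data$b), to = pmax(.data$a, .data$b)) |>
      dplyr::group_by(.data$from, .data$to) |>
      dplyr::summarise(
        reactant_product = any(.data$tag == "reactant_product"),
        shared_substrate = any(.data$tag == "shared_substrate"),
        reactions = paste(sort(unique(unlist(strsplit(.data$reaction, ",")))), collapse = ","),
        catalysts = paste(sort(unique(.data$catalyst[!is.na(.data$catalyst)])), collapse = ","),
        .groups = "drop")
  }

  vertices <- node_tab |>
    dplyr::distinct(.data$key, .data$metabolite, .data$compartment) |>
    dplyr::arrange(.data$key) |>
    dplyr::mutate(measured = FALSE) |>
    dplyr::rename(name = "key")
  igraph::graph_from_data_frame(edge_tab, directed = FALSE, vertices = vertices)
}

#' Node and edge tables of a metabolite network
#'
#' @param net An igraph network from [build_mrn()].
#' @return A tibble of vertex (or edge) attributes.
#' @export
mrn_nodes <- function(net) {
  tibble::as_tibble(igraph::as_data_frame(net, what = "vertices")) |>
    dplyr::rename(node = "name")
}

#' @rdname mrn_nodes
#' @export
mrn_edges <- function(net) {
  tibble::as_tibble(igraph::as_data_frame(net, what = "edges"))
}

#' Flag the measured node of each measured metabolite
#'
#' A metabolite measured in plasma exists in the network as several
#' compartment twins; exactly one of them carries the measurement. The
#' extracellular convention (EMRN) flags the `[e]` node, the cytoplasmic
#' convention (CMRN) the `[c]` node; if the preferred compartment is
#' absent the other of \{e, c\} is used, else the alphabetically first
#' available node.
#'
#' @param net igraph network.
#' @param measured_metabolite_ids Character vector of metabolite ids.
#' @param placement `"extracellular"` or `"cytoplasmic"`.
#' @return The network with vertex attribute `measured` set.
#' @export
assign_measured_compartment <- function(net, measured_metabolite_ids,
                                        placement = c("extracellular", "cytoplasmic")) {
  placement <- match.arg(placement)
  preferred <- if (placement == "extracellular") "e" else "c"
  fallback <- setdiff(c("e", "c"), preferred)
  nodes <- mrn_nodes(net)
  absent <- setdiff(measured_metabolite_ids, nodes$metabolite)
  if (length(absent) > 0) {
    warn(sprintf("measured metabolite(s) absent from network, dropped: %s",
                 paste(absent, collapse = ", ")))
  }
  chosen <- nodes |>
    dplyr::filter(.data$metabolite %in% measured_metabolite_ids) |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::arrange(match(.data$compartment, c(preferred, fallback)), .data$node,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  igraph::V(net)$measured <- nodes$node %in% chosen$node
  net
}

#' Restrict a network to measured nodes and their short bridges
#'
#' Keeps every measured node plus any unmeasured node lying on a path of
#' total length at most `max_path_len` between two distinct measured
#' nodes (an unmeasured node u qualifies if its two nearest distinct
#' measured nodes m1, m2 satisfy d(m1,u) + d(u,m2) <= max_path_len).
#' Distances are unweighted shortest-path edge counts.
#'
#' @param net igraph network with `measured` vertex flags set.
#' @param max_path_len Maximum total path length (default 3).
#' @return The induced subgraph on retained nodes.
#' @export
filter_to_measured <- function(net, max_path_len = 3L) {
  measured <- which(igraph::V(net)$measured)
  if (length(measured) == 0) {
    abort("no measured nodes in network", class = "metamodule_data_error")
  }
  keep <- igraph::V(net)$measured
  # enumerate simple paths of length <= max_path_len from each measured
  # node; interiors of those ending at another measured node are bridges
  # (a pendant node is on no such path and is dropped)
  for (m in measured) {
    paths <- igraph::all_simple_paths(net, from = m, cutoff = max_path_len)
    for (p in paths) {
      idx <- as.integer(p)
      last <- idx[length(idx)]
      if (last != m && igraph::V(net)$measured[last]) {
        keep[idx] <- TRUE
      }
    }
  }
  igraph::induced_subgraph(net, which(keep))
}
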