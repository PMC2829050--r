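#' Generate a synthetic metabolite reaction network
#'
#' Draws a random base graph, keeps its largest connected component,
#' labels nodes as cytoplasmic metabolites and duplicates a fraction of
#' them into extracellular twins joined by a dedicated transport
#' catalyst. The result is emitted as a reaction table (one reaction per
#' base edge, one transport reaction per twin) so that rebuilding with
#' [build_mrn()] reproduces the generated graph exactly.
#'
#' @param n_nodes Number of base metabolites (>= 10).
#' @param topology `"erdos_renyi"`, `"barabasi_albert"` or `"lattice"`.
#' @param edge_param Edge probability (ER), edges per step (BA); ignored
#'   for lattice.
#' @param twin_fraction Fraction of metabolites given an `[e]` twin.
#' @param seed Optional integer seed.
#' @return List: `network` (igraph), `reactions` (tibble in
#'   [read_reaction_table()] form), `transporters` (tibble
#'   metabolite/catalyst).
#' @export
generate_network <- function(n_nodes, topology = c("erdos_renyi",
                                                   "barabasi_albert",
                                                   "lattice"),
                             edge_param = 0.02, twin_fraction = 0.2,
                             seed = NULL) {
  topology <- match.arg(topology)
  if (n_nodes < 10) abort("n_nodes must be >= 10", class = "metamodule_config_error")
  if (!is.null(seed)) set.seed(seed)
  g <- switch(topology,
    erdos_renyi = igraph::sample_gnp(n_nodes, edge_param),
    barabasi_albert = igraph::sample_pa(n_nodes, m = max(1, round(edge_param)),
                                        directed = FALSE),
    lattice = {
      k <- ceiling(sqrt(n_nodes))
      gl <- igraph::make_lattice(c(k, k))
      igraph::induced_subgraph(gl, seq_len(n_nodes))
    })
  comp <- igraph::components(g)
  g <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  n <- igraph::vcount(g)
  if (n < 2 || igraph::ecount(g) == 0) {
    abort("generated graph is (near) empty; increase edge_param",
          class = "metamodule_config_error")
  }
  mets <- sprintf("M%03d", seq_len(n))
  el <- igraph::as_edgelist(g, names = FALSE)
  participant <- function(met, comp) tibble::tibble(metabolite = met, compartment = comp)
  base_rxn <- tibble::tibble(
    reaction_id = sprintf("R%04d", seq_len(nrow(el))),
    reactants = purrr::map(el[, 1], ~ participant(mets[.x], "c")),
    products = purrr::map(el[, 2], ~ participant(mets[.x], "c")),
    catalysts = purrr::map(seq_len(nrow(el)), ~ character(0)),
    reversible = TRUE)
  twins <- sort(sample(mets, round(twin_fraction * n)))
  transp <- tibble::tibble(metabolite = twins,
                           catalyst = sprintf("T%03d", seq_along(twins)))
  twin_rxn <- tibble::tibble(
    reaction_id = sprintf("TR%03d", seq_along(twins)),
    reactants = purrr::map(twins, participant, comp = "e"),
    products = purrr::map(twins, participant, comp = "c"),
    catalysts = purrr::map(transp$catalyst, identity),
    reversible = TRUE)
  reactions <- dplyr::bind_rows(base_rxn, twin_rxn)
  list(network = build_mrn(reactions, promiscuous = character()),
       reactions = reactions, transporters = transp)
}

#' Plant a connected high-signal module and draw p-values
#'
#' Chooses a connected subgraph of `module_size` nodes by random walk
#' (restarting until the requested size is reached), assigns its nodes
#' signal p-values ~ Beta(a_signal, 1) — concentrated near zero for
#' a_signal < 1 — and gives every other measured node a noise p-value
#' ~ Uniform(0, 1). Planted nodes are always measured; further measured
#' nodes are sampled to reach `measured_fraction` of the network.
#'
#' @param net igraph network.
#' @param module_size Planted module size.
#' @param a_signal Beta shape of the signal component (< 1).
#' @param measured_fraction Fraction of nodes carrying a measurement.
#' @param seed Optional integer seed.
#' @return List: `p_table` (tibble node/metabolite/p_value/planted),
#'   `truth` (list with `planted_module_nodes`, parameters).
#' @export
plant_module_and_pvalues <- function(net, module_size = 12L, a_signal = 0.2,
                                     measured_fraction = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- igraph::vcount(net)
  if (module_size >= n) {
    abort("module_size must be smaller than the network",
          class = "metamodule_config_error")
  }
  planted <- random_connected_subset(net, module_size)
  n_measured <- max(module_size, round(measured_fraction * n))
  keys <- igraph::V(net)$name
  others <- sample(setdiff(keys, planted), n_measured - length(planted))
  measured <- c(planted, others)
  p <- c(rbeta(length(planted), a_signal, 1), runif(length(others)))
  p <- pmax(p, 1e-12)
  p_table <- tibble::tibble(
    node = measured,
    metabolite = igraph::V(net)$metabolite[match(measured, keys)],
    p_value = p,
    planted = measured %in% planted)
  truth <- list(planted_module_nodes = sort(planted),
                a_signal = a_signal, module_size = module_size,
                measured_fraction = measured_fraction)
  list(p_table = p_table, truth = truth)
}

random_connected_subset <- function(net, size, max_restarts = 200L) {
  keys <- igraph::V(net)$name
  adj <- igraph::as_adj_list(net, mode = "all")
  for (r in seq_len(max_restarts)) {
    cur <- sample.int(igraph::vcount(net), 1)
    chosen <- cur
    while (length(chosen) < size) {
      frontier <- setdiff(unique(unlist(adj[chosen])), chosen)
      if (length(frontier) == 0) break
      chosen <- c(chosen, frontier[sample.int(length(frontier), 1)])
    }
    if (length(chosen) == size) return(keys[chosen])
  }
  abort(sprintf("no connected subgraph of size %d found", size),
        class = "metamodule_data_error")
}

#' Generate paired abundances with planted shifts and correlated blocks
#'
#' Baseline (pre) intensities are log-normal per metabolite and
#' individual. Fractional change is effect + block factor + noise: each
#' correlation block shares a per-individual latent factor (weight
#' `block_weight`) so its members' changes correlate across individuals,
#' emulating co-transported metabolite clusters. Post = pre * (1 + change),
#' with change truncated below -0.95 to keep intensities positive.
#'
#' @param metabolites Character vector of metabolite ids.
#' @param n_individuals Number of paired individuals (default 25).
#' @param effects Named numeric vector of planted fractional shifts
#'   (metabolites absent default to 0).
#' @param blocks List of lists with `members` and `weight`.
#' @param meanlog,sdlog Baseline log-normal parameters.
#' @param noise_sd Independent change noise SD.
#' @param missing_rate Fraction of cells set missing at random.
#' @param seed Optional integer seed.
#' @return Long paired abundance tibble.
#' @export
generate_abundances <- function(metabolites, n_individuals = 25L,
                                effects = numeric(), blocks = list(),
                                meanlog = log(1e5), sdlog = 0.5,
                                noise_sd = 0.1, missing_rate = 0,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eff <- setNames(rep(0, length(metabolites)), metabolites)
  eff[intersect(names(effects), metabolites)] <-
    effects[intersect(names(effects), metabolites)]
  block_w <- setNames(rep(0, length(metabolites)), metabolites)
  block_id <- setNames(rep(NA_integer_, length(metabolites)), metabolites)
  for (b in seq_along(blocks)) {
    mem <- intersect(blocks[[b]]$members, metabolites)
    block_w[mem] <- blocks[[b]]$weight
    block_id[mem] <- b
  }
  z <- matrix(rnorm(length(blocks) * n_individuals),
              nrow = max(1, length(blocks)))
  inds <- sprintf("S%02d", seq_len(n_individuals))
  grid <- tidyr::expand_grid(metabolite = metabolites, individual = inds)
  grid |>
    dplyr::mutate(
      pre = rlnorm(dplyr::n(), meanlog, sdlog),
      fc = {
        i <- match(.data$individual, inds)
        m <- .data$metabolite
        latent <- ifelse(is.na(block_id[m]), 0,
                         z[cbind(pmax(block_id[m], 1), i)] * block_w[m])
        pmax(eff[m] + latent + rnorm(dplyr::n(), 0, noise_sd), -0.95)
      },
      post = .data$pre * (1 + .data$fc)) |>
    dplyr::mutate(pre = ifelse(runif(dplyr::n()) < missing_rate, NA, .data$pre),
                  post = ifelse(runif(dplyr::n()) < missing_rate, NA, .data$post)) |>
    dplyr::select("metabolite", "individual", "pre", "post")
}

#' Generate set collections and tissue activity tables with planted truth
#'
#' One set holds exactly the planted module members (the enriched set);
#' decoy sets are random draws from the universe. Tissue activity scores
#' are random integers in \[-2, 2\]; one planted tissue gets +1 added on
#' the planted members (clipped at +2).
#'
#' @param universe Character vector of node ids.
#' @param planted_members Node ids of the planted module.
#' @param n_decoy_sets Number of decoy sets.
#' @param n_tissues Number of tissues (default 10).
#' @param seed Optional integer seed.
#' @return List: `sets` (GMT tibble), `tissues` (tibble
#'   node/tissue/score), `planted_set_id`, `planted_tissue`.
#' @export
generate_sets_and_tissues <- function(universe, planted_members,
                                      n_decoy_sets = 20L, n_tissues = 10L,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  decoys <- purrr::map(seq_len(n_decoy_sets), function(i) {
    sample(universe, sample(5:min(15, length(universe)), 1))
  })
  sets <- tibble::tibble(
    set_id = c("SET_PLANTED", sprintf("SET_D%03d", seq_len(n_decoy_sets))),
    description = c("planted enriched set", rep("decoy set", n_decoy_sets)),
    members = c(list(planted_members), decoys)) |>
    dplyr::mutate(size = purrr::map_int(.data$members, length))
  tissues <- sprintf("TIS%02d", seq_len(n_tissues))
  planted_tissue <- tissues[1]
  # most node/tissue activity calls in practice are ambiguous (score 0);
  # confident calls (+-2) are rare
  tab <- tidyr::expand_grid(node = universe, tissue = tissues) |>
    dplyr::mutate(score = sample(-2:2, dplyr::n(), replace = TRUE,
                                 prob = c(0.05, 0.15, 0.60, 0.15, 0.05)),
                  score = pmin(.data$score +
                                 (.data$tissue == planted_tissue &
                                    .data$node %in% planted_members), 2))
  list(sets = sets, tissues = tab,
       planted_set_id = "SET_PLANTED", planted_tissue = planted_tissue)
}

#' Simulate a complete study input bundle on disk
#'
#' Generates a network, planted module, paired abundances, set
#' collection and tissue table, and writes them in the package's file
#' formats together with a JSON ground-truth file.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_nodes,module_size,a_signal,measured_fraction,n_individuals
#'   Generator parameters (see the individual generators).
#' @param effect Planted fractional shift applied to planted metabolites.
#' @param topology,edge_param,twin_fraction Network parameters.
#' @param seed Integer seed controlling the whole bundle.
#' @return Invisibly, a list of file paths plus the `truth` list.
#' @export
simulate_study <- function(out_dir, n_nodes = 200L, module_size = 12L,
                           a_signal = 0.2, measured_fraction = 0.3,
                           n_individuals = 25L, effect = -0.3,
                           topology = "erdos_renyi", edge_param = 0.02,
                           twin_fraction = 0.1, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  gen <- generate_network(n_nodes, topology, edge_param, twin_fraction)
  plant <- plant_module_and_pvalues(gen$network, module_size, a_signal,
                                    measured_fraction)
  meas_mets <- unique(plant$p_table$metabolite)
  planted_mets <- unique(plant$p_table$metabolite[plant$p_table$planted])
  abund <- generate_abundances(
    meas_mets, n_individuals,
    effects = setNames(rep(effect, length(planted_mets)), planted_mets),
    blocks = list(list(members = planted_mets, weight = 0.15)))
  st <- generate_sets_and_tissues(igraph::V(gen$network)$name,
                                  plant$truth$planted_module_nodes)
  paths <- list(
    reactions = file.path(out_dir, "reactions.tsv"),
    abundances = file.path(out_dir, "abundances.csv"),
    sets = file.path(out_dir, "sets.gmt"),
    tissues = file.path(out_dir, "tissues.tsv"),
    truth_path = file.path(out_dir, "truth.json"))
  write_reaction_table(gen$reactions, paths$reactions)
  write_abundance_matrix(abund, paths$abundances)
  write_set_gmt(st$sets, paths$sets)
  readr::write_tsv(st$tissues, paths$tissues, progress = FALSE)
  truth <- c(plant$truth,
             list(planted_metabolites = planted_mets,
                  planted_set_id = st$planted_set_id,
                  planted_tissue = st$planted_tissue,
                  effect = effect, seed = seed))
  jsonlite::write_json(truth, paths$truth_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, list(truth = truth)))
}
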