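#' Default run configuration
#'
#' All thresholds and sizes steering a full pipeline run, in one list:
#' `fdr_score` (FDR behind the score threshold tau, 0.01), `q_threshold`
#' (changed-metabolite FDR, 0.05), `frequency_threshold` (AMG cutoff,
#' 0.20), `max_path_len` (bridge filter, 3), `n_replicates` /
#' `n_permutations` (100), `n_resamples` (1000), `n_ordered_resamples`
#' (200; the rank-scan null is quadratic in list length), `min_fraction_measured`
#' (0.5), `placements`, `linkage`, PCA options and the base `seed`.
#'
#' @return Named list of defaults.
#' @export
default_run_config <- function() {
  list(
    fdr_score = 0.01, q_threshold = 0.05, frequency_threshold = 0.20,
    max_path_len = 3L, n_replicates = 100L, n_permutations = 100L,
    n_resamples = 1000L, n_ordered_resamples = 200L,
    min_fraction_measured = 0.5,
    placements = c("extracellular", "cytoplasmic"),
    linkage = "complete", pca_center = TRUE, pca_scale = FALSE,
    solver_mode = "exact", seed = 1L,
    promiscuous = promiscuous_metabolites,
    exempt_reactions = character(),
    contaminants = character(), always_include = character(),
    ambiguity_groups = list())
}

#' Read and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration file and merges it over
#' [default_run_config()]. Rates must lie in (0, 1) and counts be >= 1.
#'
#' @param path YAML/JSON file; keys as in [default_run_config()] plus
#'   input paths (`reactions`, `abundances`, `sets`, `tissues`) and
#'   `out_dir`.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config not found: %s", path), class = "metamodule_config_error")
  }
  user <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  cfg <- modifyList(default_run_config(), user)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  rates <- c("fdr_score", "q_threshold", "frequency_threshold",
             "min_fraction_measured")
  for (r in rates) {
    if (!is.numeric(cfg[[r]]) || cfg[[r]] <= 0 || cfg[[r]] >= 1) {
      abort(sprintf("config rate '%s' must be in (0, 1)", r),
            class = "metamodule_config_error")
    }
  }
  counts <- c("max_path_len", "n_replicates", "n_permutations", "n_resamples")
  for (k in counts) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 1) {
      abort(sprintf("config count '%s' must be >= 1", k),
            class = "metamodule_config_error")
    }
  }
  cfg
}

#' Run the full active-module pipeline
#'
#' Stages: platform filtering, paired Wilcoxon change statistics and
#' q-values, beta-uniform mixture fit with FDR threshold, network build
#' and bridge filtering for each score placement (EMRN/CMRN), replicated
#' module search with randomized imputation, AMG aggregation, permutation
#' significance, pathway / ordered / tissue enrichment, and correlation
#' clustering plus PCA of the significantly changed metabolites. Results
#' and a manifest (parameters, seed, per-file checksums) are written to
#' `out_dir`.
#'
#' @param reactions,abundances,sets,tissues Input tibbles (as returned by
#'   the package readers) or file paths.
#' @param out_dir Output directory.
#' @param config Configuration list (see [default_run_config()]).
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(reactions, abundances, sets = NULL, tissues = NULL,
                         out_dir, config = default_run_config()) {
  config <- validate_run_config(modifyList(default_run_config(), config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(reactions)) reactions <- read_reaction_table(reactions)
  if (is.character(abundances)) abundances <- read_abundance_matrix(abundances)
  if (is.character(sets)) sets <- read_set_gmt(sets)
  if (is.character(tissues)) tissues <- read_tissue_table(tissues)

  full_net <- build_mrn(reactions, promiscuous = config$promiscuous,
                        exempt_reactions = config$exempt_reactions)
  net_mets <- unique(igraph::V(full_net)$metabolite)

  filtered <- apply_platform_filters(abundances, net_mets,
                                     config$contaminants,
                                     config$min_fraction_measured)
  change <- wilcoxon_change(filtered) |>
    dplyr::mutate(q_value = compute_qvalues(.data$p_value))
  write_results(change, file.path(out_dir, "change_table.tsv"))

  fit <- fit_bum(change$p_value) |> set_fdr_threshold(config$fdr_score)

  per_placement <- purrr::map(config$placements, function(pl) {
    net <- assign_measured_compartment(full_net, change$metabolite, pl)
    net <- filter_to_measured(net, config$max_path_len)
    net <- assign_scores(net, change, fit)
    set.seed(config$seed)
    sols <- run_replicates(net, fit, n_replicates = config$n_replicates,
                           base_seed = config$seed, mode = config$solver_mode,
                           ambiguity_groups =
                             if (length(config$ambiguity_groups) > 0)
                               config$ambiguity_groups else NULL)
    amg <- build_amg(sols, config$frequency_threshold)
    null_scores <- permute_and_solve(net, fit,
                                     n_permutations = config$n_permutations,
                                     base_seed = config$seed + 10000L,
                                     mode = config$solver_mode)
    p_sig <- compare_score_distributions(
      purrr::map_dbl(sols, "total_score"), null_scores)
    write_results(tidy(amg), file.path(out_dir, sprintf("amg_%s.tsv", pl)))

    enr <- ordered <- tissue <- NULL
    universe <- igraph::V(net)$name
    meas_nodes <- igraph::V(net)$name[igraph::V(net)$measured]
    usets <- NULL
    if (!is.null(sets)) {
      usets <- sets |>
        dplyr::mutate(members = purrr::map(.data$members, intersect, y = universe)) |>
        dplyr::filter(purrr::map_int(.data$members, length) >= 3)
    }
    if (!is.null(usets) && length(amg$selected) > 0) {
      set.seed(config$seed + 20000L)
      enr <- hypergeom_enrich(amg$selected, usets, universe) |>
        adjust_by_resampling(usets, universe, amg$selected,
                             measured = meas_nodes, match_composition = TRUE,
                             n_resamples = config$n_resamples)
      write_results(enr, file.path(out_dir, sprintf("enrichment_%s.tsv", pl)))
    }
    if (!is.null(usets)) {
      # changed metabolites ranked by magnitude of change, as measured nodes
      nodes_tab <- mrn_nodes(net)
      ranked_mets <- change |>
        dplyr::filter(!is.na(.data$q_value),
                      .data$q_value < config$q_threshold) |>
        dplyr::arrange(dplyr::desc(abs(.data$fractional_change)))
      ranked_nodes <- nodes_tab$node[nodes_tab$measured][
        match(ranked_mets$metabolite,
              nodes_tab$metabolite[nodes_tab$measured])]
      ranked_nodes <- ranked_nodes[!is.na(ranked_nodes)]
      if (length(ranked_nodes) >= 1) {
        set.seed(config$seed + 40000L)
        ordered <- ordered_enrich(ranked_nodes, usets, universe,
                                  n_resamples = config$n_ordered_resamples)
        write_results(ordered,
                      file.path(out_dir, sprintf("ordered_enrichment_%s.tsv", pl)))
      }
    }
    if (!is.null(tissues) && length(amg$selected) > 0) {
      set.seed(config$seed + 30000L)
      tissue <- tissue_enrich(amg$selected, tissues, universe,
                              measured = meas_nodes,
                              n_resamples = config$n_resamples)
      write_results(tissue, file.path(out_dir, sprintf("tissue_%s.tsv", pl)))
    }
    list(placement = pl, network = net, solutions = sols, amg = amg,
         null_scores = null_scores, significance_p = p_sig,
         enrichment = enr, ordered_enrichment = ordered, tissue = tissue)
  })
  names(per_placement) <- config$placements

  cm <- fractional_change_matrix(filtered, change, config$q_threshold,
                                 config$always_include)
  clust <- pca <- NULL
  if (nrow(cm) >= 3) {
    d <- spearman_dissimilarity(cm)
    clust <- hierarchical_cluster(d, config$linkage)
    pca <- pca_changes(cm, center = config$pca_center,
                       scale. = config$pca_scale)
    write_results(tidy(pca), file.path(out_dir, "pca_loadings.tsv"))
    write_results(glance(pca), file.path(out_dir, "pca_variance.tsv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("metamodule")),
    seed = config$seed,
    parameters = config[c("fdr_score", "q_threshold", "frequency_threshold",
                          "max_path_len", "n_replicates", "n_permutations",
                          "n_resamples", "min_fraction_measured", "linkage")],
    bum_fit = list(pi = fit$pi, a = fit$a, tau = fit$tau),
    significance = purrr::map(per_placement, "significance_p"),
    checksums = as.list(tools::md5sum(list.files(out_dir, full.names = TRUE,
                                                 pattern = "\\.tsv$"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(change = change, fit = fit, placements = per_placement,
                 change_matrix = cm, clustering = clust, pca = pca,
                 manifest = manifest))
}
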