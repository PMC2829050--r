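#' Platform-level metabolite filtering
#'
#' Removes metabolites that cannot inform the network analysis: (1) not in
#' the network metabolite universe; (2) confounded by a potential
#' contaminant; (3) measured (paired pre AND post present) in fewer than
#' `min_fraction_measured` of individuals.
#'
#' @param abundances Long paired tibble (see [read_abundance_matrix()]).
#' @param network_metabolites Character vector: metabolite universe of the
#'   reaction network.
#' @param contaminant_flags Character vector of contaminant-confounded
#'   metabolite ids.
#' @param min_fraction_measured Minimum fraction of individuals with a
#'   complete pre/post pair (default 0.5).
#' @return The filtered abundance tibble, with a `removal_log` attribute
#'   (tibble metabolite/rule) recording each removal.
#' @export
apply_platform_filters <- function(abundances, network_metabolites,
                                   contaminant_flags = character(),
                                   min_fraction_measured = 0.5) {
  coverage <- abundances |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::summarise(frac = mean(!is.na(.data$pre) & !is.na(.data$post)),
                     .groups = "drop")
  log <- dplyr::bind_rows(
    coverage |> dplyr::filter(!.data$metabolite %in% network_metabolites) |>
      dplyr::transmute(.data$metabolite, rule = "not_in_network"),
    coverage |> dplyr::filter(.data$metabolite %in% contaminant_flags) |>
      dplyr::transmute(.data$metabolite, rule = "contaminant"),
    coverage |> dplyr::filter(.data$frac < min_fraction_measured) |>
      dplyr::transmute(.data$metabolite, rule = "low_coverage"))
  out <- abundances |> dplyr::filter(!.data$metabolite %in% log$metabolite)
  if (nrow(out) == 0) warn("platform filters removed every metabolite")
  attr(out, "removal_log") <- log
  out
}

#' Resolve chromatographically ambiguous peaks
#'
#' Some peaks cannot be attributed to a single metabolite (e.g.
#' leucine/isoleucine). Each ambiguity group's intensities are assigned to
#' exactly one uniformly chosen candidate; the other candidates are absent
#' in that draw. Re-drawn independently in every search replicate.
#'
#' @param abundances Long paired tibble where each group's shared peak is
#'   present under every candidate metabolite id (identical rows).
#' @param groups List of character vectors, each the candidate ids of one
#'   group (>= 2 candidates).
#' @return Abundance tibble with one candidate retained per group, plus a
#'   `chosen` attribute naming the retained candidate per group.
#' @export
resolve_ambiguity <- function(abundances, groups) {
  universe <- unique(abundances$metabolite)
  chosen <- purrr::map_chr(groups, function(g) {
    stopifnot(length(g) >= 2)
    miss <- setdiff(g, universe)
    if (length(miss) > 0) {
      abort(sprintf("ambiguity candidate(s) not in abundance table: %s",
                    paste(miss, collapse = ", ")),
            class = "metamodule_data_error")
    }
    g[sample.int(length(g), 1L)]
  })
  drop <- setdiff(unlist(groups), chosen)
  out <- abundances |> dplyr::filter(!.data$metabolite %in% drop)
  attr(out, "chosen") <- chosen
  out
}

#' Paired change statistics per metabolite
#'
#' For each metabolite, per-individual fractional change
#' (post - pre) / pre is computed over complete pairs; the summary change
#' is the median fractional change and the p-value a two-sided one-sample
#' Wilcoxon signed-rank test of those changes against zero (exact null for
#' n <= 25 pairs, normal approximation with continuity correction beyond;
#' zero changes are dropped before ranking, ties midranked).
#'
#' @param abundances Long paired tibble.
#' @param exact_max Largest n for which the exact null is requested.
#' @return A change table: `metabolite`, `fractional_change`, `p_value`,
#'   `n_pairs`, `measured`.
#' @export
wilcoxon_change <- function(abundances, exact_max = 25L) {
  abundances |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::summarise(stats = list({
      ok <- !is.na(.data$pre) & !is.na(.data$post) & .data$pre != 0
      d <- (.data$post[ok] - .data$pre[ok]) / .data$pre[ok]
      n <- length(d)
      if (n == 0) {
        list(fc = NA_real_, p = NA_real_, n = 0L)
      } else if (all(d == 0)) {
        list(fc = 0, p = 1, n = n)
      } else {
        p <- suppressWarnings(
          wilcox.test(d, mu = 0, alternative = "two.sided",
                      exact = n <= exact_max, correct = TRUE)$p.value)
        list(fc = median(d), p = p, n = n)
      }
    }), .groups = "drop") |>
    dplyr::mutate(fractional_change = purrr::map_dbl(.data$stats, "fc"),
                  p_value = purrr::map_dbl(.data$stats, "p"),
                  n_pairs = purrr::map_int(.data$stats, "n"),
                  measured = .data$n_pairs >= 1L) |>
    dplyr::select(-"stats")
}

#' Storey q-values with smoother pi0 estimation
#'
#' Estimates the null proportion pi0 by the smoother method — pi0(lambda)
#' = #\{p > lambda\} / (m (1 - lambda)) over lambda = 0.05, 0.10, ..., 0.95,
#' smoothed with a cubic smoothing spline (df = 3) and read off at the
#' largest lambda, clipped to (0, 1] — then computes
#' q(i) = min over p(j) >= p(i) of pi0 m p(j) / rank(j), monotonized and
#' clipped to \[0, 1\].
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same order as input.
#' @export
compute_qvalues <- function(p_values) {
  m <- length(p_values)
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must be in [0, 1] and non-missing",
          class = "metamodule_data_error")
  }
  if (m < 2) return(p_values)
  lambda <- seq(0.05, 0.95, by = 0.05)
  pi0_lambda <- purrr::map_dbl(lambda, ~ mean(p_values > .x) / (1 - .x))
  pi0 <- if (length(unique(p_values)) < 4 || all(pi0_lambda == 0)) {
    max(min(pi0_lambda[length(pi0_lambda)], 1), .Machine$double.eps)
  } else {
    fit <- smooth.spline(lambda, pi0_lambda, df = 3)
    max(min(predict(fit, x = max(lambda))$y, 1), .Machine$double.eps)
  }
  ord <- order(p_values, decreasing = TRUE)
  q <- pi0 * m * p_values[ord] / rank(p_values, ties.method = "max")[ord]
  q <- cummin(q)
  pmin(q[order(ord)], 1)
}
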