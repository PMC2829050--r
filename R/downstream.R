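#' Per-individual fractional change matrix
#'
#' Spreads paired abundances into a metabolite-by-individual matrix of
#' fractional change (post - pre) / pre, with NA where either member of
#' the pair is missing. Optionally restricted to significantly changed
#' metabolites (q below a cutoff) plus an always-include list.
#'
#' @param abundances Long paired tibble.
#' @param change Optional change table with `q_value` per metabolite.
#' @param q_threshold FDR cutoff (default 0.05).
#' @param always_include Metabolite ids kept regardless of q.
#' @return Numeric matrix, metabolite rows, individual columns.
#' @export
fractional_change_matrix <- function(abundances, change = NULL,
                                     q_threshold = 0.05,
                                     always_include = character()) {
  keep <- unique(abundances$metabolite)
  if (!is.null(change)) {
    sig <- change$metabolite[!is.na(change$q_value) & change$q_value < q_threshold]
    keep <- intersect(keep, union(sig, always_include))
  }
  wide <- abundances |>
    dplyr::filter(.data$metabolite %in% keep) |>
    dplyr::mutate(fc = dplyr::if_else(is.na(.data$pre) | is.na(.data$post) |
                                        .data$pre == 0,
                                      NA_real_,
                                      (.data$post - .data$pre) / .data$pre)) |>
    dplyr::select("metabolite", "individual", "fc") |>
    tidyr::pivot_wider(names_from = "individual", values_from = "fc") |>
    dplyr::arrange(.data$metabolite)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$metabolite
  m
}

#' Spearman dissimilarity between metabolite change profiles
#'
#' d(i, j) = 1 - |rho(i, j)| with rho the Spearman rank correlation of
#' the two metabolites' fractional changes across individuals
#' (pairwise-complete). The absolute value groups co-regulated
#' metabolites regardless of direction. Constant rows have undefined
#' correlation; their pair distances are set to 1 with a warning.
#'
#' @param m Metabolite-by-individual change matrix.
#' @return Symmetric dissimilarity matrix in \[0, 1\], zero diagonal.
#' @export
spearman_dissimilarity <- function(m) {
  rho <- suppressWarnings(
    cor(t(m), method = "spearman", use = "pairwise.complete.obs"))
  if (any(is.na(rho))) {
    warn("undefined correlations (constant rows or too few pairs) set to distance 1")
    rho[is.na(rho)] <- 0
  }
  d <- 1 - abs(rho)
  diag(d) <- 0
  d
}

#' Hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering with complete (default) or average linkage.
#' Labels are ordered before clustering so ties break deterministically.
#'
#' @param d Symmetric dissimilarity matrix.
#' @param linkage `"complete"` or `"average"`.
#' @param k Optional number of flat clusters.
#' @param h Optional cut height for flat clusters.
#' @return List with `dendrogram` (an `hclust`) and, when `k` or `h`
#'   given, `clusters` (named integer vector).
#' @export
hierarchical_cluster <- function(d, linkage = c("complete", "average"),
                                 k = NULL, h = NULL) {
  linkage <- match.arg(linkage)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    abort("dissimilarity matrix must be symmetric",
          class = "metamodule_data_error")
  }
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  if (nrow(d) == 1) {
    hc <- structure(list(merge = matrix(integer(0), 0, 2), height = numeric(0),
                         order = 1L, labels = rownames(d),
                         method = linkage, dist.method = "1 - |spearman rho|"),
                    class = "hclust")
    out <- list(dendrogram = hc)
    if (!is.null(k) || !is.null(h)) out$clusters <- setNames(1L, rownames(d))
    return(out)
  }
  hc <- hclust(as.dist(d), method = linkage)
  out <- list(dendrogram = hc)
  if (!is.null(k) || !is.null(h)) {
    out$clusters <- cutree(hc, k = k, h = h)
  }
  out
}

#' PCA of fractional changes across individuals
#'
#' Individuals are observations and metabolites variables; missing
#' changes are imputed with the per-metabolite median (logged). Centered
#' by default, unscaled by default.
#'
#' @param m Metabolite-by-individual change matrix.
#' @param center,scale. Passed to [stats::prcomp()].
#' @return A `pca_changes` object wrapping the `prcomp` fit with
#'   `variance_fraction` per component and `n_imputed`.
#' @export
pca_changes <- function(m, center = TRUE, scale. = FALSE) {
  x <- t(m)  # individuals x metabolites
  n_imp <- 0L
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) {
      x[miss, j] <- median(x[, j], na.rm = TRUE)
      n_imp <- n_imp + sum(miss)
    }
  }
  if (n_imp > 0) inform(sprintf("imputed %d missing changes with metabolite medians", n_imp))
  fit <- prcomp(x, center = center, scale. = scale.)
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(fit = fit, variance_fraction = vf, n_imputed = n_imp),
            class = "pca_changes")
}

#' @export
print.pca_changes <- function(x, ...) {
  cat(sprintf("PCA of metabolite changes: top-2 components explain %.1f%% of variance\n",
              100 * sum(x$variance_fraction[1:min(2, length(x$variance_fraction))])))
  invisible(x)
}

#' @export
tidy.pca_changes <- function(x, ...) {
  rot <- x$fit$rotation
  tibble::as_tibble(rot, rownames = "metabolite") |>
    tidyr::pivot_longer(-"metabolite", names_to = "component",
                        values_to = "loading")
}

#' @export
glance.pca_changes <- function(x, ...) {
  tibble::tibble(component = paste0("PC", seq_along(x$variance_fraction)),
                 variance_fraction = x$variance_fraction)
}
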