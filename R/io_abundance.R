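#' Read a paired abundance matrix
#'
#' Reads a wide CSV/TSV of metabolite peak intensities measured on each
#' individual before and after a perturbation. The first column is
#' `metabolite`; every individual contributes a `<id>_pre` and `<id>_post`
#' column pair. Empty cells are missing measurements (never zero — zeros
#' would distort signed-rank statistics downstream).
#'
#' @param path CSV or TSV file (delimiter inferred from extension).
#' @return A tibble in long paired form with columns `metabolite`,
#'   `individual`, `pre`, `post`; `NA` marks a missing measurement.
#' @export
read_abundance_matrix <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("abundance file not found: %s", path),
          class = "metamodule_io_error")
  }
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  raw <- reader(path, col_types = readr::cols(
    metabolite = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  if (!"metabolite" %in% names(raw)) {
    abort("abundance table must have a 'metabolite' column",
          class = "metamodule_format_error")
  }
  value_cols <- setdiff(names(raw), "metabolite")
  phase <- stringr::str_match(value_cols, "^(.*)_(pre|post)$")
  if (any(is.na(phase[, 1]))) {
    abort(sprintf("column(s) not of the form <individual>_pre/_post: %s",
                  paste(value_cols[is.na(phase[, 1])], collapse = ", ")),
          class = "metamodule_format_error")
  }
  ind_pre <- sort(phase[phase[, 3] == "pre", 2])
  ind_post <- sort(phase[phase[, 3] == "post", 2])
  if (!identical(ind_pre, ind_post)) {
    odd <- c(setdiff(ind_pre, ind_post), setdiff(ind_post, ind_pre))
    abort(sprintf("unpaired individual(s) (pre without post or vice versa): %s",
                  paste(odd, collapse = ", ")),
          class = "metamodule_pairing_error")
  }
  raw |>
    tidyr::pivot_longer(-"metabolite", names_to = c("individual", "phase"),
                        names_pattern = "^(.*)_(pre|post)$",
                        values_to = "value") |>
    tidyr::pivot_wider(names_from = "phase", values_from = "value") |>
    dplyr::arrange(.data$metabolite, .data$individual)
}

#' Write a paired abundance matrix
#'
#' @param abundances Long paired tibble as from [read_abundance_matrix()].
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_abundance_matrix <- function(abundances, path) {
  wide <- abundances |>
    tidyr::pivot_longer(c("pre", "post"), names_to = "phase", values_to = "value") |>
    dplyr::mutate(col = paste0(.data$individual, "_", .data$phase)) |>
    dplyr::select("metabolite", "col", "value") |>
    tidyr::pivot_wider(names_from = "col", values_from = "value") |>
    dplyr::arrange(.data$metabolite)
  phase_order <- order(sub("_(pre|post)$", "", setdiff(names(wide), "metabolite")),
                       sub("^.*_", "", setdiff(names(wide), "metabolite")) == "post")
  wide <- wide[, c("metabolite", setdiff(names(wide), "metabolite")[phase_order])]
  writer <- if (grepl("\\.tsv$", path)) readr::write_tsv else readr::write_csv
  writer(wide, path, progress = FALSE)
  invisible(path)
}
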