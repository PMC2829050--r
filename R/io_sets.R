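#' Read a GMT set collection
#'
#' GMT dialect: one set per line, `set_id TAB description TAB member1 TAB
#' member2 ...`. Sets with no members are skipped with a warning. When a
#' `universe` is supplied, sets are restained to members present in it and
#' sets falling below `minimum_size` members-in-universe are dropped
#' (enrichment tests need at least a handful of mappable members; the
#' default floor is three).
#'
#' @param path GMT file path.
#' @param universe Optional character vector of node identifiers.
#' @param minimum_size Minimum members-in-universe to retain a set.
#' @return A tibble with columns `set_id`, `description`, `members`
#'   (list-column), `size`.
#' @export
read_set_gmt <- function(path, universe = NULL, minimum_size = 3L) {
  if (!file.exists(path)) {
    abort(sprintf("GMT file not found: %s", path), class = "metamodule_io_error")
  }
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[lines != ""]
  parsed <- purrr::map(lines, ~ stringr::str_split(.x, "\t")[[1]])
  empty <- purrr::map_int(parsed, length) < 3L
  if (any(empty)) {
    warn(sprintf("%d GMT line(s) with no members skipped", sum(empty)))
    parsed <- parsed[!empty]
  }
  sets <- tibble::tibble(
    set_id = purrr::map_chr(parsed, 1),
    description = purrr::map_chr(parsed, 2),
    members = purrr::map(parsed, ~ unique(.x[-(1:2)]))
  )
  if (!is.null(universe)) {
    sets <- sets |>
      dplyr::mutate(members = purrr::map(.data$members, intersect, y = universe)) |>
      dplyr::filter(purrr::map_int(.data$members, length) >= minimum_size)
  }
  sets |> dplyr::mutate(size = purrr::map_int(.data$members, length))
}

#' Write a GMT set collection
#'
#' @param sets Tibble as from [read_set_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_set_gmt <- function(sets, path) {
  lines <- purrr::pmap_chr(
    list(sets$set_id, sets$description, sets$members),
    function(id, desc, mem) paste(c(id, desc, mem), collapse = "\t"))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a tissue activity score table
#'
#' TSV with columns `node`, `tissue`, `score`; scores are integer-like
#' confidence-weighted activity calls in \[-2, +2\] (+ active, - inactive,
#' 0 ambiguous). Pairs not listed are treated as 0 by consumers.
#'
#' @param path TSV file path.
#' @return Tibble `node`, `tissue`, `score`.
#' @export
read_tissue_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("tissue table not found: %s", path), class = "metamodule_io_error")
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(
    node = readr::col_character(), tissue = readr::col_character(),
    score = readr::col_double()), progress = FALSE)
  if (!all(c("node", "tissue", "score") %in% names(tab))) {
    abort("tissue table needs columns node, tissue, score",
          class = "metamodule_format_error")
  }
  if (any(abs(tab$score) > 2)) {
    abort("tissue activity scores must lie in [-2, 2]",
          class = "metamodule_validation_error")
  }
  tab
}

#' Write a results table deterministically
#'
#' Sorts rows by all columns left-to-right and writes TSV, so repeated runs
#' diff bit-exactly.
#'
#' @param df A data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(df, path) {
  df <- dplyr::arrange(df, dplyr::across(dplyr::everything()))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
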