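#' Compartment codes recognised in participant tokens
#'
#' Single-letter cellular location codes used in `met[compartment]` tokens:
#' cytoplasm (c), extracellular (e), mitochondrion (m), lysosome (l),
#' Golgi (g), endoplasmic reticulum (r), peroxisome (x) and nucleus (n).
#' @export
compartment_alphabet <- c("c", "e", "m", "l", "g", "r", "x", "n")

parse_participants <- function(txt, row_id, compartments = compartment_alphabet) {
  tokens <- stringr::str_split(txt, stringr::fixed("+"))[[1]]
  tokens <- stringr::str_trim(tokens)
  tokens <- tokens[tokens != ""]
  if (length(tokens) == 0L) {
    abort(sprintf("row %s: reaction side has no participants", row_id),
          class = "metamodule_format_error")
  }
  m <- stringr::str_match(tokens, "^(.+)\\[([A-Za-z])\\]$")
  bad <- is.na(m[, 1])
  if (any(bad)) {
    abort(sprintf("row %s: malformed participant token(s): %s",
                  row_id, paste(tokens[bad], collapse = ", ")),
          class = "metamodule_format_error")
  }
  unknown <- !(m[, 3] %in% compartments)
  if (any(unknown)) {
    abort(sprintf("row %s: unknown compartment code(s): %s",
                  row_id, paste(unique(m[unknown, 3]), collapse = ", ")),
          class = "metamodule_validation_error")
  }
  tibble::tibble(metabolite = m[, 2], compartment = m[, 3])
}

#' Read a reaction table
#'
#' Parses a tab-separated reaction table into a tibble of reaction records.
#' Expected columns: `reaction_id`, `reactants`, `products`, `catalysts`,
#' `reversible`. Reactants/products are `+`-separated `met[compartment]`
#' tokens; catalysts are `;`-separated enzyme or transporter identifiers
#' (possibly empty); `reversible` is 0/1 or TRUE/FALSE.
#'
#' @param path Path to a TSV file.
#' @param compartments Allowed compartment codes.
#' @return A tibble with one row per reaction and list-columns `reactants`
#'   and `products` (each a tibble of metabolite/compartment pairs) plus a
#'   list-column `catalysts` of character vectors.
#' @export
read_reaction_table <- function(path, compartments = compartment_alphabet) {
  if (!file.exists(path)) {
    abort(sprintf("reaction table not found: %s", path),
          class = "metamodule_io_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("reaction_id", "reactants", "products", "catalysts", "reversible")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    abort(sprintf("reaction table missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "metamodule_format_error")
  }
  dup <- raw$reaction_id[duplicated(raw$reaction_id)]
  if (length(dup) > 0L) {
    abort(sprintf("duplicated reaction_id(s): %s",
                  paste(unique(dup), collapse = ", ")),
          class = "metamodule_validation_error")
  }
  out <- raw |>
    dplyr::mutate(
      reactants = purrr::map2(.data$reactants, .data$reaction_id,
                              parse_participants, compartments = compartments),
      products  = purrr::map2(.data$products, .data$reaction_id,
                              parse_participants, compartments = compartments),
      catalysts = purrr::map(.data$catalysts, function(x) {
        if (is.na(x) || x == "") character(0)
        else stringr::str_trim(stringr::str_split(x, ";")[[1]])
      }),
      reversible = as.logical(as.integer(dplyr::if_else(
        tolower(.data$reversible) %in% c("true", "false"),
        as.character(as.integer(tolower(.data$reversible) == "true")),
        .data$reversible)))
    )
  if (any(is.na(out$reversible))) {
    bad <- out$reaction_id[is.na(out$reversible)]
    abort(sprintf("row %s: reversible must be 0/1 or TRUE/FALSE",
                  paste(bad, collapse = ", ")),
          class = "metamodule_format_error")
  }
  out
}

format_participants <- function(df) {
  paste(sprintf("%s[%s]", df$metabolite, df$compartment), collapse = "+")
}

#' Write a reaction table
#'
#' Inverse of [read_reaction_table()]; rows are written in their given order
#' with a deterministic column layout so round-trips are byte-stable.
#'
#' @param reactions Tibble as returned by [read_reaction_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_reaction_table <- function(reactions, path) {
  flat <- reactions |>
    dplyr::transmute(
      .data$reaction_id,
      reactants = purrr::map_chr(.data$reactants, format_participants),
      products = purrr::map_chr(.data$products, format_participants),
      catalysts = purrr::map_chr(.data$catalysts, paste, collapse = ";"),
      reversible = as.integer(.data$reversible)
    )
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
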