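#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
#' @keywords internal
"_PACKAGE"

#' @export
generics::tidy

#' @export
generics::glance

# read a TSV with '#' comment lines, returning a tibble
read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, ...)
}

write_tsv_quiet <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

# samples-by-features tibble (first column sample_id) -> numeric matrix
table_to_matrix <- function(tbl, id_col = "sample_id") {
  stopifnot(id_col %in% names(tbl))
  m <- as.matrix(tbl[setdiff(names(tbl), id_col)])
  rownames(m) <- tbl[[id_col]]
  storage.mode(m) <- "double"
  m
}

matrix_to_table <- function(m, id_col = "sample_id") {
  tibble::as_tibble(m, rownames = id_col)
}
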