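#' Convert between alphanumeric well labels and row/column indices
#'
#' Standard microtitre labels run "A1" (top-left) to, on a 384-well plate,
#' "P24". Rows are letters, columns numbers; indices are 1-based, so
#' `well_to_indices("A1")` is row 1, column 1. Double-letter rows ("AA1") are
#' accepted for 1536-well formats.
#'
#' @param well Character vector of well labels such as "A1", "P24".
#' @param row,col Integer vectors of 1-based row and column indices.
#' @return `well_to_indices()` returns a tibble with columns `row` and `col`;
#'   `indices_to_well()` returns a character vector of labels.
#' @examples
#' well_to_indices(c("A1", "B3", "P24"))
#' indices_to_well(16, 24)
#' @export
well_to_indices <- function(well) {
  well <- toupper(trimws(as.character(well)))
  m <- regmatches(well, regexec("^([A-Z]{1,2})([0-9]{1,2})$", well))
  bad <- lengths(m) != 3L
  if (any(bad)) {
    abort(paste0("Malformed well label(s): ",
                 paste(unique(well[bad]), collapse = ", ")))
  }
  letters_part <- vapply(m, `[`, character(1), 2L)
  row <- vapply(strsplit(letters_part, ""), function(ch) {
    sum(vapply(ch, function(c1) match(c1, LETTERS), integer(1)) *
          26L^rev(seq_along(ch) - 1L))
  }, numeric(1))
  col <- as.integer(vapply(m, `[`, character(1), 3L))
  if (any(col < 1L)) abort("Well column index must be >= 1.")
  tibble::tibble(row = as.integer(row), col = col)
}

#' @rdname well_to_indices
#' @export
indices_to_well <- function(row, col) {
  row <- as.integer(row)
  col <- as.integer(col)
  if (any(row < 1L | col < 1L, na.rm = TRUE)) {
    abort("Row and column indices are 1-based and must be >= 1.")
  }
  if (any(row > 26L * 27L, na.rm = TRUE)) abort("Row index out of range.")
  lab <- ifelse(row <= 26L, LETTERS[row],
                paste0(LETTERS[(row - 1L) %/% 26L], LETTERS[((row - 1L) %% 26L) + 1L]))
  paste0(lab, col)
}
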