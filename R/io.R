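#' Read a long-format plate table
#'
#' Reads a delimited file with one row per well and assembles plates. The
#' file must contain columns `plate_id`, `cell_line`, `role`, a well
#' position (either a `well` column with labels like "A1", or `row` and
#' `col` index columns) and a measurement: either a precomputed `value`
#' (fluorescence ratio) or a `baseline`/`peak` pair, in which case the
#' signal-to-background ratio `peak / baseline` is computed per well.
#'
#' Empty strings and "NA" in the value columns become missing values and are
#' propagated, never imputed. Duplicate well assignments and unknown
#' `role`/`cell_line` tokens are hard errors.
#'
#' @param path Path to a CSV or TSV file (delimiter sniffed from content).
#' @param index_base Either 1 (default) or 0: the convention used by integer
#'   `row`/`col` columns. Ignored when positions come from well labels.
#' @param n_rows,n_cols Minimum plate shape (default 384-well format).
#' @return A named list of [plate_grid()] objects, one per
#'   `(plate_id, cell_line)` pair.
#' @export
read_plate_table <- function(path, index_base = 1L, n_rows = 16L, n_cols = 24L) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  d <- read_delim_auto(path)
  required <- c("plate_id", "cell_line", "role")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols)) {
    abort(paste0("Plate table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_cl <- !is.na(d$cell_line) & !(d$cell_line %in% CELL_LINES)
  if (any(bad_cl)) {
    abort(paste0("Unknown cell_line token(s): ",
                 paste(unique(d$cell_line[bad_cl]), collapse = ", ")))
  }
  bad_role <- !is.na(d$role) & !(d$role %in% WELL_ROLES)
  if (any(bad_role)) {
    abort(paste0("Unknown role token(s): ",
                 paste(unique(d$role[bad_role]), collapse = ", ")))
  }
  if ("well" %in% names(d)) {
    idx <- well_to_indices(d$well)
    d$row <- idx$row
    d$col <- idx$col
  } else if (all(c("row", "col") %in% names(d))) {
    if (!index_base %in% c(0L, 1L)) abort("index_base must be 0 or 1.")
    d$row <- as.integer(d$row) + (1L - as.integer(index_base))
    d$col <- as.integer(d$col) + (1L - as.integer(index_base))
  } else {
    abort("Plate table needs either a 'well' column or 'row' and 'col' columns.")
  }
  if (!"value" %in% names(d)) {
    if (!all(c("baseline", "peak") %in% names(d))) {
      abort("Plate table needs a 'value' column or 'baseline' and 'peak' columns.")
    }
    d$value <- compute_ratio(d$baseline, d$peak)
  }
  as_plate_grids(d, n_rows = n_rows, n_cols = n_cols)
}

#' Read a compound annotation table
#'
#' Reads a tab- or comma-separated compound library table keyed by
#' `compound_id`, with optional columns `name`, `pubchem_cid`, `drug_class`,
#' `approval_status` and `smiles`. When a `smiles` column is present each
#' structure is checked for parseability; records with an unparseable SMILES
#' are kept with `smiles` set to `NA` and a warning naming the compound.
#'
#' @param path Path to a delimited file with a header.
#' @param validate_smiles Check SMILES parseability (default `TRUE`; needs
#'   OpenBabel via ChemmineOB).
#' @return A tibble of compound records, one per `compound_id`.
#' @export
read_compound_table <- function(path, validate_smiles = TRUE) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  d <- read_delim_auto(path)
  if (!"compound_id" %in% names(d)) {
    abort("Compound table lacks a 'compound_id' column.")
  }
  d$compound_id <- as.character(d$compound_id)
  if (anyDuplicated(d$compound_id)) {
    abort(paste0("Duplicated compound_id(s): ",
                 paste(unique(d$compound_id[duplicated(d$compound_id)]),
                       collapse = ", ")))
  }
  if ("smiles" %in% names(d) && validate_smiles && nrow(d)) {
    ok <- vapply(d$smiles, function(s) is.na(s) || smiles_is_valid(s),
                 logical(1), USE.NAMES = FALSE)
    if (any(!ok)) {
      warn(paste0("Unparseable SMILES dropped for compound(s): ",
                  paste(d$compound_id[!ok], collapse = ", ")))
      d$smiles[!ok] <- NA_character_
    }
  }
  tibble::as_tibble(d)
}

#' The 34 published MRGPRX2-selective hit compounds
#'
#' The annotated hit list from a published paired high-throughput screen of
#' the Johns Hopkins Drug Library against cells expressing wild-type and
#' N62S-mutant MRGPRX2: 34 compounds spanning five major drug classes, each
#' with its aggregated B-score in wild-type (`b_wt`) and mutant (`b_mut`)
#' cells and the printed percent change of B-score (`pct_change`). Within
#' each class, rows are sorted by `b_wt` descending. Ships with the package
#' as a plain-text fixture so the screen arithmetic can be validated without
#' any download.
#'
#' @return A tibble with 34 rows and columns `compound_id`, `name`,
#'   `pubchem_cid`, `drug_class` (five-class grouping), `indication`
#'   (finer printed indication), `approval_status`, `b_wt`, `b_mut`,
#'   `pct_change`.
#' @examples
#' published_hits()
#' @export
published_hits <- function() {
  path <- system.file("extdata", "jhdl_hit_compounds.tsv",
                      package = "mrgscreen", mustWork = TRUE)
  read_compound_table(path, validate_smiles = FALSE)
}

#' Write and re-read screen results
#'
#' `write_results()` writes a per-compound result table as TSV with a
#' deterministic column order; `read_results()` reads it back. The
#' round-trip is lossless at full double precision (shortest round-trip
#' representation).
#'
#' @param results Non-empty data frame of per-compound results.
#' @param path Output path (TSV).
#' @param sort_within_class Sort rows by descending `b_wt` within
#'   `drug_class` (the published hit-table ordering); requires both columns.
#' @return `write_results()` returns `results` (as written) invisibly;
#'   `read_results()` returns a tibble.
#' @export
write_results <- function(results, path, sort_within_class = FALSE) {
  if (!is.data.frame(results) || nrow(results) == 0L) {
    abort("`results` must be a non-empty data frame.")
  }
  lead <- intersect(
    c("compound_id", "drug_class", "b_wt", "b_mut", "delta", "is_hit_wt",
      "differential_call", "pct_change"),
    names(results)
  )
  results <- results[, c(lead, setdiff(names(results), lead)), drop = FALSE]
  if (sort_within_class) {
    if (!all(c("drug_class", "b_wt") %in% names(results))) {
      abort("Sorting within class needs 'drug_class' and 'b_wt' columns.")
    }
    results <- dplyr::arrange(results, .data$drug_class, dplyr::desc(.data$b_wt))
  }
  readr::write_tsv(results, path)
  invisible(tibble::as_tibble(results))
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

# Sniff comma vs tab from the header line.
read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, na = c("", "NA"))
}
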