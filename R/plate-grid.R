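#' Plate grid: one physical screening plate as matrices
#'
#' A `plate_grid` holds one plate of one cell line as aligned
#' `n_rows x n_cols` matrices: the measured fluorescence ratio per well
#' (`values`, `NA` for unmeasured wells), the role of each well (`roles`,
#' one of LIBRARY / NEG_CTRL / POS_CTRL / EMPTY) and the compound occupying
#' it (`compound_ids`, `NA` for wells that carry no compound). The default
#' geometry is the 384-well format (16 rows x 24 columns).
#'
#' Invariants enforced at construction: all three matrices share the plate
#' shape; every LIBRARY well carries a compound id; control and empty wells
#' carry none.
#'
#' @param plate_id Single string identifying the physical plate.
#' @param cell_line One of `"WT"`, `"MUT"`, `"PARENTAL"`.
#' @param values Numeric matrix of well values (fluorescence ratios).
#' @param roles Character matrix of well roles.
#' @param compound_ids Character matrix of compound ids (`NA` where none).
#' @return An object of class `plate_grid`.
#' @seealso [read_plate_table()], [bscore_plates()]
#' @export
plate_grid <- function(plate_id, cell_line, values, roles, compound_ids) {
  plate_id <- as.character(plate_id)
  stopifnot(length(plate_id) == 1L, length(cell_line) == 1L)
  cell_line <- match.arg(as.character(cell_line), CELL_LINES)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  roles <- as.matrix(roles)
  compound_ids <- as.matrix(compound_ids)
  if (!identical(dim(values), dim(roles)) ||
      !identical(dim(values), dim(compound_ids))) {
    abort(sprintf("Plate %s: values/roles/compound_ids shapes differ.", plate_id))
  }
  bad_role <- !is.na(roles) & !(roles %in% WELL_ROLES)
  if (any(bad_role)) {
    abort(sprintf("Plate %s: unknown well role(s): %s", plate_id,
                  paste(unique(roles[bad_role]), collapse = ", ")))
  }
  lib <- !is.na(roles) & roles == "LIBRARY"
  if (any(lib & is.na(compound_ids))) {
    abort(sprintf("Plate %s: LIBRARY well(s) without a compound id.", plate_id))
  }
  nonlib <- !is.na(roles) & roles != "LIBRARY"
  if (any(nonlib & !is.na(compound_ids))) {
    abort(sprintf("Plate %s: control/empty well(s) carry a compound id.", plate_id))
  }
  structure(
    list(plate_id = plate_id, cell_line = cell_line,
         n_rows = nrow(values), n_cols = ncol(values),
         values = values, roles = roles, compound_ids = compound_ids),
    class = "plate_grid"
  )
}

#' @export
print.plate_grid <- function(x, ...) {
  n_lib <- sum(x$roles == "LIBRARY", na.rm = TRUE)
  cat(sprintf("<plate_grid %s (%s), %d x %d, %d library wells, %d missing values>\n",
              x$plate_id, x$cell_line, x$n_rows, x$n_cols, n_lib,
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
#' @method as_tibble plate_grid
#' @rdname plate_grid
#' @param x A `plate_grid`.
#' @param ... Unused.
as_tibble.plate_grid <- function(x, ...) {
  idx <- expand.grid(row = seq_len(x$n_rows), col = seq_len(x$n_cols))
  tibble::tibble(
    plate_id = x$plate_id,
    cell_line = x$cell_line,
    row = as.integer(idx$row),
    col = as.integer(idx$col),
    well = indices_to_well(idx$row, idx$col),
    role = x$roles[cbind(idx$row, idx$col)],
    compound_id = x$compound_ids[cbind(idx$row, idx$col)],
    value = x$values[cbind(idx$row, idx$col)]
  )
}

#' Assemble plate grids from a long table of wells
#'
#' Turns a long table (one row per well, columns `plate_id`, `cell_line`,
#' `row`, `col`, `role`, `compound_id`, `value`) into a list of
#' [plate_grid()] objects, one per `(plate_id, cell_line)` combination.
#' Missing wells stay `NA`. Plate shape defaults to the bounding box of the
#' observed indices, at least `n_rows` x `n_cols`.
#'
#' @param wells Data frame of wells in long format.
#' @param n_rows,n_cols Minimum plate shape (default 384-well geometry).
#' @return Named list of `plate_grid` objects.
#' @export
as_plate_grids <- function(wells, n_rows = 16L, n_cols = 24L) {
  required <- c("plate_id", "cell_line", "row", "col", "role", "value")
  missing_cols <- setdiff(required, names(wells))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"compound_id" %in% names(wells)) wells$compound_id <- NA_character_
  key <- paste(wells$plate_id, wells$cell_line, sep = "/")
  dup <- duplicated(paste(key, wells$row, wells$col))
  if (any(dup)) {
    w <- which(dup)[1L]
    abort(sprintf("Duplicate well assignment: plate %s well %s.",
                  key[w], indices_to_well(wells$row[w], wells$col[w])))
  }
  lapply(split(wells, key), function(d) {
    nr <- max(n_rows, max(d$row))
    nc <- max(n_cols, max(d$col))
    values <- matrix(NA_real_, nr, nc)
    roles <- matrix(NA_character_, nr, nc)
    ids <- matrix(NA_character_, nr, nc)
    at <- cbind(d$row, d$col)
    values[at] <- d$value
    roles[at] <- as.character(d$role)
    ids[at] <- as.character(d$compound_id)
    plate_grid(d$plate_id[1L], d$cell_line[1L], values, roles, ids)
  })
}
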