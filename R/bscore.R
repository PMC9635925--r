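#' Signal-to-background fluorescence ratio
#'
#' Summarises one well's kinetic calcium-flux trace as the post-injection
#' peak fluorescence divided by the pre-injection baseline. A ratio of 1
#' means no response; values below 1 (peak under baseline) are allowed.
#'
#' @param baseline,peak Non-negative numeric vectors; `baseline` must be
#'   strictly positive.
#' @return Numeric vector `peak / baseline`.
#' @examples
#' compute_ratio(100, 250)
#' @export
compute_ratio <- function(baseline, peak) {
  if (any(!is.na(baseline) & baseline <= 0)) {
    abort("`baseline` must be > 0 to form a signal-to-background ratio.")
  }
  if (any(!is.na(peak) & peak < 0)) abort("`peak` must be >= 0.")
  peak / baseline
}

#' Two-way median polish
#'
#' Decomposes a plate of well values into an overall level, additive row and
#' column effects, and residuals, by alternately sweeping row medians then
#' column medians out of the residuals (Tukey's median polish). This is the
#' positional-artifact model behind the B-score: systematic row/column
#' offsets (dispense order, edge evaporation, reader drift) are absorbed by
#' the effects, leaving compound activity in the residuals.
#'
#' Cells excluded by `mask` (controls, empty wells) and `NA` cells are
#' ignored by every median and receive `NA` residuals. A row or column with
#' no analyzable cell gets effect 0 and is flagged. Even-length medians use
#' the midpoint of the two central values. Iteration stops when the largest
#' absolute change of any effect is `<= tol`.
#'
#' @param values Numeric matrix of well values.
#' @param mask Logical matrix, `TRUE` for analyzable cells. Default: all
#'   non-missing cells.
#' @param max_iter Maximum number of row+column sweep pairs (default 100).
#' @param tol Convergence tolerance on the effects (default 1e-6).
#' @return An object of class `median_polish_fit`: list with `overall`,
#'   `row_effects`, `col_effects`, `residuals`, `n_iterations`, `converged`,
#'   and `empty_rows`/`empty_cols` flags.
#' @examples
#' fit <- median_polish(matrix(c(1, 3, 2, 4), 2, 2))
#' fit$overall
#' fit$row_effects
#' @export
median_polish <- function(values, mask = NULL, max_iter = 100L, tol = 1e-6) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(mask)) mask <- !is.na(values)
  mask <- mask & !is.na(values)
  if (!identical(dim(mask), dim(values))) {
    abort("`mask` must have the same shape as `values`.")
  }
  nr <- nrow(values)
  nc <- ncol(values)
  if (sum(rowSums(mask) > 0L) < 2L || sum(colSums(mask) > 0L) < 2L) {
    abort("Median polish needs at least 2 analyzable rows and 2 columns.")
  }
  z <- values
  z[!mask] <- NA_real_
  overall <- 0
  row_eff <- numeric(nr)
  col_eff <- numeric(nc)
  empty_rows <- rowSums(mask) == 0L
  empty_cols <- colSums(mask) == 0L
  converged <- FALSE
  iter <- 0L
  med0 <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) 0 else median(x)
  }
  for (iter in seq_len(max_iter)) {
    old <- c(overall, row_eff, col_eff)
    # rows first, then columns
    rmed <- apply(z, 1L, med0)
    rmed[empty_rows] <- 0
    z <- z - rmed
    row_eff <- row_eff + rmed
    delta <- med0(col_eff)
    col_eff <- col_eff - delta
    overall <- overall + delta
    cmed <- apply(z, 2L, med0)
    cmed[empty_cols] <- 0
    z <- sweep(z, 2L, cmed)
    col_eff <- col_eff + cmed
    delta <- med0(row_eff)
    row_eff <- row_eff - delta
    overall <- overall + delta
    if (max(abs(c(overall, row_eff, col_eff) - old)) <= tol) {
      converged <- TRUE
      break
    }
  }
  # rows/columns with no analyzable cell carry no information: effect 0
  row_eff[empty_rows] <- 0
  col_eff[empty_cols] <- 0
  structure(
    list(overall = overall, row_effects = row_eff, col_effects = col_eff,
         residuals = z, n_iterations = iter, converged = converged,
         empty_rows = empty_rows, empty_cols = empty_cols),
    class = "median_polish_fit"
  )
}

#' @export
print.median_polish_fit <- function(x, ...) {
  cat(sprintf("<median_polish_fit: %d x %d, overall %.4g, %d iteration(s), %s>\n",
              nrow(x$residuals), ncol(x$residuals), x$overall, x$n_iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
#' @method tidy median_polish_fit
tidy.median_polish_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = "overall", index = NA_integer_, estimate = x$overall),
    tibble::tibble(term = "row", index = seq_along(x$row_effects),
                   estimate = x$row_effects),
    tibble::tibble(term = "column", index = seq_along(x$col_effects),
                   estimate = x$col_effects)
  )
}

#' B-scores from a median-polish fit
#'
#' Scales median-polish residuals by 1.4826 times the median absolute
#' residual over analyzable wells (the MAD, scaled for consistency with the
#' Gaussian SD), giving the B-score: a robust, non-controls-based activity
#' score whose null distribution is comparable across plates. A plate whose
#' residual MAD is 0 is degenerate: all B-scores are set to 0 and
#' `degenerate` is flagged rather than erroring, so pathological (e.g.
#' noiseless synthetic) plates flow through the pipeline.
#'
#' @param fit A [median_polish()] fit.
#' @param plate_id Optional plate identifier carried along.
#' @return An object of class `bscore_plate`: list with `plate_id`,
#'   `b_scores` (matrix, `NA` for masked wells), `mad`, `degenerate`,
#'   `converged`.
#' @export
b_score <- function(fit, plate_id = NA_character_) {
  if (!inherits(fit, "median_polish_fit")) {
    abort("`fit` must come from median_polish().")
  }
  if (!fit$converged) {
    warn(sprintf("Plate %s: median polish hit max_iter without converging.",
                 plate_id))
  }
  r <- fit$residuals
  mad_r <- 1.4826 * median(abs(r), na.rm = TRUE)
  degenerate <- !is.finite(mad_r) || mad_r == 0
  b <- if (degenerate) {
    out <- r
    out[!is.na(out)] <- 0
    out
  } else {
    r / mad_r
  }
  structure(
    list(plate_id = plate_id, b_scores = b,
         mad = if (is.finite(mad_r)) mad_r else NA_real_,
         degenerate = degenerate, converged = fit$converged),
    class = "bscore_plate"
  )
}

#' @export
print.bscore_plate <- function(x, ...) {
  cat(sprintf("<bscore_plate %s: mad %.4g%s>\n", x$plate_id, x$mad,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' B-score normalization of screening plates
#'
#' Runs [median_polish()] and [b_score()] on every plate and returns a long
#' tibble of per-well B-scores. By default control and empty wells are
#' excluded from the polish and from the MAD, so they cannot distort
#' library statistics; they carry `NA` B-scores. Set
#' `include_controls = TRUE` to polish over control wells as well (for
#' sensitivity analysis).
#'
#' @param plates A list of [plate_grid()] objects (e.g. from
#'   [read_plate_table()] or [simulate_screen()]), or a single `plate_grid`.
#' @param include_controls Include NEG_CTRL/POS_CTRL wells in the polish
#'   (default `FALSE`).
#' @param max_iter,tol Passed to [median_polish()].
#' @return A tibble with one row per well: `plate_id`, `cell_line`, `row`,
#'   `col`, `well`, `role`, `compound_id`, `value`, `b_score`, plus
#'   per-plate `mad` and `degenerate`.
#' @export
bscore_plates <- function(plates, include_controls = FALSE,
                          max_iter = 100L, tol = 1e-6) {
  if (inherits(plates, "plate_grid")) plates <- list(plates)
  purrr::map_dfr(plates, function(p) {
    mask <- !is.na(p$roles) & p$roles == "LIBRARY"
    if (include_controls) {
      mask <- mask | (!is.na(p$roles) & p$roles %in% c("NEG_CTRL", "POS_CTRL"))
    }
    fit <- median_polish(p$values, mask = mask, max_iter = max_iter, tol = tol)
    bs <- b_score(fit, plate_id = p$plate_id)
    d <- as_tibble.plate_grid(p)
    d$b_score <- bs$b_scores[cbind(d$row, d$col)]
    d$mad <- bs$mad
    d$degenerate <- bs$degenerate
    d
  })
}

#' Aggregate replicate B-scores per compound
#'
#' Collapses per-well B-scores to one value per compound and cell line: the
#' arithmetic mean of the finite replicate B-scores, with the number of
#' replicates used recorded. Compounds with no finite replicate get `NA`.
#'
#' @param scored Long tibble from [bscore_plates()] (needs `compound_id`,
#'   `cell_line`, `b_score`; control/empty wells are dropped).
#' @return A tibble with columns `compound_id`, `cell_line`, `b` (mean
#'   B-score), `n_replicates`, and `replicates` (list-column of the finite
#'   per-replicate values).
#' @export
aggregate_bscores <- function(scored) {
  scored |>
    dplyr::filter(!is.na(.data$compound_id)) |>
    dplyr::group_by(.data$compound_id, .data$cell_line) |>
    dplyr::summarise(
      b = aggregate_replicates(.data$b_score),
      n_replicates = sum(is.finite(.data$b_score)),
      replicates = list(.data$b_score[is.finite(.data$b_score)]),
      .groups = "drop"
    )
}

#' Paired wild-type / mutant B-score table
#'
#' Pivots the output of [aggregate_bscores()] into one row per compound
#' with the wild-type aggregate in `b_wt` and the mutant aggregate in
#' `b_mut` — the layout consumed by [call_hits()],
#' [differential_select()] and [percent_change()].
#'
#' @param aggregated Tibble from [aggregate_bscores()].
#' @return A tibble with columns `compound_id`, `b_wt`, `b_mut`.
#' @export
paired_bscores <- function(aggregated) {
  needed <- c("compound_id", "cell_line", "b")
  if (!all(needed %in% names(aggregated))) {
    abort("`aggregated` needs columns compound_id, cell_line, b.")
  }
  wide <- tidyr::pivot_wider(aggregated, id_cols = "compound_id",
                             names_from = "cell_line", values_from = "b")
  out <- tibble::tibble(compound_id = wide$compound_id)
  out$b_wt <- if ("WT" %in% names(wide)) wide$WT else NA_real_
  out$b_mut <- if ("MUT" %in% names(wide)) wide$MUT else NA_real_
  out
}

#' @rdname aggregate_bscores
#' @param b Numeric vector of replicate B-scores for one compound.
#' @export
aggregate_replicates <- function(b) {
  b <- b[is.finite(b)]
  if (!length(b)) return(NA_real_)
  mean(b)
}
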