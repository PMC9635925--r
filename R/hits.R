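#' Call screen hits at a multiple of the library SD
#'
#' A compound is an active hit when its aggregated wild-type B-score
#' strictly exceeds `multiplier` times the sample standard deviation of the
#' B-scores of all library compounds (hits included; no trimming). The
#' threshold is recomputed from the data handed in — never stored stale —
#' unless an explicit `threshold` is supplied (e.g. to re-apply a published
#' cut-off to new compounds). A robust variant scales by the MAD of the
#' B-scores instead of the sample SD.
#'
#' @param scores Data frame with columns `compound_id` and the B-score
#'   column named by `b_col`.
#' @param multiplier Threshold multiple of the library SD (default 3).
#' @param b_col Name of the B-score column (default `"b"`).
#' @param threshold Optional fixed threshold overriding the computed one.
#' @param robust Use `1.4826 * MAD` in place of the sample SD.
#' @return A `screen_hits` tibble: the input plus `is_hit`, with the
#'   threshold parameters as attributes (see [glance.screen_hits()]).
#' @examples
#' scores <- tibble::tibble(compound_id = c("a", "b", "c", "d"),
#'                          b = c(0.1, -0.2, 0.3, 9))
#' hits <- call_hits(scores)
#' glance(hits)
#' @export
call_hits <- function(scores, multiplier = 3, b_col = "b", threshold = NULL,
                      robust = FALSE) {
  if (!b_col %in% names(scores)) {
    abort(sprintf("`scores` lacks the B-score column '%s'.", b_col))
  }
  b <- scores[[b_col]]
  if (sum(is.finite(b)) < 2L && is.null(threshold)) {
    abort("Hit calling needs at least 2 finite B-scores.")
  }
  sd_library <- if (robust) {
    1.4826 * median(abs(b - median(b, na.rm = TRUE)), na.rm = TRUE)
  } else {
    sd(b, na.rm = TRUE)
  }
  thr <- threshold %||% (multiplier * sd_library)
  out <- tibble::as_tibble(scores)
  out$is_hit <- !is.na(b) & b > thr
  structure(out,
            class = c("screen_hits", class(out)),
            sd_library = sd_library, multiplier = multiplier,
            threshold = thr, robust = robust)
}

#' @export
#' @method glance screen_hits
#' @rdname call_hits
#' @param x A `screen_hits` tibble.
#' @param ... Unused.
glance.screen_hits <- function(x, ...) {
  tibble::tibble(
    n_compounds = nrow(x),
    n_hits = sum(x$is_hit, na.rm = TRUE),
    hit_rate = sum(x$is_hit, na.rm = TRUE) / nrow(x),
    sd_library = attr(x, "sd_library"),
    multiplier = attr(x, "multiplier"),
    threshold = attr(x, "threshold"),
    robust = attr(x, "robust")
  )
}

#' Summarise hit potency by drug class
#'
#' Per-class count, mean and sample (n-1) SD of wild-type B-scores over a
#' hit list, with percentages relative to the summarised subset. The SD is
#' `NA` for single-member classes.
#'
#' @param hits Data frame with `compound_id` and a B-score column `b_col`.
#' @param compounds Compound annotation table with `compound_id` and
#'   `drug_class` (omit if `hits` already carries `drug_class`).
#' @param b_col Name of the B-score column (default `"b_wt"`).
#' @return A tibble with columns `drug_class`, `n`, `pct`, `mean_b`, `sd_b`,
#'   sorted by descending `n`.
#' @examples
#' class_summary(published_hits())
#' @export
class_summary <- function(hits, compounds = NULL, b_col = "b_wt") {
  if (!is.null(compounds)) {
    unknown <- setdiff(hits$compound_id, compounds$compound_id)
    if (length(unknown)) {
      abort(paste0("Compound id(s) absent from the library: ",
                   paste(unknown, collapse = ", ")))
    }
    hits <- dplyr::left_join(
      hits, dplyr::select(compounds, "compound_id", "drug_class"),
      by = "compound_id"
    )
  }
  if (!"drug_class" %in% names(hits)) {
    abort("No `drug_class` available; supply `compounds`.")
  }
  if (anyNA(hits$drug_class)) {
    abort("Every summarised compound must have a drug_class.")
  }
  b <- rlang::sym(b_col)
  hits |>
    dplyr::group_by(.data$drug_class) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_b = mean(!!b),
      sd_b = ifelse(dplyr::n() >= 2L, sd(!!b), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n), .after = "n") |>
    dplyr::arrange(dplyr::desc(.data$n))
}

#' Percent change of B-score between genotypes
#'
#' `100 * (b_mut - b_wt) / b_wt`: the percentage change of a compound's
#' activity score going from wild-type to mutant cells. -100 means the
#' response is fully lost in the mutant; values below -100 mean the mutant
#' score crossed zero. Undefined (returned as `NA` with a warning) when
#' `b_wt` is 0. Invariant under common positive rescaling of both scores.
#'
#' @param b_wt,b_mut Numeric vectors of aggregated B-scores.
#' @return Numeric vector of percent changes.
#' @examples
#' percent_change(32.17, 16.90)
#' @export
percent_change <- function(b_wt, b_mut) {
  zero <- !is.na(b_wt) & b_wt == 0
  if (any(zero)) {
    warn("percent_change undefined where b_wt == 0; returning NA.")
  }
  out <- 100 * (b_mut - b_wt) / b_wt
  out[zero] <- NA_real_
  out
}

#' Paired differential selection between genotypes
#'
#' Computes the per-compound B-score difference `delta = b_wt - b_mut` and
#' calls a compound differentially POSITIVE when its delta strictly exceeds
#' `mean(delta) + sd(delta)`, NEGATIVE when strictly below
#' `mean(delta) - sd(delta)`, and NONE otherwise. Positive calls are the
#' wild-type-selective compounds — those whose activity collapses in the
#' loss-of-function mutant. Compounds missing either genotype aggregate are
#' excluded from the window and reported via `glance()`.
#'
#' @param paired Data frame with columns `compound_id`, `b_wt`, `b_mut`.
#' @return A `differential_calls` tibble: `compound_id`, `b_wt`, `b_mut`,
#'   `delta`, `differential_call` (factor POSITIVE/NEGATIVE/NONE), with the
#'   window as attributes.
#' @examples
#' d <- tibble::tibble(compound_id = c("a", "b", "c"),
#'                     b_wt = c(20, 0.5, -0.2), b_mut = c(1, 0.4, -0.1))
#' differential_select(d)
#' @export
differential_select <- function(paired) {
  needed <- c("compound_id", "b_wt", "b_mut")
  if (!all(needed %in% names(paired))) {
    abort("`paired` needs columns compound_id, b_wt, b_mut.")
  }
  complete <- is.finite(paired$b_wt) & is.finite(paired$b_mut)
  if (sum(complete) < 2L) {
    abort("Differential selection needs at least 2 complete pairs.")
  }
  delta <- paired$b_wt - paired$b_mut
  mean_delta <- mean(delta[complete])
  sd_delta <- sd(delta[complete])
  upper <- mean_delta + sd_delta
  lower <- mean_delta - sd_delta
  call <- rep(NA_character_, nrow(paired))
  call[complete] <- dplyr::case_when(
    delta[complete] > upper ~ "POSITIVE",
    delta[complete] < lower ~ "NEGATIVE",
    .default = "NONE"
  )
  out <- tibble::as_tibble(paired)
  out$delta <- delta
  out$differential_call <- factor(call, levels = c("POSITIVE", "NEGATIVE", "NONE"))
  structure(out,
            class = c("differential_calls", class(out)),
            mean_delta = mean_delta, sd_delta = sd_delta,
            upper = upper, lower = lower,
            n_excluded = sum(!complete))
}

#' @export
#' @method glance differential_calls
#' @rdname differential_select
#' @param x A `differential_calls` tibble.
#' @param ... Unused.
glance.differential_calls <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x) - attr(x, "n_excluded"),
    n_excluded = attr(x, "n_excluded"),
    mean_delta = attr(x, "mean_delta"),
    sd_delta = attr(x, "sd_delta"),
    upper = attr(x, "upper"),
    lower = attr(x, "lower"),
    n_positive = sum(x$differential_call == "POSITIVE", na.rm = TRUE),
    n_negative = sum(x$differential_call == "NEGATIVE", na.rm = TRUE)
  )
}
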