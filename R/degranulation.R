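#' Percent release of beta-hexosaminidase
#'
#' Degranulation readout for one sample: the enzymatic signal released into
#' the supernatant as a percentage of the total cellular content
#' (supernatant plus cell lysate). Scale-invariant: multiplying both
#' signals by a common positive factor leaves the result unchanged.
#'
#' @param supernatant,lysate Non-negative signal vectors; their sum must be
#'   positive.
#' @return Numeric vector of percentages in [0, 100].
#' @examples
#' percent_release(75, 25)
#' @export
percent_release <- function(supernatant, lysate) {
  if (any(!is.na(supernatant) & supernatant < 0) ||
      any(!is.na(lysate) & lysate < 0)) {
    abort("Signals must be non-negative.")
  }
  total <- supernatant + lysate
  if (any(!is.na(total) & total == 0)) {
    abort("supernatant + lysate must be > 0.")
  }
  100 * supernatant / total
}

#' Two-way ANOVA with Sidak-adjusted genotype contrasts
#'
#' Fixed-effects two-factor ANOVA of percent release on condition,
#' genotype and their interaction, followed by the per-condition genotype
#' contrast (e.g. LAD2 vs MRGPRX2-knockout LAD2 at each drug/concentration)
#' with Sidak correction for the family of conditions:
#' `p_adj = 1 - (1 - p)^m` where `m` is the number of conditions. With a
#' single condition the adjusted p equals the raw p.
#'
#' Degenerate data with zero variance everywhere (all cells identical) are
#' reported as no effect: all F statistics 0 and all p-values 1.
#'
#' @param samples Data frame with columns `condition`, `genotype`,
#'   `percent_release` (and optionally `replicate`). Needs at least 2
#'   conditions x 2 genotypes with n >= 2 per cell; empty cells are an
#'   error naming the missing combinations.
#' @return A `genotype_effect_test` list with `anova` (tibble of F tests)
#'   and `contrasts` (tibble of per-condition genotype differences with
#'   `p_sidak`).
#' @examples
#' d <- simulate_degranulation(
#'   data.frame(condition = rep(c("vehicle", "drug"), each = 2),
#'              genotype = rep(c("LAD2", "KO"), 2),
#'              mean_release = c(5, 5, 60, 6)),
#'   noise_sd = 3, n = 6, seed = 1)
#' genotype_effect_test(d)
#' @export
genotype_effect_test <- function(samples) {
  needed <- c("condition", "genotype", "percent_release")
  if (!all(needed %in% names(samples))) {
    abort("`samples` needs columns condition, genotype, percent_release.")
  }
  d <- tibble::as_tibble(samples)
  d$condition <- factor(d$condition)
  d$genotype <- factor(d$genotype)
  if (nlevels(d$condition) < 2L || nlevels(d$genotype) < 2L) {
    abort("Need at least 2 conditions and 2 genotypes.")
  }
  cells <- dplyr::count(d, .data$condition, .data$genotype, .drop = FALSE)
  if (any(cells$n < 2L)) {
    missing_cells <- cells[cells$n < 2L, ]
    abort(paste0(
      "Cell(s) with fewer than 2 replicates: ",
      paste(sprintf("%s/%s (n=%d)", missing_cells$condition,
                    missing_cells$genotype, missing_cells$n),
            collapse = ", ")))
  }
  m <- nlevels(d$condition)

  if (stats::var(d$percent_release) == 0) {
    # all samples identical: no effects by convention
    anova_tbl <- tibble::tibble(
      term = c("condition", "genotype", "condition:genotype"),
      df = NA_integer_, statistic = 0, p_value = 1
    )
    contrasts_tbl <- tibble::tibble(
      condition = levels(d$condition),
      estimate = 0, se = 0, t_ratio = 0, p_value = 1, p_sidak = 1
    )
  } else {
    fit <- aov(percent_release ~ condition * genotype, data = d)
    a <- summary(fit)[[1]]
    terms <- trimws(rownames(a))
    keep <- terms != "Residuals"
    anova_tbl <- tibble::tibble(
      term = terms[keep],
      df = a[keep, "Df"],
      statistic = a[keep, "F value"],
      p_value = a[keep, "Pr(>F)"]
    )
    emm <- emmeans::emmeans(fit, ~ genotype | condition)
    ctr <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                           adjust = "none"))
    contrasts_tbl <- tibble::tibble(
      condition = as.character(ctr$condition),
      estimate = ctr$estimate, se = ctr$SE, t_ratio = ctr$t.ratio,
      p_value = ctr$p.value,
      p_sidak = 1 - (1 - ctr$p.value)^m
    )
  }
  structure(list(anova = anova_tbl, contrasts = contrasts_tbl,
                 n_conditions = m),
            class = "genotype_effect_test")
}

#' @export
print.genotype_effect_test <- function(x, ...) {
  cat("Two-way ANOVA (condition x genotype)\n")
  print(x$anova)
  cat(sprintf("\nPer-condition genotype contrasts (Sidak, m = %d)\n",
              x$n_conditions))
  print(x$contrasts)
  invisible(x)
}

#' @export
#' @method tidy genotype_effect_test
#' @rdname genotype_effect_test
#' @param x A `genotype_effect_test`.
#' @param ... Unused.
tidy.genotype_effect_test <- function(x, ...) x$contrasts

#' @export
#' @method glance genotype_effect_test
#' @rdname genotype_effect_test
glance.genotype_effect_test <- function(x, ...) {
  g <- x$anova[x$anova$term == "genotype", ]
  tibble::tibble(
    f_genotype = g$statistic, p_genotype = g$p_value,
    n_conditions = x$n_conditions,
    min_p_sidak = min(x$contrasts$p_sidak)
  )
}
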