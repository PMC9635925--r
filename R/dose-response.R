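#' Four-parameter logistic (Hill) dose-response curve
#'
#' The standard 4PL response model in log10 concentration:
#' `bottom + (top - bottom) / (1 + 10^((log_ec50 - x) * hill))`.
#' At `x = log_ec50` the response is the midpoint `(top + bottom) / 2`;
#' with `hill > 0` the curve rises from `bottom` (low concentration) to
#' `top` (high concentration), monotonically in `x` for `hill != 0`.
#'
#' @param x Log10 molar concentration (vectorised).
#' @param bottom,top Lower and upper response asymptotes.
#' @param log_ec50 Log10 molar EC50 (curve midpoint).
#' @param hill Hill slope.
#' @return Numeric vector of responses.
#' @examples
#' four_pl(-4, bottom = 0, top = 100, log_ec50 = -5, hill = 1)
#' @export
four_pl <- function(x, bottom, top, log_ec50, hill) {
  bottom + (top - bottom) / (1 + 10^((log_ec50 - x) * hill))
}

#' Fit a 4PL dose-response curve
#'
#' Least-squares fit of [four_pl()] to replicate dose-response data by
#' Levenberg-Marquardt (via minpack.lm), multi-started over a grid of
#' initial `log_ec50` values spanning the tested concentration range (and
#' both Hill-slope signs) to dodge local minima; the best converged start
#' by residual sum of squares wins. Deterministic given the data. An EC50
#' outside the tested concentration range is weakly identified: expect a
#' large `se_log_ec50` and an `extrapolated` flag rather than a refusal to
#' fit. The
#' standard error of `log_ec50` comes from the fit's curvature
#' (observed-information covariance).
#'
#' Fits are canonicalised so `bottom <= top` (a negative Hill slope flips
#' the asymptote roles). An EC50 outside the tested range is flagged as
#' extrapolated; an essentially flat fit (|hill| tiny or no response span)
#' is flagged degenerate and marked not converged.
#'
#' @param data Data frame of dose-response measurements.
#' @param x,response Column names for log10 molar concentration and
#'   response (defaults `"log10_conc_M"`, `"response"`, matching
#'   [simulate_dose_response()]).
#' @param n_starts Number of `log_ec50` grid starts (default 7).
#' @return An object of class `dose_response_fit` with elements `bottom`,
#'   `top`, `log_ec50`, `hill`, `ec50`, `se_log_ec50`, `rss`, `n_points`,
#'   `converged`, `degenerate`, `extrapolated`, `data`. Methods: `tidy()`,
#'   `glance()`, `predict()`, `autoplot()`.
#' @examples
#' d <- simulate_dose_response(0, 2, -5, 1, noise_sd = 0)
#' fit <- fit_dose_response(d)
#' glance(fit)
#' @export
fit_dose_response <- function(data, x = "log10_conc_M", response = "response",
                              n_starts = 7L) {
  if (!all(c(x, response) %in% names(data))) {
    abort(sprintf("`data` needs columns '%s' and '%s'.", x, response))
  }
  d <- tibble::tibble(x = data[[x]], y = data[[response]])
  d <- d[is.finite(d$x) & is.finite(d$y), ]
  if (length(unique(d$x)) < 4L) {
    abort("4PL fitting needs at least 4 distinct concentrations.")
  }
  rng <- range(d$x)
  span <- diff(range(d$y))
  starts <- tidyr::expand_grid(
    log_ec50 = seq(rng[1], rng[2], length.out = n_starts),
    hill = c(1, -1)
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ four_pl(x, bottom, top, log_ec50, hill),
        data = d,
        start = list(bottom = min(d$y), top = max(d$y),
                     log_ec50 = starts$log_ec50[i], hill = starts$hill[i]),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(
      list(bottom = NA_real_, top = NA_real_, log_ec50 = NA_real_,
           hill = NA_real_, ec50 = NA_real_, se_log_ec50 = NA_real_,
           rss = NA_real_, n_points = nrow(d), converged = FALSE,
           degenerate = TRUE, extrapolated = NA, data = d),
      class = "dose_response_fit"
    ))
  }
  p <- as.list(coef(best$fit))
  # canonical orientation: bottom <= top
  if (p$bottom > p$top) {
    p <- list(bottom = p$top, top = p$bottom,
              log_ec50 = p$log_ec50, hill = -p$hill)
  }
  se <- tryCatch(sqrt(diag(vcov(best$fit)))[["log_ec50"]],
                 error = function(e) NA_real_)
  degenerate <- abs(p$hill) < 1e-3 || (p$top - p$bottom) < 1e-8 * max(1, span)
  structure(
    list(bottom = p$bottom, top = p$top, log_ec50 = p$log_ec50,
         hill = p$hill, ec50 = 10^p$log_ec50, se_log_ec50 = se,
         rss = best$rss, n_points = nrow(d),
         converged = !degenerate, degenerate = degenerate,
         extrapolated = p$log_ec50 < rng[1] || p$log_ec50 > rng[2],
         data = d),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "<dose_response_fit: EC50 %.4g M (log10 %.3f +/- %.3f), hill %.3f, span %.3g-%.3g, %s%s>\n",
    x$ec50, x$log_ec50, x$se_log_ec50, x$hill, x$bottom, x$top,
    if (x$converged) "converged" else "NOT converged",
    if (isTRUE(x$extrapolated)) ", EC50 extrapolated" else ""))
  invisible(x)
}

#' @export
#' @method tidy dose_response_fit
#' @rdname fit_dose_response
#' @param ... Unused.
tidy.dose_response_fit <- function(x, ...) {
  tibble::tibble(
    term = c("bottom", "top", "log_ec50", "hill"),
    estimate = c(x$bottom, x$top, x$log_ec50, x$hill),
    std.error = c(NA_real_, NA_real_, x$se_log_ec50, NA_real_)
  )
}

#' @export
#' @method glance dose_response_fit
#' @rdname fit_dose_response
glance.dose_response_fit <- function(x, ...) {
  tibble::tibble(
    ec50 = x$ec50, log_ec50 = x$log_ec50, se_log_ec50 = x$se_log_ec50,
    hill = x$hill, bottom = x$bottom, top = x$top, rss = x$rss,
    n_points = x$n_points, converged = x$converged,
    degenerate = x$degenerate, extrapolated = x$extrapolated
  )
}

#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else newdata
  four_pl(x, object$bottom, object$top, object$log_ec50, object$hill)
}

#' Compare EC50s between two fitted curves
#'
#' Tests for a potency shift between two independently fitted dose-response
#' curves (e.g. wild-type vs mutant cells) with a z-statistic on the
#' difference of `log_ec50`, using the combined standard errors from the
#' fits' curvature. Also reports the EC50 fold change (second over first).
#' Antisymmetric: swapping the arguments negates `z` and inverts the fold
#' change.
#'
#' @param fit_a,fit_b Converged [fit_dose_response()] objects; by
#'   convention the reference (wild-type) first.
#' @return A one-row tibble: `log_ec50_a`, `log_ec50_b`, `diff_log_ec50`
#'   (b - a), `se_diff`, `z`, `p_value`, `fold_change` (`ec50_b / ec50_a`).
#' @export
compare_ec50 <- function(fit_a, fit_b) {
  if (!inherits(fit_a, "dose_response_fit") ||
      !inherits(fit_b, "dose_response_fit")) {
    abort("Both arguments must come from fit_dose_response().")
  }
  if (!fit_a$converged || !fit_b$converged) {
    abort("Both fits must have converged to compare EC50s.")
  }
  diff <- fit_b$log_ec50 - fit_a$log_ec50
  se <- sqrt(fit_a$se_log_ec50^2 + fit_b$se_log_ec50^2)
  z <- if (is.finite(se) && se > 0) diff / se else {
    if (diff == 0) 0 else sign(diff) * Inf
  }
  tibble::tibble(
    log_ec50_a = fit_a$log_ec50, log_ec50_b = fit_b$log_ec50,
    diff_log_ec50 = diff, se_diff = se, z = z,
    p_value = 2 * pnorm(-abs(z)),
    fold_change = 10^diff
  )
}
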