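test_that("signal-to-background ratio is peak over baseline with guards", {
  expect_equal(compute_ratio(100, 100), 1)
  expect_equal(compute_ratio(100, 250), 2.5)
  expect_equal(compute_ratio(c(100, 200), c(50, 500)), c(0.5, 2.5))
  expect_error(compute_ratio(0, 50), "> 0")
  expect_error(compute_ratio(-1, 50), "> 0")
  expect_error(compute_ratio(10, -5), ">= 0")
})

test_that("median polish reproduces hand-worked decompositions", {
  # constant plate: everything in the overall term
  fit <- median_polish(matrix(7, 4, 5))
  expect_true(fit$converged)
  expect_equal(fit$overall, 7)
  expect_equal(fit$row_effects, rep(0, 4))
  expect_equal(fit$col_effects, rep(0, 5))
  expect_equal(max(abs(fit$residuals)), 0)

  # 2x2 with rows (1,2) and (3,4), worked by hand
  fit <- median_polish(matrix(c(1, 3, 2, 4), 2, 2))
  expect_equal(fit$overall, 2.5)
  expect_equal(fit$row_effects, c(-1, 1))
  expect_equal(fit$col_effects, c(-0.5, 0.5))
  expect_equal(max(abs(fit$residuals)), 0)

  # exact additive model with median-centred effects recovers the effects
  a <- c(-2, 0, 1, 2, -1)   # median 0
  b <- c(-3, 0, 3, 1, -1, 0)  # median 0
  y <- 5 + outer(a, rep(1, 6)) + outer(rep(1, 5), b)
  fit <- median_polish(y)
  expect_equal(fit$overall, 5)
  expect_equal(fit$row_effects, a)
  expect_equal(fit$col_effects, b)
  expect_lt(max(abs(fit$residuals)), 1e-10)
})

test_that("median polish matches an independent alternating-median oracle", {
  set.seed(11)
  for (i in 1:10) {
    nr <- sample(3:6, 1)
    nc <- sample(3:6, 1)
    y <- matrix(rnorm(nr * nc), nr, nc)
    ours <- median_polish(y, tol = 1e-9, max_iter = 500)
    ref <- brute_force_polish(y)
    expect_equal(ours$overall, ref$overall, tolerance = 1e-6)
    expect_equal(ours$row_effects, ref$row, tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(ours$col_effects, ref$col, tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(ours$residuals, ref$residuals, tolerance = 1e-6,
                 ignore_attr = TRUE)
    # reconstruction identity
    recon <- ours$overall + outer(ours$row_effects, rep(1, nc)) +
      outer(rep(1, nr), ours$col_effects) + ours$residuals
    expect_equal(recon, y, tolerance = 1e-6)
  }
})

test_that("median polish agrees with stats::medpolish where the fit is unique", {
  # odd-by-odd matrices: unique cell medians, both implementations settle
  # on the same exact decomposition (even dimensions admit period-2 cycles
  # on which different stopping rules halt at different phases)
  set.seed(12)
  for (dims in list(c(3, 3), c(5, 3), c(3, 5), c(5, 5))) {
    y <- matrix(rnorm(dims[1] * dims[2]), dims[1], dims[2])
    ours <- median_polish(y, tol = 1e-9, max_iter = 500)
    ref <- stats::medpolish(y, eps = 1e-12, maxiter = 500, trace.iter = FALSE)
    expect_equal(ours$residuals, ref$residuals, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(ours$overall, ref$overall, tolerance = 1e-8)
  }
})

test_that("masked and missing cells are ignored and flagged", {
  y <- matrix(rnorm(20), 4, 5)
  mask <- matrix(TRUE, 4, 5)
  mask[2, ] <- FALSE   # whole row masked out
  fit <- median_polish(y, mask = mask)
  expect_true(all(is.na(fit$residuals[2, ])))
  expect_equal(fit$row_effects[2], 0)
  expect_true(fit$empty_rows[2])
  expect_error(median_polish(matrix(1, 1, 5)), "at least 2")
})

test_that("B-scores scale residuals by 1.4826 * median absolute residual", {
  fit <- structure(list(residuals = matrix(c(1, -1, 2, -2), 2, 2),
                        converged = TRUE),
                   class = "median_polish_fit")
  bs <- b_score(fit)
  expect_equal(bs$mad, 1.4826 * 1.5)
  expect_equal(bs$b_scores, fit$residuals / 2.2239)
  expect_false(bs$degenerate)

  # zero residuals: degenerate plate convention, B-scores all 0
  fit0 <- structure(list(residuals = matrix(0, 3, 3), converged = TRUE),
                    class = "median_polish_fit")
  bs0 <- b_score(fit0)
  expect_true(bs0$degenerate)
  expect_equal(max(abs(bs0$b_scores)), 0)
})

test_that("B-scores are invariant to row/column offsets and positive rescaling", {
  set.seed(21)
  y <- matrix(rnorm(16 * 24), 16, 24)
  b0 <- b_score(median_polish(y, tol = 1e-9, max_iter = 500))$b_scores

  shifted <- y
  shifted[5, ] <- shifted[5, ] + 3       # whole row offset
  shifted[, 7] <- shifted[, 7] - 1.5     # whole column offset
  shifted <- shifted + 0.8               # plate-wide offset
  b1 <- b_score(median_polish(shifted, tol = 1e-9, max_iter = 500))$b_scores
  expect_equal(b1, b0, tolerance = 1e-6)

  b2 <- b_score(median_polish(3.7 * y, tol = 1e-9, max_iter = 500))$b_scores
  expect_equal(b2, b0, tolerance = 1e-6)
})

test_that("replicate aggregation is the mean over finite values", {
  expect_equal(aggregate_replicates(c(10, 12, 14)), 12)
  expect_equal(aggregate_replicates(c(10, NA, 14)), 12)
  expect_equal(aggregate_replicates(7), 7)
  expect_true(is.na(aggregate_replicates(c(NA_real_, NA_real_))))

  scored <- tibble::tibble(
    compound_id = c("a", "a", "a", NA),
    cell_line = "WT",
    b_score = c(10, NA, 14, 99)
  )
  agg <- aggregate_bscores(scored)
  expect_equal(agg$b, 12)
  expect_equal(agg$n_replicates, 2L)
})

test_that("controls are excluded from the polish by default", {
  set.seed(31)
  vals <- matrix(rnorm(16 * 24, 1, 0.05), 16, 24)
  roles <- matrix("LIBRARY", 16, 24)
  roles[, 23] <- "NEG_CTRL"
  roles[, 24] <- "POS_CTRL"
  vals[, 24] <- vals[, 24] + 2   # strong positive-control response
  ids <- matrix(NA_character_, 16, 24)
  ids[, 1:22] <- sprintf("c%03d", seq_len(16 * 22))
  p <- plate_grid("P1", "WT", vals, roles, ids)

  scored <- bscore_plates(p)
  expect_true(all(is.na(scored$b_score[scored$role != "LIBRARY"])))
  excl <- scored$b_score[scored$role == "LIBRARY"]

  scored_inc <- bscore_plates(p, include_controls = TRUE)
  expect_true(all(is.finite(scored_inc$b_score[scored_inc$role == "POS_CTRL"])))
  # the hot control column must not leak into library B-scores by default
  expect_lt(abs(median(excl)), 0.5)
})
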