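test_that("screen simulation is reproducible and honours the layout", {
  cfg <- small_config(seed = 5)
  sim1 <- simulate_screen(cfg)
  sim2 <- simulate_screen(cfg)
  expect_identical(sim1$plates, sim2$plates)
  expect_identical(sim1$truth$compounds, sim2$truth$compounds)

  # 704 compounds / 352 per plate = 2 plates x 2 genotypes x 3 replicates
  expect_length(sim1$plates, 12L)
  p <- sim1$plates[[1]]
  expect_equal(sum(p$roles == "LIBRARY"), 352L)
  expect_equal(sum(p$roles == "NEG_CTRL"), 16L)
  expect_equal(sum(p$roles == "POS_CTRL"), 16L)

  # identical compound-to-well assignment across genotypes and replicates
  ids <- lapply(sim1$plates, function(p) p$compound_ids)
  wt1 <- ids[grepl("^P01", names(ids))]
  expect_true(all(vapply(wt1, identical, logical(1), wt1[[1]])))

  # different seed, different values
  sim3 <- simulate_screen(small_config(seed = 6))
  expect_false(identical(sim1$plates[[1]]$values, sim3$plates[[1]]$values))
})

test_that("with all noise off, library wells sit exactly at the baseline", {
  cfg <- screen_config(n_compounds = 352, frac_agonists = 0,
                       row_effect_sd = 0, col_effect_sd = 0, noise_sd = 0,
                       seed = 1)
  sim <- simulate_screen(cfg)
  for (p in sim$plates) {
    lib <- p$values[p$roles == "LIBRARY"]
    expect_equal(lib, rep(1, length(lib)))
    expect_equal(unique(p$values[p$roles == "POS_CTRL"]), 1 + 1.5)
  }
})

test_that("agonist count follows the seeded draw and truth is self-consistent", {
  cfg <- screen_config(n_compounds = 1000, frac_agonists = 0.03, seed = 17)
  tr <- simulate_screen(cfg)$truth$compounds
  n_agonists <- sum(tr$is_agonist)
  # ~30 expected; exact count pinned by re-running the seeded generator
  expect_gt(n_agonists, 10)
  expect_lt(n_agonists, 60)
  tr2 <- simulate_screen(cfg)$truth$compounds
  expect_equal(sum(tr2$is_agonist), n_agonists)

  # mut_effect = wt_effect * attenuation for agonists, 0 otherwise
  expect_equal(tr$mut_effect, tr$wt_effect * tr$attenuation)
  expect_true(all(tr$wt_effect[!tr$is_agonist] == 0))
  expect_true(all(tr$wt_effect[tr$is_agonist] >= 6 * 0.05))
  expect_true(all(tr$attenuation >= 0 & tr$attenuation <= 1))
})

test_that("noise-free inactive screens give all-zero B-scores (degenerate MAD)", {
  cfg <- screen_config(n_compounds = 352, frac_agonists = 0,
                       row_effect_sd = 0.05, col_effect_sd = 0.05,
                       noise_sd = 0, seed = 3)
  sim <- simulate_screen(cfg)
  scored <- bscore_plates(sim$plates)
  lib <- scored[scored$role == "LIBRARY", ]
  expect_true(all(lib$degenerate))
  expect_equal(max(abs(lib$b_score)), 0)
})

test_that("dose-response simulation follows the 4PL mean curve", {
  d <- simulate_dose_response(0, 2, -5, 1, noise_sd = 0)
  expect_equal(nrow(d), 24L)   # 8-point default grid x 3 replicates
  expect_equal(d$response[d$log10_conc_M == -5], rep(1, 3))   # midpoint
  expect_equal(sort(unique(d$log10_conc_M)),
               c(-6.5, -6, -5.5, -5, -4.5, -4, -3.5, -3))

  # asymptote: far below the EC50 the mean response approaches bottom
  lo <- simulate_dose_response(0.3, 2, -5, 1, concentrations = -12,
                               n_replicates = 1, noise_sd = 0)
  expect_equal(lo$response, 0.3, tolerance = 1e-6)

  expect_error(simulate_dose_response(0, 2, -5, 0), "non-zero")
  d1 <- simulate_dose_response(0, 2, -5, 1, noise_sd = 0.1, seed = 4)
  d2 <- simulate_dose_response(0, 2, -5, 1, noise_sd = 0.1, seed = 4)
  expect_identical(d1, d2)
})

test_that("degranulation simulation respects means, n, and bounds", {
  means <- c(vehicle = 5, drug = 60)
  d0 <- simulate_degranulation(means, noise_sd = 0, n = 6)
  expect_equal(nrow(d0), 12L)
  expect_equal(unique(d0$percent_release[d0$condition == "drug"]), 60)

  d1 <- simulate_degranulation(means, noise_sd = 10, n = 50, seed = 2)
  expect_true(all(d1$percent_release >= 0 & d1$percent_release <= 100))
  d2 <- simulate_degranulation(means, noise_sd = 10, n = 50, seed = 2)
  expect_identical(d1, d2)
  expect_error(simulate_degranulation(c(a = 150)), "\\[0, 100\\]")
})

test_that("null screens call hits at roughly the Gaussian 3-SD tail rate", {
  # no injected agonists: the 3*SD rule should fire on ~0.135% of compounds
  rates <- vapply(1:5, function(s) {
    run <- run_screen(small_config(seed = 100 + s, frac_agonists = 0))
    mean(call_hits(run$paired, b_col = "b_wt")$is_hit)
  }, numeric(1))
  n_total <- 5 * 704
  p0 <- pnorm(3, lower.tail = FALSE)
  se <- sqrt(p0 * (1 - p0) / n_total)
  expect_lt(abs(mean(rates) - p0), 3 * se + 1e-9)
})

test_that("agonists at the detectability floor are recovered as hits and positives", {
  # injected effects >= 6*noise SD with >= 80% mutant attenuation
  hit_rec <- c(0L, 0L)
  pos_rec <- c(0L, 0L)
  for (s in 1:4) {
    run <- run_screen(recovery_config(300 + s, n_compounds = 704L))
    tr <- run$truth$compounds
    eligible <- tr$is_agonist & tr$wt_effect >= 6 * 0.05 & tr$attenuation <= 0.2
    hits <- call_hits(run$paired, b_col = "b_wt")
    dc <- differential_select(run$paired)
    m <- dplyr::left_join(tr[eligible, "compound_id"], hits, by = "compound_id")
    m2 <- dplyr::left_join(tr[eligible, "compound_id"], dc, by = "compound_id")
    hit_rec <- hit_rec + c(sum(m$is_hit), nrow(m))
    pos_rec <- pos_rec + c(sum(m2$differential_call == "POSITIVE"), nrow(m2))
  }
  expect_gte(hit_rec[1] / hit_rec[2], 0.95)
  expect_gte(pos_rec[1] / pos_rec[2], 0.95)
})
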