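# Shared fixtures for the synthetic-screen tests.

# Small screen: 2 library plates per genotype/replicate, fast to polish.
small_config <- function(seed = 1, ...) {
  screen_config(n_compounds = 704L, seed = seed, ...)
}

# Recovery benchmark: every injected agonist sits near the 6*noise-SD
# detectability floor with >= 80% loss in the mutant (see vignette).
recovery_config <- function(seed, n_compounds = 3456L) {
  screen_config(
    n_compounds = n_compounds,
    agonist_effect_mean = 0.45, agonist_effect_sd = 0.15,
    mut_attenuation_mean = 0.10, mut_attenuation_sd = 0.06,
    seed = seed
  )
}

# Full pipeline: simulate -> B-scores -> paired per-compound table.
run_screen <- function(config) {
  sim <- simulate_screen(config)
  scored <- suppressWarnings(bscore_plates(sim$plates))
  list(paired = paired_bscores(aggregate_bscores(scored)),
       truth = sim$truth, scored = scored)
}

# Write a data frame to a temp file and return the path.
tmp_table <- function(d, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  if (ext == ".tsv") readr::write_tsv(d, path) else readr::write_csv(d, path)
  path
}
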