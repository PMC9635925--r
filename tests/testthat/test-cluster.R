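test_that("tanimoto is intersection over union with the documented edge cases", {
  expect_equal(tanimoto(c(TRUE, TRUE, TRUE, FALSE), c(FALSE, TRUE, TRUE, TRUE)),
               0.5)   # bits {1,2,3} vs {2,3,4}
  a <- c(TRUE, FALSE, TRUE)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(c(TRUE, FALSE), c(FALSE, TRUE)), 0)
  expect_equal(tanimoto(a, c(FALSE, TRUE, TRUE)), tanimoto(c(FALSE, TRUE, TRUE), a))
  expect_warning(both_empty <- tanimoto(c(FALSE, FALSE), c(FALSE, FALSE)),
                 "empty")
  expect_equal(both_empty, 1)
  expect_error(tanimoto(c(TRUE, TRUE), c(TRUE, TRUE, FALSE)), "lengths")
})

test_that("ECFP4 fingerprints canonicalise SMILES and behave sensibly", {
  fps <- fingerprint_compounds(c("CCO", "OCC", "CC", "CCC"),
                               c("etoh_a", "etoh_b", "ethane", "propane"))
  expect_equal(dim(fps), c(4L, 2048L))
  expect_identical(fps["etoh_a", ], fps["etoh_b", ])
  expect_gte(min(rowSums(fps)), 1)   # popcount >= 1 per molecule
  # close homologues: similar but not identical
  t_hom <- tanimoto(fps["ethane", ], fps["propane", ])
  expect_gt(t_hom, 0)
  expect_lt(t_hom, 1)
  expect_error(fingerprint_compounds("", "empty"), "empty or missing")
  expect_error(fingerprint_compounds("xx(", "bad"), "unparseable")
  expect_error(fingerprint_compounds("CCO", "a", n_bits = 1000), "power of two")
})

test_that("fingerprint similarity ranks a homologue above an unrelated scaffold", {
  # cross-toolkit sanity check against RDKit's Morgan radius-2 fingerprints:
  # both toolkits must agree that ibuprofen-like and benzene-like inputs are
  # less similar than two close tricyclic analogues
  smi <- c(imipramine = "CN(C)CCCN1c2ccccc2CCc2ccccc21",
           desipramine = "CNCCCN1c2ccccc2CCc2ccccc21",
           benzene = "c1ccccc1")
  fps <- fingerprint_compounds(smi, names(smi))
  near <- tanimoto(fps["imipramine", ], fps["desipramine", ])
  far <- tanimoto(fps["imipramine", ], fps["benzene", ])
  expect_gt(near, far)
  expect_gt(near, 0.5)
  expect_lt(far, 0.3)

  rdkit <- sprintf(
    paste0("from rdkit import Chem; from rdkit.Chem import AllChem, DataStructs; ",
           "f = lambda s: AllChem.GetMorganFingerprintAsBitVect(Chem.MolFromSmiles(s), 2, 2048); ",
           "print(DataStructs.TanimotoSimilarity(f('%s'), f('%s')), ",
           "DataStructs.TanimotoSimilarity(f('%s'), f('%s')))"),
    smi[1], smi[2], smi[1], smi[3])
  out <- tryCatch(
    system2("python", c("-c", shQuote(rdkit)), stdout = TRUE, stderr = FALSE),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (!is.null(out) && length(out) == 1L) {
    ref <- as.numeric(strsplit(out, " ")[[1]])
    expect_gt(ref[1], ref[2])   # same ordering under the independent toolkit
  }
})

test_that("butina clustering handles the degenerate extremes", {
  # everything mutually similar: one cluster
  sim <- matrix(0.9, 4, 4)
  diag(sim) <- 1
  dimnames(sim) <- list(letters[1:4], letters[1:4])
  cs <- cluster_butina(sim, cutoff = 0.6)
  expect_equal(dplyr::n_distinct(cs$cluster), 1L)
  expect_equal(glance(cs)$n_major_clusters, 1L)

  # nothing similar: all singletons, no major clusters at min size 3
  sim0 <- diag(4)
  dimnames(sim0) <- list(letters[1:4], letters[1:4])
  cs0 <- cluster_butina(sim0, cutoff = 0.6)
  expect_equal(dplyr::n_distinct(cs0$cluster), 4L)
  expect_equal(glance(cs0)$n_major_clusters, 0L)
  expect_equal(glance(cs0)$n_unclustered, 4L)
})

test_that("two cliques linked below the cutoff give exactly two clusters of 3", {
  ids <- c("a", "b", "c", "d", "e", "f")
  sim <- matrix(0.1, 6, 6, dimnames = list(ids, ids))
  sim[1:3, 1:3] <- 0.8
  sim[4:6, 4:6] <- 0.8
  diag(sim) <- 1
  cs <- cluster_butina(sim, cutoff = 0.6)
  per <- tidy(cs)
  expect_equal(nrow(per), 2L)
  expect_equal(sort(per$n_members), c(3L, 3L))
  expect_setequal(per$members[[1]], c("a", "b", "c"))
  expect_setequal(per$members[[2]], c("d", "e", "f"))
  # matches exhaustive enumeration of the greedy rule
  ref <- brute_force_butina(sim, 0.6)
  expect_equal(lapply(per$members, sort), lapply(ref, `[[`, "members"))
})

test_that("clustering equals the brute-force greedy rule on random matrices", {
  for (seed in 1:10) {
    n <- sample(3:6, 1)
    sim <- random_sim(n, seed)
    cutoff <- runif(1, 0.3, 0.7)
    cs <- cluster_butina(sim, cutoff = cutoff)
    per <- dplyr::arrange(tidy(cs), cluster)
    ref <- brute_force_butina(sim, cutoff)
    expect_equal(length(ref), nrow(per))
    expect_equal(lapply(per$members, sort), lapply(ref, `[[`, "members"))
    expect_equal(per$centroid, vapply(ref, `[[`, character(1), "centroid"))
  }
})

test_that("clustering is a deterministic partition, invariant to input order", {
  sim <- random_sim(6, 99)
  cs <- cluster_butina(sim, cutoff = 0.5)
  # partition: every id exactly once
  expect_setequal(cs$compound_id, rownames(sim))
  expect_equal(anyDuplicated(cs$compound_id), 0L)
  # every member at least cutoff-similar to its centroid
  expect_true(all(cs$sim_to_centroid >= 0.5))
  # shuffled input gives the same clustering
  perm <- c(4, 1, 6, 3, 2, 5)
  cs2 <- cluster_butina(sim[perm, perm], cutoff = 0.5)
  expect_equal(as.data.frame(cs), as.data.frame(cs2))
})
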