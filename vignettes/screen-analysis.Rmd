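---
title: "Analysing paired MRGPRX2 agonist screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing paired MRGPRX2 agonist screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrgscreen)
library(dplyr)
```

## The problem

MRGPRX2 is a mast-cell GPCR that mediates pseudo-allergic drug
hypersensitivity: certain small-molecule drugs activate it directly,
degranulating mast cells without any drug-specific IgE. A productive way to
find such drugs is a cell-based calcium-mobilization screen run in a
*paired* design: the same compound library is screened against cells
expressing wild-type MRGPRX2 and against cells expressing the
loss-of-function N62S variant. A genuine MRGPRX2 agonist lights up the
wild-type arm and is attenuated in the mutant arm; an off-target calcium
signal fires in both. `mrgscreen` implements the full analysis chain for
this design: well-ratio computation, B-score plate normalization, hit
calling, paired differential selection, percent-change scoring,
structure–activity clustering of the hits, dose-response (EC50) validation
and degranulation statistics — plus a synthetic screen generator with known
ground truth so every stage can be validated end to end.

## The model, stage by stage

### Well summaries and the B-score

Each well's kinetic trace is summarised as the signal-to-background ratio
`peak / baseline` (`compute_ratio()`). The supplementary definition of the
original extraction is not public; peak-over-baseline is standard practice
for FDSS-type readers and is documented here as an assumption.

Raw plate ratios carry positional artifacts — row and column offsets from
dispense order, edge evaporation and reader drift. The B-score removes them
without using control wells. `median_polish()` decomposes a plate
additively,

$$y_{ij} = \mu + R_i + C_j + r_{ij},$$

by alternately sweeping row medians and then column medians out of the
residuals (rows first; the median of each effect vector is folded into the
overall term; even-length medians use the midpoint; iteration stops when no
effect moves by more than `tol = 1e-6`, default cap 100 sweeps). The
B-score is the residual scaled by the robust plate noise,

$$B_{ij} = r_{ij} / (1.4826 \cdot \mathrm{median}|r|),$$

so inactive compounds sit near 0 with spread comparable across plates
(`b_score()`). Two conventions matter:

* **Controls are excluded from the polish and the MAD** (the negative and
  positive control columns would otherwise distort the row effects and the
  scale). "Non-controls-based" in the B-score literature refers to the
  normalization not relying on controls; excluding them entirely is our
  stricter reading, and `bscore_plates(include_controls = TRUE)` provides
  the sensitivity switch.
* **A plate with zero residual MAD is degenerate**, not an error: B-scores
  are set to 0 and flagged, so pathological (e.g. noiseless synthetic)
  plates flow through pipelines.

Replicates are aggregated per compound and cell line by the arithmetic mean
of finite replicate B-scores (`aggregate_bscores()`); the aggregation rule
is ours — triplicate screening is stated practice, the combination rule is
not.

A numerical caveat documented here because tests rely on it: median-polish
fixed points are not unique. On even-dimension plates tied medians admit
period-2 cycles, so two runs that differ by arbitrary offsets on *all* rows
and columns can settle ~1e-3 B-units apart. Offsets confined to a single
row, a single column, or the whole plate reproduce B-scores exactly;
the package asserts the general case only to well below any calling
threshold.

### Hit calling and the paired comparison

`call_hits()` implements the screen's decision rule: a compound is active
when its aggregated wild-type B-score strictly exceeds `multiplier` (default
3) times the sample SD of the B-scores of *all* library compounds — hits
included, since no trimming rule is published; a MAD-based robust variant
sits behind `robust = TRUE`. The threshold is always recomputed from the
scores handed in; a published cut-off (such as 18.05) can be re-applied via
the `threshold` argument.

The paired arm works on the per-compound difference
$\Delta = B_\mathrm{WT} - B_\mathrm{MUT}$ (`differential_select()`):
positive calls are compounds with $\Delta$ strictly above
$\bar\Delta + s_\Delta$, negative calls below $\bar\Delta - s_\Delta$. With
the published window (upper 6.45, lower −5.13) this implies
$\bar\Delta = 0.66$, $s_\Delta = 5.79$, which the tests reconstruct.
Selectivity is additionally expressed per compound as the percent change
`100 * (b_mut - b_wt) / b_wt` (`percent_change()`): −100 means the response
is fully lost in the mutant, values below −100 mean the mutant score
crossed zero, and the quantity is undefined (NA with a warning) at
`b_wt = 0`. Sample (n−1) SDs are used throughout — that convention is what
reproduces the published class summaries (31.71 ± 10.27 for the
fluoroquinolones; 22.07 ± 3.27 recomputed for the antineoplastics, printed
as 22.06).

The package ships the published 34-compound hit table as a plain-text
fixture (`published_hits()`) so all of this arithmetic is checkable without
any download. Two published inconsistencies are deliberately *not*
reproduced: the printed overall hit rate of 3.04% (84/3,456 is 2.43%), and
the printed mean percent reduction −89.01 ± 16.08 across the 34 hits
(recomputing from the printed B-scores gives −92.5 ± 12.6; the recomputed
value is what the package asserts).

### Structure–activity clustering

Hits are fingerprinted with folded extended-connectivity fingerprints of
diameter 4 (ECFP4, Morgan radius 2) via OpenBabel; the native 4096-bit
output is OR-folded to 2048 bits (`fingerprint_compounds()`). Similarity is
Tanimoto (intersection over union, `tanimoto()`), and clustering is greedy
sphere exclusion in the Butina style (`cluster_butina()`): neighbour lists
at similarity ≥ cutoff (default 0.6), centroids chosen by unassigned
neighbour count, ties broken lexicographically on compound id so the result
is independent of input order. Clusters need `min_report_size = 3` members
to count as "major", inclusive, because published cluster lists of this
kind contain size-3 clusters.

The original analysis used the proprietary Forge alignment engine with an
ECFP4 similarity criterion; whether its 0.6 threshold is a pure Tanimoto is
unstated. We implement the fingerprint reading of that criterion. Absolute
similarity values differ across toolkits (OpenBabel ECFP4 vs RDKit Morgan
bits disagree in detail), so no attempt is made to reproduce the published
14-cluster / 70-compound partition, whose input structures are in an
unavailable supplement; the package validates the clustering rule itself
against brute-force enumeration and checks cross-toolkit *ordering*
agreement instead.

### Dose-response validation

Validation experiments fit the four-parameter logistic in log10 molar
concentration (`four_pl()`, `fit_dose_response()`):
$y = \mathrm{bottom} + (\mathrm{top} - \mathrm{bottom}) / (1 +
10^{(\log EC_{50} - x)\,h})$, the Prism-style default for this assay class,
over the 8-point half-log grid (−6.5 … −3). Fitting is multi-start
Levenberg–Marquardt (7 EC50 starts spanning the grid × both Hill-slope
signs, best RSS wins) and deterministic given the data. Fits are
canonicalised to `bottom <= top`. The fit is intentionally unconstrained:
when the true EC50 sits at or below the lowest tested concentration the
bottom asymptote is unidentified and least squares can prefer extreme
asymptote values — the package surfaces this honestly through a large
`se_log_ec50` and an `extrapolated` flag rather than hiding it with box
constraints (constrained fits were tried and rejected: they break exact
recovery of below-grid EC50s).

`compare_ec50()` tests a potency shift between genotypes with a z-statistic
on the difference of `log_ec50` using the fits' curvature SEs. The original
study's P = 0.013 for the wild-type/N62S comparison derives from
replicate-level data that were not published; the z-test is the documented
substitute, and the published 160 nM / 283 nM values are used as simulator
inputs (fold change 1.77), never as quantities we claim to re-derive.

### Degranulation statistics

`percent_release()` expresses β-hexosaminidase release as
`100 * supernatant / (supernatant + lysate)` — the formula is not printed
in the source methods; total-content normalization is the field's standard.
`genotype_effect_test()` runs the fixed-effects two-way ANOVA
(condition × genotype) and the per-condition genotype contrast with Sidak
correction across the family of conditions, `p_adj = 1 - (1 - p)^m`
(reducing to the raw p at m = 1). All-identical input is reported as "no
effect" (F = 0, p = 1) rather than NaN. Whether the published
per-concentration stars come from EC50-level or per-concentration
comparisons is ambiguous; both routes are provided (`compare_ec50()` and
the per-condition contrasts).

## The synthetic screen generator

`simulate_screen()` generates the full paired screen with known ground
truth. Defaults are fixed once to emulate the study conditions and are not
tuned thereafter:

| parameter | default | why |
|---|---|---|
| `n_compounds` | 3456 | library size of the screened collection |
| plate format | 16 × 24, controls in the last two columns | 384-well plates with per-plate negative (buffer) and positive (agonist) columns; the true screen's layout is unpublished, this one is our own and labelled as such |
| `n_replicates` | 3 | triplicate testing |
| `frac_agonists` | 0.03 | between the 84-hit (2.4%) and 226-differential (6.5%) rates |
| `agonist_effect_mean`, `_sd` | 1.25, 0.5 (ratio units), floored at 6 × `noise_sd` | with `noise_sd = 0.05` this puts agonist B-scores at ~25 ± 10 and the 3·SD threshold near 14–18 — the printed hit-score scale (hits 18.2–44.8 at threshold 18.05) |
| `mut_attenuation_mean`, `_sd` | 0.05, 0.05, clipped to [0, 1] | ~90–95% loss in the mutant arm, mirroring the published ~90% mean reduction |
| `row/col_effect_sd` | 0.03 | additive positional artifacts at a bit over half the noise SD — visible structure that median polish removes exactly |
| `noise_sd` | 0.05 | 5% well noise around a baseline ratio of 1 |
| `pos_ctrl_effect` | 1.5 | a strong reference agonist |

Positional artifacts are additive row+column offsets — exactly the model
median polish inverts; `edge_effect` optionally multiplies border wells to
create a deliberate model violation for robustness checks. All randomness
flows from one seed in a documented draw order (agonist flags, effects,
attenuations, then per-plate artifacts and noise), so screens are
bit-reproducible. What the generator does *not* emulate: kinetic traces,
compound carry-over, dispensing failures, inter-plate drift within a
replicate, or correlated (smooth spatial) artifacts. Passing recovery tests
therefore demonstrate correctness of the *analysis chain* under its own
model assumptions, not performance on arbitrary real screens.

Two study regimes are used in the tests, chosen from design arithmetic
before any test was run:

* **Study-scale defaults** (above): agonist effects are large but
  wide-spread. Because the 3·SD rule computes its SD over *all* compounds,
  strong agonists inflate the threshold (~14–18 B-units) and the weakest
  true agonists land below it — the screen's own data show the same
  (vancomycin at B = 16.36 under a cut-off of 18.05). Sensitivity over all
  injected agonists here is ~0.86 by construction, and no test asserts
  otherwise.
* **Recovery benchmark** (`recovery_config()` in the tests and acceptance
  script): all injected effects near the detectability floor of 6 noise
  SDs (N(9, 3) × `noise_sd`, truncated at 6 × `noise_sd`) with ≥ 80% loss
  in the mutant. Under these stipulated conditions the threshold stays
  near 5 B-units and injected agonists are recovered as wild-type hits
  with sensitivity ≥ 0.95 and as differential positives at ~1.0, pooled
  over 20 seeds.

Problem sizes in the shipped tests are the package's own choices: unit
tests use 704-compound screens (2 plates per genotype per replicate); the
acceptance checks run 20 full-size recovery screens, 4 null screens, 50
noisy dose-response fits and the brute-force clustering comparisons.

## Worked example

```{r pipeline, eval = FALSE}
cfg <- screen_config(seed = 42)
sim <- simulate_screen(cfg)

paired <- sim$plates |>
  bscore_plates() |>
  aggregate_bscores() |>
  paired_bscores()

hits <- call_hits(paired, b_col = "b_wt")
glance(hits)

diff <- differential_select(paired)
glance(diff)

paired |>
  mutate(pct_change = percent_change(b_wt, b_mut)) |>
  filter(hits$is_hit) |>
  arrange(desc(b_wt))
```

For the published hit table:

```{r table, eval = FALSE}
published_hits() |> class_summary()
autoplot(call_hits(published_hits(), b_col = "b_wt", threshold = 18.05))
```

## Design choices where the design was open

* **Tidy, data-frame-first interface.** Wells, scores and results are long
  tibbles throughout; matrices appear only inside the polish. This keeps
  every stage pipeable and inspectable.
* **1-based coordinates.** Well "A1" is row 1, column 1; alphanumeric
  labels are accepted at every boundary and the label↔index mapping is a
  tested bijection. (0-based indexing invites off-by-one bugs against R
  matrices.)
* **Strict inequalities at every threshold.** A score exactly at a cut-off
  is not a hit; ties are practically impossible in floats but the
  convention is pinned by tests.
* **Δ is `b_wt - b_mut`**, so *positive* differential calls are the
  wild-type-selective compounds; a documented, deliberate orientation.
* **Missing values propagate** — empty wells, failed replicates and
  unparseable SMILES are carried as NA (with warnings where user action is
  possible), never imputed.

## Known limitations

* The generator's additive-artifact model matches what B-scores remove; a
  screen dominated by multiplicative or smooth spatial artifacts would need
  the `edge_effect` violation switch and external diagnostics.
* ECFP4 bit patterns are toolkit-specific; cluster memberships at a fixed
  cutoff are comparable within this package but not bit-for-bit against
  other software.
* The EC50 z-test treats the two fits as independent Gaussian estimates on
  the log scale; with few concentrations and extrapolated EC50s the
  curvature SE is optimistic, and such fits are flagged.
* `genotype_effect_test()` assumes a balanced complete condition × genotype
  design and refuses unbalanced-empty cells rather than guessing a
  contrast.
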