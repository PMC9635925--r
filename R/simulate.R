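#' Configuration for a synthetic paired screen
#'
#' Describes a simulated paired wild-type / mutant agonist screen with known
#' ground truth. Defaults emulate the study conditions of a 384-well
#' calcium-mobilization screen: 3,456 library compounds tested in
#' triplicate at a single concentration, a small fraction of true agonists
#' whose ratio-scale effect mirrors the published hit B-score range, strong
#' genotype-dependent attenuation of agonist effects in mutant cells
#' (~90-95% loss), additive row/column positional artifacts, and Gaussian
#' measurement noise around a baseline ratio of 1.
#'
#' Agonist effects are drawn from a normal distribution truncated below at
#' `agonist_effect_floor` (default six noise SDs) so every injected agonist
#' is in principle distinguishable from noise at the well level.
#'
#' @param n_compounds Number of library compounds (default 3456).
#' @param n_rows,n_cols Plate geometry (default 16 x 24; the last two
#'   columns hold negative and positive controls).
#' @param n_replicates Replicates per compound and genotype (default 3).
#' @param frac_agonists Fraction of compounds that are true agonists.
#' @param agonist_effect_mean,agonist_effect_sd Normal distribution of the
#'   additive agonist effect on the wild-type fluorescence ratio.
#' @param agonist_effect_floor Lower truncation of agonist effects; default
#'   `6 * noise_sd`.
#' @param mut_attenuation_mean,mut_attenuation_sd Fraction of the wild-type
#'   effect remaining in mutant cells, normal clipped to [0, 1].
#' @param row_effect_sd,col_effect_sd SD of additive per-plate row/column
#'   positional artifacts.
#' @param noise_sd SD of Gaussian well noise.
#' @param baseline_ratio Ratio of an inactive well with no artifacts.
#' @param pos_ctrl_effect Fixed additive effect of the positive-control
#'   agonist wells.
#' @param edge_effect Optional multiplicative distortion of border wells
#'   (default 0 = off); a deliberate violation of the additive
#'   row+column model used to probe B-score robustness.
#' @param seed Integer seed; every random draw flows from it.
#' @return An object of class `screen_config` (a named list).
#' @seealso [simulate_screen()]
#' @export
screen_config <- function(n_compounds = 3456L, n_rows = 16L, n_cols = 24L,
                          n_replicates = 3L, frac_agonists = 0.03,
                          agonist_effect_mean = 1.25, agonist_effect_sd = 0.5,
                          agonist_effect_floor = NULL,
                          mut_attenuation_mean = 0.05,
                          mut_attenuation_sd = 0.05,
                          row_effect_sd = 0.03, col_effect_sd = 0.03,
                          noise_sd = 0.05, baseline_ratio = 1,
                          pos_ctrl_effect = 1.5, edge_effect = 0,
                          seed = 1L) {
  if (frac_agonists < 0 || frac_agonists >= 1) {
    abort("`frac_agonists` must be in [0, 1).")
  }
  sds <- c(agonist_effect_sd, mut_attenuation_sd, row_effect_sd,
           col_effect_sd, noise_sd)
  if (any(sds < 0)) abort("All SD parameters must be >= 0.")
  if (n_cols < 3L) abort("Plate needs at least 3 columns (library + 2 control).")
  if (n_rows < 2L) abort("Plate needs at least 2 rows.")
  if (is.null(agonist_effect_floor)) agonist_effect_floor <- 6 * noise_sd
  structure(
    list(n_compounds = as.integer(n_compounds), n_rows = as.integer(n_rows),
         n_cols = as.integer(n_cols), n_replicates = as.integer(n_replicates),
         frac_agonists = frac_agonists,
         agonist_effect_mean = agonist_effect_mean,
         agonist_effect_sd = agonist_effect_sd,
         agonist_effect_floor = agonist_effect_floor,
         mut_attenuation_mean = mut_attenuation_mean,
         mut_attenuation_sd = mut_attenuation_sd,
         row_effect_sd = row_effect_sd, col_effect_sd = col_effect_sd,
         noise_sd = noise_sd, baseline_ratio = baseline_ratio,
         pos_ctrl_effect = pos_ctrl_effect, edge_effect = edge_effect,
         seed = as.integer(seed)),
    class = "screen_config"
  )
}

#' Simulate a paired wild-type / mutant screen with known truth
#'
#' Generates the full set of plates for a paired screen from a
#' [screen_config()]. Compounds are laid out sequentially (column-major)
#' over the library columns; the last-but-one column holds negative
#' controls (buffer only), the last column positive controls (a fixed
#' strong agonist effect). The compound-to-well layout is identical across
#' genotypes and replicates; every physical plate gets its own row/column
#' artifacts and noise.
#'
#' Each well value is
#' `baseline_ratio + effect + row_artifact + col_artifact + noise`, where
#' `effect` is the compound's genotype-specific agonist effect (0 for
#' inactives and negative controls, `pos_ctrl_effect` for positive
#' controls). Unassigned wells on the last plate are EMPTY with `NA`.
#'
#' Randomness is fully determined by `config$seed`; the draw order is:
#' agonist indicators, wild-type effects, mutant attenuations, then per
#' plate (WT replicates in order, then MUT) row artifacts, column
#' artifacts, and the noise matrix.
#'
#' @param config A [screen_config()].
#' @return A list with `plates` (named list of [plate_grid()] objects) and
#'   `truth` (list with per-compound tibble `compounds` and per-plate
#'   tibble `plates` holding the injected artifact vectors).
#' @examples
#' sim <- simulate_screen(screen_config(n_compounds = 100, seed = 42))
#' sim$truth$compounds
#' @export
simulate_screen <- function(config) {
  if (!inherits(config, "screen_config")) {
    abort("`config` must come from screen_config().")
  }
  cf <- config
  lib_cols <- seq_len(cf$n_cols - 2L)
  neg_col <- cf$n_cols - 1L
  pos_col <- cf$n_cols
  lib_per_plate <- cf$n_rows * length(lib_cols)
  if (lib_per_plate < 1L) abort("Plate has no library capacity.")
  n_plates <- ceiling(cf$n_compounds / lib_per_plate)

  set.seed(cf$seed)
  ids <- sprintf("SIM%05d", seq_len(cf$n_compounds))
  is_agonist <- runif(cf$n_compounds) < cf$frac_agonists
  wt_effect <- numeric(cf$n_compounds)
  wt_effect[is_agonist] <- pmax(
    rnorm(sum(is_agonist), cf$agonist_effect_mean, cf$agonist_effect_sd),
    cf$agonist_effect_floor
  )
  attenuation <- pmin(pmax(
    rnorm(cf$n_compounds, cf$mut_attenuation_mean, cf$mut_attenuation_sd),
    0), 1)
  attenuation[!is_agonist] <- 0
  mut_effect <- wt_effect * attenuation

  truth_compounds <- tibble::tibble(
    compound_id = ids, is_agonist = is_agonist,
    wt_effect = wt_effect, mut_effect = mut_effect,
    attenuation = attenuation
  )

  # static layout, shared by every genotype and replicate
  layout_ids <- matrix(NA_character_, cf$n_rows, cf$n_cols * n_plates)
  roles_one <- matrix(NA_character_, cf$n_rows, cf$n_cols)
  roles_one[, lib_cols] <- "LIBRARY"
  roles_one[, neg_col] <- "NEG_CTRL"
  roles_one[, pos_col] <- "POS_CTRL"
  slot_plate <- rep(seq_len(n_plates), each = lib_per_plate)
  slot_within <- rep(seq_len(lib_per_plate), n_plates)[seq_len(cf$n_compounds)]
  slot_plate <- slot_plate[seq_len(cf$n_compounds)]
  slot_row <- ((slot_within - 1L) %% cf$n_rows) + 1L
  slot_col <- lib_cols[((slot_within - 1L) %/% cf$n_rows) + 1L]

  plates <- list()
  truth_plates <- list()
  edge <- matrix(1, cf$n_rows, cf$n_cols)
  if (cf$edge_effect != 0) {
    edge[c(1L, cf$n_rows), ] <- 1 + cf$edge_effect
    edge[, c(1L, cf$n_cols)] <- 1 + cf$edge_effect
  }
  for (genotype in c("WT", "MUT")) {
    eff <- if (genotype == "WT") wt_effect else mut_effect
    for (rep_i in seq_len(cf$n_replicates)) {
      for (p in seq_len(n_plates)) {
        on_plate <- slot_plate == p
        roles <- roles_one
        cmp <- matrix(NA_character_, cf$n_rows, cf$n_cols)
        cmp[cbind(slot_row[on_plate], slot_col[on_plate])] <- ids[on_plate]
        unfilled <- roles == "LIBRARY" & is.na(cmp)
        roles[unfilled] <- "EMPTY"

        row_art <- rnorm(cf$n_rows, 0, cf$row_effect_sd)
        col_art <- rnorm(cf$n_cols, 0, cf$col_effect_sd)
        noise <- matrix(rnorm(cf$n_rows * cf$n_cols, 0, cf$noise_sd),
                        cf$n_rows, cf$n_cols)
        effect_mat <- matrix(0, cf$n_rows, cf$n_cols)
        effect_mat[cbind(slot_row[on_plate], slot_col[on_plate])] <- eff[on_plate]
        effect_mat[, pos_col] <- cf$pos_ctrl_effect

        values <- (cf$baseline_ratio + effect_mat +
                     outer(row_art, rep(1, cf$n_cols)) +
                     outer(rep(1, cf$n_rows), col_art) + noise) * edge
        values[roles == "EMPTY"] <- NA_real_

        plate_id <- sprintf("P%02d_%s_R%d", p, genotype, rep_i)
        plates[[plate_id]] <- plate_grid(plate_id, genotype, values, roles, cmp)
        truth_plates[[plate_id]] <- tibble::tibble(
          plate_id = plate_id, cell_line = genotype, replicate = rep_i,
          plate_index = p, row_effects = list(row_art),
          col_effects = list(col_art)
        )
      }
    }
  }
  list(plates = plates,
       truth = list(compounds = truth_compounds,
                    plates = dplyr::bind_rows(truth_plates)))
}

#' Simulate dose-response measurements from a 4PL curve
#'
#' Draws replicate responses around a four-parameter logistic mean curve
#' over a grid of log10 molar concentrations. The default grid is the
#' 8-point half-log series from -6.5 to -3 used for validation
#' dose-response experiments.
#'
#' @param bottom,top,log_ec50,hill 4PL parameters (see [four_pl()]);
#'   `hill = 0` is a degenerate flat curve and errors.
#' @param concentrations Log10 molar concentration grid.
#' @param n_replicates Replicates per concentration.
#' @param noise_sd SD of additive Gaussian response noise.
#' @param seed Optional integer seed.
#' @return A tibble with columns `log10_conc_M`, `replicate`, `response`.
#' @export
simulate_dose_response <- function(bottom, top, log_ec50, hill,
                                   concentrations = c(-6.5, -6, -5.5, -5,
                                                      -4.5, -4, -3.5, -3),
                                   n_replicates = 3L, noise_sd = 0,
                                   seed = NULL) {
  if (!length(concentrations)) abort("`concentrations` must be non-empty.")
  if (hill == 0) abort("`hill` must be non-zero (degenerate flat curve).")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (!is.null(seed)) set.seed(seed)
  d <- tidyr::expand_grid(log10_conc_M = concentrations,
                          replicate = seq_len(n_replicates))
  mu <- four_pl(d$log10_conc_M, bottom, top, log_ec50, hill)
  d$response <- mu + rnorm(nrow(d), 0, noise_sd)
  d
}

#' Simulate degranulation percent-release samples
#'
#' Draws `n` percent-release replicates per condition/genotype cell around
#' given means, clipped to [0, 100].
#'
#' @param means Either a named numeric vector (names = condition labels,
#'   genotype set to "LAD2") or a data frame with columns `condition`,
#'   `genotype`, `mean_release`.
#' @param noise_sd SD of Gaussian noise before clipping.
#' @param n Replicates per cell (default 6).
#' @param seed Optional integer seed.
#' @return A tibble with columns `condition`, `genotype`, `replicate`,
#'   `percent_release`.
#' @export
simulate_degranulation <- function(means, noise_sd = 0, n = 6L, seed = NULL) {
  if (is.numeric(means)) {
    if (is.null(names(means))) abort("Numeric `means` must be named by condition.")
    means <- tibble::tibble(condition = names(means), genotype = "LAD2",
                            mean_release = unname(means))
  }
  if (!all(c("condition", "genotype", "mean_release") %in% names(means))) {
    abort("`means` needs columns condition, genotype, mean_release.")
  }
  if (any(means$mean_release < 0 | means$mean_release > 100)) {
    abort("Mean percent release must lie in [0, 100].")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (!is.null(seed)) set.seed(seed)
  d <- tidyr::expand_grid(means, replicate = seq_len(n))
  d$percent_release <- pmin(pmax(
    d$mean_release + rnorm(nrow(d), 0, noise_sd), 0), 100)
  d[, c("condition", "genotype", "replicate", "percent_release")]
}
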