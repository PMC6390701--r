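#' Configuration for a synthetic reciprocal interaction screen
#'
#' Bundles and validates the generative parameters of the simulator.
#' The generative model mirrors the additive bias structure the median
#' polish is designed to invert: each well's absorbance is an
#' assay-wide background, plus an additive bias for the bait
#' preparation (row) and one for the prey preparation (column) — drawn
#' independently, since a protein's bait and prey preparations are
#' distinct — plus measurement noise, plus a fixed effect at wells
#' whose pair is truly interacting in that orientation. Values are
#' clipped at 0 (absorbance cannot be negative; a deliberate, small
#' deviation from pure additivity).
#'
#' Defaults describe a desk-scale screen: 50 proteins, background
#' 0.2 A650, preparation-bias SD 0.05 A650, noise SD 0.02 A650, and 30
#' planted symmetric pairs at effect `8 * noise_sd` — strong, clearly
#' resolvable interactions on a plate-reader scale.
#'
#' @param n_proteins Number of proteins (matrix is n x n).
#' @param overall_background Assay-wide background absorbance (A650).
#' @param row_effect_sd,col_effect_sd SD of per-bait-preparation and
#'   per-prey-preparation additive biases (A650).
#' @param noise_sd SD of per-well measurement noise (A650).
#' @param noise_family `"normal"` or `"lognormal-additive"` (a
#'   centred, right-skewed lognormal rescaled to `noise_sd`, to probe
#'   robustness to skewed plate noise).
#' @param n_true_pairs Number of planted truly interacting unordered
#'   pairs (self-pairs allowed); at most `choose(n, 2) + n`.
#' @param effect_size Added absorbance at truly interacting wells
#'   (A650), applied in each planted orientation.
#' @param asym_fraction Fraction of planted pairs expressed in one
#'   orientation only (self-pairs are always symmetric).
#' @param include_controls Add prey-only negative-control wells (bait
#'   id `NEG_CTRL`) and one positive-control pair (`BAK1`/`BIR4`-style
#'   known interactors, ids `POSCTRL_A`/`POSCTRL_B`) with a strong
#'   fixed effect.
#' @param seed Integer RNG seed; the full output is reproducible from
#'   the config.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_proteins = 50L,
                       overall_background = 0.2,
                       row_effect_sd = 0.05,
                       col_effect_sd = 0.05,
                       noise_sd = 0.02,
                       noise_family = c("normal", "lognormal-additive"),
                       n_true_pairs = 30L,
                       effect_size = 8 * noise_sd,
                       asym_fraction = 0,
                       include_controls = FALSE,
                       seed = 1L) {
  noise_family <- match.arg(noise_family)
  stopifnot(n_proteins >= 2L, is.finite(overall_background),
            row_effect_sd >= 0, col_effect_sd >= 0, noise_sd > 0,
            n_true_pairs >= 0L, effect_size > 0,
            asym_fraction >= 0, asym_fraction <= 1)
  max_pairs <- choose(n_proteins, 2L) + n_proteins
  if (n_true_pairs > max_pairs) {
    stop("n_true_pairs (", n_true_pairs, ") exceeds the number of ",
         "unordered pairs (", max_pairs, ")", call. = FALSE)
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 overall_background = overall_background,
                 row_effect_sd = row_effect_sd,
                 col_effect_sd = col_effect_sd,
                 noise_sd = noise_sd, noise_family = noise_family,
                 n_true_pairs = as.integer(n_true_pairs),
                 effect_size = effect_size,
                 asym_fraction = asym_fraction,
                 include_controls = isTRUE(include_controls),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# centred right-skewed additive noise: lognormal(0, 0.75) standardized
# to unit SD, then scaled to sd
rskew_noise <- function(n, sd) {
  sdlog <- 0.75
  x <- stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
  mu <- exp(sdlog^2 / 2)
  sigma <- sqrt((exp(sdlog^2) - 1) * exp(sdlog^2))
  (x - mu) / sigma * sd
}

#' Simulate a reciprocal interaction screen with ground truth
#'
#' Generates long-format well records for an all-by-all bait x prey
#' screen under the additive model described in [sim_config()],
#' together with the truth table of planted interactions, so that
#' recovery by the analysis pipeline can be scored exactly.
#'
#' @param config A `"sim_config"` object.
#' @return A list with:
#'   * `records`: data frame `bait`/`prey`/`absorbance`, one row per
#'     screen well (n^2 rows), feedable to [assemble_matrix()] /
#'     [run_primary_analysis()] unchanged;
#'   * `truth`: data frame of planted pairs: `id_a`, `id_b`
#'     (lexicographic), `orientation` (`both`, `ab`, or `ba`, with
#'     `_ab` meaning `id_a` as bait), `effect`;
#'   * `controls`: data frame of control wells (`bait`, `prey`,
#'     `absorbance`, `type` = `negative`/`positive`), empty unless
#'     `include_controls`.
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  ids <- sprintf("PROT%04d", seq_len(n))

  row_bias <- stats::rnorm(n, 0, config$row_effect_sd)
  col_bias <- stats::rnorm(n, 0, config$col_effect_sd)
  noise_fun <- switch(config$noise_family,
                      "normal" = function(k) stats::rnorm(k, 0,
                                                          config$noise_sd),
                      "lognormal-additive" = function(k)
                        rskew_noise(k, config$noise_sd))

  # planted pairs: sample unordered pairs incl. self-pairs
  ui <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  planted <- ui[sample.int(nrow(ui), config$n_true_pairs), , drop = FALSE]
  orientation <- rep("both", config$n_true_pairs)
  if (config$n_true_pairs > 0L && config$asym_fraction > 0) {
    n_asym <- round(config$asym_fraction * config$n_true_pairs)
    eligible <- which(planted[, 1L] != planted[, 2L])
    asym <- eligible[seq_len(min(n_asym, length(eligible)))]
    orientation[asym] <- sample(c("ab", "ba"), length(asym),
                                replace = TRUE)
  }

  effects <- matrix(0, n, n)
  for (k in seq_len(config$n_true_pairs)) {
    i <- planted[k, 1L]  # row index of id_a (i <= j in upper.tri)
    j <- planted[k, 2L]
    if (orientation[k] %in% c("both", "ab")) {
      effects[i, j] <- effects[i, j] + config$effect_size
    }
    if (i != j && orientation[k] %in% c("both", "ba")) {
      effects[j, i] <- effects[j, i] + config$effect_size
    }
  }

  values <- config$overall_background +
    outer(row_bias, col_bias, "+") + effects +
    matrix(noise_fun(n * n), n, n)
  values <- pmax(values, 0)

  records <- data.frame(
    bait = rep(ids, times = n),
    prey = rep(ids, each = n),
    absorbance = as.vector(values),
    stringsAsFactors = FALSE)

  truth <- data.frame(id_a = ids[planted[, 1L]],
                      id_b = ids[planted[, 2L]],
                      orientation = orientation,
                      effect = rep(config$effect_size,
                                   config$n_true_pairs),
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$id_a, truth$id_b), ]
  rownames(truth) <- NULL

  controls <- data.frame(bait = character(), prey = character(),
                         absorbance = numeric(), type = character(),
                         stringsAsFactors = FALSE)
  if (config$include_controls) {
    # prey-only wells: background + prey-preparation bias + noise
    n_neg <- max(3L, n %/% 10L)
    neg_prey <- sample.int(n, n_neg, replace = TRUE)
    neg_val <- pmax(config$overall_background + col_bias[neg_prey] +
                      noise_fun(n_neg), 0)
    # one strongly interacting known pair, both orientations
    pos_effect <- max(config$effect_size, 10 * config$noise_sd)
    pos_val <- pmax(config$overall_background + pos_effect +
                      noise_fun(2L), 0)
    controls <- data.frame(
      bait = c(rep("NEG_CTRL", n_neg), "POSCTRL_A", "POSCTRL_B"),
      prey = c(ids[neg_prey], "POSCTRL_B", "POSCTRL_A"),
      absorbance = c(neg_val, pos_val),
      type = c(rep("negative", n_neg), "positive", "positive"),
      stringsAsFactors = FALSE)
  }

  list(records = records, truth = truth, controls = controls)
}

#' Score pipeline recovery against the simulator's truth table
#'
#' A planted symmetric pair is recovered when called bidirectional; a
#' planted one-orientation pair when called unidirectional. Sensitivity
#' is the recovered fraction of planted pairs (also reported per
#' orientation class); the false-positive rate is the fraction of
#' non-planted unordered pairs called bidirectional (`fpr`), with the
#' any-class rate reported separately (`fpr_any`).
#'
#' @param hits Hit table from [call_hits()].
#' @param truth Truth table from [simulate_screen()].
#' @return A list with `sensitivity`, `sensitivity_both`,
#'   `sensitivity_single`, `fpr`, `fpr_any`, and `confusion` (planted
#'   orientation x called class contingency table).
#' @export
evaluate_recovery <- function(hits, truth) {
  hit_ids <- unique(c(hits$id_a, hits$id_b))
  if (!all(c(truth$id_a, truth$id_b) %in% hit_ids)) {
    stop("truth table references proteins absent from the hit table",
         call. = FALSE)
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  hit_key <- key(hits$id_a, hits$id_b)
  truth_key <- key(truth$id_a, truth$id_b)
  m <- match(truth_key, hit_key)
  called <- hits$class[m]
  expected <- ifelse(truth$orientation == "both", "bidirectional",
                     "unidirectional")
  recovered <- !is.na(called) & called == expected

  is_both <- truth$orientation == "both"
  planted <- hit_key %in% truth_key
  n_nonplanted <- sum(!planted)
  list(
    sensitivity = if (nrow(truth) > 0L) mean(recovered) else NA_real_,
    sensitivity_both = if (any(is_both)) mean(recovered[is_both])
                       else NA_real_,
    sensitivity_single = if (any(!is_both)) mean(recovered[!is_both])
                         else NA_real_,
    fpr = if (n_nonplanted > 0L)
      sum(hits$class == "bidirectional" & !planted) / n_nonplanted
      else NA_real_,
    fpr_any = if (n_nonplanted > 0L)
      sum(hits$class != "none" & !planted) / n_nonplanted
      else NA_real_,
    confusion = table(planted_orientation =
                        factor(truth$orientation,
                               levels = c("both", "ab", "ba")),
                      called = factor(called,
                                      levels = c("bidirectional",
                                                 "unidirectional",
                                                 "none"))))
}
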