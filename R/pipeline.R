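#' Run the full primary-screen analysis
#'
#' One-call orchestration of the hit-calling pipeline:
#' read the long-format screen, assemble the bait x prey matrix,
#' median-polish it, score the residuals in screen-wide MAD units,
#' call hits at the cutoff, summarize, and write all artifacts.
#' Deterministic for a fixed input and config.
#'
#' Artifacts written under `out_dir`: `residuals.tsv`, `scores.tsv`
#' (matrix TSVs), `row_effects.tsv` / `col_effects.tsv` /
#' `overall.tsv` (the polish decomposition), `hits.tsv` (edge list of
#' both hit classes), `summary.json` (hit counts and rates), and
#' `manifest.json` (config, package version, input checksum).
#'
#' @param input Path to a long-format screen table, or a records data
#'   frame as returned by [read_screen()] / [simulate_screen()].
#' @param out_dir Output directory (created if absent).
#' @param cutoff Score cutoff in MAD units (default 2.5).
#' @param max_iter,tol Median-polish convergence controls.
#' @param duplicate_policy Passed to [assemble_matrix()].
#' @param dialect Passed to [read_screen()] when `input` is a path.
#' @return Invisibly, a list with `matrix`, `polish`, `scores`,
#'   `hits`, `summary`, and `out_dir`.
#' @export
run_primary_analysis <- function(input, out_dir, cutoff = 2.5,
                                 max_iter = 500L, tol = 1e-8,
                                 duplicate_policy = "error",
                                 dialect = "tsv") {
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  records <- if (is.character(input)) {
    stage("read", read_screen(input, dialect = dialect))
  } else {
    stopifnot(is.data.frame(input))
    input
  }
  m <- stage("assemble", assemble_matrix(records, duplicate_policy))
  n_missing <- sum(is.na(m))
  if (n_missing > 0L) {
    message("matrix has ", n_missing, " unmeasured cell(s) of ",
            length(m))
  }
  polish <- stage("polish", median_polish(m, max_iter = max_iter,
                                          tol = tol))
  scores <- stage("score", score_residuals(polish$residuals))
  hits <- stage("call", call_hits(scores, cutoff = cutoff))
  summary <- summarize_hits(hits)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_polish(polish, out_dir)
  write_matrix(scores, file.path(out_dir, "scores.tsv"))
  write_edge_list(hits, file.path(out_dir, "hits.tsv"), which = "all")
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    pipeline = "primary_analysis",
    package_version = as.character(utils::packageVersion("ecia")),
    input = if (is.character(input)) normalizePath(input) else "<data frame>",
    input_md5 = if (is.character(input)) unname(tools::md5sum(input))
                else NA,
    n_records = nrow(records),
    config = list(cutoff = cutoff, max_iter = max_iter, tol = tol,
                  duplicate_policy = duplicate_policy,
                  dialect = dialect),
    polish = list(n_iterations = polish$n_iterations,
                  converged = polish$converged))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("primary analysis done in %.2fs: %d bidirectional, %d unidirectional of %d ordered tests",
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  summary$n_bidirectional, summary$n_unidirectional,
                  summary$n_ordered_tests))
  invisible(list(matrix = m, polish = polish, scores = scores,
                 hits = hits, summary = summary, out_dir = out_dir))
}

#' Run the retest validation stage
#'
#' Pairs the primary and retest screens, IQR-normalizes each, derives
#' the confirmation threshold from the primary bidirectional set,
#' confirms retest hits, and quantifies reproducibility by Spearman
#' correlation. Writes `validation.tsv` (per-pair normalized values,
#' geometric means, confirmed flag) and `validation_summary.json`
#' (threshold, confirmation rate, Spearman rho) under `out_dir`.
#'
#' @param primary,retest Long-format paths or records data frames for
#'   the two screens.
#' @param hits Primary hit table from [call_hits()] (or the result
#'   list of [run_primary_analysis()]).
#' @param out_dir Output directory.
#' @param joint Use joint (pooled) IQR normalization across the two
#'   screens instead of per-screen (default `FALSE`).
#' @param dialect Passed to [read_screen()] for path inputs.
#' @return Invisibly, the [confirm_hits()] result augmented with
#'   `spearman_rho` and `pairs`.
#' @export
run_validation <- function(primary, retest, hits, out_dir,
                           joint = FALSE, dialect = "tsv") {
  as_records <- function(x, name) {
    if (is.character(x)) read_screen(x, dialect = dialect)
    else { stopifnot(is.data.frame(x)); x }
  }
  if (is.list(hits) && !is.data.frame(hits) && !is.null(hits$hits)) {
    hits <- hits$hits
  }
  primary <- as_records(primary)
  retest <- as_records(retest)
  pairs <- pair_screens(primary, retest, hits)
  threshold <- derive_threshold(pairs, joint = joint)
  result <- confirm_hits(pairs, threshold, joint = joint)
  rho <- spearman_reproducibility(pairs, joint = joint)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  detail <- result$detail
  detail$primary_geo_mean <- format_num(detail$primary_geo_mean)
  detail$retest_geo_mean <- format_num(detail$retest_geo_mean)
  utils::write.table(detail, file.path(out_dir, "validation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(threshold = threshold,
         confirmation_rate = result$confirmation_rate,
         spearman_rho = rho,
         n_pairs = nrow(pairs),
         n_predicted_hits = sum(pairs$is_predicted_hit),
         n_confirmed = nrow(result$confirmed)),
    file.path(out_dir, "validation_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("validation: threshold %.6g, confirmation rate %.3f, Spearman rho %.3f",
                  threshold, result$confirmation_rate, rho))
  invisible(c(result, list(spearman_rho = rho, pairs = pairs)))
}
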