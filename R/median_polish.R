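#' Two-way median polish of an absorbance matrix
#'
#' Tukey's iterative additive decomposition of a two-way table,
#'
#' \deqn{y_{ij} = \mu + a_i + b_j + r_{ij},}
#'
#' fitted with medians so that a handful of genuinely interacting wells
#' cannot distort the background model. In a reciprocal interaction
#' screen the overall term \eqn{\mu} absorbs the assay-wide background
#' absorbance, the row effects \eqn{a_i} absorb the per-bait-preparation
#' background (expression level, stability, intrinsic stickiness), the
#' column effects \eqn{b_j} the per-prey-preparation background, and the
#' residuals \eqn{r_{ij}} carry the part of the signal attributable to a
#' physical interaction between bait i and prey j.
#'
#' Each sweep removes row medians into the row effects, re-centres the
#' column effects through the overall term, removes column medians into
#' the column effects, and re-centres the row effects (rows first, then
#' columns; the order is fixed because the fixed point of median polish
#' is not unique). Medians are taken over non-missing cells only;
#' missing cells are never imputed and stay missing in the residuals.
#' Iteration stops when the largest absolute median removed during a
#' full sweep is at most `tol`, or after `max_iter` sweeps.
#'
#' The additive identity `overall + row_effects[i] + col_effects[j] +
#' residuals[i, j] == m[i, j]` holds exactly (to floating point) after
#' every sweep, not only at convergence.
#'
#' @param m Numeric matrix, at least 2 x 2, with dimnames; `NA` cells
#'   allowed but every row and every column must contain at least one
#'   observed value.
#' @param max_iter Maximum number of full sweeps (default 500; sweep
#'   deltas shrink geometrically but typically cross `tol` only after
#'   roughly 100 sweeps at 50 x 50 and 300 at 200 x 200).
#' @param tol Convergence tolerance on the largest absolute median
#'   removed in a sweep, in absorbance units (default 1e-8).
#' @return An object of class `"polish_decomposition"`: a list with
#'   `overall` (scalar), `row_effects` and `col_effects` (named
#'   vectors), `residuals` (matrix, same shape and dimnames as `m`),
#'   `n_iterations`, `converged`, and `max_abs_change_last_iter`.
#' @seealso [reconstruct()] for the inverse, [score_residuals()] for
#'   the downstream MAD scoring.
#' @examples
#' m <- outer(c(0, 0.1, 0.3), c(0, 0.05, 0.2), "+") + 0.2
#' dimnames(m) <- list(paste0("B", 1:3), paste0("P", 1:3))
#' fit <- median_polish(m)
#' max(abs(fit$residuals))  # purely additive table: ~0
#' @export
median_polish <- function(m, max_iter = 500L, tol = 1e-8) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("matrix must be at least 2 x 2 (got ", nrow(m), " x ", ncol(m),
         ")", call. = FALSE)
  }
  stopifnot(max_iter >= 1L, tol > 0)
  empty_rows <- rownames(m)[rowSums(!is.na(m)) == 0L]
  if (length(empty_rows) > 0L) {
    stop("fully missing row(s): ", paste(empty_rows, collapse = ", "),
         call. = FALSE)
  }
  empty_cols <- colnames(m)[colSums(!is.na(m)) == 0L]
  if (length(empty_cols) > 0L) {
    stop("fully missing column(s): ", paste(empty_cols, collapse = ", "),
         call. = FALSE)
  }

  res <- m
  overall <- 0
  row_eff <- stats::setNames(numeric(nrow(m)), rownames(m))
  col_eff <- stats::setNames(numeric(ncol(m)), colnames(m))
  converged <- FALSE
  max_change <- Inf
  iter <- 0L

  for (iter in seq_len(max_iter)) {
    rdelta <- apply(res, 1L, stats::median, na.rm = TRUE)
    res <- res - rdelta
    row_eff <- row_eff + rdelta
    cshift <- stats::median(col_eff)
    col_eff <- col_eff - cshift
    overall <- overall + cshift

    cdelta <- apply(res, 2L, stats::median, na.rm = TRUE)
    res <- sweep(res, 2L, cdelta)
    col_eff <- col_eff + cdelta
    rshift <- stats::median(row_eff)
    row_eff <- row_eff - rshift
    overall <- overall + rshift

    max_change <- max(abs(rdelta), abs(cshift), abs(cdelta), abs(rshift))
    if (max_change <= tol) {
      converged <- TRUE
      break
    }
  }

  structure(list(overall = overall, row_effects = row_eff,
                 col_effects = col_eff, residuals = res,
                 n_iterations = iter, converged = converged,
                 max_abs_change_last_iter = max_change),
            class = "polish_decomposition")
}

#' @export
print.polish_decomposition <- function(x, ...) {
  cat("Two-way median polish decomposition\n")
  cat(sprintf("  %d baits x %d preys, overall effect %.6g\n",
              length(x$row_effects), length(x$col_effects), x$overall))
  cat(sprintf("  %d sweep(s), converged: %s (last max |change| %.3g)\n",
              x$n_iterations, x$converged, x$max_abs_change_last_iter))
  invisible(x)
}

#' Reconstruct the input matrix from a polish decomposition
#'
#' Adds the overall, row, column and residual components back together.
#' Used to verify the exact-additivity contract of [median_polish()];
#' missing cells stay missing.
#'
#' @param decomp A `"polish_decomposition"` object.
#' @return Numeric matrix equal (to floating point) to the polished input.
#' @export
reconstruct <- function(decomp) {
  stopifnot(inherits(decomp, "polish_decomposition"))
  decomp$overall + outer(decomp$row_effects, decomp$col_effects, "+") +
    decomp$residuals
}

#' Write polish decomposition artifacts
#'
#' Emits the decomposition as four TSV files under `dir`: a one-line
#' `overall.tsv` metadata file, `row_effects.tsv`, `col_effects.tsv`
#' and `residuals.tsv`.
#'
#' @param decomp A `"polish_decomposition"` object.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_polish <- function(decomp, dir) {
  stopifnot(inherits(decomp, "polish_decomposition"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- data.frame(overall = format_num(decomp$overall),
                     n_iterations = decomp$n_iterations,
                     converged = decomp$converged)
  utils::write.table(meta, file.path(dir, "overall.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  eff <- function(v, id_name) data.frame(id = names(v),
                                         effect = format_num(unname(v)))
  utils::write.table(eff(decomp$row_effects),
                     file.path(dir, "row_effects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(eff(decomp$col_effects),
                     file.path(dir, "col_effects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix(decomp$residuals, file.path(dir, "residuals.tsv"))
  invisible(dir)
}
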