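#' Median absolute deviation, in raw units
#'
#' The median of the absolute deviations of each value from the data
#' median: `median(|x - median(x)|)`. Deliberately applied without the
#' 1.4826 normal-consistency constant that `stats::mad()` uses by
#' default — the screen's scores and the 2.5 cutoff are expressed in
#' these raw MAD units, so users comparing against robust-z conventions
#' should divide by 1.4826.
#'
#' @param values Numeric vector with at least one finite value; `NA`s
#'   are dropped.
#' @return Non-negative scalar.
#' @examples
#' mad_raw(c(1, 2, 3, 4, 5))  # 1
#' @export
mad_raw <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) {
    stop("mad_raw() needs at least one finite value", call. = FALSE)
  }
  stats::median(abs(values - stats::median(values)))
}

#' Score polish residuals in screen-wide MAD units
#'
#' Centres every residual on the median of all non-missing residuals
#' pooled screen-wide and divides by their raw MAD ([mad_raw()]):
#'
#' \deqn{s_{ij} = (r_{ij} - \mathrm{median}(r)) / \mathrm{MAD}(r).}
#'
#' Median and MAD are pooled over the whole screen, not per row or
#' column — the polish has already removed row/column structure, and the
#' score expresses how far each well sits in the single screen-wide
#' residual distribution, whose right tail holds the true interactions.
#'
#' @param residuals Numeric residual matrix (from [median_polish()]);
#'   `NA` cells stay `NA`.
#' @return A numeric score matrix with the same shape and dimnames,
#'   with attributes `center` (the pooled median) and `spread` (the
#'   pooled MAD). By construction the pooled median of the scores is 0
#'   and their pooled MAD is 1.
#' @export
score_residuals <- function(residuals) {
  stopifnot(is.matrix(residuals), is.numeric(residuals))
  pooled <- residuals[!is.na(residuals)]
  if (length(pooled) == 0L) {
    stop("no non-missing residuals to score", call. = FALSE)
  }
  center <- stats::median(pooled)
  spread <- mad_raw(pooled)
  if (spread == 0) {
    stop("degenerate residual distribution: screen-wide MAD is 0, ",
         "scores are undefined", call. = FALSE)
  }
  scores <- (residuals - center) / spread
  attr(scores, "center") <- center
  attr(scores, "spread") <- spread
  scores
}

#' Call unidirectional and bidirectional interaction hits
#'
#' Classifies every unordered protein pair from an orientation-resolved
#' score matrix. For a pair \{A, B\} with bait-prey score `score_ab`
#' (A as bait) and prey-bait score `score_ba`:
#'
#' * the geometric-mean score `sqrt(score_ab * score_ba)` is defined
#'   only when both orientation scores are strictly positive — two
#'   below-median measurements must not multiply into a positive
#'   "hit", since true interactions live in the right tail only;
#' * `class = "bidirectional"` iff the geometric mean is defined and
#'   strictly exceeds `cutoff`;
#' * otherwise `class = "unidirectional"` iff the larger orientation
#'   score strictly exceeds `cutoff`;
#' * otherwise `class = "none"`.
#'
#' Self-pairs are measured in both directions in a single well, so
#' their single score serves as both orientation scores and as the
#' geometric mean. Pairs with one orientation missing can only be
#' unidirectional or none. The two hit classes are disjoint by
#' construction (bidirectional takes precedence).
#'
#' @param scores Square score matrix from [score_residuals()] with
#'   identical row and column identifier sets.
#' @param cutoff Positive score cutoff in MAD units; strict inequality.
#'   Default 2.5, the screen's fixed high-confidence cutoff.
#' @return A data frame (the hit table) with one row per unordered
#'   pair: `id_a`, `id_b` (lexicographically ordered), `score_ab`
#'   (id_a as bait), `score_ba` (id_b as bait), `geo_mean` (`NA` when
#'   undefined), and `class`; the cutoff used is stored in
#'   `attr(, "cutoff")`.
#' @export
call_hits <- function(scores, cutoff = 2.5) {
  stopifnot(is.matrix(scores), is.numeric(scores), cutoff > 0)
  ids <- rownames(scores)
  if (is.null(ids) || !identical(sort(ids), sort(colnames(scores)))) {
    stop("score matrix must be square with identical bait and prey ",
         "identifier sets", call. = FALSE)
  }
  scores <- scores[ids, ids, drop = FALSE]
  n <- length(ids)

  idx <- which(upper.tri(scores, diag = TRUE), arr.ind = TRUE)
  i <- idx[, 1L]
  j <- idx[, 2L]
  # ids are used as given; pair order (id_a, id_b) follows matrix order,
  # made lexicographic below
  id_a <- ids[i]
  id_b <- ids[j]
  s_ab <- scores[cbind(i, j)]  # id_a as bait
  s_ba <- scores[cbind(j, i)]  # id_b as bait
  flip <- id_a > id_b
  tmp <- id_a[flip]; id_a[flip] <- id_b[flip]; id_b[flip] <- tmp
  tmp <- s_ab[flip]; s_ab[flip] <- s_ba[flip]; s_ba[flip] <- tmp

  self <- id_a == id_b
  geo <- rep(NA_real_, length(id_a))
  both_pos <- !is.na(s_ab) & !is.na(s_ba) & s_ab > 0 & s_ba > 0
  geo[both_pos] <- sqrt(s_ab[both_pos] * s_ba[both_pos])
  geo[self] <- s_ab[self]

  max_score <- pmax(s_ab, s_ba, na.rm = TRUE)
  max_score[is.na(s_ab) & is.na(s_ba)] <- NA_real_
  cls <- rep("none", length(id_a))
  cls[!is.na(max_score) & max_score > cutoff] <- "unidirectional"
  cls[!is.na(geo) & geo > cutoff] <- "bidirectional"

  ord <- order(id_a, id_b)
  hits <- data.frame(id_a = id_a, id_b = id_b, score_ab = s_ab,
                     score_ba = s_ba, geo_mean = geo, class = cls,
                     stringsAsFactors = FALSE)[ord, ]
  rownames(hits) <- NULL
  attr(hits, "cutoff") <- cutoff
  hits
}

#' Summarize a hit table
#'
#' Counts the called interactions and relates them to the screen
#' design: the number of ordered tests is the number of measured wells,
#' and the number of unordered tests for a complete n x n screen is
#' `choose(n, 2) + n` (self-pairs are tested in both directions in a
#' single well, so they count once).
#'
#' @param hits Hit table from [call_hits()].
#' @return A list with `n_bidirectional`, `n_unidirectional`,
#'   `n_ordered_tests`, `n_unordered_tests`, `pct_unidirectional`
#'   (percent of ordered tests) and `pct_bidirectional` (percent of
#'   unordered tests), mirroring how screen-wide hit rates are
#'   conventionally quoted.
#' @export
summarize_hits <- function(hits) {
  self <- hits$id_a == hits$id_b
  n_ordered <- sum(!is.na(hits$score_ab)) + sum(!is.na(hits$score_ba[!self]))
  n_unordered <- nrow(hits)
  n_bi <- sum(hits$class == "bidirectional")
  n_uni <- sum(hits$class == "unidirectional")
  list(n_bidirectional = n_bi,
       n_unidirectional = n_uni,
       n_ordered_tests = n_ordered,
       n_unordered_tests = n_unordered,
       pct_unidirectional = if (n_ordered > 0) 100 * n_uni / n_ordered
                            else 0,
       pct_bidirectional = if (n_unordered > 0) 100 * n_bi / n_unordered
                           else 0)
}
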