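#' Interquartile-range normalization
#'
#' Robust standardization `(x - median(x)) / IQR(x)` with
#' `IQR = Q3 - Q1` under the linear-interpolation quantile rule
#' (`stats::quantile()` type 7, R's default). Applied to each screen's
#' raw absorbances separately, it puts the primary and retest screens
#' on a common scale so their values can be compared directly; the
#' result is invariant under positive affine transforms of the input.
#'
#' @param values Numeric vector of at least 4 finite values.
#' @return Numeric vector of normalized values, same length and order.
#' @examples
#' iqr_normalize(c(1, 2, 3, 4, 5))  # -1 -0.5 0 0.5 1
#' @export
iqr_normalize <- function(values) {
  if (sum(is.finite(values)) < 4L) {
    stop("iqr_normalize() needs at least 4 finite values", call. = FALSE)
  }
  iqr <- stats::IQR(values, na.rm = TRUE, type = 7L)
  if (iqr == 0) {
    stop("degenerate distribution: IQR is 0, normalization undefined",
         call. = FALSE)
  }
  (values - stats::median(values, na.rm = TRUE)) / iqr
}

#' Geometric mean of two orientation measurements
#'
#' `sqrt(ab * ba)` when both values are strictly positive, `NA`
#' otherwise — the same right-tail guard as in [call_hits()]: two
#' negative (below-median, after normalization) measurements must not
#' produce a positive geometric mean. For self-pairs pass the single
#' value as both arguments.
#'
#' @param ab,ba Numeric vectors (recycled): the bait-prey and
#'   prey-bait values.
#' @return Numeric vector of geometric means, `NA` where undefined.
#' @export
geo_mean_pair <- function(ab, ba) {
  out <- rep(NA_real_, length(ab))
  ok <- !is.na(ab) & !is.na(ba) & ab > 0 & ba > 0
  out[ok] <- sqrt(ab[ok] * ba[ok])
  out
}

#' Pair primary-screen and retest measurements
#'
#' Joins the two screens on ordered (bait, prey) wells and collapses to
#' unordered pairs carrying both orientations from both screens, plus a
#' flag marking pairs predicted as bidirectional hits in the primary
#' screen. Only pairs present (in at least one orientation) in both
#' screens are kept.
#'
#' @param primary,retest Long-format record data frames
#'   (`bait`/`prey`/`absorbance`, as from [read_screen()]).
#' @param hits Primary-screen hit table from [call_hits()].
#' @return A data frame with one row per unordered pair: `id_a`,
#'   `id_b`, `primary_ab`, `primary_ba`, `retest_ab`, `retest_ba`
#'   (raw absorbances; `_ab` has `id_a` as bait), and
#'   `is_predicted_hit`.
#' @export
pair_screens <- function(primary, retest, hits) {
  orient <- function(rec) {
    a <- pmin(rec$bait, rec$prey)
    b <- pmax(rec$bait, rec$prey)
    data.frame(id_a = a, id_b = b,
               orientation = ifelse(rec$bait == a, "ab", "ba"),
               absorbance = rec$absorbance, stringsAsFactors = FALSE)
  }
  spread <- function(rec, label) {
    o <- orient(rec)
    key <- paste(o$id_a, o$id_b, sep = "\r")
    ab <- o$absorbance[o$orientation == "ab"]
    names(ab) <- key[o$orientation == "ab"]
    ba <- o$absorbance[o$orientation == "ba"]
    names(ba) <- key[o$orientation == "ba"]
    pairs <- unique(key)
    out <- data.frame(key = pairs, stringsAsFactors = FALSE)
    out[[paste0(label, "_ab")]] <- unname(ab[pairs])
    out[[paste0(label, "_ba")]] <- unname(ba[pairs])
    # self-pairs are one well tested in both directions
    self <- sub("\r.*", "", pairs) == sub(".*\r", "", pairs)
    out[[paste0(label, "_ba")]][self] <- out[[paste0(label, "_ab")]][self]
    out
  }
  p <- spread(primary, "primary")
  r <- spread(retest, "retest")
  merged <- merge(p, r, by = "key")
  if (nrow(merged) == 0L) {
    stop("no unordered pairs are present in both screens", call. = FALSE)
  }
  parts <- strsplit(merged$key, "\r", fixed = TRUE)
  out <- data.frame(id_a = vapply(parts, `[`, "", 1L),
                    id_b = vapply(parts, `[`, "", 2L),
                    stringsAsFactors = FALSE)
  out <- cbind(out, merged[, setdiff(names(merged), "key")])
  hit_key <- paste(hits$id_a, hits$id_b, sep = "\r")[
    hits$class == "bidirectional"]
  out$is_predicted_hit <- paste(out$id_a, out$id_b, sep = "\r") %in% hit_key
  out <- out[order(out$id_a, out$id_b), ]
  rownames(out) <- NULL
  out
}

# IQR-normalize one screen's paired absorbances (both orientations
# pooled) and return per-pair geometric means; `joint` pools both
# screens' values into one normalization (fidelity of the joint variant
# to the original analysis is not claimed).
normalized_geo_means <- function(pairs, screen = c("primary", "retest"),
                                 joint = FALSE) {
  screen <- match.arg(screen)
  self <- pairs$id_a == pairs$id_b
  pool_one <- function(s) {
    ab <- pairs[[paste0(s, "_ab")]]
    ba <- pairs[[paste0(s, "_ba")]]
    c(ab, ba[!self])  # self-pair is a single well, pooled once
  }
  raw <- pool_one(screen)
  norm <- if (joint) {
    other <- setdiff(c("primary", "retest"), screen)
    both <- iqr_normalize(c(raw, pool_one(other)))
    both[seq_along(raw)]
  } else {
    iqr_normalize(raw)
  }
  n <- nrow(pairs)
  ab <- norm[seq_len(n)]
  ba <- ab
  ba[!self] <- norm[n + seq_len(sum(!self))]
  geo_mean_pair(ab, ba)
}

#' Derive the retest confirmation threshold from the primary screen
#'
#' IQR-normalizes the primary screen's paired absorbance values and
#' returns the smallest normalized geometric-mean absorbance among the
#' pairs called bidirectional in the primary screen — i.e. the
#' threshold for inclusion in the bidirectional set, expressed on the
#' normalized absorbance scale that the retest screen shares. This is
#' the only parameter-free reading of a "threshold for inclusion":
#' every included pair sits at or above it, and any retest pair
#' exceeding it would have made the set.
#'
#' @param pairs Paired measurements from [pair_screens()].
#' @param joint Logical; normalize primary and retest values jointly
#'   instead of per screen. Default `FALSE` (per-screen), the reading
#'   used throughout; the joint variant is exposed for sensitivity
#'   analysis only.
#' @return The threshold (scalar, normalized absorbance units).
#' @export
derive_threshold <- function(pairs, joint = FALSE) {
  geo <- normalized_geo_means(pairs, "primary", joint = joint)
  geo_hit <- geo[pairs$is_predicted_hit & !is.na(geo)]
  if (length(geo_hit) == 0L) {
    stop("no bidirectional primary hits with a defined normalized ",
         "geometric mean; threshold undefined", call. = FALSE)
  }
  min(geo_hit)
}

#' Confirm primary hits against the retest screen
#'
#' A retest pair is confirmed when its IQR-normalized retest
#' geometric-mean absorbance strictly exceeds `threshold`. The
#' confirmation rate is the confirmed fraction of the predicted
#' (primary bidirectional) hits present in the retest.
#'
#' @param pairs Paired measurements from [pair_screens()].
#' @param threshold Confirmation threshold from [derive_threshold()].
#' @param joint Logical; joint normalization variant (see
#'   [derive_threshold()]).
#' @return A list: `threshold`, `confirmed` (data frame of confirmed
#'   pair ids with their retest geometric means), `confirmation_rate`,
#'   and the per-pair table `detail` (normalized geometric means for
#'   both screens and the confirmed flag).
#' @export
confirm_hits <- function(pairs, threshold, joint = FALSE) {
  stopifnot(is.finite(threshold))
  geo_primary <- normalized_geo_means(pairs, "primary", joint = joint)
  geo_retest <- normalized_geo_means(pairs, "retest", joint = joint)
  confirmed <- !is.na(geo_retest) & geo_retest > threshold
  predicted <- pairs$is_predicted_hit
  rate <- if (sum(predicted) > 0L) sum(confirmed & predicted) /
    sum(predicted) else NA_real_
  detail <- data.frame(id_a = pairs$id_a, id_b = pairs$id_b,
                       primary_geo_mean = geo_primary,
                       retest_geo_mean = geo_retest,
                       is_predicted_hit = predicted,
                       confirmed = confirmed, stringsAsFactors = FALSE)
  list(threshold = threshold,
       confirmed = detail[confirmed, c("id_a", "id_b",
                                       "retest_geo_mean")],
       confirmation_rate = rate,
       detail = detail)
}

#' Spearman reproducibility between primary and retest screens
#'
#' Spearman rank correlation (ties by average rank) between the
#' IQR-normalized geometric-mean absorbances of the two screens, over
#' pairs where both are defined. Invariant under strictly monotone
#' transforms of either screen's values.
#'
#' @param pairs Paired measurements from [pair_screens()].
#' @param joint Logical; joint normalization variant.
#' @return Spearman's rho in \[-1, 1\].
#' @export
spearman_reproducibility <- function(pairs, joint = FALSE) {
  geo_p <- normalized_geo_means(pairs, "primary", joint = joint)
  geo_r <- normalized_geo_means(pairs, "retest", joint = joint)
  ok <- !is.na(geo_p) & !is.na(geo_r)
  if (sum(ok) < 3L) {
    stop("need at least 3 pairs with defined geometric means in both ",
         "screens", call. = FALSE)
  }
  stats::cor(geo_p[ok], geo_r[ok], method = "spearman")
}

#' Compare hit and negative-control value distributions
#'
#' Rank-based two-sample comparison (Mann-Whitney / Wilcoxon rank-sum)
#' between the values of called interactions and pooled negative
#' controls (prey-only wells). A confirmed hit set should separate from
#' the controls; values for non-interacting pairs should not.
#'
#' @param hit_values,control_values Non-empty numeric vectors.
#' @return A list with `U` (the Mann-Whitney U statistic for
#'   `hit_values` vs `control_values`), `p_value` (two-sided, with the
#'   normal approximation under ties), `n_hits` and `n_controls`.
#' @export
compare_distributions <- function(hit_values, control_values) {
  stopifnot(length(hit_values) > 0L, length(control_values) > 0L)
  wt <- suppressWarnings(stats::wilcox.test(hit_values, control_values,
                                            alternative = "two.sided",
                                            exact = FALSE, correct = FALSE))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       n_hits = length(hit_values), n_controls = length(control_values))
}
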