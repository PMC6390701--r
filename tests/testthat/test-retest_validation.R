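test_that("IQR normalization matches the hand-computed quantile oracle", {
  # median 3, Q1 2, Q3 4 under linear interpolation -> IQR 2
  expect_equal(iqr_normalize(c(1, 2, 3, 4, 5)),
               c(-1, -0.5, 0, 0.5, 1))
  # fixed point: already median 0, IQR 1
  x <- c(-1, -0.5, 0, 0.5, 1)
  expect_equal(iqr_normalize(x), x, tolerance = 1e-9)
  # affine invariance
  set.seed(21)
  y <- rnorm(40)
  expect_equal(iqr_normalize(3.7 * y + 11), iqr_normalize(y),
               tolerance = 1e-9)
  expect_error(iqr_normalize(c(1, 2, 3)), "at least 4")
  expect_error(iqr_normalize(rep(2, 10)), "IQR is 0")
})

test_that("geometric means require two positive orientation values", {
  expect_equal(geo_mean_pair(0.04, 0.25), 0.1)
  expect_true(is.na(geo_mean_pair(-0.1, 0.25)))
  expect_true(is.na(geo_mean_pair(0.1, 0)))
  expect_true(is.na(geo_mean_pair(-2, -8)))   # sqrt(16) must not appear
  expect_equal(geo_mean_pair(c(1, 4), c(4, NA)), c(2, NA))
})

test_that("screen pairing collapses orientations and flags predicted hits", {
  primary <- data.frame(bait = c("A", "B", "A", "C", "C"),
                        prey = c("B", "A", "C", "A", "C"),
                        absorbance = c(1.0, 1.2, 0.3, 0.25, 2.0))
  retest <- data.frame(bait = c("A", "B", "A", "C", "C"),
                       prey = c("B", "A", "C", "A", "C"),
                       absorbance = c(0.9, 1.1, 0.2, 0.2, 1.9))
  hits <- data.frame(id_a = c("A", "C"), id_b = c("B", "C"),
                     class = c("bidirectional", "bidirectional"))
  pairs <- pair_screens(primary, retest, hits)
  expect_equal(nrow(pairs), 3L)  # A-B, A-C, C-C
  ab <- pairs[pairs$id_a == "A" & pairs$id_b == "B", ]
  expect_equal(ab$primary_ab, 1.0)  # A as bait
  expect_equal(ab$primary_ba, 1.2)  # B as bait
  expect_equal(ab$retest_ab, 0.9)
  cc <- pairs[pairs$id_a == "C" & pairs$id_b == "C", ]
  expect_equal(cc$primary_ab, cc$primary_ba)  # self-pair: one well
  expect_equal(pairs$is_predicted_hit,
               c(TRUE, FALSE, TRUE))

  expect_error(pair_screens(primary,
                            data.frame(bait = "X", prey = "Y",
                                       absorbance = 1), hits),
               "no unordered pairs")
})

# paired two-screen fixture: protein i partners with protein n+1-i,
# giving n/2 unordered pairs measured in both orientations in both
# screens; the first n_hit_pairs pairs carry high absorbance in both
# orientations (the "bidirectional hit" stratum), the rest background
make_paired_fixture <- function(seed = 30, n = 40, n_hit_pairs = 5) {
  set.seed(seed)
  ids <- sprintf("P%02d", seq_len(n))
  partner <- rev(ids)
  pair_idx <- pmin(seq_len(n), n + 1L - seq_len(n))
  n_pairs <- n %/% 2L
  pair_base <- c(runif(n_hit_pairs, 0.8, 2.0),
                 runif(n_pairs - n_hit_pairs, 0.05, 0.3))
  well <- function() pmax(pair_base[pair_idx] + rnorm(n, 0, 0.03), 0.001)
  primary <- data.frame(bait = ids, prey = partner, absorbance = well())
  retest <- data.frame(bait = ids, prey = partner, absorbance = well())
  key <- data.frame(id_a = pmin(ids, partner), id_b = pmax(ids, partner))
  key <- key[!duplicated(key), ]
  key <- key[order(key$id_a), ]
  hits <- data.frame(id_a = key$id_a, id_b = key$id_b,
                     class = ifelse(seq_len(nrow(key)) <= n_hit_pairs,
                                    "bidirectional", "none"))
  list(primary = primary, retest = retest, hits = hits)
}

test_that("threshold is the minimum normalized geometric mean over hits", {
  fx <- make_paired_fixture()
  pairs <- pair_screens(fx$primary, fx$retest, fx$hits)
  thr <- derive_threshold(pairs)
  geo <- ecia:::normalized_geo_means(pairs, "primary")
  hit_geo <- geo[pairs$is_predicted_hit]
  expect_equal(thr, min(hit_geo, na.rm = TRUE))
  # every included hit sits at or above the threshold
  expect_true(all(hit_geo >= thr, na.rm = TRUE))
  # invariance under positive affine transform of raw absorbances
  fx2 <- fx
  fx2$primary$absorbance <- 4.2 * fx$primary$absorbance + 0.37
  pairs2 <- pair_screens(fx2$primary, fx2$retest, fx2$hits)
  expect_equal(derive_threshold(pairs2), thr, tolerance = 1e-9)

  no_hits <- fx$hits
  no_hits$class <- "none"
  expect_error(derive_threshold(pair_screens(fx$primary, fx$retest,
                                             no_hits)),
               "threshold undefined")
})

test_that("confirmation applies a strict threshold and is monotone", {
  fx <- make_paired_fixture()
  pairs <- pair_screens(fx$primary, fx$retest, fx$hits)
  thr <- derive_threshold(pairs)
  res <- confirm_hits(pairs, thr)
  expect_true(all(res$detail$retest_geo_mean[res$detail$confirmed] > thr,
                  na.rm = TRUE))
  expect_gte(res$confirmation_rate, 0)
  expect_lte(res$confirmation_rate, 1)
  # strict >: a pair exactly at the threshold is not confirmed
  at <- res$detail$retest_geo_mean
  res_at <- confirm_hits(pairs, max(at, na.rm = TRUE))
  expect_equal(nrow(res_at$confirmed), 0L)
  # monotone: raising the threshold never adds a confirmed pair
  grid <- sort(c(thr, thr * c(1.5, 3, 10)))
  prev <- NULL
  for (t in grid) {
    conf <- confirm_hits(pairs, t)$confirmed
    keys <- paste(conf$id_a, conf$id_b)
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})

test_that("Spearman reproducibility matches the rank oracle", {
  fx <- make_paired_fixture(seed = 31)
  pairs <- pair_screens(fx$primary, fx$retest, fx$hits)
  rho <- spearman_reproducibility(pairs)
  geo_p <- ecia:::normalized_geo_means(pairs, "primary")
  geo_r <- ecia:::normalized_geo_means(pairs, "retest")
  ok <- !is.na(geo_p) & !is.na(geo_r)
  expect_equal(rho, spearman_oracle(geo_p[ok], geo_r[ok]),
               tolerance = 1e-12)
  expect_gt(rho, 0.5)  # retest is a noisy replicate of primary

  # identical screens reproduce perfectly
  fx$retest <- fx$primary
  rho1 <- spearman_reproducibility(pair_screens(fx$primary, fx$retest,
                                                fx$hits))
  expect_equal(rho1, 1.0)

  # rank invariance under positive affine rescaling of either screen
  fx3 <- make_paired_fixture(seed = 32)
  p3 <- pair_screens(fx3$primary, fx3$retest, fx3$hits)
  fx3b <- fx3
  fx3b$primary$absorbance <- 5.5 * fx3$primary$absorbance + 0.2
  fx3b$retest$absorbance <- 0.3 * fx3$retest$absorbance + 1.1
  p3b <- pair_screens(fx3b$primary, fx3b$retest, fx3b$hits)
  expect_equal(spearman_reproducibility(p3b),
               spearman_reproducibility(p3), tolerance = 1e-9)

  # reversed ranking among the defined pairs flips the sign completely
  nn <- 16L
  idsr <- sprintf("Q%02d", seq_len(nn))
  partnerr <- rev(idsr)
  pidx <- pmin(seq_len(nn), nn + 1L - seq_len(nn))
  base_p <- c(1, 2, 3, 4, 0.10, 0.11, 0.12, 0.13)
  base_r <- c(4, 3, 2, 1, 0.10, 0.11, 0.12, 0.13)
  prim <- data.frame(bait = idsr, prey = partnerr,
                     absorbance = base_p[pidx])
  rev_retest <- data.frame(bait = idsr, prey = partnerr,
                           absorbance = base_r[pidx])
  no_hits <- data.frame(id_a = "Q01", id_b = "Q16", class = "none")
  expect_equal(spearman_reproducibility(
    pair_screens(prim, rev_retest, no_hits)), -1.0)
})

test_that("distribution comparison reproduces the brute-force U statistic", {
  # identical samples: U at its null mean, p maximal
  x <- c(1, 2, 3, 4, 5)
  res <- compare_distributions(x, x)
  expect_equal(res$U, length(x)^2 / 2)
  expect_equal(res$p_value, 1)
  # complete separation: U at its maximum
  res2 <- compare_distributions(c(10, 11, 12), c(1, 2))
  expect_equal(res2$U, 6)
  # shifted samples: U matches exhaustive pairwise counting
  set.seed(40)
  hits <- rnorm(25, 1, 0.5)
  ctrl <- rnorm(30, 0, 0.5)
  res3 <- compare_distributions(hits, ctrl)
  expect_equal(res3$U, u_oracle(hits, ctrl))
  expect_lt(res3$p_value, 0.01)
})
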