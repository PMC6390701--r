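# Independent brute-force oracles used to pin expected values.
# Deliberately naive transcriptions, kept separate from the package code.

# fixed-iteration two-way median sweep (no convergence logic)
polish_sweep_oracle <- function(m, n_iter = 500L) {
  overall <- 0
  re <- rep(0, nrow(m))
  ce <- rep(0, ncol(m))
  r <- m
  for (k in seq_len(n_iter)) {
    rd <- apply(r, 1, median, na.rm = TRUE)
    r <- r - rd
    re <- re + rd
    d <- median(ce)
    ce <- ce - d
    overall <- overall + d
    cd <- apply(r, 2, median, na.rm = TRUE)
    r <- r - matrix(cd, nrow(r), ncol(r), byrow = TRUE)
    ce <- ce + cd
    d <- median(re)
    re <- re - d
    overall <- overall + d
  }
  list(overall = overall, row_effects = re, col_effects = ce,
       residuals = r)
}

# median(|x - median(x)|) by explicit enumeration
mad_oracle <- function(x) {
  m <- median(x)
  devs <- sort(abs(x - m))
  n <- length(devs)
  if (n %% 2 == 1) devs[(n + 1) / 2] else mean(devs[n / 2 + c(0, 1)])
}

# Spearman rho as Pearson correlation of average ranks
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Mann-Whitney U by counting all (x, y) comparisons; ties count 1/2
u_oracle <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

# exhaustive reclassification of every unordered pair from a score
# matrix, straight from the hit-calling definitions
call_hits_oracle <- function(scores, cutoff) {
  ids <- rownames(scores)
  out <- list()
  for (a in ids) for (b in ids) {
    if (a > b) next
    s_ab <- scores[a, b]
    s_ba <- scores[b, a]
    if (a == b) {
      geo <- s_ab
    } else if (!is.na(s_ab) && !is.na(s_ba) && s_ab > 0 && s_ba > 0) {
      geo <- sqrt(s_ab * s_ba)
    } else {
      geo <- NA_real_
    }
    mx <- suppressWarnings(max(s_ab, s_ba, na.rm = TRUE))
    cls <- if (!is.na(geo) && geo > cutoff) {
      "bidirectional"
    } else if (is.finite(mx) && mx > cutoff) {
      "unidirectional"
    } else {
      "none"
    }
    out[[paste(a, b)]] <- data.frame(id_a = a, id_b = b, class = cls,
                                     stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# records data frame for a full matrix (helper, not an oracle)
matrix_to_records <- function(m) {
  data.frame(bait = rep(rownames(m), times = ncol(m)),
             prey = rep(colnames(m), each = nrow(m)),
             absorbance = as.vector(m), stringsAsFactors = FALSE)
}

# small labelled random matrix
rand_matrix <- function(n, p, seed, missing = 0L) {
  set.seed(seed)
  m <- matrix(rnorm(n * p, 0.3, 0.1), n, p,
              dimnames = list(sprintf("B%02d", 1:n),
                              sprintf("P%02d", 1:p)))
  if (missing > 0L) m[sample.int(n * p, missing)] <- NA
  m
}
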