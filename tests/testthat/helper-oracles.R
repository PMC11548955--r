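# independent brute-force oracles; these deliberately avoid the package's
# own code paths

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

oracle_midrank <- function(v) {
  # mid-ranks by explicit counting: 1 + #smaller + (#equal - 1)/2
  vapply(v, function(vi) 1 + sum(v < vi) + (sum(v == vi) - 1) / 2, 0)
}

oracle_spearman <- function(x, y)
  oracle_pearson(oracle_midrank(x), oracle_midrank(y))

oracle_size_factors <- function(counts) {
  ref <- which(apply(counts, 1, function(r) all(r > 0)))
  gm <- vapply(ref, function(g) prod(counts[g, ])^(1 / ncol(counts)), 0)
  vapply(seq_len(ncol(counts)), function(j)
    median(vapply(seq_along(ref), function(i) counts[ref[i], j] / gm[i], 0)),
    0)
}

# full-table dynamic program, no band, written recursively with memoization
oracle_dtw <- function(x, y) {
  n <- length(x); m <- length(y)
  memo <- matrix(NA_real_, n + 1, m + 1)
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    if (i == 0 || j == 0) return(Inf)
    if (!is.na(memo[i + 1, j + 1])) return(memo[i + 1, j + 1])
    v <- abs(x[i] - y[j]) + min(rec(i - 1, j), rec(i, j - 1), rec(i - 1, j - 1))
    memo[i + 1, j + 1] <<- v
    v
  }
  rec(n, m)
}

oracle_ccf <- function(x, y, L) {
  best <- NULL
  for (l in 0:L) {
    xs <- x[seq_len(length(x) - l)]
    ys <- y[seq.int(l + 1, length(y))]
    r <- oracle_pearson(xs, ys)
    if (is.null(best) || abs(r) > abs(best$r)) best <- list(r = r, lag = l)
  }
  best
}

# multiple correlation of y on the lag matrix via explicit normal equations
oracle_multiple_cor <- function(x, y, L) {
  T <- length(x)
  rows <- seq.int(L + 1, T)
  X <- cbind(1, vapply(0:L, function(j) x[rows - j], numeric(length(rows))))
  yt <- y[rows]
  beta <- solve(t(X) %*% X, t(X) %*% yt)
  fit <- drop(X %*% beta)
  sqrt(max(0, 1 - sum((yt - fit)^2) / sum((yt - mean(yt))^2)))
}

oracle_network_edges <- function(series, threshold) {
  ids <- rownames(series)
  out <- list()
  for (i in seq_len(nrow(series) - 1)) {
    for (j in seq.int(i + 1, nrow(series))) {
      r <- oracle_pearson(series[i, ], series[j, ])
      if (abs(r) >= threshold)
        out[[length(out) + 1]] <- data.frame(source = ids[i],
                                             target = ids[j], r = r)
    }
  }
  if (!length(out)) return(data.frame(source = character(0),
                                      target = character(0), r = numeric(0)))
  do.call(rbind, out)
}

# small builders used across test files
make_matrix <- function(values, times, reps, count_mode = TRUE,
                        features = sprintf("f%02d", seq_len(nrow(values)))) {
  dimnames(values) <- list(features, paste0(times, "_r", reps))
  omics_matrix(values, times, reps, count_mode = count_mode)
}

tiny_study <- function(seed = 42, G = 30L, T = 9L, R = 2L, ...) {
  gen_synthetic_study(G = G, T = T, R = R, n_drivers = 1L, lag = 1L,
                      seed = seed, ...)
}

write_tsv_fixture <- function(lines, path) {
  writeLines(lines, path)
  path
}
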