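test_that("size_factors reproduces the median-of-ratios worked example", {
  counts <- matrix(c(2, 4, 4, 8), 2, byrow = TRUE)
  expect_equal(unname(size_factors(counts)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-6)
  # identical columns
  same <- matrix(rep(c(3, 10, 40), 4), 3)
  expect_equal(unname(size_factors(same)), rep(1, 4))
})

test_that("size_factors matches the brute-force oracle on random counts", {
  set.seed(11)
  for (i in 1:5) {
    counts <- matrix(rpois(50 * 6, lambda = 60), 50, 6)
    counts[sample(300, 20)] <- 0
    expect_equal(unname(size_factors(counts)), oracle_size_factors(counts),
                 tolerance = 1e-10)
  }
})

test_that("size_factors agrees with DESeq2's estimator", {
  set.seed(12)
  counts <- matrix(rnbinom(80 * 6, mu = 100, size = 10), 80, 6,
                   dimnames = list(sprintf("g%02d", 1:80),
                                   sprintf("s%d", 1:6)))
  ours <- unname(size_factors(counts))
  theirs <- unname(DESeq2::estimateSizeFactorsForMatrix(counts))
  # DESeq2 takes the median on the log scale, so an even reference-gene
  # count interpolates the two middle ratios geometrically instead of
  # arithmetically; agreement is near-exact but not to machine precision
  expect_equal(ours, theirs, tolerance = 2e-3)
})

test_that("size_factors falls back to total counts when no reference gene", {
  counts <- matrix(c(0, 5, 5, 0), 2, byrow = TRUE)
  expect_warning(f <- size_factors(counts), "total-count")
  expect_equal(unname(f), c(1, 1))
})

test_that("size_factors track imposed depth scalings proportionally", {
  set.seed(13)
  base <- matrix(rnbinom(60 * 6, mu = 200, size = 10) + 1, 60, 6)
  cj <- c(0.5, 0.8, 1, 1.2, 1.6, 2)
  scaled <- round(sweep(base, 2, cj, `*`))
  f <- size_factors(scaled)
  ratio <- f / cj
  expect_lt(diff(range(ratio)) / mean(ratio), 0.1)
})

test_that("average_replicates averages normalized values per time point", {
  m <- make_matrix(matrix(c(10, 14), 1), c("T1", "T1"), c("1", "2"))
  expect_equal(unname(average_replicates(m)[1, ]), 12)
  expect_equal(unname(average_replicates(m, factors = c(1, 2))[1, ]), 8.5)
  # single replicate is the identity
  m1 <- make_matrix(matrix(1:3, 1), c("T1", "T2", "T3"), rep("1", 3))
  expect_equal(unname(average_replicates(m1)[1, ]), c(1, 2, 3))
})

test_that("average_replicates commutes with feature subsetting", {
  st <- tiny_study()
  full <- average_replicates(st$expression)
  sub <- st$expression
  keep <- c("g003", "g010", "g021")
  sub$values <- sub$values[keep, ]
  expect_equal(average_replicates(sub), full[keep, ])
})

test_that("align_timepoints keeps the shared time window", {
  g <- make_matrix(matrix(1:7, 1, dimnames = NULL) * 1.0,
                   paste0("T", 1:7), rep("1", 7))
  m7 <- make_matrix(matrix(seq(2, 14, 2), 1), paste0("T", 1:7), rep("1", 7),
                    count_mode = FALSE)
  expect_length(align_timepoints(g, m7)$time_points, 7L)

  m8 <- make_matrix(matrix(1:7, 1) * 1.0, paste0("T", 2:8), rep("1", 7),
                    count_mode = FALSE)
  expect_message(st <- align_timepoints(g, m8), "dropping")
  expect_equal(st$time_points, paste0("T", 2:7))

  dis <- make_matrix(matrix(1:3, 1) * 1.0, paste0("X", 1:3), rep("1", 3),
                     count_mode = FALSE)
  expect_error(align_timepoints(g, dis), "insufficient overlap")
})

test_that("count-mode gene series are log scale, normalized mode untouched", {
  st <- tiny_study()
  study <- align_timepoints(st$expression, st$metabolites)
  manual <- log1p(average_replicates(st$expression,
                                     size_factors(st$expression$values)))
  expect_equal(study$gene_series, manual)
  norm <- st$expression; norm$count_mode <- FALSE
  study2 <- align_timepoints(norm, st$metabolites)
  expect_equal(study2$gene_series, average_replicates(norm))
  expect_equal(unname(study2$size_factors), rep(1, ncol(norm$values)))
})

test_that("znorm matches the closed form and flags degeneracy", {
  z <- znorm(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  expect_false(attr(z, "degenerate"))
  zc <- znorm(c(5, 5, 5))
  expect_equal(as.numeric(zc), c(0, 0, 0))
  expect_true(attr(zc, "degenerate"))
  # idempotence on an already-normalized series
  expect_equal(as.numeric(znorm(as.numeric(z))), as.numeric(z),
               tolerance = 1e-12)
})

test_that("impute_missing interpolates and guards the missing fraction", {
  expect_equal(impute_missing(c(1, NA, 3)), c(1, 2, 3))
  expect_equal(impute_missing(c(NA, 2, 3)), c(2, 2, 3))
  expect_equal(impute_missing(c(1, 2, NA)), c(1, 2, 2))
  expect_error(impute_missing(rep(NA_real_, 5)), "missing")
  expect_error(impute_missing(c(1, NA, NA, NA, NA, 2, 3, 4, 5, 6)), "1/3")
})

test_that("metabolite NAs are imputed on the per-time series", {
  v <- matrix(c(1, NA, 3, 4, 5, 6), 1)
  m <- make_matrix(v, paste0("T", c(1, 1, 2, 2, 3, 3)),
                   rep(c("1", "2"), 3), count_mode = FALSE)
  g <- make_matrix(matrix(1:3, 1) * 1.0, paste0("T", 1:3), rep("1", 3))
  st <- align_timepoints(g, m)
  expect_equal(unname(st$metabolite_series[1, ]), c(1, 3.5, 5.5))
})
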