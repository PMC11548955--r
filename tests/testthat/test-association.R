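test_that("pearson and spearman handle the textbook cases", {
  expect_equal(pearson_score(c(1, 2, 3), c(2, 4, 6))$score, 1)
  expect_equal(pearson_score(c(1, 2, 3), c(3, 2, 1))$score, -1)
  expect_equal(spearman_score(c(1, 2, 3, 4), c(1, 8, 27, 64))$score, 1)
  expect_equal(spearman_score(c(1, 2, 3, 4), c(64, 27, 8, 1))$score, -1)
  d <- pearson_score(c(2, 2, 2), c(1, 2, 3))
  expect_true(d$degenerate)
  expect_equal(d$score, 0)
})

test_that("pearson/spearman match direct-formula oracles on 100 instances", {
  set.seed(21)
  for (i in 1:100) {
    x <- rnorm(20); y <- rnorm(20)
    expect_equal(pearson_score(x, y)$score, oracle_pearson(x, y),
                 tolerance = 1e-12)
    xt <- sample(1:6, 15, replace = TRUE)  # heavy ties
    yt <- sample(1:6, 15, replace = TRUE)
    if (sd(xt) == 0 || sd(yt) == 0) next
    expect_equal(spearman_score(xt, yt)$score, oracle_spearman(xt, yt),
                 tolerance = 1e-12)
  }
})

test_that("delay_embed lays out shadow-manifold coordinates", {
  e <- delay_embed(c(1, 2, 3, 4), E = 2, tau = 1)
  expect_equal(attr(e, "anchors"), 2:4)
  expect_equal(e, cbind(c(2, 3, 4), c(1, 2, 3)), ignore_attr = TRUE)
  e1 <- delay_embed(c(5, 6, 7), E = 1, tau = 1)
  expect_equal(unname(e1[, 1]), c(5, 6, 7))
  e3 <- delay_embed(1:6, E = 3, tau = 2)
  expect_equal(attr(e3, "anchors"), 5:6)
  expect_equal(e3, rbind(c(5, 3, 1), c(6, 4, 2)), ignore_attr = TRUE)
  expect_error(delay_embed(1:4, E = 3, tau = 2), "too short")
})

test_that("ccm self-map skill is near perfect on a logistic map", {
  p <- gen_coupled_logistic(100, r_x = 3.8, seed = 5)
  s <- ccm_score(p$x, p$x)
  expect_gte(s$score, 0.99)
  expect_equal(s$best_lag, 0L)
})

test_that("ccm flags degenerate input and rejects too-short series", {
  expect_true(ccm_score(rep(1, 20), rnorm(20))$degenerate)
  expect_true(ccm_score(rnorm(20), rep(2, 20))$degenerate)
  expect_error(ccm_score(rnorm(5), rnorm(5)), "too short")
})

test_that("ccm detects the planted direction in coupled logistic maps", {
  p <- gen_coupled_logistic(400, beta_xy = 0.8, beta_yx = 0, seed = 3)
  fwd <- ccm_score(p$x, p$y)
  rev <- ccm_score(p$y, p$x)
  expect_gte(fwd$score, 0.8)
  expect_gt(fwd$score, rev$score)
  expect_gt(fwd$delta_rho, 0)
})

test_that("ccm skill is non-decreasing in library size on average", {
  pos <- 0L
  for (seed in 1:20) {
    p <- gen_coupled_logistic(200, beta_xy = 0.8, seed = seed)
    prof <- ccm_score(p$x, p$y)$details$rho_by_lib
    if (cor(prof, as.numeric(names(prof)), method = "spearman") > 0)
      pos <- pos + 1L
  }
  expect_gt(pos, 10L)
})

test_that("granger recovers strong lag-1 coupling and flags degeneracy", {
  set.seed(22)
  x <- rnorm(300)
  y <- c(0, 0.9 * x[-300]) + rnorm(300, sd = 0.1)
  s <- granger_score(x, y, max_lag = 1)
  expect_gte(s$score, 0.99)
  expect_equal(s$best_lag, 1L)
  expect_true(granger_score(rep(1, 50), rnorm(50))$degenerate)
  expect_error(granger_score(rnorm(6), rnorm(6), max_lag = 5), NA)
  expect_error(granger_score(rnorm(3), rnorm(3), max_lag = 1), "short")
})

test_that("granger median score never decreases with coupling strength", {
  meds <- vapply(c(0, 0.25, 0.5, 0.75), function(a) {
    median(vapply(1:60, function(i) {
      p <- gen_var_pair(120, a_yx = a, seed = i * 7L)
      granger_score(p$x, p$y, 1)$score
    }, 0))
  }, 0)
  expect_true(all(diff(meds) >= 0))
})

test_that("cca equals the multiple correlation of y on the lag matrix", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  expect_equal(cca_score(x, x, max_lag = 0)$score, 1)
  set.seed(23)
  xr <- rnorm(40)
  y1 <- c(0, xr[-40])                       # y_t = x_{t-1}, noiseless
  expect_gte(cca_score(xr, y1, max_lag = 1)$score, 0.999)
  for (i in 1:20) {
    xx <- rnorm(30); yy <- rnorm(30)
    L <- sample(0:3, 1)
    expect_equal(cca_score(xx, yy, max_lag = L)$score,
                 oracle_multiple_cor(xx, yy, L), tolerance = 1e-8)
  }
})

test_that("dtw reproduces the hand-computed dynamic program", {
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 3)), 1)
  expect_equal(dtw_score(c(1, 5, 3, 7), c(1, 5, 3, 7))$score, 1)
  set.seed(24)
  for (i in 1:20) {
    a <- rnorm(30); b <- rnorm(30)
    expect_equal(dtw_distance(a, b), oracle_dtw(a, b))
  }
  # banded distance can only be >= the unconstrained one
  a <- rnorm(25); b <- rnorm(25)
  expect_gte(dtw_distance(a, b, band = 3), dtw_distance(a, b))
})

test_that("ccf finds the true lead and matches the lagged-Pearson oracle", {
  set.seed(25)
  x <- as.numeric(arima.sim(list(ar = 0.7), 60))
  y <- c(0, 0, x[1:58])                     # y_t = x_{t-2}
  s <- ccf_score(x, y, max_lag = 4)
  expect_equal(s$score, 1)
  expect_equal(s$best_lag, 2L)
  expect_equal(ccf_score(x, x, max_lag = 4)$best_lag, 0L)
  for (i in 1:20) {
    a <- rnorm(200); b <- rnorm(200)
    o <- oracle_ccf(a, b, 5)
    got <- ccf_score(a, b, max_lag = 5)
    expect_equal(got$score, o$r, tolerance = 1e-12)
    expect_equal(got$best_lag, o$lag)
  }
})

test_that("scores are invariant to positive affine maps of the gene", {
  set.seed(26)
  x <- as.numeric(arima.sim(list(ar = 0.6), 40))
  y <- as.numeric(arima.sim(list(ar = 0.6), 40))
  x2 <- 3.7 * x + 11
  pairs <- list(
    pearson = function(a) pearson_score(a, y)$score,
    spearman = function(a) spearman_score(a, y)$score,
    ccf = function(a) ccf_score(a, y, 2)$score,
    cca = function(a) cca_score(a, y, 1)$score,
    dtw = function(a) dtw_score(a, y)$score,
    ccm = function(a) ccm_score(a, y, max_lag = 1)$score)
  for (nm in names(pairs))
    expect_equal(pairs[[nm]](x2), pairs[[nm]](x), tolerance = 1e-8,
                 label = nm)
})

test_that("score_all_genes covers every gene and ignores gene order", {
  st <- tiny_study(seed = 31, G = 40)
  study <- align_timepoints(st$expression, st$metabolites)
  cfg <- pipeline_config("target_met", method = "ccf", max_lag = 2)
  sc <- score_all_genes(study, cfg)
  expect_length(sc, 40L)
  expect_true(all(is.finite(vapply(sc, function(a) a$score, 0))))

  # permuting the gene rows leaves every per-gene score unchanged
  perm <- sample(rownames(study$gene_series))
  study2 <- study
  study2$gene_series <- study$gene_series[perm, ]
  sc2 <- score_all_genes(study2, cfg)
  expect_equal(vapply(sc2, function(a) a$score, 0)[names(sc)],
               vapply(sc, function(a) a$score, 0))

  # a gene identical to the target trajectory scores 1 under pearson
  study3 <- study
  study3$gene_series["g005", ] <- study$metabolite_series["target_met", ]
  cfg_p <- pipeline_config("target_met", method = "pearson")
  expect_equal(score_all_genes(study3, cfg_p)[["g005"]]$score, 1)

  cfg_bad <- pipeline_config("target_metX", method = "pearson")
  expect_error(score_all_genes(study, cfg_bad), "target_met")
})
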