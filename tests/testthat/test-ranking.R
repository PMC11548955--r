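test_that("find_peak pinpoints peak and decline, with the end-point rule", {
  p <- find_peak(c(1, 3, 2))
  expect_equal(p$t_peak, 2L)
  expect_equal(p$t_decline, 3L)
  # first index wins on ties
  expect_equal(find_peak(c(1, 3, 3, 2))$t_peak, 2L)
  # peak at the last point falls back with a warning
  expect_warning(pe <- find_peak(c(1, 2, 5)), "last time point")
  expect_equal(pe$t_peak, 2L)
  expect_equal(pe$t_decline, 3L)
  # ... to the latest interior local maximum when one exists
  expect_warning(pl <- find_peak(c(1, 4, 2, 3, 2, 5)), "last")
  expect_equal(pl$t_peak, 4L)
  expect_error(find_peak(c(2, 2, 2)), "no peak")
})

test_that("log2_fold_change matches the worked arithmetic", {
  counts <- matrix(c(8, 8, 2, 2,
                     5, 5, 5, 5,
                     0, 0, 7, 7), 3, byrow = TRUE)
  m <- make_matrix(counts, c("T1", "T1", "T2", "T2"), c("1", "2", "1", "2"))
  peak <- list(t_peak = 1L, t_decline = 2L)
  fc <- log2_fold_change(m, peak = peak, pseudocount = 1)
  expect_equal(unname(fc), c(log2(9 / 3), 0, log2(1 / 8)))
  # size factors rescale the means
  fc2 <- log2_fold_change(m, factors = c(2, 2, 1, 1), peak = peak)
  expect_equal(unname(fc2[1]), log2((4 + 1) / (2 + 1)))
})

test_that("minmax and cat_score follow their closed forms", {
  expect_equal(minmax(c(2, 4, 6)), c(0, 0.5, 1))
  expect_warning(z <- minmax(c(3, 3)), "constant")
  expect_equal(z, c(0, 0))
  expect_warning(s1 <- minmax(7), "constant")
  expect_equal(s1, 0)
  expect_equal(cat_score(1, 1), sqrt(2))
  expect_equal(cat_score(0, 0), 0)
  expect_equal(cat_score(0.6, 0.8), 1)
  expect_error(cat_score(1.2, 0), "\\[0, 1\\]")
})

test_that("annotation_bonus applies ordered first-match rules", {
  expect_equal(annotation_bonus("acyl-transferase"), 0.2)
  expect_equal(annotation_bonus("Hypothetical Protein"), 0.1)
  expect_equal(annotation_bonus("ribosomal protein L3"), 0)
  expect_equal(annotation_bonus(c("", NA, "EC 2.3.1")), c(0, 0, 0.2))
  # first matching rule wins even when later rules also match
  rules <- list(list(pattern = "protein", bonus = 0.5),
                list(pattern = "hypothetical", bonus = 0.1))
  expect_equal(annotation_bonus("hypothetical protein", rules), 0.5)
})

test_that("rank_genes orders by final score with documented tie-breaks", {
  cfg <- pipeline_config("m", method = "pearson", top_n_agent = 3L)
  s <- c(a = 0.9, b = 0.9, c = 0.1, d = -0.5)
  f <- c(a = 2, b = 2, c = 0.5, d = 1)
  r <- rank_genes(s, f, NULL, cfg)
  expect_equal(r$rank, 1:4)
  # identical metrics: alphabetical gene id
  expect_equal(r$gene_id[1:2], c("a", "b"))
  # negative association clamps to zero before normalization
  expect_equal(r$norm_score[r$gene_id == "d"], 0)
  expect_length(attr(r, "agent_payload"), 3L)
  flt <- attr(r, "filtered")
  expect_setequal(flt$gene_id, c("a", "b"))

  expect_error(rank_genes(s, f[-1], NULL, cfg), "differ")
})

test_that("ranking is invariant to a constant shift of the raw scores", {
  set.seed(41)
  cfg <- pipeline_config("m", method = "pearson")
  s <- setNames(runif(30), sprintf("g%02d", 1:30))
  f <- setNames(rnorm(30), names(s))
  r1 <- rank_genes(s, f, NULL, cfg)
  r2 <- rank_genes(s + 5, f, NULL, cfg)
  expect_equal(r2$gene_id, r1$gene_id)
  expect_equal(r2$cat_score, r1$cat_score)
})

test_that("final score responds monotonically to score and |fc|", {
  set.seed(42)
  cfg <- pipeline_config("m", method = "pearson")
  s <- setNames(runif(20, 0.05, 0.95), sprintf("g%02d", 1:20))
  f <- setNames(rnorm(20), names(s))
  base <- rank_genes(s, f, NULL, cfg)
  gid <- "g07"
  up_s <- s; up_s[gid] <- min(up_s[gid] + 0.02, max(up_s))  # stay inside range
  r_s <- rank_genes(up_s, f, NULL, cfg)
  expect_gte(r_s$final_score[r_s$gene_id == gid],
             base$final_score[base$gene_id == gid])
  up_f <- f; up_f[gid] <- sign(f[gid]) * (abs(f[gid]) + 0.05)
  r_f <- rank_genes(s, up_f, NULL, cfg)
  expect_gte(r_f$final_score[r_f$gene_id == gid],
             base$final_score[base$gene_id == gid])
})

test_that("an absent annotation table equals an empty one", {
  set.seed(43)
  cfg <- pipeline_config("m", method = "pearson")
  s <- setNames(runif(25), sprintf("g%02d", 1:25))
  f <- setNames(rnorm(25), names(s))
  r0 <- rank_genes(s, f, NULL, cfg)
  r1 <- rank_genes(s, f, setNames(character(0), character(0)), cfg)
  expect_equal(r1, r0, ignore_attr = TRUE)
  expect_true(all(r0$bonus == 0))
})

test_that("annotation bonuses lift matching genes in the final score", {
  cfg <- pipeline_config("m", method = "pearson")
  s <- c(g1 = 0.5, g2 = 0.5)
  f <- c(g1 = 1, g2 = 1)
  ann <- c(g1 = "terpene synthase")
  r <- rank_genes(s, f, ann, cfg)
  expect_equal(r$gene_id[1], "g1")
  expect_equal(r$bonus[r$gene_id == "g1"], 0.2)
  expect_equal(r$final_score[r$gene_id == "g1"] -
                 r$final_score[r$gene_id == "g2"], 0.2)
})

test_that("metabolite_network keeps the target's component only", {
  tt <- seq(0, 2 * pi, length.out = 12)
  m1 <- sin(tt)
  set.seed(44)
  series <- rbind(m1 = m1, m2 = 2 * m1, m3 = rnorm(12))
  net <- metabolite_network(series, "m1", threshold = 0.8)
  expect_equal(nrow(net), 1L)
  expect_equal(net$r, 1)
  expect_setequal(c(net$source, net$target), c("m1", "m2"))
  expect_equal(nrow(metabolite_network(series, "m1", threshold = 1.01)), 0L)

  # a tight pair not connected to the target is dropped
  series2 <- rbind(series, m4 = series["m3", ] + rnorm(12, sd = 0.01),
                   m5 = rnorm(12))
  net2 <- metabolite_network(series2, "m1", threshold = 0.8)
  expect_false(any(c("m3", "m4") %in% c(net2$source, net2$target)))

  # constant series are excluded with a warning
  series3 <- rbind(series, flat = rep(1, 12))
  expect_warning(net3 <- metabolite_network(series3, "m1"), "flat")
  expect_equal(net3, net)
})

test_that("metabolite_network agrees with the all-pairs oracle", {
  set.seed(45)
  series <- matrix(rnorm(10 * 12), 10, 12,
                   dimnames = list(sprintf("m%02d", 1:10), NULL))
  # low threshold makes the graph fully connected, so component
  # restriction is a no-op and the edge sets must match exactly
  net <- metabolite_network(series, "m01", threshold = 0.05)
  ora <- oracle_network_edges(series, 0.05)
  key <- function(d) sort(paste(d$source, d$target))
  expect_equal(key(net), key(ora))
  expect_equal(sort(net$r), sort(ora$r), tolerance = 1e-12)
})
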