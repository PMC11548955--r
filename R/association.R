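#' Association score container
#'
#' Every estimator returns one of these: the score that enters the CAT
#' vector, the selected lag (when the method is lag-aware), auxiliary
#' diagnostics and a degeneracy flag (constant input).
#'
#' @param method estimator name.
#' @param score numeric score.
#' @param best_lag selected lag, or `NA` for lag-blind methods.
#' @param p_value auxiliary p-value (Granger), or `NA`.
#' @param delta_rho CCM convergence `rho(L_max) - rho(L_min)`, or `NA`.
#' @param degenerate flag for constant/unscorable input.
#' @param details optional method-specific diagnostics list.
#' @return an `assoc_score` list.
#' @export
assoc_score <- function(method, score, best_lag = NA_integer_,
                        p_value = NA_real_, delta_rho = NA_real_,
                        degenerate = FALSE, details = NULL) {
  structure(list(method = method, score = score,
                 best_lag = if (is.na(best_lag)) NA_integer_
                            else as.integer(best_lag),
                 p_value = p_value, delta_rho = delta_rho,
                 degenerate = isTRUE(degenerate), details = details),
            class = "assoc_score")
}

#' @export
print.assoc_score <- function(x, ...) {
  cat(sprintf("assoc_score[%s]: %.4f (lag %s%s%s)\n", x$method, x$score,
              ifelse(is.na(x$best_lag), "n/a", x$best_lag),
              if (!is.na(x$p_value)) sprintf(", p=%.3g", x$p_value) else "",
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

check_pair <- function(x, y, min_t = 3L, stage = "association") {
  if (length(x) != length(y))
    ol_stop(stage, "series lengths differ (", length(x), " vs ",
            length(y), ")")
  if (length(x) < min_t)
    ol_stop(stage, "series too short: T = ", length(x), ", need >= ", min_t)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    ol_stop(stage, "series contain non-finite values")
  invisible(length(x))
}

#' Pearson correlation score
#'
#' @param x candidate cause series (gene expression over time).
#' @param y effect series (target metabolite concentration).
#' @return an [assoc_score()] with score in `[-1, 1]`, no lag.
#' @export
pearson_score <- function(x, y) {
  check_pair(x, y, 3L)
  if (sd(x) == 0 || sd(y) == 0)
    return(assoc_score("pearson", 0, degenerate = TRUE))
  assoc_score("pearson", cor(x, y))
}

#' Spearman correlation score (Pearson on mid-ranks, average-rank ties)
#' @inheritParams pearson_score
#' @export
spearman_score <- function(x, y) {
  check_pair(x, y, 3L)
  if (sd(x) == 0 || sd(y) == 0)
    return(assoc_score("spearman", 0, degenerate = TRUE))
  assoc_score("spearman", cor(x, y, method = "spearman"))
}

#' Delay embedding (shadow manifold coordinates)
#'
#' Row t holds `(s_t, s_{t-tau}, ..., s_{t-(E-1)tau})` — most recent
#' coordinate first — for every anchor t from `(E-1)*tau + 1` to `T`
#' (1-based). The anchor indices are attached as `attr(, "anchors")`.
#'
#' @param series numeric vector.
#' @param E embedding dimension (>= 1).
#' @param tau embedding delay (>= 1).
#' @return numeric matrix `n_anchors x E`.
#' @export
delay_embed <- function(series, E, tau) {
  T <- length(series)
  if (E < 1 || tau < 1) ol_stop("association", "E and tau must be >= 1")
  if (T <= (E - 1) * tau)
    ol_stop("association", "series too short for E=", E, ", tau=", tau)
  anchors <- seq.int((E - 1) * tau + 1L, T)
  emb <- vapply(seq_len(E) - 1L, function(j) series[anchors - j * tau],
                numeric(length(anchors)))
  emb <- matrix(emb, nrow = length(anchors), ncol = E)
  attr(emb, "anchors") <- anchors
  emb
}

#' CCM embedding parameters
#'
#' Defaults suit short longitudinal designs (7-29 time points): `E = 2`,
#' `tau = 1`, `k = E + 1` neighbors, and a library schedule of contiguous
#' prefixes from `E + 2` anchors up to all anchors. The step-1 schedule is
#' thinned to at most 40 evenly spaced sizes for long benchmark series
#' (min and max always kept, so the reported score and convergence delta
#' are unchanged).
#'
#' @param E embedding dimension.
#' @param tau embedding delay.
#' @param L_lib optional explicit library-size schedule.
#' @param max_libs cap on the schedule length before thinning.
#' @return an `embedding_params` list with fields `E`, `tau`, `k`, `L_lib`.
#' @export
embedding_params <- function(E = 2L, tau = 1L, L_lib = NULL, max_libs = 40L) {
  if (E < 1 || tau < 1) ol_stop("association", "E and tau must be >= 1")
  structure(list(E = as.integer(E), tau = as.integer(tau),
                 k = as.integer(E + 1L), L_lib = L_lib,
                 max_libs = as.integer(max_libs)),
            class = "embedding_params")
}

lib_schedule <- function(emb, n_anchor) {
  lmin <- emb$E + 2L
  if (!is.null(emb$L_lib)) {
    sizes <- sort(unique(as.integer(emb$L_lib)))
    sizes <- sizes[sizes >= lmin & sizes <= n_anchor]
    if (!length(sizes))
      ol_stop("association", "no valid library size in schedule")
    return(sizes)
  }
  if (n_anchor < lmin)
    ol_stop("association", "too few anchors (", n_anchor,
            ") for library minimum ", lmin)
  sizes <- seq.int(lmin, n_anchor)
  if (length(sizes) > emb$max_libs)
    sizes <- unique(round(seq(lmin, n_anchor, length.out = emb$max_libs)))
  sizes
}

#' Convergent cross-mapping score
#'
#' Tests "gene x drives metabolite y": the effect series y is
#' delay-embedded and the cause x is reconstructed from y's shadow manifold
#' by simplex-style weighted nearest neighbors. The score is the cross-map
#' skill rho (Pearson between x and its reconstruction) at the maximal
#' library for the best candidate lag; convergence is
#' `delta_rho = rho(L_max) - rho(L_min)` and should be positive for a true
#' causal direction. Candidate lag `l` shifts x back so that x at `t - l`
#' is tested against y at `t`; ties in skill resolve to the smallest lag.
#'
#' @inheritParams pearson_score
#' @param emb an [embedding_params()] object.
#' @param max_lag maximum candidate lag L (>= 0).
#' @return an [assoc_score()]; `details$rho_by_lib` carries the skill
#'   profile of the best lag.
#' @export
ccm_score <- function(x, y, emb = embedding_params(), max_lag = 0L) {
  T <- check_pair(x, y, (emb$E - 1L) * emb$tau + emb$E + 3L)
  if (sd(y) == 0 || sd(x) == 0)
    return(assoc_score("ccm", 0, best_lag = 0L, degenerate = TRUE))
  best <- NULL
  for (lag in 0:max_lag) {
    xs <- x[seq_len(T - lag)]
    ys <- y[seq.int(lag + 1L, T)]
    if (length(ys) <= (emb$E - 1L) * emb$tau + emb$E + 2L) break
    embm <- delay_embed(ys, emb$E, emb$tau)
    xa <- xs[attr(embm, "anchors")]
    sizes <- lib_schedule(emb, nrow(embm))
    rho <- .ccm_skill(embm, xa, sizes, emb$k)
    ok <- is.finite(rho)
    if (!any(ok)) next
    sc <- rho[max(which(ok))]
    if (is.null(best) || sc > best$score + 1e-12) {
      best <- list(score = sc, lag = lag,
                   delta = rho[max(which(ok))] - rho[min(which(ok))],
                   rho = rho, sizes = sizes)
    }
  }
  if (is.null(best))
    return(assoc_score("ccm", 0, best_lag = 0L, degenerate = TRUE))
  assoc_score("ccm", best$score, best_lag = best$lag,
              delta_rho = best$delta,
              details = list(rho_by_lib = setNames(best$rho, best$sizes)))
}

#' Granger causality score
#'
#' Nested OLS: the restricted model regresses `y_t` on its own lags
#' `1..p`, the unrestricted model adds lags of x; the block F-test p-value
#' is converted to `score = 1 - p`. The order p is chosen by AIC of the
#' unrestricted fit over `1..max_lag` (falling back to p = 1 with a message
#' when the series is too short for larger orders).
#'
#' @inheritParams pearson_score
#' @param max_lag maximum VAR order L (>= 1).
#' @return an [assoc_score()] with score in `[0, 1]`, `best_lag = p` and
#'   the F-test `p_value`.
#' @export
granger_score <- function(x, y, max_lag = 1L) {
  max_lag <- max(1L, as.integer(max_lag))
  T <- check_pair(x, y, 6L)
  if (sd(x) == 0 || sd(y) == 0)
    return(assoc_score("granger", 0, best_lag = NA_integer_,
                       degenerate = TRUE))
  # order p needs T - p rows and 2p + 1 coefficients, plus >= 1 df for F
  feasible <- Filter(function(p) (T - p) - (2L * p + 1L) >= 2L,
                     seq_len(max_lag))
  if (!length(feasible))
    ol_stop("association", "series too short for any Granger order <= ",
            max_lag)
  if (length(feasible) < max_lag)
    message("[association] Granger order capped at ", max(feasible),
            " by series length")
  fits <- lapply(feasible, function(p) granger_fit(x, y, p))
  aic <- vapply(fits, function(f) f$aic, 0)
  if (all(!is.finite(aic)))
    return(assoc_score("granger", 0, degenerate = TRUE))
  pick <- which.min(aic)
  f <- fits[[pick]]
  if (f$degenerate)
    return(assoc_score("granger", 0, best_lag = feasible[pick],
                       degenerate = TRUE))
  assoc_score("granger", 1 - f$p_value, best_lag = feasible[pick],
              p_value = f$p_value)
}

granger_fit <- function(x, y, p) {
  T <- length(y)
  rows <- seq.int(p + 1L, T)
  ylag <- vapply(seq_len(p), function(j) y[rows - j], numeric(length(rows)))
  xlag <- vapply(seq_len(p), function(j) x[rows - j], numeric(length(rows)))
  yt <- y[rows]
  n <- length(yt)
  Xr <- cbind(1, matrix(ylag, nrow = n))
  Xu <- cbind(Xr, matrix(xlag, nrow = n))
  fr <- lm.fit(Xr, yt); fu <- lm.fit(Xu, yt)
  rss_r <- sum(fr$residuals^2); rss_u <- sum(fu$residuals^2)
  df2 <- n - fu$rank
  if (fu$rank < ncol(Xu) || df2 < 1L || rss_u <= 0)
    return(list(aic = Inf, p_value = NA_real_, degenerate = TRUE))
  Fstat <- ((rss_r - rss_u) / p) / (rss_u / df2)
  list(aic = n * log(rss_u / n) + 2 * ncol(Xu),
       p_value = pf(Fstat, p, df2, lower.tail = FALSE), degenerate = FALSE)
}

#' Canonical correlation score over a lag matrix
#'
#' X collects columns `x_t, x_{t-1}, ..., x_{t-L}` on rows `t = L+1..T`;
#' with a univariate response the first canonical correlation equals the
#' multiple correlation coefficient of y on X (the square root of R^2).
#' A rank-deficient lag matrix is ridge-regularized
#' (`lambda = 1e-8 * trace(X'X)`) with a warning.
#'
#' @inheritParams pearson_score
#' @param max_lag number of lagged copies of x to include (L >= 0).
#' @return an [assoc_score()] with score in `[0, 1]`.
#' @export
cca_score <- function(x, y, max_lag = 0L) {
  L <- as.integer(max_lag)
  T <- check_pair(x, y, 2L * L + 3L)
  rows <- seq.int(L + 1L, T)
  X <- vapply(0:L, function(j) x[rows - j], numeric(length(rows)))
  X <- matrix(X, nrow = length(rows))
  yt <- y[rows]
  if (sd(yt) == 0 || all(apply(X, 2L, sd) == 0))
    return(assoc_score("cca", 0, best_lag = L, degenerate = TRUE))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- yt - mean(yt)
  G <- crossprod(Xc)
  qrX <- qr(Xc)
  if (qrX$rank < ncol(Xc)) {
    ol_warn("association", "rank-deficient lag matrix; ridge-regularized")
    G <- G + diag(1e-8 * sum(diag(G)), ncol(G))
  }
  beta <- solve(G, crossprod(Xc, yc))
  fit <- drop(Xc %*% beta)
  r2 <- sum(fit * yc) / sum(yc^2)
  assoc_score("cca", sqrt(max(0, min(1, r2))), best_lag = L)
}

#' Dynamic time warping distance (raw dynamic program)
#'
#' Classic DP with local cost `|x_i - y_j|`, steps (1,0), (0,1), (1,1), no
#' slope weights; optionally constrained to a Sakoe-Chiba band.
#'
#' @param x,y numeric vectors (not normalized here).
#' @param band optional band half-width in index units.
#' @return cumulative alignment cost at the end of both series.
#' @export
dtw_distance <- function(x, y, band = NULL) {
  n <- length(x); m <- length(y)
  if (n < 1L || m < 1L) ol_stop("association", "empty series")
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1L, 1L] <- 0
  ratio <- m / n
  for (i in seq_len(n)) {
    js <- seq_len(m)
    if (!is.null(band))
      js <- js[abs(js - i * ratio) <= band]
    if (!length(js)) ol_stop("association", "band too narrow")
    for (j in js) {
      cost <- abs(x[i] - y[j])
      D[i + 1L, j + 1L] <- cost + min(D[i, j + 1L], D[i + 1L, j], D[i, j])
    }
  }
  if (!is.finite(D[n + 1L, m + 1L]))
    ol_stop("association", "band too narrow for a complete path")
  D[n + 1L, m + 1L]
}

#' Dynamic time warping similarity score
#'
#' Both series are z-normalized (population sd) before alignment; the
#' distance D is mapped to `score = 1 / (1 + D/T)` in (0, 1].
#'
#' @inheritParams pearson_score
#' @param band optional Sakoe-Chiba band half-width.
#' @return an [assoc_score()]; `details$distance` holds D.
#' @export
dtw_score <- function(x, y, band = NULL) {
  T <- check_pair(x, y, 2L)
  zx <- znorm(x); zy <- znorm(y)
  degen <- isTRUE(attr(zx, "degenerate")) || isTRUE(attr(zy, "degenerate"))
  D <- dtw_distance(as.numeric(zx), as.numeric(zy), band = band)
  assoc_score("dtw", 1 / (1 + D / T), degenerate = degen,
              details = list(distance = D))
}

#' Cross-correlation function score (gene leads only)
#'
#' For each lag `l` in `0..max_lag` compute the Pearson correlation between
#' `x_{t-l}` and `y_t` over the overlapping window; the score is the value
#' of maximal absolute correlation, the best lag its `l` (smallest on
#' ties).
#'
#' @inheritParams pearson_score
#' @param max_lag maximum lead L (>= 0); requires `T - L >= 3`.
#' @return an [assoc_score()] with score in `[-1, 1]`.
#' @export
ccf_score <- function(x, y, max_lag = 0L) {
  L <- as.integer(max_lag)
  T <- check_pair(x, y, L + 3L)
  best <- NULL
  for (lag in 0:L) {
    xs <- x[seq_len(T - lag)]
    ys <- y[seq.int(lag + 1L, T)]
    if (length(xs) < 3L || sd(xs) == 0 || sd(ys) == 0) next
    r <- cor(xs, ys)
    if (is.null(best) || abs(r) > abs(best$r) + 1e-15)
      best <- list(r = r, lag = lag)
  }
  if (is.null(best))
    return(assoc_score("ccf", 0, best_lag = 0L, degenerate = TRUE))
  assoc_score("ccf", best$r, best_lag = best$lag)
}

#' Score every gene against the target metabolite
#'
#' Applies the configured estimator to each gene series versus the target
#' metabolite series of an aligned study. Degenerate genes are retained
#' with score 0 and the degenerate flag. Results are deterministic given
#' `cfg$seed` and independent of gene order.
#'
#' @param study an `aligned_study` from [align_timepoints()].
#' @param cfg a [pipeline_config()].
#' @return named list of [assoc_score()], one per gene.
#' @export
score_all_genes <- function(study, cfg) {
  stopifnot(inherits(study, "aligned_study"),
            inherits(cfg, "pipeline_config"))
  mets <- rownames(study$metabolite_series)
  if (!cfg$target_metabolite %in% mets) {
    near <- agrep(cfg$target_metabolite, mets, max.distance = 0.3,
                  value = TRUE)
    ol_stop("association", "unknown target metabolite '",
            cfg$target_metabolite, "'",
            if (length(near)) paste0("; did you mean: ",
                                     paste(head(near, 5L), collapse = ", "))
            else "")
  }
  target <- study$metabolite_series[cfg$target_metabolite, ]
  set.seed(cfg$seed)
  emb <- embedding_params(cfg$embedding_dim, cfg$embedding_delay)
  scorer <- switch(cfg$method,
    pearson  = function(g) pearson_score(g, target),
    spearman = function(g) spearman_score(g, target),
    ccm      = function(g) ccm_score(g, target, emb, cfg$max_lag),
    granger  = function(g) granger_score(g, target, max(1L, cfg$max_lag)),
    cca      = function(g) cca_score(g, target, cfg$max_lag),
    dtw      = function(g) dtw_score(g, target),
    ccf      = function(g) ccf_score(g, target, cfg$max_lag))
  res <- lapply(seq_len(nrow(study$gene_series)), function(i) {
    g <- study$gene_series[i, ]
    if (sd(g) == 0) return(assoc_score(cfg$method, 0, degenerate = TRUE))
    scorer(g)
  })
  names(res) <- rownames(study$gene_series)
  res
}
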