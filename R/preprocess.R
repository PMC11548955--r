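#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factors estimated the DESeq way: each
#' sample's factor is the median, over genes positive in every sample, of
#' the ratio between that sample's count and the gene's geometric mean.
#' When no gene is positive everywhere the function falls back to
#' total-count ratios (column sum over mean column sum) with a warning.
#'
#' @param counts non-negative numeric matrix, genes x samples.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "omics_matrix")) counts <- counts$values
  if (any(counts < 0)) ol_stop("preprocess", "counts must be non-negative")
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    ol_warn("preprocess",
            "no gene positive in all samples; using total-count factors")
    cs <- colSums(counts)
    if (any(cs <= 0)) ol_stop("preprocess", "all-zero sample column")
    return(cs / mean(cs))
  }
  logg <- log(counts[ref, , drop = FALSE])
  loggm <- rowMeans(logg)
  f <- apply(exp(logg - loggm), 2L, median)
  if (any(f <= 0)) ol_stop("preprocess", "non-positive size factor")
  f
}

#' Average replicates into a features x time matrix
#'
#' Cell (f, t) is the arithmetic mean over the replicates at time t of
#' `value / factor`. Factors default to 1 (metabolite intensities are never
#' depth-corrected; only expression counts are).
#'
#' @param m an [omics_matrix()].
#' @param factors optional per-sample positive reals, in the (canonical)
#'   sample order of `m`.
#' @param na.rm drop missing replicates from each per-time mean (a time
#'   point with no observed replicate yields `NaN`, for later imputation).
#' @return numeric matrix features x T with time labels as column names.
#' @export
average_replicates <- function(m, factors = NULL, na.rm = FALSE) {
  stopifnot(inherits(m, "omics_matrix"))
  if (is.null(factors)) factors <- rep(1, ncol(m$values))
  if (length(factors) != ncol(m$values) || any(factors <= 0))
    ol_stop("preprocess", "factors must be positive, one per sample")
  norm <- sweep(m$values, 2L, factors, `/`)
  tl <- factor(m$time, levels = m$time_order)
  if (any(tabulate(tl, nbins = length(m$time_order)) == 0L))
    ol_stop("preprocess", "time label with zero samples")
  out <- t(apply(norm, 1L, function(v) tapply(v, tl, mean, na.rm = na.rm)))
  # t() of a 1-time-point apply collapses; restore shape
  if (length(m$time_order) == 1L) out <- matrix(out, ncol = 1L)
  dimnames(out) <- list(rownames(m$values), m$time_order)
  out
}

#' Align two omics matrices on their shared time points
#'
#' Restricts both designs to the intersection of their time labels (kept in
#' the expression design's order), size-factor-normalizes and
#' replicate-averages the expression counts, replicate-averages the
#' metabolite intensities, and imputes any missing metabolite cells.
#'
#' @param genes expression [omics_matrix()] (count mode or normalized).
#' @param metabolites metabolite [omics_matrix()].
#' @return an `aligned_study` list with elements `time_points`,
#'   `gene_series` (genes x T), `metabolite_series` (metabolites x T),
#'   `size_factors`, and the time-restricted input matrices (`genes`,
#'   `metabolites`) kept for fold-change computation.
#' @export
align_timepoints <- function(genes, metabolites) {
  stopifnot(inherits(genes, "omics_matrix"),
            inherits(metabolites, "omics_matrix"))
  shared <- intersect(genes$time_order, metabolites$time_order)
  if (length(shared) < 3L)
    ol_stop("preprocess", "insufficient overlap: only ", length(shared),
            " shared time point(s), need >= 3")
  dropped <- c(setdiff(genes$time_order, shared),
               setdiff(metabolites$time_order, shared))
  if (length(dropped))
    message("[preprocess] dropping unshared time points: ",
            paste(unique(dropped), collapse = ", "))
  g <- subset_times(genes, shared)
  m <- subset_times(metabolites, shared)
  sf <- if (g$count_mode) size_factors(g$values) else rep(1, ncol(g$values))
  gser <- average_replicates(g, sf)
  # estimators see log-scale expression in count mode: correlation and
  # state-space methods behave badly on the heavy right skew of raw counts
  if (g$count_mode) gser <- log1p(gser)
  mser <- average_replicates(m, na.rm = TRUE)
  if (anyNA(mser) || any(!is.finite(mser)))
    mser <- t(apply(mser, 1L, function(v) {
      v[!is.finite(v)] <- NA_real_
      impute_missing(v)
    }))
  structure(list(time_points = shared, gene_series = gser,
                 metabolite_series = mser, size_factors = sf,
                 genes = g, metabolites = m),
            class = "aligned_study")
}

subset_times <- function(m, keep) {
  sel <- m$time %in% keep
  omics_matrix(m$values[, sel, drop = FALSE], m$time[sel], m$replicate[sel],
               time_order = keep, count_mode = m$count_mode)
}

#' z-normalize a series (population standard deviation)
#'
#' Population (1/T) sd is used so tiny series do not degenerate; a constant
#' series maps to all zeros and is flagged via `attr(, "degenerate")`.
#'
#' @param series numeric vector, length >= 2.
#' @return normalized vector, mean 0 and population sd 1 (or all zeros).
#' @export
znorm <- function(series) {
  if (length(series) < 2L) ol_stop("preprocess", "znorm needs length >= 2")
  mu <- mean(series)
  s <- sqrt(mean((series - mu)^2))
  if (s == 0) return(structure(rep(0, length(series)), degenerate = TRUE))
  structure((series - mu) / s, degenerate = FALSE)
}

#' Impute missing values in a time series
#'
#' Linear interpolation over the time index; leading/trailing `NA`s take the
#' nearest observed value. More than a third missing is an error (the
#' estimators need genuinely observed dynamics).
#'
#' @param series numeric vector with possible `NA`s.
#' @return complete numeric vector.
#' @export
impute_missing <- function(series) {
  ok <- is.finite(series)
  if (all(ok)) return(series)
  if (mean(!ok) > 1 / 3 + 1e-9)
    ol_stop("preprocess", "more than 1/3 of the series is missing")
  approx(x = which(ok), y = series[ok], xout = seq_along(series),
         method = "linear", rule = 2)$y
}
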