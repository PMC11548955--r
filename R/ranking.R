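#' Locate the target metabolite's peak and decline time points
#'
#' The peak is the time index of maximal mean concentration (first index on
#' ties); the decline point is the next sampled time point. When the
#' maximum sits at the final time point — so no decline point exists — the
#' peak is shifted back to the latest interior local maximum if there is
#' one, otherwise to the penultimate index, with a warning either way.
#'
#' @param target_series numeric vector (length >= 3) of per-time means.
#' @return list with 1-based `t_peak`, `t_decline`, and `shifted` flag.
#' @export
find_peak <- function(target_series) {
  T <- length(target_series)
  if (T < 3L) ol_stop("ranking", "need at least 3 time points")
  if (max(target_series) == min(target_series))
    ol_stop("ranking", "no peak: target series is constant")
  t_peak <- which.max(target_series)
  shifted <- FALSE
  if (t_peak == T) {
    interior <- seq.int(2L, T - 1L)
    locmax <- interior[target_series[interior] >= target_series[interior - 1L] &
                       target_series[interior] >= target_series[interior + 1L]]
    t_peak <- if (length(locmax)) max(locmax) else T - 1L
    shifted <- TRUE
    ol_warn("ranking", "target peaks at the last time point; using index ",
            t_peak, " so a decline point exists")
  }
  list(t_peak = t_peak, t_decline = t_peak + 1L, shifted = shifted)
}

#' Normalized log2 fold change between peak and decline time points
#'
#' For each gene: `log2((mean normalized count at peak + pc) /
#' (mean normalized count at decline + pc))`, where normalized means
#' count / size factor. A pseudocount `pc` (default 1) guards zeros.
#'
#' @param counts genes x samples matrix (or [omics_matrix()]).
#' @param factors per-sample size factors (default all 1).
#' @param time_labels per-sample time labels (taken from the
#'   `omics_matrix` when one is given).
#' @param peak a [find_peak()] result, or a list with `t_peak`/`t_decline`
#'   as 1-based indices into the ordered unique time labels.
#' @param time_order the total order of time labels (defaults to the
#'   matrix's own order).
#' @param pseudocount positive pseudocount.
#' @return named numeric vector of log2 fold changes, one per gene.
#' @export
log2_fold_change <- function(counts, factors = NULL, time_labels = NULL,
                             peak, time_order = NULL, pseudocount = 1) {
  if (inherits(counts, "omics_matrix")) {
    time_labels <- counts$time
    time_order <- time_order %||% counts$time_order
    counts <- counts$values
  }
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L,
                                             dimnames = list("gene", NULL))
  if (is.null(time_labels))
    ol_stop("ranking", "time_labels required for a plain matrix")
  time_order <- time_order %||% order_time_labels(unique(time_labels))
  if (pseudocount <= 0) ol_stop("ranking", "pseudocount must be positive")
  factors <- factors %||% rep(1, ncol(counts))
  norm <- sweep(counts, 2L, factors, `/`)
  lab_peak <- time_order[peak$t_peak]
  lab_dec <- time_order[peak$t_decline]
  sel_p <- time_labels == lab_peak
  sel_d <- time_labels == lab_dec
  if (!any(sel_p) || !any(sel_d))
    ol_stop("ranking", "peak/decline time points need >= 1 replicate each")
  mp <- rowMeans(norm[, sel_p, drop = FALSE])
  md <- rowMeans(norm[, sel_d, drop = FALSE])
  setNames(log2((mp + pseudocount) / (md + pseudocount)), rownames(counts))
}

#' Min-max normalization to [0, 1]
#'
#' `(v - min) / (max - min)`; an all-equal input (including a singleton)
#' maps to all zeros with a warning.
#'
#' @param values numeric vector, length >= 1.
#' @return numeric vector in `[0, 1]`.
#' @export
minmax <- function(values) {
  if (!length(values)) ol_stop("ranking", "empty input")
  if (anyNA(values)) ol_stop("ranking", "NA in values")
  rng <- range(values)
  if (rng[1] == rng[2]) {
    ol_warn("ranking", "constant input to min-max; returning zeros")
    return(rep(0, length(values)))
  }
  (values - rng[1]) / (rng[2] - rng[1])
}

#' CAT score: magnitude of the (association, fold-change) vector
#'
#' @param s_norm min-max-normalized association score(s) in `[0, 1]`.
#' @param f_norm min-max-normalized |log2 FC| in `[0, 1]`.
#' @return `sqrt(s_norm^2 + f_norm^2)`, in `[0, sqrt(2)]`.
#' @export
cat_score <- function(s_norm, f_norm) {
  if (any(s_norm < 0 | s_norm > 1) || any(f_norm < 0 | f_norm > 1))
    ol_stop("ranking", "cat_score inputs must lie in [0, 1]")
  sqrt(s_norm^2 + f_norm^2)
}

#' Rule-based annotation bonus
#'
#' The first matching rule's bonus applies; no match scores 0. With the
#' default rules enzymes earn 0.2 and unknown-function genes 0.1.
#'
#' @param description character vector of free-text gene descriptions.
#' @param rules ordered rule list, see [default_score_rules()].
#' @return numeric vector of bonuses in `[0, 1]`.
#' @export
annotation_bonus <- function(description, rules = default_score_rules()) {
  bonus <- rep(0, length(description))
  undecided <- !is.na(description) & nzchar(description)
  todo <- which(undecided)
  for (r in rules) {
    if (!length(todo)) break
    hit <- grepl(r$pattern, description[todo], ignore.case = TRUE)
    bonus[todo[hit]] <- r$bonus
    todo <- todo[!hit]
  }
  bonus
}

#' Heuristic CAT-score ranking of candidate genes
#'
#' Association scores are clamped at zero from below (or taken absolute in
#' `negative_mode`), fold changes enter as |log2 FC|; both are min-max
#' normalized across genes, combined into the CAT score, and the annotation
#' bonus is added. Genes sort by final score (ties: CAT score, then gene
#' id). The attributes carry the plain-text agent payload for the top
#' `cfg$top_n_agent` genes and the threshold-filtered sub-list.
#'
#' @param scores named list of [assoc_score()] (or named numeric vector).
#' @param fcs named numeric vector of raw log2 fold changes.
#' @param annotations named character vector from [read_annotation()], or
#'   `NULL` for no annotation file.
#' @param cfg a [pipeline_config()].
#' @return data.frame of RankedGene rows with attributes `agent_payload`
#'   (list of gene/final_score/description records) and `filtered`
#'   (data.frame of genes passing `assoc_threshold` and `fc_threshold`).
#' @export
rank_genes <- function(scores, fcs, annotations = NULL, cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.list(scores) && !is.data.frame(scores)) {
    s_raw <- vapply(scores, function(a) a$score, 0)
    lags <- vapply(scores, function(a)
      if (is.na(a$best_lag)) NA_integer_ else a$best_lag, 1L)
  } else {
    s_raw <- scores
    lags <- rep(NA_integer_, length(scores))
    names(lags) <- names(scores)
  }
  if (is.null(names(s_raw)) || is.null(names(fcs)))
    ol_stop("ranking", "scores and fcs must be named by gene id")
  if (!setequal(names(s_raw), names(fcs))) {
    diff <- c(setdiff(names(s_raw), names(fcs)),
              setdiff(names(fcs), names(s_raw)))
    ol_stop("ranking", "gene sets differ between scores and fold changes: ",
            paste(head(diff, 10L), collapse = ", "))
  }
  genes <- names(s_raw)
  f_raw <- fcs[genes]
  s_clamped <- if (cfg$negative_mode) abs(s_raw) else pmax(s_raw, 0)
  s_norm <- suppressWarnings(minmax(s_clamped))
  f_norm <- suppressWarnings(minmax(abs(f_raw)))
  cat <- cat_score(s_norm, f_norm)
  desc <- if (is.null(annotations)) rep("", length(genes))
          else unname(ifelse(genes %in% names(annotations),
                             annotations[genes], ""))
  bonus <- annotation_bonus(desc, cfg$score_rules)
  final <- cat + bonus
  ord <- order(-final, -cat, genes)
  df <- data.frame(rank = seq_along(genes), gene_id = genes[ord],
                   method = cfg$method, score = unname(s_raw[ord]),
                   best_lag = unname(lags[ord]),
                   log2fc = unname(f_raw[ord]),
                   norm_score = unname(s_norm[ord]),
                   norm_fc = unname(f_norm[ord]),
                   cat_score = unname(cat[ord]), bonus = bonus[ord],
                   final_score = unname(final[ord]), description = desc[ord],
                   stringsAsFactors = FALSE)
  top <- head(df, cfg$top_n_agent)
  payload <- lapply(seq_len(nrow(top)), function(i)
    list(gene_id = top$gene_id[i],
         final_score = top$final_score[i],
         description = top$description[i]))
  keep <- df$score >= cfg$assoc_threshold & abs(df$log2fc) >= cfg$fc_threshold
  attr(df, "agent_payload") <- payload
  attr(df, "filtered") <- df[keep, , drop = FALSE]
  df
}

#' Metabolite correlation network around the target
#'
#' Pearson correlations among replicate-averaged metabolite series; edges
#' with `|r| >= threshold` are kept, then the network is restricted to the
#' connected component containing the target (an isolated target yields an
#' empty edge list). Degenerate (constant) series are excluded with a
#' warning.
#'
#' @param metabolite_series metabolites x T numeric matrix with row names.
#' @param target row name of the target metabolite.
#' @param threshold absolute-correlation cutoff (default 0.8).
#' @return data.frame with columns `source`, `target`, `r`.
#' @export
metabolite_network <- function(metabolite_series, target, threshold = 0.8) {
  if (nrow(metabolite_series) < 2L)
    ol_stop("ranking", "need at least 2 metabolites for a network")
  if (!target %in% rownames(metabolite_series))
    ol_stop("ranking", "target '", target, "' not among the metabolites")
  sds <- apply(metabolite_series, 1L, sd)
  if (any(sds == 0)) {
    ol_warn("ranking", "excluding constant metabolite series: ",
            paste(rownames(metabolite_series)[sds == 0], collapse = ", "))
    metabolite_series <- metabolite_series[sds > 0, , drop = FALSE]
  }
  ids <- rownames(metabolite_series)
  empty <- data.frame(source = character(0), target = character(0),
                      r = numeric(0), stringsAsFactors = FALSE)
  if (!target %in% ids || length(ids) < 2L) return(empty)
  cm <- cor(t(metabolite_series))
  pairs <- which(upper.tri(cm) & abs(cm) >= threshold, arr.ind = TRUE)
  if (!nrow(pairs)) return(empty)
  edges <- data.frame(source = ids[pairs[, 1L]], target = ids[pairs[, 2L]],
                      r = cm[pairs], stringsAsFactors = FALSE)
  # connected component containing the target, by breadth-first search
  comp <- target
  frontier <- target
  while (length(frontier)) {
    nb <- unique(c(edges$target[edges$source %in% frontier],
                   edges$source[edges$target %in% frontier]))
    frontier <- setdiff(nb, comp)
    comp <- c(comp, frontier)
  }
  out <- edges[edges$source %in% comp & edges$target %in% comp, ,
               drop = FALSE]
  rownames(out) <- NULL
  out[order(-abs(out$r), out$source, out$target), , drop = FALSE]
}
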