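#' Construct an omics matrix
#'
#' The basic container for both transcript counts and metabolite
#' concentrations: a features x samples numeric matrix plus the longitudinal
#' design (one time label and one replicate tag per sample). Columns are
#' canonicalized to (time order, replicate order) so that file column order
#' never influences downstream scores.
#'
#' @param values numeric matrix, rows = features, columns = samples; row and
#'   column names required and unique. Missing cells are `NA`, never 0.
#' @param time per-sample time labels (character), same length as `ncol`.
#' @param replicate per-sample replicate tags (character).
#' @param time_order optional character vector giving the total order of the
#'   time labels; defaults to numeric-prefix order (so "T10" follows "T9").
#' @param count_mode logical; `TRUE` marks non-negative count data that will
#'   be size-factor normalized, `FALSE` marks already-normalized intensities.
#' @return an object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, time, replicate, time_order = NULL,
                         count_mode = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    ol_stop("io", "values must be a numeric matrix")
  fid <- rownames(values); sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    ol_stop("io", "values must carry feature (row) and sample (column) names")
  if (anyDuplicated(fid))
    ol_stop("io", "duplicated feature id: ",
            paste(unique(fid[duplicated(fid)]), collapse = ", "))
  if (anyDuplicated(sid))
    ol_stop("io", "duplicated sample id: ",
            paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (length(time) != ncol(values) || length(replicate) != ncol(values))
    ol_stop("io", "time/replicate labels must match the number of samples")
  time <- as.character(time); replicate <- as.character(replicate)
  if (anyDuplicated(paste(time, replicate)))
    ol_stop("io", "each sample must map to a unique (time, replicate) pair")
  if (is.null(time_order)) time_order <- order_time_labels(unique(time))
  if (!setequal(time_order, unique(time)))
    ol_stop("io", "time_order must cover exactly the observed time labels")
  if (count_mode) {
    if (anyNA(values))
      ol_stop("io", "count-mode matrix contains missing values")
    if (any(values < 0))
      ol_stop("io", "count-mode matrix contains negative values")
  }
  ord <- order(match(time, time_order), replicate)
  m <- structure(
    list(values = values[, ord, drop = FALSE],
         time = time[ord], replicate = replicate[ord],
         time_order = time_order, count_mode = count_mode),
    class = "omics_matrix")
  m
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix: %d features x %d samples (%d time points, %s)\n",
              nrow(x$values), ncol(x$values), length(x$time_order),
              if (x$count_mode) "count mode" else "normalized mode"))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

# order time labels by their first embedded number ("T10" > "T9"); labels
# without a number keep their appearance order, after the numbered ones
order_time_labels <- function(labels) {
  num <- suppressWarnings(as.numeric(sub("^[^0-9-]*(-?[0-9.]+).*$", "\\1",
                                         labels)))
  labels[order(is.na(num), num, seq_along(labels))]
}

sniff_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a features x samples matrix from delimited text
#'
#' First column holds feature ids, remaining columns one sample each. The
#' design is taken either from an explicit table (`design`) or from the
#' header convention `<time>_r<replicate>` (e.g. `T3_r2`).
#'
#' @param path CSV or TSV file (delimiter sniffed from the extension).
#' @param design optional data.frame with columns `sample`, `time`,
#'   `replicate` (and optionally `time_order` giving the rank of each time
#'   label); or a path to such a delimited file. When absent the header
#'   convention is used.
#' @param count_mode see [omics_matrix()].
#' @return an [omics_matrix()].
#' @export
read_matrix <- function(path, design = NULL, count_mode = TRUE) {
  if (!file.exists(path)) ol_stop("io", "cannot read file: ", path)
  raw <- read.delim(path, sep = sniff_delim(path), header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) ol_stop("io", "no features in ", path)
  fid <- as.character(raw[[1L]])
  if (anyDuplicated(fid))
    ol_stop("io", "duplicated feature id in ", basename(path), ": ",
            paste(unique(fid[duplicated(fid)]), collapse = ", "))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(apply(raw[, -1L, drop = FALSE], 2,
                                              as.numeric))) &
                   !is.na(as.matrix(raw[, -1L, drop = FALSE])),
                 arr.ind = TRUE)
    loc <- if (nrow(bad)) sprintf(" (row %s, column %s)", fid[bad[1, 1]],
                                  colnames(raw)[-1L][bad[1, 2]]) else ""
    ol_stop("io", "non-numeric cell in ", basename(path), loc)
  }
  rownames(vals) <- fid
  sid <- colnames(vals)

  if (is.character(design) && length(design) == 1L)
    design <- read.delim(design, sep = sniff_delim(design), header = TRUE,
                         stringsAsFactors = FALSE)
  if (is.null(design)) {
    m <- regmatches(sid, regexec("^(.*)_r([^_]+)$", sid))
    bad <- vapply(m, length, 1L) != 3L
    if (any(bad))
      ol_stop("io", "sample(s) not matching '<time>_r<replicate>' and no ",
              "design given: ", paste(sid[bad], collapse = ", "))
    time <- vapply(m, `[`, "", 2L)
    repl <- vapply(m, `[`, "", 3L)
    time_order <- NULL
  } else {
    need <- c("sample", "time", "replicate")
    if (!all(need %in% names(design)))
      ol_stop("io", "design needs columns: ", paste(need, collapse = ", "))
    idx <- match(sid, design$sample)
    if (anyNA(idx))
      ol_stop("io", "sample(s) without a design entry: ",
              paste(sid[is.na(idx)], collapse = ", "))
    time <- as.character(design$time[idx])
    repl <- as.character(design$replicate[idx])
    time_order <- if ("time_order" %in% names(design)) {
      u <- !duplicated(design$time)
      as.character(design$time[u][order(design$time_order[u])])
    } else NULL
  }
  omics_matrix(vals, time, repl, time_order = time_order,
               count_mode = count_mode)
}

#' Write an omics matrix back to delimited text
#'
#' Inverse of [read_matrix()] under the header convention; values are
#' printed at full precision (15 significant digits) so a round-trip
#' reproduces them to well under 1e-9 relative error.
#'
#' @param m an [omics_matrix()].
#' @param path output file; delimiter sniffed from the extension.
#' @param id_column name for the first (feature id) column.
#' @export
write_matrix <- function(m, path, id_column = "feature") {
  stopifnot(inherits(m, "omics_matrix"))
  df <- data.frame(id = rownames(m$values),
                   format(m$values, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  names(df)[-1L] <- paste0(m$time, "_r", m$replicate)
  write.table(df, path, sep = sniff_delim(path), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a gene functional-annotation table
#'
#' Two or more delimited columns: gene id, free-text description (extra
#' columns ignored, eggNOG-mapper style). Later duplicates of an id
#' overwrite earlier ones with a warning; a missing description becomes the
#' empty string. Genes absent from the table are treated as unannotated.
#'
#' @param path delimited text file; a `#`-prefixed header line is tolerated.
#' @return named character vector (names = gene ids, values = descriptions).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) ol_stop("io", "cannot read annotation: ", path)
  if (file.size(path) == 0L) return(setNames(character(0), character(0)))
  raw <- tryCatch(
    read.delim(path, sep = sniff_delim(path), header = FALSE,
               comment.char = "#", stringsAsFactors = FALSE,
               quote = "", colClasses = "character"),
    error = function(e) ol_stop("io", "unreadable annotation file: ",
                                conditionMessage(e)))
  if (nrow(raw) == 0L) return(setNames(character(0), character(0)))
  if (ncol(raw) < 2L) raw[[2L]] <- ""
  ids <- as.character(raw[[1L]])
  desc <- as.character(raw[[2L]])
  desc[is.na(desc)] <- ""
  if (anyDuplicated(ids)) {
    ol_warn("io", "duplicated gene id(s) in annotation, last entry wins: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
    keep <- !duplicated(ids, fromLast = TRUE)
    ids <- ids[keep]; desc <- desc[keep]
  }
  setNames(desc, ids)
}

#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline with the published defaults:
#' association/correlation threshold 0.5, fold-change threshold 1 (i.e.
#' 2-fold), agent payload of the top 100 genes, enzyme bonus 0.2 and
#' unknown-function bonus 0.1.
#'
#' @param target_metabolite feature id of the target metabolite.
#' @param method one of `"pearson"`, `"spearman"`, `"ccm"`, `"granger"`,
#'   `"cca"`, `"dtw"`, `"ccf"`.
#' @param max_lag maximum candidate lag L (integer >= 0) for the lag-aware
#'   estimators.
#' @param embedding_dim,embedding_delay CCM shadow-manifold parameters E and
#'   tau.
#' @param pseudocount added to both fold-change means (guards zeros).
#' @param score_rules ordered list of `list(pattern =, bonus =)` annotation
#'   rules; see [default_score_rules()].
#' @param assoc_threshold,fc_threshold filtering thresholds on the raw
#'   association score and on |log2 FC|.
#' @param top_n_agent number of top-ranked genes emitted in the agent
#'   payload.
#' @param count_mode `TRUE` if the expression matrix holds raw counts.
#' @param negative_mode if `TRUE` the CAT vector uses |score| instead of
#'   `max(score, 0)`, surfacing anticorrelated genes.
#' @param seed integer seed controlling any stochastic step.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(target_metabolite, method = "ccm", max_lag = 1L,
                            embedding_dim = 2L, embedding_delay = 1L,
                            pseudocount = 1, score_rules = default_score_rules(),
                            assoc_threshold = 0.5, fc_threshold = 1,
                            top_n_agent = 100L, count_mode = TRUE,
                            negative_mode = FALSE, seed = 1L) {
  methods <- c("pearson", "spearman", "ccm", "granger", "cca", "dtw", "ccf")
  if (!is.character(method) || length(method) != 1L || !method %in% methods)
    ol_stop("config", "method must be one of: ",
            paste(methods, collapse = ", "))
  if (max_lag < 0) ol_stop("config", "max_lag must be >= 0")
  if (embedding_dim < 1 || embedding_delay < 1)
    ol_stop("config", "embedding_dim and embedding_delay must be >= 1")
  if (pseudocount <= 0) ol_stop("config", "pseudocount must be positive")
  for (r in score_rules) {
    if (!is.list(r) || is.null(r$pattern) || is.null(r$bonus))
      ol_stop("config", "each score rule needs fields 'pattern' and 'bonus'")
    if (r$bonus < 0 || r$bonus > 1)
      ol_stop("config", "score-rule bonus must lie in [0,1]")
    ok <- tryCatch({grepl(r$pattern, "x", ignore.case = TRUE); TRUE},
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) ol_stop("config", "invalid regex in score rules: ", r$pattern)
  }
  structure(list(target_metabolite = target_metabolite, method = method,
                 max_lag = as.integer(max_lag),
                 embedding_dim = as.integer(embedding_dim),
                 embedding_delay = as.integer(embedding_delay),
                 pseudocount = pseudocount, score_rules = score_rules,
                 assoc_threshold = assoc_threshold,
                 fc_threshold = fc_threshold,
                 top_n_agent = as.integer(top_n_agent),
                 count_mode = isTRUE(count_mode),
                 negative_mode = isTRUE(negative_mode),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Default annotation scoring rules
#'
#' Enzyme-like descriptions earn a bonus of 0.2, unknown-function
#' descriptions 0.1; the first matching rule wins and anything else scores 0.
#' @return ordered list of `list(pattern =, bonus =)` rules.
#' @export
default_score_rules <- function() {
  list(
    list(pattern = paste0("synthase|synthetase|transferase|reductase|oxidase|",
                          "hydrolase|kinase|ligase|lyase|isomerase|",
                          "dehydrogenase|\\bEC[ :]?\\d"),
         bonus = 0.2),
    list(pattern = "unknown function|hypothetical protein|uncharacterized",
         bonus = 0.1)
  )
}

ranked_table_columns <- c("rank", "gene_id", "method", "score", "best_lag",
                          "log2fc", "norm_score", "norm_fc", "cat_score",
                          "bonus", "final_score", "description")

#' Write a ranked-gene table
#'
#' Fixed column schema (`rank, gene_id, method, score, best_lag, log2fc,
#' norm_score, norm_fc, cat_score, bonus, final_score, description`);
#' numbers printed with 6 significant digits.
#'
#' @param ranking data.frame from [rank_genes()], sorted by final score.
#' @param path output file (delimiter sniffed from the extension).
#' @export
write_ranked_table <- function(ranking, path) {
  if (!is.data.frame(ranking) ||
      !all(ranked_table_columns %in% names(ranking)))
    ol_stop("io", "ranking must carry the RankedGene columns")
  if (nrow(ranking)) {
    if (anyNA(ranking$final_score) || any(!is.finite(ranking$final_score)))
      ol_stop("io", "non-finite final scores cannot be ranked")
    if (is.unsorted(rev(ranking$final_score)))
      ol_stop("io", "ranking must be sorted by final score, descending")
  }
  out <- ranking[, ranked_table_columns]
  num <- vapply(out, is.numeric, TRUE) & !names(out) %in% c("rank", "best_lag")
  out[num] <- lapply(out[num], signif, digits = 6L)
  write.table(out, path, sep = sniff_delim(path), quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read back a ranked-gene table written by [write_ranked_table()]
#' @param path the file to read.
#' @return data.frame with the RankedGene columns.
#' @export
read_ranked_table <- function(path) {
  df <- read.delim(path, sep = sniff_delim(path), header = TRUE,
                   stringsAsFactors = FALSE)
  if (!all(ranked_table_columns %in% names(df)))
    ol_stop("io", "not a ranked table: ", path)
  df
}
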