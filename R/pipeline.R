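#' Run the full association pipeline
#'
#' read -> preprocess -> per-gene association -> fold change -> CAT-score
#' ranking -> metabolite network, writing `ranked_table.csv`,
#' `network_edges.tsv`, `agent_payload.json`, `manifest.json` and
#' best-effort PNG plots into `outdir`. Any stage error aborts with a
#' stage-tagged message and removes partial outputs. Reruns with identical
#' inputs and configuration produce byte-identical ranked tables.
#'
#' @param expression path to the expression matrix (or an
#'   [omics_matrix()]).
#' @param metabolites path to the metabolite matrix (or an
#'   [omics_matrix()]).
#' @param cfg a [pipeline_config()].
#' @param annotation optional annotation file path (or named character
#'   vector).
#' @param outdir output directory, created if needed.
#' @param design optional design table or file, passed to [read_matrix()].
#' @param network_threshold |r| cutoff for the metabolite network.
#' @return invisibly, a list with `ranking`, `network`, `peak`, `scores`,
#'   `study`, `manifest` and the output paths.
#' @export
run_pipeline <- function(expression, metabolites, cfg, annotation = NULL,
                         outdir = "omiclink_out", design = NULL,
                         network_threshold = 0.8) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t0 <- Sys.time()
  warnings_seen <- character(0)
  timings <- list()
  collect <- function(stage, expr) {
    tic <- Sys.time()
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e)
        ol_stop(stage, conditionMessage(e))),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    timings[[stage]] <<- round(as.numeric(Sys.time() - tic, units = "secs"),
                               3)
    res
  }
  made_dir <- !dir.exists(outdir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    if (made_dir) unlink(outdir, recursive = TRUE)
    stop(e)
  }

  tryCatch({
    hash_of <- function(p) if (is.character(p) && length(p) == 1L &&
                               file.exists(p))
      unname(tools::md5sum(p)) else NA_character_
    input_hashes <- list(expression = hash_of(expression),
                         metabolites = hash_of(metabolites),
                         annotation = hash_of(annotation))

    gm <- collect("read", {
      if (inherits(expression, "omics_matrix")) expression
      else read_matrix(expression, design = design,
                       count_mode = cfg$count_mode)
    })
    mm <- collect("read", {
      if (inherits(metabolites, "omics_matrix")) metabolites
      else read_matrix(metabolites, design = design, count_mode = FALSE)
    })
    ann <- collect("read", {
      if (is.null(annotation)) NULL
      else if (is.character(annotation) && length(annotation) == 1L &&
               file.exists(annotation)) read_annotation(annotation)
      else annotation
    })

    study <- collect("preprocess", align_timepoints(gm, mm))
    scores <- collect("association", score_all_genes(study, cfg))
    target <- study$metabolite_series[cfg$target_metabolite, ]
    peak <- collect("ranking", find_peak(target))
    fcs <- collect("ranking", log2_fold_change(
      study$genes, factors = study$size_factors, peak = peak,
      pseudocount = cfg$pseudocount))
    ranking <- collect("ranking", rank_genes(scores, fcs, ann, cfg))
    network <- collect("ranking", metabolite_network(
      study$metabolite_series, cfg$target_metabolite,
      threshold = network_threshold))

    path_rank <- file.path(outdir, "ranked_table.csv")
    path_net <- file.path(outdir, "network_edges.tsv")
    path_payload <- file.path(outdir, "agent_payload.json")
    path_manifest <- file.path(outdir, "manifest.json")
    written <- c(path_rank, path_net, path_payload, path_manifest)

    collect("write", {
      write_ranked_table(ranking, path_rank)
      write.table(network, path_net, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      jsonlite::write_json(attr(ranking, "agent_payload"), path_payload,
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
    plots <- pipeline_plots(outdir, study, ranking, peak, cfg)
    written <- c(written, plots)

    manifest <- list(
      package = "omiclink",
      version = as.character(utils::packageVersion("omiclink")),
      created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
      config = unclass(cfg),
      input_hashes = input_hashes,
      seed = cfg$seed,
      n_genes = nrow(study$gene_series),
      n_metabolites = nrow(study$metabolite_series),
      time_points = study$time_points,
      peak = peak[c("t_peak", "t_decline", "shifted")],
      timings_sec = timings,
      warnings = warnings_seen)
    jsonlite::write_json(manifest, path_manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)

    invisible(list(ranking = ranking, network = network, peak = peak,
                   scores = scores, study = study, manifest = manifest,
                   paths = list(ranked_table = path_rank,
                                network = path_net,
                                agent_payload = path_payload,
                                manifest = path_manifest, plots = plots)))
  }, error = on_fail)
}

# best-effort plots; failures never gate the run
pipeline_plots <- function(outdir, study, ranking, peak, cfg) {
  out <- character(0)
  target <- study$metabolite_series[cfg$target_metabolite, ]
  tp <- seq_along(study$time_points)
  safe_png <- function(name, draw) {
    p <- file.path(outdir, name)
    ok <- tryCatch({
      grDevices::png(p, width = 900, height = 600)
      on.exit(grDevices::dev.off(), add = TRUE)
      draw()
      TRUE
    }, error = function(e) FALSE)
    if (ok) out <<- c(out, p)
  }
  safe_png("target_trajectory.png", function() {
    plot(tp, target, type = "b", xaxt = "n", xlab = "time point",
         ylab = cfg$target_metabolite,
         main = "Target metabolite trajectory")
    graphics::axis(1, at = tp, labels = study$time_points)
    graphics::abline(v = peak$t_peak, col = "red", lty = 2)
    graphics::abline(v = peak$t_decline, col = "blue", lty = 3)
  })
  topk <- head(ranking$gene_id, 5L)
  safe_png("top_genes.png", function() {
    zt <- as.numeric(znorm(target))
    plot(tp, zt, type = "b", lwd = 2, xlab = "time point", ylab = "z-score",
         ylim = c(-3, 3), main = "Top-ranked genes vs target")
    for (i in seq_along(topk))
      graphics::lines(tp, as.numeric(znorm(study$gene_series[topk[i], ])),
                      col = i + 1)
    graphics::legend("topright", legend = c("target", topk), lwd = 1,
                     col = seq_len(length(topk) + 1), cex = 0.8)
  })
  safe_png("top_genes_heatmap.png", function() {
    k <- head(ranking$gene_id, 25L)
    mat <- t(apply(study$gene_series[k, , drop = FALSE], 1L,
                   function(v) as.numeric(znorm(v))))
    ord <- stats::hclust(stats::dist(mat))$order
    graphics::image(t(mat[rev(ord), , drop = FALSE]),
                    main = "Top genes (z-scored)", xaxt = "n", yaxt = "n")
  })
  safe_png("sample_pca.png", function() {
    lg <- log1p(sweep(study$genes$values, 2L, study$size_factors, `/`))
    keep <- apply(lg, 1L, sd) > 0
    pc <- stats::prcomp(t(lg[keep, , drop = FALSE]), scale. = FALSE)
    cols <- as.integer(factor(study$genes$time,
                              levels = study$genes$time_order))
    plot(pc$x[, 1L], pc$x[, 2L], col = cols, pch = 19, xlab = "PC1",
         ylab = "PC2", main = "Sample PCA (log normalized counts)")
  })
  out
}

#' Generate and write a synthetic study from the command line
#'
#' CLI-facing wrapper around [gen_synthetic_study()] +
#' [write_synthetic_study()].
#'
#' @inheritParams gen_synthetic_study
#' @param outdir output directory.
#' @return invisibly, the written file paths.
#' @export
cmd_simulate <- function(outdir, G = 100L, T = 13L, R = 3L, n_drivers = 1L,
                         lag = 1L, effect = 1, depth_spread = 0.25,
                         seed = 1L) {
  study <- gen_synthetic_study(G = G, T = T, R = R, n_drivers = n_drivers,
                               lag = lag, effect = effect,
                               depth_spread = depth_spread, seed = seed)
  write_synthetic_study(study, outdir)
}

#' Command-line entry point
#'
#' Implements the `run` and `simulate` subcommands; see
#' `inst/cli/omiclink.R` for the installed script. Exit codes: 0 success,
#' 2 usage error, 1 stage failure.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (integer), invisibly.
#' @export
omiclink_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0(
    "usage: omiclink run --expression FILE --metabolites FILE ",
    "--target ID [options]\n",
    "       omiclink simulate --outdir DIR [options]\n")
  if (!length(args)) { cat(usage); return(invisible(2L)) }
  sub <- args[[1L]]
  rest <- args[-1L]
  status <- tryCatch({
    if (sub == "run") cli_run(rest)
    else if (sub == "simulate") cli_simulate(rest)
    else { cat(usage); 2L }
  }, usage_error = function(e) { message(conditionMessage(e)); 2L },
     error = function(e) { message(conditionMessage(e)); 1L })
  invisible(status)
}

usage_stop <- function(...) {
  stop(structure(class = c("usage_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

cli_run <- function(args) {
  spec <- list(
    optparse::make_option("--expression", type = "character"),
    optparse::make_option("--metabolites", type = "character"),
    optparse::make_option("--annotation", type = "character",
                          default = NULL),
    optparse::make_option("--design", type = "character", default = NULL),
    optparse::make_option("--target", type = "character"),
    optparse::make_option("--method", type = "character", default = "ccm"),
    optparse::make_option("--lag", type = "integer", default = 1L),
    optparse::make_option("--embedding-dim", type = "integer", default = 2L,
                          dest = "embedding_dim"),
    optparse::make_option("--tau", type = "integer", default = 1L),
    optparse::make_option("--pseudocount", type = "double", default = 1),
    optparse::make_option("--top-n", type = "integer", default = 100L,
                          dest = "top_n"),
    optparse::make_option("--assoc-threshold", type = "double",
                          default = 0.5, dest = "assoc_threshold"),
    optparse::make_option("--fc-threshold", type = "double", default = 1,
                          dest = "fc_threshold"),
    optparse::make_option("--rules", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--normalized-mode", action = "store_true",
                          default = FALSE, dest = "normalized_mode"),
    optparse::make_option("--outdir", type = "character",
                          default = "omiclink_out"))
  opt <- tryCatch(
    optparse::parse_args(optparse::OptionParser(option_list = spec),
                         args = args),
    error = function(e) usage_stop("bad arguments: ", conditionMessage(e)))
  for (need in c("expression", "metabolites", "target"))
    if (is.null(opt[[need]])) usage_stop("missing required --", need)
  methods <- c("pearson", "spearman", "ccm", "granger", "cca", "dtw", "ccf")
  if (!opt$method %in% methods)
    usage_stop("unknown method '", opt$method, "'; valid methods: ",
               paste(methods, collapse = ", "))
  rules <- if (is.null(opt$rules)) default_score_rules() else {
    rl <- jsonlite::read_json(opt$rules, simplifyVector = FALSE)
    lapply(rl, function(r) list(pattern = r$pattern, bonus = r$bonus))
  }
  cfg <- pipeline_config(
    target_metabolite = opt$target, method = opt$method, max_lag = opt$lag,
    embedding_dim = opt$embedding_dim, embedding_delay = opt$tau,
    pseudocount = opt$pseudocount, score_rules = rules,
    assoc_threshold = opt$assoc_threshold, fc_threshold = opt$fc_threshold,
    top_n_agent = opt$top_n, count_mode = !opt$normalized_mode,
    seed = opt$seed)
  run_pipeline(opt$expression, opt$metabolites, cfg,
               annotation = opt$annotation, outdir = opt$outdir,
               design = opt$design)
  0L
}

cli_simulate <- function(args) {
  spec <- list(
    optparse::make_option("--outdir", type = "character",
                          default = "omiclink_sim"),
    optparse::make_option("--genes", type = "integer", default = 100L),
    optparse::make_option("--timepoints", type = "integer", default = 13L),
    optparse::make_option("--replicates", type = "integer", default = 3L),
    optparse::make_option("--drivers", type = "integer", default = 1L),
    optparse::make_option("--lag", type = "integer", default = 1L),
    optparse::make_option("--effect", type = "double", default = 1),
    optparse::make_option("--depth-spread", type = "double", default = 0.25,
                          dest = "depth_spread"),
    optparse::make_option("--seed", type = "integer", default = 1L))
  opt <- tryCatch(
    optparse::parse_args(optparse::OptionParser(option_list = spec),
                         args = args),
    error = function(e) usage_stop("bad arguments: ", conditionMessage(e)))
  res <- tryCatch(
    cmd_simulate(opt$outdir, G = opt$genes, T = opt$timepoints,
                 R = opt$replicates, n_drivers = opt$drivers,
                 lag = opt$lag, effect = opt$effect,
                 depth_spread = opt$depth_spread, seed = opt$seed),
    error = function(e) {
      if (grepl("must be|must lie", conditionMessage(e)))
        usage_stop(conditionMessage(e))
      stop(e)
    })
  message("wrote: ", paste(res, collapse = ", "))
  0L
}
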