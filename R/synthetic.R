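#' Coupled logistic maps (causality benchmark system)
#'
#' Two logistic maps with optional unidirectional or bidirectional
#' coupling:
#' `x[t+1] = x[t] * (r_x * (1 - x[t]) - beta_yx * y[t])`,
#' `y[t+1] = y[t] * (r_y * (1 - y[t]) - beta_xy * x[t])`,
#' so `beta_xy` is the strength of the x -> y influence. 100 burn-in steps
#' are discarded. Trajectories leaving [0, 1] abort with an error.
#'
#' @param N series length after burn-in.
#' @param r_x,r_y logistic growth rates, in [3.5, 4].
#' @param beta_xy,beta_yx coupling strengths in [0, 1).
#' @param x0,y0 initial conditions in (0, 1); drawn uniformly in
#'   (0.2, 0.8) from `seed` when `NULL`.
#' @param seed integer seed (only used for random initial conditions).
#' @return list with numeric vectors `x` and `y`, each length N.
#' @export
gen_coupled_logistic <- function(N, r_x = 3.8, r_y = 3.5, beta_xy = 0,
                                 beta_yx = 0, x0 = NULL, y0 = NULL,
                                 seed = 1L) {
  if (r_x < 3.5 || r_x > 4 || r_y < 3.5 || r_y > 4)
    ol_stop("synthetic", "growth rates must lie in [3.5, 4]")
  if (beta_xy < 0 || beta_xy >= 1 || beta_yx < 0 || beta_yx >= 1)
    ol_stop("synthetic", "couplings must lie in [0, 1)")
  set.seed(seed)
  x0 <- x0 %||% runif(1, 0.2, 0.8)
  y0 <- y0 %||% runif(1, 0.2, 0.8)
  if (x0 <= 0 || x0 >= 1 || y0 <= 0 || y0 >= 1)
    ol_stop("synthetic", "initial conditions must lie in (0, 1)")
  burn <- 100L
  n <- N + burn
  x <- numeric(n); y <- numeric(n)
  x[1L] <- x0; y[1L] <- y0
  for (t in seq_len(n - 1L)) {
    x[t + 1L] <- x[t] * (r_x * (1 - x[t]) - beta_yx * y[t])
    y[t + 1L] <- y[t] * (r_y * (1 - y[t]) - beta_xy * x[t])
    if (!is.finite(x[t + 1L]) || !is.finite(y[t + 1L]) ||
        x[t + 1L] < 0 || x[t + 1L] > 1 || y[t + 1L] < 0 || y[t + 1L] > 1)
      ol_stop("synthetic", "unstable parameters: trajectory left [0, 1]")
  }
  list(x = x[seq.int(burn + 1L, n)], y = y[seq.int(burn + 1L, n)])
}

#' Bivariate VAR(1) pair (Granger calibration system)
#'
#' `x[t] = a_xx * x[t-1] + e`, `y[t] = a_yx * x[t-1] + a_xx * y[t-1] + e'`
#' with independent Gaussian innovations; `a_yx = 0` gives a null pair.
#' 50 burn-in steps are discarded.
#'
#' @param N series length after burn-in.
#' @param a_xx autoregression coefficient (|a_xx| < 1 for stationarity).
#' @param a_yx cross coefficient (x -> y).
#' @param noise_sd innovation standard deviation.
#' @param seed integer seed.
#' @return list with numeric vectors `x` and `y`.
#' @export
gen_var_pair <- function(N, a_xx = 0.5, a_yx = 0, noise_sd = 1, seed = 1L) {
  if (abs(a_xx) >= 1)
    ol_stop("synthetic", "nonstationary parameters: |a_xx| must be < 1")
  set.seed(seed)
  burn <- 50L
  n <- N + burn
  ex <- rnorm(n, sd = noise_sd); ey <- rnorm(n, sd = noise_sd)
  x <- numeric(n); y <- numeric(n)
  for (t in seq.int(2L, n)) {
    x[t] <- a_xx * x[t - 1L] + ex[t]
    y[t] <- a_yx * x[t - 1L] + a_xx * y[t - 1L] + ey[t]
  }
  list(x = x[seq.int(burn + 1L, n)], y = y[seq.int(burn + 1L, n)])
}

# smooth latent gene trajectory: low-order random Fourier series over the
# design, standardized to sd 1
latent_trajectory <- function(T, n_harmonics = 3L) {
  tt <- seq_len(T) / T
  z <- numeric(T)
  for (h in seq_len(n_harmonics))
    z <- z + rnorm(1, sd = 1 / h) * sin(2 * pi * h * tt + runif(1, 0, 2 * pi))
  s <- sd(z)
  if (s == 0) z else z / s
}

# driver trajectory: a single logistic pulse (sharp induction, short
# plateau, shut-off), the canonical profile of a strongly induced
# biosynthetic gene over a developmental course
driver_pulse <- function(T) {
  t_on <- runif(1, 0.3 * T, 0.45 * T)
  t_off <- t_on + runif(1, 0.08 * T, 0.2 * T)
  w <- runif(1, 0.5, 1.0)
  tt <- seq_len(T)
  p <- 1 / (1 + exp(-(tt - t_on) / w)) * (1 - 1 / (1 + exp(-(tt - t_off) / w)))
  p / max(p)
}

#' Generate a synthetic longitudinal transcriptome + metabolome study
#'
#' Emulates the designs the pipeline targets: T time points with R
#' replicates, negative-binomial expression counts (fixed dispersion 0.1)
#' with log-normal per-sample depth factors, a small set of driver genes
#' whose smooth pulse trajectories drive the target metabolite through a
#' lagged saturating (Michaelis-Menten-style) response plus Gaussian noise,
#' independent smooth decoy genes, and decoy metabolites correlated with
#' the target at assorted strengths for network tests.
#'
#' @param G number of genes (>= 20).
#' @param T number of time points (5..40).
#' @param R replicates per time point (>= 1).
#' @param n_drivers number of driver genes (0 allowed: pure null study).
#' @param lag response lag in sampling steps (`lag < T/2`).
#' @param effect driver effect size: scales the driver pulse amplitude on
#'   the log-expression scale (1 = a strong, clearly induced gene).
#' @param depth_spread standard deviation of log depth factors.
#' @param noise_frac metabolite noise sd as a fraction of its dynamic
#'   range.
#' @param n_decoy_mets decoy metabolites in the metabolite matrix.
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param seed integer seed; regeneration with the same seed is
#'   bit-identical.
#' @return a `synthetic_study` list: `expression` and `metabolites`
#'   ([omics_matrix()] objects), `truth` (list of driver records with
#'   `gene`, `lag`, `effect`), `depth_factors`, `seed`.
#' @export
gen_synthetic_study <- function(G = 100L, T = 13L, R = 3L, n_drivers = 1L,
                                lag = 1L, effect = 1, depth_spread = 0.25,
                                noise_frac = 0.05, n_decoy_mets = 9L,
                                dispersion = 0.1, seed = 1L) {
  if (G < 20L) ol_stop("synthetic", "G must be >= 20")
  if (T < 5L || T > 40L) ol_stop("synthetic", "T must lie in 5..40")
  if (R < 1L) ol_stop("synthetic", "R must be >= 1")
  if (lag >= T / 2) ol_stop("synthetic", "lag must be < T/2")
  set.seed(seed)
  for (attempt in seq_len(10L)) {
    study <- try(gen_study_once(G, T, R, n_drivers, lag, effect,
                                depth_spread, noise_frac, n_decoy_mets,
                                dispersion, seed = NULL),
                 silent = TRUE)
    if (!inherits(study, "try-error")) {
      study$seed <- as.integer(seed)
      return(study)
    }
  }
  ol_stop("synthetic", "could not generate a non-constant target in 10 tries")
}

gen_study_once <- function(G, T, R, n_drivers, lag, effect, depth_spread,
                           noise_frac, n_decoy_mets, dispersion, seed) {
  genes <- sprintf("g%03d", seq_len(G))
  drivers <- if (n_drivers > 0L) genes[seq_len(n_drivers)] else character(0)
  base_log <- rnorm(G, mean = log(150), sd = 0.8)

  latent <- matrix(0, G, T, dimnames = list(genes, NULL))
  pulses <- matrix(0, max(n_drivers, 1L), T)
  for (i in seq_len(G)) {
    if (genes[i] %in% drivers) {
      # drivers swing ~ 3*effect natural-log units (a ~20-fold induction
      # at effect = 1) plus mild per-time biological noise
      p <- driver_pulse(T)
      pulses[match(genes[i], drivers), ] <- p
      latent[i, ] <- 3 * effect * (p - mean(p)) + rnorm(T, sd = 0.1)
    } else {
      # most transcriptome genes vary mildly over a time course: smooth
      # component with exponentially distributed amplitude (median ~0.3
      # natural-log units) plus per-time biological noise
      amp <- min(rexp(1, rate = 2.5), 2)
      latent[i, ] <- amp * latent_trajectory(T) + rnorm(T, sd = 0.15)
    }
  }

  # target metabolite: saturating (Michaelis-Menten-style) response to the
  # lagged driver signal; K = 0.7 keeps the response below full saturation
  if (n_drivers > 0L) {
    drive <- colSums(pulses[seq_len(n_drivers), , drop = FALSE])
    lagged <- c(rep(drive[1L], lag), drive)[seq_len(T)]
    conc <- 100 * lagged / (0.7 + lagged)
  } else {
    z <- latent_trajectory(T) + rnorm(T, sd = 0.3)
    conc <- 50 + 15 * z
  }
  rng <- diff(range(conc))
  if (rng < 1e-8) ol_stop("synthetic", "constant target")

  time_lab <- sprintf("T%02d", seq_len(T))
  sample_time <- rep(time_lab, each = R)
  sample_rep <- rep(paste0("", seq_len(R)), times = T)
  sample_ids <- paste0(sample_time, "_r", sample_rep)
  n_samp <- T * R

  depth <- exp(rnorm(n_samp, mean = 0, sd = depth_spread))
  mu <- exp(sweep(latent, 1L, base_log, `+`))           # G x T means
  counts <- matrix(0L, G, n_samp, dimnames = list(genes, sample_ids))
  for (j in seq_len(n_samp)) {
    tj <- match(sample_time[j], time_lab)
    counts[, j] <- rnbinom(G, size = 1 / dispersion, mu = depth[j] * mu[, tj])
  }

  met_ids <- c("target_met", sprintf("met%02d", seq_len(n_decoy_mets)))
  met_latent <- matrix(0, length(met_ids), T, dimnames = list(met_ids, NULL))
  met_latent["target_met", ] <- conc
  if (n_decoy_mets > 0L) {
    # decoys span strong mimics to independent metabolites
    alpha <- seq(0.95, 0, length.out = n_decoy_mets)
    for (d in seq_len(n_decoy_mets)) {
      indep <- latent_trajectory(T)
      zc <- as.numeric(znorm(conc))
      mix <- alpha[d] * zc + sqrt(1 - alpha[d]^2) * indep
      met_latent[d + 1L, ] <- 50 + 15 * mix
    }
  }
  mets <- matrix(0, length(met_ids), n_samp,
                 dimnames = list(met_ids, sample_ids))
  for (j in seq_len(n_samp)) {
    tj <- match(sample_time[j], time_lab)
    noise <- rnorm(length(met_ids),
                   sd = noise_frac * apply(met_latent, 1L, function(v)
                     max(diff(range(v)), 1e-6)))
    mets[, j] <- pmax(met_latent[, tj] + noise, 0)
  }

  truth <- lapply(seq_along(drivers), function(i)
    list(gene = drivers[i], lag = as.integer(lag), effect = effect))
  structure(list(
    expression = omics_matrix(counts * 1.0, sample_time, sample_rep,
                              time_order = time_lab, count_mode = TRUE),
    metabolites = omics_matrix(mets, sample_time, sample_rep,
                               time_order = time_lab, count_mode = FALSE),
    truth = truth, depth_factors = setNames(depth, sample_ids),
    seed = NA_integer_), class = "synthetic_study")
}

#' Write a synthetic study to the pipeline's file contracts
#'
#' Produces `expression.csv`, `metabolites.csv` and a `truth.json` sidecar
#' recording the planted drivers and the seed.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_synthetic_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pe <- file.path(dir, "expression.csv")
  pm <- file.path(dir, "metabolites.csv")
  pt <- file.path(dir, "truth.json")
  write_matrix(study$expression, pe, id_column = "gene")
  write_matrix(study$metabolites, pm, id_column = "metabolite")
  jsonlite::write_json(list(seed = study$seed, truth = study$truth), pt,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(expression = pe, metabolites = pm, truth = pt))
}

#' Read back a truth sidecar written by [write_synthetic_study()]
#' @param path truth.json path.
#' @return list with `seed` and `truth` entries.
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
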