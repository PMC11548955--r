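#' @useDynLib omiclink, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx cor lm.fit median pf quantile rnbinom rnorm
#'   runif sd setNames
#' @importFrom utils head read.delim write.table
NULL

# shared condition helpers: every user-facing message carries the stage name
ol_stop <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

ol_warn <- function(stage, ...) {
  warning(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

# geometric mean that returns 0 when any entry is 0 (reference-gene filter
# handles that case upstream)
geomean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a
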