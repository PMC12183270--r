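# Internal helpers shared across modules.

#' @importFrom data.table fread fwrite data.table as.data.table
#' @importFrom stats rnorm runif rbinom
NULL

.datatable.aware <- TRUE

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.log_levels <- c(debug = 10L, info = 20L, warn = 30L, quiet = 100L)

mag_log <- function(msg, level = "info") {
  threshold <- getOption("magat.log_level", "info")
  if (.log_levels[[level]] >= .log_levels[[threshold]]) {
    message(sprintf("[magat] %s", msg))
  }
  invisible(NULL)
}

#' Derive a named sub-stream seed from a root seed
#'
#' All randomness in the pipeline flows from one root seed, fanned out to
#' per-stage sub-streams (e.g. `"smote"`, `"init"`, `"folds"`) so that a
#' stage re-run in isolation draws the same numbers it would draw inside
#' the full pipeline.
#'
#' @param seed integer root seed.
#' @param stream character stream name.
#' @return An integer seed in `[1, 2^31 - 2]`, deterministic in both
#'   arguments.
#' @examples
#' substream_seed(1, "smote")
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483563  # < 2^31, keeps all arithmetic exact in doubles
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% m
  out <- ((abs(as.numeric(seed)) %% m) * 48271 + h) %% m
  as.integer(out + 1)
}

with_stream_seed <- function(seed, stream, code) {
  withr::with_seed(substream_seed(seed, stream), code)
}

leaky_relu <- function(x, slope = 0.2) {
  x * (slope + (1 - slope) * (x > 0))
}

leaky_relu_grad <- function(x, slope = 0.2) {
  slope + (1 - slope) * (x > 0)
}

# Row-wise softmax of a matrix that may contain -Inf entries.
row_softmax <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  e <- exp(m - mx)
  e[is.na(e)] <- 0  # rows of all -Inf cannot occur (self-loops), guard anyway
  e / rowSums(e)
}

is_wholenumber <- function(x, tol = 1e-9) abs(x - round(x)) < tol
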