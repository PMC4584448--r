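#' @importFrom stats median sd quantile rnorm runif setNames aggregate
#' @importFrom rlang abort warn .data
#' @importFrom Rcpp evalCpp
#' @useDynLib ercnet, .registration = TRUE
NULL

# typed conditions so callers (and the pipeline driver) can distinguish
# configuration mistakes from data problems
abort_config <- function(msg, ...) {
  abort(msg, class = "ercnet_config_error", ...)
}

abort_data <- function(msg, ...) {
  abort(msg, class = "ercnet_data_error", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# robust z-score relative to median / MAD (scaled to SD under normality)
robust_z <- function(x) {
  m <- median(x)
  s <- median(abs(x - m)) * 1.4826
  if (s <= 0) s <- sd(x)
  if (!is.finite(s) || s <= 0) return(rep(0, length(x)))
  (x - m) / s
}

# ms -> samples, round half up (the half-sample case is not realizable)
ms_to_samples <- function(ms, fs) {
  floor(ms * fs / 1000 + 0.5)
}

# deterministic child seeds below 2^31, derived from a user seed
derive_seeds <- function(seed, n) {
  as.integer((as.numeric(seed) + 104729 * seq_len(n)) %% 2147483647)
}

# content hash used by the pipeline manifest (serialize to temp file, md5)
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

hash_file <- function(path) unname(tools::md5sum(path))
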