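#' Derive a reproducible sub-seed from a master seed and a tag
#'
#' Deterministically maps a master seed plus any number of tag components
#' (node labels, null-model kind, replicate index, ...) to an integer seed
#' below 2^31. Used throughout the package so that per-node and per-replicate
#' computations are reproducible in isolation and independent of execution
#' order.
#'
#' @param seed integer master seed.
#' @param ... tag components; coerced to character and concatenated.
#' @return a single integer in `[1, 2147483628]`.
#' @export
#' @examples
#' sub_seed(1, "ER", 17)
sub_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "|")
  bytes <- utf8ToInt(key)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483629
  as.integer(h + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
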