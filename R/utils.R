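#' @useDynLib mcmae, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd pnorm quantile
#' @importFrom utils write.csv read.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a stream of integers
#'
#' Mixes any number of integer components (a master seed, a subject index,
#' a channel index, ...) into a single seed in `[0, 2^31 - 2]` with a
#' multiplicative hash.  Used everywhere a module needs per-item seeds that
#' are a pure function of a master seed, so cohorts and masks of any size
#' are reproducible.
#'
#' @param ... integer components, combined in order.
#' @return a single integer seed.
#' @export
hash_seed <- function(...) {
  parts <- as.numeric(unlist(list(...)))
  stopifnot(all(is.finite(parts)))
  m <- 2147483629  # largest prime < 2^31
  h <- 104729
  for (v in parts) {
    h <- (h * 69069 + (v %% m) + 1) %% m
    # extra diffusion so close seeds do not yield close streams
    h <- (h * 3876547 + 268435459) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_mcmae <- function(...) stop(sprintf(...), call. = FALSE)

assert_shape3 <- function(shape, what = "shape") {
  if (length(shape) != 3L || any(!is.finite(shape)) || any(shape < 1))
    stop_mcmae("%s must be three positive integers", what)
  as.integer(shape)
}
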