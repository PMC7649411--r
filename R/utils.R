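#' @importFrom Rcpp sourceCpp
#' @importFrom methods as is
#' @importFrom stats rnorm runif rgamma var sd setNames aggregate
#' @importFrom utils write.table head
#' @useDynLib gblupsim, .registration = TRUE
NULL

# Deterministic 31-bit hash of a character string, exact in double arithmetic.
str_hash <- function(name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  h
}

#' Derive a named random stream seed from a master seed
#'
#' A single master seed drives every stage of the simulator; each stage
#' (historical population, panel selection, QTL effects, breeding, phenotype
#' noise, genotyping noise, error injection, ...) draws from its own stream so
#' that stages are individually reproducible and mutually independent.
#'
#' @param master integer master seed.
#' @param name stream name, e.g. `"historical"`.
#' @return An integer seed in `[1, 2^31 - 1)`.
#' @export
seed_stream <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1, length(name) == 1)
  as.integer(1 + (abs(master) * 48271 + str_hash(as.character(name)) * 16807) %%
               2147483629)
}

# Evaluate expr under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_bad_arg <- function(...) stop(..., call. = FALSE)

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x))
    stop_bad_arg(name, " must be a single integer >= ", min, " (got ", x, ")")
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi)
    stop_bad_arg(name, " must be in [", lo, ", ", hi, "]")
  as.numeric(x)
}
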