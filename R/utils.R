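# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG state
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so every stage of the pipeline is independently reproducible
#' and skipping a stage does not shift the random draws of later ones.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Counter-based seed stream: one master seed expanded per (stage, index) so
# stages draw from independent, reproducible streams. Kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(offset)) %% 2147483587)
}

# choose(n, 2) without integer overflow
ch2 <- function(x) x * (x - 1) / 2

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
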