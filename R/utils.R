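# Internal helpers: condition classes, rounding, seeded evaluation, hashing.

stop_icr <- function(msg, class = "icr_validation_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "icr_error")))
}

stop_range <- function(msg) stop_icr(msg, class = c("icr_range_error", "icr_validation_error"))

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

#' Round half away from zero
#'
#' Commercial rounding, as used in printed clinical frequency tables:
#' 14.545 rounds to 15 at 0 decimals, not 14 as under R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return rounded numeric vector.
#' @examples
#' round_half_away(c(14.545, 34.545, -2.5) * 1, 0)
#' @export
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Evaluate expr under a given seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a reproducible substream seed from a root seed and a stage label so
# that adding a pipeline stage never perturbs the draws of earlier stages.
substream_seed <- function(root_seed, stage) {
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 1000000007
  as.integer((as.numeric(root_seed) * 48271 + h) %% 2147483647)
}

# 32-bit polynomial string hash; used only for config provenance stamps.
string_hash <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 131 + code) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
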