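# Internal helpers: seeded RNG streams and small validators.

MERSENNE31 <- 2147483647

#' Stable 31-bit hash of a character key
#'
#' Deterministic across sessions and platforms (pure integer arithmetic in
#' doubles, exact below 2^53). Used to derive independent RNG stream seeds
#' per (library, replicate) from one master seed, so adding a library never
#' perturbs the streams of the others.
#' @noRd
stable_hash <- function(key) {
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% MERSENNE31
  h
}

#' @noRd
stream_seed <- function(master_seed, ...) {
  key <- paste(c(...), collapse = "/")
  s <- (as.numeric(master_seed) * 1103515245 + stable_hash(key)) %% MERSENNE31
  as.integer(s)
}

#' Evaluate `code` under a temporary RNG seed, restoring global RNG state
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == floor(x)
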