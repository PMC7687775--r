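# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG state
#'
#' Evaluates `expr` after seeding the RNG with `seed`, then restores the
#' caller's RNG state so that simulation helpers do not perturb the global
#' random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Canonical variant key strings
#'
#' @param chr,pos,ref,alt vectors describing variants.
#' @return character vector `"chr:pos:ref:alt"`.
#' @noRd
variant_key <- function(chr, pos, ref, alt) {
  paste(chr, pos, ref, alt, sep = ":")
}

# log(sum(exp(x))) computed stably
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Format doubles so that write -> read -> write round-trips byte-identically.
num_chr <- function(x) sprintf("%.17g", x)

stop_data <- function(...) stop(..., call. = FALSE)
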