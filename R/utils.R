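#' @keywords internal
"_PACKAGE"

## Residues that count as compared sites in p-distance work.
.BASES <- c("A", "C", "G", "T")

#' Run an expression under a fixed seed without touching global RNG state
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that no function perturbs (or depends on) the caller's
#' `.Random.seed`.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
#' @examples
#' with_seed(1, runif(2))
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Normalize a taxon name for exact matching: trim, squeeze whitespace.
normalize_name <- function(x) {
  x <- gsub("[[:space:]]+", " ", trimws(as.character(x)))
  x
}

## Consistent stop() with sprintf formatting.
bc_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
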