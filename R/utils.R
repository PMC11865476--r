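#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded generation does not
#' perturb the surrounding random stream.
#'
#' @param seed integer seed (kept below 2^31 by callers).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Derive a child seed from a parent seed
#'
#' Deterministic expansion of one master seed into per-item/per-stage seeds,
#' always within the 32-bit integer range.
#'
#' @param seed parent integer seed.
#' @param i child index.
#' @return integer seed.
#' @export
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 9973) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x) && x >= 0

#' @importFrom stats rpois runif rnorm quantile prcomp pchisq pnorm rbinom sd var aggregate
#' @importFrom utils write.csv read.csv head
NULL
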