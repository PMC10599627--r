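#' @importFrom methods new is validObject slot slotNames
#' @importFrom stats rnorm rpois rnbinom rlnorm runif median var sd cor
#'   pnorm setNames quantile nls nls.control coef resid optim ks.test
#'   p.adjust complete.cases aggregate mad
#' @importFrom utils head tail
NULL

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. seed = NULL leaves the RNG stream alone.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer or NULL")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a master seed so pipeline stages get independent,
# reproducible streams. Kept below 2^31 - 1.
childSeed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

assertScalarCount <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) ||
      (positive && x <= 0) || (!positive && x < 0)) {
    stop(sprintf("'%s' must be a single %s integer", name,
                 if (positive) "positive" else "non-negative"))
  }
  invisible(as.integer(x))
}
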