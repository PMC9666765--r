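#' @importFrom stats rnorm runif prcomp dist
#' @importFrom utils read.csv write.csv
#' @import methods
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a child seed from a base seed and a stream index, kept inside the
# 32-bit signed integer range.
childSeed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 9973) %% 2147483647)
}

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used when reporting percentages: 0.5 always
#' rounds away from zero, unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return `x` rounded half-up to `digits` places.
#' @examples
#' roundHalfUp(c(0.5, 1.5, 2.5))   # 1 2 3
#' @export
roundHalfUp <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

stopIf <- function(cond, ...) if (cond) stop(..., call. = FALSE)
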