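#' Round half away from zero
#'
#' Report-table rounding: 0.005 rounds to 0.01, unlike [base::round()]'s
#' round-half-even. Used for the 2-decimal percentages and Ka/Ks ratios in
#' output tables; full precision is retained internally everywhere else.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up (away from zero for negatives).
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a total, 2 decimals
#'
#' @param count numerator count.
#' @param total denominator count; must be > 0.
#' @return `100 * count / total`, rounded half-up to 2 decimals.
#' @examples
#' percentOf(428, 2542)   # 16.84
#' percentOf(2542, 28712) # 8.85
#' @export
percentOf <- function(count, total) {
  stopifnot(total > 0, count >= 0)
  roundHalfUp(100 * count / total, 2)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL uses the current stream.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# Derived per-stage seed so one pipeline seed drives independent substreams.
# Kept below 2^31 - 1 (R integers are 32-bit).
substreamSeed <- function(seed, stage) {
  offsets <- c(
    genome = 101L, homology = 211L, expression = 307L, terms = 401L,
    evolve = 503L, general = 601L
  )
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 7919 + off * 104729) %% 2147483647)
}
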