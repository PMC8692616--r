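#' Trapezoidal integral
#'
#' Plain trapezoid rule over possibly non-uniform (but strictly monotone) x.
#'
#' @param x numeric axis, strictly monotone.
#' @param y numeric values, same length as `x`.
#' @return scalar integral.
#' @keywords internal
trapz_int <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' All randomness in the package flows from a master seed; each stage draws its
#' own sub-seed so stages can be re-run independently without disturbing the
#' stream of any other stage. Kept below 2^31 so it is a valid R integer.
#'
#' @param master integer master seed.
#' @param label character tag naming the consumer.
#' @return integer seed.
#' @export
derive_seed <- function(master, label) {
  h <- rlang::hash(list(as.integer(master), as.character(label)))
  (strtoi(substr(h, 1, 7), base = 16L) %% .Machine$integer.max) + 1L
}

#' Hash an R object (configs, tables) for provenance stamping
#' @param x any serialisable object.
#' @return character hash.
#' @export
config_hash <- function(x) rlang::hash(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

# vectorised column standard deviations (n-1 denominator)
col_sds <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  v <- (colSums(X * X) - n * mu^2) / (n - 1)
  sqrt(pmax(v, 0))
}

#' Run code with a private RNG state
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
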