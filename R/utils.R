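`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
## .Random.seed is restored afterwards. seed = NULL leaves the RNG untouched.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

## Type-1 empirical quantile: the smallest order statistic x_(k) with k/n >= q.
## Used for thresholds and normalisation references so that a brute-force
## sort-based check reproduces the value exactly.
quantileType1 <- function(x, q) {
  n <- length(x)
  sort(x)[max(1L, min(n, as.integer(ceiling(q * n))))]
}

## sdlog of a mean-1 lognormal with coefficient of variation cv.
lnormSdlog <- function(cv) sqrt(log1p(cv^2))

## Mean-1 lognormal multipliers.
rlnormMean1 <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- lnormSdlog(cv)
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

trapezoidIntegral <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}
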