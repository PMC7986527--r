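#' Convert milliseconds to a whole number of samples
#'
#' All time windows in this package are specified in milliseconds and
#' converted to samples by `floor(ms * fs / 1000)`, so that window lengths
#' are exact at any sampling rate that divides evenly into the window.
#'
#' @param ms Time in milliseconds (may be negative).
#' @param fs Sampling rate in Hz.
#' @return Integer number of samples.
#' @keywords internal
msToSamples <- function(ms, fs) {
  as.integer(floor(ms * fs / 1000))
}

## Round half away from zero (base round() rounds half to even).
roundHalfAway <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's RNG afterwards so simulation calls do not clobber user code.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Minimum-norm solution of A x = b via the Moore-Penrose inverse.
pseudoSolve <- function(a, b) {
  sv <- svd(a)
  pos <- sv$d > max(sv$d) * .Machine$double.eps * length(sv$d)
  drop(sv$v[, pos, drop = FALSE] %*%
         ((t(sv$u[, pos, drop = FALSE]) %*% b) / sv$d[pos]))
}

## Population (divide-by-n) standard deviation.
popSd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}
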