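# Internal helpers shared across modules.

#' @importFrom stats fft rnorm runif rgamma
#' @importFrom utils head
#' @useDynLib actinwave, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate expr under a fixed seed without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive n child seeds (< 2^31) from one master seed, reproducibly.
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# note argument order: pmax/pmin take attributes (incl. dim) from arg 1
clip01 <- function(x) pmin(pmax(x, 0), 1)

# Signed coordinates 0, 1, ..., S/2-1, -S/2, ..., -1 so that spatial filters
# are centred on pixel [1, 1] with periodic wrap (ready for FFT convolution).
wrapCoords <- function(S) {
  g <- 0:(S - 1)
  ifelse(g < S / 2, g, g - S)
}

# 2-D circular convolution via FFT; filterF is the FFT of the kernel.
convFFT <- function(imgF, filterF) {
  stats::fft(imgF * filterF, inverse = TRUE) / length(filterF)
}

# Reflect-pad a matrix on the right/bottom to size S x S.
reflectPad <- function(m, S) {
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(S >= nr, S >= nc)
  if (nr == S && nc == S) return(m)
  ri <- c(seq_len(nr), rev(seq_len(nr)))[seq_len(S)]
  ci <- c(seq_len(nc), rev(seq_len(nc)))[seq_len(S)]
  m[ri, ci, drop = FALSE]
}

# Box-filter sum over a (2h+1) x (2h+1) window with replicate padding.
boxSum <- function(m, h) {
  if (h == 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq(1 - h, nr + h), 1L), nr)
  p <- m[ri, , drop = FALSE]
  cs <- apply(p, 2, cumsum)
  w <- 2L * h + 1L
  rows <- cs[w:(w + nr - 1L), , drop = FALSE] -
    rbind(0, cs[seq_len(nr - 1L), , drop = FALSE])
  ci <- pmin(pmax(seq(1 - h, nc + h), 1L), nc)
  p <- rows[, ci, drop = FALSE]
  cs <- t(apply(p, 1, cumsum))
  cs[, w:(w + nc - 1L), drop = FALSE] -
    cbind(0, cs[, seq_len(nc - 1L), drop = FALSE])
}

# Central-difference spatial gradients with replicated borders.
imageGradients <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  left  <- m[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  right <- m[, c(2:nc, nc), drop = FALSE]
  up    <- m[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  down  <- m[c(2:nr, nr), , drop = FALSE]
  list(gx = (right - left) / 2, gy = (down - up) / 2)
}

isWholeNumber <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && abs(x - round(x)) < 1e-8
}
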