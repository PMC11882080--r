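#' Build a Morlet filter bank for the first-order scattering transform
#'
#' Constructs \code{J * L} oriented band-pass Morlet wavelets plus one
#' Gaussian low-pass, sampled on a periodic grid of side \code{size} and
#' stored in the frequency domain. The mother wavelet is
#' \deqn{\psi(u) = \alpha\,(e^{i\,\xi\cdot u} - \beta)\,e^{-|u|^2/2\sigma^2},}
#' with \eqn{\beta} computed per filter so the discrete sum is exactly zero;
#' scale \code{j} dilates it by \code{2^(j-1)} (halving its peak frequency)
#' and orientation \code{l} rotates it to \code{thetaDeg[l] = 90 - (l-1) *
#' 180/L} degrees. \code{thetaDeg} labels the orientation of the filter's
#' stripes (its wave vector is perpendicular), so horizontal image features
#' excite the \code{theta = 0} filter.
#'
#' @param J number of dyadic scales (default 4).
#' @param L number of orientations (default 12, i.e. 15-degree steps).
#' @param size transform side length in pixels; must be divisible by
#'   \code{2^J}.
#' @param sigma0 Gaussian width of the mother wavelet, pixels.
#' @param xi0 central frequency of the mother wavelet, radians/pixel.
#' @param slant envelope anisotropy (default \code{4 / L}); values below 1
#'   elongate the filter along its stripes, sharpening orientation
#'   selectivity.
#' @return a \linkS4class{MorletBank} with \code{1 + J*L} filters.
#' @export
#' @examples
#' bank <- buildMorletBank(J = 3, L = 8, size = 64)
#' bank
buildMorletBank <- function(J = 4, L = 12, size = 512, sigma0 = 0.8,
                            xi0 = 3 * pi / 4, slant = 4 / L) {
  if (J <= 0 || L <= 0) stop("invalid config: J and L must be positive")
  J <- as.integer(J); L <- as.integer(L); size <- as.integer(size)
  if (size %% 2L^J != 0L)
    stop("invalid config: size must be divisible by 2^J (pad the frame)")
  co <- wrapCoords(size)
  X <- matrix(co, size, size, byrow = TRUE)   # x = column offset
  Y <- matrix(co, size, size)                 # y = row offset
  thetaDeg <- 90 - (seq_len(L) - 1) * 180 / L
  alpha <- slant / (2 * pi * sigma0^2)
  psiF <- vector("list", J * L)
  for (j in seq_len(J)) {
    s <- 2^(j - 1)
    for (l in seq_len(L)) {
      phiW <- (thetaDeg[l] + 90) * pi / 180   # wave-vector direction
      a1 <- (cos(phiW) * X + sin(phiW) * Y) / s
      a2 <- (-sin(phiW) * X + cos(phiW) * Y) / s
      env <- exp(-(a1^2 + (slant * a2)^2) / (2 * sigma0^2))
      wave <- exp(1i * xi0 * a1)
      beta <- sum(wave * env) / sum(env)
      psi <- (alpha / s^2) * (wave - beta) * env
      psiF[[(j - 1L) * L + l]] <- stats::fft(psi)
    }
  }
  sigmaPhi <- sigma0 * 2^(J - 1)
  phi <- exp(-(X^2 + Y^2) / (2 * sigmaPhi^2))
  phi <- phi / sum(phi)                        # unit DC gain
  new("MorletBank", psiF = psiF, phiF = Re(stats::fft(phi)) + 0 * X,
      J = J, L = L, size = size, thetaDeg = thetaDeg,
      sigma0 = sigma0, xi0 = xi0, slant = slant)
}

# Average-pool a matrix by an integer factor.
.avgPool <- function(m, f) {
  if (f == 1L) return(m)
  nr <- nrow(m) %/% f
  nc <- ncol(m) %/% f
  ri <- rep(seq_len(nr), each = f)
  ci <- rep(seq_len(nc), each = f)
  t(rowsum(t(rowsum(m, ri)), ci)) / f^2
}

#' First-order scattering transform of one frame
#'
#' Computes \code{S0 = I * phi} and \code{S1[j,l] = |I * psi[j,l]| * phi},
#' each subsampled by \code{2^J} via average pooling after the low-pass, so a
#' \code{512 x 512} frame with \code{J = 4} yields \code{1 + J*L} maps of
#' \code{32 x 32} pixels. Frames smaller than the bank are reflect-padded on
#' the right/bottom up to the transform size; convolutions are periodic FFT
#' convolutions. All S1 values are non-negative.
#'
#' @param frame numeric matrix no larger than the bank size.
#' @param bank a \linkS4class{MorletBank}.
#' @return a \linkS4class{ScatterMaps}.
#' @export
scatterFirstOrder <- function(frame, bank) {
  if (nrow(frame) != ncol(frame)) stop("shape error: frame must be square")
  if (nrow(frame) > bank@size)
    stop("shape error: frame exceeds the bank's transform size")
  fr <- reflectPad(frame, bank@size)
  f <- 2L^bank@J
  m <- bank@size %/% f
  nMaps <- 1L + bank@J * bank@L
  maps <- array(0, dim = c(m, m, nMaps))
  F <- stats::fft(fr)
  maps[, , 1] <- .avgPool(Re(convFFT(F, bank@phiF)), f)
  for (k in seq_len(bank@J * bank@L)) {
    U <- Mod(convFFT(F, bank@psiF[[k]]))
    S1 <- Re(convFFT(stats::fft(U), bank@phiF))
    maps[, , k + 1L] <- .avgPool(pmax(S1, 0), f)
  }
  idx <- data.frame(
    alpha = seq_len(nMaps),
    order = c(0L, rep(1L, nMaps - 1L)),
    j = c(NA_integer_, rep(seq_len(bank@J), each = bank@L)),
    l = c(NA_integer_, rep(seq_len(bank@L), times = bank@J)),
    thetaDeg = c(NA_real_, rep(bank@thetaDeg, times = bank@J)))
  new("ScatterMaps", maps = maps, index = idx)
}

#' Scattering feature vector
#'
#' Sums each scattering map over its pixels, giving the
#' \code{(1 + J*L)}-dimensional translation-invariant frame descriptor
#' \code{v_alpha = sum_{i,j} X_alpha(i,j)}; all components are non-negative.
#'
#' @param x a \linkS4class{ScatterMaps}, or a frame matrix if \code{bank} is
#'   supplied.
#' @param bank optional \linkS4class{MorletBank} used when \code{x} is a raw
#'   frame.
#' @return numeric vector, one component per map (named \code{S0},
#'   \code{S1.j.l}).
#' @export
scatterFeatureVector <- function(x, bank = NULL) {
  if (!is(x, "ScatterMaps")) {
    if (is.null(bank)) stop("supply a MorletBank to transform a raw frame")
    x <- scatterFirstOrder(x, bank)
  }
  v <- apply(x@maps, 3, sum)
  names(v) <- ifelse(x@index$order == 0L, "S0",
                     paste0("S1.", x@index$j, ".", x@index$l))
  v
}

#' SVM-weighted reconstruction map
#'
#' The pixelwise weighted sum \code{X_r(i,j) = sum_alpha w_alpha
#' X_alpha(i,j)} of the scattering maps under a trained linear model's
#' weights. Because all maps are non-negative, the sign of \code{X_r} at a
#' pixel localises which class the texture there supports; its total equals
#' \code{w . v} for the frame's feature vector \code{v}.
#'
#' @param maps a \linkS4class{ScatterMaps}.
#' @param weights numeric vector, one weight per map.
#' @return numeric matrix of the same size as the maps.
#' @export
svmReconstruct <- function(maps, weights) {
  d <- dim(maps@maps)
  if (length(weights) != d[3])
    stop("shape error: need one weight per scattering map")
  out <- matrix(0, d[1], d[2])
  for (k in seq_len(d[3])) out <- out + weights[k] * maps@maps[, , k]
  out
}

#' Angular table of first-order SVM weights
#'
#' Arranges the first-order weight components (S0 excluded) by scale \code{j}
#' and stripe orientation \code{thetaDeg}, ready for polar plotting of which
#' orientations support each class.
#'
#' @param weights numeric vector of \code{1 + J*L} weights (S0 first) or
#'   \code{J*L} first-order weights.
#' @param bank the \linkS4class{MorletBank} the features came from.
#' @return data.frame with \code{J*L} rows: \code{j}, \code{l},
#'   \code{thetaDeg}, \code{w}.
#' @export
angularWeightTable <- function(weights, bank) {
  n1 <- bank@J * bank@L
  if (length(weights) == n1 + 1L) weights <- weights[-1L]
  if (length(weights) != n1)
    stop("shape error: weight length does not match the bank")
  data.frame(j = rep(seq_len(bank@J), each = bank@L),
             l = rep(seq_len(bank@L), times = bank@J),
             thetaDeg = rep(bank@thetaDeg, times = bank@J),
             w = as.numeric(weights))
}

#' Scattering feature table for a set of videos
#'
#' @param videos list of \linkS4class{WaveVideo}.
#' @param bank a \linkS4class{MorletBank} matching the frame size.
#' @return data.frame with columns \code{videoId}, \code{frame},
#'   \code{topography}, \code{field} and \code{v1..v(1+JL)}.
#' @export
scatterFeatureTable <- function(videos, bank) {
  rows <- list()
  i <- 0L
  for (v in videos) {
    for (t in seq_len(nFrames(v))) {
      i <- i + 1L
      vec <- scatterFeatureVector(getFrame(v, t), bank)
      rows[[i]] <- data.frame(videoId = videoId(v), frame = t - 1L,
                              topography = topography(v), field = fieldState(v),
                              t(unname(vec)))
    }
  }
  out <- do.call(rbind, rows)
  names(out)[-(1:4)] <- paste0("v", seq_len(ncol(out) - 4L))
  rownames(out) <- NULL
  out
}
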