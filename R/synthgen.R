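#' Configuration for one synthetic actin-wave video
#'
#' Bundles every knob of the synthetic video generator. The defaults encode
#' the imaging geometry of the study the generator emulates: 512 x 512 px
#' frames covering 107.52 um (0.21 um/px), one frame per 10 s, ridge-guided
#' band spacing of 7.6 px (the 1.6 um ridge pitch), leftward field drift of
#' 0.5 px/frame and a random cell wander of 0.3 px/frame.
#'
#' Wave propagation is rendered as an oscillatory phase slosh of the band
#' pattern (amplitude \code{waveAmp} radians over a \code{wavePeriod}-frame
#' cycle) rather than a steady phase advance, so that the net motion of the
#' texture equals the imposed drift and remains recoverable by phase
#' correlation or corner tracking.
#'
#' @param imageSize frame side length in pixels.
#' @param bandPeriod ridge-guided wave spacing in pixels (must be >= 2).
#' @param bandWidth band thickness in pixels (Gaussian profile FWHM scale).
#' @param orientationDeg direction of the ridged bands; 0 = horizontal.
#' @param blobCount number of wave sources in flat-surface videos.
#' @param blobRadius maximum wavefront radius in pixels (default scales with
#'   the frame, \code{0.15 * imageSize}).
#' @param driftVelocity \code{c(vx, vy)} coherent drift in pixels/frame
#'   (nonzero only when the electric field is on).
#' @param driftOnset number of initial frames before the drift becomes
#'   active (default 0 = drift from the first frame), emulating the latency
#'   between field onset and the cellular response.
#' @param wanderSigma per-frame standard deviation of the random walk of the
#'   cell centre, pixels/frame.
#' @param noiseSigma additive Gaussian intensity noise.
#' @param nFrames number of frames.
#' @param seed RNG seed; identical configs give bit-identical videos.
#' @param waveAmp amplitude of the band-phase slosh in radians.
#' @param wavePeriod period of the band-phase slosh in frames.
#' @param modPeriod period of the along-band intensity modulation in pixels
#'   (gives the quasi-1D waves trackable 2-D structure).
#' @param ringSpeed radial expansion speed of flat-surface wavefronts,
#'   pixels/frame; the default \code{blobRadius / wavePeriod} makes ring
#'   re-nucleation share the generator's common internal-dynamics period, so
#'   all wave motion is periodic and only drift plus wander move the texture
#'   on average.
#' @param distractors add small static "unfused cell" blobs outside the cell.
#' @param distractorCount how many such blobs.
#' @param umPerPx,sPerFrame physical metadata copied into the video.
#' @return a validated list of class \code{SynthConfig}.
#' @export
#' @examples
#' cfg <- synthConfig(imageSize = 64, nFrames = 5, seed = 7)
#' v <- genRidgedVideo(cfg)
synthConfig <- function(imageSize = 512, bandPeriod = 7.6, bandWidth = 2.5,
                        orientationDeg = 0, blobCount = 4,
                        blobRadius = 0.15 * imageSize,
                        driftVelocity = c(0, 0), driftOnset = 0,
                        wanderSigma = 0.3,
                        noiseSigma = 0.03, nFrames = 60, seed = 1,
                        waveAmp = pi, wavePeriod = 20,
                        modPeriod = 3 * bandPeriod,
                        ringSpeed = blobRadius / wavePeriod,
                        distractors = FALSE, distractorCount = 6,
                        umPerPx = 107.52 / 512, sPerFrame = 10) {
  if (!isWholeNumber(imageSize) || imageSize < 16)
    stop("invalid config: imageSize must be an integer >= 16")
  if (bandPeriod < 2)
    stop("invalid config: bandPeriod must be at least 2 pixels")
  if (noiseSigma < 0) stop("invalid config: noiseSigma must be >= 0")
  if (wanderSigma < 0) stop("invalid config: wanderSigma must be >= 0")
  if (!isWholeNumber(nFrames) || nFrames < 1)
    stop("invalid config: nFrames must be a positive integer")
  if (length(driftVelocity) != 2 || !all(is.finite(driftVelocity)))
    stop("invalid config: driftVelocity must be c(vx, vy)")
  if (driftOnset < 0) stop("invalid config: driftOnset must be >= 0")
  cfg <- list(imageSize = as.integer(imageSize), bandPeriod = bandPeriod,
              bandWidth = bandWidth, orientationDeg = orientationDeg,
              blobCount = blobCount, blobRadius = blobRadius,
              driftVelocity = driftVelocity,
              driftOnset = as.integer(driftOnset),
              wanderSigma = wanderSigma,
              noiseSigma = noiseSigma, nFrames = as.integer(nFrames),
              seed = as.integer(seed), waveAmp = waveAmp,
              wavePeriod = wavePeriod, modPeriod = modPeriod,
              ringSpeed = ringSpeed, distractors = isTRUE(distractors),
              distractorCount = distractorCount,
              umPerPx = umPerPx, sPerFrame = sPerFrame)
  class(cfg) <- "SynthConfig"
  cfg
}

# Shared scaffolding: cell-mask parameters, wander path, distractors.
# Drifting cells are framed so the transit is centred in the field of view
# (as an experimenter would frame a cell that migrates during acquisition).
.synthScene <- function(cfg) {
  S <- cfg$imageSize
  Tn <- cfg$nFrames
  driftFrames <- max(0, Tn - 1 - cfg$driftOnset)
  centre0 <- S / 2 + runif(2, -0.05 * S, 0.05 * S) -
    cfg$driftVelocity * driftFrames / 2
  driftDisp <- outer(pmax(0, (seq_len(Tn) - 1) - cfg$driftOnset),
                     cfg$driftVelocity)             # Tn x 2
  lobeAmp <- runif(3, 0, 0.08)
  lobePhase <- runif(3, 0, 2 * pi)
  steps <- matrix(rnorm(2 * Tn, sd = cfg$wanderSigma), nrow = 2)
  steps[, 1] <- 0
  wander <- apply(steps, 1, cumsum)           # Tn x 2
  if (Tn == 1) wander <- matrix(wander, 1, 2)
  distr <- NULL
  if (cfg$distractors) {
    ang <- runif(cfg$distractorCount, 0, 2 * pi)
    rad <- runif(cfg$distractorCount, 0.42 * S, 0.52 * S)
    distr <- cbind(x = S / 2 + rad * cos(ang), y = S / 2 + rad * sin(ang),
                   r = runif(cfg$distractorCount, 0.02 * S, 0.035 * S))
  }
  xm <- matrix(0:(S - 1), S, S, byrow = TRUE)   # x = column index
  ym <- matrix(0:(S - 1), S, S)                 # y = row index
  list(S = S, Tn = Tn, centre0 = centre0, lobeAmp = lobeAmp,
       lobePhase = lobePhase, wander = wander, driftDisp = driftDisp,
       distr = distr, xm = xm, ym = ym, edge = max(2, S / 64),
       R0 = 0.32 * S)
}

.cellMask <- function(sc, dx, dy) {
  r <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx)
  Rb <- sc$R0 * (1 + sc$lobeAmp[1] * cos(2 * ang + sc$lobePhase[1]) +
                   sc$lobeAmp[2] * cos(3 * ang + sc$lobePhase[2]) +
                   sc$lobeAmp[3] * cos(4 * ang + sc$lobePhase[3]))
  1 / (1 + exp((r - Rb) / sc$edge))
}

.addDistractors <- function(img, sc) {
  if (is.null(sc$distr)) return(img)
  for (k in seq_len(nrow(sc$distr))) {
    d2 <- (sc$xm - sc$distr[k, "x"])^2 + (sc$ym - sc$distr[k, "y"])^2
    img <- img + 0.5 * exp(-d2 / (2 * sc$distr[k, "r"]^2))
  }
  img
}

.finishVideo <- function(framesList, cfg, topography, videoId) {
  arr <- array(unlist(framesList, use.names = FALSE),
               dim = c(cfg$imageSize, cfg$imageSize, cfg$nFrames))
  waveVideo(arr,
            topography = topography,
            field = if (any(cfg$driftVelocity != 0)) "on" else "off",
            umPerPx = cfg$umPerPx, sPerFrame = cfg$sPerFrame,
            videoId = videoId)
}

#' Generate a synthetic ridged-surface (quasi-1D wave) video
#'
#' Renders bright elongated bands aligned with \code{orientationDeg} inside a
#' soft-edged, slowly wandering cell mask. Band intensity is modulated along
#' the band direction so the texture carries trackable 2-D structure, and the
#' band phase sloshes periodically to mimic wave propagation. The whole
#' texture translates rigidly with the cell centre, whose motion is
#' \code{driftVelocity} plus a Gaussian random walk.
#'
#' @param cfg a \code{\link{synthConfig}}.
#' @param videoId identifier stored in the result.
#' @return a \linkS4class{WaveVideo} labeled \code{topography = "ridged"};
#'   \code{field} is \code{"on"} iff the drift velocity is nonzero.
#' @export
genRidgedVideo <- function(cfg, videoId = "ridged") {
  stopifnot(inherits(cfg, "SynthConfig"))
  withSeed(cfg$seed, {
    sc <- .synthScene(cfg)
    th <- cfg$orientationDeg * pi / 180
    u0 <- runif(1, 0, cfg$bandPeriod)
    psi0 <- runif(1, 0, 2 * pi)
    sloshPhase <- runif(1, 0, 2 * pi)
    bw <- cfg$bandWidth / 2
    framesList <- vector("list", sc$Tn)
    for (t in seq_len(sc$Tn)) {
      cx <- sc$centre0[1] + sc$driftDisp[t, 1] + sc$wander[t, 1]
      cy <- sc$centre0[2] + sc$driftDisp[t, 2] + sc$wander[t, 2]
      dx <- sc$xm - cx
      dy <- sc$ym - cy
      mask <- .cellMask(sc, dx, dy)
      uperp <- -dx * sin(th) + dy * cos(th)
      upar <- dx * cos(th) + dy * sin(th)
      shift <- cfg$waveAmp / (2 * pi) * cfg$bandPeriod *
        sin(2 * pi * (t - 1) / cfg$wavePeriod + sloshPhase)
      d <- abs((uperp - u0 - shift + cfg$bandPeriod / 2) %% cfg$bandPeriod -
                 cfg$bandPeriod / 2)
      bands <- exp(-d^2 / (2 * bw^2))
      modu <- 0.75 + 0.25 * cos(2 * pi * upar / cfg$modPeriod + psi0)
      img <- 0.05 + 0.85 * mask * bands * modu
      img <- .addDistractors(img, sc)
      if (cfg$noiseSigma > 0)
        img <- img + matrix(rnorm(sc$S^2, sd = cfg$noiseSigma), sc$S, sc$S)
      framesList[[t]] <- clip01(img)
    }
    .finishVideo(framesList, cfg, "ridged", videoId)
  })
}

#' Generate a synthetic flat-surface (isotropic 2D wave) video
#'
#' Renders isotropic annular wavefronts expanding from \code{blobCount}
#' randomly placed sources inside the cell mask; ring radii grow at
#' \code{ringSpeed} pixels/frame and re-nucleate when they reach
#' \code{blobRadius}. A field of persistent speckle puncta (cortical
#' fluorescence heterogeneity) is superimposed and moves rigidly with the
#' cell, so the video carries stable trackable structure alongside the
#' travelling wavefronts. There is no preferred texture axis. Centre motion
#' is drift plus random walk, as for ridged videos.
#'
#' @inheritParams genRidgedVideo
#' @return a \linkS4class{WaveVideo} labeled \code{topography = "flat"}.
#' @export
genFlatVideo <- function(cfg, videoId = "flat") {
  stopifnot(inherits(cfg, "SynthConfig"))
  withSeed(cfg$seed, {
    sc <- .synthScene(cfg)
    nb <- cfg$blobCount
    srcR <- 0.55 * sc$R0 * sqrt(runif(nb))
    srcA <- runif(nb, 0, 2 * pi)
    srcX <- srcR * cos(srcA)
    srcY <- srcR * sin(srcA)
    r0 <- runif(nb, 0, cfg$blobRadius)
    ringSigma <- cfg$bandWidth
    nSpk <- 10L
    spkR <- 0.8 * sc$R0 * sqrt(runif(nSpk))
    spkA <- runif(nSpk, 0, 2 * pi)
    spkX <- spkR * cos(spkA)
    spkY <- spkR * sin(spkA)
    spkS <- runif(nSpk, 2, 4)
    framesList <- vector("list", sc$Tn)
    for (t in seq_len(sc$Tn)) {
      cx <- sc$centre0[1] + sc$driftDisp[t, 1] + sc$wander[t, 1]
      cy <- sc$centre0[2] + sc$driftDisp[t, 2] + sc$wander[t, 2]
      dx <- sc$xm - cx
      dy <- sc$ym - cy
      mask <- .cellMask(sc, dx, dy)
      pattern <- 0
      for (k in seq_len(nb)) {
        rk <- (r0[k] + cfg$ringSpeed * (t - 1)) %% cfg$blobRadius
        dist <- sqrt((dx - srcX[k])^2 + (dy - srcY[k])^2)
        pattern <- pattern + exp(-(dist - rk)^2 / (2 * ringSigma^2))
      }
      speckle <- 0
      for (k in seq_len(nSpk)) {
        d2 <- (dx - spkX[k])^2 + (dy - spkY[k])^2
        speckle <- speckle + exp(-d2 / (2 * spkS[k]^2))
      }
      img <- 0.05 + mask *
        (0.12 + 0.45 * pmin(1, pattern) + 0.38 * pmin(1, speckle))
      img <- .addDistractors(img, sc)
      if (cfg$noiseSigma > 0)
        img <- img + matrix(rnorm(sc$S^2, sd = cfg$noiseSigma), sc$S, sc$S)
      framesList[[t]] <- clip01(img)
    }
    .finishVideo(framesList, cfg, "flat", videoId)
  })
}

#' Dataset layout specification for the synthetic generator
#'
#' Describes per-environment video counts and per-video frame counts. The
#' default (\code{defaultDatasetSpec()}) mirrors the study layout: 12 + 4 + 5
#' + 8 videos for flat/no-field, flat/field, ridged/no-field and ridged/field
#' with 748, 312, 395 and 1061 frames respectively (2516 frames, 29 videos).
#'
#' Field-on videos draw their per-video drift magnitude from a Gamma
#' distribution with mean \code{driftMean} and shape \code{driftShape}
#' (pointing along \code{driftDirDeg}), emulating heterogeneity in how
#' strongly individual cells respond to the field, and a per-video response
#' lag uniform on \code{[0, responseLagMax]} frames before the drift sets in,
#' emulating the latency between field onset and the cellular response.
#' Field-off videos always have zero drift.
#'
#' @param flatOff,flatOn,ridgedOff,ridgedOn integer vectors of per-video
#'   frame counts for each environment.
#' @param imageSize frame side length for every generated video.
#' @param masterSeed seed from which all per-video seeds derive.
#' @param driftMean mean field-on drift magnitude, pixels/frame.
#' @param driftShape Gamma shape of the per-video drift magnitude.
#' @param driftDirDeg drift direction in degrees (180 = leftward).
#' @param responseLagMax maximum response lag of field-on videos, frames
#'   (capped at half the video length).
#' @param ... further arguments forwarded to \code{\link{synthConfig}} for
#'   every video (e.g. \code{noiseSigma}, \code{bandPeriod}).
#' @return a list of class \code{SynthDatasetSpec}.
#' @export
#' @examples
#' sp <- synthDatasetSpec(flatOff = c(30, 30), flatOn = 30,
#'                        ridgedOff = c(30, 30), ridgedOn = 30,
#'                        imageSize = 64, masterSeed = 1)
#' summary(sp)
synthDatasetSpec <- function(flatOff, flatOn, ridgedOff, ridgedOn,
                             imageSize = 512, masterSeed = 1,
                             driftMean = 0.5, driftShape = 3,
                             driftDirDeg = 180, responseLagMax = 50, ...) {
  counts <- list(FlatE0 = as.integer(flatOff), FlatE = as.integer(flatOn),
                 RidgedE0 = as.integer(ridgedOff), RidgedE = as.integer(ridgedOn))
  if (any(vapply(counts, length, integer(1)) < 1L))
    stop("every environment needs at least one video")
  if (any(unlist(counts) < 1L)) stop("every video needs at least one frame")
  spec <- list(counts = counts, imageSize = as.integer(imageSize),
               masterSeed = as.integer(masterSeed), driftMean = driftMean,
               driftShape = driftShape, driftDirDeg = driftDirDeg,
               responseLagMax = responseLagMax, extra = list(...))
  class(spec) <- "SynthDatasetSpec"
  spec
}

#' @rdname synthDatasetSpec
#' @export
defaultDatasetSpec <- function(imageSize = 512, masterSeed = 1, ...) {
  synthDatasetSpec(
    flatOff   = c(95, 30, 61, 60, 98, 30, 31, 125, 62, 52, 45, 59),
    flatOn    = c(65, 66, 55, 126),
    ridgedOff = c(120, 31, 122, 62, 60),
    ridgedOn  = c(181, 115, 131, 157, 101, 171, 84, 121),
    imageSize = imageSize, masterSeed = masterSeed, ...)
}

#' @param object a \code{SynthDatasetSpec}.
#' @describeIn synthDatasetSpec per-environment video and frame totals.
#' @export
summary.SynthDatasetSpec <- function(object, ...) {
  data.frame(env = names(object$counts),
             nVideos = vapply(object$counts, length, integer(1)),
             nFrames = vapply(object$counts, sum, integer(1)),
             row.names = NULL)
}

#' Generate a labeled synthetic dataset
#'
#' Materialises every video described by a \code{\link{synthDatasetSpec}}:
#' per-video seeds (and field-on drift magnitudes) are derived
#' deterministically from the master seed, so the same spec always produces
#' bit-identical pixel data.
#'
#' @param spec a \code{\link{synthDatasetSpec}}.
#' @return a list of \linkS4class{WaveVideo} objects carrying ground-truth
#'   topography and field labels.
#' @export
genDataset <- function(spec) {
  stopifnot(inherits(spec, "SynthDatasetSpec"))
  nTotal <- sum(vapply(spec$counts, length, integer(1)))
  seeds <- deriveSeeds(spec$masterSeed, nTotal)
  mags <- withSeed(spec$masterSeed + 1L,
                   rgamma(nTotal, shape = spec$driftShape,
                          rate = spec$driftShape / spec$driftMean))
  lags <- withSeed(spec$masterSeed + 2L,
                   runif(nTotal, 0, spec$responseLagMax))
  dirRad <- spec$driftDirDeg * pi / 180
  videos <- list()
  idx <- 0L
  for (env in names(spec$counts)) {
    ridged <- grepl("^Ridged", env)
    fieldOn <- !grepl("E0$", env)
    for (i in seq_along(spec$counts[[env]])) {
      idx <- idx + 1L
      nf <- spec$counts[[env]][i]
      drift <- if (fieldOn) mags[idx] * c(cos(dirRad), sin(dirRad)) else c(0, 0)
      onset <- if (fieldOn) floor(min(lags[idx], nf / 2)) else 0
      args <- c(list(imageSize = spec$imageSize, nFrames = nf,
                     seed = seeds[idx], driftVelocity = drift,
                     driftOnset = onset),
                spec$extra)
      cfg <- do.call(synthConfig, args)
      vid <- sprintf("%s_%02d", env, i)
      videos[[vid]] <- if (ridged) genRidgedVideo(cfg, vid) else
        genFlatVideo(cfg, vid)
    }
  }
  videos
}

#' Band-pass spectral anisotropy of a frame
#'
#' Log-ratio of band-pass spectral energy near the vertical frequency axis to
#' that near the horizontal frequency axis. Frames dominated by horizontal
#' bands (intensity varying along y) score positive; isotropic frames score
#' near zero. Used as a model-free sanity statistic for the synthetic
#' generator and for rotation checks.
#'
#' @param frame numeric matrix.
#' @param freqRange radial frequency band considered, cycles/pixel.
#' @param halfAngleDeg angular half-width of each sector, degrees.
#' @return a scalar; positive = horizontal-band anisotropy.
#' @export
spectralAnisotropy <- function(frame, freqRange = c(0.04, 0.35),
                               halfAngleDeg = 30) {
  S <- nrow(frame)
  stopifnot(ncol(frame) == S)
  P <- Mod(stats::fft(frame - mean(frame)))^2
  f <- wrapCoords(S) / S
  fx <- matrix(f, S, S, byrow = TRUE)
  fy <- matrix(f, S, S)
  r <- sqrt(fx^2 + fy^2)
  ang <- atan2(fy, fx) * 180 / pi
  inBand <- r >= freqRange[1] & r <= freqRange[2]
  distTo <- function(a, target) {
    d <- abs((a - target) %% 180)
    pmin(d, 180 - d)
  }
  eY <- sum(P[inBand & distTo(ang, 90) <= halfAngleDeg])
  eX <- sum(P[inBand & distTo(ang, 0) <= halfAngleDeg])
  log((eY + 1e-12) / (eX + 1e-12))
}

#' Subpixel displacement between two frames by phase correlation
#'
#' Estimates the translation taking \code{frameA} to \code{frameB} from the
#' peak of the normalised cross-power spectrum, refined to subpixel precision
#' by a parabolic fit around the peak. Used to verify that the synthetic
#' generator's imposed drift is recoverable independently of the tracking
#' pipeline.
#'
#' The cross-power normalisation is regularised by \code{eps * max|R|} so
#' that frequencies carrying no signal energy do not contribute random
#' phases (plain 1/|R| whitening is badly biased on smooth, noise-free
#' images).
#'
#' @param frameA,frameB numeric matrices of identical size.
#' @param eps relative regularisation of the spectral whitening.
#' @return \code{c(dx, dy)} in pixels: \code{frameB} is approximately
#'   \code{frameA} translated by this vector.
#' @export
phaseCorrelation <- function(frameA, frameB, eps = 1e-2) {
  stopifnot(all(dim(frameA) == dim(frameB)))
  A <- stats::fft(frameA - mean(frameA))
  B <- stats::fft(frameB - mean(frameB))
  R <- A * Conj(B)
  R <- R / (Mod(R) + eps * max(Mod(R)))
  cc <- Re(stats::fft(R, inverse = TRUE)) / length(R)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  nr <- nrow(cc); nc <- ncol(cc)
  wrap <- function(i, n) ifelse(i - 1 < n / 2, i - 1, i - 1 - n)
  refine <- function(vm, v0, vp) {
    den <- 2 * (2 * v0 - vm - vp)
    if (abs(den) < 1e-12) 0 else (vp - vm) / den
  }
  ri <- pk[1]; ci <- pk[2]
  rm1 <- cc[(ri - 2) %% nr + 1, ci]; rp1 <- cc[ri %% nr + 1, ci]
  cm1 <- cc[ri, (ci - 2) %% nc + 1]; cp1 <- cc[ri, ci %% nc + 1]
  dy <- wrap(ri, nr) + refine(rm1, cc[ri, ci], rp1)
  dx <- wrap(ci, nc) + refine(cm1, cc[ri, ci], cp1)
  # peak sits at minus the displacement of B relative to A
  c(dx = -dx, dy = -dy)
}

#' Mean drift of a video by lagged phase correlation
#'
#' Estimates the coherent per-frame drift by phase-correlating frame pairs
#' \code{lag} frames apart and taking the per-component median of the
#' per-lag displacements over all such pairs. Using a lag larger than one
#' frame makes the true shift large compared with the sub-pixel peak-locking
#' error of phase correlation, and the median rejects occasional wrong-peak
#' matches between self-similar wave textures; the default lag of 20 frames
#' also spans one full wave-slosh cycle of the synthetic generator, so
#' internal wave motion cancels.
#'
#' @param video a \linkS4class{WaveVideo} (at least \code{lag + 1} frames).
#' @param lag frame separation of correlated pairs.
#' @return \code{c(dx, dy)} in pixels/frame.
#' @export
estimateDrift <- function(video, lag = 20) {
  Tn <- nFrames(video)
  if (Tn <= lag) stop("insufficient frames: need more than 'lag' frames")
  d <- vapply(seq_len(Tn - lag), function(t)
    phaseCorrelation(getFrame(video, t), getFrame(video, t + lag)),
    numeric(2))
  apply(d, 1, stats::median) / lag
}
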