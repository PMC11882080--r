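#' Corner-detection configuration (Shi-Tomasi)
#'
#' Study settings: up to 300 corners, quality level 0.2 relative to the best
#' corner, minimum separation 7 px, and a 10 px structure-tensor window.
#'
#' @param nCorners maximum number of corners returned.
#' @param qualityLevel fraction of the maximum score below which candidate
#'   corners are rejected (in (0, 1]).
#' @param minDistance minimum Euclidean distance between returned corners,
#'   pixels.
#' @param tensorWindow side of the structure-tensor summation window, pixels
#'   (even values are widened to the next odd size for symmetry).
#' @return a list of class \code{CornerConfig}.
#' @export
cornerConfig <- function(nCorners = 300, qualityLevel = 0.2,
                         minDistance = 7, tensorWindow = 10) {
  if (qualityLevel <= 0 || qualityLevel > 1)
    stop("invalid config: qualityLevel must be in (0, 1]")
  if (minDistance < 0) stop("invalid config: minDistance must be >= 0")
  structure(list(nCorners = as.integer(nCorners),
                 qualityLevel = qualityLevel, minDistance = minDistance,
                 tensorWindow = as.integer(tensorWindow)),
            class = "CornerConfig")
}

#' Lucas-Kanade configuration
#'
#' Study settings: a 30 x 30 tracking window (centred, so effectively 31 x
#' 31) and 3 pyramid levels above the full-resolution image.
#'
#' @param window window side in pixels; even values are widened to the next
#'   odd size so the window can be centred on the tracked point.
#' @param pyramidLevels number of coarser pyramid levels (0 = none).
#' @param maxIter iterative refinement cap per level.
#' @param eps convergence threshold on the update step, pixels.
#' @param minEigFloor per-pixel floor on the smallest structure-tensor
#'   eigenvalue (scaled by window area) below which a point is lost.
#' @return a list of class \code{LKConfig}.
#' @export
lkConfig <- function(window = 30, pyramidLevels = 3, maxIter = 30,
                     eps = 0.01, minEigFloor = 1e-4) {
  if (pyramidLevels < 0) stop("invalid config: pyramidLevels must be >= 0")
  winHalf <- as.integer(floor(window / 2))
  structure(list(window = 2L * winHalf + 1L, winHalf = winHalf,
                 pyramidLevels = as.integer(pyramidLevels),
                 maxIter = as.integer(maxIter), eps = eps,
                 minEigFloor = minEigFloor),
            class = "LKConfig")
}

#' Shi-Tomasi corner score map
#'
#' Per-pixel minimum eigenvalue of the windowed structure tensor
#' \code{M = sum_w [Ix^2, IxIy; IxIy, Iy^2]}, with central-difference
#' gradients and a uniform box window. Flat regions score ~0, edges have one
#' vanishing eigenvalue, corners have both eigenvalues large.
#'
#' @param frame numeric matrix.
#' @param cfg a \code{\link{cornerConfig}}.
#' @return matrix of non-negative scores, same size as the frame.
#' @export
structureTensorScores <- function(frame, cfg = cornerConfig()) {
  g <- imageGradients(frame)
  h <- max(1L, cfg$tensorWindow %/% 2L)
  sxx <- boxSum(g$gx * g$gx, h)
  syy <- boxSum(g$gy * g$gy, h)
  sxy <- boxSum(g$gx * g$gy, h)
  tr <- sxx + syy
  disc <- sqrt(pmax((sxx - syy)^2 + 4 * sxy^2, 0))
  pmax((tr - disc) / 2, 0)
}

#' Detect corners by thresholding and greedy non-maximum suppression
#'
#' Keeps pixels scoring at least \code{qualityLevel * max(score)}, sorts them
#' by descending score, and walks the list greedily removing any corner
#' within \code{minDistance} of an already accepted one; the first
#' \code{nCorners} survivors are returned. The count decreases as the quality
#' level rises; an empty set is legitimate.
#'
#' @inheritParams structureTensorScores
#' @param margin exclude corners within this many pixels of the frame border
#'   (useful to guarantee that a subsequent tracking window fits).
#' @return data.frame with 0-based \code{x}, \code{y} and \code{score},
#'   ordered by descending score.
#' @export
detectCorners <- function(frame, cfg = cornerConfig(), margin = 0L) {
  R <- structureTensorScores(frame, cfg)
  if (margin > 0L) {
    lo <- margin + 1L
    mask <- matrix(TRUE, nrow(R), ncol(R))
    mask[lo:(nrow(R) - margin), lo:(ncol(R) - margin)] <- FALSE
    R[mask] <- 0
  }
  mx <- max(R)
  empty <- data.frame(x = numeric(0), y = numeric(0), score = numeric(0))
  if (mx <= 0) return(empty)
  cand <- which(R >= cfg$qualityLevel * mx, arr.ind = TRUE)
  sc <- R[cand]
  ord <- order(sc, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  sc <- sc[ord]
  keptX <- numeric(0); keptY <- numeric(0); keptS <- numeric(0)
  d2min <- cfg$minDistance^2
  for (i in seq_len(nrow(cand))) {
    x <- cand[i, 2] - 1; y <- cand[i, 1] - 1
    if (length(keptX) &&
        any((keptX - x)^2 + (keptY - y)^2 < d2min)) next
    keptX <- c(keptX, x); keptY <- c(keptY, y); keptS <- c(keptS, sc[i])
    if (length(keptX) >= cfg$nCorners) break
  }
  data.frame(x = keptX, y = keptY, score = keptS)
}

#' Gaussian image pyramid
#'
#' Level 1 is the input; each further level is the previous one blurred with
#' a Gaussian (sigma = 1) and decimated by 2. Levels that would fall below
#' 16 px are dropped.
#'
#' @param frame numeric matrix.
#' @param levels number of additional (coarser) levels requested.
#' @return list of matrices, finest first.
#' @export
buildPyramid <- function(frame, levels) {
  pyr <- list(frame)
  for (l in seq_len(levels)) {
    prev <- pyr[[length(pyr)]]
    if (min(dim(prev)) < 16L) break
    blurred <- EBImage::imageData(
      EBImage::gblur(prev, sigma = 1, boundary = "replicate"))
    pyr[[length(pyr) + 1L]] <- blurred[seq(1, nrow(blurred), by = 2),
                                       seq(1, ncol(blurred), by = 2),
                                       drop = FALSE]
  }
  pyr
}

#' Pyramidal Lucas-Kanade flow for a set of points
#'
#' For each point, solves the 2 x 2 normal equations of the window-summed
#' brightness-constancy residual between \code{frameA} and \code{frameB},
#' iteratively refined coarse-to-fine over a Gaussian pyramid. A point's
#' status becomes 0 (lost) when its window leaves the image, the window
#' structure tensor is near-singular, or the refinement does not converge.
#'
#' @param frameA,frameB consecutive frames (matrices) or pre-built pyramids
#'   from \code{\link{buildPyramid}}.
#' @param points data.frame or matrix with 0-based columns \code{x},
#'   \code{y}.
#' @param cfg an \code{\link{lkConfig}}.
#' @return list with \code{points} (data.frame \code{x}, \code{y} of new
#'   positions) and integer \code{status} (1 = tracked, 0 = lost).
#' @export
lkFlow <- function(frameA, frameB, points, cfg = lkConfig()) {
  pyrA <- if (is.list(frameA)) frameA else buildPyramid(frameA, cfg$pyramidLevels)
  pyrB <- if (is.list(frameB)) frameB else buildPyramid(frameB, cfg$pyramidLevels)
  nLev <- min(length(pyrA), length(pyrB))
  pts <- as.matrix(as.data.frame(points)[, c("x", "y")])
  if (!nrow(pts)) return(list(points = data.frame(x = numeric(0), y = numeric(0)),
                              status = integer(0)))
  res <- lk_track_cpp(pyrA[seq_len(nLev)], pyrB[seq_len(nLev)], pts,
                      cfg$winHalf, cfg$maxIter, cfg$eps, cfg$minEigFloor)
  list(points = data.frame(x = res$points[, 1], y = res$points[, 2]),
       status = as.integer(res$status))
}

#' Track corners through a whole video
#'
#' Detects Shi-Tomasi corners on the first frame only and follows them with
#' pyramidal Lucas-Kanade flow through every consecutive frame pair, using a
#' progressively smaller set of surviving corners; a trajectory that is lost
#' never revives.
#'
#' @param video a \linkS4class{WaveVideo} with at least 2 frames.
#' @param cornerCfg a \code{\link{cornerConfig}}.
#' @param lkCfg an \code{\link{lkConfig}}.
#' @param margin border margin forwarded to \code{\link{detectCorners}}.
#' @return a \linkS4class{TrackSet}.
#' @export
trackVideo <- function(video, cornerCfg = cornerConfig(), lkCfg = lkConfig(),
                       margin = 0L) {
  Tn <- nFrames(video)
  if (Tn < 2L) stop("insufficient frames: tracking needs at least 2")
  corners <- detectCorners(getFrame(video, 1), cornerCfg, margin = margin)
  n0 <- nrow(corners)
  rows <- vector("list", Tn)
  if (n0 == 0L) {
    return(new("TrackSet",
               tracks = data.frame(track = integer(0), frame = integer(0),
                                   x = numeric(0), y = numeric(0)),
               nFrames = as.integer(Tn), videoId = videoId(video)))
  }
  alive <- seq_len(n0)
  pos <- corners[, c("x", "y")]
  rows[[1]] <- data.frame(track = alive, frame = 0L, x = pos$x, y = pos$y)
  pyrPrev <- buildPyramid(getFrame(video, 1), lkCfg$pyramidLevels)
  for (t in 2:Tn) {
    if (!length(alive)) break
    pyrCur <- buildPyramid(getFrame(video, t), lkCfg$pyramidLevels)
    fl <- lkFlow(pyrPrev, pyrCur, pos, lkCfg)
    ok <- fl$status == 1L
    alive <- alive[ok]
    pos <- fl$points[ok, , drop = FALSE]
    if (length(alive))
      rows[[t]] <- data.frame(track = alive, frame = t - 1L,
                              x = pos$x, y = pos$y)
    pyrPrev <- pyrCur
  }
  tracks <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  tracks <- tracks[order(tracks$track, tracks$frame), ]
  rownames(tracks) <- NULL
  new("TrackSet", tracks = tracks, nFrames = as.integer(Tn),
      videoId = videoId(video))
}

#' Pooled velocity summary of a track set
#'
#' Averages the per-step displacements (pixels/frame) over all alive steps of
#' all trajectories — each step counts once, so long trajectories weigh more
#' (\code{perTrajectory = TRUE} instead averages per-trajectory means). The
#' reported magnitude is \code{v = sqrt(vx^2 + vy^2)} of the mean velocity,
#' which vanishes for zero-mean wandering even when the mean speed does not.
#'
#' @param tracks a \linkS4class{TrackSet}.
#' @param video optional \linkS4class{WaveVideo} supplying physical metadata
#'   for um/s conversions.
#' @param perTrajectory average per-trajectory means instead of pooling steps.
#' @return a \linkS4class{FlowSummary}.
#' @export
flowSummary <- function(tracks, video = NULL, perTrajectory = FALSE) {
  tr <- tracks@tracks
  steps <- do.call(rbind, lapply(split(tr, tr$track), function(d) {
    if (nrow(d) < 2L) return(NULL)
    data.frame(track = d$track[-1], dx = diff(d$x), dy = diff(d$y))
  }))
  if (is.null(steps) || !nrow(steps))
    stop("undefined summary: no tracked steps")
  if (perTrajectory) {
    vx <- mean(tapply(steps$dx, steps$track, mean))
    vy <- mean(tapply(steps$dy, steps$track, mean))
  } else {
    vx <- mean(steps$dx)
    vy <- mean(steps$dy)
  }
  v <- sqrt(vx^2 + vy^2)
  umPerS <- numeric(0)
  if (!is.null(video)) {
    f <- video@umPerPx / video@sPerFrame
    umPerS <- c(vx = vx * f, vy = vy * f, v = v * f)
  }
  new("FlowSummary", vx = vx, vy = vy, v = v,
      nSteps = nrow(steps), nTracks = length(unique(steps$track)),
      umPerS = umPerS)
}

#' Split a video into consecutive n-frame sub-videos
#'
#' Consecutive \code{n}-frame segments starting from the first frame; when
#' the frame count is not divisible by \code{n} the last \code{n} frames are
#' added as one extra segment, and a video shorter than \code{n} is returned
#' whole. A 95-frame video with \code{n = 60} therefore yields frames
#' [0, 60) and [35, 95).
#'
#' @param video a \linkS4class{WaveVideo}.
#' @param n segment length in frames (>= 2).
#' @return list of \linkS4class{WaveVideo} sub-videos; ids get a
#'   \code{_sSTART} suffix.
#' @export
subdivideVideo <- function(video, n) {
  if (n < 2) stop("invalid config: segment length must be >= 2")
  Tn <- nFrames(video)
  if (Tn <= n) return(list(video))
  starts <- seq(0L, Tn - n, by = n)
  if (Tn %% n != 0L) starts <- c(starts, Tn - n)
  lapply(starts, function(s) {
    waveVideo(frames(video)[, , (s + 1):(s + n), drop = FALSE],
              topography = topography(video), field = fieldState(video),
              umPerPx = video@umPerPx, sPerFrame = video@sPerFrame,
              videoId = sprintf("%s_s%d", videoId(video), s))
  })
}

#' Optical-flow feature table for a set of (sub)videos
#'
#' Tracks each video and summarises it as the 3-dimensional feature
#' \code{(vx, vy, v)} used for electric-field classification.
#'
#' @param videos list of \linkS4class{WaveVideo}.
#' @param cornerCfg,lkCfg detection and tracking configurations.
#' @param perTrajectory forwarded to \code{\link{flowSummary}}.
#' @return data.frame with columns \code{videoId}, \code{topography},
#'   \code{field}, \code{vx}, \code{vy}, \code{v}, \code{nFrames}.
#' @export
flowFeatureTable <- function(videos, cornerCfg = cornerConfig(),
                             lkCfg = lkConfig(), perTrajectory = FALSE) {
  rows <- lapply(videos, function(v) {
    ts <- trackVideo(v, cornerCfg, lkCfg)
    fs <- flowSummary(ts, v, perTrajectory)
    data.frame(videoId = videoId(v), topography = topography(v),
               field = fieldState(v), vx = fs@vx, vy = fs@vy, v = fs@v,
               nFrames = nFrames(v))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
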