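#' Construct a WaveVideo
#'
#' @param frames an \code{M x M x T} array, a single matrix, or a list of
#'   equally sized square matrices (temporal order preserved).
#' @param topography \code{"flat"}, \code{"ridged"} or \code{NA}.
#' @param field \code{"on"}, \code{"off"} or \code{NA}.
#' @param umPerPx micrometres per pixel.
#' @param sPerFrame seconds per frame.
#' @param videoId identifier used in train/test splits.
#' @return a validated \linkS4class{WaveVideo}.
#' @export
waveVideo <- function(frames, topography = NA_character_,
                      field = NA_character_, umPerPx = 107.52 / 512,
                      sPerFrame = 10, videoId = "video") {
  if (is.list(frames)) {
    if (!length(frames)) stop("empty input: no frames supplied")
    dims <- vapply(frames, dim, integer(2))
    if (any(dims != dims[, 1])) stop("format error: mixed frame sizes")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[1, 1], dims[2, 1], length(frames)))
  } else if (is.matrix(frames)) {
    frames <- array(frames, dim = c(dim(frames), 1L))
  }
  new("WaveVideo", frames = frames,
      topography = as.character(topography), field = as.character(field),
      umPerPx = umPerPx, sPerFrame = sPerFrame, videoId = as.character(videoId))
}

.rescaleFrames <- function(arr, normalize) {
  normalize <- match.arg(normalize, c("video", "frame", "none"))
  if (normalize == "none") return(clip01(arr))
  if (normalize == "video") {
    rng <- range(arr)
    if (diff(rng) == 0) return(array(0, dim(arr)))
    return((arr - rng[1]) / diff(rng))
  }
  for (t in seq_len(dim(arr)[3])) {
    rng <- range(arr[, , t])
    arr[, , t] <- if (diff(rng) == 0) 0 else (arr[, , t] - rng[1]) / diff(rng)
  }
  arr
}

.readImageFile <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]  # first channel of RGB input
  img
}

#' Read and write videos as multi-page TIFF stacks
#'
#' \code{loadVideo} reads either a multi-page grayscale TIFF stack or a
#' directory of per-frame TIFF/PNG images (sorted by file name).
#' \code{saveVideo} writes a 32-bit multi-page TIFF; every save/load cycle
#' reproduces intensities to the storage precision of 2^-32 (about 2.4e-10
#' on the [0, 1] scale).
#'
#' @param path file (multi-page TIFF) or directory of frame images.
#' @param normalize intensity policy: \code{"none"} (clip to [0,1], the
#'   default for data already on [0,1]), \code{"video"} (min-max over the
#'   whole stack) or \code{"frame"} (per-frame min-max). The choice is
#'   recorded nowhere in the pixels, so pick one policy per study.
#' @param ... metadata forwarded to \code{\link{waveVideo}}.
#' @return \code{loadVideo}: a \linkS4class{WaveVideo}; \code{saveVideo}:
#'   the path, invisibly.
#' @export
loadVideo <- function(path, normalize = "none", ...) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("empty input: no frame images in ", path)
    pages <- lapply(files, .readImageFile)
  } else {
    if (!file.exists(path)) stop("empty input: no such file ", path)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!length(pages)) stop("empty input: TIFF stack has no pages")
    pages <- lapply(pages, function(img)
      if (length(dim(img)) == 3L) img[, , 1] else img)
  }
  dims <- vapply(pages, dim, integer(2))
  if (any(dims != dims[, 1])) stop("format error: mixed frame sizes")
  arr <- array(unlist(pages, use.names = FALSE),
               dim = c(dims[1, 1], dims[2, 1], length(pages)))
  arr <- .rescaleFrames(arr, normalize)
  waveVideo(arr, ...)
}

#' @param video a \linkS4class{WaveVideo}.
#' @rdname loadVideo
#' @export
saveVideo <- function(video, path) {
  pages <- lapply(seq_len(nFrames(video)), function(t) getFrame(video, t))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Save or load a labeled dataset with a JSON manifest
#'
#' \code{saveDataset} writes one TIFF stack per video plus
#' \code{manifest.json} recording video ids, labels, frame counts and
#' physical metadata; \code{loadDataset} restores the labeled list.
#'
#' @param videos list of \linkS4class{WaveVideo}.
#' @param dir output directory (created if needed).
#' @return \code{saveDataset}: the directory, invisibly;
#'   \code{loadDataset}: a named list of \linkS4class{WaveVideo}.
#' @export
saveDataset <- function(videos, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- lapply(videos, function(v) {
    file <- paste0(videoId(v), ".tif")
    saveVideo(v, file.path(dir, file))
    list(videoId = videoId(v), file = file, nFrames = nFrames(v),
         topography = topography(v), field = fieldState(v),
         umPerPx = v@umPerPx, sPerFrame = v@sPerFrame)
  })
  jsonlite::write_json(unname(manifest), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname saveDataset
#' @export
loadDataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  videos <- lapply(manifest, function(m) {
    loadVideo(file.path(dir, m$file),
              topography = if (is.null(m$topography)) NA else m$topography,
              field = if (is.null(m$field)) NA else m$field,
              umPerPx = m$umPerPx, sPerFrame = m$sPerFrame,
              videoId = m$videoId)
  })
  names(videos) <- vapply(manifest, `[[`, character(1), "videoId")
  videos
}

# Linear-index matrix (p^2 x N) into a M x M frame for 0-based anchors.
.patchIndices <- function(M, p, anchorRow, anchorCol) {
  offsets <- as.vector(outer(seq_len(p), (seq_len(p) - 1L) * M, `+`))
  anchorLin <- anchorCol * M + anchorRow
  outer(offsets, anchorLin, `+`)
}

.makePatchSet <- function(frame, p, anchorRow, anchorCol, frameIndex) {
  idx <- .patchIndices(nrow(frame), p, anchorRow, anchorCol)
  X <- matrix(frame[idx], nrow = p * p)
  new("PatchSet", X = X,
      positions = data.frame(frame = frameIndex, row = anchorRow,
                             col = anchorCol),
      p = as.integer(p))
}

#' Extract patches from a frame
#'
#' \code{extractRandomPatches} draws \code{n} anchors uniformly (with
#' replacement, so patches may coincide or overlap) over the
#' \code{(M - p + 1)^2} valid top-left positions. \code{extractAllPatches}
#' returns every overlapping patch at stride 1 in row-major anchor order.
#'
#' @param frame numeric matrix (one video frame).
#' @param n number of patches to draw.
#' @param p patch side length in pixels.
#' @param seed optional seed for reproducible anchors.
#' @param frameIndex 0-based frame index recorded in the positions table.
#' @return a \linkS4class{PatchSet} with \code{d = p^2} rows.
#' @export
#' @examples
#' f <- getFrame(genFlatVideo(synthConfig(imageSize = 48, nFrames = 1,
#'                                        seed = 3)), 1)
#' ps <- extractRandomPatches(f, n = 50, p = 12, seed = 1)
#' dim(patchMatrix(ps))  # 144 x 50
extractRandomPatches <- function(frame, n, p, seed = NULL, frameIndex = 0L) {
  M <- nrow(frame)
  if (p > M) stop("invalid config: patch size exceeds frame size")
  if (n < 1) stop("invalid config: need at least one patch")
  draw <- function() {
    list(r = sample(0:(M - p), n, replace = TRUE),
         c = sample(0:(M - p), n, replace = TRUE))
  }
  a <- if (is.null(seed)) draw() else withSeed(seed, draw())
  .makePatchSet(frame, p, a$r, a$c, frameIndex)
}

#' @rdname extractRandomPatches
#' @export
extractAllPatches <- function(frame, p, frameIndex = 0L) {
  M <- nrow(frame)
  if (p > M) stop("invalid config: patch size exceeds frame size")
  nA <- M - p + 1L
  # row-major anchor order: (0,0), (0,1), ..., (0,nA-1), (1,0), ...
  anchorRow <- rep(0:(nA - 1L), each = nA)
  anchorCol <- rep(0:(nA - 1L), times = nA)
  .makePatchSet(frame, p, anchorRow, anchorCol, frameIndex)
}

#' Rotate frames and videos by multiples of 90 degrees
#'
#' Rotations are exact pixel permutations (no interpolation), counterclockwise
#' in the displayed image (row 1 at the top). With the package's y-down
#' coordinate convention a 90-degree CCW rotation maps a displacement
#' \code{(dx, dy)} to \code{(dy, -dx)}.
#'
#' @param frame numeric matrix.
#' @param degCCW rotation angle: 0, 90, 180 or 270.
#' @return the rotated matrix / \linkS4class{WaveVideo}.
#' @export
rotateFrame <- function(frame, degCCW) {
  k <- (as.integer(degCCW) %/% 90L) %% 4L
  if (degCCW %% 90 != 0) stop("rotations must be multiples of 90 degrees")
  for (i in seq_len(k)) frame <- t(frame)[ncol(frame):1, , drop = FALSE]
  frame
}

#' @param video a \linkS4class{WaveVideo}.
#' @rdname rotateFrame
#' @export
rotateVideo <- function(video, degCCW) {
  if (degCCW %% 360 == 0) return(video)
  arr <- frames(video)
  out <- array(0, dim(arr))
  for (t in seq_len(dim(arr)[3])) out[, , t] <- rotateFrame(arr[, , t], degCCW)
  waveVideo(out, topography = topography(video), field = fieldState(video),
            umPerPx = video@umPerPx, sPerFrame = video@sPerFrame,
            videoId = paste0(videoId(video), "_r", degCCW %% 360))
}

#' Four-fold rotation augmentation of a video list
#'
#' Returns, for every input video, its 0/90/180/270-degree CCW rotations with
#' labels copied. Rotated copies keep the source id as a prefix, so
#' leakage-safe splits can group them with their source video.
#'
#' @param videos list of \linkS4class{WaveVideo}.
#' @return a list of \code{4 * length(videos)} videos.
#' @export
rotateAugment <- function(videos) {
  out <- list()
  for (v in videos)
    for (deg in c(0, 90, 180, 270)) {
      rv <- rotateVideo(v, deg)
      out[[videoId(rv)]] <- rv
    }
  out
}

# Strip the rotation suffix to recover the source video id.
baseVideoId <- function(ids) sub("_r(90|180|270)$", "", ids)
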