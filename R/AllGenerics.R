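#' Accessors for actinwave objects
#'
#' Small accessor generics: \code{frames()} returns the pixel array of a
#' \linkS4class{WaveVideo}, \code{getFrame()} one frame as a matrix,
#' \code{nFrames()} the frame count, \code{frameSize()} the side length,
#' \code{topography()} / \code{fieldState()} / \code{videoId()} the metadata,
#' \code{patchMatrix()} the \code{d x N} matrix of a \linkS4class{PatchSet},
#' and \code{atoms()} the \code{d x M} matrix of a
#' \linkS4class{PatchDictionary}.
#'
#' @param x the object.
#' @param i frame number (1-based).
#' @return the slot contents described above.
#' @name accessors
#' @examples
#' v <- genFlatVideo(synthConfig(imageSize = 32, nFrames = 2, seed = 1))
#' nFrames(v); frameSize(v); topography(v)
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameSize", function(x) standardGeneric("frameSize"))
#' @rdname accessors
#' @export
setGeneric("topography", function(x) standardGeneric("topography"))
#' @rdname accessors
#' @export
setGeneric("fieldState", function(x) standardGeneric("fieldState"))
#' @rdname accessors
#' @export
setGeneric("videoId", function(x) standardGeneric("videoId"))
#' @rdname accessors
#' @export
setGeneric("patchMatrix", function(x) standardGeneric("patchMatrix"))
#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname accessors
setMethod("frames", "WaveVideo", function(x) x@frames)
#' @rdname accessors
setMethod("getFrame", "WaveVideo", function(x, i) x@frames[, , i])
#' @rdname accessors
setMethod("nFrames", "WaveVideo", function(x) dim(x@frames)[3])
#' @rdname accessors
setMethod("frameSize", "WaveVideo", function(x) dim(x@frames)[1])
#' @rdname accessors
setMethod("topography", "WaveVideo", function(x) x@topography)
#' @rdname accessors
setMethod("fieldState", "WaveVideo", function(x) x@field)
#' @rdname accessors
setMethod("videoId", "WaveVideo", function(x) x@videoId)
#' @rdname accessors
setMethod("patchMatrix", "PatchSet", function(x) x@X)
#' @rdname accessors
setMethod("atoms", "PatchDictionary", function(x) x@D)

setMethod("show", "WaveVideo", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "WaveVideo '%s': %d x %d px, %d frames | topography=%s field=%s | %.3f um/px, %g s/frame\n",
    object@videoId, d[1], d[2], d[3], object@topography, object@field,
    object@umPerPx, object@sPerFrame))
})

setMethod("show", "PatchSet", function(object) {
  cat(sprintf("PatchSet: %d patches of %d x %d px (d = %d)\n",
              ncol(object@X), object@p, object@p, nrow(object@X)))
})

setMethod("show", "PatchDictionary", function(object) {
  cat(sprintf("PatchDictionary: %d atoms of dimension %d (lambda = %g%s%s)\n",
              ncol(object@D), nrow(object@D), object@lambda,
              if (object@centered) ", patch-mean centered" else "",
              if (length(object@scores)) ", ranked" else ""))
})

setMethod("show", "MorletBank", function(object) {
  cat(sprintf(
    "MorletBank: J=%d scales x L=%d orientations + low-pass = %d filters at %d px\n",
    object@J, object@L, object@J * object@L + 1L, object@size))
})

setMethod("show", "ScatterMaps", function(object) {
  d <- dim(object@maps)
  cat(sprintf("ScatterMaps: %d maps of %d x %d px\n", d[3], d[1], d[2]))
})

setMethod("show", "TrackSet", function(object) {
  cat(sprintf("TrackSet '%s': %d trajectories over %d frames (%d alive at end)\n",
              object@videoId, length(unique(object@tracks$track)),
              object@nFrames,
              sum(tapply(object@tracks$frame, object@tracks$track, max) ==
                    object@nFrames - 1L)))
})

setMethod("show", "FlowSummary", function(object) {
  cat(sprintf(
    "FlowSummary: vx=%.4f vy=%.4f |v|=%.4f px/frame (%d steps, %d tracks)\n",
    object@vx, object@vy, object@v, object@nSteps, object@nTracks))
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan: %d leakage-safe splits\n", length(object@splits)))
  for (i in seq_along(object@splits))
    cat(sprintf("  split %d: %d train / %d test videos\n", i,
                length(object@splits[[i]]$train), length(object@splits[[i]]$test)))
})

setMethod("show", "LinearSVM", function(object) {
  cat(sprintf("LinearSVM: %d features, penalty=%s, C=%g (%d nonzero weights)\n",
              length(object@w), object@penalty, object@cost,
              sum(object@w != 0)))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: frame accuracy %.1f%% (%d rows)",
              100 * object@frameAccuracy, nrow(object@scores)))
  if (nrow(object@videoPred))
    cat(sprintf(", video accuracy %.1f%% (%d videos)",
                100 * object@videoAccuracy, nrow(object@videoPred)))
  cat("\n")
})
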