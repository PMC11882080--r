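#' @import methods
NULL

#' Grayscale actin-wave video with microenvironment metadata
#'
#' Container for one fluorescence time-lapse video: an \code{M x M x T} array
#' of intensities in \code{[0, 1]} plus the metadata needed downstream
#' (ground-truth labels when known, physical pixel size and frame interval).
#'
#' Coordinates follow the imaging convention used throughout the package:
#' 0-based, origin at the top-left pixel, \code{x} = column (rightward),
#' \code{y} = row (downward). Velocities are reported in this frame.
#'
#' @slot frames numeric array, \code{M x M x T}, values in \code{[0, 1]}.
#' @slot topography \code{"flat"}, \code{"ridged"} or \code{NA} (unlabeled).
#' @slot field electric-field state: \code{"on"}, \code{"off"} or \code{NA}.
#' @slot umPerPx physical pixel size in micrometres (default 107.52/512).
#' @slot sPerFrame frame interval in seconds (default 10, i.e. 0.1 frames/s).
#' @slot videoId identifier used for leakage-safe train/test splits.
#' @exportClass WaveVideo
setClass("WaveVideo", slots = c(
  frames     = "array",
  topography = "character",
  field      = "character",
  umPerPx    = "numeric",
  sPerFrame  = "numeric",
  videoId    = "character"
))

setValidity("WaveVideo", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be an M x M x T array")
  if (d[1] != d[2]) return("frames must be square")
  if (d[3] < 1L) return("video must contain at least one frame")
  if (!all(is.finite(object@frames))) return("frame intensities must be finite")
  rng <- range(object@frames)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    return("frame intensities must lie in [0, 1]")
  if (!is.na(object@topography) && !object@topography %in% c("flat", "ridged"))
    return("topography must be 'flat', 'ridged' or NA")
  if (!is.na(object@field) && !object@field %in% c("on", "off"))
    return("field must be 'on', 'off' or NA")
  if (!(length(object@umPerPx) == 1L && object@umPerPx > 0))
    return("umPerPx must be a positive scalar")
  if (!(length(object@sPerFrame) == 1L && object@sPerFrame > 0))
    return("sPerFrame must be a positive scalar")
  TRUE
})

#' Set of vectorised square image patches
#'
#' Each column of \code{X} is one vectorised \code{p x p} patch (column-major
#' within the patch, so \code{d = p^2}); \code{positions} records where each
#' column came from as 0-based \code{(frame, row, col)} top-left anchors.
#'
#' @slot X numeric matrix, \code{p^2 x N}.
#' @slot positions data.frame with columns \code{frame}, \code{row},
#'   \code{col}; row \code{i} locates column \code{i} of \code{X}.
#' @slot p patch side length in pixels.
#' @exportClass PatchSet
setClass("PatchSet", slots = c(
  X = "matrix", positions = "data.frame", p = "integer"
))

setValidity("PatchSet", function(object) {
  if (nrow(object@X) != object@p^2) return("nrow(X) must equal p^2")
  if (ncol(object@X) != nrow(object@positions))
    return("positions must have one row per patch column")
  if (!all(c("frame", "row", "col") %in% names(object@positions)))
    return("positions needs columns frame, row, col")
  TRUE
})

#' Learned patch dictionary
#'
#' A \code{d x M} matrix of unit-norm atoms learned by alternating sparse
#' coding and block-coordinate dictionary updates, together with the sparsity
#' weight it was trained at and (after ranking) per-atom leave-one-atom-out
#' reconstruction-error scores.
#'
#' @slot D numeric matrix, \code{d x M}; every column has unit Euclidean norm.
#' @slot lambda sparsity weight used during learning.
#' @slot centered whether per-patch means were subtracted before encoding
#'   (they are added back for reconstruction).
#' @slot scores per-atom reconstruction-error scores (empty until ranked).
#' @exportClass PatchDictionary
setClass("PatchDictionary", slots = c(
  D = "matrix", lambda = "numeric", centered = "logical", scores = "numeric"
))

setValidity("PatchDictionary", function(object) {
  nrm <- sqrt(colSums(object@D^2))
  if (any(abs(nrm - 1) > 1e-8)) return("dictionary atoms must have unit norm")
  if (length(object@scores) && length(object@scores) != ncol(object@D))
    return("scores must be empty or one per atom")
  TRUE
})

#' Morlet wavelet filter bank for the first-order scattering transform
#'
#' Holds one low-pass Gaussian \code{phi} at scale \code{2^J} and \code{J*L}
#' oriented band-pass Morlet wavelets \code{psi[j, l]}, all stored in the
#' frequency domain at a fixed transform size. The angle \code{thetaDeg[l]}
#' labels the orientation of the filter's elongated stripes, so a horizontal
#' image feature is matched by the \code{theta = 0} filter.
#'
#' @slot psiF list of \code{J*L} complex matrices (FFTs of the wavelets),
#'   ordered scale-major: \code{(j=1, l=1..L), (j=2, l=1..L), ...}.
#' @slot phiF FFT of the low-pass filter (normalised to unit DC gain).
#' @slot J number of dyadic scales.
#' @slot L number of orientations.
#' @slot size transform side length in pixels (divisible by \code{2^J}).
#' @slot thetaDeg orientation grid, \code{90 - (l-1) * 180/L} degrees.
#' @slot sigma0 Gaussian width of the mother wavelet in pixels.
#' @slot xi0 central frequency of the mother wavelet in radians/pixel.
#' @slot slant anisotropy of the Gaussian envelope (smaller = more elongated).
#' @exportClass MorletBank
setClass("MorletBank", slots = c(
  psiF = "list", phiF = "matrix", J = "integer", L = "integer",
  size = "integer", thetaDeg = "numeric",
  sigma0 = "numeric", xi0 = "numeric", slant = "numeric"
))

setValidity("MorletBank", function(object) {
  if (length(object@psiF) != object@J * object@L)
    return("bank must hold J*L band-pass filters")
  if (object@size %% 2L^object@J != 0L)
    return("transform size must be divisible by 2^J")
  if (length(object@thetaDeg) != object@L)
    return("thetaDeg must have one angle per orientation")
  TRUE
})

#' Scattering output maps of one frame
#'
#' The \code{1 + J*L} downsampled maps produced by the zeroth- and first-order
#' scattering transform of one frame: \code{S0 = I * phi} and
#' \code{S1[j,l] = |I * psi[j,l]| * phi}, each subsampled by \code{2^J}.
#'
#' @slot maps numeric array \code{m x m x (1 + J*L)} with
#'   \code{m = size / 2^J}; map 1 is S0, then S1 ordered scale-major.
#' @slot index data.frame describing each map: \code{alpha}, \code{order}
#'   (0 or 1), \code{j}, \code{l}, \code{thetaDeg} (NA for S0).
#' @exportClass ScatterMaps
setClass("ScatterMaps", slots = c(maps = "array", index = "data.frame"))

setValidity("ScatterMaps", function(object) {
  d <- dim(object@maps)
  if (length(d) != 3L || d[1] != d[2]) return("maps must be m x m x n")
  if (d[3] != nrow(object@index)) return("index must describe every map")
  TRUE
})

#' Corner trajectories tracked across a video
#'
#' Long-format trajectories of Shi-Tomasi corners tracked by pyramidal
#' Lucas-Kanade flow. A trajectory contributes one row per frame in which it
#' is alive; it terminates (and never revives) at the first tracking failure.
#'
#' @slot tracks data.frame with columns \code{track}, \code{frame} (0-based),
#'   \code{x}, \code{y} (0-based pixel coordinates).
#' @slot nFrames number of frames in the source video.
#' @slot videoId identifier of the source video.
#' @exportClass TrackSet
setClass("TrackSet", slots = c(
  tracks = "data.frame", nFrames = "integer", videoId = "character"
))

setValidity("TrackSet", function(object) {
  tr <- object@tracks
  if (!all(c("track", "frame", "x", "y") %in% names(tr)))
    return("tracks needs columns track, frame, x, y")
  if (nrow(tr)) {
    byTrack <- split(tr$frame, tr$track)
    if (any(!vapply(byTrack, function(f) all(diff(f) == 1L), logical(1))))
      return("each trajectory must cover strictly consecutive frames")
  }
  TRUE
})

#' Pooled optical-flow velocity summary
#'
#' Mean per-step corner velocity of a (sub)video: \code{vx} and \code{vy} are
#' averages over all alive steps of all trajectories (pixels/frame) and
#' \code{v = sqrt(vx^2 + vy^2)} is the magnitude of that mean. When physical
#' metadata is available the same quantities are also given in micrometres
#' per second.
#'
#' @slot vx,vy mean velocity components, pixels/frame.
#' @slot v magnitude of the mean velocity, pixels/frame.
#' @slot nSteps number of pooled trajectory steps.
#' @slot nTracks number of contributing trajectories.
#' @slot umPerS optional named vector \code{(vx, vy, v)} in um/s.
#' @exportClass FlowSummary
setClass("FlowSummary", slots = c(
  vx = "numeric", vy = "numeric", v = "numeric",
  nSteps = "integer", nTracks = "integer", umPerS = "numeric"
))

#' Leakage-safe assignment of videos to train/test splits
#'
#' @slot splits list; each element is \code{list(train =, test =)} of video
#'   ids with empty intersection.
#' @slot seed RNG seed the plan was drawn with.
#' @exportClass SplitPlan
setClass("SplitPlan", slots = c(splits = "list", seed = "integer"))

setValidity("SplitPlan", function(object) {
  for (s in object@splits) {
    if (!all(c("train", "test") %in% names(s)))
      return("each split needs train and test components")
    if (length(intersect(s$train, s$test)))
      return("a video id appears in both train and test of one split")
  }
  TRUE
})

#' Linear support-vector machine
#'
#' Linear max-margin classifier \code{f(v) = w . v + b} trained with the
#' squared hinge loss and an L1 or L2 penalty on \code{w} (the intercept is
#' not penalised), following the convention that the loss term carries the
#' weight \code{C}.
#'
#' @slot w weight vector, one entry per feature.
#' @slot b intercept.
#' @slot penalty \code{"l1"} or \code{"l2"}.
#' @slot cost the loss weight C.
#' @slot objective value of the training objective at the solution.
#' @slot converged optimiser convergence flag.
#' @exportClass LinearSVM
setClass("LinearSVM", slots = c(
  w = "numeric", b = "numeric", penalty = "character", cost = "numeric",
  objective = "numeric", converged = "logical"
))

#' Classification report for one train/test split
#'
#' Frame-level (or sub-video-level) scores and predictions on the test set,
#' the confusion matrices (true labels on rows), and majority-vote per-video
#' labels when frame voting applies.
#'
#' @slot scores data.frame with columns \code{videoId}, \code{label},
#'   \code{score}, \code{pred} for every test row.
#' @slot frameConfusion 2x2 matrix of test rows, true class on rows.
#' @slot frameAccuracy fraction of test rows classified correctly.
#' @slot videoConfusion 2x2 matrix of test videos after majority voting.
#' @slot videoAccuracy fraction of test videos classified correctly.
#' @slot videoPred data.frame of per-video majority-vote results.
#' @slot model the fitted \linkS4class{LinearSVM}.
#' @slot split \code{list(train =, test =)} of video ids used.
#' @exportClass EvalReport
setClass("EvalReport", slots = c(
  scores = "data.frame",
  frameConfusion = "matrix", frameAccuracy = "numeric",
  videoConfusion = "matrix", videoAccuracy = "numeric",
  videoPred = "data.frame",
  model = "LinearSVM", split = "list"
))
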