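#' Run one of the study's classification experiments end-to-end
#'
#' Orchestrates a full binary-classification experiment on a labeled set of
#' videos: selects the videos the experiment layout asks for, extracts
#' features on the requested track, builds leakage-safe video-level splits,
#' trains a linear SVM per split with the track's penalty/C convention
#' (dictionary: L1, C = 1000; scattering: L1, C = 5000; flow: L2, C = 10)
#' and evaluates with majority voting for the frame-level tracks.
#'
#' Layouts: \code{"topo-nofield"} classifies flat vs ridged using only
#' field-off videos; \code{"topo-all"} uses all videos; \code{"topo-field"}
#' only field-on videos; \code{"field"} classifies field-on vs field-off
#' regardless of topography. Positive classes are ridged and field-on. Frame
#' tracks use class-wise grouped splits (every video tested exactly once);
#' the flow track uses random 2:1 splits.
#'
#' @param videos named list of labeled \linkS4class{WaveVideo}.
#' @param track \code{"dict"}, \code{"scatter"} or \code{"flow"}.
#' @param experiment one of the layouts above.
#' @param nSplits number of train/test splits.
#' @param seed seed for split sampling (and dictionary learning).
#' @param dictCfg \code{\link{dictConfig}} for the dict track.
#' @param patchesPerFrame training patches per frame (dict track).
#' @param bank \linkS4class{MorletBank} for the scatter track (default built
#'   to match the frame size).
#' @param cornerCfg,lkCfg flow-track configurations.
#' @param penalty,C override the track's SVM convention.
#' @param features optionally, a precomputed feature table for these videos
#'   (skips feature extraction).
#' @return list with \code{reports} (one \linkS4class{EvalReport} per
#'   split), \code{summary} (accuracy data.frame), \code{features}, and for
#'   the dict track the reduced \code{dictionary}.
#' @export
runExperiment <- function(videos, track = c("dict", "scatter", "flow"),
                          experiment = c("topo-nofield", "topo-all",
                                         "topo-field", "field"),
                          nSplits = 3, seed = 1,
                          dictCfg = dictConfig(), patchesPerFrame = 300,
                          bank = NULL,
                          cornerCfg = cornerConfig(), lkCfg = lkConfig(),
                          penalty = NULL, C = NULL, features = NULL) {
  track <- match.arg(track)
  experiment <- match.arg(experiment)
  fieldOf <- vapply(videos, fieldState, character(1))
  sel <- switch(experiment,
                "topo-nofield" = fieldOf == "off",
                "topo-all" = rep(TRUE, length(videos)),
                "topo-field" = fieldOf == "on",
                "field" = rep(TRUE, length(videos)))
  videos <- videos[sel]
  if (experiment == "field" && track != "flow")
    stopifnot(length(unique(vapply(videos, fieldState, character(1)))) == 2L)
  labelCol <- if (experiment == "field") "field" else "topography"
  positive <- if (experiment == "field") "on" else "ridged"

  svmSettings <- switch(track,
                        dict = list(penalty = "l1", C = 1000),
                        scatter = list(penalty = "l1", C = 5000),
                        flow = list(penalty = "l2", C = 10))
  if (!is.null(penalty)) svmSettings$penalty <- penalty
  if (!is.null(C)) svmSettings$C <- C

  dictionary <- NULL
  if (is.null(features)) {
    features <- switch(track,
      dict = {
        patches <- collectTrainingPatches(videos, nPerFrame = patchesPerFrame,
                                          p = dictCfg$patchSize, seed = seed)
        full <- learnDictionary(patches, dictCfg)
        dictionary <- rankAndReduce(patches, full, dictCfg$retainedAtoms)
        dictFeatureTable(videos, dictionary)
      },
      scatter = {
        if (is.null(bank)) {
          sz <- frameSize(videos[[1]])
          bank <- buildMorletBank(size = sz)
        }
        scatterFeatureTable(videos, bank)
      },
      flow = flowFeatureTable(videos, cornerCfg, lkCfg))
  }

  ids <- unique(features$videoId)
  labelOf <- features[[labelCol]][match(ids, features$videoId)]
  plan <- if (track == "flow")
    makeRandomSplits(ids, nSplits = nSplits, seed = seed)
  else
    makeVideoSplits(ids, labelOf, nSplits = nSplits, seed = seed)
  reports <- runSplits(features, plan, labelCol, positive,
                       penalty = svmSettings$penalty, C = svmSettings$C,
                       vote = track != "flow")
  summary <- data.frame(
    split = seq_along(reports),
    frameAccuracy = vapply(reports, function(r) r@frameAccuracy, numeric(1)),
    videoAccuracy = vapply(reports, function(r) r@videoAccuracy, numeric(1)))
  list(reports = reports, summary = summary, features = features,
       dictionary = dictionary, plan = plan)
}

#' Sub-video sweep of flow-track field classification
#'
#' Implements the segment-length experiment: every video is cut into
#' consecutive \code{n}-frame sub-videos (plus the final \code{n} frames when
#' the length is not divisible), each sub-video is tracked and summarised as
#' \code{(vx, vy, v)}, and field-on vs field-off classification is repeated
#' over \code{nSplits} random 2:1 splits (grouped by source video, so
#' sub-videos of one video never straddle a split). Reports mean and
#' standard deviation of the test accuracy per \code{n}.
#'
#' @param videos named list of labeled \linkS4class{WaveVideo}.
#' @param nValues segment lengths to sweep (study: 30..80 frames).
#' @param nSplits random splits per segment length (study: 8).
#' @param seed RNG seed.
#' @param cornerCfg,lkCfg tracking configurations.
#' @param vOnly use the velocity magnitude as the sole feature.
#' @return data.frame with columns \code{n}, \code{meanAccuracy},
#'   \code{sdAccuracy}, \code{nSubvideos}; per-split accuracies in
#'   \code{attr(, "accuracies")}.
#' @export
runSubvideoSweep <- function(videos, nValues = c(30, 40, 50, 60, 70, 80),
                             nSplits = 8, seed = 1,
                             cornerCfg = cornerConfig(), lkCfg = lkConfig(),
                             vOnly = FALSE) {
  accs <- list()
  rows <- list()
  for (n in nValues) {
    subs <- unlist(lapply(videos, subdivideVideo, n = n), recursive = FALSE)
    feat <- flowFeatureTable(subs, cornerCfg, lkCfg)
    feat$source <- sub("_s[0-9]+$", "", feat$videoId)
    if (vOnly) feat <- feat[, c("videoId", "source", "field", "v")]
    plan <- withSeed(seed + n, {
      srcs <- unique(feat$source)
      nTest <- max(1L, round(length(srcs) / 3))
      sp <- lapply(seq_len(nSplits), function(k) {
        test <- sample(srcs, nTest)
        list(train = feat$videoId[!feat$source %in% test],
             test = feat$videoId[feat$source %in% test])
      })
      new("SplitPlan", splits = sp, seed = as.integer(seed + n))
    })
    reports <- runSplits(feat, plan, "field", "on",
                         penalty = "l2", C = 10, vote = FALSE)
    acc <- vapply(reports, function(r) r@frameAccuracy, numeric(1))
    accs[[as.character(n)]] <- acc
    rows[[as.character(n)]] <- data.frame(
      n = n, meanAccuracy = mean(acc), sdAccuracy = stats::sd(acc),
      nSubvideos = nrow(feat))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "accuracies") <- accs
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
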