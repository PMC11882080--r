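test_that("grouped video splits match the study layout and never leak", {
  ids <- c(sprintf("R%02d", 1:5), sprintf("F%02d", 1:12))
  classes <- c(rep("ridged", 5), rep("flat", 12))
  plan <- makeVideoSplits(ids, classes, nSplits = 3, seed = 2)
  testSizes <- vapply(plan@splits, function(s) length(s$test), integer(1))
  ridgedTest <- vapply(plan@splits, function(s)
    sum(grepl("^R", s$test)), integer(1))
  flatTest <- vapply(plan@splits, function(s)
    sum(grepl("^F", s$test)), integer(1))
  # 5 ridged split as 2/2/1, 12 flat as 4/4/4
  expect_identical(sort(ridgedTest), c(1L, 2L, 2L))
  expect_identical(flatTest, rep(4L, 3))
  expect_identical(sort(testSizes), c(5L, 6L, 6L))
  # every video tested exactly once, no leakage in any split
  allTest <- unlist(lapply(plan@splits, `[[`, "test"))
  expect_identical(sort(allTest), sort(ids))
  for (s in plan@splits) {
    expect_length(intersect(s$train, s$test), 0L)
    expect_identical(sort(c(s$train, s$test)), sort(ids))
  }
  expect_error(makeVideoSplits(ids[1:4], c("a", "a", "b", "b"), nSplits = 3),
               "infeasible split")
})

test_that("three-way split of 3 + 3 videos tests each video exactly once", {
  ids <- sprintf("v%d", 1:6)
  classes <- rep(c("a", "b"), each = 3)
  plan <- makeVideoSplits(ids, classes, nSplits = 3, seed = 1)
  allTest <- unlist(lapply(plan@splits, `[[`, "test"))
  expect_identical(sort(allTest), sort(ids))
  expect_true(all(vapply(plan@splits, function(s) length(s$test), integer(1)) == 2L))
})

test_that("rotated copies stay on the same side of every split", {
  ids <- as.vector(outer(sprintf("v%d", 1:6), c("", "_r90", "_r180", "_r270"),
                         paste0))
  classes <- rep(rep(c("a", "b"), each = 3), 4)
  plan <- makeVideoSplits(ids, classes, nSplits = 3, seed = 4)
  for (s in plan@splits) {
    base <- sub("_r(90|180|270)$", "", s$test)
    expect_length(intersect(base, sub("_r(90|180|270)$", "", s$train)), 0L)
    # each tested source contributes all 4 rotations
    expect_identical(length(s$test) %% 4L, 0L)
  }
})

test_that("random 2:1 splits have the study proportions", {
  ids <- sprintf("v%02d", 1:29)
  plan <- makeRandomSplits(ids, nSplits = 3, seed = 9)
  for (s in plan@splits) {
    expect_identical(length(s$test), 10L)
    expect_identical(length(s$train), 19L)
    expect_length(intersect(s$train, s$test), 0L)
  }
})

test_that("the linear SVM separates separable data and honours its penalties", {
  set.seed(1)
  X <- rbind(matrix(rnorm(40, 2), 20), matrix(rnorm(40, -2), 20))
  y <- rep(c(1, -1), each = 20)
  m <- trainSVM(X, y, "l2", C = 10)
  expect_true(m@converged)
  expect_identical(unname(sign(predict(m, X))), y)
  # L1 with small C zeroes out uninformative weights exactly
  Xn <- cbind(X, matrix(rnorm(40 * 8), 40))
  m1 <- trainSVM(Xn, y, "l1", C = 0.01)
  expect_gt(sum(m1@w == 0), 0)
  # duplicated feature column under L2: weight splits evenly
  Xd <- cbind(X[, 1], X[, 1], X[, 2])
  m2 <- trainSVM(Xd, y, "l2", C = 10)
  expect_lt(abs(m2@w[1] - m2@w[2]), 1e-3)
  # single-class input is degenerate
  expect_error(trainSVM(X[1:20, ], y[1:20], "l2", C = 1),
               "degenerate training")
  # labels can be characters with an explicit positive class
  mc <- trainSVM(X, ifelse(y == 1, "on", "off"), "l2", C = 10,
                 positive = "on")
  expect_identical(unname(sign(predict(mc, X))), y)
})

test_that("the decision direction agrees with an independent SVM implementation", {
  skip_if_not_installed("e1071")
  set.seed(7)
  X <- rbind(matrix(rnorm(60, 1.5), 30), matrix(rnorm(60, -1.5), 30))
  y <- rep(c(1, -1), each = 30)
  m <- trainSVM(X, y, "l2", C = 10)
  sv <- e1071::svm(X, factor(y, levels = c(1, -1)), kernel = "linear",
                   cost = 10, scale = FALSE)
  w <- drop(t(sv$coefs) %*% sv$SV)
  cosang <- sum(w * m@w) / sqrt(sum(w^2) * sum(m@w^2))
  expect_gt(cosang, 0.99)
})

test_that("majority voting labels videos correctly despite frame errors", {
  mkTable <- function(scores, videoId) {
    data.frame(videoId = videoId, label = "ridged",
               v1 = scores, stringsAsFactors = FALSE)
  }
  model <- new("LinearSVM", w = 1, b = 0, penalty = "l2", cost = 1,
               objective = 0, converged = TRUE)
  # video A: 4 of 31 frames on the wrong side; video B: 26 of 60
  tab <- rbind(mkTable(c(rep(1, 27), rep(-1, 4)), "A"),
               mkTable(c(rep(1, 34), rep(-1, 26)), "B"))
  rep1 <- evaluateModel(model, tab, "label", positive = "ridged")
  expect_identical(rep1@videoPred$pred, c(1, 1))
  expect_identical(rep1@videoAccuracy, 1)
  expect_identical(rep1@videoPred$nMisclassified, c(4L, 26L))
  # frame-level confusion rows sum to the per-class test counts
  expect_identical(sum(rep1@frameConfusion[1, ]), 91L)
  # exact tie broken by the sign of the mean score
  tie <- mkTable(c(2, 2, -1, -1), "T")
  repT <- evaluateModel(model, tie, "label", positive = "ridged")
  expect_identical(repT@videoPred$pred, 1)
  tie2 <- mkTable(c(1, 1, -2, -2), "T2")
  expect_identical(evaluateModel(model, tie2, "label",
                                 positive = "ridged")@videoPred$pred, -1)
})

test_that("voting can only help when per-video error rates are below one half", {
  vids <- frameTrackVideos()
  off <- vids[vapply(vids, fieldState, character(1)) == "off"]
  bank <- buildMorletBank(size = 64)
  res <- runExperiment(off, "scatter", "topo-nofield", nSplits = 3, seed = 3,
                       bank = bank)
  for (r in res$reports) {
    expect_identical(sum(r@frameConfusion), nrow(r@scores))
    if (all(r@videoPred$nMisclassified / r@videoPred$nFrames < 0.5))
      expect_gte(r@videoAccuracy, r@frameAccuracy)
  }
})

test_that("mixed-field topography layouts run end-to-end without leakage", {
  vids <- frameTrackVideos()
  bank <- buildMorletBank(size = 64)
  res <- runExperiment(vids, "scatter", "topo-all", nSplits = 3, seed = 11,
                       bank = bank)
  expect_length(res$reports, 3L)
  for (s in res$plan@splits)
    expect_length(intersect(s$train, s$test), 0L)
  # every selected video appears in exactly one test set
  allTest <- unlist(lapply(res$plan@splits, `[[`, "test"))
  expect_identical(sort(allTest), sort(unique(res$features$videoId)))
  expect_true(all(res$summary$frameAccuracy >= 0))
})

test_that("rotation augmentation degrades dictionary classification only mildly", {
  vids <- frameTrackVideos()
  off <- vids[vapply(vids, fieldState, character(1)) == "off"]
  cfg <- dictConfig(nAtoms = 32, patchSize = 12, lambda = 1,
                    retainedAtoms = 16, epochs = 6, seed = 7)
  base <- runExperiment(off, "dict", "topo-nofield", nSplits = 3, seed = 7,
                        dictCfg = cfg, patchesPerFrame = 100)
  aug <- runExperiment(rotateAugment(off), "dict", "topo-nofield",
                       nSplits = 3, seed = 7, dictCfg = cfg,
                       patchesPerFrame = 100)
  expect_gt(mean(aug$summary$frameAccuracy),
            mean(base$summary$frameAccuracy) - 0.10)
  # no rotated copy of a test video ever appears in training
  for (s in aug$plan@splits) {
    expect_length(intersect(sub("_r(90|180|270)$", "", s$train),
                            sub("_r(90|180|270)$", "", s$test)), 0L)
  }
})
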