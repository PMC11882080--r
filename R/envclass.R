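#' Leakage-safe video-level train/test splits
#'
#' \code{makeVideoSplits} partitions the videos of each class into
#' \code{nSplits} groups of as-equal-as-possible size (e.g. 5 ridged videos
#' into groups of 2/2/1) and builds one split per group: that group is the
#' test set, all other videos the training set, so every video is tested
#' exactly once and no video contributes frames to both sides of any split.
#' \code{makeRandomSplits} instead draws \code{nSplits} independent random
#' splits at a fixed test fraction (the 2:1 train:test layout used for flow
#' features).
#'
#' Ids that differ only by a rotation suffix (\code{_r90} etc., as produced
#' by \code{\link{rotateAugment}}) are grouped with their source video, so
#' rotated copies can never leak across a split.
#'
#' @param ids character vector of video ids.
#' @param classes class label per id (same length).
#' @param nSplits number of splits.
#' @param seed RNG seed.
#' @param testFraction fraction of videos in each test set (random splits).
#' @return a \linkS4class{SplitPlan}.
#' @export
makeVideoSplits <- function(ids, classes, nSplits = 3, seed = 1) {
  base <- baseVideoId(ids)
  byClass <- split(unique(base), classes[!duplicated(base)])
  short <- names(byClass)[vapply(byClass, length, integer(1)) < nSplits]
  if (length(short))
    stop("infeasible split: class '", short[1], "' has fewer videos than splits")
  groupsOf <- function(v) {
    v <- sample(v)
    split(v, rep(seq_len(nSplits), length.out = length(v)))
  }
  grouped <- withSeed(seed, lapply(byClass, groupsOf))
  expand <- function(baseIds) ids[base %in% baseIds]
  splits <- lapply(seq_len(nSplits), function(k) {
    test <- unlist(lapply(grouped, `[[`, k), use.names = FALSE)
    list(train = expand(setdiff(unique(base), test)), test = expand(test))
  })
  new("SplitPlan", splits = splits, seed = as.integer(seed))
}

#' @rdname makeVideoSplits
#' @export
makeRandomSplits <- function(ids, nSplits = 3, testFraction = 1 / 3,
                             seed = 1) {
  base <- unique(baseVideoId(ids))
  nTest <- max(1L, round(length(base) * testFraction))
  allBase <- baseVideoId(ids)
  splits <- withSeed(seed, lapply(seq_len(nSplits), function(k) {
    test <- sample(base, nTest)
    list(train = ids[!allBase %in% test], test = ids[allBase %in% test])
  }))
  new("SplitPlan", splits = splits, seed = as.integer(seed))
}

# Squared-hinge objective/gradient; w is the full parameter vector with the
# intercept last. For the L1 path, par = (w+, w-, b) with box constraints.
.svmObjective <- function(X, y, C, penalty) {
  nF <- ncol(X)
  if (penalty == "l2") {
    fn <- function(par) {
      w <- par[seq_len(nF)]; b <- par[nF + 1L]
      h <- pmax(0, 1 - y * (drop(X %*% w) + b))
      C * sum(h^2) + 0.5 * sum(w^2)
    }
    gr <- function(par) {
      w <- par[seq_len(nF)]; b <- par[nF + 1L]
      h <- pmax(0, 1 - y * (drop(X %*% w) + b))
      gw <- -2 * C * drop(crossprod(X, y * h)) + w
      c(gw, -2 * C * sum(y * h))
    }
    list(fn = fn, gr = gr, par0 = numeric(nF + 1L),
         lower = rep(-Inf, nF + 1L),
         toW = function(par) list(w = par[seq_len(nF)], b = par[nF + 1L]))
  } else {
    fn <- function(par) {
      w <- par[seq_len(nF)] - par[nF + seq_len(nF)]
      b <- par[2L * nF + 1L]
      h <- pmax(0, 1 - y * (drop(X %*% w) + b))
      C * sum(h^2) + sum(par[seq_len(2L * nF)])
    }
    gr <- function(par) {
      w <- par[seq_len(nF)] - par[nF + seq_len(nF)]
      b <- par[2L * nF + 1L]
      h <- pmax(0, 1 - y * (drop(X %*% w) + b))
      g <- -2 * C * drop(crossprod(X, y * h))
      c(g + 1, -g + 1, -2 * C * sum(y * h))
    }
    list(fn = fn, gr = gr, par0 = numeric(2L * nF + 1L),
         lower = c(rep(0, 2L * nF), -Inf),
         toW = function(par) list(w = par[seq_len(nF)] - par[nF + seq_len(nF)],
                                  b = par[2L * nF + 1L]))
  }
}

#' Train a linear SVM with squared hinge loss
#'
#' Minimises \code{C * sum_i max(0, 1 - y_i (w . x_i + b))^2 + P(w)} with
#' \code{P(w) = ||w||_1} or \code{0.5 ||w||_2^2} (intercept unpenalised), via
#' L-BFGS-B from a zero start — deterministic given the data. The L1 path
#' uses the positive/negative weight split, so inactive weights are exactly
#' zero. Features are used raw (no standardisation), matching the convention
#' of reporting weights on the original feature scale.
#'
#' @param X numeric matrix of training rows (features in columns).
#' @param y labels in \code{-1/+1} (or a factor/character vector together
#'   with \code{positive}).
#' @param penalty \code{"l1"} or \code{"l2"}.
#' @param C loss weight.
#' @param positive which label maps to +1 when \code{y} is not numeric.
#' @param maxIter optimiser iteration cap.
#' @return a \linkS4class{LinearSVM}.
#' @export
trainSVM <- function(X, y, penalty = c("l2", "l1"), C = 1,
                     positive = NULL, maxIter = 5000L) {
  penalty <- match.arg(penalty)
  X <- as.matrix(X)
  if (!is.numeric(y)) {
    if (is.null(positive)) stop("supply 'positive' for non-numeric labels")
    y <- ifelse(y == positive, 1, -1)
  }
  if (!all(y %in% c(-1, 1))) stop("labels must be -1/+1")
  if (length(unique(y)) < 2L)
    stop("degenerate training: both classes must be present")
  ob <- .svmObjective(X, y, C, penalty)
  fit <- stats::optim(ob$par0, ob$fn, ob$gr, method = "L-BFGS-B",
                      lower = ob$lower,
                      control = list(maxit = as.integer(maxIter),
                                     factr = 10, pgtol = 1e-10))
  wb <- ob$toW(fit$par)
  new("LinearSVM", w = as.numeric(wb$w), b = wb$b, penalty = penalty,
      cost = C,
      objective = fit$value, converged = fit$convergence == 0L)
}

#' @describeIn trainSVM decision scores \code{f(v) = w . v + b} for the rows
#'   of \code{newdata} (a matrix or a feature table containing the feature
#'   columns).
#' @param object a \linkS4class{LinearSVM}.
#' @param newdata matrix of rows to score.
#' @export
setMethod("predict", "LinearSVM", function(object, newdata) {
  drop(as.matrix(newdata) %*% object@w) + object@b
})

# Feature columns of a long feature table (v1..vk or vx/vy/v).
featureColumns <- function(table) {
  cols <- grep("^v[0-9]+$", names(table), value = TRUE)
  if (!length(cols)) cols <- intersect(c("vx", "vy", "v"), names(table))
  if (!length(cols)) stop("no feature columns found")
  cols
}

#' Evaluate a linear SVM on a labeled feature table
#'
#' Scores every row, predicts by \code{sign(f)}, and when \code{vote} is
#' TRUE additionally labels each video by the majority of its frame
#' predictions (exact ties broken by the sign of the video's mean score).
#' Confusion matrices put true classes on rows; the positive class comes
#' first.
#'
#' @param model a \linkS4class{LinearSVM}.
#' @param table feature table with columns \code{videoId}, feature columns,
#'   and the label column.
#' @param labelCol which column holds the class labels.
#' @param positive label mapped to +1.
#' @param vote majority-vote videos from frame predictions.
#' @param split optional \code{list(train =, test =)} recorded in the report.
#' @return an \linkS4class{EvalReport}.
#' @export
evaluateModel <- function(model, table, labelCol, positive, vote = TRUE,
                          split = list()) {
  cols <- featureColumns(table)
  y <- ifelse(table[[labelCol]] == positive, 1, -1)
  score <- predict(model, as.matrix(table[, cols]))
  pred <- ifelse(score >= 0, 1, -1)
  scores <- data.frame(videoId = table$videoId, label = y, score = score,
                       pred = pred)
  classNames <- c(positive, paste0("not_", positive))
  conf <- function(truth, prediction) {
    m <- matrix(0L, 2, 2, dimnames = list(truth = classNames,
                                          predicted = classNames))
    m[1, 1] <- sum(truth == 1 & prediction == 1)
    m[1, 2] <- sum(truth == 1 & prediction == -1)
    m[2, 1] <- sum(truth == -1 & prediction == 1)
    m[2, 2] <- sum(truth == -1 & prediction == -1)
    m
  }
  frameConf <- conf(y, pred)
  videoPred <- data.frame()
  videoConf <- matrix(0L, 2, 2)
  videoAcc <- NA_real_
  if (vote) {
    agg <- lapply(split(scores, scores$videoId), function(d) {
      nPos <- sum(d$pred == 1)
      nNeg <- sum(d$pred == -1)
      vp <- if (nPos > nNeg) 1 else if (nPos < nNeg) -1
        else if (mean(d$score) >= 0) 1 else -1   # tie rule: sign of mean score
      data.frame(videoId = d$videoId[1], label = d$label[1], pred = vp,
                 nFrames = nrow(d), nMisclassified = sum(d$pred != d$label))
    })
    videoPred <- do.call(rbind, agg)
    rownames(videoPred) <- NULL
    videoConf <- conf(videoPred$label, videoPred$pred)
    videoAcc <- mean(videoPred$pred == videoPred$label)
  }
  new("EvalReport", scores = scores,
      frameConfusion = frameConf, frameAccuracy = mean(pred == y),
      videoConfusion = videoConf, videoAccuracy = videoAcc,
      videoPred = videoPred, model = model, split = split)
}

#' Train and evaluate over every split of a plan
#'
#' For each split: fits the SVM on the training videos' rows and evaluates on
#' the test videos' rows.
#'
#' @inheritParams evaluateModel
#' @param table labeled feature table for all videos.
#' @param plan a \linkS4class{SplitPlan}.
#' @param penalty,C SVM settings.
#' @return list of \linkS4class{EvalReport}, one per split.
#' @export
runSplits <- function(table, plan, labelCol, positive,
                      penalty = "l2", C = 1, vote = TRUE) {
  cols <- featureColumns(table)
  lapply(plan@splits, function(s) {
    trainRows <- table[table$videoId %in% s$train, ]
    testRows <- table[table$videoId %in% s$test, ]
    model <- trainSVM(as.matrix(trainRows[, cols]), trainRows[[labelCol]],
                      penalty = penalty, C = C, positive = positive)
    evaluateModel(model, testRows, labelCol, positive, vote = vote, split = s)
  })
}
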