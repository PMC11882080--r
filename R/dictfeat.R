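#' Configuration for sparse dictionary learning
#'
#' Defaults follow the study settings: 100 atoms learned from 20 x 20 patches
#' at sparsity weight lambda = 1, processed in mini-batches of 15 patches,
#' then reduced to the 30 atoms with the largest leave-one-atom-out
#' reconstruction errors.
#'
#' @param nAtoms dictionary size M.
#' @param patchSize patch side length p in pixels (d = p^2).
#' @param lambda L1 sparsity weight (>= 0).
#' @param batchSize mini-batch size for the coding step.
#' @param retainedAtoms atoms kept after ranking (<= nAtoms).
#' @param epochs alternating-minimisation passes over the data.
#' @param dictPasses block-coordinate passes over atoms per dictionary step.
#' @param tol coordinate-descent convergence tolerance for the sparse codes.
#' @param maxIter sparse-code solver iteration cap.
#' @param center subtract each patch's mean before encoding (added back on
#'   reconstruction).
#' @param seed initialisation seed.
#' @return a list of class \code{DictConfig}.
#' @export
dictConfig <- function(nAtoms = 100, patchSize = 20, lambda = 1,
                       batchSize = 15, retainedAtoms = min(30, nAtoms),
                       epochs = 10,
                       dictPasses = 2, tol = 1e-6, maxIter = 1000,
                       center = TRUE, seed = 1) {
  if (lambda < 0) stop("invalid config: lambda must be >= 0")
  if (retainedAtoms > nAtoms)
    stop("invalid config: retainedAtoms must not exceed nAtoms")
  structure(list(nAtoms = as.integer(nAtoms),
                 patchSize = as.integer(patchSize), lambda = lambda,
                 batchSize = as.integer(batchSize),
                 retainedAtoms = as.integer(retainedAtoms),
                 epochs = as.integer(epochs),
                 dictPasses = as.integer(dictPasses),
                 tol = tol, maxIter = as.integer(maxIter),
                 center = isTRUE(center), seed = as.integer(seed)),
            class = "DictConfig")
}

#' Sparse coding of patches against a fixed dictionary
#'
#' Solves, independently for every column \code{x} of \code{X},
#' \deqn{\min_s \tfrac12 \|x - D s\|_2^2 + \lambda \|s\|_1}
#' by cyclic coordinate descent with soft-thresholding (ties at zero broken
#' toward zero). The result is deterministic for fixed inputs; for an
#' orthonormal dictionary it reduces to elementwise soft-thresholding of
#' \code{t(D) \%*\% x}.
#'
#' @param X \code{d x N} patch matrix (or a \linkS4class{PatchSet}).
#' @param D \code{d x M} dictionary matrix (or a
#'   \linkS4class{PatchDictionary}, whose lambda is then the default).
#' @param lambda sparsity weight.
#' @param tol,maxIter solver controls.
#' @param warmStart optional \code{M x N} initial codes.
#' @return \code{M x N} matrix of sparse codes.
#' @export
sparseEncode <- function(X, D, lambda = NULL, tol = 1e-6, maxIter = 1000L,
                         warmStart = NULL) {
  if (is(X, "PatchSet")) X <- X@X
  if (is(D, "PatchDictionary")) {
    if (is.null(lambda)) lambda <- D@lambda
    D <- D@D
  }
  if (is.null(lambda)) stop("lambda must be given")
  if (nrow(X) != nrow(D))
    stop("shape error: patch dimension does not match dictionary")
  S0 <- if (is.null(warmStart)) matrix(0, ncol(D), ncol(X)) else warmStart
  lasso_cd_encode(crossprod(D), crossprod(D, X), lambda, tol,
                  as.integer(maxIter), S0)
}

#' Sparse-coding objective
#'
#' Value of \code{sum_i 1/2 ||x_i - D s_i||^2 + lambda ||s_i||_1} over all
#' patches; used to monitor the alternating minimisation.
#'
#' @inheritParams sparseEncode
#' @param S \code{M x N} code matrix.
#' @return scalar objective value.
#' @export
codingObjective <- function(X, D, S, lambda) {
  if (is(X, "PatchSet")) X <- X@X
  if (is(D, "PatchDictionary")) D <- D@D
  0.5 * sum((X - D %*% S)^2) + lambda * sum(abs(S))
}

# Exact block-coordinate dictionary step under the unit-norm constraint:
# with A = S S' and B = X S', the constrained minimiser over atom j (codes
# fixed) is the normalised residual correlation.
.dictStep <- function(D, A, B, passes) {
  for (pass in seq_len(passes)) {
    for (j in seq_len(ncol(D))) {
      u <- B[, j] - D %*% A[, j] + D[, j] * A[j, j]
      nu <- sqrt(sum(u^2))
      if (nu > 1e-12) D[, j] <- u / nu
    }
  }
  D
}

#' Learn a patch dictionary by alternating minimisation
#'
#' Alternates (i) sparse coding of all patches against the current dictionary
#' (mini-batched, warm-started from the previous epoch's codes so the full
#' objective is non-increasing across every half-step) and (ii) a block
#' coordinate-descent dictionary update with renormalisation after each
#' column, which keeps every atom at unit Euclidean norm. Initial atoms are a
#' seeded random sample of the (normalised) patches themselves.
#'
#' @param X \code{d x N} patch matrix or \linkS4class{PatchSet}; requires
#'   \code{N >= nAtoms}.
#' @param cfg a \code{\link{dictConfig}}.
#' @param trace return the per-half-step objective trajectory in
#'   \code{attr(, "objective")}.
#' @return a \linkS4class{PatchDictionary} with \code{nAtoms} unit-norm atoms.
#' @export
learnDictionary <- function(X, cfg = dictConfig(), trace = FALSE) {
  if (is(X, "PatchSet")) X <- X@X
  N <- ncol(X)
  M <- cfg$nAtoms
  if (N < M) stop("insufficient data: need at least as many patches as atoms")
  means <- if (cfg$center) colMeans(X) else rep(0, N)
  Xc <- sweep(X, 2, means)
  D <- withSeed(cfg$seed, {
    pick <- sample.int(N, M)
    D0 <- Xc[, pick, drop = FALSE]
    nrm <- sqrt(colSums(D0^2))
    bad <- nrm < 1e-9
    if (any(bad))
      D0[, bad] <- matrix(rnorm(nrow(Xc) * sum(bad)), nrow(Xc))
    sweep(D0, 2, sqrt(colSums(D0^2)), `/`)
  })
  order <- withSeed(cfg$seed + 1L, sample.int(N))  # fixed mini-batch shuffle
  batches <- split(order, ceiling(seq_along(order) / cfg$batchSize))
  S <- matrix(0, M, N)
  obj <- numeric(0)
  for (epoch in seq_len(cfg$epochs)) {
    for (b in batches) {
      S[, b] <- sparseEncode(Xc[, b, drop = FALSE], D, cfg$lambda,
                             tol = cfg$tol, maxIter = cfg$maxIter,
                             warmStart = S[, b, drop = FALSE])
    }
    if (trace) obj <- c(obj, codingObjective(Xc, D, S, cfg$lambda))
    A <- tcrossprod(S)
    B <- tcrossprod(Xc, S)
    D <- .dictStep(D, A, B, cfg$dictPasses)
    if (trace) obj <- c(obj, codingObjective(Xc, D, S, cfg$lambda))
  }
  out <- new("PatchDictionary", D = D, lambda = cfg$lambda,
             centered = cfg$center, scores = numeric(0))
  if (trace) attr(out, "objective") <- obj
  out
}

#' Rank atoms by leave-one-atom-out reconstruction error and reduce
#'
#' With codes \code{S} computed once against the full dictionary, scores each
#' atom \code{j} by \code{e_j = sum_i ||x_i - (D s_i)_{-j}||^2}, the total
#' reconstruction error when atom j's contribution is removed at fixed codes.
#' Unused atoms score exactly the baseline error and rank last; removing an
#' atom can never reduce the error. \code{rankAndReduce} keeps the \code{k}
#' atoms with the largest scores.
#'
#' @param X patch matrix or \linkS4class{PatchSet} (the ranking dataset).
#' @param dict a \linkS4class{PatchDictionary}.
#' @param lambda sparsity weight (defaults to the dictionary's).
#' @return \code{rankAtoms}: a data.frame \code{(atom, score)} sorted by
#'   descending score, with the baseline full-dictionary error in
#'   \code{attr(, "baseline")}; \code{rankAndReduce}: a
#'   \linkS4class{PatchDictionary} of \code{k} atoms (scores slot filled,
#'   atoms ordered by descending score).
#' @export
rankAtoms <- function(X, dict, lambda = NULL) {
  if (is(X, "PatchSet")) X <- X@X
  if (is.null(lambda)) lambda <- dict@lambda
  Xc <- if (dict@centered) sweep(X, 2, colMeans(X)) else X
  S <- sparseEncode(Xc, dict@D, lambda)
  R <- Xc - dict@D %*% S
  baseline <- sum(R^2)
  cross <- colSums(dict@D * (R %*% t(S)))
  e <- baseline + 2 * cross + rowSums(S^2)
  out <- data.frame(atom = order(e, decreasing = TRUE),
                    score = sort(e, decreasing = TRUE))
  attr(out, "baseline") <- baseline
  out
}

#' @param k number of atoms to retain.
#' @rdname rankAtoms
#' @export
rankAndReduce <- function(X, dict, k, lambda = NULL) {
  if (k > ncol(dict@D)) stop("invalid config: k exceeds the number of atoms")
  rk <- rankAtoms(X, dict, lambda)
  keep <- rk$atom[seq_len(k)]
  new("PatchDictionary", D = dict@D[, keep, drop = FALSE],
      lambda = dict@lambda, centered = dict@centered,
      scores = rk$score[seq_len(k)])
}

# Iterate over all overlapping patches of a frame in blocks, calling
# fun(X, idx) with the raw patch block and its linear pixel indices.
.forAllPatchBlocks <- function(frame, p, blockSize, fun) {
  M <- nrow(frame)
  nA <- M - p + 1L
  anchorRow <- rep(0:(nA - 1L), each = nA)
  anchorCol <- rep(0:(nA - 1L), times = nA)
  nTot <- nA * nA
  for (start in seq(1L, nTot, by = blockSize)) {
    sel <- start:min(start + blockSize - 1L, nTot)
    idx <- .patchIndices(M, p, anchorRow[sel], anchorCol[sel])
    fun(matrix(frame[idx], nrow = p * p), idx)
  }
  invisible(NULL)
}

#' Sparse-coding reconstruction of a whole frame
#'
#' Encodes every overlapping patch of the frame against the dictionary,
#' decodes, and sets each output pixel to the average of its value over all
#' patches that contain it (interior pixels are covered by \code{p^2}
#' patches).
#'
#' @param frame numeric matrix.
#' @param dict a \linkS4class{PatchDictionary} (typically the reduced one).
#' @param lambda sparsity weight (defaults to the dictionary's).
#' @param blockSize patches encoded per block (memory/speed trade-off).
#' @return reconstructed frame, same size as the input.
#' @export
reconstructFrame <- function(frame, dict, lambda = NULL, blockSize = 4096L) {
  if (is.null(lambda)) lambda <- dict@lambda
  p <- as.integer(sqrt(nrow(dict@D)))
  acc <- matrix(0, nrow(frame), ncol(frame))
  cnt <- matrix(0, nrow(frame), ncol(frame))
  .forAllPatchBlocks(frame, p, blockSize, function(X, idx) {
    means <- if (dict@centered) colMeans(X) else rep(0, ncol(X))
    S <- sparseEncode(sweep(X, 2, means), dict@D, lambda)
    recon <- dict@D %*% S + rep(means, each = nrow(X))
    # indices repeat across patches but are unique at a fixed within-patch
    # offset, so accumulate one offset row at a time
    for (o in seq_len(nrow(idx))) {
      acc[idx[o, ]] <<- acc[idx[o, ]] + recon[o, ]
      cnt[idx[o, ]] <<- cnt[idx[o, ]] + 1
    }
  })
  acc / pmax(cnt, 1)
}

#' Per-frame dictionary feature vector
#'
#' The k-dimensional frame descriptor \code{v_k = sum_i |s_{i,k}|}: the total
#' absolute activation of atom k over the sparse codes of all overlapping
#' patches of the frame. Components are non-negative by construction.
#'
#' @inheritParams reconstructFrame
#' @return numeric vector with one component per atom.
#' @export
dictFeatureVector <- function(frame, dict, lambda = NULL, blockSize = 4096L) {
  if (is.null(lambda)) lambda <- dict@lambda
  p <- as.integer(sqrt(nrow(dict@D)))
  v <- numeric(ncol(dict@D))
  .forAllPatchBlocks(frame, p, blockSize, function(X, idx) {
    Xc <- if (dict@centered) sweep(X, 2, colMeans(X)) else X
    S <- sparseEncode(Xc, dict@D, lambda)
    v <<- v + rowSums(abs(S))
  })
  v
}

#' Collect random training patches from many videos
#'
#' Draws \code{nPerFrame} random \code{p x p} patches from every frame of
#' every video, reproducibly from one seed.
#'
#' @param videos list of \linkS4class{WaveVideo}.
#' @param nPerFrame patches per frame (study setting: 300).
#' @param p patch side length (study setting: 20).
#' @param seed master seed.
#' @return a \linkS4class{PatchSet} pooling all patches.
#' @export
collectTrainingPatches <- function(videos, nPerFrame = 300, p = 20, seed = 1) {
  totalFrames <- sum(vapply(videos, nFrames, integer(1)))
  seeds <- deriveSeeds(seed, totalFrames)
  Xs <- list(); poss <- list()
  fi <- 0L
  for (v in videos) {
    for (t in seq_len(nFrames(v))) {
      fi <- fi + 1L
      ps <- extractRandomPatches(getFrame(v, t), nPerFrame, p,
                                 seed = seeds[fi], frameIndex = t - 1L)
      Xs[[fi]] <- ps@X
      poss[[fi]] <- ps@positions
    }
  }
  new("PatchSet", X = do.call(cbind, Xs), positions = do.call(rbind, poss),
      p = as.integer(p))
}

#' Dictionary feature table for a set of videos
#'
#' Computes \code{\link{dictFeatureVector}} for every frame of every video and
#' returns a long feature table ready for SVM classification.
#'
#' @inheritParams collectTrainingPatches
#' @param dict a \linkS4class{PatchDictionary}.
#' @param lambda sparsity weight (defaults to the dictionary's).
#' @return data.frame with columns \code{videoId}, \code{frame},
#'   \code{topography}, \code{field} and \code{v1..vk}.
#' @export
dictFeatureTable <- function(videos, dict, lambda = NULL) {
  rows <- list()
  i <- 0L
  for (v in videos) {
    for (t in seq_len(nFrames(v))) {
      i <- i + 1L
      vec <- dictFeatureVector(getFrame(v, t), dict, lambda)
      rows[[i]] <- data.frame(videoId = videoId(v), frame = t - 1L,
                              topography = topography(v), field = fieldState(v),
                              t(vec))
    }
  }
  out <- do.call(rbind, rows)
  names(out)[-(1:4)] <- paste0("v", seq_len(ncol(out) - 4L))
  rownames(out) <- NULL
  out
}
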