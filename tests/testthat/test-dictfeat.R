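test_that("sparse coding matches closed-form soft-thresholding for orthonormal dictionaries", {
  set.seed(1)
  d <- 16
  Q <- qr.Q(qr(matrix(rnorm(d * d), d)))
  X <- matrix(rnorm(d * 7), d)
  soft <- function(z, l) sign(z) * pmax(abs(z) - l, 0)
  for (lambda in c(0.1, 0.5, 1)) {
    S <- sparseEncode(X, Q, lambda)
    expect_lt(max(abs(S - soft(crossprod(Q, X), lambda))), 1e-8)
  }
  # lambda above max |D'x| kills every coefficient
  big <- max(abs(crossprod(Q, X))) + 0.1
  expect_identical(unique(as.vector(sparseEncode(X, Q, big))), 0)
  # lambda = 0 with invertible square D reproduces least squares exactly
  expect_lt(max(abs(sparseEncode(X, Q, 0) - solve(Q, X))), 1e-8)
  expect_error(sparseEncode(X[-1, ], Q, 1), "shape error")
})

test_that("sparse coding agrees with an independent lasso solver", {
  skip_if_not_installed("glmnet")
  set.seed(4)
  d <- 30; M <- 12
  D <- matrix(rnorm(d * M), d)
  D <- sweep(D, 2, sqrt(colSums(D^2)), `/`)
  X <- matrix(rnorm(d * 5), d)
  S <- sparseEncode(X, D, 0.4)
  for (i in 1:5) {
    g <- glmnet::glmnet(D, X[, i], lambda = 0.4 / d, standardize = FALSE,
                        intercept = FALSE, thresh = 1e-14)
    expect_lt(max(abs(S[, i] - as.numeric(g$beta))), 1e-5)
  }
})

test_that("sparsity increases with lambda at fixed data", {
  set.seed(2)
  D <- matrix(rnorm(25 * 10), 25)
  D <- sweep(D, 2, sqrt(colSums(D^2)), `/`)
  X <- matrix(rnorm(25 * 20), 25)
  nnz <- vapply(c(0.05, 0.2, 0.8), function(l)
    sum(sparseEncode(X, D, l) != 0), numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("dictionary learning recovers planted atoms up to sign and permutation", {
  pd <- plantedPatchData()
  cfg <- dictConfig(nAtoms = 8, lambda = 0.2, epochs = 30, center = FALSE,
                    seed = 4)
  D <- learnDictionary(pd$X, cfg, trace = TRUE)
  expect_lt(max(abs(sqrt(colSums(atoms(D)^2)) - 1)), 1e-8)
  best <- apply(abs(crossprod(atoms(D), pd$atoms)), 2, max)
  expect_true(all(best >= 0.95))
  # alternating-minimisation objective is non-increasing at every half-step
  obj <- attr(D, "objective")
  expect_true(all(diff(obj) <= 1e-10 * abs(obj[-length(obj)])))
  expect_error(learnDictionary(pd$X[, 1:5], cfg), "insufficient data")
})

test_that("the learned code beats the best rank-1 baseline on study-like patches", {
  fx <- frameTrackDictionary()
  Xc <- sweep(patchMatrix(fx$patches), 2, colMeans(patchMatrix(fx$patches)))
  S <- sparseEncode(Xc, fx$full@D, fx$full@lambda)
  dictErr <- mean(colSums((Xc - fx$full@D %*% S)^2))
  sv <- svd(Xc, nu = 1, nv = 1)
  rank1Err <- mean(colSums((Xc - sv$d[1] * sv$u %*% t(sv$v))^2))
  expect_lt(dictErr, rank1Err)
})

test_that("atom ranking reproduces brute-force leave-one-atom-out errors", {
  set.seed(6)
  d <- 12; M <- 5; N <- 40
  D <- matrix(rnorm(d * M), d); D <- sweep(D, 2, sqrt(colSums(D^2)), `/`)
  X <- matrix(rnorm(d * N), d)
  dict <- new("PatchDictionary", D = D, lambda = 0.2, centered = FALSE,
              scores = numeric(0))
  rk <- rankAtoms(X, dict)
  S <- sparseEncode(X, D, 0.2)
  eBrute <- vapply(seq_len(M), function(j)
    sum((X - D[, -j, drop = FALSE] %*% S[-j, , drop = FALSE])^2), numeric(1))
  expect_equal(rk$score, sort(eBrute, decreasing = TRUE), tolerance = 1e-10)
  expect_identical(rk$atom, order(eBrute, decreasing = TRUE))
  # removing any atom can never reduce the error below the full-D baseline
  expect_true(all(rk$score >= attr(rk, "baseline") - 1e-10))
})

test_that("used atoms outrank unused atoms and reduction keeps the top k", {
  # 2-atom toy: atom 1 used by every patch, atom 2 never active
  D <- cbind(c(1, 0, 0), c(0, 1, 0))
  X <- cbind(c(2, 0, 0), c(3, 0, 0), c(1.5, 0, 0), c(2.5, 0, 0), c(4, 0, 0))
  dict <- new("PatchDictionary", D = D, lambda = 0.01, centered = FALSE,
              scores = numeric(0))
  rk <- rankAtoms(X, dict)
  expect_identical(rk$atom[1], 1L)
  # unused atom scores exactly the baseline error and ranks last
  expect_equal(rk$score[2], attr(rk, "baseline"), tolerance = 1e-12)
  expect_error(rankAndReduce(X, dict, 3), "invalid config")
  red <- rankAndReduce(X, dict, 1)
  expect_identical(ncol(atoms(red)), 1L)
  expect_identical(atoms(red)[, 1], D[, 1])
  # study-scale reduction count
  fx <- frameTrackDictionary()
  expect_identical(ncol(atoms(fx$reduced)), 16L)
  expect_length(fx$reduced@scores, 16L)
})

test_that("frame reconstruction denoises and beats the mean-intensity baseline", {
  fx <- frameTrackDictionary()
  vids <- frameTrackVideos()
  ridged <- vids[[which(vapply(vids, topography, character(1)) == "ridged")[1]]]
  f <- getFrame(ridged, 1)
  rec <- reconstructFrame(f, fx$reduced)
  expect_identical(dim(rec), dim(f))
  expect_lt(mean((rec - f)^2), mean((mean(f) - f)^2))
  # pure-noise input comes back with reduced variance
  set.seed(8)
  noise <- matrix(runif(48 * 48), 48, 48)
  expect_lt(var(as.vector(reconstructFrame(noise, fx$reduced))),
            var(as.vector(noise)))
})

test_that("a frame tiled with one atom reconstructs exactly at lambda ~ 0", {
  # period-2 stripe atom: every patch of its tiling is +/- the atom, so the
  # whole frame lies in the dictionary span and overlap-averaging is exact
  p <- 4L
  atom <- matrix(rep_len(c(1, -1), p), p, p)  # rows alternate +1 / -1
  atom <- atom / sqrt(sum(atom^2))
  stripes <- 0.5 + 0.3 * (-1)^(row(matrix(0, 16, 16)) - 1)
  dict <- new("PatchDictionary", D = matrix(as.vector(atom), ncol = 1),
              lambda = 1e-9, centered = TRUE, scores = numeric(0))
  rec <- reconstructFrame(stripes, dict, lambda = 1e-9)
  expect_lt(max(abs(rec - stripes)), 1e-6)
})

test_that("dictionary feature vectors obey their algebraic contracts", {
  fx <- frameTrackDictionary()
  zero <- matrix(0, 32, 32)
  expect_identical(unique(dictFeatureVector(zero, fx$reduced)), 0)
  # homogeneity at lambda = 0 without centering
  set.seed(9)
  D <- matrix(rnorm(16 * 4), 16); D <- sweep(D, 2, sqrt(colSums(D^2)), `/`)
  dict0 <- new("PatchDictionary", D = D, lambda = 0, centered = FALSE,
               scores = numeric(0))
  f <- matrix(runif(100), 10, 10) * 0.5
  v1 <- dictFeatureVector(f, dict0, lambda = 0)
  v2 <- dictFeatureVector(2 * f, dict0, lambda = 0)
  expect_equal(v2, 2 * v1, tolerance = 1e-5)  # limited by the CD tolerance
  # non-negativity and ridged-frame activation
  vids <- frameTrackVideos()
  ridged <- vids[[which(vapply(vids, topography, character(1)) == "ridged")[1]]]
  v <- dictFeatureVector(getFrame(ridged, 1), fx$reduced)
  expect_true(all(v >= 0))
  expect_gt(max(v), 0)
})

test_that("feature summation matches a direct per-patch encoding oracle", {
  fx <- frameTrackDictionary()
  vids <- frameTrackVideos()
  f <- getFrame(vids[[1]], 1)[1:24, 1:24]
  v <- dictFeatureVector(f, fx$reduced)
  ap <- extractAllPatches(f, 12)
  Xc <- sweep(patchMatrix(ap), 2, colMeans(patchMatrix(ap)))
  S <- sparseEncode(Xc, fx$reduced@D, fx$reduced@lambda)
  expect_equal(v, rowSums(abs(S)), tolerance = 1e-10)
})
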