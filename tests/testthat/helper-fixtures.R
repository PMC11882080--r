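# Shared fixtures and small independent oracles. Everything is generated in
# code; expensive objects are built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache, inherits = FALSE))
    assign(name, expr, envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

# Circular (wrap-around) shift of a matrix by integer (dx, dy).
circShift <- function(m, dx, dy = 0) {
  nr <- nrow(m); nc <- ncol(m)
  m[((seq_len(nr) - 1 - dy) %% nr) + 1, ((seq_len(nc) - 1 - dx) %% nc) + 1]
}

# Subpixel shift by a spectral phase ramp (exact for band-limited content).
spectralShift <- function(m, dx, dy) {
  S <- nrow(m)
  co <- ifelse(0:(S - 1) < S / 2, 0:(S - 1), 0:(S - 1) - S)
  kx <- matrix(co, S, S, byrow = TRUE) / S
  ky <- matrix(co, S, S) / S
  Re(stats::fft(stats::fft(m) * exp(-2i * pi * (kx * dx + ky * dy)),
                inverse = TRUE)) / S^2
}

# Rank-based AUC of a scalar statistic separating two groups.
rankAUC <- function(pos, neg) {
  mean(outer(pos, neg, `>`)) + 0.5 * mean(outer(pos, neg, `==`))
}

# Autocorrelation decay length along one axis: lag at which the mean
# (circular) autocorrelation first drops below 1/2.
acfDecayLength <- function(m, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (axis == "y") m <- t(m)
  m <- m - mean(m)
  ac <- rowMeans(apply(m, 1, function(row) {
    f <- Mod(stats::fft(row))^2
    a <- Re(stats::fft(f, inverse = TRUE)) / length(f)
    a / a[1]
  }))
  half <- ac[seq_len(length(ac) %/% 2)]
  below <- which(half < 0.5)
  if (!length(below)) return(length(half))
  k <- below[1]
  if (k == 1) return(0.5)
  # linear interpolation of the 0.5 crossing between lags k-2 and k-1
  (k - 2) + (half[k - 1] - 0.5) / (half[k - 1] - half[k])
}

# Labeled frame-track dataset: 64 px videos, 8 frames each, both topographies
# with and without field (field-on videos exist so every layout is exercised).
frameTrackVideos <- function() fixture("frameTrackVideos",
  genDataset(synthDatasetSpec(
    flatOff = rep(8, 6), flatOn = 8,
    ridgedOff = rep(8, 6), ridgedOn = 8,
    imageSize = 64, masterSeed = 11)))

# Labeled flow-track dataset: 96 px videos of 100 frames, five per
# environment.
flowTrackVideos <- function() fixture("flowTrackVideos",
  genDataset(synthDatasetSpec(
    flatOff = rep(100, 5), flatOn = rep(100, 5),
    ridgedOff = rep(100, 5), ridgedOn = rep(100, 5),
    imageSize = 96, masterSeed = 21)))

# Corner config used throughout flow tests (fewer corners than the study
# default keeps tracking fast at 96 px).
testCornerCfg <- function() cornerConfig(nCorners = 50)

# A small dictionary learned on the no-field frame-track videos.
frameTrackDictionary <- function() fixture("frameTrackDictionary", {
  vids <- frameTrackVideos()
  off <- vids[vapply(vids, fieldState, character(1)) == "off"]
  patches <- collectTrainingPatches(off, nPerFrame = 150, p = 12, seed = 3)
  full <- learnDictionary(patches, dictConfig(nAtoms = 32, patchSize = 12,
                                              lambda = 1, retainedAtoms = 16,
                                              epochs = 6, seed = 3))
  list(patches = patches, full = full,
       reduced = rankAndReduce(patches, full, 16))
})

# Planted sparse ground truth for dictionary-recovery tests: every patch is a
# 2-sparse combination of K random unit atoms plus small Gaussian noise.
plantedPatchData <- function(d = 36, K = 8, n = 2000, noiseSd = 0.01,
                             seed = 3) {
  set.seed(seed)
  A <- matrix(rnorm(d * K), d)
  A <- sweep(A, 2, sqrt(colSums(A^2)), `/`)
  X <- vapply(seq_len(n), function(i) {
    k <- sample(K, 2)
    co <- runif(2, 0.5, 1.5) * sample(c(-1, 1), 2, replace = TRUE)
    drop(A[, k] %*% co) + rnorm(d, sd = noiseSd)
  }, numeric(d))
  list(atoms = A, X = X)
}
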