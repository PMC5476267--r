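# Filter banks, cepstral features, SBV models, activation features,
# deltas and combination.

test_that("mel filter bank has the documented shape and triangle structure", {
  bank <- melFilterBank(40, nFFT = 512, rate = 22050)
  filt <- filterMatrix(bank)
  expect_equal(dim(filt), c(40, 257))

  # unimodal: rises then falls (no second rise after the first fall)
  for (k in seq_len(40)) {
    s <- sign(diff(filt[k, filt[k, ] > 0 | c(filt[k, -1], 0) > 0]))
    s <- s[s != 0]
    expect_true(all(diff(s) <= 0))
  }
  centers <- apply(filt, 1, which.max)
  expect_true(all(diff(centers) > 0))

  expect_error(melFilterBank(300, nFFT = 512, rate = 22050), "resolution")
})

test_that("NMF filter bank learning recovers planted spectral bumps", {
  nBins <- 257; K <- 12
  centers <- round(seq(20, 240, length.out = K))
  Wtrue <- vapply(centers, function(c0) {
    w <- stats::dnorm(seq_len(nBins), c0, 4); w / sum(w)
  }, numeric(nBins))
  specs <- withr::with_seed(31, {
    lapply(1:4, function(i) {
      H <- matrix(stats::rexp(K * 80) * (stats::runif(K * 80) < 0.4), K, 80)
      specFromMatrix(Wtrue %*% (H + 0.01))
    })
  })
  bank <- learnNmfFilterBank(specs, K = K, seed = 6)
  filt <- filterMatrix(bank)
  expect_equal(nrow(filt), K)

  peaks <- apply(filt, 1, which.max)
  sim <- outer(peaks, centers, function(a, b) abs(a - b))
  perm <- hungarianAssignment(sim)
  expect_lte(mean(abs(peaks - centers[perm])), 2)

  # filters sorted by peak frequency, L1-normalized
  expect_true(all(diff(peaks) >= 0))
  expect_equal(rowSums(filt), rep(1, K), tolerance = 1e-9)

  bank2 <- learnNmfFilterBank(specs, K = K, seed = 6)
  expect_identical(filt, filterMatrix(bank2))

  expect_error(learnNmfFilterBank(list(), K = 4), "at least one")
})

test_that("cepstral features have 13 columns and the log-DCT scaling law", {
  tone <- toneSignal(3000, duration = 0.5)
  spec <- magnitudeSpectrogram(tone)
  bank <- melFilterBank(40, 512, 22050)
  feats <- cepstralFeatures(spec, bank)
  expect_equal(ncol(featureMatrix(feats)), 13)
  expect_identical(featureLayout(feats), c(paste0("c", 1:12), "logE"))

  # identical frames give identical rows
  flat <- specFromMatrix(matrix(rep(stats::rexp(257), 5), 257, 5))
  ff <- featureMatrix(cepstralFeatures(flat, bank))
  expect_equal(ff[1, ], ff[5, ], tolerance = 1e-12)

  # doubling amplitude: logE shifts by log 4, C1..C12 unchanged (scale
  # moves into the discarded C0 under log + orthogonal DCT)
  tone2 <- new("AudioSignal", samples = 2 * samples(tone),
               sampleRate = 22050)
  f1 <- featureMatrix(cepstralFeatures(spec, bank))
  f2 <- featureMatrix(cepstralFeatures(magnitudeSpectrogram(tone2), bank))
  expect_equal(f2[, 1:12], f1[, 1:12], tolerance = 1e-8)
  expect_equal(f2[, 13] - f1[, 13], rep(log(4), nrow(f1)), tolerance = 1e-8)
})

test_that("the DCT is orthonormal: inverting recovers log energies", {
  D <- birdnmf:::.dctMatrix(40)
  expect_equal(D %*% t(D), diag(40), tolerance = 1e-12)
  withr::with_seed(2, e <- rnorm(40))
  expect_lt(max(abs(t(D) %*% (D %*% e) - e)), 1e-9)
})

test_that("per-class SBV models have K*C columns in class-blocked order", {
  specsByClass <- setNames(
    lapply(1:12, function(i) tinySpecs(1, nBins = 30, nFrames = 25,
                                       seed = 40 + i)),
    sprintf("sp%02d", 1:12))
  model <- learnClassSbvs(specsByClass, K = 4, maxIter = 30, nRestarts = 3,
                          seed = 2)
  expect_equal(ncol(sbvMatrix(model)), 48)   # K = 4, C = 12
  expect_equal(classLabels(model), sprintf("sp%02d", 1:12))

  model2 <- learnClassSbvs(specsByClass, K = 4, maxIter = 30, nRestarts = 3,
                           seed = 2)
  expect_identical(sbvMatrix(model), sbvMatrix(model2))
})

test_that("SBVs of spectrally disjoint classes stay on their own bands", {
  nBins <- 40
  lowBand <- 1:18; highBand <- 23:40
  mkClass <- function(band, seed) {
    withr::with_seed(seed, {
      lapply(1:3, function(i) {
        M <- matrix(0, nBins, 30)
        M[band, ] <- stats::rexp(length(band) * 30)
        specFromMatrix(M)
      })
    })
  }
  model <- learnClassSbvs(list(low = mkClass(lowBand, 1),
                               high = mkClass(highBand, 2)),
                          K = 4, seed = 3)
  W <- sbvMatrix(model)
  mass <- function(cols, band) {
    colSums(W[band, cols, drop = FALSE]) / pmax(colSums(W[, cols]), 1e-12)
  }
  expect_true(all(mass(1:4, lowBand) >= 0.9))
  expect_true(all(mass(5:8, highBand) >= 0.9))

  expect_error(
    learnClassSbvs(list(a = list(specFromMatrix(matrix(0, 4, 5))))),
    "'a'")
})

test_that("H_CC features have nCeps + 1 columns and G_NMF is a valid index", {
  specsByClass <- setNames(
    lapply(1:12, function(i) tinySpecs(1, nBins = 30, nFrames = 25,
                                       seed = 60 + i)),
    sprintf("sp%02d", 1:12))
  model <- learnClassSbvs(specsByClass, K = 4, maxIter = 30, nRestarts = 3,
                          seed = 2)
  spec <- tinySpecs(1, nBins = 30, nFrames = 20, seed = 77)[[1]]
  feats <- hccFeatures(spec, model, seed = 5)
  X <- featureMatrix(feats)
  expect_equal(ncol(X), 14)                    # 13 cepstra + G_NMF
  expect_identical(featureLayout(feats)[14], "gnmf")
  g <- X[, 14]
  expect_true(all(g == round(g) & g >= 1 & g <= 48))

  noG <- hccFeatures(spec, model, withGnmf = FALSE, seed = 5)
  expect_equal(ncol(featureMatrix(noG)), 13)
})

test_that("G_NMF points into the generating class's column block", {
  nBins <- 40
  bands <- list(1:18, 23:40)
  mkClass <- function(band, seed) {
    withr::with_seed(seed, {
      lapply(1:3, function(i) {
        M <- matrix(0, nBins, 30)
        M[band, ] <- stats::rexp(length(band) * 30)
        specFromMatrix(M)
      })
    })
  }
  model <- learnClassSbvs(list(low = mkClass(bands[[1]], 1),
                               high = mkClass(bands[[2]], 2)),
                          K = 4, seed = 3)
  # a fresh pure-class spectrogram from the low band
  pure <- mkClass(bands[[1]], 99)[[1]]
  g <- featureMatrix(hccFeatures(pure, model, nCeps = 6, seed = 8))[, "gnmf"]
  expect_gt(mean(g <= 4), 0.5)          # majority inside class block 1
})

test_that("delta features double the dimension with the regression formula", {
  bank <- melFilterBank(40, 512, 22050)
  spec <- magnitudeSpectrogram(toneSignal(2000, duration = 0.3))
  feats <- cepstralFeatures(spec, bank)
  wide <- appendDeltas(feats)
  expect_equal(ncol(featureMatrix(wide)), 26)
  expect_identical(featureLayout(wide)[14], "d_c1")

  # constant features -> zero deltas
  const <- new("ShortTimeFeatures", X = matrix(5, 10, 2),
               layout = c("a", "b"))
  expect_true(all(featureMatrix(appendDeltas(const))[, 3:4] == 0))

  # linear ramp c(t) = a t -> delta = a on interior frames
  a <- 0.7
  ramp <- new("ShortTimeFeatures", X = matrix(a * (1:20), 20, 1),
              layout = "r")
  d <- featureMatrix(appendDeltas(ramp))[, 2]
  expect_equal(d[3:18], rep(a, 16), tolerance = 1e-12)
})

test_that("feature concatenation preserves order and rejects mismatches", {
  A <- new("ShortTimeFeatures", X = matrix(1, 5, 2), layout = c("a1", "a2"))
  B <- new("ShortTimeFeatures", X = matrix(2, 5, 3),
           layout = c("b1", "b2", "b3"))
  AB <- concatFeatures(A, B)
  expect_identical(featureLayout(AB), c("a1", "a2", "b1", "b2", "b3"))

  empty <- new("ShortTimeFeatures", X = matrix(numeric(0), 5, 0),
               layout = character(0))
  expect_identical(featureLayout(concatFeatures(A, empty)),
                   featureLayout(A))

  Bshort <- new("ShortTimeFeatures", X = matrix(2, 4, 1), layout = "b")
  expect_error(concatFeatures(A, Bshort), "frame counts differ")
})

test_that("front-end dimensional contracts hold end to end", {
  bank <- melFilterBank(40, 512, 22050)
  spec <- magnitudeSpectrogram(toneSignal(4000, duration = 0.3))
  mfcc <- cepstralFeatures(spec, bank)
  expect_equal(ncol(featureMatrix(mfcc)), 13)
  expect_equal(ncol(featureMatrix(appendDeltas(mfcc))), 26)

  specsByClass <- setNames(
    lapply(1:12, function(i) tinySpecs(1, nBins = 257, nFrames = 12,
                                       seed = 80 + i)),
    sprintf("sp%02d", 1:12))
  model <- learnClassSbvs(specsByClass, K = 4, maxIter = 15, nRestarts = 2,
                          seed = 2)
  hcc <- hccFeatures(spec, model, seed = 3)
  expect_equal(ncol(featureMatrix(hcc)), 14)
  combined <- concatFeatures(mfcc, hcc)
  expect_equal(ncol(featureMatrix(combined)), 27)
  expect_equal(ncol(featureMatrix(appendDeltas(combined))), 54)
})
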