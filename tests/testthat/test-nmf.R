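# KL divergence, multiplicative updates, decomposition and inference.

test_that("KL divergence matches hand-computed values and conventions", {
  # D(2 || 1) = 2 ln 2 - 2 + 1
  expect_equal(klDivergence(matrix(2), matrix(1), matrix(1)), 2 * log(2) - 1,
               tolerance = 1e-12)
  # 0 log(0/x) vanishes: D(0 || 1) = 1
  expect_equal(klDivergence(matrix(0), matrix(1), matrix(1)), 1)
  # V = WH exactly -> 0
  W <- matrix(c(1, 2, 3, 4), 2)
  H <- matrix(c(0.5, 1, 2, 0.1), 2)
  expect_equal(klDivergence(W %*% H, W, H), 0)
  # zero model mass under positive data -> +Inf, returned not thrown
  expect_identical(klDivergence(matrix(1), matrix(0), matrix(0)), Inf)
})

test_that("multiplicative updates fix exact factorizations and keep zeros", {
  withr::with_seed(11, {
    W <- matrix(runif(8, 0.2, 1), 4, 2)
    H <- matrix(runif(6, 0.2, 1), 2, 3)
  })
  V <- W %*% H
  expect_equal(updateW(V, W, H), W, tolerance = 1e-9)
  expect_equal(updateH(V, W, H), H, tolerance = 1e-9)

  # zeros persist: multiplicative updates cannot resurrect them
  W0 <- W; W0[, 2] <- 0
  expect_true(all(updateW(V, W0, H)[, 2] == 0))
  H0 <- H; H0[2, ] <- 0
  expect_true(all(updateH(V, W, H0)[2, ] == 0))
})

test_that("every update step is monotone in KL on random problems", {
  for (case in 1:50) {
    withr::with_seed(1000 + case, {
      nF <- sample(4:8, 1); nT <- sample(4:10, 1)
      K <- sample(1:3, 1)
      V <- matrix(stats::rexp(nF * nT), nF, nT)
      W <- matrix(runif(nF * K, 0.05, 1), nF, K)
      H <- matrix(runif(K * nT, 0.05, 1), K, nT)
    })
    before <- klDivergence(V, W, H)
    W2 <- updateW(V, W, H)
    mid <- klDivergence(V, W2, H)
    H2 <- updateH(V, W2, H)
    after <- klDivergence(V, W2, H2)
    expect_lte(mid, before * (1 + 1e-10) + 1e-10)
    expect_lte(after, mid * (1 + 1e-10) + 1e-10)
    expect_true(all(W2 >= 0) && all(H2 >= 0))
  }
})

test_that("rank-1 positive matrices are factorized to numerical exactness", {
  withr::with_seed(3, {
    w <- runif(5, 0.1, 1); h <- runif(7, 0.1, 1)
  })
  V <- outer(w, h)
  fit <- nmfDecompose(V, 1, seed = 2)
  expect_lt(utils::tail(divergenceTrace(fit), 1), 1e-6 * sum(V))
})

test_that("the divergence trace is non-increasing and runs are seeded", {
  withr::with_seed(8, V <- matrix(stats::rexp(60), 6, 10))
  fit <- nmfDecompose(V, 2, seed = 4)
  tr <- divergenceTrace(fit)
  expect_true(all(diff(tr) <= 1e-10 * (abs(tr[-length(tr)]) + 1)))

  fit2 <- nmfDecompose(V, 2, seed = 4)
  expect_identical(basisMatrix(fit), basisMatrix(fit2))
  expect_identical(activations(fit), activations(fit2))

  expect_warning(nmfDecompose(V, 8, seed = 1), "overcomplete")
})

test_that("K = 1 factorizations reach the closed-form KL optimum", {
  # For K = 1 the generalized-KL optimum is the independence model
  # outer(rowSums, colSums) / total -- an oracle independent of the
  # multiplicative-update path.
  for (case in 1:5) {
    withr::with_seed(200 + case, V <- matrix(stats::rexp(12), 3, 4))
    oracle <- klDivergence(V, matrix(rowSums(V)),
                           matrix(colSums(V) / sum(V), 1))
    fit <- nmfDecompose(V, 1, seed = case)
    expect_lte(utils::tail(divergenceTrace(fit), 1), oracle + 1e-3)
  }
})

test_that("rescaling a component leaves WH and the divergence unchanged", {
  withr::with_seed(21, {
    V <- matrix(stats::rexp(40), 5, 8)
    W <- matrix(runif(10, 0.1, 1), 5, 2)
    H <- matrix(runif(16, 0.1, 1), 2, 8)
  })
  c0 <- 3.25
  W2 <- W; W2[, 1] <- W2[, 1] * c0
  H2 <- H; H2[1, ] <- H2[1, ] / c0
  expect_equal(W2 %*% H2, W %*% H, tolerance = 1e-12)
  expect_equal(klDivergence(V, W2, H2), klDivergence(V, W, H),
               tolerance = 1e-12)
})

test_that("activation inference recovers a planted H against fixed bases", {
  # well-conditioned basis: disjoint spectral supports
  W <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)) * 0.5
  withr::with_seed(5, H0 <- matrix(runif(2 * 6, 0.2, 2), 2, 6))
  V <- W %*% H0
  H <- inferActivations(V, W, maxIter = 500, tol = 0, seed = 9)
  expect_lt(max(abs(H - H0)) / max(H0), 1e-3)

  tr <- attr(H, "divergenceTrace")
  expect_true(all(diff(tr) <= 1e-10 * (abs(tr[-length(tr)]) + 1)))

  # all-zero data drives activations toward zero
  Hz <- inferActivations(matrix(0, 4, 5), W, maxIter = 300, seed = 2)
  expect_lt(max(Hz), 1e-6)
})

test_that("NMF model archives round-trip through the text format", {
  withr::with_seed(14, V <- matrix(stats::rexp(30), 5, 6))
  fit <- nmfDecompose(V, 2, seed = 3)
  dir <- withr::local_tempdir()
  saveNMFModel(fit, dir)
  back <- loadNMFModel(dir)
  expect_equal(basisMatrix(back), basisMatrix(fit), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(activations(back), activations(fit), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back@config$seed, 3)
})
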