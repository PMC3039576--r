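test_that("Gaussian kernel has unit self-similarity and the Hamming identity", {
  x <- matrix(c(0.3, 0.7, 0.1), 1)
  expect_equal(gaussianKernel(x, x, gamma = 0.5)[1, 1], 1)

  # for binary vectors, squared distance = Hamming distance
  b1 <- matrix(c(1, 0, 1, 1, 0), 1)
  b2 <- matrix(c(0, 0, 1, 0, 1), 1)  # differs in 3 positions
  expect_equal(gaussianKernel(b1, b2, gamma = 0.25)[1, 1], exp(-0.25 * 3))
})

test_that("Gaussian kernel matches the brute-force oracle and is PSD", {
  withr::with_seed(11, X <- matrix(runif(20 * 6), 20))
  rownames(X) <- paste0("p", 1:20)
  K <- gaussianKernel(X, gamma = 0.25)
  expect_equal(K, oracleGaussian(X, X, 0.25), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lt(max(abs(K - t(K))), 1e-12)
  expect_equal(unname(diag(K)), rep(1, 20))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  expect_true(all(K > 0 & K <= 1))
})

test_that("degenerate and invalid kernel inputs are handled", {
  expect_error(gaussianKernel(matrix(1, 2, 2), gamma = 0), "positive")
  expect_error(gaussianKernel(matrix(1, 2, 2), gamma = -1), "positive")
  empty <- matrix(numeric(0), nrow = 3, ncol = 0,
                  dimnames = list(paste0("p", 1:3), NULL))
  K <- gaussianKernel(empty, gamma = 0.5)
  expect_true(all(K == 1))
  expect_true(isTRUE(attr(K, "degenerate")))
})

test_that("kernel fusion is the weighted element-wise sum", {
  withr::with_seed(12, {
    kernels <- lapply(channelNames(), function(ch) {
      X <- matrix(runif(15 * 4), 15)
      rownames(X) <- paste0("p", 1:15)
      gaussianKernel(X, gamma = 0.25)
    })
  })
  names(kernels) <- channelNames()

  # degenerate weights select one channel exactly
  wC <- c(P = 0, F = 0, C = 1, AA = 0, diAA = 0)
  expect_equal(fuseKernels(kernels, wC), kernels$C, ignore_attr = TRUE)

  # convexity: identical channels fuse to themselves
  same <- lapply(channelNames(), function(ch) kernels$P)
  names(same) <- channelNames()
  w <- c(P = 0.4, F = 0.3, C = 0.2, AA = 0.05, diAA = 0.05)
  expect_equal(fuseKernels(same, w), kernels$P, ignore_attr = TRUE)

  # brute-force weighted sum + PSD of the fusion
  expected <- 0 * kernels$P
  for (ch in channelNames()) expected <- expected + w[[ch]] * kernels[[ch]]
  fused <- fuseKernels(kernels, w)
  expect_equal(fused, expected, tolerance = 1e-12)
  expect_gte(min(eigen(fused, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
})

test_that("fusion is linear in the weights", {
  withr::with_seed(13, {
    kernels <- lapply(channelNames(), function(ch) {
      X <- matrix(runif(10 * 3), 10)
      rownames(X) <- paste0("p", 1:10)
      gaussianKernel(X, gamma = 0.5)
    })
  })
  names(kernels) <- channelNames()
  w1 <- c(P = 0.5, F = 0.2, C = 0.1, AA = 0.1, diAA = 0.1)
  w2 <- c(P = 0.1, F = 0.1, C = 0.6, AA = 0.1, diAA = 0.1)
  alpha <- 0.3
  wMix <- alpha * w1 + (1 - alpha) * w2
  expect_equal(fuseKernels(kernels, wMix),
               alpha * fuseKernels(kernels, w1) +
                 (1 - alpha) * fuseKernels(kernels, w2),
               tolerance = 1e-12)
})

test_that("rectangular fusion commutes with slicing", {
  d <- generateDataset(tinyConfig(seed = 31))
  ch <- buildChannels(d)
  n <- nProteins(d)
  testIdx <- 1:7
  w <- c(P = 0.3, F = 0.2, C = 0.3, AA = 0.1, diAA = 0.1)

  chTest <- lapply(ch[channelNames()], function(m) m[testIdx, , drop = FALSE])
  rect <- channelKernels(ch, 0.25, testChannels = chTest)
  fusedRect <- fuseKernels(rect, w)

  fusedFull <- fuseKernels(channelKernels(ch, 0.25), w)
  expect_equal(fusedRect, fusedFull[testIdx, , drop = FALSE],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("fusion validates weights, shapes and channel coverage", {
  K <- gaussianKernel(matrix(runif(12), 6, dimnames = list(paste0("p", 1:6),
                                                           NULL)),
                      gamma = 1)
  kernels <- stats::setNames(rep(list(K), 5), channelNames())
  expect_error(fuseKernels(kernels[-1], c(P = 1, F = 0, C = 0, AA = 0,
                                          diAA = 0)), "missing channel")
  expect_error(fuseKernels(kernels, c(P = 0.5, F = 0.5)), "named")
  expect_error(fuseKernels(kernels, c(P = 0.7, F = 0.7, C = -0.4, AA = 0,
                                      diAA = 0)), "non-negative")
  expect_error(fuseKernels(kernels, c(P = 0.5, F = 0.1, C = 0.1, AA = 0.1,
                                      diAA = 0.1)), "sum to 1")
  bad <- kernels
  bad$AA <- bad$AA[1:5, 1:5]
  expect_error(fuseKernels(bad, c(P = 0.2, F = 0.2, C = 0.2, AA = 0.2,
                                  diAA = 0.2)), "shape")
})
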