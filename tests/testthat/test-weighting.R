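test_that("k-fold splits obey the equal-size-with-remainder rule", {
  f <- kfoldSplit(103, 5, seed = 1)
  expect_equal(as.vector(table(f)), c(20L, 20L, 20L, 20L, 23L))
  expect_equal(as.vector(table(kfoldSplit(10, 5, seed = 1))), rep(2L, 5))
  # disjoint cover: every example appears in exactly one fold
  expect_equal(sort(unique(f)), 1:5)
  expect_length(f, 103)
  expect_error(kfoldSplit(4, 5, seed = 1), "must be >=")
  expect_error(kfoldSplit(10, 1, seed = 1), "K must be >= 2")
})

test_that("fold assignment is deterministic in the seed", {
  expect_identical(kfoldSplit(50, 5, seed = 9), kfoldSplit(50, 5, seed = 9))
  expect_false(identical(kfoldSplit(50, 5, seed = 9),
                         kfoldSplit(50, 5, seed = 10)))
})

test_that("a perfectly separable channel scores SE = MCC = 1", {
  withr::with_seed(7, labels <- sample(rep(c("a", "b", "c"), each = 15)))
  K <- blockKernel(labels, off = 0.05)
  s <- scoreChannel(K, labels, cvK = 3, C = 8, seed = 5)
  expect_equal(s$SE, 1)
  expect_equal(s$MCC, 1)
  expect_equal(s$product, 1)
})

test_that("a label-shuffled channel scores near zero MCC", {
  withr::with_seed(8, {
    labels <- rep(c("a", "b"), each = 100)
    K <- blockKernel(labels, off = 0.05)
    shuffled <- sample(labels)
  })
  s <- scoreChannel(K, shuffled, cvK = 5, C = 8, seed = 5)
  expect_lt(abs(s$MCC), 0.1)
  expect_lt(abs(s$product), 0.1)
})

test_that("identical channel kernels receive identical scores and weights", {
  withr::with_seed(9, labels <- sample(rep(c("a", "b"), each = 12)))
  K <- blockKernel(labels, off = 0.2)
  s1 <- scoreChannel(K, labels, cvK = 3, C = 4, seed = 3, channel = "P")
  s2 <- scoreChannel(K, labels, cvK = 3, C = 4, seed = 3, channel = "C")
  expect_equal(s1$SE, s2$SE)
  expect_equal(s1$MCC, s2$MCC)

  kernels <- stats::setNames(rep(list(K), 5), channelNames())
  w <- estimateWeights(kernels, labels, cvK = 3, C = 4, seed = 3)
  expect_equal(as.numeric(w), rep(0.2, 5), tolerance = 1e-12)
})

test_that("weights are the normalized clamped SE*MCC products", {
  withr::with_seed(10, labels <- sample(rep(c("a", "b", "c"), each = 12)))
  good <- blockKernel(labels, off = 0.05)
  withr::with_seed(11, noiseLabels <- sample(labels))
  useless <- blockKernel(noiseLabels, off = 0.05)
  kernels <- list(P = good, F = useless, C = good, AA = useless,
                  diAA = useless)
  w <- estimateWeights(kernels, labels, cvK = 3, C = 8, seed = 6)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(w >= 0))
  tab <- attr(w, "scores")
  clamped <- pmax(tab$product, 0)
  expect_equal(unname(w[tab$channel]), clamped / sum(clamped),
               tolerance = 1e-12)
  # the informative channels dominate
  expect_gt(w[["P"]] + w[["C"]], 0.9)
})

test_that("all-useless channels fall back to uniform weights with a warning", {
  withr::with_seed(12, {
    labels <- rep(c("a", "b"), each = 20)
    shuffledK <- blockKernel(sample(labels), off = 0.05)
  })
  kernels <- stats::setNames(rep(list(shuffledK), 5), channelNames())
  expect_warning(w <- estimateWeights(kernels, labels, cvK = 5, C = 128,
                                      seed = 4),
                 "uniform")
  expect_equal(as.numeric(w), rep(0.2, 5))
})

test_that("weight estimation is invariant to channel presentation order", {
  d <- generateDataset(tinyConfig(seed = 13))
  kernels <- channelKernels(buildChannels(d), 0.25)
  labels <- unname(locations(d))
  w1 <- estimateWeights(kernels, labels, cvK = 3, C = 8, seed = 2)
  w2 <- estimateWeights(rev(kernels), labels, cvK = 3, C = 8, seed = 2)
  expect_equal(w1, w2, ignore_attr = TRUE)
})

test_that("more informative channels never get smaller weights", {
  # hold every other channel byte-identical and raise only the P-aspect
  # informativeness, coupling the emission draws across levels
  cfg <- tinyConfig(nPerClass = 15, seed = 77,
                    informativeness = c(P = 0, F = 0.2, C = 0.5),
                    missingRate = c(P = 1, F = 0.1, C = 0))
  d <- generateDataset(cfg)
  fixed <- channelKernels(buildChannels(d), 0.25)
  labels <- unname(locations(d))
  classIdx <- match(labels, cfg$classNames)
  poolSize <- cfg$poolSize
  n <- nProteins(d)
  u <- withr::with_seed(88, matrix(runif(n * poolSize), n))

  weightAt <- function(inf) {
    rows <- list()
    for (i in seq_len(n)) {
      emit <- which(u[i, ] < inf)   # common random numbers across levels
      if (length(emit)) {
        rows[[length(rows) + 1]] <- data.frame(
          protein_id = proteinIds(d)[i],
          term = sprintf("GO:%07d", 1000000 + classIdx[i] * 1000 + emit),
          aspect = "P")
      }
    }
    ann <- if (length(rows)) do.call(rbind, rows) else
      data.frame(protein_id = character(), term = character(),
                 aspect = character())
    vocab <- buildGoVocabulary(ann, "P")
    kernels <- fixed
    kernels$P <- gaussianKernel(
      goBinaryMatrix(proteinIds(d), ann, vocab, "P"), gamma = 0.25)
    w <- estimateWeights(kernels, labels, cvK = 3, C = 8, seed = 5)
    w[["P"]]
  }
  weights <- vapply(c(0.05, 0.35, 0.9), weightAt, numeric(1))
  expect_true(all(diff(weights) >= 0))
})
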