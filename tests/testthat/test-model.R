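test_that("config grids are validated against the supported values", {
  cfg <- modelConfig()
  expect_equal(cfg$cvK, c(3, 5, 10))
  expect_equal(sort(cfg$gamma), sort(2^-(1:4)))
  expect_equal(cfg$C, 2^(1:11))
  expect_error(modelConfig(cvK = 4), "subset")
  expect_error(modelConfig(gamma = 0.3), "subset")
  expect_error(modelConfig(C = 3), "subset")
  expect_error(modelConfig(channels = "XX"), "subset")
  expect_error(modelConfig(cvK = numeric()), "subset")
})

test_that("a grid of size one selects that combination", {
  d <- generateDataset(tinyConfig(seed = 51))
  m <- trainGoTlm(d, tinyGrid(seed = 4))
  p <- modelParams(m)
  expect_equal(p$cvK, 3)
  expect_equal(p$gamma, 2^-2)
  expect_equal(p$C, 2^3)
  expect_equal(sum(kernelWeights(m)), 1, tolerance = 1e-12)
})

test_that("an AA-only model reduces to a plain RBF SVM on composition", {
  d <- generateDataset(tinyConfig(nClasses = 2, nPerClass = 15, seed = 52,
                                  aaConcentration = 5))
  test <- generateDataset(tinyConfig(nClasses = 2, nPerClass = 10, seed = 53,
                                     aaConcentration = 5))
  gamma <- 2^-1; cost <- 2^2
  m <- trainGoTlm(d, modelConfig(cvK = 3, gamma = gamma, C = cost, seed = 6,
                                 channels = "AA"))
  expect_equal(unname(kernelWeights(m)[["AA"]]), 1)
  ours <- predict(m, test)$predicted_location

  # independent route: e1071's own radial kernel on the raw features
  aaTrain <- buildChannels(d)$AA
  aaTest <- buildChannels(test)$AA
  ref <- e1071::svm(aaTrain, factor(unname(locations(d))),
                    type = "C-classification", kernel = "radial",
                    gamma = gamma, cost = cost, scale = FALSE)
  theirs <- as.character(predict(ref, aaTest))
  expect_identical(ours, theirs)
})

test_that("training validates labels, class counts and size", {
  d <- generateDataset(tinyConfig(seed = 54))
  lab <- locations(d)
  unlabeled <- LocDataset(proteinSequences(d), goAnnotations(d),
                          lab[seq_len(nProteins(d) - 2)])
  expect_error(trainGoTlm(unlabeled, tinyGrid()), "labeled")
  oneClass <- LocDataset(proteinSequences(d), goAnnotations(d),
                         stats::setNames(rep("x", nProteins(d)),
                                         proteinIds(d)))
  expect_error(trainGoTlm(oneClass, tinyGrid()), ">= 2 location classes")
})

test_that("prediction is total, deterministic and vocabulary-frozen", {
  d <- generateDataset(tinyConfig(seed = 55))
  m <- trainGoTlm(d, tinyGrid(seed = 7))

  # a protein with no annotations and an alien composition still gets a label
  lone <- LocDataset(c(lonely = "PPPPPPPPPPGGGGGGGGGG"))
  p <- predict(m, lone)
  expect_identical(nrow(p), 1L)
  expect_true(p$predicted_location %in% locationClasses(m))

  # a duplicate of a training protein predicts like its twin
  twinId <- proteinIds(d)[1]
  twin <- LocDataset(
    stats::setNames(as.character(proteinSequences(d)[1]), "copycat"),
    local({
      a <- goAnnotations(d)
      a <- a[a$protein_id == twinId, , drop = FALSE]
      a$protein_id <- "copycat"
      a
    }))
  orig <- predict(m, d[1])
  dup <- predict(m, twin)
  expect_identical(dup$predicted_location, orig$predicted_location)

  # predictions never depend on test labels (no leakage)
  test <- generateDataset(tinyConfig(seed = 56))
  relabeled <- LocDataset(proteinSequences(test), goAnnotations(test),
                          stats::setNames(
                            rev(unname(locations(test))), proteinIds(test)))
  expect_identical(predict(m, test)$predicted_location,
                   predict(m, relabeled)$predicted_location)
})

test_that("masking a channel equals zeroing its weight then renormalizing", {
  d <- generateDataset(tinyConfig(seed = 57))
  kernels <- channelKernels(buildChannels(d), 0.25)
  labels <- unname(locations(d))
  wFull <- estimateWeights(kernels, labels, cvK = 3, C = 8, seed = 9)
  mask <- setdiff(channelNames(), "C")
  wMasked <- goTLM:::estimateWeightsMasked(kernels, labels, cvK = 3, C = 8,
                                           seed = 9, channels = mask)
  expect_equal(unname(wMasked[["C"]]), 0)
  manual <- pmax(attr(wFull, "scores")$product, 0)
  names(manual) <- attr(wFull, "scores")$channel
  manual["C"] <- 0
  manual <- manual / sum(manual)
  expect_equal(wMasked[channelNames()], manual[channelNames()],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("cross-validation reports are structurally sound and leak-free", {
  d <- generateDataset(tinyConfig(nPerClass = 15, seed = 58))
  cfg <- tinyGrid(seed = 10, outerFolds = 3)
  r <- crossValidate(d, cfg)
  expect_s3_class(r, "gotlmReport")
  expect_equal(nrow(r$perClass), length(locationClasses(d)))
  expect_equal(rowSums(r$foldWeights), rep(1, 3), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(r$confusion), nProteins(d))  # each example tested once
  expect_equal(r$overallAccuracy, overallSE(r$confusion))

  small <- generateDataset(tinyConfig(nPerClass = c(12, 12, 2), seed = 59))
  expect_error(crossValidate(small, tinyGrid(outerFolds = 3)),
               "fewer members")
})

test_that("identical seed and config reproduce reports exactly", {
  d <- generateDataset(tinyConfig(nPerClass = 15, seed = 60))
  cfg <- tinyGrid(seed = 11, outerFolds = 3)
  r1 <- crossValidate(d, cfg)
  r2 <- crossValidate(d, cfg)
  expect_identical(r1$confusion, r2$confusion)
  expect_identical(r1$foldWeights, r2$foldWeights)
  expect_identical(r1$perClass, r2$perClass)
})

test_that("holdout evaluation trains only on the training partition", {
  train <- generateDataset(tinyConfig(nPerClass = 15, seed = 61))
  cfgTest <- tinyConfig(nPerClass = 8, seed = 62)
  test <- generateDataset(cfgTest)
  # regenerate with non-overlapping ids
  renamed <- stats::setNames(as.character(proteinSequences(test)),
                             paste0("t_", proteinIds(test)))
  ann <- goAnnotations(test)
  ann$protein_id <- paste0("t_", ann$protein_id)
  lab <- stats::setNames(unname(locations(test)),
                         paste0("t_", proteinIds(test)))
  test <- LocDataset(renamed, ann, lab)

  r <- holdoutEvaluate(train, test, tinyGrid(seed = 12))
  expect_s3_class(r, "gotlmReport")
  expect_equal(sum(r$confusion), nProteins(test))
  expect_equal(nrow(r$perClass), length(r$classes))

  expect_error(holdoutEvaluate(train, train, tinyGrid()), "overlap")
  empty <- LocDataset(c(x1 = "MKV"))[integer(0)]
  expect_error(holdoutEvaluate(train, empty, tinyGrid()), "empty")
})

test_that("evaluation reports serialize to the TSV layout", {
  d <- generateDataset(tinyConfig(nPerClass = 15, seed = 63))
  r <- crossValidate(d, tinyGrid(seed = 13, outerFolds = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeEvalReport(r, path)
  lines <- readLines(path)
  expect_match(lines[1], "^# overall_accuracy\t")
  tab <- utils::read.delim(path, comment.char = "#")
  expect_equal(nrow(tab), length(r$classes))
  expect_named(tab, c("class", "size", "SP", "SE", "MCC"))
})
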