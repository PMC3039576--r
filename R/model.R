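# End-to-end training and evaluation.  Training grid-searches the inner
# fold count cvK, the shared Gaussian width gamma and the SVM cost C;
# for each grid point the five channel weights are re-estimated on the
# training partition and the fused-kernel SVM is scored by internal
# cross-validation overall accuracy.  The winning combination is refit
# on all training data.

CVK_GRID <- c(3, 5, 10)
GAMMA_GRID <- 2^-(1:4)
C_GRID <- 2^(1:11)

#' Model configuration
#'
#' Hyper-parameter grids and protocol settings.  The defaults are the
#' full search grids: `cvK` in {3, 5, 10}, `gamma` in {2^-1, ..., 2^-4},
#' `C` in {2^1, ..., 2^11}; any non-empty subset of each may be given to
#' narrow the search.  `channels` masks the fused kernel to a subset of
#' the five channels (an ablated model, e.g. dropping the cellular
#' component channel).
#'
#' @param cvK Inner fold-count grid, subset of {3, 5, 10}.
#' @param gamma Gaussian-width grid, subset of {2^-1, 2^-2, 2^-3, 2^-4};
#'   shared across all five channels.
#' @param C Cost grid, subset of {2^1, ..., 2^11}.
#' @param outerFolds Outer cross-validation fold count (default 5).
#' @param seed Integer seed; all randomness derives from it.
#' @param channels Channel subset to use (default all five).
#' @return A list of class `gotlmConfig`.
#' @export
#' @examples
#' modelConfig(cvK = 5, gamma = 2^-2, C = 2^7, seed = 11)
modelConfig <- function(cvK = CVK_GRID, gamma = GAMMA_GRID, C = C_GRID,
                        outerFolds = 5, seed = 1,
                        channels = channelNames()) {
  inGrid <- function(x, grid) {
    all(vapply(x, function(v) any(abs(v - grid) < 1e-12), logical(1)))
  }
  if (!length(cvK) || !inGrid(cvK, CVK_GRID)) {
    stop("cvK must be a non-empty subset of {", paste(CVK_GRID, collapse = ", "), "}")
  }
  if (!length(gamma) || !inGrid(gamma, GAMMA_GRID)) {
    stop("gamma must be a non-empty subset of {2^-1, 2^-2, 2^-3, 2^-4}")
  }
  if (!length(C) || !inGrid(C, C_GRID)) {
    stop("C must be a non-empty subset of {2^1, ..., 2^11}")
  }
  channels <- unique(channels)
  if (!length(channels) || !all(channels %in% channelNames())) {
    stop("channels must be a non-empty subset of ",
         paste(channelNames(), collapse = ", "))
  }
  if (outerFolds < 2) stop("outerFolds must be >= 2")
  structure(list(cvK = sort(unique(cvK)),
                 gamma = sort(unique(gamma), decreasing = TRUE),
                 C = sort(unique(C)),
                 outerFolds = as.integer(outerFolds),
                 seed = as.integer(seed),
                 channels = channels),
            class = "gotlmConfig")
}

# Weight estimation restricted to the configured channel subset; masked
# channels get weight 0, the rest are normalized over their own
# products — equivalent to zeroing then renormalizing.
estimateWeightsMasked <- function(kernels, labels, cvK, C, seed, channels) {
  if (setequal(channels, channelNames())) {
    return(estimateWeights(kernels, labels, cvK = cvK, C = C, seed = seed))
  }
  scores <- lapply(channels, function(ch) {
    scoreChannel(kernels[[ch]], labels, cvK = cvK, C = C, seed = seed,
                 channel = ch)
  })
  tab <- data.frame(
    channel = vapply(scores, `[[`, "", "channel"),
    SE = vapply(scores, `[[`, 0, "SE"),
    MCC = vapply(scores, `[[`, 0, "MCC"),
    product = vapply(scores, `[[`, 0, "product"),
    stringsAsFactors = FALSE
  )
  clamped <- pmax(tab$product, 0)
  w <- stats::setNames(rep(0, length(channelNames())), channelNames())
  if (sum(clamped) <= 0) {
    warning("all unmasked channel SE*MCC products are <= 0; ",
            "using uniform weights over unmasked channels")
    w[tab$channel] <- 1 / nrow(tab)
  } else {
    w[tab$channel] <- clamped / sum(clamped)
  }
  tab$weight <- unname(w[tab$channel])
  attr(w, "scores") <- tab
  w
}

# Internal CV accuracy of a fused kernel under given folds.
fusedCvAccuracy <- function(fused, labels, fold, C, classes) {
  M <- matrix(0L, length(classes), length(classes),
              dimnames = list(classes, classes))
  for (f in sort(unique(fold))) {
    testIdx <- which(fold == f)
    trainIdx <- which(fold != f)
    fit <- ovoTrain(fused[trainIdx, trainIdx, drop = FALSE],
                    labels[trainIdx], C = C, classOrder = classes)
    pred <- ovoPredict(fit, fused[testIdx, trainIdx, drop = FALSE])
    M <- M + confusionMatrix(labels[testIdx], pred, classes)
  }
  overallSE(M)
}

#' Train a weighted multi-kernel localization model
#'
#' For every grid combination `(cvK, gamma, C)` the channel weights are
#' estimated on the full training set by inner cross-validation and the
#' fused-kernel SVM is scored by internal CV overall accuracy; the
#' combination with the best accuracy wins (ties: smallest `C`, then
#' largest `gamma`, then smallest `cvK`).  Weights and the one-vs-one
#' SVM are then refit on all data with the winning parameters.
#'
#' @param dataset A fully labeled [LocDataset-class] with >= 2 classes.
#' @param config A [modelConfig()].
#' @return A fitted [GoTlmModel-class].
#' @export
trainGoTlm <- function(dataset, config = modelConfig()) {
  stopifnot(is(dataset, "LocDataset"), inherits(config, "gotlmConfig"))
  labels <- unname(locations(dataset))
  if (anyNA(labels)) stop("all proteins must be labeled for training")
  classes <- locationClasses(dataset)
  if (length(classes) < 2) stop("training needs >= 2 location classes")
  n <- nProteins(dataset)
  maxK <- max(config$cvK)
  smallest <- min(table(labels))
  if (n < maxK) stop("dataset too small for cvK = ", maxK, " folds")
  if (smallest < 2) {
    stop("every class needs >= 2 members; consider fewer folds or ",
         "merging rare locations")
  }
  channels <- buildChannels(dataset)
  vocabularies <- attr(channels, "vocabularies")
  foldSeed <- childSeed(config$seed, 1)

  kernelsByGamma <- lapply(stats::setNames(config$gamma, config$gamma),
                           function(g) channelKernels(channels, g))
  best <- NULL
  for (C in config$C) {
    for (gamma in config$gamma) {
      kernels <- kernelsByGamma[[as.character(gamma)]]
      for (cvK in config$cvK) {
        w <- estimateWeightsMasked(kernels, labels, cvK = cvK, C = C,
                                   seed = foldSeed,
                                   channels = config$channels)
        fused <- fuseKernels(kernels, w)
        fold <- kfoldSplit(n, cvK, foldSeed)
        acc <- fusedCvAccuracy(fused, labels, fold, C, classes)
        gotlmLog("grid cvK=%d gamma=%g C=%g: internal CV accuracy %.4f",
                 cvK, gamma, C, acc)
        # Enumeration order (C asc, gamma desc, cvK asc) + strict
        # improvement implements the tie-breaking rule.
        if (is.null(best) || acc > best$acc + 1e-12) {
          best <- list(acc = acc, cvK = cvK, gamma = gamma, C = C,
                       weights = w, fused = fused)
        }
      }
    }
  }
  gotlmLog("selected cvK=%d gamma=%g C=%g (internal CV accuracy %.4f)",
           best$cvK, best$gamma, best$C, best$acc)
  svmFit <- ovoTrain(best$fused, labels, C = best$C, classOrder = classes)
  new("GoTlmModel",
      classes = classes,
      vocabularies = vocabularies,
      channels = channels[channelNames()],
      trainIds = proteinIds(dataset),
      weights = as.numeric(best$weights) |>
        stats::setNames(names(best$weights)),
      channelScores = attr(best$weights, "scores") %||% data.frame(),
      params = list(cvK = best$cvK, gamma = best$gamma, C = best$C,
                    internalAccuracy = best$acc),
      config = unclass(config),
      svm = svmFit,
      version = MODEL_FORMAT)
}

#' Predict subcellular locations for new proteins
#'
#' Builds the test feature channels against the model's frozen
#' vocabularies (out-of-vocabulary GO terms are dropped and counted),
#' computes rectangular test-vs-train channel kernels, fuses them with
#' the stored weights and applies the one-vs-one SVM with
#' majority voting (ties go to the class earlier in the stored class
#' order).
#'
#' @param object A fitted [GoTlmModel-class].
#' @param newdata A [LocDataset-class] (labels, if any, are ignored).
#' @param ... Ignored.
#' @return `data.frame` with columns `protein_id`,
#'   `predicted_location`, `votes` (votes for the winning class) and
#'   `margin` (vote lead over the runner-up).
#' @export
setMethod("predict", "GoTlmModel", function(object, newdata, ...) {
  stopifnot(is(newdata, "LocDataset"))
  testChannels <- buildChannels(newdata, vocabularies = object@vocabularies)
  kernels <- channelKernels(object@channels, object@params$gamma,
                            testChannels = testChannels)
  fused <- fuseKernels(kernels, object@weights)
  out <- ovoPredict(object@svm, fused, decisionSummary = TRUE)
  data.frame(protein_id = proteinIds(newdata),
             predicted_location = out$predicted,
             votes = out$votes,
             margin = out$margin,
             stringsAsFactors = FALSE)
})

makeReport <- function(confusion, config, foldWeights = NULL,
                       foldParams = NULL) {
  report <- list(
    classes = rownames(confusion),
    confusion = confusion,
    perClass = perClassMetrics(confusion),
    overallAccuracy = overallSE(confusion),
    mcc = multiclassMCC(confusion),
    foldWeights = foldWeights,
    foldParams = foldParams,
    maskedChannels = setdiff(channelNames(), config$channels),
    ablated = !setequal(config$channels, channelNames()),
    config = unclass(config)
  )
  class(report) <- "gotlmReport"
  report
}

#' @export
print.gotlmReport <- function(x, ...) {
  cat("goTLM evaluation report",
      if (isTRUE(x$ablated))
        paste0("(ablated: -", paste(x$maskedChannels, collapse = ",-"), ")"),
      "\n")
  cat(sprintf("  overall accuracy: %.4f   multiclass MCC: %.4f\n",
              x$overallAccuracy, x$mcc))
  print(x$perClass[, c("class", "size", "SP", "SE", "MCC")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Subset a LocDataset by index or protein id
#'
#' @param x A [LocDataset-class].
#' @param i Integer/logical indices or protein ids.
#' @param j,...,drop Ignored.
#' @return A [LocDataset-class] restricted to the selected proteins.
#' @export
setMethod("[", "LocDataset", function(x, i, j, ..., drop = FALSE) {
  ids <- proteinIds(x)
  if (is.character(i)) i <- match(i, ids)
  keep <- ids[i]
  ann <- goAnnotations(x)
  lab <- locations(x)[keep]
  lab <- lab[!is.na(lab)]
  LocDataset(proteinSequences(x)[i],
             ann[ann$protein_id %in% keep, , drop = FALSE],
             lab)
})

#' Outer k-fold cross-validation of the full training pipeline
#'
#' The dataset is split into `config$outerFolds` random folds.  Within
#' each training partition the complete [trainGoTlm()] procedure runs
#' (weight estimation and grid search included), so no information
#' leaks from the held-out fold; held-out predictions are pooled into
#' one confusion matrix.
#'
#' @param dataset A fully labeled [LocDataset-class].
#' @param config A [modelConfig()].
#' @return A `gotlmReport`: per-class SP/SE/MCC, overall accuracy, the
#'   pooled confusion matrix, per-fold kernel weights and selected
#'   parameters.
#' @export
crossValidate <- function(dataset, config = modelConfig()) {
  stopifnot(is(dataset, "LocDataset"), inherits(config, "gotlmConfig"))
  labels <- unname(locations(dataset))
  if (anyNA(labels)) stop("all proteins must be labeled for cross-validation")
  classes <- locationClasses(dataset)
  counts <- table(labels)
  if (min(counts) < config$outerFolds) {
    stop("class '", names(counts)[which.min(counts)], "' has fewer members (",
         min(counts), ") than outer folds (", config$outerFolds,
         "); use fewer folds")
  }
  n <- nProteins(dataset)
  fold <- kfoldSplit(n, config$outerFolds, childSeed(config$seed, 1000))
  M <- matrix(0L, length(classes), length(classes),
              dimnames = list(classes, classes))
  foldWeights <- matrix(NA_real_, config$outerFolds, length(channelNames()),
                        dimnames = list(paste0("fold", seq_len(config$outerFolds)),
                                        channelNames()))
  foldParams <- vector("list", config$outerFolds)
  for (f in seq_len(config$outerFolds)) {
    trainIdx <- which(fold != f)
    testIdx <- which(fold == f)
    foldConfig <- config
    foldConfig$seed <- childSeed(config$seed, 2000 + f)
    model <- trainGoTlm(dataset[trainIdx], foldConfig)
    pred <- predict(model, dataset[testIdx])
    M <- M + confusionMatrix(labels[testIdx], pred$predicted_location, classes)
    foldWeights[f, ] <- kernelWeights(model)
    foldParams[[f]] <- modelParams(model)
    gotlmLog("outer fold %d/%d done (cum. accuracy %.4f)",
             f, config$outerFolds, overallSE(M))
  }
  makeReport(M, config, foldWeights = foldWeights, foldParams = foldParams)
}

#' Holdout (independent test set) evaluation
#'
#' Trains on the training dataset only and reports metrics on the
#' disjoint test dataset.
#'
#' @param trainData,testData Labeled [LocDataset-class] objects with
#'   disjoint protein id sets; `testData` must be non-empty.
#' @param config A [modelConfig()].
#' @return A `gotlmReport` (same structure as [crossValidate()]'s), plus
#'   the fitted model in `$model`.
#' @export
holdoutEvaluate <- function(trainData, testData, config = modelConfig()) {
  stopifnot(is(trainData, "LocDataset"), is(testData, "LocDataset"))
  if (nProteins(testData) == 0) stop("test dataset is empty")
  overlap <- intersect(proteinIds(trainData), proteinIds(testData))
  if (length(overlap)) {
    stop("training and test id sets overlap: ",
         paste(utils::head(overlap, 5), collapse = ", "))
  }
  testLabels <- unname(locations(testData))
  if (anyNA(testLabels)) stop("all test proteins must be labeled")
  model <- trainGoTlm(trainData, config)
  classes <- sort(union(locationClasses(trainData), unique(testLabels)))
  pred <- predict(model, testData)
  M <- confusionMatrix(testLabels, pred$predicted_location, classes)
  report <- makeReport(M, config,
                       foldWeights = matrix(kernelWeights(model), 1,
                                            dimnames = list("train",
                                                            channelNames())),
                       foldParams = list(modelParams(model)))
  report$model <- model
  report
}
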