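# Non-parametric kernel-weight estimation.  Each channel kernel is
# scored on its own by K-fold cross-validation of a single-kernel
# multiclass SVM; the channel weight is its sensitivity x MCC product,
# clamped at zero and normalized across channels:
#   w_e = SE_e * MCC_e / sum_c SE_c * MCC_c .

#' Random K-fold assignment
#'
#' A seeded random permutation is cut into contiguous blocks: the first
#' `K - 1` folds have `floor(n / K)` examples and the last fold takes
#' the remainder, so every example is tested exactly once.
#'
#' @param n Number of examples.
#' @param K Number of folds, `2 <= K <= n`.
#' @param seed Integer seed; the same seed reproduces the assignment.
#' @return Integer vector of length `n` giving each example's fold.
#' @export
#' @examples
#' table(kfoldSplit(103, 5, seed = 1))
kfoldSplit <- function(n, K, seed) {
  if (K < 2) stop("K must be >= 2")
  if (n < K) stop("n (", n, ") must be >= K (", K, ")")
  perm <- withSeed(seed, sample.int(n))
  base <- n %/% K
  sizes <- c(rep(base, K - 1), n - base * (K - 1))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(K), times = sizes)
  fold
}

#' Cross-validated score of one channel kernel
#'
#' Trains a single-kernel one-vs-one SVM per fold and pools one
#' confusion matrix over all test folds; returns the overall sensitivity
#' and aggregate multiclass MCC, and their product.  Folds are plain
#' random splits (no stratification), so a fold may miss a class.
#'
#' @param K Square kernel matrix aligned with `labels`.
#' @param labels Character location labels, one per kernel row.
#' @param cvK Number of inner folds.
#' @param C SVM regularization parameter.
#' @param seed Integer seed for the fold split.
#' @param channel Channel name used in diagnostics.
#' @return List with `channel`, `SE`, `MCC`, `product`.
#' @export
scoreChannel <- function(K, labels, cvK, C, seed, channel = "channel") {
  stopifnot(nrow(K) == ncol(K), nrow(K) == length(labels))
  classes <- sort(unique(labels))
  fold <- kfoldSplit(length(labels), cvK, seed)
  M <- matrix(0L, length(classes), length(classes),
              dimnames = list(classes, classes))
  for (f in seq_len(cvK)) {
    testIdx <- which(fold == f)
    trainIdx <- which(fold != f)
    fit <- tryCatch(
      ovoTrain(K[trainIdx, trainIdx, drop = FALSE], labels[trainIdx],
               C = C, classOrder = classes),
      error = function(e) {
        stop("channel ", channel, ", fold ", f, ": ", conditionMessage(e))
      })
    pred <- ovoPredict(fit, K[testIdx, trainIdx, drop = FALSE])
    M <- M + confusionMatrix(labels[testIdx], pred, classes)
  }
  se <- overallSE(M)
  mcc <- multiclassMCC(M)
  list(channel = channel, SE = se, MCC = mcc, product = se * mcc)
}

#' Estimate the five kernel weights by inner cross-validation
#'
#' Scores each channel with [scoreChannel()] under the *same* fold
#' assignment, clamps negative SE×MCC products to zero (a
#' worse-than-random channel contributes nothing) and normalizes to sum
#' 1.  If every product is zero, uniform weights 1/5 are returned with a
#' warning.
#'
#' @param kernels Named list of the five square channel kernels.
#' @param labels Character location labels aligned to the kernel rows.
#' @inheritParams scoreChannel
#' @return Named numeric weights over the five channels; attribute
#'   `"scores"` holds the per-channel SE/MCC/product table.
#' @export
estimateWeights <- function(kernels, labels, cvK, C, seed) {
  missing <- setdiff(channelNames(), names(kernels))
  if (length(missing)) {
    stop("missing channel kernel(s): ", paste(missing, collapse = ", "))
  }
  scores <- lapply(channelNames(), function(ch) {
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
  if (sum(clamped) <= 0) {
    warning("all channel SE*MCC products are <= 0; using uniform weights")
    w <- rep(1 / length(channelNames()), length(channelNames()))
  } else {
    w <- clamped / sum(clamped)
  }
  w <- stats::setNames(w, tab$channel)[channelNames()]
  tab$weight <- unname(w[tab$channel])
  attr(w, "scores") <- tab
  w
}

#' Write a channel-score table as TSV
#'
#' Five rows: channel, SE, MCC, product, weight — the data behind a
#' kernel-weight-distribution plot.
#'
#' @param weights Output of [estimateWeights()] (with its `scores`
#'   attribute) or a [GoTlmModel-class].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeChannelScores <- function(weights, path) {
  tab <- if (is(weights, "GoTlmModel")) channelScores(weights) else
    attr(weights, "scores")
  if (is.null(tab)) stop("no channel scores attached to 'weights'")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
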