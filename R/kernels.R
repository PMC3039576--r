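# Gaussian channel kernels and their weighted fusion.  Each channel e
# contributes K_e(x, y) = exp(-gamma * ||x - y||^2); the fused kernel is
# the convex combination sum_e w_e K_e, which stays symmetric positive
# semi-definite because each Gaussian channel is PSD and the weights are
# non-negative.

#' Gaussian (RBF) kernel between two feature matrices
#'
#' `K[i, j] = exp(-gamma * ||X[i, ] - Y[j, ]||^2)`.  When `Y` is omitted
#' the square training kernel is returned, exactly symmetric with a unit
#' diagonal.  A zero-dimensional feature space (empty GO vocabulary)
#' gives the all-ones kernel — an uninformative degenerate channel,
#' flagged via attribute `"degenerate"` — so datasets with a missing
#' aspect still train.
#'
#' @param X Feature matrix (rows = proteins), rownames used as ids.
#' @param Y Optional second feature matrix with the same number of
#'   columns; defaults to `X`.
#' @param gamma Positive kernel width parameter.
#' @return Kernel matrix `nrow(X)` x `nrow(Y)` with dimnames from the
#'   input rownames.
#' @export
#' @examples
#' K <- gaussianKernel(diag(3), gamma = 0.5)
#' diag(K)
gaussianKernel <- function(X, Y = NULL, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0) {
    stop("gamma must be a single positive number")
  }
  X <- as.matrix(X)
  square <- is.null(Y)
  Y <- if (square) X else as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("X and Y must share feature dimension")
  if (ncol(X) == 0) {
    K <- matrix(1, nrow(X), nrow(Y), dimnames = list(rownames(X), rownames(Y)))
    attr(K, "degenerate") <- TRUE
    gotlmLog("degenerate channel: empty feature space, all-ones kernel")
    return(K)
  }
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  K <- exp(-gamma * d2)
  if (square) {
    K <- (K + t(K)) / 2
    diag(K) <- 1
  }
  dimnames(K) <- list(rownames(X), rownames(Y))
  K
}

#' Validate and normalize kernel weights
#'
#' @param weights Named numeric vector over the five channels.
#' @return The weights reordered to canonical channel order.
#' @keywords internal
checkKernelWeights <- function(weights) {
  if (!setequal(names(weights), channelNames())) {
    stop("weights must be named by the five channels: ",
         paste(channelNames(), collapse = ", "))
  }
  w <- weights[channelNames()]
  if (any(w < 0)) stop("kernel weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-8) stop("kernel weights must sum to 1")
  w
}

#' Fuse channel kernels with non-negative weights
#'
#' Element-wise weighted sum of the five channel kernels.  All kernels
#' must share shape and dimnames (protein id ordering).
#'
#' @param kernels Named list of the five channel kernel matrices.
#' @param weights Named non-negative weights summing to 1.
#' @return The fused kernel matrix.
#' @export
fuseKernels <- function(kernels, weights) {
  w <- checkKernelWeights(weights)
  missing <- setdiff(channelNames(), names(kernels))
  if (length(missing)) {
    stop("missing channel kernel(s): ", paste(missing, collapse = ", "))
  }
  ref <- kernels[[channelNames()[1]]]
  for (ch in channelNames()) {
    K <- kernels[[ch]]
    if (!all(dim(K) == dim(ref))) stop("kernel shape mismatch in channel ", ch)
    if (!identical(dimnames(K), dimnames(ref))) {
      stop("kernel id ordering mismatch in channel ", ch)
    }
  }
  fused <- matrix(0, nrow(ref), ncol(ref), dimnames = dimnames(ref))
  for (ch in channelNames()) {
    fused <- fused + w[[ch]] * kernels[[ch]]
  }
  fused
}

#' Compute the five channel kernels
#'
#' @param channels Feature channel list from [buildChannels()].
#' @param gamma Positive kernel width, shared across channels.
#' @param testChannels Optional second channel list; if given,
#'   rectangular test-vs-train kernels are returned.
#' @return Named list of five kernel matrices.
#' @export
channelKernels <- function(channels, gamma, testChannels = NULL) {
  out <- lapply(stats::setNames(channelNames(), channelNames()), function(ch) {
    if (is.null(testChannels)) {
      gaussianKernel(channels[[ch]], gamma = gamma)
    } else {
      gaussianKernel(testChannels[[ch]], channels[[ch]], gamma = gamma)
    }
  })
  out
}

#' Write a kernel matrix to a whitespace-delimited text file
#'
#' Dense matrix dump with an id header row, for inspection.
#'
#' @param K Kernel matrix with dimnames.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeKernel <- function(K, path) {
  utils::write.table(format(K, digits = 10), path, quote = FALSE,
                     sep = " ", col.names = NA)
  invisible(path)
}
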