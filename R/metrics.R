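# Confusion-matrix bookkeeping and performance measures.  With M the
# L x L confusion matrix (rows = true class, columns = predicted), the
# per-class quantities are
#   p_l = M[l, l]                      (true positives)
#   q_l = sum_{i != l, j != l} M[i, j] (true negatives)
#   r_l = sum_{i != l} M[i, l]         (false positives)
#   s_l = sum_{j != l} M[l, j]         (false negatives)
# and the aggregates p, q, r, s are their sums over classes.  Overall
# sensitivity SE = trace(M) / total (identical to overall accuracy) and
# the aggregate multiclass MCC is
#   (p q - r s) / sqrt((p + r)(p + s)(q + r)(q + s)).

#' Confusion matrix from paired label vectors
#'
#' @param yTrue,yPred Equal-length label vectors; every label must be in
#'   `classes`.
#' @param classes Ordered class names defining row/column order.
#' @return Integer `L x L` matrix, rows = true class, columns =
#'   predicted class.
#' @export
#' @examples
#' confusionMatrix(c("a", "a", "b"), c("a", "b", "b"), classes = c("a", "b"))
confusionMatrix <- function(yTrue, yPred, classes) {
  if (length(yTrue) != length(yPred)) {
    stop("yTrue and yPred must have equal length")
  }
  bad <- setdiff(unique(c(yTrue, yPred)), classes)
  if (length(bad)) {
    stop("label(s) not in classes: ", paste(bad, collapse = ", "))
  }
  t1 <- factor(yTrue, levels = classes)
  t2 <- factor(yPred, levels = classes)
  m <- table(true = t1, predicted = t2)
  matrix(as.integer(m), nrow = length(classes),
         dimnames = list(classes, classes))
}

#' Per-class confusion quantities for one class
#'
#' @param M Confusion matrix (rows = true, columns = predicted).
#' @param l Class index (1-based) or class name.
#' @return List with `p` (true positives), `q` (true negatives), `r`
#'   (false positives), `s` (false negatives) for class `l`.
#' @export
classQuantities <- function(M, l) {
  M <- as.matrix(M)
  if (is.character(l)) l <- match(l, rownames(M))
  stopifnot(!is.na(l), l >= 1, l <= nrow(M))
  list(p = M[l, l],
       q = sum(M[-l, -l, drop = FALSE]),
       r = sum(M[-l, l]) ,
       s = sum(M[l, -l]))
}

#' Aggregate confusion quantities over all classes
#'
#' @param M Confusion matrix.
#' @return List with `p`, `q`, `r`, `s`: per-class quantities summed
#'   over classes.
#' @export
aggregateQuantities <- function(M) {
  M <- as.matrix(M)
  per <- lapply(seq_len(nrow(M)), function(l) classQuantities(M, l))
  list(p = sum(vapply(per, `[[`, 0, "p")),
       q = sum(vapply(per, `[[`, 0, "q")),
       r = sum(vapply(per, `[[`, 0, "r")),
       s = sum(vapply(per, `[[`, 0, "s")))
}

#' Overall sensitivity (= overall accuracy)
#'
#' @param M Confusion matrix with a positive total count.
#' @return `trace(M) / sum(M)`, in `[0, 1]`.
#' @export
overallSE <- function(M) {
  M <- as.matrix(M)
  total <- sum(M)
  if (total <= 0) stop("confusion matrix is empty")
  sum(diag(M)) / total
}

#' Aggregate multiclass Matthews correlation coefficient
#'
#' Built from the aggregate quantities p, q, r, s (see file header).
#' When any factor of the denominator is zero the value is 0 by
#' convention, so useless predictors get zero rather than NaN.
#'
#' @param M Confusion matrix with a positive total count.
#' @return MCC in `[-1, 1]`.
#' @export
multiclassMCC <- function(M) {
  M <- as.matrix(M)
  if (sum(M) <= 0) stop("confusion matrix is empty")
  a <- aggregateQuantities(M)
  denomFactors <- c(a$p + a$r, a$p + a$s, a$q + a$r, a$q + a$s)
  if (any(denomFactors == 0)) return(0)
  (a$p * a$q - a$r * a$s) / sqrt(prod(denomFactors))
}

#' Per-class specificity, sensitivity and MCC
#'
#' For each class l: `SE_l = p_l / (p_l + s_l)` (recall), `SP_l = p_l /
#' (p_l + r_l)` (precision, the convention in the subcellular
#' localization literature), and the binary MCC of class l versus rest.
#' Zero denominators give 0; for SP/SE the `spDefined`/`seDefined`
#' columns flag where this happened.
#'
#' @param M Confusion matrix with a positive total count.
#' @return `data.frame` with columns `class`, `size` (true class count),
#'   `SP`, `SE`, `MCC`, `spDefined`, `seDefined`.
#' @export
perClassMetrics <- function(M) {
  M <- as.matrix(M)
  if (sum(M) <= 0) stop("confusion matrix is empty")
  classes <- rownames(M) %||% as.character(seq_len(nrow(M)))
  rows <- lapply(seq_len(nrow(M)), function(l) {
    cq <- classQuantities(M, l)
    spDef <- (cq$p + cq$r) > 0
    seDef <- (cq$p + cq$s) > 0
    denomFactors <- c(cq$p + cq$r, cq$p + cq$s, cq$q + cq$r, cq$q + cq$s)
    mcc <- if (any(denomFactors == 0)) 0 else
      (cq$p * cq$q - cq$r * cq$s) / sqrt(prod(denomFactors))
    data.frame(class = classes[l],
               size = cq$p + cq$s,
               SP = if (spDef) cq$p / (cq$p + cq$r) else 0,
               SE = if (seDef) cq$p / (cq$p + cq$s) else 0,
               MCC = mcc,
               spDefined = spDef,
               seDefined = seDef,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an evaluation report as TSV
#'
#' Per-location table (location, size, SP, SE, MCC) followed by a
#' comment line with the overall accuracy.
#'
#' @param report Evaluation report from [crossValidate()] or
#'   [holdoutEvaluate()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeEvalReport <- function(report, path) {
  per <- report$perClass[, c("class", "size", "SP", "SE", "MCC")]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# overall_accuracy\t%.6f", report$overallAccuracy), con)
  if (!is.null(report$ablated) && isTRUE(report$ablated)) {
    writeLines(sprintf("# ablated_channels\t%s",
                       paste(report$maskedChannels, collapse = ",")), con)
  }
  utils::write.table(per, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
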