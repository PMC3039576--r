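# One-vs-one multiclass SVM over a precomputed kernel.
#
# The square training kernel K (symmetric PSD) is factored once through
# its eigendecomposition, K = Phi Phi^T with Phi = V D^(1/2), and the
# binary C-SVC subproblems are solved by libsvm (e1071) with a *linear*
# kernel on the rows of Phi — the decision functions are identical to
# training on K directly, since <Phi_i, Phi_j> = K_ij.  New points with
# kernel column k against the training rows map to D^(-1/2) V^T k.
# The voting layer is kept in-package so the tie rule is explicit:
# vote ties go to the class that comes earlier in the stored class
# order.

# Empirical feature map of a square PSD kernel.  Eigenvalues below
# tol * max(eigenvalue) are treated as numerical zeros (a Gaussian
# kernel is PSD up to rounding).
kernelFeatureMap <- function(K, tol = 1e-10) {
  e <- eigen(K, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 1)
  if (!any(keep)) keep[1] <- TRUE
  vals <- e$values[keep]
  V <- e$vectors[, keep, drop = FALSE]
  list(Phi = V %*% diag(sqrt(vals), length(vals)),
       V = V, vals = vals)
}

# Map rectangular test-vs-train kernel rows into the training feature
# space: Phi_test = Ktest V D^(-1/2).
mapNewRows <- function(map, Ktest) {
  Ktest %*% map$V %*% diag(1 / sqrt(map$vals), length(map$vals))
}

# Fit all pairwise binary SVMs on a square training kernel.
# K: n x n kernel, y: character labels, classOrder: full class order.
ovoTrain <- function(K, y, C, classOrder) {
  stopifnot(nrow(K) == ncol(K), nrow(K) == length(y))
  present <- classOrder[classOrder %in% unique(y)]
  map <- kernelFeatureMap(K)
  fits <- list()
  if (length(present) >= 2) {
    pairIdx <- utils::combn(length(present), 2)
    for (k in seq_len(ncol(pairIdx))) {
      a <- present[pairIdx[1, k]]
      b <- present[pairIdx[2, k]]
      idx <- which(y %in% c(a, b))
      ysub <- factor(y[idx], levels = c(a, b))
      fit <- tryCatch(
        e1071::svm(map$Phi[idx, , drop = FALSE], ysub, type = "C-classification",
                   kernel = "linear", cost = C, scale = FALSE),
        error = function(e) {
          stop("SVM training failed for class pair (", a, ", ", b, "): ",
               conditionMessage(e))
        })
      fits[[paste(a, b, sep = "|")]] <- list(a = a, b = b, fit = fit)
    }
  }
  list(classOrder = classOrder, present = present, C = C,
       map = map, fits = fits)
}

# Predict labels from a rectangular kernel (test rows x training columns).
ovoPredict <- function(model, Ktest, decisionSummary = FALSE) {
  nTest <- nrow(Ktest)
  present <- model$present
  if (length(present) == 1) {
    pred <- rep(present, nTest)
    if (!decisionSummary) return(pred)
    return(data.frame(predicted = pred, votes = 0L, margin = 0L,
                      stringsAsFactors = FALSE))
  }
  PhiTest <- mapNewRows(model$map, Ktest)
  votes <- matrix(0L, nTest, length(present),
                  dimnames = list(NULL, present))
  for (pf in model$fits) {
    lab <- as.character(predict(pf$fit, PhiTest))
    for (cls in c(pf$a, pf$b)) {
      hit <- lab == cls
      votes[hit, cls] <- votes[hit, cls] + 1L
    }
  }
  # Columns are in class order, so "first" max implements the tie rule.
  winner <- max.col(votes, ties.method = "first")
  pred <- present[winner]
  if (!decisionSummary) return(pred)
  top <- votes[cbind(seq_len(nTest), winner)]
  second <- vapply(seq_len(nTest), function(i) {
    v <- votes[i, ]
    v[winner[i]] <- -1L
    max(v)
  }, integer(1))
  data.frame(predicted = pred, votes = top, margin = top - second,
             stringsAsFactors = FALSE)
}
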