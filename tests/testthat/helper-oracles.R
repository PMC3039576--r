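# Independent brute-force oracles, deliberately coded with plain loops
# so they share no code path with the package implementation.

options(goTLM.verbose = FALSE)

# Per-class and aggregate confusion quantities by explicit summation.
oracleQuantities <- function(M) {
  L <- nrow(M)
  out <- list(p = numeric(L), q = numeric(L), r = numeric(L), s = numeric(L))
  for (l in seq_len(L)) {
    out$p[l] <- M[l, l]
    q <- 0
    for (i in seq_len(L)) for (j in seq_len(L)) {
      if (i != l && j != l) q <- q + M[i, j]
    }
    out$q[l] <- q
    r <- 0
    for (i in seq_len(L)) if (i != l) r <- r + M[i, l]
    out$r[l] <- r
    s <- 0
    for (j in seq_len(L)) if (j != l) s <- s + M[l, j]
    out$s[l] <- s
  }
  out
}

oracleSE <- function(M) {
  num <- 0
  for (l in seq_len(nrow(M))) num <- num + M[l, l]
  num / sum(M)
}

oracleMCC <- function(M) {
  a <- oracleQuantities(M)
  p <- sum(a$p); q <- sum(a$q); r <- sum(a$r); s <- sum(a$s)
  denom <- (p + r) * (p + s) * (q + r) * (q + s)
  if (denom == 0) return(0)
  (p * q - r * s) / sqrt(denom)
}

oraclePerClassMCC <- function(M, l) {
  a <- oracleQuantities(M)
  p <- a$p[l]; q <- a$q[l]; r <- a$r[l]; s <- a$s[l]
  denom <- (p + r) * (p + s) * (q + r) * (q + s)
  if (denom == 0) return(0)
  (p * q - r * s) / sqrt(denom)
}

# Textbook binary MCC from (TP, TN, FP, FN).
binaryMCC <- function(tp, tn, fp, fn) {
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

# Element-wise Gaussian kernel.
oracleGaussian <- function(X, Y, gamma) {
  K <- matrix(0, nrow(X), nrow(Y))
  for (i in seq_len(nrow(X))) for (j in seq_len(nrow(Y))) {
    K[i, j] <- exp(-gamma * sum((X[i, ] - Y[j, ])^2))
  }
  K
}

randomConfusion <- function(L, maxCount = 50) {
  matrix(sample.int(maxCount + 1, L * L, replace = TRUE) - 1L, L, L,
         dimnames = list(paste0("c", 1:L), paste0("c", 1:L)))
}

# A perfectly class-separating block kernel: 1 within class, `off`
# between classes (PSD for 0 <= off <= 1).
blockKernel <- function(labels, off = 0.1) {
  same <- outer(labels, labels, "==")
  K <- matrix(off, length(labels), length(labels))
  K[same] <- 1
  diag(K) <- 1
  K
}

# Small fast synthetic datasets for model-level tests.
tinyConfig <- function(nClasses = 3, nPerClass = 12, seed = 7, ...) {
  generatorConfig(nClasses = nClasses, nPerClass = nPerClass,
                  seqLen = c(40, 60), seed = seed, ...)
}

tinyGrid <- function(seed = 1, ...) {
  modelConfig(cvK = 3, gamma = 2^-2, C = 2^3, seed = seed, ...)
}
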