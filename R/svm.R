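# Support-vector classifier, RBF kernel, one-vs-one multiclass.
# Binary subproblems are solved with a deterministic SMO: sweeps over all
# examples, pairing each KKT violator with the example of maximal error
# difference. Small training sets (hundreds of flagged spectra) keep the
# dense kernel matrix cheap.

rbf_kernel <- function(X, Y, gamma) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  exp(-gamma * pmax(d2, 0))
}

# sklearn-style "scale" kernel width heuristic: 1 / (p * Var(X))
gamma_scale <- function(X) {
  v <- stats::var(as.vector(as.matrix(X)))
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(X) * v)
}

svm_binary_train <- function(K, y, C, tol = 1e-3, max_passes = 200L) {
  n <- length(y)
  alpha <- numeric(n)
  b <- 0
  f <- function() as.vector(K %*% (alpha * y)) + b
  E <- f() - y
  passes <- 0L
  repeat {
    changed <- 0L
    for (i in seq_len(n)) {
      ri <- E[i] * y[i]
      if (!((ri < -tol && alpha[i] < C) || (ri > tol && alpha[i] > 0))) next
      j <- which.max(abs(E - E[i]))
      if (j == i) next
      ai_old <- alpha[i]; aj_old <- alpha[j]
      if (y[i] != y[j]) {
        L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
      } else {
        L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
      }
      if (L >= H) next
      eta <- 2 * K[i, j] - K[i, i] - K[j, j]
      if (eta >= 0) next
      aj <- aj_old - y[j] * (E[i] - E[j]) / eta
      aj <- min(H, max(L, aj))
      if (abs(aj - aj_old) < 1e-7) next
      ai <- ai_old + y[i] * y[j] * (aj_old - aj)
      b1 <- b - E[i] - y[i] * (ai - ai_old) * K[i, i] -
        y[j] * (aj - aj_old) * K[i, j]
      b2 <- b - E[j] - y[i] * (ai - ai_old) * K[i, j] -
        y[j] * (aj - aj_old) * K[j, j]
      b <- if (ai > 0 && ai < C) b1
           else if (aj > 0 && aj < C) b2
           else (b1 + b2) / 2
      alpha[i] <- ai; alpha[j] <- aj
      E <- as.vector(K %*% (alpha * y)) + b - y
      changed <- changed + 1L
    }
    passes <- passes + 1L
    if (changed == 0L || passes >= max_passes) break
  }
  list(alpha = alpha, b = b)
}

# one-vs-one RBF SVM over integer/character class labels
svm_ovo_fit <- function(X, y, C, gamma) {
  X <- as.matrix(X)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("fit error: single class")
  pairs <- utils::combn(classes, 2L, simplify = FALSE)
  K_full <- rbf_kernel(X, X, gamma)
  models <- lapply(pairs, function(p) {
    idx <- which(y %in% p)
    ysub <- ifelse(y[idx] == p[1L], 1, -1)
    fit <- svm_binary_train(K_full[idx, idx, drop = FALSE], ysub, C)
    sv <- which(fit$alpha > 1e-10)
    list(pos = p[1L], neg = p[2L], idx = idx[sv],
         coef = (fit$alpha * ysub)[sv], b = fit$b)
  })
  structure(list(X = X, classes = classes, gamma = gamma, C = C,
                 models = models),
            class = "ovo_svm")
}

svm_ovo_predict <- function(object, Xnew) {
  Xnew <- as.matrix(Xnew)
  classes <- object$classes
  votes <- matrix(0, nrow(Xnew), length(classes),
                  dimnames = list(NULL, as.character(classes)))
  margin <- votes
  for (m in object$models) {
    if (length(m$idx)) {
      Kx <- rbf_kernel(Xnew, object$X[m$idx, , drop = FALSE], object$gamma)
      dec <- as.vector(Kx %*% m$coef) + m$b
    } else {
      dec <- rep(m$b, nrow(Xnew))
    }
    ipos <- match(m$pos, classes); ineg <- match(m$neg, classes)
    wi <- ifelse(dec >= 0, ipos, ineg)
    idx <- cbind(seq_len(nrow(Xnew)), wi)
    votes[idx] <- votes[idx] + 1
    margin[, ipos] <- margin[, ipos] + dec
    margin[, ineg] <- margin[, ineg] - dec
  }
  # ties: larger summed decision margin, then class order
  best <- apply(votes + 1e-9 * pmin(pmax(margin, -1e6), 1e6) / 1e6, 1L,
                which.max)
  classes[best]
}
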