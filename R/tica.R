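# Time-lagged independent component analysis on collective-variable
# matrices: generalized eigenproblem C(tau) v = lambda C(0) v with the
# lagged covariance symmetrized and C(0) ridge-regularized. Lagged pairs
# never span segment boundaries.

.asSegments <- function(x) {
  if (is(x, "CVMatrix")) splitSegments(x@values, x@segmentStarts)
  else if (is.matrix(x)) list(x)
  else if (is.list(x)) lapply(x, as.matrix)
  else stop("expected a CVMatrix, matrix or list of matrices")
}

#' Fit a tICA model
#'
#' Data are mean-centered with the pooled mean; the instantaneous
#' covariance C(0) and the lag-tau covariance C(tau) are accumulated per
#' segment and pooled; C(tau) is symmetrized as (C + t(C)) / 2 and C(0)
#' receives a ridge epsilon on its diagonal before the generalized
#' eigenproblem is solved through a Cholesky transform. Eigenvalues are
#' sorted descending; eigenvectors are normalized to t(V) C(0) V = I
#' with the sign fixed so the largest-magnitude loading is positive.
#'
#' @param x a [CVMatrix-class], a frames x CV matrix, or a list of
#'   per-segment matrices.
#' @param lag lag time in frames (default 25).
#' @param epsilon ridge on C(0); default 1e-10 * trace(C0) / n_cv.
#' @return a [TICAModel-class]
#' @export
fitTICA <- function(x, lag = 25L, epsilon = NULL) {
  segs <- .asSegments(x)
  lag <- as.integer(lag)
  d <- ncol(segs[[1]])
  if (d < 2L) stop("need at least 2 collective variables")
  if (any(vapply(segs, nrow, integer(1)) <= lag))
    stop("lag must be shorter than every segment")
  nTot <- sum(vapply(segs, nrow, integer(1)))
  mu <- Reduce(`+`, lapply(segs, colSums)) / nTot
  C0 <- matrix(0, d, d); Ct <- matrix(0, d, d)
  nPairs <- 0L
  for (s in segs) {
    Xc <- sweep(s, 2, mu)
    n <- nrow(Xc)
    C0 <- C0 + crossprod(Xc)
    Ct <- Ct + crossprod(Xc[1:(n - lag), , drop = FALSE],
                         Xc[(1 + lag):n, , drop = FALSE])
    nPairs <- nPairs + (n - lag)
  }
  C0 <- C0 / nTot
  Ct <- Ct / nPairs
  Ct <- (Ct + t(Ct)) / 2
  if (is.null(epsilon)) epsilon <- 1e-10 * sum(diag(C0)) / d
  C0r <- C0 + diag(epsilon, d)
  L <- tryCatch(chol(C0r), error = function(e)
    stop("C(0) is singular even after regularization: ",
         conditionMessage(e)))
  A1 <- backsolve(L, Ct, transpose = TRUE)      # L^-T Ct
  M <- t(backsolve(L, t(A1), transpose = TRUE)) # L^-T Ct L^-1
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  V <- backsolve(L, e$vectors)                  # v = L^-1 u
  # sign convention: largest-|loading| entry positive
  for (j in seq_len(d)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  cvn <- colnames(segs[[1]])
  if (is.null(cvn)) cvn <- paste0("cv", seq_len(d))
  new("TICAModel", mean = as.numeric(mu), eigenvalues = e$values,
      eigenvectors = V, lag = lag, epsilon = epsilon, cvNames = cvn)
}

#' Cumulative kinetic content of the leading components
#'
#' Fraction of the summed positive eigenvalues captured by the first
#' \code{k} components: sum_{i<=k} max(lambda_i, 0) / sum_i
#' max(lambda_i, 0).
#'
#' @param model a [TICAModel-class].
#' @param k number of leading components.
#' @return fraction in [0, 1]
#' @export
kineticContent <- function(model, k) {
  lam <- pmax(model@eigenvalues, 0)
  if (k < 1L || k > length(lam)) stop("k out of range")
  tot <- sum(lam)
  if (tot == 0) return(0)
  sum(lam[seq_len(k)]) / tot
}

#' Project CV data onto the leading tICA components
#'
#' @param model a [TICAModel-class].
#' @param x a [CVMatrix-class] or frames x CV matrix (CV count must
#'   match the model).
#' @param k number of components to keep (default 3).
#' @return frames x k numeric matrix
#' @export
projectTICA <- function(model, x, k = 3L) {
  X <- if (is(x, "CVMatrix")) x@values else as.matrix(x)
  if (ncol(X) != length(model@mean))
    stop("CV count does not match the model")
  k <- min(as.integer(k), ncol(model@eigenvectors))
  sweep(X, 2, model@mean) %*% model@eigenvectors[, seq_len(k), drop = FALSE]
}

#' Implied timescale of a tICA component
#'
#' @param model a [TICAModel-class].
#' @param i component index (default 1).
#' @return -lag / log(lambda_i) in frames (NaN when lambda_i <= 0)
#' @export
ticaTimescale <- function(model, i = 1L) {
  lam <- model@eigenvalues[i]
  if (lam <= 0) return(NaN)
  -model@lag / log(lam)
}
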