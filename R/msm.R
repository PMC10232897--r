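# Markov state model construction: k-means microstates on the tICA
# projections, sliding-window transition counts at a lag, count-matrix
# symmetrization (detailed balance by construction), implied timescales,
# GMRQ cross-validation and PCCA+ macrostates.

# deterministic k-means++ seeding (D^2 sampling)
.kmeansppCenters <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  i <- sample.int(n, 1L)
  centers[1, ] <- X[i, ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in seq_len(k)[-1]) {
    tot <- sum(d2)
    i <- if (tot <= 0) sample.int(n, 1L)
         else sample.int(n, 1L, prob = d2 / tot)
    centers[j, ] <- X[i, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

#' Cluster projected frames into microstates
#'
#' k-means (Lloyd iterations) from a seeded k-means++ start; the same
#' seed always reproduces the same centers and assignments.
#'
#' @param x a frames x d matrix, a list of per-segment matrices, or a
#'   [CVMatrix-class].
#' @param k number of microstates (default 200).
#' @param seed integer RNG seed for the k-means++ start.
#' @param maxIter Lloyd iterations (default 100).
#' @return a [MarkovModel-class] holding centers and per-segment
#'   assignments (transition matrix slots are filled by [buildTPM()])
#' @export
clusterMicrostates <- function(x, k = 200L, seed = NULL, maxIter = 100L) {
  segs <- .asSegments(x)
  X <- do.call(rbind, segs)
  k <- as.integer(k)
  if (nrow(X) < k) stop("fewer frames than requested microstates")
  km <- withSeed(seed, {
    centers <- .kmeanspppSafe(X, k)
    stats::kmeans(X, centers = centers, iter.max = maxIter,
                  algorithm = "Lloyd")
  })
  nf <- vapply(segs, nrow, integer(1))
  assign <- split(km$cluster, rep(seq_along(segs), nf))
  names(assign) <- NULL
  new("MarkovModel", centers = km$centers,
      assignments = lapply(assign, as.integer),
      lag = NA_integer_, counts = matrix(0, 0, 0),
      tpm = matrix(0, 0, 0), pi = numeric(),
      active = integer(),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

# k-means++ with duplicate-center guard (exact-duplicate frames can
# yield coincident centers; kmeans() then errors)
.kmeanspppSafe <- function(X, k) {
  centers <- .kmeansppCenters(X, k)
  dup <- duplicated(centers)
  tries <- 0L
  while (any(dup) && tries < 25L) {
    centers[dup, ] <- X[sample.int(nrow(X), sum(dup)), , drop = FALSE] +
      stats::rnorm(sum(dup) * ncol(X), sd = 1e-8)
    dup <- duplicated(centers)
    tries <- tries + 1L
  }
  centers
}

# undirected connected components of a non-negative adjacency matrix
.largestComponent <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      nb <- which((A[u, ] > 0 | A[, u] > 0) & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  sizes <- vapply(seq_len(cur), function(cc) sum(A[comp == cc, comp == cc]),
                  numeric(1))
  which(comp == which.max(sizes))
}

#' Build the transition probability matrix
#'
#' Sliding-window transition counts at lag \code{lag} are accumulated
#' within each segment, trimmed to the largest connected set of states
#' (with a warning when states are dropped), symmetrized as
#' (C + t(C)) / 2 to enforce detailed balance, and row-normalized. The
#' stationary distribution is proportional to the symmetrized row sums,
#' so pi_i T_ij = pi_j T_ji holds exactly.
#'
#' @param model a [MarkovModel-class] from [clusterMicrostates()], or a
#'   list of integer assignment vectors.
#' @param lag lag time in frames.
#' @param symmetrize logical (default TRUE).
#' @param nStates total number of state labels; inferred when missing.
#' @return a [MarkovModel-class] with counts, tpm, pi and active filled
#' @export
buildTPM <- function(model, lag, symmetrize = TRUE, nStates = NULL) {
  assign <- if (is(model, "MarkovModel")) model@assignments else model
  lag <- as.integer(lag)
  if (any(vapply(assign, length, integer(1)) <= lag))
    stop("lag must be shorter than every segment")
  K <- nStates %||% max(unlist(assign))
  C <- matrix(0, K, K)
  for (a in assign) {
    n <- length(a)
    from <- a[1:(n - lag)]
    to <- a[(1 + lag):n]
    C <- C + matrix(tabulate(from + K * (to - 1L), nbins = K * K), K, K)
  }
  if (sum(C) == 0) stop("empty count matrix")
  keep <- .largestComponent(C)
  if (length(keep) < K)
    warning(K - length(keep),
            " state(s) outside the largest connected set dropped")
  C <- C[keep, keep, drop = FALSE]
  Cs <- if (symmetrize) (C + t(C)) / 2 else C
  rs <- rowSums(Cs)
  T <- Cs / rs
  piv <- if (symmetrize) rs / sum(rs) else .stationaryFromTPM(T)
  out <- if (is(model, "MarkovModel")) model
         else new("MarkovModel", centers = matrix(0, 0, 0),
                  assignments = lapply(assign, as.integer),
                  seed = NA_integer_)
  out@lag <- lag
  out@counts <- Cs
  out@tpm <- T
  out@pi <- piv
  out@active <- as.integer(keep)
  out
}

.stationaryFromTPM <- function(T) {
  e <- eigen(t(T))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

# spectrum of a reversible TPM via the symmetric similarity transform
# D^{1/2} T D^{-1/2}; returns eigenvalues (desc) and right eigenvectors
.tpmEigen <- function(T, piv) {
  s <- sqrt(piv)
  A <- T * outer(s, 1 / s)
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  V <- e$vectors / s
  list(values = e$values, vectors = V)
}

#' Implied timescale test
#'
#' For each lag, builds the symmetrized TPM and reports
#' t_i = -lag / log(lambda_i) for the leading non-unit eigenvalues.
#' Markovian dynamics give timescales that are flat in the lag.
#'
#' @param assignments list of integer assignment vectors (or a
#'   [MarkovModel-class]).
#' @param lags integer vector of lags (frames).
#' @param nTimescales how many timescales to report (default 5).
#' @return data.frame with columns lag, index, eigenvalue, timescale
#'   (frames; NaN with a warning when an eigenvalue is <= 0, Inf when
#'   an eigenvalue reaches 1 within tolerance)
#' @export
impliedTimescales <- function(assignments, lags, nTimescales = 5L) {
  if (is(assignments, "MarkovModel")) assignments <- assignments@assignments
  rows <- list()
  for (lg in as.integer(lags)) {
    m <- buildTPM(assignments, lg)
    e <- .tpmEigen(m@tpm, m@pi)
    nts <- min(nTimescales, length(e$values) - 1L)
    if (nts < 1L) next
    lam <- e$values[1L + seq_len(nts)]
    ts <- rep(NaN, nts)
    pos <- lam > 0 & lam < 1 - 1e-12
    ts[pos] <- -lg / log(lam[pos])
    ts[lam >= 1 - 1e-12] <- Inf
    if (any(lam <= 0))
      warning("non-positive TPM eigenvalue at lag ", lg,
              "; timescale undefined (NaN)")
    rows[[length(rows) + 1L]] <-
      data.frame(lag = lg, index = seq_len(nts) + 1L,
                 eigenvalue = lam, timescale = ts)
  }
  do.call(rbind, rows)
}

#' Implied timescales of an explicit transition matrix
#'
#' @param T row-stochastic transition matrix.
#' @param lag lag time the matrix was built at (frames; default 1).
#' @param nTimescales how many to report.
#' @return data.frame with columns index, eigenvalue, timescale
#' @export
tpmImpliedTimescales <- function(T, lag = 1L, nTimescales = 5L) {
  lam <- sort(Re(eigen(T, only.values = TRUE)$values), decreasing = TRUE)
  nts <- min(nTimescales, length(lam) - 1L)
  lam <- lam[1L + seq_len(nts)]
  ts <- rep(NaN, nts)
  pos <- lam > 0 & lam < 1 - 1e-12
  ts[pos] <- -lag / log(lam[pos])
  ts[lam >= 1 - 1e-12] <- Inf
  data.frame(index = seq_len(nts) + 1L, eigenvalue = lam, timescale = ts)
}

#' GMRQ cross-validation score
#'
#' Generalized matrix Rayleigh quotient: how well the leading
#' eigenvectors of the training-set TPM diagonalize the test-set TPM,
#' R = Tr[(t(V) S T V) (t(V) S V)^-1], with V the first n right
#' eigenvectors of the training TPM, T the test TPM and S the diagonal
#' matrix of test-set equilibrium populations. With train = test the
#' score equals the sum of the top-n eigenvalues.
#'
#' @param trainAssign,testAssign lists of integer assignment vectors.
#' @param lag lag time in frames.
#' @param n number of eigenvectors (default 3).
#' @return numeric score
#' @export
gmrqScore <- function(trainAssign, testAssign, lag, n = 3L) {
  K <- max(unlist(c(trainAssign, testAssign)))
  train <- buildTPM(trainAssign, lag, nStates = K)
  eTr <- .tpmEigen(train@tpm, train@pi)
  V <- eTr$vectors[, seq_len(n), drop = FALSE]
  test <- buildTPM(testAssign, lag, nStates = K)
  # restrict both models to the states retained in both
  commonStates <- intersect(train@active, test@active)
  if (length(commonStates) < length(train@active) ||
      length(commonStates) < length(test@active))
    warning("train/test state sets differ; scoring on the ",
            length(commonStates), " shared state(s)")
  iTr <- match(commonStates, train@active)
  iTe <- match(commonStates, test@active)
  V <- V[iTr, , drop = FALSE]
  T <- test@tpm[iTe, iTe, drop = FALSE]
  S <- diag(test@pi[iTe] / sum(test@pi[iTe]), length(iTe))
  num <- t(V) %*% S %*% T %*% V
  den <- t(V) %*% S %*% V
  if (rcond(den) < 1e-14) stop("singular t(V) S V in GMRQ score")
  sum(diag(num %*% solve(den)))
}

# PCCA+ inner-simplex construction on the first m right eigenvectors of
# a reversible TPM. Memberships below 0 (possible for weakly metastable
# states) are clipped and rows renormalized; crisp states by argmax.
.pccaISA <- function(X) {
  m <- ncol(X)
  ind <- integer(m)
  ortho <- X
  norms <- rowSums(ortho^2)
  ind[1] <- which.max(norms)
  ortho <- sweep(ortho, 2, X[ind[1], ])
  if (m >= 2L) for (j in 2:m) {
    norms <- rowSums(ortho^2)
    ind[j] <- which.max(norms)
    v <- ortho[ind[j], ]
    v <- v / sqrt(sum(v^2))
    ortho <- ortho - (ortho %*% v) %*% t(v)
  }
  A <- solve(X[ind, , drop = FALSE])
  X %*% A
}

#' PCCA+ macrostate assignment
#'
#' Groups the microstates of a reversible TPM into \code{m} metastable
#' macrostates from its first \code{m} right eigenvectors using the
#' inner-simplex PCCA+ construction. Membership rows sum to 1; the
#' crisp map is the argmax membership. A warning is raised when the
#' spectral gap does not support \code{m} states.
#'
#' @param model a [MarkovModel-class] with a symmetrized TPM.
#' @param m number of macrostates (default 9).
#' @return a [MacrostateModel-class]
#' @export
pccaMacrostates <- function(model, m = 9L) {
  T <- model@tpm
  piv <- model@pi
  m <- as.integer(m)
  if (m > nrow(T)) stop("more macrostates than microstates")
  db <- max(abs(piv * T - t(piv * T)))
  if (db > 1e-8)
    stop("TPM is not reversible with respect to pi (symmetrize counts first)")
  e <- .tpmEigen(T, piv)
  if (m < nrow(T) && e$values[m + 1] > 0 &&
      e$values[m] / e$values[m + 1] < 1.05)
    warning("weak spectral gap after ", m,
            " states; macrostate count may not be supported")
  X <- e$vectors[, seq_len(m), drop = FALSE]
  X[, 1] <- 1
  chi <- .pccaISA(X)
  chi[chi < 0] <- 0
  chi <- chi / rowSums(chi)
  crisp <- max.col(chi, ties.method = "first")
  if (!all(seq_len(m) %in% crisp))
    warning("empty macrostate under the crisp map")
  pops <- as.numeric(tapply(piv, factor(crisp, levels = seq_len(m)), sum))
  pops[is.na(pops)] <- 0
  # pi-weighted coarse-grained TPM on the crisp partition
  macroT <- matrix(0, m, m)
  for (a in seq_len(m)) {
    ia <- which(crisp == a)
    if (!length(ia)) next
    wa <- piv[ia] / sum(piv[ia])
    for (b in seq_len(m)) {
      ib <- which(crisp == b)
      if (length(ib))
        macroT[a, b] <- sum(wa * rowSums(T[ia, ib, drop = FALSE]))
    }
  }
  new("MacrostateModel", memberships = chi, crisp = crisp,
      populations = pops / sum(pops), macroTPM = macroT)
}

#' Stationary macrostate populations
#'
#' @param piv microstate stationary distribution.
#' @param crisp integer microstate -> macrostate map.
#' @return numeric vector of macrostate populations (sums to 1)
#' @export
macrostatePopulations <- function(piv, crisp) {
  m <- max(crisp)
  pops <- as.numeric(tapply(piv, factor(crisp, levels = seq_len(m)), sum))
  pops[is.na(pops)] <- 0
  pops / sum(pops)
}
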