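# The RED (rare event detection) protocol: non-negative matrix
# factorization of the smoothed contact time series into c spatial
# components (contact patterns) and temporal weights (when each pattern
# dominates), normalization by the constitutive pairs, and extraction of
# structure-differentiating contact pairs (SDCPs).

# NNDSVD initialization (average-variant: zeros replaced by the data
# mean so no update rule stalls on exact zeros).
.nndsvda <- function(A, k) {
  s <- svd(A, nu = k, nv = k)
  t <- nrow(A); p <- ncol(A)
  W <- matrix(0, t, k); H <- matrix(0, k, p)
  W[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  H[1, ] <- sqrt(s$d[1]) * abs(s$v[, 1])
  if (k >= 2L) for (j in 2:k) {
    u <- s$u[, j]; v <- s$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
    nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
    if (nup * nvp >= nun * nvn && nup * nvp > 0) {
      sc <- sqrt(s$d[j] * nup * nvp)
      W[, j] <- sc * up / nup; H[j, ] <- sc * vp / nvp
    } else if (nun * nvn > 0) {
      sc <- sqrt(s$d[j] * nun * nvn)
      W[, j] <- sc * un / nun; H[j, ] <- sc * vn / nvn
    }
  }
  m <- mean(A)
  W[W == 0] <- m; H[H == 0] <- m
  list(W = W, H = H)
}

# Exact construction for (numerically) rank-2 non-negative data: the
# columns live in a 2-dimensional cone whose extreme rays are data
# columns, so W = [extreme rays] and H = the non-negative coordinates
# give an exact factorization (a rank-2 non-negative matrix always has
# non-negative rank 2).
.rank2ConeInit <- function(A) {
  s <- svd(A, nu = 2, nv = 2)
  B <- diag(s$d[1:2]) %*% t(s$v[, 1:2])  # 2-D coordinates of columns
  if (sum(B[1, ]) < 0) B <- -B           # Perron direction positive
  ang <- atan2(B[2, ], B[1, ])
  R <- cbind(B[, which.min(ang)], B[, which.max(ang)])
  if (abs(det(R)) < 1e-12 * max(abs(B))^2) return(NULL)
  H <- pmax(solve(R, B), 0)
  HHt <- tcrossprod(H)
  if (rcond(HHt) < 1e-12) return(NULL)
  W <- pmax(A %*% t(H) %*% solve(HHt), 0)
  list(W = W, H = H)
}

# HALS (hierarchical alternating least squares) minimization of
# ||A - W H||_F with W, H >= 0 elementwise. Each outer iteration runs
# a few inner column/row sweeps on the cached Gram matrices
# (accelerated-HALS scheme), which speeds up the tail of the
# convergence considerably.
.nmfHALS <- function(A, W, H, maxIter, tol, nInner = 4L) {
  normA <- frobenius(A)
  errPrev <- Inf
  iter <- 0L
  converged <- FALSE
  tiny <- 1e-16
  for (iter in seq_len(maxIter)) {
    AHt <- A %*% t(H); HHt <- H %*% t(H)
    for (rep in seq_len(nInner)) {
      for (j in seq_len(nrow(H))) {
        denom <- max(HHt[j, j], tiny)
        W[, j] <- pmax(W[, j] + (AHt[, j] - W %*% HHt[, j]) / denom, 0)
      }
    }
    WtA <- crossprod(W, A); WtW <- crossprod(W)
    for (rep in seq_len(nInner)) {
      for (j in seq_len(nrow(H))) {
        denom <- max(WtW[j, j], tiny)
        H[j, ] <- pmax(H[j, ] +
                         (WtA[j, ] - WtW[j, , drop = FALSE] %*% H) / denom,
                       0)
      }
    }
    err <- frobenius(A - W %*% H)
    if (is.finite(errPrev) && abs(errPrev - err) <= tol * max(normA, tiny)) {
      converged <- TRUE
      errPrev <- err
      break
    }
    errPrev <- err
  }
  # projected-ALS polish: when the optimum is interior (strictly
  # positive factors), exact alternating least squares with clipping
  # collapses the slow HALS tail; the best iterate is kept, so the
  # polish can only improve the fit
  best <- list(W = W, H = H, error = errPrev)
  for (p in seq_len(40L)) {
    HHt <- tcrossprod(H)
    if (rcond(HHt) < 1e-12) break
    W <- pmax(A %*% t(H) %*% solve(HHt), 0)
    WtW <- crossprod(W)
    if (rcond(WtW) < 1e-12) break
    H <- pmax(solve(WtW, crossprod(W, A)), 0)
    err <- frobenius(A - W %*% H)
    if (err < best$error) {
      best <- list(W = W, H = H, error = err)
    } else break
  }
  list(W = best$W, H = best$H, error = best$error, iterations = iter,
       converged = converged)
}

#' Fit the RED non-negative factorization
#'
#' Decomposes a trimmed, smoothed contact series (frames x pairs) into
#' \code{c} components: a non-negative spatial matrix (c x pairs, one
#' contact pattern per row) and a non-negative temporal matrix
#' (frames x c, the weight of each pattern over time), minimizing the
#' Frobenius reconstruction error by hierarchical alternating least
#' squares from a deterministic non-negative double-SVD start (or a
#' seeded random start). After fitting, each component is rescaled so
#' its temporal weights peak at 1; the product is unchanged.
#'
#' @param cts a [ContactSeries-class] (smoothed input recommended) or a
#'   non-negative frames x features matrix.
#' @param c number of components (>= 2, default 5).
#' @param seed integer seed; only used when \code{init = "random"}.
#' @param maxIter maximum update sweeps (default 500).
#' @param tol relative change in reconstruction error that stops the
#'   iteration (default 1e-8).
#' @param init "nndsvd" (deterministic, default) or "random".
#' @return a [REDModel-class]
#' @export
fitRED <- function(cts, c = 5L, seed = NULL, maxIter = 500L, tol = 1e-8,
                   init = c("nndsvd", "random")) {
  init <- match.arg(init)
  if (is.matrix(cts)) {
    A <- cts
    pidx <- data.frame(resI = rep(1L, ncol(A)),
                       resJ = seq_len(ncol(A)) + 1L)
    segs <- 1L
  } else {
    A <- cts@values
    pidx <- cts@pairIndex
    segs <- cts@segmentStarts
  }
  if (min(A) < 0) stop("negative values in contact series")
  c <- as.integer(c)
  if (c < 2L) stop("c must be >= 2")
  if (nrow(A) <= c) stop("need more frames than components")
  st <- if (init == "nndsvd") {
    st0 <- NULL
    if (c == 2L) {
      # exactly rank-2 input admits a closed-form factorization; use
      # it as the start whenever the third singular value vanishes
      dd <- svd(A, nu = 0, nv = 0)$d
      if (length(dd) >= 3 && dd[3] < 1e-10 * dd[1])
        st0 <- .rank2ConeInit(A)
    }
    if (is.null(st0)) .nndsvda(A, c) else st0
  } else {
    withSeed(seed, list(W = matrix(stats::runif(nrow(A) * c, 0, mean(A) * 2),
                                   ncol = c),
                        H = matrix(stats::runif(c * ncol(A), 0, 1), nrow = c)))
  }
  fit <- .nmfHALS(A, st$W, st$H, as.integer(maxIter), tol)
  if (!fit$converged)
    warning(sprintf(
      "NMF did not converge in %d iterations (final error %.4g)",
      fit$iterations, fit$error))
  W <- fit$W; H <- fit$H
  # scale convention: dominant temporal weight of each component is 1,
  # so spatial values are comparable to contact occupancies
  for (j in seq_len(c)) {
    f <- max(W[, j])
    if (f > 0) { W[, j] <- W[, j] / f; H[j, ] <- H[j, ] * f }
  }
  new("REDModel", spatial = H, temporal = W,
      normFactors = rep(NA_real_, c), constitutivePairs = integer(),
      reconError = fit$error, pairIndex = pidx,
      segmentStarts = segs,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      iterations = fit$iterations, converged = fit$converged)
}

#' Identify constitutive contact pairs
#'
#' Constitutive pairs contribute a similar, high weight to every spatial
#' component (they appear as a horizontal line when components are
#' plotted against each other) and are used to put the components on a
#' common scale. A pair is selected when the coefficient of variation of
#' its spatial values across components is below \code{cvMax} and its
#' mean is above \code{meanMin}.
#'
#' @param model a fitted [REDModel-class].
#' @param cvMax coefficient-of-variation threshold (default 0.15).
#' @param meanMin mean spatial weight threshold (default 0.5).
#' @return integer vector of pair column indices
#' @export
identifyConstitutivePairs <- function(model, cvMax = 0.15, meanMin = 0.5) {
  H <- model@spatial
  m <- colMeans(H)
  s <- apply(H, 2, stats::sd)
  cv <- ifelse(m > 0, s / m, Inf)
  idx <- which(cv < cvMax & m > meanMin)
  if (!length(idx))
    stop("no constitutive pairs found; relax cvMax/meanMin thresholds")
  idx
}

#' Normalize RED components by their constitutive pairs
#'
#' Each spatial component is divided by the mean spatial value of the
#' constitutive pairs in that component, and the corresponding temporal
#' weights are multiplied by the same factor, so the reconstruction
#' (temporal x spatial) is unchanged while constitutive pairs sit at 1
#' in every component and components become directly comparable.
#'
#' @param model a fitted [REDModel-class].
#' @param constitutive integer pair columns from
#'   [identifyConstitutivePairs()].
#' @return normalized [REDModel-class] (normFactors filled in)
#' @export
normalizeComponents <- function(model, constitutive) {
  constitutive <- as.integer(constitutive)
  if (!length(constitutive)) stop("constitutive pair set is empty")
  H <- model@spatial; W <- model@temporal
  f <- rowMeans(H[, constitutive, drop = FALSE])
  if (any(f <= 0))
    stop("non-positive normalization factor in component(s) ",
         paste(which(f <= 0), collapse = ", "))
  res <- model
  res@spatial <- H / f
  res@temporal <- sweep(W, 2, f, `*`)
  res@normFactors <- f
  res@constitutivePairs <- constitutive
  res
}

#' Extract structure-differentiating contact pairs (SDCPs)
#'
#' Subtracts the spatial array of one normalized component from another;
#' constitutive contributions cancel, leaving the pairs that change
#' between the two conformational states. Pairs whose difference exceeds
#' \code{kSigma} times the (plain) standard deviation of the difference
#' array are reported: positive differences are contacts formed in the
#' from -> to transition, negative ones are broken.
#'
#' @param model a normalized [REDModel-class].
#' @param compFrom,compTo component indices.
#' @param kSigma saliency threshold in standard deviations (default 4).
#' @return data.frame with columns resI, resJ, pair (column index),
#'   compFrom, compTo, delta, direction ("formed"/"broken"), group
#'   (user-fillable annotation, NA)
#' @export
extractSDCPs <- function(model, compFrom, compTo, kSigma = 4) {
  if (!all(is.finite(model@normFactors)))
    warning("model is not normalized; SDCP deltas mix component scales")
  H <- model@spatial
  stopifnot(compFrom >= 1, compTo >= 1,
            compFrom <= nrow(H), compTo <= nrow(H))
  delta <- H[compTo, ] - H[compFrom, ]
  thr <- kSigma * stats::sd(delta)
  sel <- which(abs(delta) > thr)
  sel <- sel[order(-abs(delta[sel]))]
  data.frame(
    resI = model@pairIndex$resI[sel],
    resJ = model@pairIndex$resJ[sel],
    pair = sel,
    compFrom = rep(as.integer(compFrom), length(sel)),
    compTo = rep(as.integer(compTo), length(sel)),
    delta = delta[sel],
    direction = if (length(sel)) ifelse(delta[sel] > 0, "formed", "broken")
                else character(),
    group = rep(NA_character_, length(sel)),
    row.names = NULL
  )
}

#' Component dominance timeline
#'
#' Per-frame temporal weights (for stacked-area plots) together with the
#' dominant component label and the transition events, i.e. the frames
#' at which the dominant component changes.
#'
#' @param model a [REDModel-class] (normalized recommended).
#' @return list with elements \code{weights} (frames x c matrix),
#'   \code{dominant} (integer per frame), \code{events} (data.frame
#'   frame, from, to; the frame is the first frame of the new regime)
#' @export
dominanceTimeline <- function(model) {
  W <- model@temporal
  dom <- max.col(W, ties.method = "first")
  ch <- which(diff(dom) != 0) + 1L
  # a change at a segment boundary is replica bookkeeping, not an event
  ch <- setdiff(ch, model@segmentStarts)
  events <- data.frame(frame = ch, from = dom[pmax(ch - 1L, 1L)],
                       to = dom[ch])
  list(weights = W, dominant = dom, events = events)
}
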