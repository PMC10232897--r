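# Transition path theory on a reversible Markov state model: forward
# committor by direct linear solve, reactive flux matrix
# J_ij = pi_i (1 - q_i) T_ij q_j, net flux, and iterative decomposition
# of the net flux into pathways by repeated widest-path (maximum
# bottleneck) extraction.

#' Forward committor
#'
#' Probability of reaching the target set before the source set from
#' each state: q = 0 on the source, 1 on the target, and
#' q_i = sum_j T_ij q_j on intermediates, solved directly.
#'
#' @param T row-stochastic transition matrix.
#' @param source,target disjoint, non-empty integer state sets.
#' @return numeric committor vector
#' @export
committor <- function(T, source, target) {
  n <- nrow(T)
  source <- as.integer(source); target <- as.integer(target)
  if (!length(source) || !length(target)) stop("empty source or target set")
  if (length(intersect(source, target)))
    stop("source and target sets must be disjoint")
  q <- numeric(n)
  q[target] <- 1
  inter <- setdiff(seq_len(n), c(source, target))
  if (length(inter)) {
    A <- diag(length(inter)) - T[inter, inter, drop = FALSE]
    b <- rowSums(T[inter, target, drop = FALSE])
    if (rcond(A) < 1e-14)
      stop("singular committor system; intermediate state(s) ",
           paste(inter, collapse = ", "), " may be disconnected")
    q[inter] <- solve(A, b)
  }
  q
}

#' Reactive flux matrices
#'
#' Gross flux J_ij = pi_i (1 - q_i) T_ij q_j with q the forward
#' committor; net flux J+ = max(0, J - t(J)) elementwise; total
#' source-to-target flux F = sum of net flux out of the source set.
#'
#' @param T row-stochastic transition matrix (reversible).
#' @param piv stationary distribution.
#' @param q forward committor from [committor()].
#' @param source,target state sets (used for the total flux and carried
#'   into the result).
#' @return a [FluxResult-class] without pathways (see
#'   [decomposePathways()])
#' @export
fluxMatrix <- function(T, piv, q, source, target) {
  n <- nrow(T)
  J <- (piv * (1 - q)) * T * rep(q, each = n)
  diag(J) <- 0
  Jnet <- pmax(J - t(J), 0)
  F <- sum(Jnet[source, , drop = FALSE])
  new("FluxResult", committor = q, grossFlux = J, netFlux = Jnet,
      totalFlux = F,
      pathways = data.frame(path = character(), flux = numeric(),
                            normFlux = numeric(), cumFlux = numeric()),
      source = as.integer(source), target = as.integer(target))
}

# widest (maximum-bottleneck) path from any source to any target on a
# non-negative weight matrix; Dijkstra variant maximizing the minimum
# edge weight. Ties broken towards the lowest state index.
.widestPath <- function(W, source, target) {
  n <- nrow(W)
  width <- rep(-Inf, n)
  prev <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  width[source] <- Inf
  repeat {
    cand <- which(!visited & width > -Inf)
    if (!length(cand)) break
    u <- cand[which.max(width[cand])]
    visited[u] <- TRUE
    if (u %in% target) break
    nb <- which(W[u, ] > 0 & !visited)
    for (v in nb) {
      w2 <- min(width[u], W[u, v])
      if (w2 > width[v]) { width[v] <- w2; prev[v] <- u }
    }
  }
  hit <- target[visited[target]]
  if (!length(hit)) return(NULL)
  dst <- hit[which.max(width[hit])]
  path <- dst
  while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
  list(path = path, width = width[dst])
}

#' Decompose the net flux into pathways
#'
#' Iteratively extracts the highest-flux pathway from source to target:
#' the widest (maximum-bottleneck) path is found with a Dijkstra-type
#' search, assigned its bottleneck flux, and that flux is subtracted
#' along the path; the loop stops at the requested cumulative coverage
#' of the total flux, at \code{nPaths} pathways, or when the network is
#' exhausted.
#'
#' @param flux a [FluxResult-class] from [fluxMatrix()].
#' @param coverage stop once this fraction of the total flux is
#'   decomposed (default 0.95).
#' @param nPaths optional hard cap on the number of pathways.
#' @param gross use the gross instead of the net flux matrix (default
#'   FALSE).
#' @return the [FluxResult-class] with the pathway table filled:
#'   columns path ("a -> b -> c"), flux, normFlux (flux / total) and
#'   cumFlux (cumulative normalized flux)
#' @export
decomposePathways <- function(flux, coverage = 0.95, nPaths = Inf,
                              gross = FALSE) {
  W <- if (gross) flux@grossFlux else flux@netFlux
  F <- flux@totalFlux
  src <- flux@source; dst <- flux@target
  paths <- list()
  carried <- 0
  tol <- max(F, .Machine$double.eps) * 1e-12
  while (carried < coverage * F - tol && length(paths) < nPaths) {
    wp <- .widestPath(W, src, dst)
    if (is.null(wp) || wp$width <= tol) {
      if (carried < F - max(F, 1) * 1e-9 && coverage >= 1)
        warning("target unreachable before full coverage")
      break
    }
    f <- wp$width
    p <- wp$path
    for (i in seq_len(length(p) - 1L))
      W[p[i], p[i + 1L]] <- max(W[p[i], p[i + 1L]] - f, 0)
    carried <- carried + f
    paths[[length(paths) + 1L]] <-
      data.frame(path = paste(p, collapse = " -> "), flux = f)
  }
  if (!length(paths)) {
    warning("no source-to-target pathway in the flux network")
    return(flux)
  }
  tab <- do.call(rbind, paths)
  tab$normFlux <- tab$flux / F
  tab$cumFlux <- cumsum(tab$normFlux)
  out <- flux
  out@pathways <- tab
  out
}

#' One-call transition path analysis
#'
#' Committor, flux matrices and pathway decomposition for a reversible
#' Markov model.
#'
#' @param model a [MarkovModel-class] (symmetrized).
#' @param source,target disjoint microstate sets (indices into the
#'   active states of the model).
#' @param coverage,nPaths passed to [decomposePathways()].
#' @return a [FluxResult-class]
#' @export
transitionPaths <- function(model, source, target, coverage = 0.95,
                            nPaths = Inf) {
  q <- committor(model@tpm, source, target)
  fx <- fluxMatrix(model@tpm, model@pi, q, source, target)
  decomposePathways(fx, coverage = coverage, nPaths = nPaths)
}
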