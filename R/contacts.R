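# Residue-residue contact time series: the input matrix of the RED
# protocol. A pair is in contact in a frame when the minimum distance
# between any atom of one residue and any atom of the other is below the
# cutoff (3.5 Angstrom by default, heavy atoms only by default).

# residue table: unique (chainId, resId) in atom order, with atom index list
.residueGroups <- function(top, heavyOnly = TRUE) {
  keep <- if (heavyOnly) !isHydrogen(top) else rep(TRUE, nrow(top))
  key <- paste(top$chainId, top$resId, sep = "\r")
  ukey <- unique(key)
  groups <- lapply(ukey, function(k) which(key == k & keep))
  resId <- top$resId[match(ukey, key)]
  keepRes <- lengths(groups) > 0L
  list(resId = resId[keepRes], atoms = groups[keepRes])
}

# minimum inter-residue distance per frame between two atom groups
.minPairDistance <- function(co, atomsA, atomsB) {
  nf <- dim(co)[1]
  best <- rep(Inf, nf)
  for (a in atomsA) {
    da <- co[, a, , drop = FALSE]
    for (b in atomsB) {
      d2 <- (co[, a, 1] - co[, b, 1])^2 + (co[, a, 2] - co[, b, 2])^2 +
            (co[, a, 3] - co[, b, 3])^2
      best <- pmin(best, d2)
    }
  }
  sqrt(best)
}

#' Compute the binary residue-contact time series
#'
#' One column per unordered residue pair; an entry is 1 iff the minimum
#' interatomic distance between the two residues is below \code{cutoff}
#' in that frame.
#'
#' @param traj a [Trajectory-class] with at least one frame and two
#'   residues.
#' @param cutoff contact cutoff in Angstrom (default 3.5).
#' @param heavyOnly logical; exclude hydrogens from the distance test
#'   (default TRUE).
#' @return a raw (binary) [ContactSeries-class]
#' @export
computeContactSeries <- function(traj, cutoff = 3.5, heavyOnly = TRUE) {
  if (nFrames(traj) < 1L) stop("empty trajectory")
  rg <- .residueGroups(traj@topology, heavyOnly)
  nres <- length(rg$resId)
  if (nres < 2L) stop("need at least 2 residues")
  co <- traj@coords
  nf <- dim(co)[1]
  npair <- (nres * (nres - 1L)) %/% 2L
  vals <- matrix(0, nf, npair)
  resI <- integer(npair); resJ <- integer(npair)
  k <- 0L
  for (i in seq_len(nres - 1L)) {
    for (j in seq((i + 1L), nres)) {
      k <- k + 1L
      d <- .minPairDistance(co, rg$atoms[[i]], rg$atoms[[j]])
      vals[, k] <- as.numeric(d < cutoff)
      ri <- rg$resId[i]; rj <- rg$resId[j]
      resI[k] <- min(ri, rj); resJ[k] <- max(ri, rj)
    }
  }
  new("ContactSeries", values = vals,
      pairIndex = data.frame(resI = resI, resJ = resJ),
      smoothed = FALSE, window = NA_integer_,
      segmentStarts = traj@segmentStarts, cutoff = cutoff)
}

#' Remove contact pairs that never change
#'
#' Drops columns that are constant across all frames (pairs always in or
#' never in contact over the whole series); the remaining columns each
#' change state at least once and carry the dynamic information.
#'
#' @param cts a raw (binary) [ContactSeries-class].
#' @param verbose logical, report how many pairs were removed.
#' @return trimmed [ContactSeries-class]
#' @export
trimInvariantPairs <- function(cts, verbose = TRUE) {
  if (cts@smoothed) stop("trimming operates on the raw binary series")
  v <- cts@values
  dynamic <- matrixStats_colAnyChange(v)
  if (!any(dynamic))
    stop("no dynamic contacts: every pair is invariant across the series")
  if (verbose)
    message(sum(!dynamic), " invariant pair(s) removed, ",
            sum(dynamic), " retained")
  res <- cts
  res@values <- v[, dynamic, drop = FALSE]
  res@pairIndex <- cts@pairIndex[dynamic, , drop = FALSE]
  rownames(res@pairIndex) <- NULL
  res
}

matrixStats_colAnyChange <- function(v) {
  if (nrow(v) == 1L) return(rep(FALSE, ncol(v)))
  colSums(abs(v - rep(v[1, ], each = nrow(v)))) > 0
}

#' Smooth a contact series with a sliding mean
#'
#' Centered per-column sliding mean of length \code{window} frames. The
#' window is truncated at series edges and at segment boundaries, so
#' replicas are never averaged together.
#'
#' @param cts a [ContactSeries-class].
#' @param window window length in frames (default 25).
#' @return smoothed [ContactSeries-class]
#' @export
smoothContacts <- function(cts, window = 25L) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (window == 1L) return(cts)
  segLen <- segmentLengths(cts@segmentStarts, nrow(cts@values))
  if (window > min(segLen))
    stop("window (", window, ") exceeds the shortest segment (",
         min(segLen), " frames)")
  v <- cts@values
  out <- v
  left <- (window - 1L) %/% 2L
  right <- window - 1L - left
  ends <- c(cts@segmentStarts[-1] - 1L, nrow(v))
  for (s in seq_along(cts@segmentStarts)) {
    rows <- cts@segmentStarts[s]:ends[s]
    n <- length(rows)
    cs <- rbind(0, apply(v[rows, , drop = FALSE], 2, cumsum))
    lo <- pmax(seq_len(n) - left, 1L)
    hi <- pmin(seq_len(n) + right, n)
    out[rows, ] <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
      (hi - lo + 1L)
  }
  res <- cts
  res@values <- pmin(pmax(out, 0), 1)
  res@smoothed <- TRUE
  res@window <- window
  res
}

#' Concatenate contact series along the time axis
#'
#' @param ctsList list of [ContactSeries-class] objects with identical
#'   pair indices (strict mode) or overlapping ones (intersect mode).
#' @param mode "strict" (error on any mismatch) or "intersect" (keep the
#'   common pairs with a warning).
#' @return concatenated [ContactSeries-class] with segment boundaries at
#'   the joins
#' @export
concatenateContacts <- function(ctsList, mode = c("strict", "intersect")) {
  mode <- match.arg(mode)
  stopifnot(length(ctsList) >= 1L)
  if (length(ctsList) == 1L) return(ctsList[[1]])
  keys <- lapply(ctsList, function(x)
    paste(x@pairIndex$resI, x@pairIndex$resJ, sep = "-"))
  common <- Reduce(intersect, keys)
  if (mode == "strict") {
    same <- all(vapply(keys, function(k) identical(k, keys[[1]]), logical(1)))
    if (!same)
      stop("pair indices differ between inputs (use mode = 'intersect')")
    cols <- lapply(keys, function(k) seq_along(k))
  } else {
    if (!length(common)) stop("no residue pairs common to all inputs")
    if (any(vapply(keys, length, integer(1)) != length(common)))
      warning("pair sets differ; keeping the ", length(common),
              " common pair(s)")
    cols <- lapply(keys, function(k) match(common, k))
  }
  vals <- do.call(rbind, Map(function(x, cc) x@values[, cc, drop = FALSE],
                             ctsList, cols))
  nf <- vapply(ctsList, function(x) nrow(x@values), integer(1))
  offs <- cumsum(c(0L, nf[-length(nf)]))
  starts <- unlist(Map(function(x, o) x@segmentStarts + o, ctsList, offs))
  pidx <- ctsList[[1]]@pairIndex[cols[[1]], , drop = FALSE]
  rownames(pidx) <- NULL
  smoothed <- vapply(ctsList, function(x) x@smoothed, logical(1))
  new("ContactSeries", values = vals, pairIndex = pidx,
      smoothed = any(smoothed),
      window = ctsList[[1]]@window,
      segmentStarts = as.integer(starts), cutoff = ctsList[[1]]@cutoff)
}
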