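# Synthetic fixtures with exact ground truth: (a) bead-model
# trajectories with planted, time-localized contact-pattern changes and
# a ligand bead that switches binding site at the event; (b) Gaussian
# displacement networks with a closed-form covariance for the entropy
# measures; (c) collective-variable time series emitted from a known
# Markov chain.
#
# Bead geometry: residue cores sit on well-separated random base
# positions (>= 16 A apart). Every designated contact pair owns two
# satellite atoms, one on each residue; when the contact is active both
# satellites move to the pair midpoint, 3.0 A apart (cutoff - 0.5), and
# when inactive they park 0.5 A from their own core. A static safety
# check guarantees that no other atom-pair combination can come within
# cutoff + 1.0 A, so positional noise up to ~0.3 A cannot flip
# unintended pairs.

.canonPairs <- function(p) {
  if (is.null(p) || !length(p)) return(matrix(integer(), 0, 2))
  if (is.list(p)) p <- do.call(rbind, p)
  p <- matrix(as.integer(p), ncol = 2)
  p <- cbind(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2]))
  if (any(p[, 1] == p[, 2])) stop("self-pair in contact specification")
  unique(p)
}

.pairKey <- function(p) paste(p[, 1], p[, 2], sep = "-")

# sequential placement with minimum separation; the box grows with the
# number of designated pairs so that pair midpoints (where contact
# satellites meet) stay well separated too
.placeBases <- function(n, minSep, nPairs = 0L) {
  L <- max(2.5 * minSep, (n^(1 / 3) + 1) * minSep,
           2.6 * (max(nPairs, 1)^(1 / 3)) * 10)
  pts <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    for (try in 1:2000) {
      p <- stats::runif(3, 0, L)
      if (i == 1L ||
          min(sqrt(rowSums(sweep(pts[seq_len(i - 1L), , drop = FALSE],
                                 2, p)^2))) >= minSep) {
        pts[i, ] <- p
        break
      }
    }
    if (anyNA(pts[i, ])) stop("could not place residue bases; spec too dense")
  }
  pts
}

# Geometric realization of the designated contacts. Each pair owns a
# private "meeting point" near its inter-base segment: when the contact
# is active, the two satellites sit contactDist apart straddling that
# point along the base-base axis; parked satellites rest 0.5 A from
# their own core. Meeting points (and ligand offsets) that bring any
# foreign atom pair closer than `safety` are re-drawn locally until the
# static check passes, so unintended contacts are geometrically
# impossible at moderate noise.
.buildBeadGeometry <- function(bases, designated, ligSites, contactDist,
                               safety) {
  nres <- nrow(bases)
  ndp <- nrow(designated)
  axisOf <- function(p) {
    a <- bases[designated[p, 2], ] - bases[designated[p, 1], ]
    a / sqrt(sum(a^2))
  }
  drawMeet <- function(p) {
    bi <- bases[designated[p, 1], ]; bj <- bases[designated[p, 2], ]
    axis <- bj - bi
    len <- sqrt(sum(axis^2)); axis <- axis / len
    tt <- stats::runif(1, 0.30, 0.70)
    r <- stats::rnorm(3); r <- r - sum(r * axis) * axis
    nr <- sqrt(sum(r^2))
    if (nr < 1e-12) { r <- c(axis[2], -axis[1], 0); nr <- sqrt(sum(r^2)) }
    off <- stats::runif(1, 0, min(9, len / 3))
    bi + tt * len * axis + off * r / nr
  }
  meets <- if (ndp) t(vapply(seq_len(ndp), drawMeet, numeric(3)))
           else matrix(numeric(), 0, 3)
  nlig <- length(ligSites)
  ligDir <- if (nlig) matrix(stats::rnorm(3 * nlig), nlig, 3)
            else matrix(numeric(), 0, 3)
  for (iter in 1:400) {
    actI <- actJ <- prkI <- prkJ <- matrix(numeric(), 0, 3)
    if (ndp) {
      V <- t(vapply(seq_len(ndp), axisOf, numeric(3)))
      actI <- meets - V * contactDist / 2
      actJ <- meets + V * contactDist / 2
      ui <- meets - bases[designated[, 1], , drop = FALSE]
      ui <- ui / sqrt(rowSums(ui^2))
      uj <- meets - bases[designated[, 2], , drop = FALSE]
      uj <- uj / sqrt(rowSums(uj^2))
      prkI <- bases[designated[, 1], , drop = FALSE] + 0.5 * ui
      prkJ <- bases[designated[, 2], , drop = FALSE] + 0.5 * uj
    }
    ligPos <- if (nlig) {
      d <- ligDir / sqrt(rowSums(ligDir^2))
      lp <- bases[ligSites, , drop = FALSE] + contactDist * d
      rownames(lp) <- as.character(ligSites)
      lp
    } else matrix(numeric(), 0, 3)
    pos <- rbind(bases, actI, actJ, prkI, prkJ, ligPos)
    owner <- c(seq_len(nres), designated[, 1], designated[, 2],
               designated[, 1], designated[, 2], rep(nres + 1L, nlig))
    # entity to redraw when a position conflicts: pair id, -site index
    # for the ligand, 0 for fixed cores
    entity <- c(rep(0L, nres), rep(seq_len(ndp), 4L), -seq_len(max(nlig, 0L)))
    D <- as.matrix(stats::dist(pos))
    diag(D) <- Inf
    bad <- D < safety & outer(owner, owner, `!=`)
    if (ndp) {
      ai <- nres + seq_len(ndp); aj <- nres + ndp + seq_len(ndp)
      bad[cbind(ai, aj)] <- FALSE
      bad[cbind(aj, ai)] <- FALSE
    }
    if (nlig) {
      li <- nres + 4L * ndp + seq_len(nlig)
      for (k in seq_len(nlig)) {
        own <- which(owner == ligSites[k])
        bad[li[k], own] <- FALSE
        bad[own, li[k]] <- FALSE
      }
    }
    if (!any(bad)) {
      return(list(actI = actI, actJ = actJ, prkI = prkI, prkJ = prkJ,
                  ligPos = ligPos))
    }
    hit <- unique(entity[unique(as.vector(which(bad, arr.ind = TRUE)))])
    hit <- hit[hit != 0L]
    if (!length(hit))
      stop("residue cores conflict; base placement too dense")
    for (e in hit) {
      if (e > 0L) meets[e, ] <- drawMeet(e)
      else ligDir[-e, ] <- stats::rnorm(3)
    }
  }
  stop("could not construct a conflict-free bead geometry for this spec")
}

#' Generate a bead-model trajectory with planted contact events
#'
#' @param spec list with fields:
#'   \describe{
#'     \item{nResidues}{number of bead residues.}
#'     \item{states}{list of conformational states; each a list with
#'       \code{contacts} (2-column matrix of residue pairs in contact),
#'       optional \code{noncontacts} (pairs that must not touch; error
#'       if a pair appears in both) and optional \code{ligandSite}
#'       (residue id the ligand bead binds).}
#'     \item{nFrames}{total frames.}
#'     \item{eventFrames}{strictly increasing frame indices at which the
#'       next state begins (length = number of states - 1).}
#'     \item{sigma}{isotropic positional noise sd in Angstrom
#'       (default 0.2).}
#'     \item{flickerPairs, flickerRate}{pairs toggling independently per
#'       frame with the given contact probability (default none, 0.1).}
#'     \item{constitutivePairs, dropRate}{pairs in contact in every
#'       state except for rare random dropouts (default none, 0.02).}
#'     \item{frameInterval}{ns per frame (default 0.8).}
#'     \item{cutoff}{contact cutoff the geometry is designed for
#'       (default 3.5).}
#'     \item{seed}{RNG seed (required for reproducibility).}
#'   }
#' @param writeDir optional directory; when given, topology
#'   (\code{topology.pdb}) and coordinates (\code{trajectory.pdb},
#'   multi-model) are written there.
#' @return list with \code{trajectory} (a [Trajectory-class]),
#'   \code{truth} (stateByFrame, eventFrames, switchingPairs,
#'   patternByState, designated pair sets, ligandSiteByFrame) and the
#'   filled \code{spec}
#' @export
genPlantedTrajectory <- function(spec, writeDir = NULL) {
  nres <- spec$nResidues
  states <- spec$states
  nFrames <- spec$nFrames
  eventFrames <- as.integer(spec$eventFrames %||% integer())
  sigma <- spec$sigma %||% 0.2
  cutoff <- spec$cutoff %||% 3.5
  frameInterval <- spec$frameInterval %||% 0.8
  flicker <- .canonPairs(spec$flickerPairs)
  flickerRate <- spec$flickerRate %||% 0.1
  consti <- .canonPairs(spec$constitutivePairs)
  dropRate <- spec$dropRate %||% 0.02
  if (length(states) != length(eventFrames) + 1L)
    stop("need one more state than event frames")
  if (length(eventFrames) &&
      (is.unsorted(eventFrames, strictly = TRUE) ||
       min(eventFrames) <= 1L || max(eventFrames) > nFrames))
    stop("eventFrames must be strictly increasing and inside (1, nFrames]")
  stContacts <- lapply(states, function(s) .canonPairs(s$contacts))
  for (s in seq_along(states)) {
    non <- .canonPairs(states[[s]]$noncontacts)
    if (nrow(non) &&
        length(intersect(.pairKey(stContacts[[s]]), .pairKey(non))))
      stop("state ", s, ": pair designated both in and out of contact")
  }
  if (length(states) >= 2L)
    for (s in seq_len(length(states) - 1L))
      if (identical(sort(.pairKey(stContacts[[s]])),
                    sort(.pairKey(stContacts[[s + 1L]]))))
        stop("consecutive states ", s, " and ", s + 1L,
             " have identical contact targets")
  designated <- .canonPairs(rbind(do.call(rbind, stContacts),
                                  flicker, consti))
  if (any(designated > nres)) stop("pair references residue beyond nResidues")
  hasLigand <- any(vapply(states, function(s) !is.null(s$ligandSite),
                          logical(1)))
  if (hasLigand &&
      !all(vapply(states, function(s) !is.null(s$ligandSite), logical(1))))
    stop("either every state or no state must define a ligandSite")
  contactDist <- cutoff - 0.5
  safety <- cutoff + 1.0

  withSeed(spec$seed %||% stop("spec$seed is required"), {
    ndp <- nrow(designated)
    bases <- .placeBases(nres, 16, ndp)
    ligSites <- if (hasLigand)
      unique(unlist(lapply(states, `[[`, "ligandSite"))) else integer()
    geom <- .buildBeadGeometry(bases, designated, ligSites, contactDist,
                               safety)
    actI <- geom$actI; actJ <- geom$actJ
    prkI <- geom$prkI; prkJ <- geom$prkJ
    ligPos <- geom$ligPos

    # topology: core atom per residue, two satellites per designated
    # pair, one ligand bead
    ndp <- nrow(designated)
    atomRes <- c(seq_len(nres), designated[, 1], designated[, 2],
                 if (hasLigand) nres + 1L)
    atomName <- c(rep("BB", nres),
                  sprintf("SI%d", seq_len(ndp)), sprintf("SJ%d", seq_len(ndp)),
                  if (hasLigand) "L1")
    natoms <- length(atomRes)
    top <- data.frame(atomId = seq_len(natoms), atomName = atomName,
                      element = "C", resId = atomRes,
                      resName = ifelse(atomRes > nres, "LIG", "BEA"),
                      chainId = "A", stringsAsFactors = FALSE)
    ord <- order(top$resId)
    top <- top[ord, , drop = FALSE]
    top$atomId <- seq_len(natoms)
    rownames(top) <- NULL
    atIdx <- order(ord)  # original slot -> row in ordered topology
    coreAt <- atIdx[seq_len(nres)]
    satIAt <- atIdx[nres + seq_len(ndp)]
    satJAt <- atIdx[nres + ndp + seq_len(ndp)]
    ligAt <- if (hasLigand) atIdx[natoms] else NA_integer_

    stateByFrame <- rep(seq_along(states),
                        diff(c(1L, eventFrames, nFrames + 1L)))
    designatedKey <- .pairKey(designated)
    inState <- vapply(stContacts, function(sc)
      designatedKey %in% .pairKey(sc), logical(ndp))
    inState <- matrix(inState, nrow = ndp)
    isFlicker <- designatedKey %in% .pairKey(flicker)
    isConsti <- designatedKey %in% .pairKey(consti)

    # active flags per frame x pair
    active <- inState[, stateByFrame, drop = FALSE]  # ndp x nFrames
    if (any(isFlicker))
      active[isFlicker, ] <- matrix(
        stats::runif(sum(isFlicker) * nFrames) < flickerRate,
        sum(isFlicker), nFrames)
    if (any(isConsti))
      active[isConsti, ] <- matrix(
        stats::runif(sum(isConsti) * nFrames) >= dropRate,
        sum(isConsti), nFrames)

    co <- array(NA_real_, c(nFrames, natoms, 3))
    for (d in 1:3) co[, coreAt, d] <- rep(bases[, d], each = nFrames)
    for (p in seq_len(ndp)) {
      act <- active[p, ]
      for (d in 1:3) {
        co[, satIAt[p], d] <- ifelse(act, actI[p, d], prkI[p, d])
        co[, satJAt[p], d] <- ifelse(act, actJ[p, d], prkJ[p, d])
      }
    }
    ligandSiteByFrame <- rep(NA_integer_, nFrames)
    if (hasLigand) {
      siteOfState <- vapply(states, function(s)
        as.integer(s$ligandSite %||% NA_integer_), integer(1))
      ligandSiteByFrame <- siteOfState[stateByFrame]
      for (d in 1:3)
        co[, ligAt, d] <- ligPos[as.character(ligandSiteByFrame), d]
    }
    if (sigma > 0)
      co <- co + array(stats::rnorm(length(co), sd = sigma), dim(co))

    # noiseless contact pattern per state (brute-force double loop over
    # the template geometry, independent of the contacts module)
    patternByState <- lapply(seq_along(states), function(s) {
      posS <- matrix(NA_real_, natoms, 3)
      posS[coreAt, ] <- bases
      for (p in seq_len(ndp)) {
        act <- inState[p, s] || isConsti[p]
        posS[satIAt[p], ] <- if (act) actI[p, ] else prkI[p, ]
        posS[satJAt[p], ] <- if (act) actJ[p, ] else prkJ[p, ]
      }
      if (hasLigand)
        posS[ligAt, ] <- ligPos[as.character(siteOfState[s]), ]
      nresTot <- nres + as.integer(hasLigand)
      pat <- matrix(FALSE, nresTot, nresTot)
      for (i in seq_len(nresTot - 1L)) for (j in (i + 1L):nresTot) {
        ai <- which(top$resId == i); aj <- which(top$resId == j)
        dmin <- min(sqrt(outer(rowSums(posS[ai, , drop = FALSE]^2),
                               rowSums(posS[aj, , drop = FALSE]^2), `+`) -
                         2 * posS[ai, , drop = FALSE] %*%
                             t(posS[aj, , drop = FALSE])))
        pat[i, j] <- dmin < cutoff
      }
      pat
    })
    switching <- list()
    if (length(states) >= 2L) for (s in seq_len(length(states) - 1L)) {
      dpat <- patternByState[[s + 1L]] - patternByState[[s]]
      ij <- which(dpat != 0, arr.ind = TRUE)
      if (nrow(ij))
        switching[[s]] <- data.frame(
          event = s, resI = ij[, 1], resJ = ij[, 2],
          direction = ifelse(dpat[ij] > 0, "formed", "broken"))
    }
    switchingPairs <- if (length(switching)) do.call(rbind, switching)
      else data.frame(event = integer(), resI = integer(),
                      resJ = integer(), direction = character())
    rownames(switchingPairs) <- NULL

    traj <- trajectoryFromCoords(top, co, frameInterval)
    if (!is.null(writeDir)) {
      dir.create(writeDir, recursive = TRUE, showWarnings = FALSE)
      ref <- traj
      ref@coords <- co[1, , , drop = FALSE]
      writeTrajectoryPDB(ref, file.path(writeDir, "topology.pdb"))
      writeTrajectoryPDB(traj, file.path(writeDir, "trajectory.pdb"))
    }
    list(
      trajectory = traj,
      truth = list(stateByFrame = stateByFrame, eventFrames = eventFrames,
                   switchingPairs = switchingPairs,
                   patternByState = patternByState,
                   designatedPairs = designated,
                   flickerPairs = flicker, constitutivePairs = consti,
                   ligandSiteByFrame = ligandSiteByFrame),
      spec = spec
    )
  })
}

#' Generate a Gaussian displacement network with known covariance
#'
#' Variables are grouped into named blocks (motifs). Two topologies are
#' supported. \code{type = "factors"}: shared latent factors, each
#' loading onto the variables of its target blocks, plus independent
#' noise, giving covariance C = Lambda Lambda' + diag(noise^2).
#' \code{type = "chain"}: a latent AR(1)-style chain s_1 -> s_2 -> ...
#' (s_i = transfer_i * s_{i-1} + e_i), block i's variables loading on
#' s_i, so downstream blocks share information with upstream ones only
#' through the intermediate latent states (conditional independence by
#' construction).
#'
#' @param spec list with fields \code{type}, \code{blocks} (named
#'   integer vector of block sizes), \code{nFrames}, \code{seed},
#'   \code{noiseSd} (scalar or per-block, default 1), and either
#'   \code{factors} (list of \code{list(targets =, loading =)}) or
#'   \code{transfer} (numeric per block; first entry ignored),
#'   \code{latentNoise} (sd of the chain innovations, default 0.5),
#'   \code{loading} (scalar or per-block, default 1).
#' @return list with \code{samples} (nFrames x V matrix),
#'   \code{covariance} (exact V x V), \code{blocks} (named list of
#'   column indices) and the \code{spec}
#' @export
genGaussianNetwork <- function(spec) {
  sizes <- spec$blocks
  stopifnot(!is.null(names(sizes)), all(sizes >= 1))
  V <- sum(sizes)
  blockOf <- rep(names(sizes), sizes)
  blocks <- lapply(names(sizes), function(b) which(blockOf == b))
  names(blocks) <- names(sizes)
  noiseSd <- spec$noiseSd %||% 1
  if (length(noiseSd) == 1L) noiseSd <- stats::setNames(
    rep(noiseSd, length(sizes)), names(sizes))
  noiseVec <- noiseSd[blockOf]
  type <- spec$type %||% "factors"
  if (type == "factors") {
    fac <- spec$factors %||% list()
    Lambda <- matrix(0, V, length(fac))
    for (f in seq_along(fac)) {
      tg <- fac[[f]]$targets
      ld <- fac[[f]]$loading %||% 1
      if (length(ld) == 1L) ld <- stats::setNames(rep(ld, length(tg)), tg)
      for (b in tg) Lambda[blocks[[b]], f] <- ld[[b]]
    }
    C <- Lambda %*% t(Lambda) + diag(noiseVec^2, V)
  } else if (type == "chain") {
    B <- length(sizes)
    a <- spec$transfer %||% rep(0.8, B)
    ln <- spec$latentNoise %||% 0.5
    if (length(ln) == 1L) ln <- rep(ln, B)
    Svar <- numeric(B)
    Svar[1] <- 1
    if (B >= 2L) for (i in 2:B) Svar[i] <- a[i]^2 * Svar[i - 1] + ln[i]^2
    Ss <- diag(Svar)
    if (B >= 2L) for (i in 1:(B - 1L)) for (j in (i + 1L):B) {
      Ss[i, j] <- Ss[j, i] <- prod(a[(i + 1L):j]) * Svar[i]
    }
    ld <- spec$loading %||% 1
    if (length(ld) == 1L) ld <- rep(ld, B)
    L <- matrix(0, V, B)
    for (i in seq_len(B)) L[blocks[[i]], i] <- ld[i]
    C <- L %*% Ss %*% t(L) + diag(noiseVec^2, V)
  } else stop("unknown network type '", type, "'")
  U <- tryCatch(chol(C), error = function(e)
    stop("implied covariance is not positive definite"))
  samples <- withSeed(spec$seed %||% stop("spec$seed is required"), {
    Z <- matrix(stats::rnorm(spec$nFrames * V), spec$nFrames, V)
    Z %*% U
  })
  colnames(samples) <- paste0(blockOf, ".", unlist(lapply(sizes, seq_len)))
  list(samples = samples, covariance = C, blocks = blocks, spec = spec)
}

#' Sample a discrete Markov chain
#'
#' @param tpm row-stochastic transition matrix.
#' @param n chain length.
#' @param init initial state; default drawn from the stationary
#'   distribution.
#' @return integer state sequence
#' @export
sampleMarkovChain <- function(tpm, n, init = NULL) {
  K <- nrow(tpm)
  if (max(abs(rowSums(tpm) - 1)) > 1e-8) stop("tpm rows must sum to 1")
  cum <- t(apply(tpm, 1, cumsum))
  s <- integer(n)
  piv <- .stationaryFromTPM(tpm)
  s[1] <- if (is.null(init)) sample.int(K, 1, prob = piv) else as.integer(init)
  if (n >= 2L) {
    u <- stats::runif(n)
    for (t in 2:n) {
      s[t] <- sum(u[t] > cum[s[t - 1L], ]) + 1L
    }
  }
  s
}

#' Generate CV time series from a hidden Markov chain
#'
#' The latent chain is sampled from the given transition matrix and
#' each frame's CV vector is drawn from the emitting state's Gaussian.
#'
#' @param spec list with fields \code{tpm} (row-stochastic,
#'   irreducible), \code{means} (states x CV matrix of emission means),
#'   \code{sds} (scalar or states x CV), \code{nFrames} (total over all
#'   segments), \code{nSegments} (default 1) and \code{seed}.
#' @return list with \code{segments} (list of matrices), \code{labels}
#'   (list of integer vectors), \code{tpm} and the \code{spec}
#' @export
genMarkovCV <- function(spec) {
  tpm <- as.matrix(spec$tpm)
  means <- as.matrix(spec$means)
  K <- nrow(tpm)
  stopifnot(nrow(means) == K)
  if (length(.largestComponent(tpm)) < K)
    stop("transition matrix is reducible")
  d <- ncol(means)
  sds <- spec$sds %||% 1
  if (length(sds) == 1L) sds <- matrix(sds, K, d)
  nSeg <- spec$nSegments %||% 1L
  nPer <- rep(spec$nFrames %/% nSeg, nSeg)
  nPer[nSeg] <- nPer[nSeg] + spec$nFrames %% nSeg
  withSeed(spec$seed %||% stop("spec$seed is required"), {
    labels <- lapply(nPer, function(n) sampleMarkovChain(tpm, n))
    segments <- lapply(labels, function(lab) {
      n <- length(lab)
      means[lab, , drop = FALSE] +
        matrix(stats::rnorm(n * d), n, d) * sds[lab, , drop = FALSE]
    })
    list(segments = segments, labels = labels, tpm = tpm, spec = spec)
  })
}
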