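# Gaussian configurational-entropy measures of allosteric coordination
# between structural motifs: differential entropy from the displacement
# covariance, total correlation (TC), conditional TC, coordination
# information (CI / NCI) of a transmitter onto a receiver, and mutual
# coordination information (MCI / NMCI) identifying channel residues.
# All entropies are in nats.

#' Displacement ensemble of a motif
#'
#' Per-frame displacement of the motif's atoms relative to a reference
#' conformation, computed on a superposed trajectory. Scalar mode stores
#' the Euclidean distance of each atom to its reference position (one
#' variable per atom); vector mode stores the (dx, dy, dz) deviations
#' (three variables per atom).
#'
#' @param traj a superposed [Trajectory-class] (see [superpose()]).
#' @param resIds residue ids of the motif.
#' @param ref reference [Trajectory-class] (first frame used), same
#'   topology indexing.
#' @param mode "scalar" (default) or "vector".
#' @param atoms atom policy: "ca" (default), "heavy" or "all".
#' @param name motif name carried into results.
#' @return a [DisplacementEnsemble-class]
#' @export
displacementEnsemble <- function(traj, resIds, ref,
                                 mode = c("scalar", "vector"),
                                 atoms = c("ca", "heavy", "all"),
                                 name = NA_character_) {
  mode <- match.arg(mode)
  atoms <- match.arg(atoms)
  if (!traj@aligned)
    stop("trajectory has not been superposed; run superpose() first")
  sel <- switch(atoms,
    ca = atomSelection(resIds = resIds, atomNames = "CA"),
    heavy = atomSelection(resIds = resIds, heavyOnly = TRUE),
    all = atomSelection(resIds = resIds))
  it <- resolveSelection(sel, traj@topology)
  ir <- resolveSelection(sel, ref@topology)
  if (length(it) != length(ir))
    stop("motif resolves to different atom counts on trajectory and reference")
  refXYZ <- matrix(ref@coords[1, ir, ], ncol = 3)
  co <- traj@coords
  nf <- dim(co)[1]
  na <- length(it)
  resOfAtom <- traj@topology$resId[it]
  if (mode == "scalar") {
    S <- matrix(NA_real_, nf, na)
    for (k in seq_len(na)) {
      a <- it[k]
      S[, k] <- sqrt((co[, a, 1] - refXYZ[k, 1])^2 +
                     (co[, a, 2] - refXYZ[k, 2])^2 +
                     (co[, a, 3] - refXYZ[k, 3])^2)
    }
    vm <- data.frame(atomId = it, resId = resOfAtom, comp = "d")
  } else {
    S <- matrix(NA_real_, nf, 3L * na)
    for (k in seq_len(na)) {
      a <- it[k]
      S[, 3 * k - 2] <- co[, a, 1] - refXYZ[k, 1]
      S[, 3 * k - 1] <- co[, a, 2] - refXYZ[k, 2]
      S[, 3 * k]     <- co[, a, 3] - refXYZ[k, 3]
    }
    vm <- data.frame(atomId = rep(it, each = 3L),
                     resId = rep(resOfAtom, each = 3L),
                     comp = rep(c("x", "y", "z"), na))
  }
  new("DisplacementEnsemble", samples = S, varMap = vm, mode = mode,
      motif = as.character(name))
}

# coerce an ensemble / matrix / list of those to a plain sample matrix
.ens2mat <- function(x) {
  if (is(x, "DisplacementEnsemble")) x@samples
  else if (is.matrix(x)) x
  else if (is.numeric(x)) matrix(x, ncol = 1)
  else if (is.list(x)) do.call(cbind, lapply(x, .ens2mat))
  else stop("expected a DisplacementEnsemble, matrix or list of them")
}

.ensIds <- function(x) {
  if (is(x, "DisplacementEnsemble"))
    paste(x@varMap$atomId, x@varMap$comp)
  else if (is.list(x) && !is.data.frame(x))
    unlist(lapply(x, .ensIds))
  else character()
}

.checkDisjoint <- function(...) {
  ids <- lapply(list(...), .ensIds)
  all <- unlist(ids)
  if (length(all) && anyDuplicated(all))
    stop("motifs share atoms; joint covariance would double-count them")
  invisible(TRUE)
}

#' Gaussian differential entropy of an ensemble
#'
#' H = 1/2 * (N log(2 pi e) + log det C) with C the sample covariance.
#' Eigenvalues of C are floored at the absolute value \code{evFloor}
#' (squared Angstrom for displacement data) so that rigid or
#' near-rigid degrees of freedom stay finite; an absolute floor keeps
#' the flooring identical between marginal and joint covariances, so
#' zero-variance blocks cancel exactly in the difference-based measures.
#'
#' @param x a [DisplacementEnsemble-class], sample matrix or list.
#' @param evFloor absolute eigenvalue floor (default 1e-8).
#' @return entropy in nats
#' @export
nbitEntropy <- function(x, evFloor = 1e-8) {
  X <- .ens2mat(x)
  if (!all(is.finite(X))) stop("non-finite values in ensemble")
  C <- stats::cov(X)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, evFloor)
  0.5 * (length(ev) * log(2 * pi * exp(1)) + sum(log(ev)))
}

#' Total correlation of a set of motifs
#'
#' TC(X_1, ..., X_N) = sum_i H(X_i) - H(X_1, ..., X_N): the total
#' information shared among the motifs (0 for independent motifs).
#'
#' @param motifs list of >= 2 ensembles (pairwise disjoint atoms).
#' @param evFloor passed to [nbitEntropy()].
#' @return nats
#' @export
totalCorrelation <- function(motifs, evFloor = 1e-8) {
  if (length(motifs) < 2L) stop("total correlation needs >= 2 motifs")
  do.call(.checkDisjoint, motifs)
  sum(vapply(motifs, nbitEntropy, numeric(1), evFloor = evFloor)) -
    nbitEntropy(motifs, evFloor = evFloor)
}

#' Conditional total correlation
#'
#' TC(X_1, ..., X_N | X_m) = sum_i [H(X_i, X_m) - H(X_m)] -
#' [H(X_1, ..., X_N, X_m) - H(X_m)]: the information shared among the
#' motifs once the conditioner's contribution is removed.
#'
#' @param motifs list of >= 2 ensembles.
#' @param conditioner ensemble disjoint from the motifs.
#' @param evFloor passed to [nbitEntropy()].
#' @return nats
#' @export
conditionalTC <- function(motifs, conditioner, evFloor = 1e-8) {
  if (length(motifs) < 2L) stop("conditional TC needs >= 2 motifs")
  do.call(.checkDisjoint, c(motifs, list(conditioner)))
  Hm <- nbitEntropy(conditioner, evFloor = evFloor)
  sum(vapply(motifs, function(x)
        nbitEntropy(list(x, conditioner), evFloor = evFloor) - Hm,
      numeric(1))) -
    (nbitEntropy(c(motifs, list(conditioner)), evFloor = evFloor) - Hm)
}

# a receiver given as a single ensemble is split into per-residue blocks
# (TC needs at least two blocks); a list is used as given
.receiverBlocks <- function(receiver) {
  if (is.list(receiver) && !is(receiver, "DisplacementEnsemble"))
    return(receiver)
  splitByResidue(receiver)
}

#' Split an ensemble into per-residue ensembles
#'
#' @param ens a [DisplacementEnsemble-class].
#' @return named list of single-residue ensembles
#' @export
splitByResidue <- function(ens) {
  stopifnot(is(ens, "DisplacementEnsemble"))
  res <- unique(ens@varMap$resId)
  out <- lapply(res, function(r) {
    cols <- which(ens@varMap$resId == r)
    new("DisplacementEnsemble", samples = ens@samples[, cols, drop = FALSE],
        varMap = ens@varMap[cols, , drop = FALSE], mode = ens@mode,
        motif = paste0(ens@motif, ":", r))
  })
  names(out) <- as.character(res)
  out
}

#' Drop residues from an ensemble
#'
#' @param ens a [DisplacementEnsemble-class].
#' @param resIds residues to remove.
#' @return reduced [DisplacementEnsemble-class]
#' @export
dropResidues <- function(ens, resIds) {
  cols <- which(!ens@varMap$resId %in% resIds)
  if (!length(cols)) stop("dropping all residues of the ensemble")
  new("DisplacementEnsemble", samples = ens@samples[, cols, drop = FALSE],
      varMap = ens@varMap[cols, , drop = FALSE], mode = ens@mode,
      motif = ens@motif)
}

#' Coordination information of a transmitter onto a receiver
#'
#' CI = TC(receiver) - TC(receiver | transmitter): the information
#' shared within the receiver that is also shared with the transmitter.
#' NCI = 100 * CI / TC(receiver), the percentage of the receiver's
#' internal coordination explained by the transmitter. A receiver given
#' as one ensemble is split into per-residue blocks.
#'
#' @param receiver ensemble or list of ensembles.
#' @param transmitter ensemble disjoint from the receiver.
#' @param evFloor passed to [nbitEntropy()].
#' @param tol TC below which NCI is reported as NA (default 1e-10).
#' @return list(ci = nats, nci = percent, tcReceiver = nats)
#' @export
coordinationInformation <- function(receiver, transmitter,
                                    evFloor = 1e-8, tol = 1e-10) {
  blocks <- .receiverBlocks(receiver)
  tc <- totalCorrelation(blocks, evFloor = evFloor)
  ci <- tc - conditionalTC(blocks, transmitter, evFloor = evFloor)
  nci <- if (tc <= tol) {
    warning("receiver total correlation ~ 0; NCI undefined")
    NA_real_
  } else 100 * ci / tc
  list(ci = ci, nci = nci, tcReceiver = tc)
}

#' Mutual coordination information through a channel
#'
#' MCI = CI(R, X_m) + CI(R, X_n) - CI(R, X_m u X_n), the coordination
#' information between receiver and transmitter that is also shared
#' with the channel; NMCI = 100 * MCI / CI(R, X_m). The union
#' transmitter is the concatenation of transmitter and channel.
#'
#' @param receiver ensemble or list of ensembles.
#' @param transmitter,channel ensembles; receiver, transmitter and
#'   channel must be pairwise disjoint.
#' @param evFloor passed to [nbitEntropy()].
#' @param tol CI below which NMCI is reported as NA.
#' @return list(mci = nats, nmci = percent, ciTransmitter = nats)
#' @export
mutualCoordination <- function(receiver, transmitter, channel,
                               evFloor = 1e-8, tol = 1e-10) {
  blocks <- .receiverBlocks(receiver)
  do.call(.checkDisjoint, c(blocks, list(transmitter), list(channel)))
  cim <- coordinationInformation(blocks, transmitter, evFloor, tol)
  cin <- coordinationInformation(blocks, channel, evFloor, tol)
  ciu <- coordinationInformation(blocks, list(transmitter, channel),
                                 evFloor, tol)
  mci <- cim$ci + cin$ci - ciu$ci
  nmci <- if (abs(cim$ci) <= tol) {
    warning("transmitter coordination information ~ 0; NMCI undefined")
    NA_real_
  } else 100 * mci / cim$ci
  list(mci = mci, nmci = nmci, ciTransmitter = cim$ci)
}

#' Motif-by-motif coordination matrix
#'
#' Total correlation of each motif (split into per-residue blocks) on
#' the diagonal (nats) and the normalized coordination information
#' (percent) off the diagonal, rows acting as receiver and columns as
#' transmitter. NCI is generally asymmetric because the receiver
#' normalization differs.
#'
#' @param ensembles named list of [DisplacementEnsemble-class] objects.
#' @param evFloor passed to [nbitEntropy()].
#' @return a [CoordinationMatrix-class]
#' @export
coordinationMatrix <- function(ensembles, evFloor = 1e-8) {
  stopifnot(length(ensembles) >= 2L, !is.null(names(ensembles)))
  n <- length(ensembles)
  M <- matrix(NA_real_, n, n,
              dimnames = list(receiver = names(ensembles),
                              transmitter = names(ensembles)))
  mode <- unique(vapply(ensembles, function(e) e@mode, character(1)))
  for (i in seq_len(n)) {
    blocks <- .receiverBlocks(ensembles[[i]])
    M[i, i] <- totalCorrelation(blocks, evFloor = evFloor)
    for (j in seq_len(n)[-i]) {
      M[i, j] <- coordinationInformation(blocks, ensembles[[j]],
                                         evFloor = evFloor)$nci
    }
  }
  new("CoordinationMatrix", values = M, motifs = names(ensembles),
      mode = mode[1])
}

#' Per-residue channel profile
#'
#' NMCI of the receiver-transmitter coordination computed with each
#' candidate residue ensemble as the channel: residues on the allosteric
#' path score high, off-path residues near zero.
#'
#' @param receiver ensemble or list of ensembles.
#' @param transmitter ensemble.
#' @param candidates named list of per-residue ensembles (e.g. from
#'   [splitByResidue()]), disjoint from receiver and transmitter.
#' @param evFloor passed to [nbitEntropy()].
#' @return data.frame with columns residue, nmci
#' @export
channelProfile <- function(receiver, transmitter, candidates,
                           evFloor = 1e-8) {
  vals <- vapply(candidates, function(ch) {
    out <- tryCatch(
      suppressWarnings(mutualCoordination(receiver, transmitter, ch,
                                          evFloor = evFloor))$nmci,
      error = function(e) NA_real_)
    out
  }, numeric(1))
  data.frame(residue = names(candidates), nmci = as.numeric(vals),
             row.names = NULL)
}

#' Per-residue transmitter contribution
#'
#' Leave-one-residue-out drop in coordination information:
#' contribution(r) = CI(receiver, transmitter) -
#' CI(receiver, transmitter without r). Residues carrying the shared
#' signal account for most of the CI; redundant residues score near 0.
#'
#' @param receiver ensemble or list of ensembles.
#' @param transmitter ensemble with >= 2 residues.
#' @param evFloor passed to [nbitEntropy()].
#' @return data.frame with columns residue, contribution (nats)
#' @export
transmitterContribution <- function(receiver, transmitter,
                                    evFloor = 1e-8) {
  res <- unique(transmitter@varMap$resId)
  if (length(res) < 2L)
    stop("leave-one-out contribution needs a transmitter with >= 2 residues")
  full <- coordinationInformation(receiver, transmitter,
                                  evFloor = evFloor)$ci
  contrib <- vapply(res, function(r)
    full - coordinationInformation(receiver, dropResidues(transmitter, r),
                                   evFloor = evFloor)$ci,
    numeric(1))
  data.frame(residue = res, contribution = contrib, row.names = NULL)
}
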