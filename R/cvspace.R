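# Collective variables and binding-mode observables: center-of-mass
# distances, the cavity coordinate (ligand position along the bisector
# of the x- and z-axes after orienting the gate helix along x), distance
# -threshold binding-mode classification and contact probabilities.

.comSeries <- function(traj, atomIdx) {
  m <- atomMasses(traj@topology$element[atomIdx])
  w <- m / sum(m)
  co <- traj@coords
  nf <- dim(co)[1]
  out <- matrix(NA_real_, nf, 3)
  for (d in 1:3)
    out[, d] <- matrix(co[, atomIdx, d], nrow = nf) %*% w
  out
}

#' Center-of-mass distance between two atom groups
#'
#' @param traj a [Trajectory-class].
#' @param groupA,groupB [AtomSelection-class] objects (non-empty).
#' @return numeric vector, per-frame Euclidean distance between the
#'   mass-weighted centers (Angstrom)
#' @export
comDistance <- function(traj, groupA, groupB) {
  ia <- resolveSelection(groupA, traj@topology)
  ib <- resolveSelection(groupB, traj@topology)
  ca <- .comSeries(traj, ia)
  cb <- .comSeries(traj, ib)
  sqrt(rowSums((ca - cb)^2))
}

#' Cavity coordinate of a probe group
#'
#' Scalar ligand-position coordinate: per frame, the complex is rotated
#' so that the long axis of the gate helix (first principal axis of the
#' helix selection, oriented from its first to its last atom) lies along
#' x and the protein center of mass sits directly above the helix center
#' of mass (positive z, zero y). The origin is the center of mass of the
#' serine-site selection and the coordinate is the displacement of the
#' probe center of mass projected on the unit bisector of the x- and
#' z-axes, (x + z) / sqrt(2).
#'
#' @param traj a [Trajectory-class].
#' @param h4Sel helix selection (>= 2 atoms spanning >= 2 residues).
#' @param serSel origin selection (e.g. the two serine residues).
#' @param probeSel probe (ligand) selection.
#' @param proteinSel selection defining the protein center of mass;
#'   default: all atoms not in \code{probeSel}.
#' @return numeric vector, per-frame cavity coordinate (Angstrom)
#' @export
cavityCoordinate <- function(traj, h4Sel, serSel, probeSel,
                             proteinSel = NULL) {
  top <- traj@topology
  ih <- resolveSelection(h4Sel, top)
  is <- resolveSelection(serSel, top)
  ip <- resolveSelection(probeSel, top)
  if (length(unique(top$resId[ih])) < 2L)
    stop("helix selection must span at least 2 residues")
  iprot <- if (is.null(proteinSel)) setdiff(seq_len(nrow(top)), ip)
           else resolveSelection(proteinSel, top)
  mh <- atomMasses(top$element[ih]); mh <- mh / sum(mh)
  mp <- atomMasses(top$element[iprot]); mp <- mp / sum(mp)
  ms <- atomMasses(top$element[is]); ms <- ms / sum(ms)
  ml <- atomMasses(top$element[ip]); ml <- ml / sum(ml)
  co <- traj@coords
  nf <- dim(co)[1]
  out <- numeric(nf)
  bis <- c(1, 0, 1) / sqrt(2)
  for (f in seq_len(nf)) {
    H <- matrix(co[f, ih, ], ncol = 3)
    comH <- colSums(H * mh)
    Hc <- sweep(H, 2, comH)
    sv <- svd(Hc)
    if (sv$d[1] < 1e-8) stop("degenerate helix axis (helix atoms coincide)")
    e1 <- sv$v[, 1]
    # orient the axis from the first to the last helix atom (N -> C)
    if (sum(e1 * (H[nrow(H), ] - H[1, ])) < 0) e1 <- -e1
    comP <- colSums(matrix(co[f, iprot, ], ncol = 3) * mp)
    vz <- comP - comH
    vz <- vz - sum(vz * e1) * e1
    nz <- sqrt(sum(vz^2))
    if (nz < 1e-8)
      stop("protein center of mass lies on the helix axis; frame ", f)
    e3 <- vz / nz
    e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
            e3[3] * e1[1] - e3[1] * e1[3],
            e3[1] * e1[2] - e3[2] * e1[1])
    R <- rbind(e1, e2, e3)  # rows map lab frame onto (x, y, z)
    origin <- as.vector(R %*% colSums(matrix(co[f, is, ], ncol = 3) * ms))
    probe <- as.vector(R %*% colSums(matrix(co[f, ip, ], ncol = 3) * ml))
    out[f] <- sum((probe - origin) * bis)
  }
  out
}

#' Classify ligand binding modes from site distances
#'
#' A frame is labelled \code{SER} when the probe-to-Ser-site distance is
#' below \code{dSite} and smaller than the probe-to-Trp-site distance;
#' \code{TRP} symmetrically; \code{OTHER} otherwise. The default 6
#' Angstrom site radius also captures water-bridged variants of each
#' mode.
#'
#' @param serDist,trpDist numeric per-frame distances (Angstrom).
#' @param dSite site radius threshold (default 6.0).
#' @return factor with levels SER, TRP, OTHER
#' @export
classifyBindingMode <- function(serDist, trpDist, dSite = 6.0) {
  if (length(serDist) != length(trpDist))
    stop("distance channels must have equal length")
  lab <- rep("OTHER", length(serDist))
  lab[serDist < dSite & serDist < trpDist] <- "SER"
  lab[trpDist < dSite & trpDist <= serDist] <- "TRP"
  factor(lab, levels = c("SER", "TRP", "OTHER"))
}

#' Contact probability between two residues
#'
#' Percentage of frames in which the two residues have at least one
#' atom pair closer than \code{cutoff}.
#'
#' @param traj a [Trajectory-class].
#' @param resA,resB residue ids.
#' @param cutoff Angstrom (default 3.5).
#' @param heavyOnly logical (default TRUE).
#' @param frames optional logical or integer frame subset (e.g. frames
#'   in one binding mode).
#' @return percentage in [0, 100]
#' @export
contactProbability <- function(traj, resA, resB, cutoff = 3.5,
                               heavyOnly = TRUE, frames = NULL) {
  top <- traj@topology
  keep <- if (heavyOnly) !isHydrogen(top) else rep(TRUE, nrow(top))
  ia <- which(top$resId == resA & keep)
  ib <- which(top$resId == resB & keep)
  if (!length(ia) || !length(ib)) stop("residue not found in topology")
  d <- .minPairDistance(traj@coords, ia, ib)
  if (!is.null(frames)) d <- d[frames]
  if (!length(d)) stop("no frames selected")
  100 * mean(d < cutoff)
}

#' Evaluate a set of collective variables
#'
#' Each definition is a list with a unique \code{name}, a \code{type}
#' ("com_distance" or "cavity") and the selections it needs (each given
#' as a list understood by [resolveSelection()]): \code{groupA}/
#' \code{groupB} for distances; \code{h4}/\code{ser}/\code{probe} (and
#' optionally \code{protein}) for the cavity coordinate. Columns are
#' evaluated in config order.
#'
#' @param traj a [Trajectory-class].
#' @param defs list of CV definitions.
#' @return a [CVMatrix-class]
#' @export
buildCVMatrix <- function(traj, defs) {
  if (!length(defs)) stop("empty CV configuration")
  cols <- lapply(defs, function(d) {
    if (is.null(d$name)) stop("CV definition lacks a name")
    switch(d$type,
      com_distance = comDistance(traj, d$groupA, d$groupB),
      cavity = cavityCoordinate(traj, d$h4, d$ser, d$probe,
                                d$protein %||% NULL),
      stop("unknown CV type '", d$type, "'")
    )
  })
  new("CVMatrix", values = do.call(cbind, cols), defs = defs,
      segmentStarts = traj@segmentStarts,
      frameInterval = traj@frameInterval)
}
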