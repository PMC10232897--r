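# Structure / trajectory input-output and least-squares superposition.
#
# PDB parsing is delegated to bio3d. Trajectories are read from
# multi-model PDB files, DCD files (bio3d::read.dcd) or plain-text CSV
# coordinate tables (frames x 3*atoms, columns x1,y1,z1,x2,...); the
# package's own writer emits multi-model PDB and CSV so fixtures stay
# text-only.

#' Construct an atom selection
#'
#' @param resIds integer residue ids to keep (default: all).
#' @param atomNames character atom names to keep (default: all).
#' @param heavyOnly logical, drop hydrogens.
#' @param chainIds character chain ids to keep (default: all).
#' @return an [AtomSelection-class] object
#' @examples
#' atomSelection(resIds = 1:10, atomNames = "CA")
#' @export
atomSelection <- function(resIds = integer(), atomNames = character(),
                          heavyOnly = FALSE, chainIds = character()) {
  new("AtomSelection", resIds = as.integer(resIds),
      atomNames = as.character(atomNames), heavyOnly = isTRUE(heavyOnly),
      chainIds = as.character(chainIds))
}

#' Resolve an atom selection against a topology
#'
#' @param sel an [AtomSelection-class] (or a list with the same fields).
#' @param top a topology data.frame (see [Trajectory-class]).
#' @return integer vector of atom indices (1-based); error if empty.
#' @export
resolveSelection <- function(sel, top) {
  if (is.list(sel))
    sel <- atomSelection(resIds = sel$resIds %||% integer(),
                         atomNames = sel$atomNames %||% character(),
                         heavyOnly = sel$heavyOnly %||% FALSE,
                         chainIds = sel$chainIds %||% character())
  keep <- rep(TRUE, nrow(top))
  if (length(sel@resIds)) keep <- keep & top$resId %in% sel@resIds
  if (length(sel@atomNames)) keep <- keep & top$atomName %in% sel@atomNames
  if (length(sel@chainIds)) keep <- keep & top$chainId %in% sel@chainIds
  if (sel@heavyOnly) keep <- keep & !isHydrogen(top)
  idx <- which(keep)
  if (!length(idx))
    stop("atom selection resolves to zero atoms on this topology")
  idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a PDB structure
#'
#' Parses a PDB file into a topology and a single-frame [Trajectory-class].
#' When alternate-location duplicates are present, the first altloc of each
#' atom is kept and a warning is issued.
#'
#' @param path PDB file.
#' @return list with elements \code{topology} (data.frame) and
#'   \code{trajectory} (single-frame Trajectory), coordinates in Angstrom
#'   and residue ids taken from the PDB numbering.
#' @export
readStructure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    { out <- NULL
      utils::capture.output(out <- suppressWarnings(bio3d::read.pdb(path)))
      out },
    error = function(e) stop("PDB parse error in '", path,
                             "': ", conditionMessage(e)))
  at <- pdb$atom
  if (any(!is.na(at$alt) & at$alt != "" & at$alt != "A") ||
      any(grepl("^ATOM.{12}[B-Z]", readLines(path, warn = FALSE))))
    warning("altloc records present; first altloc kept")
  if (is.null(at) || nrow(at) == 0L) stop("no atoms parsed from ", path)
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " alternate-location duplicate atom(s) dropped, ",
            "first altloc kept")
    at <- at[!dup, , drop = FALSE]
  }
  el <- at$elesy
  el[is.na(el) | el == ""] <- substr(gsub("^[0-9]+", "",
                                          at$elety[is.na(el) | el == ""]), 1, 1)
  ch <- at$chain
  ch[is.na(ch) | ch == ""] <- "A"
  top <- data.frame(atomId = seq_len(nrow(at)), atomName = at$elety,
                    element = el, resId = as.integer(at$resno),
                    resName = at$resid, chainId = ch,
                    stringsAsFactors = FALSE)
  xyz <- matrix(c(at$x, at$y, at$z), ncol = 3)
  co <- array(NA_real_, c(1L, nrow(top), 3L))
  co[1, , ] <- xyz
  traj <- new("Trajectory", topology = top, coords = co,
              frameInterval = NA_real_, segmentStarts = 1L, aligned = FALSE)
  list(topology = top, trajectory = traj)
}

#' Assemble a Trajectory from a coordinate array
#'
#' @param top topology data.frame.
#' @param coords frames x atoms x 3 array (Angstrom).
#' @param frameInterval ns per frame.
#' @param segmentStarts 1-based replica start frames.
#' @return a [Trajectory-class]
#' @export
trajectoryFromCoords <- function(top, coords, frameInterval = NA_real_,
                                 segmentStarts = 1L) {
  new("Trajectory", topology = top, coords = coords,
      frameInterval = as.numeric(frameInterval),
      segmentStarts = as.integer(segmentStarts), aligned = FALSE)
}

.readCoordFile <- function(path, nAtomsExpected) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
  } else if (ext == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE)
    xyz <- pdb$xyz
    if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  } else if (ext %in% c("csv", "txt")) {
    xyz <- as.matrix(utils::read.csv(path, header = FALSE))
  } else {
    stop("unreadable trajectory format '", ext, "' for file ", path)
  }
  xyz <- unclass(xyz)
  if (!is.null(nAtomsExpected) && ncol(xyz) != 3L * nAtomsExpected)
    stop(sprintf("atom-count mismatch in '%s': file has %d atoms, topology %d",
                 path, ncol(xyz) %/% 3L, nAtomsExpected))
  xyz
}

#' Read and concatenate coordinate files
#'
#' Frames are concatenated in the given order and
#' \code{segmentStarts} is set at the file joins, so lagged statistics
#' never cross file boundaries.
#'
#' @param paths character vector of coordinate files (multi-model PDB,
#'   DCD or CSV).
#' @param top topology data.frame matching the files.
#' @param frameInterval ns per frame.
#' @return a [Trajectory-class]
#' @export
readTrajectory <- function(paths, top, frameInterval = NA_real_) {
  stopifnot(length(paths) >= 1L)
  mats <- lapply(paths, .readCoordFile, nAtomsExpected = nrow(top))
  nf <- vapply(mats, nrow, integer(1))
  starts <- as.integer(cumsum(c(1L, nf[-length(nf)])))
  xyz <- do.call(rbind, mats)
  co <- array(NA_real_, c(nrow(xyz), nrow(top), 3L))
  co[, , 1] <- xyz[, seq(1, ncol(xyz), by = 3), drop = FALSE]
  co[, , 2] <- xyz[, seq(2, ncol(xyz), by = 3), drop = FALSE]
  co[, , 3] <- xyz[, seq(3, ncol(xyz), by = 3), drop = FALSE]
  trajectoryFromCoords(top, co, frameInterval, starts)
}

#' Frame times in nanoseconds
#'
#' @param traj a [Trajectory-class] with a finite frame interval.
#' @return numeric vector, time 0 at the first frame of the trajectory.
#' @export
frameTimes <- function(traj) {
  if (!is.finite(traj@frameInterval))
    stop("trajectory has no frame interval")
  (seq_len(nFrames(traj)) - 1) * traj@frameInterval
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a [Trajectory-class].
#' @param path output file.
#' @return invisibly, the path
#' @export
writeTrajectoryPDB <- function(traj, path) {
  top <- traj@topology
  co <- traj@coords
  nf <- dim(co)[1]
  con <- file(path, "w")
  on.exit(close(con))
  multi <- nf > 1L
  for (f in seq_len(nf)) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      top$atomId %% 100000L, substr(top$atomName, 1, 4),
      substr(top$resName, 1, 3), substr(top$chainId, 1, 1),
      top$resId %% 10000L, co[f, , 1], co[f, , 2], co[f, , 3], 1, 0,
      substr(top$element, 1, 2))
    writeLines(lines, con)
    writeLines(if (multi) "ENDMDL" else "END", con)
  }
  if (multi) writeLines("END", con)
  invisible(path)
}

#' Write trajectory coordinates as plain CSV
#'
#' One row per frame, columns x1,y1,z1,x2,... No header. Coordinates are
#' rounded to 1e-3 Angstrom (PDB precision) so the two text formats
#' round-trip identically.
#'
#' @param traj a [Trajectory-class].
#' @param path output file.
#' @return invisibly, the path
#' @export
writeTrajectoryCSV <- function(traj, path) {
  co <- traj@coords
  nf <- dim(co)[1]; na <- dim(co)[2]
  flat <- matrix(NA_real_, nf, 3L * na)
  flat[, seq(1, 3 * na, by = 3)] <- co[, , 1]
  flat[, seq(2, 3 * na, by = 3)] <- co[, , 2]
  flat[, seq(3, 3 * na, by = 3)] <- co[, , 3]
  utils::write.table(round(flat, 3), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# Optimal rotation (Kabsch, SVD closed form, reflections forbidden)
# mapping centered P onto centered Q; returns 3x3 matrix R such that
# P %*% R best matches Q.
kabschRotation <- function(P, Q) {
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Superpose a trajectory onto a reference structure
#'
#' Each frame is rigid-body transformed (closed-form least-squares
#' rotation via SVD, no reflections) to minimize the RMSD of the selected
#' atoms against the reference; the transform is applied to all atoms.
#'
#' @param traj a [Trajectory-class].
#' @param ref a Trajectory whose first frame is the reference.
#' @param sel an [AtomSelection-class] resolving to >= 3 non-collinear
#'   atoms on both topologies, with equal counts.
#' @return a superposed [Trajectory-class] (\code{aligned} flag set)
#' @export
superpose <- function(traj, ref, sel) {
  it <- resolveSelection(sel, traj@topology)
  ir <- resolveSelection(sel, ref@topology)
  if (length(it) != length(ir))
    stop("selection resolves to different atom counts on the two topologies")
  if (length(it) < 3L) stop("superposition needs at least 3 selected atoms")
  refXYZ <- matrix(ref@coords[1, ir, ], ncol = 3)
  cq <- colMeans(refXYZ)
  Qc <- sweep(refXYZ, 2, cq)
  sv <- svd(Qc)$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("degenerate (collinear) alignment selection")
  co <- traj@coords
  out <- co
  nf <- dim(co)[1]
  for (f in seq_len(nf)) {
    P <- matrix(co[f, it, ], ncol = 3)
    cp <- colMeans(P)
    R <- kabschRotation(sweep(P, 2, cp), Qc)
    allXYZ <- sweep(matrix(co[f, , ], ncol = 3), 2, cp)
    out[f, , ] <- sweep(allXYZ %*% R, 2, cq, `+`)
  }
  res <- traj
  res@coords <- out
  res@aligned <- TRUE
  res
}

#' RMSD of selected atoms against a reference, per frame
#'
#' @inheritParams superpose
#' @return numeric vector of RMSD values (Angstrom), one per frame
#' @export
rmsdToReference <- function(traj, ref, sel) {
  it <- resolveSelection(sel, traj@topology)
  ir <- resolveSelection(sel, ref@topology)
  if (length(it) != length(ir))
    stop("selection resolves to different atom counts on the two topologies")
  refXYZ <- matrix(ref@coords[1, ir, ], ncol = 3)
  vapply(seq_len(nFrames(traj)), function(f) {
    d <- matrix(traj@coords[f, it, ], ncol = 3) - refXYZ
    sqrt(mean(rowSums(d^2)))
  }, numeric(1))
}
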