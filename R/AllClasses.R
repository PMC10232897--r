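#' @import methods
NULL

#' Trajectory: coordinates plus residue-indexed topology
#'
#' Container for a coordinate trajectory in Angstrom. The topology is a
#' data.frame with one row per atom and columns \code{atomId} (1-based,
#' contiguous), \code{atomName}, \code{element}, \code{resId} (1-based,
#' strictly increasing within a chain), \code{resName} and \code{chainId}.
#' \code{segmentStarts} marks the first frame of each independent replica
#' (1-based, first element always 1); lagged statistics downstream never
#' span a segment boundary.
#'
#' @slot topology data.frame, one row per atom.
#' @slot coords numeric array, frames x atoms x 3, Angstrom.
#' @slot frameInterval numeric, ns between stored frames.
#' @slot segmentStarts integer, first frame index of each replica.
#' @slot aligned logical, TRUE after [superpose()] has been applied.
#' @exportClass Trajectory
setClass("Trajectory",
  representation(
    topology = "data.frame",
    coords = "array",
    frameInterval = "numeric",
    segmentStarts = "integer",
    aligned = "logical"
  ),
  prototype(frameInterval = NA_real_, segmentStarts = 1L, aligned = FALSE)
)

setValidity("Trajectory", function(object) {
  top <- object@topology
  need <- c("atomId", "atomName", "element", "resId", "resName", "chainId")
  if (!all(need %in% names(top)))
    return(paste("topology lacks columns:",
                 paste(setdiff(need, names(top)), collapse = ", ")))
  if (length(dim(object@coords)) != 3L || dim(object@coords)[3] != 3L)
    return("coords must be a frames x atoms x 3 array")
  if (dim(object@coords)[2] != nrow(top))
    return("atom count of coords does not match topology")
  if (!all(is.finite(object@coords)))
    return("coords contain non-finite values")
  if (!identical(top$atomId, seq_len(nrow(top))))
    return("atomId must be contiguous 1..n_atoms")
  sb <- object@segmentStarts
  if (length(sb) == 0L || sb[1] != 1L || is.unsorted(sb, strictly = TRUE))
    return("segmentStarts must be sorted, starting at 1")
  if (any(sb > dim(object@coords)[1]))
    return("segmentStarts beyond last frame")
  # residue ids strictly increasing within a chain (in atom order)
  for (ch in unique(top$chainId)) {
    r <- top$resId[top$chainId == ch]
    if (any(diff(r) < 0))
      return(sprintf("resId not non-decreasing within chain %s", ch))
  }
  TRUE
})

#' Atom selection predicate
#'
#' A reusable selection over a topology: residue ids, atom names and a
#' heavy-atom flag. Resolve against a concrete topology with
#' [resolveSelection()].
#'
#' @slot resIds integer residue ids (empty = all residues).
#' @slot atomNames character atom names (empty = all names).
#' @slot heavyOnly logical, drop hydrogens.
#' @slot chainIds character chain ids (empty = all chains).
#' @exportClass AtomSelection
setClass("AtomSelection",
  representation(resIds = "integer", atomNames = "character",
                 heavyOnly = "logical", chainIds = "character"),
  prototype(resIds = integer(), atomNames = character(),
            heavyOnly = FALSE, chainIds = character())
)

#' Residue-contact time series
#'
#' Frames x residue-pair occupancy matrix. Raw series are binary (contact
#' iff the minimum interatomic distance is below the cutoff); smoothed
#' series hold sliding-window means in [0, 1]. \code{pairIndex} maps each
#' column to its unordered residue pair (resI < resJ).
#'
#' @slot values numeric matrix, frames x n_pairs.
#' @slot pairIndex data.frame with columns resI, resJ.
#' @slot smoothed logical.
#' @slot window integer, smoothing window (frames); NA when raw.
#' @slot segmentStarts integer.
#' @slot cutoff numeric, contact cutoff in Angstrom.
#' @exportClass ContactSeries
setClass("ContactSeries",
  representation(values = "matrix", pairIndex = "data.frame",
                 smoothed = "logical", window = "integer",
                 segmentStarts = "integer", cutoff = "numeric"),
  prototype(smoothed = FALSE, window = NA_integer_, segmentStarts = 1L,
            cutoff = NA_real_)
)

setValidity("ContactSeries", function(object) {
  v <- object@values
  if (ncol(v) != nrow(object@pairIndex))
    return("pairIndex rows must match value columns")
  if (!all(c("resI", "resJ") %in% names(object@pairIndex)))
    return("pairIndex needs columns resI, resJ")
  pi <- object@pairIndex
  if (any(pi$resI >= pi$resJ))
    return("pairIndex must satisfy resI < resJ")
  if (anyDuplicated(pi[c("resI", "resJ")]))
    return("duplicate residue pairs in pairIndex")
  if (length(v) && (min(v) < 0 || max(v) > 1))
    return("contact values must lie in [0, 1]")
  if (!object@smoothed && length(v) && !all(v %in% c(0, 1)))
    return("raw contact values must be binary")
  sb <- object@segmentStarts
  if (length(sb) == 0L || sb[1] != 1L || is.unsorted(sb, strictly = TRUE))
    return("segmentStarts must be sorted, starting at 1")
  TRUE
})

#' RED decomposition model
#'
#' Non-negative factorization of a contact time series into \code{c}
#' spatial components (rows of \code{spatial}, one weight per residue
#' pair) and their temporal weights (columns of \code{temporal}). After
#' [normalizeComponents()] the mean spatial weight over the constitutive
#' pairs is 1 in every component and \code{normFactors} records the
#' per-component factors (which cancel in the reconstruction).
#'
#' @slot spatial numeric matrix, c x n_pairs, non-negative.
#' @slot temporal numeric matrix, frames x c, non-negative.
#' @slot normFactors numeric length c; NA before normalization.
#' @slot constitutivePairs integer column indices used for normalization.
#' @slot reconError numeric, Frobenius norm of the residual.
#' @slot pairIndex data.frame carried from the input series.
#' @slot segmentStarts integer.
#' @slot seed integer or NA.
#' @slot iterations integer, update sweeps performed.
#' @slot converged logical.
#' @exportClass REDModel
setClass("REDModel",
  representation(spatial = "matrix", temporal = "matrix",
                 normFactors = "numeric", constitutivePairs = "integer",
                 reconError = "numeric", pairIndex = "data.frame",
                 segmentStarts = "integer", seed = "integer",
                 iterations = "integer", converged = "logical"),
  prototype(normFactors = NA_real_, constitutivePairs = integer(),
            seed = NA_integer_, converged = FALSE, segmentStarts = 1L)
)

setValidity("REDModel", function(object) {
  if (nrow(object@spatial) != ncol(object@temporal))
    return("component count mismatch between spatial and temporal")
  if (min(object@spatial) < 0 || min(object@temporal) < 0)
    return("factor matrices must be non-negative")
  if (ncol(object@spatial) != nrow(object@pairIndex))
    return("spatial columns must match pairIndex rows")
  TRUE
})

#' Collective-variable matrix
#'
#' Frames x CV values (Angstrom for distance CVs) plus the definitions
#' that produced each column, in config order.
#'
#' @slot values numeric matrix, frames x n_cv.
#' @slot defs list of CV definitions (name, type, selections).
#' @slot segmentStarts integer.
#' @slot frameInterval numeric, ns.
#' @exportClass CVMatrix
setClass("CVMatrix",
  representation(values = "matrix", defs = "list",
                 segmentStarts = "integer", frameInterval = "numeric"),
  prototype(segmentStarts = 1L, frameInterval = NA_real_)
)

setValidity("CVMatrix", function(object) {
  if (ncol(object@values) != length(object@defs))
    return("one definition per CV column required")
  nms <- vapply(object@defs, function(d) d$name, character(1))
  if (anyDuplicated(nms)) return("CV names must be unique")
  if (!all(is.finite(object@values))) return("CV values must be finite")
  TRUE
})

#' tICA model
#'
#' Solution of the generalized eigenproblem C(tau) v = lambda C(0) v on
#' mean-centered CV data, with eigenvectors normalized to
#' t(V) C(0) V = I and eigenvalues sorted descending.
#'
#' @slot mean numeric, per-CV mean.
#' @slot eigenvalues numeric, descending.
#' @slot eigenvectors numeric matrix, columns V_i.
#' @slot lag integer, frames.
#' @slot epsilon numeric ridge added to C(0).
#' @slot cvNames character.
#' @exportClass TICAModel
setClass("TICAModel",
  representation(mean = "numeric", eigenvalues = "numeric",
                 eigenvectors = "matrix", lag = "integer",
                 epsilon = "numeric", cvNames = "character")
)

#' Microstate Markov model
#'
#' k-means microstates, lagged transition counts, the symmetrized
#' row-stochastic transition probability matrix and its stationary
#' distribution. States outside the largest connected set of the count
#' graph are dropped (ergodic trimming); \code{active} maps retained
#' matrix rows back to original cluster labels.
#'
#' @slot centers numeric matrix, k x d cluster centers.
#' @slot assignments list of integer vectors, one per segment.
#' @slot lag integer, frames.
#' @slot counts numeric matrix, symmetrized transition counts.
#' @slot tpm numeric matrix, row-stochastic.
#' @slot pi numeric stationary distribution.
#' @slot active integer, retained state labels.
#' @slot seed integer or NA.
#' @exportClass MarkovModel
setClass("MarkovModel",
  representation(centers = "matrix", assignments = "list", lag = "integer",
                 counts = "matrix", tpm = "matrix", pi = "numeric",
                 active = "integer", seed = "integer"),
  prototype(seed = NA_integer_, lag = NA_integer_)
)

setValidity("MarkovModel", function(object) {
  T <- object@tpm
  if (length(T)) {
    if (nrow(T) != ncol(T)) return("tpm must be square")
    if (max(abs(rowSums(T) - 1)) > 1e-10) return("tpm rows must sum to 1")
    p <- object@pi
    if (length(p) != nrow(T)) return("pi length must match tpm")
    if (any(p < 0) || abs(sum(p) - 1) > 1e-10)
      return("pi must be a probability distribution")
  }
  TRUE
})

#' Macrostate (PCCA+) model
#'
#' Fuzzy memberships of microstates in metastable macrostates, the crisp
#' argmax map, stationary macrostate populations and the coarse-grained
#' transition matrix.
#'
#' @slot memberships numeric matrix, k x m, rows sum to 1.
#' @slot crisp integer, microstate -> macrostate.
#' @slot populations numeric, length m, sums to 1.
#' @slot macroTPM numeric matrix, m x m.
#' @exportClass MacrostateModel
setClass("MacrostateModel",
  representation(memberships = "matrix", crisp = "integer",
                 populations = "numeric", macroTPM = "matrix")
)

setValidity("MacrostateModel", function(object) {
  M <- object@memberships
  if (min(M) < -1e-10 || max(M) > 1 + 1e-10)
    return("memberships must lie in [0, 1]")
  if (max(abs(rowSums(M) - 1)) > 1e-8)
    return("membership rows must sum to 1")
  if (abs(sum(object@populations) - 1) > 1e-8)
    return("populations must sum to 1")
  if (!all(seq_len(ncol(M)) %in% object@crisp))
    return("every macrostate must be non-empty under the crisp map")
  TRUE
})

#' Transition-path-theory result
#'
#' Forward committor, gross and net reactive flux matrices, the total
#' source-to-target flux and the pathway decomposition table.
#'
#' @slot committor numeric per microstate (0 on source, 1 on target).
#' @slot grossFlux numeric matrix J_ij = pi_i (1 - q_i) T_ij q_j.
#' @slot netFlux numeric matrix max(0, J - t(J)).
#' @slot totalFlux numeric.
#' @slot pathways data.frame: path, flux, normFlux, cumFlux.
#' @slot source,target integer state sets.
#' @exportClass FluxResult
setClass("FluxResult",
  representation(committor = "numeric", grossFlux = "matrix",
                 netFlux = "matrix", totalFlux = "numeric",
                 pathways = "data.frame", source = "integer",
                 target = "integer")
)

#' Displacement ensemble for entropy analysis
#'
#' Per-frame displacements of one motif's atoms relative to a reference
#' conformation, taken from a superposed trajectory. Scalar mode stores
#' one Euclidean distance per atom; vector mode the (dx, dy, dz)
#' deviations. \code{varMap} maps sample columns to (atom, residue,
#' component).
#'
#' @slot samples numeric matrix, frames x n_vars.
#' @slot varMap data.frame with columns atomId, resId, comp.
#' @slot mode character, "scalar" or "vector".
#' @slot motif character name.
#' @exportClass DisplacementEnsemble
setClass("DisplacementEnsemble",
  representation(samples = "matrix", varMap = "data.frame",
                 mode = "character", motif = "character"),
  prototype(mode = "scalar", motif = NA_character_)
)

setValidity("DisplacementEnsemble", function(object) {
  if (ncol(object@samples) != nrow(object@varMap))
    return("varMap rows must match sample columns")
  if (!all(is.finite(object@samples))) return("samples must be finite")
  if (!object@mode %in% c("scalar", "vector"))
    return("mode must be 'scalar' or 'vector'")
  TRUE
})

#' Motif-by-motif coordination matrix
#'
#' Square matrix over motifs: total correlation (nats) on the diagonal,
#' normalized coordination information (percent, row = receiver,
#' column = transmitter) off the diagonal.
#'
#' @slot values numeric matrix with motif dimnames.
#' @slot motifs character.
#' @slot mode character, displacement mode the measures were computed in.
#' @exportClass CoordinationMatrix
setClass("CoordinationMatrix",
  representation(values = "matrix", motifs = "character", mode = "character")
)

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@coords)
  cat(sprintf("Trajectory: %d frames, %d atoms, %d residues, %d segment(s)%s\n",
              d[1], d[2], length(unique(paste(object@topology$chainId,
                                              object@topology$resId))),
              length(object@segmentStarts),
              if (object@aligned) " [aligned]" else ""))
  if (is.finite(object@frameInterval))
    cat(sprintf("  frame interval: %g ns\n", object@frameInterval))
})

setMethod("show", "ContactSeries", function(object) {
  cat(sprintf("ContactSeries: %d frames x %d pairs (%s), %d segment(s)\n",
              nrow(object@values), ncol(object@values),
              if (object@smoothed)
                sprintf("smoothed, window %d", object@window) else "raw",
              length(object@segmentStarts)))
})

setMethod("show", "REDModel", function(object) {
  cat(sprintf(
    "REDModel: %d components, %d pairs, %d frames; recon error %.4g%s\n",
    nrow(object@spatial), ncol(object@spatial), nrow(object@temporal),
    object@reconError,
    if (all(is.finite(object@normFactors))) " [normalized]" else ""))
})

setMethod("show", "TICAModel", function(object) {
  cat(sprintf("TICAModel: %d CVs, lag %d frames\n  eigenvalues: %s\n",
              length(object@mean), object@lag,
              paste(signif(object@eigenvalues, 4), collapse = ", ")))
})

setMethod("show", "MarkovModel", function(object) {
  cat(sprintf("MarkovModel: %d active microstates, lag %d frames\n",
              nrow(object@tpm), object@lag))
})

setMethod("show", "MacrostateModel", function(object) {
  cat(sprintf("MacrostateModel: %d macrostates over %d microstates\n",
              ncol(object@memberships), nrow(object@memberships)))
  cat("  populations:",
      paste(sprintf("%.3f", object@populations), collapse = " "), "\n")
})

setMethod("show", "FluxResult", function(object) {
  cat(sprintf("FluxResult: total flux %.4g, %d pathway(s)\n",
              object@totalFlux, nrow(object@pathways)))
})

setMethod("show", "DisplacementEnsemble", function(object) {
  cat(sprintf("DisplacementEnsemble '%s': %d frames x %d vars (%s mode)\n",
              object@motif, nrow(object@samples), ncol(object@samples),
              object@mode))
})

setMethod("show", "CoordinationMatrix", function(object) {
  cat(sprintf(
    "CoordinationMatrix over %d motifs (TC in nats on diagonal, NCI %% off)\n",
    length(object@motifs)))
  print(round(object@values, 2))
})
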