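# Accessor generics. Slot access from user code is discouraged; these are
# the supported surface.

#' Number of frames
#' @param x a Trajectory, ContactSeries or CVMatrix
#' @return integer
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of atoms
#' @param x a Trajectory
#' @return integer
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Topology table
#' @param x a Trajectory
#' @return data.frame, one row per atom
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' Coordinate array (frames x atoms x 3, Angstrom)
#' @param x a Trajectory
#' @return numeric array
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Segment start frames (1-based, first is 1)
#' @param x an object carrying replica structure
#' @return integer vector
#' @export
setGeneric("segmentStarts", function(x) standardGeneric("segmentStarts"))

#' Residue-pair index of a contact series
#' @param x a ContactSeries or REDModel
#' @return data.frame with columns resI, resJ
#' @export
setGeneric("pairIndex", function(x) standardGeneric("pairIndex"))

#' Numeric payload of a container
#' @param x a ContactSeries, CVMatrix, DisplacementEnsemble or
#'   CoordinationMatrix
#' @return numeric matrix
#' @export
setGeneric("valueMatrix", function(x) standardGeneric("valueMatrix"))

#' Spatial components of a RED model (c x n_pairs)
#' @param x a REDModel
#' @return numeric matrix
#' @export
setGeneric("spatialComponents", function(x) standardGeneric("spatialComponents"))

#' Temporal weights of a RED model (frames x c)
#' @param x a REDModel
#' @return numeric matrix
#' @export
setGeneric("temporalWeights", function(x) standardGeneric("temporalWeights"))

#' Transition probability matrix
#' @param x a MarkovModel
#' @return row-stochastic numeric matrix
#' @export
setGeneric("transitionMatrix", function(x) standardGeneric("transitionMatrix"))

#' Stationary distribution
#' @param x a MarkovModel
#' @return numeric vector summing to 1
#' @export
setGeneric("stationaryDistribution",
           function(x) standardGeneric("stationaryDistribution"))

setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[1])
setMethod("nFrames", "ContactSeries", function(x) nrow(x@values))
setMethod("nFrames", "CVMatrix", function(x) nrow(x@values))
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[2])
setMethod("topology", "Trajectory", function(x) x@topology)
setMethod("coords", "Trajectory", function(x) x@coords)
setMethod("segmentStarts", "Trajectory", function(x) x@segmentStarts)
setMethod("segmentStarts", "ContactSeries", function(x) x@segmentStarts)
setMethod("segmentStarts", "CVMatrix", function(x) x@segmentStarts)
setMethod("pairIndex", "ContactSeries", function(x) x@pairIndex)
setMethod("pairIndex", "REDModel", function(x) x@pairIndex)
setMethod("valueMatrix", "ContactSeries", function(x) x@values)
setMethod("valueMatrix", "CVMatrix", function(x) {
  v <- x@values
  colnames(v) <- vapply(x@defs, function(d) d$name, character(1))
  v
})
setMethod("valueMatrix", "DisplacementEnsemble", function(x) x@samples)
setMethod("valueMatrix", "CoordinationMatrix", function(x) x@values)
setMethod("spatialComponents", "REDModel", function(x) x@spatial)
setMethod("temporalWeights", "REDModel", function(x) x@temporal)
setMethod("transitionMatrix", "MarkovModel", function(x) x@tpm)
setMethod("stationaryDistribution", "MarkovModel", function(x) x@pi)
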