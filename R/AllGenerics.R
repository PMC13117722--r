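#' Number of beads in a system or trajectory
#' @param x a [ParticleSystem-class] or [TrajectorySlice-class].
#' @return integer bead count.
#' @export
setGeneric("nBeads", function(x) standardGeneric("nBeads"))

#' Number of molecules
#' @param x a [ParticleSystem-class] or [TrajectorySlice-class].
#' @return integer molecule count.
#' @export
setGeneric("nMolecules", function(x) standardGeneric("nMolecules"))

#' Bead table accessor
#' @param x a [ParticleSystem-class] or [TrajectorySlice-class].
#' @return the bead `data.frame`.
#' @export
setGeneric("beadData", function(x) standardGeneric("beadData"))

#' Coordinate accessor
#' @param x a [ParticleSystem-class].
#' @return numeric nBeads x 3 matrix, nm.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Box vector accessor
#' @param x a [ParticleSystem-class].
#' @return numeric length-3 box in nm.
#' @export
setGeneric("boxVector", function(x) standardGeneric("boxVector"))

#' Group label accessor
#' @param x a [ParticleSystem-class].
#' @return character vector of per-bead temperature-coupling groups.
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' Number of trajectory frames
#' @param x a [TrajectorySlice-class].
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Frame times
#' @param x a [TrajectorySlice-class].
#' @return numeric vector of frame times in ps.
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' Extract one frame
#' @param x a [TrajectorySlice-class].
#' @param i frame index (1-based).
#' @return list with elements `time` (ps), `coords` (nBeads x 3, nm)
#'   and `box` (length-3, nm).
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))
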