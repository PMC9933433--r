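# Generics for the accessor surface. Implementations live in accessors.R.

#' @export
setGeneric("species", function(x) standardGeneric("species"))
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @export
setGeneric("cellMatrix", function(x) standardGeneric("cellMatrix"))
#' @export
setGeneric("pbcFlags", function(x) standardGeneric("pbcFlags"))
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @export
setGeneric("timestep", function(x) standardGeneric("timestep"))
#' @export
setGeneric("velocities", function(x) standardGeneric("velocities"))
#' @export
setGeneric("hasVelocities", function(x) standardGeneric("hasVelocities"))
#' @export
setGeneric("tensors", function(x) standardGeneric("tensors"))
#' @export
setGeneric("configId", function(x) standardGeneric("configId"))
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @export
setGeneric("splitLabels", function(x) standardGeneric("splitLabels"))
#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))
#' @export
setGeneric("callCount", function(x) standardGeneric("callCount"))
#' @export
setGeneric("resetCallCount", function(x) standardGeneric("resetCallCount"))
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))
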