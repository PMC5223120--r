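#' @describeIn ArenaFrame-class pixel array accessor
#' @param object an object.
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @describeIn ArenaFrame-class resolution (mm/pixel) accessor
#' @export
setGeneric("resolution", function(object) standardGeneric("resolution"))

#' @describeIn ArenaFrame-class timestamp (minutes) accessor
#' @export
setGeneric("timestamp", function(object) standardGeneric("timestamp"))

#' @describeIn ArenaFrame-class camera label accessor
#' @export
setGeneric("cameraId", function(object) standardGeneric("cameraId"))

#' @describeIn FrameDetections-class seed blob table accessor
#' @export
setGeneric("seeds", function(object) standardGeneric("seeds"))

#' @describeIn FrameDetections-class ant blob table accessor
#' @export
setGeneric("ants", function(object) standardGeneric("ants"))

#' @describeIn PointPattern-class coordinate matrix accessor
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))

#' @describeIn PointPattern-class observation region accessor
#' @export
setGeneric("region", function(object) standardGeneric("region"))

#' @describeIn PointPattern-class number of points
#' @export
setGeneric("nPoints", function(object) standardGeneric("nPoints"))
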