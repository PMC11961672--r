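#' @rdname EnhancerModelFit-class
#' @param object,x an object
#' @export
setGeneric("modelName", function(object) standardGeneric("modelName"))

#' @rdname EnhancerModelSet-class
#' @param object an object
#' @export
setGeneric("bestModels", function(object) standardGeneric("bestModels"))

#' @rdname EnhancerModelSet-class
#' @export
setGeneric("deltaBIC", function(object) standardGeneric("deltaBIC"))

#' @rdname ChannelStack-class
#' @param object an object
#' @export
setGeneric("dapi", function(object) standardGeneric("dapi"))

#' @rdname ChannelStack-class
#' @export
setGeneric("fish", function(object) standardGeneric("fish"))

#' @rdname ChannelStack-class
#' @export
setGeneric("marker", function(object) standardGeneric("marker"))

#' @rdname EnrichmentMap-class
#' @param object an object
#' @export
setGeneric("enrichmentRatio", function(object) standardGeneric("enrichmentRatio"))

#' @rdname EnrichmentMap-class
#' @export
setGeneric("spotMedianMap", function(object) standardGeneric("spotMedianMap"))

#' @rdname EnrichmentMap-class
#' @export
setGeneric("randomMedianMap", function(object) standardGeneric("randomMedianMap"))
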