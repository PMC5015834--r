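#' @rdname accessors
#' @export
setGeneric("neuronNames", function(x) standardGeneric("neuronNames"))

#' @rdname accessors
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("neuronTable", function(x) standardGeneric("neuronTable"))

#' @rdname accessors
#' @export
setGeneric("neuronLayers", function(x) standardGeneric("neuronLayers"))

#' @rdname accessors
#' @export
setGeneric("somaPositions", function(x) standardGeneric("somaPositions"))

#' @rdname accessors
#' @export
setGeneric("neuronLayers<-", function(x, value) standardGeneric("neuronLayers<-"))

#' @rdname accessors
#' @export
setGeneric("somaPositions<-", function(x, value) standardGeneric("somaPositions<-"))
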