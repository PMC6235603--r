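#' Accessors for burstclique objects
#'
#' Structural accessors for \linkS4class{NetworkRealization} and friends:
#' adjacency and parameter matrices, neuron classes, excitabilities and
#' structural degrees; spike tables and burst interval series.
#'
#' @param object a burstclique S4 object.
#' @return The corresponding slot content, or a derived vector (degrees in
#'   counts, \code{igi} in seconds).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setGeneric("neuronClass", function(object) standardGeneric("neuronClass"))
#' @rdname accessors
#' @export
setGeneric("excitability", function(object) standardGeneric("excitability"))
#' @rdname accessors
#' @export
setGeneric("coupling", function(object) standardGeneric("coupling"))
#' @rdname accessors
#' @export
setGeneric("inDegree", function(object) standardGeneric("inDegree"))
#' @rdname accessors
#' @export
setGeneric("outDegree", function(object) standardGeneric("outDegree"))
#' @rdname accessors
#' @export
setGeneric("totalDegree", function(object) standardGeneric("totalDegree"))
#' @rdname accessors
#' @export
setGeneric("nNeurons", function(object) standardGeneric("nNeurons"))
#' @rdname accessors
#' @export
setGeneric("spikes", function(object) standardGeneric("spikes"))
#' @rdname accessors
#' @export
setGeneric("igi", function(object) standardGeneric("igi"))
#' @rdname accessors
#' @export
setGeneric("populationBursts", function(object) standardGeneric("populationBursts"))
#' @rdname accessors
#' @export
setGeneric("abortedBursts", function(object) standardGeneric("abortedBursts"))
#' @rdname accessors
#' @export
setGeneric("functionalEdges", function(object) standardGeneric("functionalEdges"))
#' @rdname accessors
#' @export
setGeneric("driverTable", function(object) standardGeneric("driverTable"))

#' @rdname accessors
#' @export
setMethod("adjacency", "NetworkRealization", function(object) object@adjacency)
#' @rdname accessors
#' @export
setMethod("neuronClass", "NetworkRealization", function(object) object@neuronClass)
#' @rdname accessors
#' @export
setMethod("excitability", "NetworkRealization", function(object) object@excitability)
#' @rdname accessors
#' @export
setMethod("coupling", "NetworkRealization", function(object) object@G)
#' @rdname accessors
#' @export
setMethod("inDegree", "NetworkRealization",
          function(object) rowSums(object@adjacency))
#' @rdname accessors
#' @export
setMethod("outDegree", "NetworkRealization",
          function(object) colSums(object@adjacency))
#' @rdname accessors
#' @export
setMethod("totalDegree", "NetworkRealization",
          function(object) rowSums(object@adjacency) + colSums(object@adjacency))
#' @rdname accessors
#' @export
setMethod("nNeurons", "NetworkRealization",
          function(object) nrow(object@adjacency))
#' @rdname accessors
#' @export
setMethod("nNeurons", "SpikeData", function(object) object@nNeurons)
#' @rdname accessors
#' @export
setMethod("spikes", "SpikeData", function(object) object@spikes)
#' @rdname accessors
#' @export
setMethod("igi", "BurstCatalog", function(object) {
  if (nrow(object@pb) < 2) return(numeric(0))
  diff(object@pb$peak) / 1000
})
#' @rdname accessors
#' @export
setMethod("populationBursts", "BurstCatalog", function(object) object@pb)
#' @rdname accessors
#' @export
setMethod("abortedBursts", "BurstCatalog", function(object) object@ab)
#' @rdname accessors
#' @export
setMethod("functionalEdges", "FunctionalGraph", function(object) object@edges)
#' @rdname accessors
#' @export
setMethod("driverTable", "DriverReport", function(object) object@table)
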