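#' @rdname TrajectorySpec-class
#' @param x an object with an event grid.
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname TrajectorySpec-class
#' @export
setGeneric("nStages", function(x) standardGeneric("nStages"))

#' @rdname SubtypeModel-class
#' @param object a fitted model object.
#' @export
setGeneric("eventSequences", function(object) standardGeneric("eventSequences"))

#' @rdname SubtypeModel-class
#' @export
setGeneric("mixtureFractions",
           function(object) standardGeneric("mixtureFractions"))

#' @rdname SubtypeModel-class
#' @export
setGeneric("nSubtypes", function(object) standardGeneric("nSubtypes"))

#' @rdname ClusterSolution-class
#' @param object a clustering result.
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @rdname StabilityMatrix-class
#' @param object an object carrying a stability matrix.
#' @export
setGeneric("stabilityMatrix",
           function(object) standardGeneric("stabilityMatrix"))

#' @rdname ClusterSolution-class
#' @export
setGeneric("silhouetteCurve",
           function(object) standardGeneric("silhouetteCurve"))

#' @rdname ClusterSolution-class
#' @export
setGeneric("clusterMembers", function(object) standardGeneric("clusterMembers"))

#' @rdname SelectionResult-class
#' @param object a selection result.
#' @export
setGeneric("cvic", function(object) standardGeneric("cvic"))

#' @rdname SelectionResult-class
#' @export
setGeneric("chosenSubtypes", function(object) standardGeneric("chosenSubtypes"))
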