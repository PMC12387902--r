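#' @name accessors
#' @title Accessors for RorschachMap classes
#' @description Small accessor generics: slot access from user code should go
#'   through these rather than `@`.
#' @param x,object an object of the documented class.
#' @param ... further arguments for methods.
NULL

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname accessors
#' @export
setGeneric("cohortGroups", function(x) standardGeneric("cohortGroups"))

#' @rdname accessors
#' @export
setGeneric("variableNames", function(x) standardGeneric("variableNames"))

#' @rdname accessors
#' @export
setGeneric("cohortCounts", function(x) standardGeneric("cohortCounts"))

#' @rdname accessors
#' @export
setGeneric("scaledMatrix", function(x) standardGeneric("scaledMatrix"))

#' Normalized association matrix from a trained contractive map
#'
#' @param object a trained [AutoCMFit-class].
#' @param ... unused.
#' @return an [AssociationMatrix-class].
#' @export
setGeneric("associationMatrix",
           function(object, ...) standardGeneric("associationMatrix"))

#' @rdname accessors
#' @export
setGeneric("embeddingCoords", function(x) standardGeneric("embeddingCoords"))

#' @rdname accessors
#' @export
setGeneric("embeddingStress", function(x) standardGeneric("embeddingStress"))

#' @rdname accessors
#' @export
setGeneric("somCodebook", function(x) standardGeneric("somCodebook"))

#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setGeneric("trainingEpochs", function(x) standardGeneric("trainingEpochs"))

#' @rdname accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname accessors
#' @export
setGeneric("graphKind", function(x) standardGeneric("graphKind"))

#' @rdname accessors
#' @export
setGeneric("nodeDegrees", function(x) standardGeneric("nodeDegrees"))

#' @rdname accessors
#' @export
setGeneric("violationTable", function(x) standardGeneric("violationTable"))
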