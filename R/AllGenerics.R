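#' Accessor generics
#'
#' Small accessor family for the package's S4 classes: ids, grids, counts
#' and flags. Prefer these over direct slot access.
#'
#' @param x an object of one of the package's classes.
#' @return The requested component (ids, matrix, count or flag).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("itemIds", function(x) standardGeneric("itemIds"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setGeneric("groupOf", function(x) standardGeneric("groupOf"))

#' @rdname accessors
#' @export
setGeneric("referenceRule", function(x) standardGeneric("referenceRule"))

#' @rdname accessors
#' @export
setGeneric("trainingGroups", function(x) standardGeneric("trainingGroups"))

#' @rdname accessors
#' @export
setGeneric("referenceValues", function(x) standardGeneric("referenceValues"))

#' @rdname accessors
#' @export
setGeneric("excludedItems", function(x) standardGeneric("excludedItems"))

#' @rdname accessors
#' @export
setGeneric("centeredValues", function(x) standardGeneric("centeredValues"))

#' @rdname accessors
#' @export
setGeneric("nFunctional", function(x) standardGeneric("nFunctional"))

#' @rdname accessors
#' @export
setGeneric("trainingValues", function(x) standardGeneric("trainingValues"))

#' @rdname accessors
#' @export
setGeneric("nTraining", function(x) standardGeneric("nTraining"))

#' @rdname accessors
#' @export
setGeneric("trainingLabels", function(x) standardGeneric("trainingLabels"))

#' @rdname accessors
#' @export
setGeneric("axisLoadings", function(x) standardGeneric("axisLoadings"))

#' @rdname accessors
#' @export
setGeneric("leftVectors", function(x) standardGeneric("leftVectors"))

#' @rdname accessors
#' @export
setGeneric("singularValues", function(x) standardGeneric("singularValues"))

#' @rdname accessors
#' @export
setGeneric("nAxes", function(x) standardGeneric("nAxes"))

#' @rdname accessors
#' @export
setGeneric("referenceVector", function(x) standardGeneric("referenceVector"))

#' @rdname accessors
#' @export
setGeneric("componentScores", function(x) standardGeneric("componentScores"))

#' @rdname accessors
#' @export
setGeneric("isScaled", function(x) standardGeneric("isScaled"))

#' @rdname accessors
#' @export
setGeneric("rowKind", function(x) standardGeneric("rowKind"))

#' @rdname accessors
#' @export
setGeneric("filterTable", function(x) standardGeneric("filterTable"))
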