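#' @rdname ResponseMatrix-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("responses", function(object) standardGeneric("responses"))

#' @rdname ResponseMatrix-class
#' @export
setGeneric("groupLabels", function(object) standardGeneric("groupLabels"))

#' @rdname ResponseMatrix-class
#' @export
setGeneric("itemNames", function(object) standardGeneric("itemNames"))

#' @rdname ItemParameters-class
#' @export
setGeneric("discrimination", function(object) standardGeneric("discrimination"))

#' @rdname ItemParameters-class
#' @export
setGeneric("difficulty", function(object) standardGeneric("difficulty"))

#' @rdname ItemParameters-class
#' @export
setGeneric("scalingConstant", function(object) standardGeneric("scalingConstant"))

#' @rdname ItemParameters-class
#' @export
setGeneric("itemLoadings", function(object) standardGeneric("itemLoadings"))

#' @rdname ItemParameters-class
#' @export
setGeneric("itemCommunalities", function(object) standardGeneric("itemCommunalities"))

#' @rdname TwoPLFit-class
#' @export
setGeneric("itemParams", function(object) standardGeneric("itemParams"))

#' @rdname FitSummary-class
#' @export
setGeneric("fitSummary", function(object) standardGeneric("fitSummary"))

#' @rdname DIFTestResult-class
#' @export
setGeneric("difTable", function(object) standardGeneric("difTable"))

#' @rdname DIFTestResult-class
#' @export
setGeneric("anchorItems", function(object) standardGeneric("anchorItems"))

#' @rdname ClassificationIndices-class
#' @export
setGeneric("indicesTable", function(object) standardGeneric("indicesTable"))
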