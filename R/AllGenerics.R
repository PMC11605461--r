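#' @rdname CodeMap-class
#' @param object a `CodeMap`.
#' @export
setGeneric("vocabularySize", function(object) standardGeneric("vocabularySize"))

#' @rdname CodeMap-class
#' @export
setGeneric("groupIds", function(object) standardGeneric("groupIds"))

#' @rdname PathwaySet-class
#' @param object a `PathwaySet`.
#' @export
setGeneric("pathwayTokens", function(object) standardGeneric("pathwayTokens"))

#' @rdname PathwaySet-class
#' @export
setGeneric("pathwayInfo", function(object) standardGeneric("pathwayInfo"))

#' @rdname PathwaySet-class
#' @export
setGeneric("pathwayLabels", function(object) standardGeneric("pathwayLabels"))

#' @rdname Vocabulary-class
#' @param object a `Vocabulary`.
#' @export
setGeneric("vocabTokens", function(object) standardGeneric("vocabTokens"))

#' @rdname SeqModel-class
#' @param object a `SeqModel`.
#' @export
setGeneric("modelConfig", function(object) standardGeneric("modelConfig"))

#' @rdname SeqModel-class
#' @export
setGeneric("parameterCount", function(object) standardGeneric("parameterCount"))
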