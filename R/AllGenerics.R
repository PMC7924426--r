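#' Accessors for SymSlice classes
#'
#' @param object a SymSlice S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))

#' @rdname accessors
#' @export
setGeneric("isIsotropic", function(object) standardGeneric("isIsotropic"))

#' @rdname accessors
#' @export
setGeneric("planeNormal", function(object) standardGeneric("planeNormal"))

#' @rdname accessors
#' @export
setGeneric("planeOffset", function(object) standardGeneric("planeOffset"))

#' @rdname accessors
#' @export
setGeneric("axisU", function(object) standardGeneric("axisU"))

#' @rdname accessors
#' @export
setGeneric("axisV", function(object) standardGeneric("axisV"))

#' @rdname accessors
#' @export
setGeneric("residualRMS", function(object) standardGeneric("residualRMS"))

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("thresholds", function(object) standardGeneric("thresholds"))
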