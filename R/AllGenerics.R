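#' @rdname accessors
#' @export
setGeneric("estimate", function(object) standardGeneric("estimate"))
#' @rdname accessors
#' @export
setGeneric("stdError", function(object) standardGeneric("stdError"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("confInt", function(object) standardGeneric("confInt"))
#' @rdname accessors
#' @export
setGeneric("nSnps", function(object) standardGeneric("nSnps"))
#' @rdname accessors
#' @export
setGeneric("effectScale", function(object) standardGeneric("effectScale"))
#' @rdname accessors
#' @export
setGeneric("methodLabel", function(object) standardGeneric("methodLabel"))

#' @rdname instrumentset-accessors
#' @export
setGeneric("exposureName", function(object) standardGeneric("exposureName"))
#' @rdname instrumentset-accessors
#' @export
setGeneric("unitLabel", function(object) standardGeneric("unitLabel"))
#' @rdname instrumentset-accessors
#' @export
setGeneric("snpTable", function(object) standardGeneric("snpTable"))

#' @rdname harmonize
#' @export
setGeneric("harmonizedData",
           function(object, keep = c("retained", "all"))
             standardGeneric("harmonizedData"))
#' @rdname harmonize
#' @export
setGeneric("harmonizationAudit",
           function(object) standardGeneric("harmonizationAudit"))

#' @rdname mrIVW
#' @export
setGeneric("heterogeneity", function(object) standardGeneric("heterogeneity"))

#' @rdname mrPresso
#' @export
setGeneric("globalPvalue", function(object) standardGeneric("globalPvalue"))
#' @rdname mrPresso
#' @export
setGeneric("outliers", function(object) standardGeneric("outliers"))
#' @rdname mrPresso
#' @export
setGeneric("correctedEstimate",
           function(object) standardGeneric("correctedEstimate"))
#' @rdname mrPresso
#' @export
setGeneric("distortionPvalue",
           function(object) standardGeneric("distortionPvalue"))
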