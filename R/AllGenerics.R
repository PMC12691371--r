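# Accessor generics for the screen-design classes. Slot access stays
# internal; downstream code goes through these.

#' @rdname GuideLibrary-accessors
#' @export
setGeneric("guideIds", function(x) standardGeneric("guideIds"))

#' @rdname GuideLibrary-accessors
#' @export
setGeneric("targetGenes", function(x) standardGeneric("targetGenes"))

#' @rdname GuideLibrary-accessors
#' @export
setGeneric("guideRoles", function(x) standardGeneric("guideRoles"))

#' @rdname GuideLibrary-accessors
#' @export
setGeneric("safeGuides", function(x) standardGeneric("safeGuides"))

#' @rdname GuideLibrary-accessors
#' @export
setGeneric("nGuides", function(x) standardGeneric("nGuides"))

#' @rdname GuideLibrary-accessors
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname DualDesign-accessors
#' @export
setGeneric("constructIds", function(x) standardGeneric("constructIds"))

#' @rdname DualDesign-accessors
#' @export
setGeneric("pairLabels", function(x, ...) standardGeneric("pairLabels"))

#' @rdname DualDesign-accessors
#' @export
setGeneric("designCounts", function(x) standardGeneric("designCounts"))

#' @rdname DualDesign-accessors
#' @export
setGeneric("constructTable", function(x) standardGeneric("constructTable"))
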