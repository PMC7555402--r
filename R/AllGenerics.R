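#' @rdname CesmImagePair-accessors
#' @export
setGeneric("leImage", function(x) standardGeneric("leImage"))

#' @rdname CesmImagePair-accessors
#' @export
setGeneric("rcImage", function(x) standardGeneric("rcImage"))

#' @rdname CesmImagePair-accessors
#' @export
setGeneric("roiMask", function(x) standardGeneric("roiMask"))

#' @rdname CesmImagePair-accessors
#' @export
setGeneric("lesionIds", function(x) standardGeneric("lesionIds"))

#' @rdname CesmCohort-accessors
#' @export
setGeneric("lesionRecords", function(x) standardGeneric("lesionRecords"))

#' @rdname CesmCohort-accessors
#' @export
setGeneric("imagePairs", function(x) standardGeneric("imagePairs"))

#' @rdname RadiomicFeatureSet-accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Extract ROI pixel values from one image of a pair
#'
#' Returns exactly the pixel values where the mask is foreground, in
#' row-major (row-by-row, left-to-right) order.
#'
#' @param pair A \linkS4class{CesmImagePair}.
#' @param which \code{"LE"} or \code{"RC"}.
#' @return Numeric vector of length \code{sum(roiMask(pair))}.
#' @export
setGeneric("extractRoiPixels",
           function(pair, which = c("LE", "RC"))
               standardGeneric("extractRoiPixels"))
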