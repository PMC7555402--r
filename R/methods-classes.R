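#' Accessors for CesmImagePair
#'
#' @param x A \linkS4class{CesmImagePair}.
#' @return \code{leImage}, \code{rcImage}: numeric matrix; \code{roiMask}:
#'   logical matrix; \code{lesionIds}: character.
#' @name CesmImagePair-accessors
NULL

#' @rdname CesmImagePair-accessors
#' @export
setMethod("leImage", "CesmImagePair", function(x) x@le)

#' @rdname CesmImagePair-accessors
#' @export
setMethod("rcImage", "CesmImagePair", function(x) x@rc)

#' @rdname CesmImagePair-accessors
#' @export
setMethod("roiMask", "CesmImagePair", function(x) x@mask)

#' @rdname CesmImagePair-accessors
#' @export
setMethod("lesionIds", "CesmImagePair", function(x) x@lesionId)

setMethod("show", "CesmImagePair", function(object) {
    d <- dim(object@le)
    cat("CesmImagePair '", object@lesionId, "': ", d[1], "x", d[2],
        " LE/RC, ", sum(object@mask), " ROI pixels, ",
        object@bitDepth, "-bit\n", sep = "")
})

#' Accessors for CesmCohort
#'
#' @param x A \linkS4class{CesmCohort}.
#' @return \code{lesionRecords}: DataFrame of histology labels;
#'   \code{imagePairs}: SimpleList of \linkS4class{CesmImagePair};
#'   \code{lesionIds}: character vector.
#' @name CesmCohort-accessors
NULL

#' @rdname CesmCohort-accessors
#' @export
setMethod("lesionRecords", "CesmCohort", function(x) x@records)

#' @rdname CesmCohort-accessors
#' @export
setMethod("imagePairs", "CesmCohort", function(x) x@pairs)

#' @rdname CesmCohort-accessors
#' @export
setMethod("lesionIds", "CesmCohort",
          function(x) as.character(x@records$lesion_id))

#' @rdname CesmCohort-accessors
#' @param i Index (numeric, logical or lesion_id character).
#' @export
setMethod("[", "CesmCohort", function(x, i) {
    if (is.character(i)) i <- match(i, lesionIds(x))
    initialize(x, records = x@records[i, , drop = FALSE],
               pairs = x@pairs[i])
})

setMethod("length", "CesmCohort", function(x) nrow(x@records))

setMethod("show", "CesmCohort", function(object) {
    n <- length(object)
    cat("CesmCohort with", n, "lesions\n")
    if (n > 0) {
        d <- dim(object@pairs[[1]]@le)
        rec <- object@records
        cat(sprintf("  images: %dx%d LE/RC pairs\n", d[1], d[2]))
        cat(sprintf("  ER+ (>=1%%): %d | PR+ (>=20%%): %d | Ki67+ (>=20%%): %d | HER2+: %d | G3: %d\n",
                    sum(rec$er_pct >= 1), sum(rec$pr_pct >= 20),
                    sum(rec$ki67_pct >= 20), sum(rec$her2 == "+"),
                    sum(rec$grade == "G3")))
    }
})

setMethod("extractRoiPixels", "CesmImagePair", function(pair, which) {
    which <- match.arg(toupper(which), c("LE", "RC"))
    img <- if (which == "LE") pair@le else pair@rc
    # row-major: traverse rows, then columns; R matrices are column-major
    timg <- t(img)
    tmask <- t(pair@mask)
    as.numeric(timg[tmask])
})

#' Accessors for RadiomicFeatureSet
#'
#' @param x A \linkS4class{RadiomicFeatureSet}.
#' @return \code{featureMatrix}: lesions-in-rows numeric matrix (n x 14)
#'   convenient for model fitting; the assay itself is features x lesions.
#' @name RadiomicFeatureSet-accessors
NULL

#' @rdname RadiomicFeatureSet-accessors
#' @export
setMethod("featureMatrix", "RadiomicFeatureSet", function(x)
    t(SummarizedExperiment::assay(x, "features")))

setMethod("show", "TaskResult", function(object) {
    if (object@feasible)
        cat(sprintf("TaskResult %s: %d+/%d- , LOO AUC = %.2f%%\n",
                    object@task, object@nPos, object@nNeg, 100 * object@auc))
    else
        cat(sprintf("TaskResult %s: infeasible (%s)\n",
                    object@task, object@message))
})
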