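#' Canonical first-order radiomic feature names
#'
#' The fixed 14-column naming of the lesion feature vector: the seven
#' first-order statistics (Mean, VC, Max-Min, Skewness, Entropy,
#' RelativeSmoothness, Kurtosis) computed on the low-energy (\code{LE_})
#' and recombined (\code{RC_}) region of interest.
#'
#' @param prefix Optional subset: \code{"LE"}, \code{"RC"}, or \code{"both"}
#'   (default) for all 14 names in canonical order.
#' @return Character vector of feature names.
#' @export
#' @examples
#' cesmFeatureNames()
cesmFeatureNames <- function(prefix = c("both", "LE", "RC")) {
    prefix <- match.arg(prefix)
    base <- c("Mean", "VC", "Max-Min", "Skewness", "Entropy",
              "RelativeSmoothness", "Kurtosis")
    le <- paste0("LE_", base)
    rc <- paste0("RC_", base)
    switch(prefix, LE = le, RC = rc, both = c(le, rc))
}

#' Paired low-energy / recombined lesion image
#'
#' Holds one lesion's low-energy (LE) and recombined (RC) grayscale
#' images together with the shared binary region-of-interest mask.
#' LE pixels are non-negative integers at the stored bit depth; RC pixels
#' may be negative (subtraction imaging) and are never clipped.
#'
#' @slot lesionId Character scalar identifier.
#' @slot le Numeric matrix, low-energy image (non-negative).
#' @slot rc Numeric matrix, recombined image, same shape as \code{le}.
#' @slot mask Logical matrix, same shape; \code{TRUE} marks ROI pixels.
#' @slot bitDepth Integer, nominal bit depth of the acquisition.
#' @slot pixelRange Numeric length-2, representable (min, max) gray level,
#'   used to normalize intensities for relative smoothness.
#'
#' @export
setClass("CesmImagePair",
    representation(
        lesionId   = "character",
        le         = "matrix",
        rc         = "matrix",
        mask       = "matrix",
        bitDepth   = "integer",
        pixelRange = "numeric"
    )
)

setValidity("CesmImagePair", function(object) {
    msg <- character()
    if (length(object@lesionId) != 1L || is.na(object@lesionId) ||
        !nzchar(object@lesionId))
        msg <- c(msg, "lesionId must be a single non-empty string")
    d <- dim(object@le)
    if (!identical(d, dim(object@rc)) || !identical(d, dim(object@mask)))
        msg <- c(msg, sprintf(
            "lesion '%s': le, rc and mask must have identical shapes",
            object@lesionId))
    if (!is.logical(object@mask))
        msg <- c(msg, "mask must be a logical matrix")
    else if (sum(object@mask) < 16L)
        msg <- c(msg, sprintf(
            "lesion '%s': mask has %d foreground pixels; at least 16 are required for stable moments",
            object@lesionId, sum(object@mask)))
    if (any(object@le < 0))
        msg <- c(msg, sprintf("lesion '%s': LE image has negative pixels",
                              object@lesionId))
    if (length(object@pixelRange) != 2L ||
        object@pixelRange[2] <= object@pixelRange[1])
        msg <- c(msg, "pixelRange must be (min, max) with max > min")
    if (length(msg)) msg else TRUE
})

#' Construct a CesmImagePair
#'
#' @param lesionId Lesion identifier.
#' @param le,rc Numeric matrices of identical shape (LE non-negative).
#' @param mask Logical (or 0/1) matrix of the same shape, >= 16 foreground
#'   pixels.
#' @param bitDepth Nominal bit depth (default 16).
#' @param pixelRange Representable intensity range; defaults to
#'   \code{c(0, 2^bitDepth - 1)}.
#' @return A \linkS4class{CesmImagePair}.
#' @export
#' @examples
#' img <- matrix(100 + rnorm(400), 20, 20)
#' m <- matrix(FALSE, 20, 20); m[5:15, 5:15] <- TRUE
#' CesmImagePair("L001", le = abs(img), rc = img - 90, mask = m)
CesmImagePair <- function(lesionId, le, rc, mask, bitDepth = 16L,
                          pixelRange = c(0, 2^bitDepth - 1)) {
    if (!is.logical(mask)) {
        storage.mode(mask) <- "double"
        mask <- mask != 0
    }
    new("CesmImagePair", lesionId = as.character(lesionId),
        le = le, rc = rc, mask = mask,
        bitDepth = as.integer(bitDepth), pixelRange = as.numeric(pixelRange))
}

#' Cohort of lesions: histology table plus image pairs
#'
#' Aligned container for a CESM lesion cohort: one row of histology labels
#' (\code{er_pct}, \code{pr_pct}, \code{ki67_pct}, \code{her2},
#' \code{grade}) and one \linkS4class{CesmImagePair} per lesion, sorted by
#' \code{lesion_id}.
#'
#' @slot records A \link[S4Vectors]{DataFrame} with columns
#'   \code{lesion_id}, \code{patient_id}, \code{er_pct}, \code{pr_pct},
#'   \code{ki67_pct}, \code{her2} (\code{"+"}/\code{"-"}), \code{grade}
#'   (\code{"G1"}/\code{"G2"}/\code{"G3"}).
#' @slot pairs A \link[S4Vectors]{SimpleList} of
#'   \linkS4class{CesmImagePair}, parallel to \code{records}.
#' @export
setClass("CesmCohort",
    representation(records = "DFrame", pairs = "SimpleList")
)

.recordColumns <- c("lesion_id", "patient_id", "er_pct", "pr_pct",
                    "ki67_pct", "her2", "grade")

setValidity("CesmCohort", function(object) {
    msg <- character()
    rec <- object@records
    missing <- setdiff(.recordColumns, colnames(rec))
    if (length(missing))
        msg <- c(msg, paste("records lacks columns:",
                            paste(missing, collapse = ", ")))
    if (nrow(rec) != length(object@pairs))
        msg <- c(msg, "records and pairs disagree in length")
    if (!length(msg) && nrow(rec) > 0) {
        ids <- rec$lesion_id
        if (anyDuplicated(ids))
            msg <- c(msg, "duplicated lesion_id in records")
        pids <- vapply(object@pairs, function(p) p@lesionId, character(1))
        if (!identical(as.character(ids), pids))
            msg <- c(msg, "pairs are not aligned with records by lesion_id")
        if (any(rec$er_pct < 0 | rec$er_pct > 100, na.rm = TRUE) ||
            any(rec$pr_pct < 0 | rec$pr_pct > 100, na.rm = TRUE) ||
            any(rec$ki67_pct < 0 | rec$ki67_pct > 100, na.rm = TRUE))
            msg <- c(msg, "receptor percentages must lie in [0, 100]")
        if (!all(rec$her2 %in% c("+", "-")))
            msg <- c(msg, "her2 must be '+' or '-'")
        if (!all(rec$grade %in% c("G1", "G2", "G3")))
            msg <- c(msg, "grade must be one of G1, G2, G3")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a CesmCohort
#'
#' @param records data.frame or DataFrame of histology labels (see
#'   \linkS4class{CesmCohort}).
#' @param pairs List of \linkS4class{CesmImagePair} aligned with
#'   \code{records}.
#' @return A \linkS4class{CesmCohort}, sorted by \code{lesion_id}.
#' @export
CesmCohort <- function(records, pairs) {
    records <- as(as.data.frame(records), "DataFrame")
    if (nrow(records) > 0) {
        ord <- order(as.character(records$lesion_id))
        records <- records[ord, , drop = FALSE]
        pairs <- pairs[ord]
    }
    new("CesmCohort", records = records,
        pairs = S4Vectors::SimpleList(as.list(pairs)))
}

#' Lesion-by-feature radiomic data set
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} whose single
#' \code{"features"} assay holds the 14 first-order features (rows, in the
#' canonical \code{\link{cesmFeatureNames}} order) by lesion (columns);
#' \code{colData} carries the histology labels. Undefined features (e.g.
#' the variation coefficient at near-zero mean) are stored as \code{NA}.
#'
#' @export
setClass("RadiomicFeatureSet", contains = "SummarizedExperiment")

setValidity("RadiomicFeatureSet", function(object) {
    msg <- character()
    if (!"features" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'features' is required")
    else if (!identical(rownames(object), cesmFeatureNames()))
        msg <- c(msg, "rownames must be the 14 canonical feature names")
    if (length(msg)) msg else TRUE
})

#' Result of one binary classification task
#'
#' Leave-one-out linear-discriminant result for one binary histological or
#' molecular outcome: per-lesion cross-validated discriminant scores, the
#' ROC curve swept over all score thresholds, and its trapezoidal AUC.
#' An infeasible task (a class with fewer than 2 lesions) is flagged with
#' \code{feasible = FALSE} and carries a diagnostic message.
#'
#' @slot task Task name (\code{"ER"}, \code{"PR"}, \code{"Ki67"},
#'   \code{"Grade"}, \code{"TN"}, \code{"HER2"}).
#' @slot nPos,nNeg Class sizes.
#' @slot labels Integer 0/1 vector (1 = positive class), one per lesion.
#' @slot looScores Numeric cross-validated scores, parallel to
#'   \code{labels}.
#' @slot lesionIds Lesion identifiers, parallel to \code{labels}.
#' @slot rocPoints Two-column matrix (FPR, TPR) from (0,0) to (1,1).
#' @slot auc Area under the ROC curve in [0, 1].
#' @slot feasible Logical; FALSE when the task could not be evaluated.
#' @slot message Diagnostic for infeasible tasks ("" otherwise).
#' @export
setClass("TaskResult",
    representation(
        task      = "character",
        nPos      = "integer",
        nNeg      = "integer",
        labels    = "integer",
        looScores = "numeric",
        lesionIds = "character",
        rocPoints = "matrix",
        auc       = "numeric",
        feasible  = "logical",
        message   = "character"
    )
)

setValidity("TaskResult", function(object) {
    msg <- character()
    if (object@feasible) {
        if (length(object@looScores) != object@nPos + object@nNeg)
            msg <- c(msg, "looScores length must equal nPos + nNeg")
        rp <- object@rocPoints
        if (ncol(rp) != 2L ||
            any(rp[1, ] != 0) || any(rp[nrow(rp), ] != 1) ||
            any(diff(rp[, 1]) < 0) || any(diff(rp[, 2]) < 0))
            msg <- c(msg, "rocPoints must go monotonically from (0,0) to (1,1)")
        if (object@auc < 0 || object@auc > 1)
            msg <- c(msg, "auc must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})
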