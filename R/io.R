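#' Write a cohort to disk
#'
#' Serializes a \linkS4class{CesmCohort} to plain raster files: 16-bit
#' grayscale TIFF for the LE and RC images (the RC image, which may be
#' negative, is stored with an integer offset recorded in the manifest so
#' pixel values round-trip exactly), 8-bit PNG (0/255) for the masks, a
#' labels CSV with header
#' \code{lesion_id,patient_id,er_pct,pr_pct,ki67_pct,her2,grade}, and a
#' JSON manifest binding files to lesion ids and recording provenance.
#'
#' @param cohort A \linkS4class{CesmCohort}.
#' @param dir Output directory (created if needed).
#' @param provenance Named list stored verbatim in the manifest (e.g. the
#'   generating config and seed).
#' @return Path to the manifest JSON, invisibly.
#' @export
writeCohort <- function(cohort, dir, provenance = list()) {
    stopifnot(is(cohort, "CesmCohort"))
    dir.create(file.path(dir, "images"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(dir, "masks"), showWarnings = FALSE)
    rcOffset <- 32768L
    maxVal <- 65535
    entries <- lapply(as.list(imagePairs(cohort)), function(p) {
        id <- p@lesionId
        lePath <- file.path("images", paste0(id, "_LE.tif"))
        rcPath <- file.path("images", paste0(id, "_RC.tif"))
        maskPath <- file.path("masks", paste0(id, "_mask.png"))
        rcStored <- p@rc + rcOffset
        if (any(p@le > maxVal) || any(rcStored < 0) ||
            any(rcStored > maxVal))
            stop("lesion '", id, "': pixel values exceed the 16-bit ",
                 "storage range")
        tiff::writeTIFF(p@le / maxVal, file.path(dir, lePath),
                        bits.per.sample = 16L, compression = "none")
        tiff::writeTIFF(rcStored / maxVal, file.path(dir, rcPath),
                        bits.per.sample = 16L, compression = "none")
        png::writePNG(ifelse(p@mask, 1, 0), file.path(dir, maskPath))
        list(lesion_id = id, le_path = lePath, rc_path = rcPath,
             mask_path = maskPath, rc_offset = rcOffset,
             bit_depth = p@bitDepth)
    })
    labelsPath <- "labels.csv"
    utils::write.csv(as.data.frame(lesionRecords(cohort)),
                     file.path(dir, labelsPath),
                     row.names = FALSE, quote = FALSE)
    manifest <- list(entries = entries, labels_path = labelsPath,
                     provenance = provenance)
    manifestPath <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(manifestPath)
}

.readGray <- function(path, asIs = TRUE) {
    lp <- tolower(path)
    img <- if (grepl("\\.tiff?$", lp)) {
        tiff::readTIFF(path, as.is = asIs)
    } else if (grepl("\\.png$", lp)) {
        x <- png::readPNG(path, info = TRUE)
        depth <- attr(x, "info")$bit.depth
        round(x * (2^depth - 1))
    } else stop("unsupported image format: ", path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    matrix(as.numeric(img), nrow(img), ncol(img))
}

#' Load a cohort from a manifest
#'
#' Reads the on-disk representation written by \code{\link{writeCohort}}
#' (or any manifest following the same schema) back into a validated
#' \linkS4class{CesmCohort}, aligned and sorted by \code{lesion_id}.
#' PNG/TIFF pixels are used at their stored integer values; a recorded
#' \code{rc_offset} is subtracted from the RC image to restore negative
#' subtraction values. Shape mismatches, empty masks, unreadable files
#' and manifest/labels mismatches are reported as errors naming the
#' offending lesion or path.
#'
#' @param manifestPath Path to the manifest JSON.
#' @return A \linkS4class{CesmCohort} (empty manifest gives an empty
#'   cohort).
#' @export
loadCohort <- function(manifestPath) {
    if (!file.exists(manifestPath))
        stop("manifest not found: ", manifestPath)
    manifest <- jsonlite::read_json(manifestPath)
    dir <- dirname(manifestPath)
    labels <- utils::read.csv(file.path(dir, manifest$labels_path),
                              stringsAsFactors = FALSE,
                              colClasses = c(lesion_id = "character",
                                             patient_id = "character",
                                             her2 = "character",
                                             grade = "character"))
    entries <- manifest$entries
    if (length(entries) == 0L) {
        if (nrow(labels) > 0L)
            stop("labels table has ", nrow(labels),
                 " lesions missing from the manifest")
        empty <- labels[0, .recordColumns]
        return(CesmCohort(empty, list()))
    }
    ids <- vapply(entries, function(e) e$lesion_id, character(1))
    if (anyDuplicated(ids))
        stop("duplicated lesion_id in manifest: ",
             ids[duplicated(ids)][1])
    if (!setequal(ids, labels$lesion_id))
        stop("manifest and labels table disagree: missing from labels: [",
             paste(setdiff(ids, labels$lesion_id), collapse = ", "),
             "]; missing from manifest: [",
             paste(setdiff(labels$lesion_id, ids), collapse = ", "), "]")
    pairs <- lapply(entries, function(e) {
        id <- e$lesion_id
        readOne <- function(rel) {
            path <- file.path(dir, rel)
            if (!file.exists(path))
                stop("lesion '", id, "': file not found: ", path)
            tryCatch(.readGray(path),
                     error = function(err) stop(
                         "lesion '", id, "': unreadable image ", path,
                         " (", conditionMessage(err), ")", call. = FALSE))
        }
        le <- readOne(e$le_path)
        rc <- readOne(e$rc_path)
        mask <- readOne(e$mask_path) != 0
        if (!identical(dim(le), dim(rc)) ||
            !identical(dim(le), dim(mask)))
            stop("lesion '", id,
                 "': LE/RC/mask shapes do not match")
        if (sum(mask) < 16L)
            stop("lesion '", id, "': mask has ", sum(mask),
                 " foreground pixels (>= 16 required)")
        offset <- if (is.null(e$rc_offset)) 0 else e$rc_offset
        bitDepth <- if (is.null(e$bit_depth)) 16L else
            as.integer(e$bit_depth)
        CesmImagePair(id, le = le, rc = rc - offset, mask = mask,
                      bitDepth = bitDepth)
    })
    labels <- labels[match(ids, labels$lesion_id), , drop = FALSE]
    CesmCohort(labels, pairs)
}
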