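#' Seven first-order gray-level statistics of an ROI
#'
#' Computes the first-order radiomic features of a region of interest from
#' its raw pixel values: arithmetic mean; variation coefficient
#' (VC = sigma/mu); gray-level range (max - min); skewness (m3/sigma^3);
#' histogram entropy over \code{nBins} equal-width bins spanning the ROI's
#' own [min, max]; relative smoothness 1 - 1/(1 + sigma_norm^2) where
#' sigma_norm is the standard deviation of the pixels after linear
#' rescaling of the representable range to [0, 1]; and kurtosis
#' (m4/sigma^4, non-excess). Moments are population moments by default
#' (divisor n), switchable to sample moments.
#'
#' Degenerate inputs are flagged rather than propagated as infinities:
#' VC is \code{NA} when |mu| falls below \code{epsilon} (a fraction of the
#' representable range, relevant for near-zero-mean recombined images);
#' skewness and kurtosis are \code{NA} when sigma = 0; entropy is 0 by
#' convention when max = min.
#'
#' @param pixels Numeric vector of ROI pixel values (>= 16 values for
#'   stable moments; shorter vectors are accepted with a warning-free
#'   best-effort computation so unit-scale examples remain usable).
#' @param nBins Number of equal-width histogram bins for entropy
#'   (default 256).
#' @param pixelRange Representable (min, max) gray level of the image,
#'   used only by relative smoothness and the VC epsilon.
#' @param epsilonFrac |mean| below \code{epsilonFrac * diff(pixelRange)}
#'   flags VC as undefined. Default 1e-9.
#' @param sampleMoments Use divisor n-1 (and the adjusted standardized
#'   moment estimators) instead of population moments. Default FALSE.
#' @param excessKurtosis Report kurtosis - 3. Default FALSE.
#' @param logBase Base of the entropy logarithm (default 2: bits).
#' @return Named numeric of length 7: \code{Mean}, \code{VC},
#'   \code{Max-Min}, \code{Skewness}, \code{Entropy},
#'   \code{RelativeSmoothness}, \code{Kurtosis}.
#' @export
#' @examples
#' firstOrderFeatures(c(0, 0, 1, 1), nBins = 2, pixelRange = c(0, 1))
firstOrderFeatures <- function(pixels, nBins = 256L,
                               pixelRange = c(0, 65535),
                               epsilonFrac = 1e-9,
                               sampleMoments = FALSE,
                               excessKurtosis = FALSE,
                               logBase = 2) {
    stopifnot(is.numeric(pixels), length(pixels) >= 2L, nBins >= 2L,
              all(is.finite(pixels)))
    n <- length(pixels)
    mu <- mean(pixels)
    dev <- pixels - mu
    if (sampleMoments) {
        s2 <- sum(dev^2) / (n - 1)
        sigma <- sqrt(s2)
        # adjusted Fisher-Pearson standardized moments
        skew <- if (sigma > 0)
            (n / ((n - 1) * (n - 2))) * sum(dev^3) / sigma^3 else NA_real_
        kurt <- if (sigma > 0)
            sum(dev^4) / ((n - 1) * s2^2) else NA_real_
    } else {
        s2 <- sum(dev^2) / n
        sigma <- sqrt(s2)
        skew <- if (sigma > 0) (sum(dev^3) / n) / sigma^3 else NA_real_
        kurt <- if (sigma > 0) (sum(dev^4) / n) / sigma^4 else NA_real_
    }
    if (!is.na(kurt) && excessKurtosis) kurt <- kurt - 3
    rangeWidth <- diff(pixelRange)
    eps <- epsilonFrac * rangeWidth
    # constant input also flags VC: a degenerate ROI carries no dispersion
    # information and a hard 0 would silently dominate downstream models
    vc <- if (abs(mu) <= eps || sigma == 0) NA_real_ else sigma / mu
    mn <- min(pixels); mx <- max(pixels)
    ent <- .histogramEntropy(pixels, nBins, logBase)
    sigmaNorm <- sigma / rangeWidth
    rs <- 1 - 1 / (1 + sigmaNorm^2)
    c("Mean" = mu, "VC" = vc, "Max-Min" = mx - mn, "Skewness" = skew,
      "Entropy" = ent, "RelativeSmoothness" = rs, "Kurtosis" = kurt)
}

# Shannon entropy of the equal-width histogram over [min, max] of the
# values themselves; max == min collapses to a single bin (entropy 0).
.histogramEntropy <- function(pixels, nBins, logBase = 2) {
    mn <- min(pixels); mx <- max(pixels)
    if (mx == mn) return(0)
    width <- (mx - mn) / nBins
    idx <- floor((pixels - mn) / width) + 1L
    idx[idx > nBins] <- nBins  # x == max falls into the last bin
    p <- tabulate(idx, nbins = as.integer(nBins)) / length(pixels)
    p <- p[p > 0]
    -sum(p * log(p, base = logBase))
}

#' Extract the 14-feature vectors of a cohort
#'
#' Applies \code{\link{firstOrderFeatures}} to the LE and RC ROI pixels of
#' every lesion, producing the canonical lesion-by-feature data set.
#' Lesions with undefined features (near-zero mean for VC, zero variance
#' for skewness/kurtosis) keep \code{NA} in those cells and are reported
#' via a message.
#'
#' @param x A \linkS4class{CesmCohort} or a list of
#'   \linkS4class{CesmImagePair}.
#' @param nBins,epsilonFrac,sampleMoments,excessKurtosis,logBase Passed to
#'   \code{\link{firstOrderFeatures}}.
#' @param records Optional histology table when \code{x} is a bare list of
#'   pairs; taken from the cohort otherwise.
#' @return A \linkS4class{RadiomicFeatureSet} (features x lesions), with
#'   the histology labels in \code{colData} when available.
#' @export
extractFeatures <- function(x, nBins = 256L, epsilonFrac = 1e-9,
                            sampleMoments = FALSE, excessKurtosis = FALSE,
                            logBase = 2, records = NULL) {
    if (is(x, "CesmCohort")) {
        records <- lesionRecords(x)
        pairs <- as.list(imagePairs(x))
    } else {
        pairs <- as.list(x)
    }
    if (length(pairs) == 0L)
        stop("no image pairs to extract features from")
    featOne <- function(pair) {
        vals <- lapply(c("LE", "RC"), function(w) {
            px <- extractRoiPixels(pair, w)
            firstOrderFeatures(px, nBins = nBins,
                               pixelRange = pair@pixelRange,
                               epsilonFrac = epsilonFrac,
                               sampleMoments = sampleMoments,
                               excessKurtosis = excessKurtosis,
                               logBase = logBase)
        })
        c(vals[[1]], vals[[2]])
    }
    mat <- vapply(pairs, featOne, numeric(14L))
    rownames(mat) <- cesmFeatureNames()
    colnames(mat) <- vapply(pairs, function(p) p@lesionId, character(1))
    nMissing <- sum(is.na(mat))
    if (nMissing > 0) {
        bad <- colnames(mat)[colSums(is.na(mat)) > 0]
        message(sprintf(
            "%d undefined feature value(s) in %d lesion(s): %s",
            nMissing, length(bad), paste(bad, collapse = ", ")))
    }
    cd <- if (!is.null(records)) as(as.data.frame(records), "DataFrame")
          else S4Vectors::DataFrame(lesion_id = colnames(mat))
    rownames(cd) <- colnames(mat)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(features = mat), colData = cd,
        metadata = list(nBins = nBins, epsilonFrac = epsilonFrac,
                        sampleMoments = sampleMoments,
                        excessKurtosis = excessKurtosis,
                        logBase = logBase))
    new("RadiomicFeatureSet", se)
}

#' Write a feature matrix as CSV
#'
#' One row per lesion: \code{lesion_id} followed by the 14 canonical
#' feature columns; undefined values are written as empty cells.
#'
#' @param fs A \linkS4class{RadiomicFeatureSet}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureCsv <- function(fs, path) {
    m <- featureMatrix(fs)
    df <- data.frame(lesion_id = rownames(m), m, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE,
                     fileEncoding = "UTF-8")
    invisible(path)
}
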