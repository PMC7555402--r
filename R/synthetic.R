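#' Default histology label model for synthetic cohorts
#'
#' Marginal distributions emulating the class balance of a typical
#' malignant CESM cohort of 68 lesions: ER positive (>= 1\%) in 58/68,
#' PR positive (>= 20\%) in 33/68, Ki67 positive (>= 20\%) in 47/68,
#' HER2 positive in 16/68, grade G1/G2/G3 in proportions 14/28/26.
#' Receptor percentages are drawn from piecewise power-law marginals (a
#' below-cutoff segment and an above-cutoff segment, each a power-shaped
#' rescaling of the uniform) coupled by a Gaussian copula; ER and PR are
#' positively dependent (copula correlation 0.6), reflecting their strong
#' clinical co-expression, which also raises the triple-negative fraction
#' above the independence value.
#'
#' @return A list with components \code{er}, \code{pr}, \code{ki67}
#'   (each \code{list(negFrac, cutoff, negShape, posShape)}),
#'   \code{her2Prob}, \code{gradeProbs} (named G1/G2/G3, summing to 1)
#'   and \code{copula} (named correlations \code{er_pr}, \code{er_ki67},
#'   \code{pr_ki67}).
#' @export
defaultLabelModel <- function() {
    list(
        er   = list(negFrac = 10 / 68, cutoff = 1,  negShape = 1, posShape = 0.35),
        pr   = list(negFrac = 35 / 68, cutoff = 20, negShape = 1, posShape = 0.8),
        ki67 = list(negFrac = 21 / 68, cutoff = 20, negShape = 1, posShape = 0.9),
        her2Prob   = 16 / 68,
        gradeProbs = c(G1 = 14, G2 = 28, G3 = 26) / 68,
        copula     = c(er_pr = 0.6, er_ki67 = 0, pr_ki67 = 0)
    )
}

# quantile function of one piecewise power-law percentage marginal
.labelQuantile <- function(u, m) {
    below <- u < m$negFrac
    q <- numeric(length(u))
    q[below] <- m$cutoff * (1 - 1e-9) * (u[below] / m$negFrac)^m$negShape
    q[!below] <- m$cutoff +
        (100 - m$cutoff) * ((u[!below] - m$negFrac) / (1 - m$negFrac))^m$posShape
    q
}

# population mean and sd of a percentage marginal, by quadrature on a
# fixed midpoint grid (deterministic; no RNG involved)
.labelMoments <- function(m, K = 16384L) {
    u <- (seq_len(K) - 0.5) / K
    q <- .labelQuantile(u, m)
    mu <- mean(q)
    list(mean = mu, sd = sqrt(mean((q - mu)^2)))
}

#' Configuration of a synthetic CESM cohort
#'
#' Bundles everything that defines a reproducible synthetic cohort:
#' cohort size, root RNG seed, image geometry, the histology label model,
#' the planted feature-label effects, and the texture noise scale.
#'
#' The in-ROI texture of each image is a skew-normal random field whose
#' location (mean), scale (standard deviation) and shape (asymmetry) are
#' affine in per-lesion latent variables; \code{effectMap} ties those
#' latents to standardized histology labels so that the population
#' correlation between a label and a downstream *extracted* feature
#' equals the requested target (continuous labels: Pearson correlation in
#' (-1, 1); binary labels \code{her2}/\code{grade}: standardized mean
#' difference). Targets are divided by stored per-feature calibration
#' constants that compensate the attenuation introduced by finite-ROI
#' sampling noise and the mild non-linearity of the feature maps (see
#' \code{inst/scripts/calibrate_effects.R}).
#'
#' @param nLesions Number of lesions (default 68).
#' @param seed Integer root seed; all randomness derives from it through
#'   one L'Ecuyer-CMRG root stream plus one child stream per lesion.
#' @param imageSize Pixels per side of the square frames (default 64).
#' @param roiRadiusPx Radius of the disc ROI in pixels (default 18); the
#'   disc must fit fully inside the frame.
#' @param labelModel As \code{\link{defaultLabelModel}}.
#' @param effectMap \code{NULL} (no planted effects) or a data.frame with
#'   columns \code{label} (one of \code{er_pct}, \code{pr_pct},
#'   \code{ki67_pct}, \code{her2}, \code{grade}), \code{feature} (one of
#'   \code{\link{cesmFeatureNames}()}) and \code{effect}.
#' @param noiseSd Baseline in-ROI texture standard deviation in gray
#'   levels (default 3000 on the 16-bit scale); 0 gives noise-free
#'   constant-intensity ROIs.
#' @param texture Baseline texture parameters: per-image background mean
#'   and sd and ROI mean, plus the latent sensitivities (\code{locK},
#'   \code{scaleK} as fractions of \code{noiseSd}, \code{shapeK} on the
#'   skew-normal shape, baseline shape \code{shape0}).
#' @return A validated list of class \code{"CohortConfig"}.
#' @export
#' @examples
#' cfg <- cohortConfig(nLesions = 8, seed = 1)
cohortConfig <- function(nLesions = 68L, seed = 1L,
                         imageSize = 64L, roiRadiusPx = 18L,
                         labelModel = defaultLabelModel(),
                         effectMap = NULL,
                         noiseSd = 3000,
                         texture = list(
                             le = list(bgMean = 12000, bgSd = 800, roiMean = 30000),
                             rc = list(bgMean = 0,     bgSd = 150, roiMean = 8000),
                             shape0 = 2.0, locK = 0.25, scaleK = 0.25,
                             shapeK = 1.0, quant0 = 250, quantK = 80)) {
    cfg <- list(nLesions = as.integer(nLesions), seed = as.integer(seed),
                imageSize = as.integer(imageSize),
                roiRadiusPx = as.integer(roiRadiusPx),
                labelModel = labelModel, effectMap = effectMap,
                noiseSd = noiseSd, texture = texture,
                bitDepth = 16L, rngKind = "L'Ecuyer-CMRG")
    class(cfg) <- "CohortConfig"
    validateCohortConfig(cfg)
    cfg
}

#' Validate a cohort configuration
#'
#' Checks structural invariants (grade probabilities summing to 1, ROI
#' disc fitting inside the frame) and the feasibility of the planted
#' effect map: every target must be attainable after calibration and the
#' implied latent correlation structure must be positive semi-definite.
#' Infeasible entries are rejected with a diagnostic naming the offending
#' (label, feature, effect) triple.
#'
#' @param config A \code{"CohortConfig"} list.
#' @return \code{config}, invisibly, or an error.
#' @export
validateCohortConfig <- function(config) {
    stopifnot(inherits(config, "CohortConfig"))
    lm <- config$labelModel
    if (config$nLesions < 1L)
        stop("nLesions must be positive")
    if (abs(sum(lm$gradeProbs) - 1) > 1e-12)
        stop("grade probabilities must sum to 1 (got ",
             format(sum(lm$gradeProbs), digits = 17), ")")
    if (any(lm$gradeProbs < 0))
        stop("grade probabilities must be non-negative")
    if (lm$her2Prob <= 0 || lm$her2Prob >= 1)
        stop("her2Prob must lie strictly in (0, 1)")
    if (config$roiRadiusPx < 3L)
        stop("roiRadiusPx must be at least 3 (>= 16 ROI pixels)")
    if (config$roiRadiusPx > config$imageSize / 2 - 1)
        stop(sprintf(
            "roiRadiusPx = %d does not fit inside a %dx%d frame",
            config$roiRadiusPx, config$imageSize, config$imageSize))
    if (config$noiseSd < 0)
        stop("noiseSd must be non-negative")
    .resolveEffects(config)  # errors on any infeasible planted effect
    invisible(config)
}

## Effect-planting machinery ------------------------------------------------

# Which latent texture parameter drives each feature family. Entropy is
# driven by the gray-level granularity latent, not the scale: histogram
# entropy over bins spanning the ROI's own [min, max] is scale-invariant,
# so the field's standard deviation cannot move it.
.featureLatent <- c(
    "Mean" = "loc", "VC" = "scale", "Max-Min" = "scale",
    "Skewness" = "shape", "Entropy" = "ent",
    "RelativeSmoothness" = "scale", "Kurtosis" = "shape")

# Calibration constants: Pearson correlation between each extracted
# feature and its driving latent under the default generator settings
# (64x64 frames, radius-18 ROI, noiseSd 3000), estimated at n = 40000 by
# inst/scripts/calibrate_effects.R. Planted targets are divided by these.
.featureAttenuation <- c(
    "LE_Mean" = 0.992, "LE_VC" = 0.990, "LE_Max-Min" = 0.946,
    "LE_Skewness" = 0.921, "LE_Entropy" = 0.772,
    "LE_RelativeSmoothness" = 0.979, "LE_Kurtosis" = 0.580,
    "RC_Mean" = 0.992, "RC_VC" = 0.925, "RC_Max-Min" = 0.947,
    "RC_Skewness" = 0.921, "RC_Entropy" = 0.770,
    "RC_RelativeSmoothness" = 0.979, "RC_Kurtosis" = 0.585)

.validEffectLabels <- c("er_pct", "pr_pct", "ki67_pct", "her2", "grade")

# population prevalence of the positive class for binary planted labels
.binaryPrevalence <- function(label, lm) {
    if (label == "her2") lm$her2Prob else unname(lm$gradeProbs["G3"])
}

# approximate correlation matrix of the standardized label scores; the
# Gaussian-copula correlation is used for the continuous trio (a close
# upper bound on the induced Pearson correlation) and binary labels are
# independent of everything under the default model
.labelScoreCorrelation <- function(lm) {
    R <- diag(5)
    rownames(R) <- colnames(R) <- .validEffectLabels
    cp <- lm$copula
    R["er_pct", "pr_pct"] <- R["pr_pct", "er_pct"] <- cp[["er_pr"]]
    R["er_pct", "ki67_pct"] <- R["ki67_pct", "er_pct"] <- cp[["er_ki67"]]
    R["pr_pct", "ki67_pct"] <- R["ki67_pct", "pr_pct"] <- cp[["pr_ki67"]]
    R
}

# Resolve the effect map into per-latent label loadings.
# Returns a list keyed by latent name ("LE_loc", "RC_scale", ...), each a
# list(loadings = named numeric over labels, resid = residual sd).
.resolveEffects <- function(config) {
    em <- config$effectMap
    out <- list()
    if (is.null(em) || nrow(em) == 0L) return(out)
    stopifnot(all(c("label", "feature", "effect") %in% colnames(em)))
    lm <- config$labelModel
    R <- .labelScoreCorrelation(lm)
    claimedBy <- list()  # latent -> feature that claimed it, per label set
    for (k in seq_len(nrow(em))) {
        lab <- as.character(em$label[k])
        feat <- as.character(em$feature[k])
        eff <- as.numeric(em$effect[k])
        triple <- sprintf("(%s, %s, %g)", lab, feat, eff)
        if (!lab %in% .validEffectLabels)
            stop("effectMap entry ", triple, ": unknown label")
        if (!feat %in% cesmFeatureNames())
            stop("effectMap entry ", triple, ": unknown feature")
        base <- sub("^(LE|RC)_", "", feat)
        img <- sub("_.*$", "", feat)
        latent <- paste0(img, "_", .featureLatent[[base]])
        if (lab %in% c("her2", "grade")) {
            # standardized mean difference -> point-biserial correlation
            pi <- .binaryPrevalence(lab, lm)
            rho <- eff / sqrt(eff^2 + 1 / (pi * (1 - pi)))
        } else {
            rho <- eff
            if (abs(rho) >= 1)
                stop("effectMap entry ", triple,
                     ": |correlation| must be < 1")
        }
        rhoPrime <- rho / .featureAttenuation[[feat]]
        if (abs(rhoPrime) >= 1)
            stop("effectMap entry ", triple,
                 ": target not attainable after calibration (needs latent loading ",
                 format(rhoPrime, digits = 3), ")")
        prev <- claimedBy[[latent]]
        if (!is.null(prev) && prev != feat)
            stop("effectMap entries for features '", prev, "' and '", feat,
                 "' both drive the ", latent,
                 " latent; their joint correlation structure is inconsistent (entry ",
                 triple, ")")
        claimedBy[[latent]] <- feat
        if (is.null(out[[latent]]))
            out[[latent]] <- list(loadings = structure(
                numeric(5), names = .validEffectLabels))
        if (out[[latent]]$loadings[lab] != 0)
            stop("duplicate effectMap entry for label '", lab,
                 "' on latent ", latent, " (entry ", triple, ")")
        out[[latent]]$loadings[lab] <- rhoPrime
    }
    for (latent in names(out)) {
        w <- out[[latent]]$loadings
        v <- drop(t(w) %*% R %*% w)
        if (v > 1) {
            inv <- paste(sprintf("(%s -> %s)",
                                 names(w)[w != 0], latent), collapse = ", ")
            stop("effectMap is jointly inconsistent: implied latent ",
                 "correlation structure for ", latent,
                 " is not positive semi-definite (loadings ", inv,
                 " have quadratic form ", format(v, digits = 4), " > 1)")
        }
        out[[latent]]$resid <- sqrt(max(0, 1 - v))
    }
    out
}

# standardized label scores for one or more records
.labelScores <- function(records, lm) {
    scoreCont <- function(x, m) {
        mom <- .labelMoments(m)
        (x - mom$mean) / mom$sd
    }
    her2 <- as.numeric(records$her2 == "+")
    g3 <- as.numeric(records$grade == "G3")
    piH <- lm$her2Prob
    piG <- unname(lm$gradeProbs["G3"])
    cbind(
        er_pct   = scoreCont(records$er_pct, lm$er),
        pr_pct   = scoreCont(records$pr_pct, lm$pr),
        ki67_pct = scoreCont(records$ki67_pct, lm$ki67),
        her2     = (her2 - piH) / sqrt(piH * (1 - piH)),
        grade    = (g3 - piG) / sqrt(piG * (1 - piG)))
}

## Texture field ------------------------------------------------------------

# Skew-normal deviates with exact zero mean and unit sd for any shape:
# z = delta|z0| + sqrt(1-delta^2) z1, centered and rescaled.
.rskewnorm <- function(n, shape) {
    delta <- shape / sqrt(1 + shape^2)
    z0 <- abs(stats::rnorm(n))
    z1 <- stats::rnorm(n)
    z <- delta * z0 + sqrt(1 - delta^2) * z1
    muz <- delta * sqrt(2 / pi)
    sz <- sqrt(1 - 2 * delta^2 / pi)
    (z - muz) / sz
}

# filled-disc ROI mask, centered in the frame
.discMask <- function(size, radius) {
    ctr <- (size + 1) / 2
    d2 <- outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, `+`)
    d2 <= radius^2
}

#' Render one lesion's LE/RC image pair
#'
#' Draws the paired low-energy and recombined images of one lesion from
#' the generator's texture model: an unstructured Gaussian background
#' (independent of the histology labels) and a skew-normal in-ROI field
#' whose mean, standard deviation and asymmetry are affine in per-lesion
#' latents tied to the lesion's standardized labels through the planted
#' effect map. The recombined image mimics subtraction imaging: its
#' background is centered at zero (negative pixels are produced and
#' preserved) and only the ROI carries enhancement. Pixels are rounded to
#' integers; the LE image is clamped to the representable range.
#'
#' @param record One-row data.frame (or list) with the lesion's labels
#'   (\code{er_pct}, \code{pr_pct}, \code{ki67_pct}, \code{her2},
#'   \code{grade}) and \code{lesion_id}.
#' @param config A \code{"CohortConfig"}.
#' @param rngState Optional \code{.Random.seed} vector (L'Ecuyer-CMRG
#'   state) giving the lesion's private random stream; the same state
#'   reproduces the identical pair. \code{NULL} uses the current RNG.
#' @return A \linkS4class{CesmImagePair}.
#' @export
renderLesionPair <- function(record, config, rngState = NULL) {
    stopifnot(inherits(config, "CohortConfig"))
    record <- as.data.frame(record)
    if (any(c(record$er_pct, record$pr_pct, record$ki67_pct) < 0) ||
        any(c(record$er_pct, record$pr_pct, record$ki67_pct) > 100))
        stop("record labels out of range for lesion ", record$lesion_id)
    if (!is.null(rngState)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv())
        })
        assign(".Random.seed", rngState, envir = globalenv())
    }
    size <- config$imageSize
    mask <- .discMask(size, config$roiRadiusPx)
    nRoi <- sum(mask)
    eff <- .resolveEffects(config)
    s <- .labelScores(record, config$labelModel)[1, ]
    tx <- config$texture
    latent <- function(key) {
        e <- stats::rnorm(1)  # lesion-level heterogeneity, always consumed
        if (is.null(eff[[key]])) e
        else sum(eff[[key]]$loadings * s) + eff[[key]]$resid * e
    }
    drawImage <- function(side, bg) {
        # latent draw order is fixed: loc, scale, shape, ent, then pixels
        tLoc <- latent(paste0(side, "_loc"))
        tScale <- latent(paste0(side, "_scale"))
        tShape <- latent(paste0(side, "_shape"))
        tEnt <- latent(paste0(side, "_ent"))
        xi <- bg$roiMean + tx$locK * config$noiseSd * tLoc
        omega <- config$noiseSd * max(0.05, 1 + tx$scaleK * tScale)
        if (config$noiseSd == 0) omega <- 0
        alpha <- tx$shape0 + tx$shapeK * tShape
        # gray-level granularity: the in-ROI texture is quantized to a
        # per-lesion step, the designated driver of histogram entropy
        # (larger step -> fewer occupied bins -> lower entropy)
        quant <- max(8, tx$quant0 - tx$quantK * tEnt)
        img <- matrix(stats::rnorm(size * size, bg$bgMean, bg$bgSd),
                      size, size)
        roi <- xi + omega * .rskewnorm(nRoi, alpha)
        img[mask] <- round(roi / quant) * quant
        round(img)
    }
    le <- drawImage("LE", tx$le)
    rc <- drawImage("RC", tx$rc)
    maxVal <- 2^config$bitDepth - 1
    le[le < 0] <- 0
    le[le > maxVal] <- maxVal
    CesmImagePair(record$lesion_id, le = le, rc = rc, mask = mask,
                  bitDepth = config$bitDepth,
                  pixelRange = c(0, maxVal))
}

#' Generate a complete synthetic CESM cohort
#'
#' Draws the histology table from the label model (Gaussian copula over
#' the receptor percentages, independent HER2 and grade) and renders one
#' LE/RC image pair per lesion. All randomness stems from the root seed
#' through the L'Ecuyer-CMRG generator: the labels use the root stream
#' and each lesion's images use their own child stream, so the cohort is
#' byte-identical across runs and stable under per-lesion parallelism.
#' The caller's global RNG state is left untouched.
#'
#' @param config A \code{"CohortConfig"} from \code{\link{cohortConfig}}.
#' @return A \linkS4class{CesmCohort} with \code{config$nLesions} lesions
#'   (one synthetic patient per lesion).
#' @export
#' @examples
#' coh <- generateCohort(cohortConfig(nLesions = 4, seed = 7))
#' coh
generateCohort <- function(config) {
    validateCohortConfig(config)
    n <- config$nLesions
    lm <- config$labelModel
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    oldKind <- RNGkind()
    on.exit({
        RNGkind(oldKind[1], oldKind[2], oldKind[3])
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    suppressWarnings(RNGkind("L'Ecuyer-CMRG"))
    set.seed(config$seed)

    # histology labels from the root stream
    R3 <- diag(3)
    cp <- lm$copula
    R3[1, 2] <- R3[2, 1] <- cp[["er_pr"]]
    R3[1, 3] <- R3[3, 1] <- cp[["er_ki67"]]
    R3[2, 3] <- R3[3, 2] <- cp[["pr_ki67"]]
    L <- chol(R3)
    z <- matrix(stats::rnorm(3 * n), n, 3) %*% L
    u <- stats::pnorm(z)
    width <- max(3L, nchar(as.character(n)))
    records <- data.frame(
        lesion_id  = sprintf(paste0("L%0", width, "d"), seq_len(n)),
        patient_id = sprintf(paste0("P%0", width, "d"), seq_len(n)),
        er_pct   = .labelQuantile(u[, 1], lm$er),
        pr_pct   = .labelQuantile(u[, 2], lm$pr),
        ki67_pct = .labelQuantile(u[, 3], lm$ki67),
        her2  = ifelse(stats::runif(n) < lm$her2Prob, "+", "-"),
        grade = c("G1", "G2", "G3")[
            1L + findInterval(stats::runif(n),
                              cumsum(lm$gradeProbs)[1:2] + 0)],
        stringsAsFactors = FALSE)

    # one child stream per lesion, split off the root state
    state <- get(".Random.seed", envir = globalenv())
    pairs <- vector("list", n)
    for (i in seq_len(n)) {
        state <- parallel::nextRNGStream(state)
        pairs[[i]] <- renderLesionPair(records[i, ], config,
                                       rngState = state)
    }
    CesmCohort(records, pairs)
}
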