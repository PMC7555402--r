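test_that("cohort configuration invariants are enforced", {
    lm <- defaultLabelModel()
    expect_equal(sum(lm$gradeProbs), 1, tolerance = 1e-13)
    lmBad <- lm
    lmBad$gradeProbs <- c(G1 = 0.3, G2 = 0.3, G3 = 0.3)
    expect_error(cohortConfig(labelModel = lmBad), "sum to 1")
    expect_error(cohortConfig(imageSize = 32, roiRadiusPx = 16),
                 "does not fit")
    expect_error(cohortConfig(effectMap = data.frame(
        label = "er_pct", feature = "LE_VC", effect = 1.2)),
        "< 1")
    expect_error(cohortConfig(effectMap = data.frame(
        label = "ki67_pct", feature = "RC_Kurtosis", effect = 0.9)),
        "not attainable")
    # two features claiming the same latent is jointly inconsistent
    expect_error(cohortConfig(effectMap = data.frame(
        label = "ki67_pct", feature = c("RC_VC", "RC_Max-Min"),
        effect = 0.3)),
        "inconsistent")
    # loadings too large jointly for one latent
    expect_error(cohortConfig(effectMap = data.frame(
        label = c("er_pct", "ki67_pct"), feature = "RC_VC",
        effect = c(0.8, 0.8))),
        "not positive semi-definite")
})

test_that("a default cohort has the requested size and valid labels", {
    coh <- generateCohort(cohortConfig(nLesions = 68, seed = 2))
    expect_equal(length(coh), 68L)
    expect_length(imagePairs(coh), 68L)
    rec <- as.data.frame(lesionRecords(coh))
    expect_true(all(rec$er_pct >= 0 & rec$er_pct <= 100))
    expect_true(all(rec$pr_pct >= 0 & rec$pr_pct <= 100))
    expect_true(all(rec$ki67_pct >= 0 & rec$ki67_pct <= 100))
    expect_true(all(rec$her2 %in% c("+", "-")))
    expect_true(all(rec$grade %in% c("G1", "G2", "G3")))
    expect_false(anyDuplicated(rec$lesion_id) > 0)
})

test_that("identical config and seed regenerate byte-identical cohorts", {
    cfg <- cohortConfig(nLesions = 6, seed = 31, imageSize = 32,
                        roiRadiusPx = 8)
    a <- generateCohort(cfg)
    b <- generateCohort(cfg)
    expect_identical(as.data.frame(lesionRecords(a)),
                     as.data.frame(lesionRecords(b)))
    for (i in seq_len(6)) {
        expect_identical(leImage(imagePairs(a)[[i]]),
                         leImage(imagePairs(b)[[i]]))
        expect_identical(rcImage(imagePairs(a)[[i]]),
                         rcImage(imagePairs(b)[[i]]))
        expect_identical(roiMask(imagePairs(a)[[i]]),
                         roiMask(imagePairs(b)[[i]]))
    }
    # and the generator does not disturb the caller's RNG
    set.seed(99); before <- rnorm(3)
    set.seed(99); invisible(generateCohort(cfg)); after <- rnorm(3)
    expect_identical(before, after)
})

test_that("renderLesionPair is a pure function of its RNG state", {
    cfg <- cohortConfig(nLesions = 2, seed = 5, imageSize = 32,
                        roiRadiusPx = 8)
    rec <- data.frame(lesion_id = "LX", patient_id = "PX",
                      er_pct = 50, pr_pct = 30, ki67_pct = 25,
                      her2 = "-", grade = "G2")
    suppressWarnings(RNGkind("L'Ecuyer-CMRG"))
    set.seed(123)
    st <- .Random.seed
    p1 <- renderLesionPair(rec, cfg, rngState = st)
    p2 <- renderLesionPair(rec, cfg, rngState = st)
    RNGkind("default")
    expect_identical(leImage(p1), leImage(p2))
    expect_identical(rcImage(p1), rcImage(p2))
    expect_error(renderLesionPair(
        transform(rec, er_pct = 130), cfg), "out of range")
})

test_that("the ROI mask equals brute-force disc rasterization", {
    for (geom in list(c(32, 8), c(64, 18), c(33, 9))) {
        cfg <- cohortConfig(nLesions = 1, seed = 1,
                            imageSize = geom[1], roiRadiusPx = geom[2])
        coh <- generateCohort(cfg)
        m <- roiMask(imagePairs(coh)[[1]])
        expect_equal(sum(m), bfDiscCount(geom[1], geom[2]))
        expect_true(sum(m) >= 16)
    }
})

test_that("noise-free ROIs have exactly the model variance of zero", {
    cfg <- cohortConfig(nLesions = 3, seed = 4, imageSize = 32,
                        roiRadiusPx = 8, noiseSd = 0)
    coh <- generateCohort(cfg)
    for (p in as.list(imagePairs(coh))) {
        roi <- extractRoiPixels(p, "LE")
        expect_equal(stats::var(roi), 0)
        expect_equal(stats::var(extractRoiPixels(p, "RC")), 0)
    }
})

test_that("without planted effects, labels and features are independent", {
    # average sample correlation over replicate cohorts stays within
    # Monte-Carlo bounds of zero
    reps <- 12; n <- 100
    rs <- matrix(NA_real_, reps, 3)
    for (r in seq_len(reps)) {
        coh <- generateCohort(cohortConfig(
            nLesions = n, seed = 1000 + r, imageSize = 32,
            roiRadiusPx = 8))
        fs <- extractFeatures(coh)
        X <- featureMatrix(fs)
        rec <- as.data.frame(SummarizedExperiment::colData(fs))
        rs[r, ] <- c(cor(rec$ki67_pct, X[, "RC_VC"]),
                     cor(rec$er_pct, X[, "LE_Mean"]),
                     cor(rec$pr_pct, X[, "RC_Skewness"]))
    }
    expect_true(all(abs(colMeans(rs)) < 3 / sqrt(reps * n)))
})

test_that("single planted effects are recovered in feature space", {
    # continuous label: Pearson target on a shape-driven feature
    cfg <- cohortConfig(nLesions = 1200, seed = 21, effectMap =
        data.frame(label = "pr_pct", feature = "LE_Skewness",
                   effect = 0.4))
    fs <- extractFeatures(generateCohort(cfg))
    rec <- as.data.frame(SummarizedExperiment::colData(fs))
    r <- cor(rec$pr_pct, featureMatrix(fs)[, "LE_Skewness"])
    expect_true(abs(r - 0.4) < 0.05)

    # negative target on the granularity-driven entropy
    cfg2 <- cohortConfig(nLesions = 1200, seed = 22, effectMap =
        data.frame(label = "er_pct", feature = "RC_Entropy",
                   effect = -0.3))
    fs2 <- extractFeatures(generateCohort(cfg2))
    rec2 <- as.data.frame(SummarizedExperiment::colData(fs2))
    r2 <- cor(rec2$er_pct, featureMatrix(fs2)[, "RC_Entropy"])
    expect_true(abs(r2 + 0.3) < 0.05)
})

test_that("binary planted effects realize the standardized mean difference", {
    cfg <- cohortConfig(nLesions = 2000, seed = 23, effectMap =
        data.frame(label = "her2", feature = "RC_Mean", effect = 1.2))
    fs <- extractFeatures(generateCohort(cfg))
    rec <- as.data.frame(SummarizedExperiment::colData(fs))
    v <- featureMatrix(fs)[, "RC_Mean"]
    pos <- rec$her2 == "+"
    sp <- sqrt(((sum(pos) - 1) * var(v[pos]) +
                (sum(!pos) - 1) * var(v[!pos])) / (length(v) - 2))
    d <- (mean(v[pos]) - mean(v[!pos])) / sp
    expect_true(abs(d - 1.2) < 0.15)
})
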