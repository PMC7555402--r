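recOf <- function(er = 50, pr = 50, ki = 25, her2 = "-", grade = "G2")
    data.frame(er_pct = er, pr_pct = pr, ki67_pct = ki, her2 = her2,
               grade = grade)

test_that("task labelers apply the clinical cutoff rules", {
    expect_equal(binarizeLabels(recOf(er = 0.5), "ER")$y, 0L)
    expect_equal(binarizeLabels(recOf(er = 1.0), "ER")$y, 1L)
    expect_equal(binarizeLabels(recOf(pr = 19.99), "PR")$y, 0L)
    expect_equal(binarizeLabels(recOf(pr = 20), "PR")$y, 1L)
    expect_equal(binarizeLabels(recOf(ki = 20), "Ki67")$y, 1L)
    expect_equal(binarizeLabels(recOf(grade = "G3"), "Grade")$y, 1L)
    expect_equal(binarizeLabels(recOf(grade = "G2"), "Grade")$y, 0L)
    expect_equal(binarizeLabels(recOf(her2 = "+"), "HER2")$y, 1L)
    # triple negative: ER-, PR- and HER2- all required
    expect_equal(binarizeLabels(recOf(er = 0, pr = 0, her2 = "-"),
                                "TN")$y, 1L)
    expect_equal(binarizeLabels(recOf(er = 0, pr = 0, her2 = "+"),
                                "TN")$y, 0L)
    expect_equal(binarizeLabels(recOf(er = 5, pr = 0, her2 = "-"),
                                "TN")$y, 0L)
    expect_error(binarizeLabels(recOf(), "XYZ"), "unknown task")

    counts <- binarizeLabels(rbind(recOf(er = 0), recOf(), recOf()),
                             "ER")
    expect_equal(counts$nPos, 2L)
    expect_equal(counts$nNeg, 1L)
})

test_that("the closed-form LDA matches the reference implementation", {
    skip_if_not_installed("MASS")
    set.seed(19)
    n <- 40; p <- 3
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("f", 1:p)
    y <- rep(c(0L, 1L), each = n / 2)
    X[y == 1L, 1] <- X[y == 1L, 1] + 1.2

    fit <- fitLda(X, y, ridge = 0)
    ref <- MASS::lda(X, grouping = factor(y))
    expect_equal(unname(fit$means), unname(ref$means),
                 tolerance = 1e-10)
    expect_equal(unname(fit$priors), unname(c(ref$prior)),
                 tolerance = 1e-12)

    # LOO posteriors against explicit per-fold reference refits
    refLoo <- vapply(seq_len(n), function(i) {
        f <- MASS::lda(X[-i, ], grouping = factor(y[-i]))
        predict(f, X[i, , drop = FALSE])$posterior[1, "1"]
    }, numeric(1))
    ours <- stats::plogis(looCv(X, y, ridge = 0))
    expect_equal(unname(ours), unname(refLoo), tolerance = 1e-8)
})

test_that("LDA degenerate inputs are rejected with guidance", {
    set.seed(4)
    X <- cbind(a = rnorm(12), b = rnorm(12))
    X <- cbind(X, c = X[, "a"])  # duplicated feature column
    y <- rep(c(0, 1), 6)
    expect_error(fitLda(X, y, ridge = 0), "ridge")
    expect_silent(fit <- fitLda(X, y, ridge = 1e-6))
    expect_error(fitLda(X[y == 0, ], y[y == 0]), "both classes")
    Xna <- X; Xna[1, 1] <- NA
    expect_error(fitLda(Xna, y), "missing")
})

test_that("discriminant scores behave like the Gaussian posterior", {
    set.seed(30)
    n <- 200; p <- 4
    X <- matrix(rnorm(n * p), n, p)
    y <- rbinom(n, 1, 0.4)
    X[y == 1, ] <- X[y == 1, ] + 0.8
    fit <- fitLda(X, y, ridge = 0)

    # score at the midpoint of class means vanishes for equal priors
    fitEq <- fitLda(X[c(which(y == 0)[1:50], which(y == 1)[1:50]), ],
                    rep(c(0, 1), each = 50), ridge = 0)
    mid <- colMeans(fitEq$means)
    expect_equal(ldaScore(fitEq, mid), 0, tolerance = 1e-9)

    # affine in x along the discriminant direction
    x0 <- rnorm(p)
    dirv <- fit$w / sqrt(sum(fit$w^2))
    s <- vapply(c(0, 1, 2.5), function(tt)
        ldaScore(fit, x0 + tt * dirv), numeric(1))
    expect_equal(s[3] - s[1], 2.5 * (s[2] - s[1]), tolerance = 1e-9)

    # logistic transform of the score equals the direct two-Gaussian
    # posterior with pooled covariance
    dens <- function(x, mu, S) exp(-0.5 * mahalanobis(
        matrix(x, 1), mu, S))
    for (i in 1:10) {
        x <- rnorm(p)
        num <- fit$priors[2] * dens(x, fit$means["pos", ], fit$sigma)
        den <- num + fit$priors[1] * dens(x, fit$means["neg", ],
                                          fit$sigma)
        expect_equal(stats::plogis(ldaScore(fit, x)), num / den,
                     tolerance = 1e-10)
    }
})

test_that("leave-one-out equals independent from-scratch refits", {
    set.seed(41)
    n <- 8
    X <- matrix(rnorm(n * 2), n, 2)
    y <- rep(c(0, 1), 4)
    loo <- looCv(X, y, ridge = 1e-8)
    for (i in seq_len(n)) {
        refit <- fitLda(X[-i, , drop = FALSE], y[-i], ridge = 1e-8)
        expect_equal(loo[i], ldaScore(refit, X[i, ]), tolerance = 1e-12)
    }
    # permutation equivariance
    perm <- sample(n)
    expect_equal(looCv(X[perm, ], y[perm], ridge = 1e-8), loo[perm],
                 tolerance = 1e-12)
    # perfectly separated 1-D data scores with the correct signs
    Xs <- matrix(c(0, 1, 2, 3, 10, 11, 12, 13), ncol = 1)
    ys <- rep(c(0, 1), each = 4)
    ls <- looCv(Xs, ys, ridge = 1e-8)
    expect_true(all(ls[ys == 1] > 0) && all(ls[ys == 0] < 0))
})

test_that("fold-wise standardization introduces no leakage channel", {
    # LDA is affine-equivariant, so standardizing inside each training
    # fold must reproduce the unstandardized ranking (identical AUC)
    set.seed(55)
    n <- 40
    X <- cbind(rnorm(n, sd = 5), rnorm(n, sd = 0.1))
    y <- rbinom(n, 1, 0.5)
    y[1:2] <- c(0, 1)
    a1 <- rocAuc(looCv(X, y, ridge = 0), y)$auc
    a2 <- rocAuc(looCv(X, y, ridge = 0, standardize = TRUE), y)$auc
    expect_equal(a1, a2, tolerance = 1e-8)
})

test_that("ROC/AUC obey their identities and invariances", {
    r <- rocAuc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
    expect_equal(r$auc, 1.0)
    expect_equal(rocAuc(rep(2.2, 10), rep(c(0, 1), 5))$auc, 0.5)

    set.seed(50)
    for (i in 1:25) {
        n <- sample(8:30, 1)
        y <- c(0, 1, rbinom(n - 2, 1, 0.5))
        sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # many ties
        got <- rocAuc(sc, y)
        expect_equal(got$auc, bfAucPairs(sc, y), tolerance = 1e-12)
        rp <- got$rocPoints
        expect_equal(rp[1, ], c(fpr = 0, tpr = 0))
        expect_equal(rp[nrow(rp), ], c(fpr = 1, tpr = 1))
        expect_true(all(diff(rp[, 1]) >= 0) && all(diff(rp[, 2]) >= 0))
        # invariance under a strictly increasing transform
        expect_equal(rocAuc(exp(3 * sc), y)$auc, got$auc)
        if (requireNamespace("pROC", quietly = TRUE))
            expect_equal(got$auc, as.numeric(pROC::auc(
                response = y, predictor = sc, direction = "<",
                levels = c(0, 1), quiet = TRUE)), tolerance = 1e-12)
    }
    expect_error(rocAuc(1:4, rep(1, 4)), "both classes")
})

test_that("all six tasks run on a cohort and degrade gracefully", {
    coh <- generateCohort(cohortConfig(nLesions = 60, seed = 66,
                                       imageSize = 32, roiRadiusPx = 8))
    fs <- extractFeatures(coh)
    res <- runAllTasks(fs)
    expect_length(res, 6L)
    expect_setequal(names(res), taskDefinitions()$name)
    summ <- taskSummary(res)
    for (i in seq_len(nrow(summ)))
        expect_equal(summ$n_pos[i] + summ$n_neg[i], 60L)
    feas <- !is.na(summ$auc_pct)
    expect_true(any(feas))
    expect_true(all(summ$auc_pct[feas] >= 0 & summ$auc_pct[feas] <= 100))
    # any infeasible task is flagged with a reason, others unaffected
    if (any(!feas))
        expect_true(all(nzchar(summ$note[!feas])))

    # force a task below the feasibility threshold
    rec <- as.data.frame(lesionRecords(coh))
    rec$her2 <- "-"; rec$her2[1] <- "+"
    fs2 <- fs
    SummarizedExperiment::colData(fs2) <- as(rec, "DFrame")
    res2 <- runAllTasks(fs2, tasks = c("HER2", "Ki67"))
    expect_false(res2[["HER2"]]@feasible)
    expect_true(res2[["Ki67"]]@feasible)
})
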