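#' The six binary histological/molecular tasks
#'
#' Task definitions with their positivity rules: ER+ iff ER >= 1\%, PR+
#' iff PR >= 20\%, Ki67+ iff Ki67 >= 20\% (cutoffs included on the
#' positive side, matching the clinical ER >= 1\% convention), Grade+ iff
#' G3 (high grade), HER2+ iff HER2 positive, and TN+ iff ER-, PR- and
#' HER2- all hold (triple negative).
#'
#' @return data.frame with columns \code{name} and \code{cutoff}
#'   (\code{NA} where not applicable).
#' @export
taskDefinitions <- function() {
    data.frame(name = c("ER", "PR", "Ki67", "Grade", "TN", "HER2"),
               cutoff = c(1, 20, 20, NA, NA, NA),
               stringsAsFactors = FALSE)
}

#' Binarize histology labels for one task
#'
#' @param records data.frame/DataFrame with columns \code{er_pct},
#'   \code{pr_pct}, \code{ki67_pct}, \code{her2}, \code{grade}.
#' @param task Task name (see \code{\link{taskDefinitions}}).
#' @return List with \code{y} (integer 0/1, 1 = positive), \code{nPos},
#'   \code{nNeg}.
#' @export
#' @examples
#' rec <- data.frame(er_pct = c(0.5, 1), pr_pct = 0, ki67_pct = 30,
#'                   her2 = "-", grade = "G2")
#' binarizeLabels(rec, "ER")$y
binarizeLabels <- function(records, task) {
    records <- as.data.frame(records)
    y <- switch(task,
        ER   = records$er_pct >= 1,
        PR   = records$pr_pct >= 20,
        Ki67 = records$ki67_pct >= 20,
        Grade = records$grade == "G3",
        HER2 = records$her2 == "+",
        TN   = records$er_pct < 1 & records$pr_pct < 20 &
               records$her2 == "-",
        stop("unknown task: ", task))
    if (anyNA(y))
        stop("task ", task, ": required label fields contain NA")
    y <- as.integer(y)
    list(y = y, nPos = sum(y == 1L), nNeg = sum(y == 0L))
}

#' Fit a two-class linear discriminant from its closed form
#'
#' Gaussian classes with a pooled covariance: per-class mean vectors,
#' pooled within-class covariance with divisor n - 2 plus an optional
#' ridge on the diagonal, and empirical class priors. The discriminant
#' of class k is \eqn{\delta_k(x) = x' \Sigma^{-1}\mu_k -
#' \frac{1}{2}\mu_k' \Sigma^{-1}\mu_k + \log \pi_k}.
#'
#' @param X Numeric matrix, observations in rows (no missing values).
#' @param y Binary vector (0/1 or logical), 1 = positive class.
#' @param ridge Scalar added to the covariance diagonal; \code{NULL}
#'   (default) uses \code{1e-6 * trace(Sigma)/p}, and 0 requests the
#'   unregularized fit (errors if singular).
#' @return An object of class \code{"cesmLDA"}: \code{means} (2 x p,
#'   rows neg/pos), \code{sigma}, \code{priors}, \code{w} (discriminant
#'   direction \eqn{\Sigma^{-1}(\mu_+ - \mu_-)}), \code{bias},
#'   \code{ridge}, \code{featureNames}.
#' @export
fitLda <- function(X, y, ridge = NULL) {
    X <- as.matrix(X)
    y <- as.integer(as.logical(y))
    stopifnot(nrow(X) == length(y))
    if (anyNA(X))
        stop("X contains missing values; drop incomplete rows first")
    n0 <- sum(y == 0L); n1 <- sum(y == 1L)
    if (n0 == 0L || n1 == 0L)
        stop("both classes must be present")
    n <- n0 + n1
    if (n < 3L)
        stop("need at least 3 observations to pool a covariance")
    p <- ncol(X)
    mu0 <- colMeans(X[y == 0L, , drop = FALSE])
    mu1 <- colMeans(X[y == 1L, , drop = FALSE])
    C0 <- sweep(X[y == 0L, , drop = FALSE], 2, mu0)
    C1 <- sweep(X[y == 1L, , drop = FALSE], 2, mu1)
    sigma <- (crossprod(C0) + crossprod(C1)) / (n - 2)
    if (is.null(ridge)) ridge <- 1e-6 * sum(diag(sigma)) / p
    sigmaR <- sigma + diag(ridge, p)
    w <- tryCatch(solve(sigmaR, mu1 - mu0),
                  error = function(e) stop(
                      "pooled covariance is singular; refit with a ",
                      "positive ridge", call. = FALSE))
    priors <- c(n0, n1) / n
    bias <- -0.5 * sum((mu1 + mu0) * w) + log(priors[2] / priors[1])
    structure(list(means = rbind(neg = mu0, pos = mu1), sigma = sigmaR,
                   priors = priors, w = w, bias = bias, ridge = ridge,
                   featureNames = colnames(X)),
              class = "cesmLDA")
}

#' Linear discriminant score of an observation
#'
#' Difference of class discriminants \eqn{\delta_+(x) - \delta_-(x)};
#' monotone in the positive-class posterior, which equals
#' \code{plogis(score)}.
#'
#' @param model A \code{"cesmLDA"} fit.
#' @param x Numeric vector (one observation) or matrix (rows scored
#'   separately).
#' @return Numeric score(s).
#' @export
ldaScore <- function(model, x) {
    if (is.matrix(x)) drop(x %*% model$w) + model$bias
    else sum(x * model$w) + model$bias
}

#' Leave-one-out cross-validated discriminant scores
#'
#' For each observation the model is refit on all remaining rows and the
#' held-out row is scored. Optional feature standardization is computed
#' inside each training fold (means and sds of the n-1 training rows)
#' and applied to the held-out row, so no information leaks across
#' folds.
#'
#' @param X Numeric matrix (complete rows).
#' @param y Binary labels.
#' @param ridge Passed to \code{\link{fitLda}}.
#' @param standardize Standardize features within each training fold
#'   (default FALSE).
#' @return Numeric vector of LOO scores in input row order.
#' @export
looCv <- function(X, y, ridge = NULL, standardize = FALSE) {
    X <- as.matrix(X)
    y <- as.integer(as.logical(y))
    n <- nrow(X)
    if (n < 4L)
        stop("leave-one-out needs at least 4 observations")
    if (sum(y == 1L) < 2L || sum(y == 0L) < 2L)
        stop("both classes need at least 2 members for leave-one-out")
    vapply(seq_len(n), function(i) {
        Xt <- X[-i, , drop = FALSE]
        yt <- y[-i]
        if (sum(yt == 1L) == 0L || sum(yt == 0L) == 0L)
            stop("leaving out observation ", i, " empties a class")
        xi <- X[i, ]
        if (standardize) {
            m <- colMeans(Xt)
            s <- apply(Xt, 2, stats::sd)
            s[s == 0] <- 1
            Xt <- sweep(sweep(Xt, 2, m), 2, s, "/")
            xi <- (xi - m) / s
        }
        ldaScore(fitLda(Xt, yt, ridge = ridge), xi)
    }, numeric(1))
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps all unique score thresholds (classifying \code{score >=
#' threshold} as positive), yielding a ROC from (0,0) to (1,1), and
#' integrates it by the trapezoidal rule. Tied scores advance the curve
#' diagonally, so the AUC equals the Mann-Whitney identity
#' \eqn{[\#(pos > neg) + \#(pos = neg)/2] / (n_+ n_-)}.
#'
#' @param scores Numeric scores (larger = more positive).
#' @param y Binary labels (1 = positive).
#' @return List with \code{rocPoints} (matrix with columns \code{fpr},
#'   \code{tpr}) and \code{auc}.
#' @export
#' @examples
#' rocAuc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$auc
rocAuc <- function(scores, y) {
    y <- as.integer(as.logical(y))
    stopifnot(length(scores) == length(y), all(is.finite(scores)))
    nPos <- sum(y == 1L); nNeg <- sum(y == 0L)
    if (nPos == 0L || nNeg == 0L)
        stop("both classes must be present to build a ROC curve")
    ord <- order(scores, decreasing = TRUE)
    ys <- y[ord]; ss <- scores[ord]
    # collapse tied scores into single threshold steps
    lastOfBlock <- c(ss[-length(ss)] != ss[-1], TRUE)
    tp <- cumsum(ys)[lastOfBlock]
    fp <- cumsum(1L - ys)[lastOfBlock]
    tpr <- c(0, tp / nPos)
    fpr <- c(0, fp / nNeg)
    auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
    list(rocPoints = cbind(fpr = fpr, tpr = tpr), auc = auc)
}

#' Run all six classification tasks
#'
#' Binarizes each outcome, drops lesions with missing feature values
#' (with a message), fits the pooled-covariance linear discriminant
#' under leave-one-out cross-validation and summarizes each task with
#' its pooled-score ROC and AUC. A task whose smaller class has fewer
#' than 2 usable lesions is reported infeasible; the others are
#' unaffected.
#'
#' @param fs A \linkS4class{RadiomicFeatureSet} with histology labels in
#'   \code{colData}.
#' @param ridge,standardize Passed to \code{\link{looCv}}.
#' @param tasks Character subset of task names (default: all six).
#' @return \link[S4Vectors]{SimpleList} of \linkS4class{TaskResult}.
#' @export
runAllTasks <- function(fs, ridge = NULL, standardize = FALSE,
                        tasks = taskDefinitions()$name) {
    stopifnot(is(fs, "RadiomicFeatureSet"))
    X <- featureMatrix(fs)
    if (is.null(rownames(X)))
        rownames(X) <- as.character(seq_len(nrow(X)))
    rec <- as.data.frame(SummarizedExperiment::colData(fs))
    complete <- stats::complete.cases(X)
    if (!all(complete))
        message(sum(!complete), " lesion(s) dropped for undefined ",
                "feature values: ",
                paste(rownames(X)[!complete], collapse = ", "))
    Xc <- X[complete, , drop = FALSE]
    recc <- rec[complete, , drop = FALSE]
    res <- lapply(tasks, function(tk) {
        bl <- binarizeLabels(recc, tk)
        if (min(bl$nPos, bl$nNeg) < 2L)
            return(new("TaskResult", task = tk,
                       nPos = bl$nPos, nNeg = bl$nNeg,
                       labels = integer(), looScores = numeric(),
                       lesionIds = character(),
                       rocPoints = matrix(numeric(), 0, 2),
                       auc = NA_real_, feasible = FALSE,
                       message = sprintf(
                           "smaller class has %d lesion(s); need >= 2",
                           min(bl$nPos, bl$nNeg))))
        scores <- looCv(Xc, bl$y, ridge = ridge,
                        standardize = standardize)
        roc <- rocAuc(scores, bl$y)
        new("TaskResult", task = tk, nPos = bl$nPos, nNeg = bl$nNeg,
            labels = bl$y, looScores = scores,
            lesionIds = rownames(Xc),
            rocPoints = roc$rocPoints, auc = roc$auc,
            feasible = TRUE, message = "")
    })
    names(res) <- tasks
    S4Vectors::SimpleList(res)
}

#' Summarize task results as a table
#'
#' @param results \code{SimpleList} of \linkS4class{TaskResult} from
#'   \code{\link{runAllTasks}}.
#' @return data.frame with \code{task}, \code{n_pos}, \code{n_neg},
#'   \code{auc_pct} (AUC as a percentage; NA for infeasible tasks) and
#'   \code{note}.
#' @export
taskSummary <- function(results) {
    data.frame(
        task = vapply(results, function(r) r@task, character(1)),
        n_pos = vapply(results, function(r) r@nPos, integer(1)),
        n_neg = vapply(results, function(r) r@nNeg, integer(1)),
        auc_pct = vapply(results, function(r)
            if (r@feasible) 100 * r@auc else NA_real_, numeric(1)),
        note = vapply(results, function(r) r@message, character(1)),
        stringsAsFactors = FALSE)
}

#' Overlayed ROC curves of all feasible tasks
#'
#' @param results \code{SimpleList} of \linkS4class{TaskResult}.
#' @param file Optional PNG path; \code{NULL} draws on the current
#'   device.
#' @return \code{file} (or NULL), invisibly.
#' @export
plotRocCurves <- function(results, file = NULL) {
    feasible <- Filter(function(r) r@feasible, as.list(results))
    if (!is.null(file)) {
        grDevices::png(file, width = 640, height = 640)
        on.exit(grDevices::dev.off())
    }
    graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "gray",
                   xlab = "False positive rate",
                   ylab = "True positive rate",
                   main = "LOO ROC curves")
    cols <- grDevices::hcl.colors(max(1L, length(feasible)), "Dark 3")
    for (i in seq_along(feasible)) {
        r <- feasible[[i]]
        graphics::lines(r@rocPoints[, 1], r@rocPoints[, 2],
                        col = cols[i], lwd = 2)
    }
    graphics::legend("bottomright", bty = "n", lwd = 2,
                     col = cols[seq_along(feasible)],
                     legend = vapply(feasible, function(r)
                         sprintf("%s (AUC %.1f%%)", r@task, 100 * r@auc),
                         character(1)))
    invisible(file)
}
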