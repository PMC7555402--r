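#' Pearson correlation test with pairwise deletion
#'
#' Sample Pearson correlation of two vectors after pairwise removal of
#' missing entries, with the two-sided p-value of the t statistic
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on n-2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with \code{r}, \code{p}, \code{n} (pairwise-complete
#'   count).
#' @export
#' @examples
#' pearsonTest(1:10, (1:10)^1.3 + rnorm(10))
pearsonTest <- function(x, y) {
    stopifnot(length(x) == length(y))
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3L)
        stop("fewer than 3 pairwise-complete observations (", n, ")")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("correlation undefined: constant input vector")
    ct <- stats::cor.test(x, y, method = "pearson",
                          alternative = "two.sided")
    list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of two independent
#' groups. \code{mode = "exact"} enumerates the permutation null (valid
#' without ties up to \code{exactCap} total observations; with ties it
#' falls back to the normal mode with a warning); \code{mode = "normal"}
#' uses the tie-corrected normal approximation with continuity
#' correction; \code{mode = "auto"} picks exact when admissible. The U
#' statistic reported is that of group \code{a}, computed from midranks.
#'
#' @param a,b Numeric vectors (non-empty).
#' @param mode \code{"auto"}, \code{"exact"} or \code{"normal"}.
#' @param exactCap Largest \code{length(a) + length(b)} for which the
#'   exact null is enumerated (default 25).
#' @return List with \code{U}, \code{p}, \code{mode} (the mode actually
#'   used).
#' @export
#' @examples
#' mannWhitneyTest(c(1, 2, 3), c(4, 5, 6), mode = "exact")
mannWhitneyTest <- function(a, b, mode = c("auto", "exact", "normal"),
                            exactCap = 25L) {
    mode <- match.arg(mode)
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) == 0L || length(b) == 0L)
        stop("both groups must be non-empty")
    hasTies <- anyDuplicated(c(a, b)) > 0L
    n <- length(a) + length(b)
    useExact <- switch(mode,
        exact = TRUE,
        normal = FALSE,
        auto = !hasTies && n <= exactCap)
    if (useExact && hasTies) {
        warning("exact Mann-Whitney requested with ties; ",
                "falling back to the normal approximation")
        useExact <- FALSE
    }
    if (useExact && n > exactCap) {
        warning("exact Mann-Whitney requested for n = ", n, " > cap ",
                exactCap, "; falling back to the normal approximation")
        useExact <- FALSE
    }
    # midrank U statistic of group a
    r <- rank(c(a, b))
    U <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
    wt <- suppressWarnings(stats::wilcox.test(
        a, b, alternative = "two.sided", exact = useExact,
        correct = TRUE))
    list(U = unname(U), p = wt$p.value,
         mode = if (useExact) "exact" else "normal")
}

#' Bonferroni adjustment
#'
#' \code{min(1, familySize * p)} elementwise. The family size may exceed
#' the number of p-values supplied (tests belonging to the same declared
#' family may be adjusted in batches) but never be smaller.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param familySize Declared family size (>= \code{length(p)}).
#' @return Adjusted p-values, same order.
#' @export
#' @examples
#' bonferroniAdjust(c(0.01, 0.2), familySize = 14)
bonferroniAdjust <- function(p, familySize) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    if (familySize < length(p))
        stop("familySize (", familySize,
             ") is smaller than the number of tests (", length(p), ")")
    pmin(1, familySize * p)
}

#' Feature-histology association table
#'
#' For every first-order feature: Pearson correlation against each
#' continuous outcome (ER\%, PR\%, Ki67\%) and a Mann-Whitney test
#' against each grouping outcome (HER2 +/- and histological grade, split
#' G3 versus G1+G2, with the positive group first), with raw and
#' Bonferroni-adjusted p-values. Missing feature values are removed
#' pairwise and the per-row complete count is reported.
#'
#' @param fs A \linkS4class{RadiomicFeatureSet} whose \code{colData}
#'   carries the histology labels.
#' @param family \code{"per_outcome"} (default): each outcome's 14 tests
#'   form one Bonferroni family; \code{"global"}: all 70 tests form one
#'   family.
#' @param mwMode Mann-Whitney mode (see \code{\link{mannWhitneyTest}}).
#' @return A \link[S4Vectors]{DataFrame} with columns \code{outcome},
#'   \code{feature}, \code{statistic_type}, \code{statistic},
#'   \code{n_used}, \code{p_raw}, \code{p_adjusted}, \code{family_size}.
#' @export
associationTable <- function(fs, family = c("per_outcome", "global"),
                             mwMode = "auto") {
    family <- match.arg(family)
    stopifnot(is(fs, "RadiomicFeatureSet"))
    X <- featureMatrix(fs)
    rec <- as.data.frame(SummarizedExperiment::colData(fs))
    needed <- c("er_pct", "pr_pct", "ki67_pct", "her2", "grade")
    missing <- setdiff(needed, colnames(rec))
    if (length(missing))
        stop("outcome column(s) missing from colData: ",
             paste(missing, collapse = ", "))
    feats <- cesmFeatureNames()
    cont <- list(ER = rec$er_pct, PR = rec$pr_pct, Ki67 = rec$ki67_pct)
    grp <- list(HER2 = rec$her2 == "+", Grade = rec$grade == "G3")
    rows <- list()
    for (oc in names(cont)) {
        y <- cont[[oc]]
        if (stats::sd(y, na.rm = TRUE) == 0)
            stop("outcome ", oc, " is constant across the cohort")
        for (f in feats) {
            pt <- pearsonTest(X[, f], y)
            rows[[length(rows) + 1L]] <- data.frame(
                outcome = oc, feature = f, statistic_type = "pearson_r",
                statistic = pt$r, n_used = pt$n, p_raw = pt$p,
                stringsAsFactors = FALSE)
        }
    }
    for (oc in names(grp)) {
        pos <- grp[[oc]]
        if (all(pos) || all(!pos))
            stop("outcome ", oc, " has a single group in this cohort")
        for (f in feats) {
            v <- X[, f]
            ok <- is.finite(v)
            mt <- mannWhitneyTest(v[ok & pos], v[ok & !pos],
                                  mode = mwMode)
            rows[[length(rows) + 1L]] <- data.frame(
                outcome = oc, feature = f,
                statistic_type = "mannwhitney_U",
                statistic = mt$U, n_used = sum(ok), p_raw = mt$p,
                stringsAsFactors = FALSE)
        }
    }
    tab <- do.call(rbind, rows)
    if (family == "global") {
        tab$family_size <- nrow(tab)
        tab$p_adjusted <- bonferroniAdjust(tab$p_raw, nrow(tab))
    } else {
        tab$family_size <- length(feats)
        tab$p_adjusted <- NA_real_
        for (oc in unique(tab$outcome)) {
            sel <- tab$outcome == oc
            tab$p_adjusted[sel] <- bonferroniAdjust(tab$p_raw[sel],
                                                    length(feats))
        }
    }
    S4Vectors::DataFrame(tab)
}

#' Render the association table as text
#'
#' Markdown-style layout with an LE block and an RC block per outcome,
#' correlations to two decimals and significance stars on the raw
#' p-value: * p < 0.10, ** p < 0.05, *** p < 0.01.
#'
#' @param tab Output of \code{\link{associationTable}}.
#' @return Character vector of lines, invisibly printed with \code{cat}
#'   if assigned to nothing.
#' @export
formatAssociationTable <- function(tab) {
    tab <- as.data.frame(tab)
    stars <- function(p) ifelse(p < 0.01, " ***",
                         ifelse(p < 0.05, " **",
                         ifelse(p < 0.10, " *", "")))
    lines <- character()
    for (blk in c("LE", "RC")) {
        feats <- cesmFeatureNames(blk)
        lines <- c(lines,
                   paste0("| Features | ",
                          paste(feats, collapse = " | "), " |"),
                   paste0("|", paste(rep("---", length(feats) + 1),
                                     collapse = "|"), "|"))
        for (oc in unique(tab$outcome)) {
            sub <- tab[tab$outcome == oc & tab$feature %in% feats, ]
            sub <- sub[match(feats, sub$feature), ]
            cells <- ifelse(
                sub$statistic_type == "pearson_r",
                paste0(sprintf("%.2f", sub$statistic),
                       stars(sub$p_raw)),
                paste0(sprintf("%.0f", sub$statistic),
                       stars(sub$p_raw)))
            ocLabel <- if (oc %in% c("ER", "PR", "Ki67"))
                paste0(oc, " (%)") else oc
            lines <- c(lines, paste0("| ", ocLabel, " | ",
                                     paste(cells, collapse = " | "),
                                     " |"))
        }
        lines <- c(lines, "")
    }
    lines <- c(lines,
               "* p-value < 0.10, ** p-value < 0.05, *** p-value < 0.01.")
    class(lines) <- "cesmTextTable"
    lines
}

#' @export
print.cesmTextTable <- function(x, ...) {
    cat(unclass(x), sep = "\n")
    invisible(x)
}
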