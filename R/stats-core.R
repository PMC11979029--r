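## Statistical kernel used by every downstream module. Each function
## returns plain numeric results so callers can vectorize over peptides.

#' Two-sided Wilcoxon/Mann-Whitney rank-sum test
#'
#' Compares two independent samples by ranks. The p-value is exact
#' (full enumeration of the U null distribution) when the combined
#' sample size is at most `exactLimit` and there are no ties; otherwise
#' the normal approximation with tie correction and continuity
#' correction is used. At the study's group sizes (24 + 24) the
#' approximate branch always applies, so p-values are reproducible
#' bit-for-bit given this rule.
#'
#' @param x,y Numeric vectors, each of length >= 1.
#' @param exactLimit Combined-size bound below which the exact
#'   distribution is enumerated (default 14).
#' @return List with `statistic` (the Mann-Whitney U of `x`), `p_value`
#'   and `method_detail` (`"exact"` or `"approximate"`, with a
#'   `"tie-corrected"` note when ties are present).
#' @examples
#' rankSumTest(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1, exact
#' @export
rankSumTest <- function(x, y, exactLimit = 14L) {
    if (length(x) < 1L || length(y) < 1L)
        stop("both samples must be non-empty")
    if (any(!is.finite(x)) || any(!is.finite(y)))
        stop("samples must be finite and free of NA")
    ties <- anyDuplicated(c(x, y)) > 0L
    n <- length(x) + length(y)
    if (!ties && n <= exactLimit) {
        ht <- stats::wilcox.test(x, y, exact = TRUE)
        detail <- "exact"
    } else {
        ## all-tied input has a degenerate null distribution: every
        ## labelling gives the same statistic
        r <- rank(c(x, y))
        tab <- table(r)
        m <- length(x)
        sigma2 <- (m * (n - m) / 12) *
            ((n + 1) - sum(tab^3 - tab) / (n * (n - 1)))
        if (sigma2 <= 0) {
            return(list(statistic = m * (n - m) / 2, p_value = 1,
                        method_detail = "approximate, degenerate (all tied)"))
        }
        ht <- suppressWarnings(
            stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
        detail <- if (ties) "approximate, tie-corrected" else "approximate"
    }
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method_detail = detail)
}

#' Pearson chi-squared test on a 2x2 contingency table
#'
#' Plain Pearson chi-squared with 1 df and no continuity correction,
#' used to compare per-group peptide missing/observed counts. The table
#' layout is `rbind(c(a, b), c(c, d))` with rows = outcome
#' (e.g. missing / observed) and columns = group.
#'
#' @param a,b,c,d Non-negative counts.
#' @return List with `statistic`, `p_value`, `method_detail`.
#' @examples
#' chi2TwoByTwo(20, 4, 10, 14)$statistic  # 8.888...
#' @export
chi2TwoByTwo <- function(a, b, c, d) {
    counts <- c(a, b, c, d)
    if (any(!is.finite(counts)) || any(counts < 0))
        stop("counts must be non-negative")
    tab <- matrix(counts, nrow = 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("degenerate 2x2 table: a row or column margin is zero")
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method_detail = "pearson, 1 df, no continuity correction")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up procedure at level `q`. Applied separately within
#' each test family (quantitative track, missingness track), mirroring
#' the separate FDR control of each analysis.
#'
#' @param pValues Numeric vector of p-values in \[0, 1\].
#' @param q FDR level in (0, 1).
#' @return List with `q_values` (monotone-enforced adjusted p-values)
#'   and `reject` (logical; `q_values <= q`).
#' @export
bhAdjust <- function(pValues, q = 0.01) {
    if (length(pValues) &&
        (any(!is.finite(pValues)) || any(pValues < 0 | pValues > 1)))
        stop("p-values must lie in [0, 1]")
    if (!is.finite(q) || q <= 0 || q >= 1)
        stop("q must lie in (0, 1)")
    qv <- stats::p.adjust(pValues, method = "BH")
    list(q_values = qv, reject = qv <= q)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties; two-sided p from the t approximation on
#' `rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearmanCorr <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    keep <- is.finite(x) & is.finite(y)
    x <- x[keep]; y <- y[keep]
    n <- length(x)
    if (n < 3L) stop("need at least 3 paired observations")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("correlation undefined for a constant vector")
    ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE, continuity = FALSE))
    list(rho = unname(ht$estimate), p_value = ht$p.value, n = n)
}

#' Rank-based AUC
#'
#' Area under the ROC curve via the rank (Mann-Whitney) formulation:
#' (concordant pairs + 0.5 * tied pairs) / (positive x negative pairs),
#' i.e. the probability a random positive scores above a random
#' negative.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Logical (or 0/1) vector; `TRUE`/1 = positive class.
#' @return AUC in \[0, 1\].
#' @export
aucRank <- function(scores, labels) {
    if (is.numeric(labels)) {
        if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
        labels <- labels == 1
    }
    if (!is.logical(labels) || length(labels) != length(scores))
        stop("labels must be logical/0-1, same length as scores")
    if (any(!is.finite(scores))) stop("scores must be finite")
    n1 <- sum(labels); n0 <- sum(!labels)
    if (n1 == 0L || n0 == 0L) stop("both classes must be present")
    r <- rank(scores)
    (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance two-sample t with `n1 + n2 - 2` df (two-sided), for
#' group comparisons where only means, SDs and sample sizes are
#' available (e.g. a published cohort baseline table). Inputs are
#' typically rounded summaries, so recomputed p-values match published
#' ones only to rounding accuracy. `pooled = FALSE` gives the
#' Welch-Satterthwaite alternative.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1 (`sd1 > 0`,
#'   `n1 >= 2`).
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @param pooled Use the pooled-variance statistic (default `TRUE`).
#' @return List with `statistic` (t), `df`, `p_value`, `method_detail`.
#' @examples
#' tTestSummary(1.48, 0.51, 24, 1.93, 0.59, 24)$p_value  # ~0.0070
#' @export
tTestSummary <- function(mean1, sd1, n1, mean2, sd2, n2, pooled = TRUE) {
    if (any(c(sd1, sd2) <= 0)) stop("standard deviations must be positive")
    if (any(c(n1, n2) < 2)) stop("each group needs n >= 2")
    if (pooled) {
        sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
        se <- sqrt(sp2 * (1 / n1 + 1 / n2))
        df <- n1 + n2 - 2
        detail <- "pooled variance"
    } else {
        v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
        se <- sqrt(v1 + v2)
        df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
        detail <- "welch"
    }
    t <- (mean1 - mean2) / se
    list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df),
         method_detail = detail)
}
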