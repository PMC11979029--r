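## builders for small two-group experiments
twoGroupExperiment <- function(quant, nPerGroup) {
    toyExperiment(quant, rep(c("long_lived", "short_lived"),
                             each = nPerGroup))
}

test_that("quantitative track rejects a separated peptide and respects BH arithmetic", {
    ## n = 4 per group: the exact two-sided rank-sum floor is 2/70 = 0.0286,
    ## so as its own family the separated peptide is rejected at q = 0.05 ...
    sep <- matrix(c(10, 11, 12, 13, 1, 2, 3, 4), 1,
                  dimnames = list("SEP__1", paste0("s", 1:8)))
    pe1 <- twoGroupExperiment(sep, 4)
    r1 <- quantTrack(pe1, "SEP__1", qLevel = 0.05)
    expect_true(r1$reject)
    expect_equal(r1$direction, "higher_in_long")
    expect_equal(r1$p, 2 / 70)
    ## ... but never at q = 0.01 (floor above the threshold), and never
    ## among m null peptides at q = 0.05 (step-up needs p <= k q / m)
    expect_false(quantTrack(pe1, "SEP__1", qLevel = 0.01)$reject)
    set.seed(14)
    nulls <- matrix(rexp(50 * 8), 50,
                    dimnames = list(sprintf("N%02d__1", 1:50),
                                    paste0("s", 1:8)))
    pe50 <- twoGroupExperiment(rbind(sep, nulls), 4)
    r50 <- quantTrack(pe50, rownames(pe50), qLevel = 0.05)
    expect_false(r50$reject[r50$peptide_id == "SEP__1"])
})

test_that("identical group distributions yield no quantitative discoveries", {
    set.seed(2)
    q <- matrix(rexp(30 * 8), 30,
                dimnames = list(sprintf("P%02d__1", 1:30), paste0("s", 1:8)))
    pe <- twoGroupExperiment(q, 4)
    r <- quantTrack(pe, rownames(pe), qLevel = 0.01)
    expect_false(any(r$reject))
    expect_true(all(r$direction == "none"))
})

test_that("quantitative track enforces the stratification contract", {
    q <- matrix(c(1, NA, 3, 4, 5, 6, 7, 8), 1,
                dimnames = list("P__1", paste0("s", 1:8)))
    pe <- twoGroupExperiment(q, 4)
    expect_error(quantTrack(pe, "P__1"), "stratification")
})

test_that("a planted 2-SD shift at 24 v 24 is recovered with correct direction", {
    hit <- 0
    for (s in 1:10) {
        set.seed(100 + s)
        q <- matrix(rnorm(100 * 48, mean = 10), 100,
                    dimnames = list(sprintf("P%03d__1", 1:100),
                                    paste0("s", 1:48)))
        q["P001__1", 1:24] <- q["P001__1", 1:24] + 2
        pe <- twoGroupExperiment(q, 24)
        r <- quantTrack(pe, rownames(pe), qLevel = 0.01)
        i <- r$peptide_id == "P001__1"
        hit <- hit + (r$reject[i] && r$direction[i] == "higher_in_long")
    }
    expect_gte(hit, 9)
})

test_that("missingness track calls direction from group missing rates", {
    n <- 24
    q <- matrix(rexp(3 * 2 * n), 3,
                dimnames = list(c("GONE__1", "EQ__1", "BAL__1"),
                                paste0("s", 1:(2 * n))))
    q["GONE__1", (n + 1):(2 * n)] <- NA          # absent in all short-lived
    q["EQ__1", c(1:6, n + 1:6)] <- NA            # equal missingness
    q["BAL__1", c(1, n + 1)] <- NA
    pe <- twoGroupExperiment(q, n)
    r <- missingTrack(pe, rownames(pe), qLevel = 0.01)
    gone <- r[r$peptide_id == "GONE__1", ]
    expect_true(gone$reject)
    expect_equal(gone$direction, "higher_in_long")
    expect_equal(gone$statistic, oracleChi2(0, 24, 24, 0))
    eq <- r[r$peptide_id == "EQ__1", ]
    expect_equal(eq$p, 1)
    expect_false(eq$reject)
})

test_that("missingness track excludes degenerate peptides and fully observed input errors", {
    n <- 6
    q <- matrix(rexp(2 * 2 * n), 2,
                dimnames = list(c("ALLMISS__1", "OK__1"),
                                paste0("s", 1:(2 * n))))
    q["ALLMISS__1", ] <- NA
    q["OK__1", 1] <- NA
    pe <- twoGroupExperiment(q, n)
    r <- suppressMessages(missingTrack(pe, rownames(pe), qLevel = 0.01))
    expect_false("ALLMISS__1" %in% r$peptide_id)
    excl <- attr(r, "excluded")
    expect_equal(excl$peptide_id, "ALLMISS__1")
    expect_match(excl$reason, "missing in every sample")

    qq <- matrix(1:(2 * 2 * n), 2,
                 dimnames = list(c("A__1", "B__1"), paste0("s", 1:(2 * n))))
    expect_error(missingTrack(twoGroupExperiment(qq, n), c("A__1", "B__1")),
                 "stratification")
})

test_that("the two BH families are independent", {
    set.seed(77)
    n <- 12
    base <- matrix(rexp(40 * 2 * n), 40,
                   dimnames = list(sprintf("P%02d__1", 1:40),
                                   paste0("s", 1:(2 * n))))
    base[1:15, 1] <- NA  # 15 incomplete peptides
    pe1 <- twoGroupExperiment(base, n)
    extra <- base
    extraRows <- matrix(rexp(10 * 2 * n), 10,
                        dimnames = list(sprintf("X%02d__1", 1:10),
                                        paste0("s", 1:(2 * n))))
    extraRows[, 2] <- NA
    pe2 <- twoGroupExperiment(rbind(extra, extraRows), n)
    d1 <- suppressMessages(differentialAnalysis(pe1, 0.05))
    d2 <- suppressMessages(differentialAnalysis(pe2, 0.05))
    ## growing the missingness family leaves the quantitative q-values alone
    expect_equal(d1$quantitative$q, d2$quantitative$q)
    expect_equal(d1$quantitative$reject, d2$quantitative$reject)
})

test_that("rollup counts peptides and distinct proteins per category", {
    res <- data.frame(
        peptide_id = c("A__1", "A__2", "B__1", "C__1", "D__1"),
        track = c(rep("quantitative", 4), "missingness"),
        direction = c("higher_in_long", "higher_in_long", "higher_in_long",
                      "lower_in_long", "none"),
        reject = c(TRUE, TRUE, TRUE, TRUE, FALSE))
    pmap <- c(A__1 = "A", A__2 = "A", B__1 = "B", C__1 = "C", D__1 = "D")
    rc <- rollupCounts(res, pmap)
    qh <- rc[rc$track == "quantitative" & rc$direction == "higher_in_long", ]
    expect_equal(qh$n_peptides, 3)
    expect_equal(qh$n_distinct_proteins, 2)
    ql <- rc[rc$track == "quantitative" & rc$direction == "lower_in_long", ]
    expect_equal(ql$n_peptides, 1)
    expect_equal(ql$n_distinct_proteins, 1)
    expect_equal(sum(rc$n_peptides), sum(res$reject))
    ## no rejections at all -> all zeros
    none <- res; none$reject <- FALSE
    expect_true(all(rollupCounts(none, pmap)$n_peptides == 0))
    ## one protein in two categories is counted once per category
    both <- data.frame(peptide_id = c("A__1", "A__2"),
                       track = "quantitative",
                       direction = c("higher_in_long", "lower_in_long"),
                       reject = TRUE)
    rb <- rollupCounts(both, pmap)
    expect_equal(sum(rb$n_distinct_proteins), 2)
    expect_error(rollupCounts(res, pmap[-1]), "unmapped")
})

test_that("joint-family adjustment is available behind a flag", {
    set.seed(9)
    n <- 8
    q <- matrix(rexp(20 * 2 * n), 20,
                dimnames = list(sprintf("P%02d__1", 1:20),
                                paste0("s", 1:(2 * n))))
    q[1:8, 1] <- NA
    pe <- twoGroupExperiment(q, n)
    sep <- suppressMessages(differentialAnalysis(pe, 0.05, family = "separate"))
    joint <- suppressMessages(differentialAnalysis(pe, 0.05, family = "joint"))
    m <- length(sep$quantitative$p) + length(sep$missingness$p)
    expect_equal(joint$quantitative$q,
                 p.adjust(c(sep$quantitative$p, sep$missingness$p),
                          "BH")[seq_along(sep$quantitative$p)])
    expect_equal(nrow(joint$missingness), nrow(sep$missingness))
})
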