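test_that("the three encodings match hand-constructed matrices", {
    q <- matrix(c(1, 2, NA,
                  4, NA, 6,
                  7, 8, 9,
                  0, 2, 3), nrow = 4, byrow = TRUE,
                dimnames = list(c("A__1", "B__1", "C__1", "D__1"),
                                c("s1", "s2", "s3")))
    pe <- toyExperiment(q, c("long_lived", "long_lived", "short_lived"))
    cc <- encodePeptides(pe, "complete_continuous")
    expect_identical(colnames(cc), c("C__1", "D__1"))
    expect_equal(cc["s1", ], c(C__1 = 7, D__1 = 0))
    mb <- encodePeptides(pe, "missing_binary")
    expect_identical(colnames(mb), c("A__1", "B__1"))
    expect_equal(mb["s3", ], c(A__1 = 0, B__1 = 1))
    expect_equal(mb["s2", ], c(A__1 = 1, B__1 = 0))
    zi <- encodePeptides(pe, "all_zero_imputed")
    expect_equal(dim(zi), c(3L, 4L))
    expect_equal(zi["s3", "A__1"], 0)
    expect_equal(zi["s2", "B__1"], 0)
    expect_equal(zi["s1", "D__1"], 0)  # observed zero stays zero
    expect_error(encodePeptides(pe, "bogus"))
})

test_that("the stratified 2:1 split reproduces the study composition", {
    ann <- data.frame(sample_id = sprintf("s%02d", 1:48),
                      group = rep(c("long_lived", "short_lived"), each = 24))
    sp <- splitCohort(ann, seed = 4)
    expect_length(sp$discovery_ids, 32)
    expect_length(sp$holdout_ids, 16)
    expect_length(intersect(sp$discovery_ids, sp$holdout_ids), 0)
    expect_true(all(sp$composition["discovery", ] == c(16, 16)))
    expect_true(all(sp$composition["holdout", ] == c(8, 8)))
    expect_identical(sp, splitCohort(ann, seed = 4))
    expect_false(identical(sp$discovery_ids,
                           splitCohort(ann, seed = 5)$discovery_ids))
    toy <- data.frame(sample_id = letters[1:12],
                      group = rep(c("long_lived", "short_lived"), each = 6))
    spToy <- splitCohort(toy, seed = 1)
    expect_true(all(spToy$composition["discovery", ] == c(4, 4)))
    expect_true(all(spToy$composition["holdout", ] == c(2, 2)))
    tiny <- data.frame(sample_id = letters[1:2],
                       group = c("long_lived", "short_lived"))
    expect_error(splitCohort(tiny, 1), "too small")
})

test_that("a perfect separator is selected with CV AUC 1", {
    set.seed(6)
    n <- 24
    x <- cbind(SEP__1 = rep(c(1, 0), each = n / 2) + rnorm(n, 0, 0.01),
               matrix(rnorm(n * 20), n,
                      dimnames = list(NULL, sprintf("N%02d__1", 1:20))))
    rownames(x) <- paste0("s", 1:n)
    y <- rep(c(TRUE, FALSE), each = n / 2)
    m <- fitLongevityModel(x, y, cvControl(4, 3, seed = 2))
    expect_equal(cvAuc(m), 1)
    expect_true("SEP__1" %in% selectedPeptides(m))
})

test_that("constant features give the degenerate chance-level model", {
    x <- matrix(1, 10, 3, dimnames = list(paste0("s", 1:10),
                                          c("A__1", "B__1", "C__1")))
    y <- rep(c(TRUE, FALSE), 5)
    m <- fitLongevityModel(x, y, cvControl(2, 1, seed = 1))
    expect_equal(cvAuc(m), 0.5)
    expect_length(selectedPeptides(m), 0)
    hold <- x[1:4, , drop = FALSE] * 2 + 1
    rownames(hold) <- paste0("h", 1:4)
    ev <- evaluateHoldout(m, hold, y[1:4])
    expect_equal(ev$holdout_auc, 0.5)
    expect_error(fitLongevityModel(x, rep(TRUE, 10)), "both classes")
    expect_error(fitLongevityModel(x[, 0], y), "empty")
})

test_that("holdout evaluation is leakage-guarded and discovery-invariant", {
    set.seed(10)
    co <- generateCohort(syntheticConfig(nProteins = 40, nMarkers = 0,
                                         seed = 55))
    pe <- toVolumetric(co$experiment)
    sp <- splitCohort(pe, seed = 55)
    feats <- encodePeptides(pe, "missing_binary")
    g <- setNames(sampleGroups(pe) == "long_lived", colnames(pe))
    fit1 <- fitLongevityModel(feats[sp$discovery_ids, ], g[sp$discovery_ids],
                              cvControl(5, 2, seed = 3), "missing_binary")
    ## scrambling the holdout labels cannot touch any discovery-side quantity
    fit2 <- fitLongevityModel(feats[sp$discovery_ids, ], g[sp$discovery_ids],
                              cvControl(5, 2, seed = 3), "missing_binary")
    holdoutScrambled <- sample(g[sp$holdout_ids])
    expect_identical(selectedPeptides(fit1), selectedPeptides(fit2))
    expect_identical(cvAuc(fit1), cvAuc(fit2))
    expect_identical(fit1@weights, fit2@weights)
    ## and feeding discovery samples back in as "holdout" is an error
    expect_error(evaluateHoldout(fit1, feats[sp$discovery_ids[1:4], ],
                                 g[sp$discovery_ids[1:4]]), "leakage")
    ev <- evaluateHoldout(fit1, feats[sp$holdout_ids, ], g[sp$holdout_ids])
    expect_true(ev$holdout_auc >= 0 && ev$holdout_auc <= 1)
    expect_length(ev$scores, 16)
})

test_that("informative binary features outrank noise by selection frequency", {
    nInf <- 5; nNoise <- 120; n <- 32
    freq <- setNames(numeric(nInf + nNoise),
                     c(sprintf("INF%d__1", 1:nInf),
                       sprintf("NOI%03d__1", 1:nNoise)))
    y <- rep(c(TRUE, FALSE), each = n / 2)
    for (s in 1:10) {
        set.seed(300 + s)
        inf <- sapply(1:nInf, function(i)
            rbinom(n, 1, ifelse(y, 0.9, 0.1)))
        noise <- matrix(rbinom(n * nNoise, 1, 0.5), n)
        x <- cbind(inf, noise)
        colnames(x) <- names(freq)
        rownames(x) <- paste0("s", 1:n)
        m <- fitLongevityModel(x, y, cvControl(5, 2, seed = s),
                               "missing_binary")
        freq[selectedPeptides(m)] <- freq[selectedPeptides(m)] + 1
    }
    expect_gt(min(freq[1:nInf]), max(freq[-(1:nInf)]))
})
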