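toyRegions <- list(
    C9X = list(length = 30, regions = data.frame(
        name = c("beta chain", "alpha chain", "C9Xa"),
        kind = c("chain", "chain", "anaphylatoxin"),
        start = c(1L, 16L, 16L), end = c(15L, 30L, 22L))))

test_that("peptide ids parse per the SYMBOL__N[ox] convention", {
    p <- parsePeptideId("C3__95")
    expect_equal(p$protein_symbol, "C3")
    expect_equal(p$ordinal, 95L)
    expect_false(p$modified)
    p <- parsePeptideId("APOB__264ox")
    expect_equal(p$protein_symbol, "APOB")
    expect_equal(p$ordinal, 264L)
    expect_true(p$modified)
    expect_error(parsePeptideId("C3-95"), "malformed")
    expect_error(parsePeptideId(""), "non-empty")
    ## id comparison is case-insensitive, preserving the raw form
    expect_true(samePeptideId("C4A__136", "C4a__136"))
    expect_false(samePeptideId("C4A__136", "C4A__137"))
})

test_that("exact-match localization returns every 1-based inclusive interval", {
    hit <- locatePeptide("ACD", "WWACDY")
    expect_equal(hit$start, 3L)
    expect_equal(hit$end, 5L)
    expect_equal(nrow(locatePeptide("QQQ", "WWACDY")), 0L)
    multi <- locatePeptide("ACG", "ACGWACG")
    expect_equal(multi$start, c(1L, 5L))
    overlapping <- locatePeptide("AA", "AAA")
    expect_equal(overlapping$start, c(1L, 2L))
    expect_error(locatePeptide("AXB", "WWACDY"), "alphabet")
    expect_error(locatePeptide("ACDWW", "ACD"), "shorter")
})

test_that("located intervals round-trip to the peptide sequence", {
    co <- generateCohort(syntheticConfig(nProteins = 15, nMarkers = 0,
                                         seed = 44))
    rd <- as.data.frame(SummarizedExperiment::rowData(co$experiment))
    seqs <- as.character(co$proteins)
    set.seed(1)
    for (i in sample(nrow(rd), 25)) {
        loc <- locatePeptide(rd$sequence[i], seqs[[rd$protein[i]]])
        expect_gte(nrow(loc), 1)
        for (j in seq_len(nrow(loc)))
            expect_identical(substr(seqs[[rd$protein[i]]],
                                    loc$start[j], loc$end[j]),
                             rd$sequence[i])
    }
})

test_that("region labels carry residue-exact overlap fractions", {
    ## fully inside the beta chain
    inBeta <- annotateRegion("C9X", 3, 9, toyRegions)
    expect_equal(inBeta$region, "beta chain")
    expect_equal(inBeta$overlap_fraction, 1)
    expect_true(inBeta$contained)
    ## straddling the 15|16 chain boundary: 10..19 -> 6 and 4 residues
    straddle <- annotateRegion("C9X", 10, 19, toyRegions)
    chains <- straddle[straddle$kind == "chain", ]
    expect_equal(chains$overlap_fraction[chains$region == "beta chain"], 0.6)
    expect_equal(chains$overlap_fraction[chains$region == "alpha chain"], 0.4)
    expect_false(any(chains$contained))
    ## disjoint exhaustive chains: fractions sum to 1
    expect_equal(sum(chains$overlap_fraction), 1)
    ## nested anaphylatoxin inside the alpha chain: both reported at 1.0
    nested <- annotateRegion("C9X", 17, 21, toyRegions)
    expect_setequal(nested$region, c("alpha chain", "C9Xa"))
    expect_equal(nested$overlap_fraction, c(1, 1))
    expect_error(annotateRegion("NOPE", 1, 5, toyRegions), "unknown protein")
})

test_that("region summaries mirror the chain-restriction pattern", {
    protSeq <- c(C9X = paste(rep("ACDEFGHIKL", 3), collapse = ""))
    ## four lower_in_long peptides inside the beta chain (1..15)
    hits <- data.frame(
        peptide_id = sprintf("C9X__%d", 1:5),
        protein = "C9X",
        sequence = c("ACDE", "CDEF", "DEFG", "EFGH", "ACDEFGHIKLACD"),
        direction = c(rep("lower_in_long", 4), "higher_in_long"))
    mapped <- mapPeptides(hits, protSeq, toyRegions)
    sm <- summarizeRegions(mapped)
    lower <- sm[sm$direction == "lower_in_long", ]
    expect_equal(lower$region, "beta chain")
    expect_equal(lower$n_peptides, 4)
    ## input order cannot change the summary
    perm <- mapped[sample(nrow(mapped)), ]
    expect_equal(summarizeRegions(perm), sm)
    ## no differential peptides -> empty summary
    expect_equal(nrow(summarizeRegions(mapped[0, ])), 0L)
})

test_that("one peptide per chain yields one count per chain row", {
    protSeq <- c(C9X = "ACDEFGHIKLMNPQRSTVWYYWVTSRQPNM")  # no repeats
    regions3 <- list(C9X = list(length = 30, regions = data.frame(
        name = c("beta chain", "alpha chain", "gamma chain"), kind = "chain",
        start = c(1L, 11L, 21L), end = c(10L, 20L, 30L))))
    hits <- data.frame(peptide_id = sprintf("C9X__%d", 1:3),
                       protein = "C9X",
                       sequence = c(substr(protSeq, 2, 7),
                                    substr(protSeq, 12, 18),
                                    substr(protSeq, 23, 28)),
                       direction = "higher_in_long")
    sm <- summarizeRegions(mapPeptides(hits, protSeq, regions3))
    expect_equal(nrow(sm), 3L)
    expect_true(all(sm$n_peptides == 1))
    expect_setequal(sm$region, c("beta chain", "alpha chain", "gamma chain"))
})

test_that("multi-site matches are all reported but summarized once by default", {
    protSeq <- c(P1 = "ACDACDACDWWW")
    regions <- list(P1 = list(length = 12, regions = data.frame(
        name = "beta chain", kind = "chain", start = 1L, end = 12L)))
    hits <- data.frame(peptide_id = "P1__1", protein = "P1",
                       sequence = "ACD", direction = "higher_in_long")
    mapped <- mapPeptides(hits, protSeq, regions)
    expect_equal(max(mapped$match_index), 3L)
    expect_equal(summarizeRegions(mapped)$n_peptides, 1)
    expect_equal(summarizeRegions(mapped, allMatches = TRUE)$n_peptides, 1)
})
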