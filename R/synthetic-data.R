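## Synthetic cohort generator. Emulates the statistical structure the
## downstream analysis assumes -- latent log-normal peptide abundances
## nested in proteins, group abundance effects, abundance-dependent
## (MNAR) detection, group-differential detection for selected
## peptides, and surface-marker percentages driven by designated
## peptides -- together with the ground truth needed for recovery
## tests. All distributions are stand-ins: the source study publishes
## no distributional description of its peptide quantities.

.AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## One root seed governs all draws; stages use root + fixed offsets
## (documented contract, kept below 2^31).
.deriveSeed <- function(seed, offset) {
    as.integer((as.numeric(seed) + 97L * offset) %% (.Machine$integer.max - 1))
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study design: 24 samples per survival group and
#' a peptidome of ~1000 peptides nested in 150 proteins with roughly
#' half the peptides fully observed, 5% carrying a group abundance
#' effect of 1.5 latent-SD, 5% carrying a group-differential detection
#' (informative missingness) effect, and 25 surface markers linked to
#' differential peptides.
#'
#' @param nPerGroup Samples per survival group.
#' @param nProteins Number of proteins.
#' @param peptidesPerProtein Expected peptides per protein; counts are
#'   drawn as `1 + Poisson(peptidesPerProtein - 1)` unless
#'   `fixedPeptidesPerProtein = TRUE`, which gives every protein exactly
#'   `round(peptidesPerProtein)` peptides.
#' @param fixedPeptidesPerProtein Use a fixed per-protein count.
#' @param fracDifferential Fraction of peptides given a group abundance
#'   shift.
#' @param effectSize Standardized group mean shift, in units of the
#'   total latent log-abundance SD (protein effect + residual = 1).
#' @param detectionMidpoint Latent log-abundance at 50% detection.
#' @param detectionSlope Steepness of the logistic detection curve
#'   (> 0).
#' @param fracInformativeMissing Fraction of peptides whose detection
#'   midpoint differs between groups (signal in missingness only).
#' @param informativeShift Between-group detection-midpoint offset for
#'   informative-missing peptides, in latent-SD units.
#' @param nMarkers Number of surface markers (each measured in the
#'   LEV/MEV/SEV size classes).
#' @param markerLinkStrength Correlation magnitude in \[0, 1) between a
#'   marker and the latent signal of its linked peptides.
#' @param linkedPeptidesPerMarker Differential peptides driving each
#'   marker.
#' @param proteinEffectSd,residualSd SDs of the protein-level shared
#'   random effect and the peptide residual; their squares sum to 1 so
#'   `effectSize` is on the total-SD scale.
#' @param peptideMeanSd SD of per-peptide mean latent abundances.
#' @param volumeFor20ug Per-sample ul of plasma-equivalent yielding
#'   20 ug EV protein (constant across samples by default).
#' @param seed Root integer seed.
#' @return A validated list of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(nPerGroup = 24L, nProteins = 150L,
                            peptidesPerProtein = 7,
                            fixedPeptidesPerProtein = FALSE,
                            fracDifferential = 0.05, effectSize = 1.5,
                            detectionMidpoint = -3, detectionSlope = 2,
                            fracInformativeMissing = 0.05,
                            informativeShift = 2, nMarkers = 25L,
                            markerLinkStrength = 0.8,
                            linkedPeptidesPerMarker = 2L,
                            proteinEffectSd = sqrt(0.3),
                            residualSd = sqrt(0.7), peptideMeanSd = 2,
                            volumeFor20ug = 5, seed = 1L) {
    cfg <- list(nPerGroup = as.integer(nPerGroup),
                nProteins = as.integer(nProteins),
                peptidesPerProtein = peptidesPerProtein,
                fixedPeptidesPerProtein = isTRUE(fixedPeptidesPerProtein),
                fracDifferential = fracDifferential,
                effectSize = effectSize,
                detectionMidpoint = detectionMidpoint,
                detectionSlope = detectionSlope,
                fracInformativeMissing = fracInformativeMissing,
                informativeShift = informativeShift,
                nMarkers = as.integer(nMarkers),
                markerLinkStrength = markerLinkStrength,
                linkedPeptidesPerMarker = as.integer(linkedPeptidesPerMarker),
                proteinEffectSd = proteinEffectSd, residualSd = residualSd,
                peptideMeanSd = peptideMeanSd,
                volumeFor20ug = volumeFor20ug, seed = as.integer(seed))
    fr <- c(cfg$fracDifferential, cfg$fracInformativeMissing,
            cfg$markerLinkStrength)
    if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1) ||
        cfg$markerLinkStrength >= 1)
        stop("configuration error: fractions must lie in [0,1] and ",
             "markerLinkStrength in [0,1)")
    if (cfg$nPerGroup < 1L || cfg$nProteins < 1L ||
        cfg$peptidesPerProtein < 1 || cfg$nMarkers < 0L)
        stop("configuration error: counts must be >= 1")
    if (!is.finite(cfg$detectionSlope) || cfg$detectionSlope <= 0)
        stop("configuration error: detectionSlope must be > 0")
    if (cfg$volumeFor20ug <= 0)
        stop("configuration error: volumeFor20ug must be > 0")
    class(cfg) <- "SyntheticConfig"
    cfg
}

#' Abundance-dependent detection (MNAR mechanism)
#'
#' Each latent log-abundance is observed with probability
#' `plogis((latent - midpoint) * slope)`; unobserved entries become
#' `NA` and observed entries are carried to the positive quantity scale
#' as `exp(latent)`. This is the simplest monotone mechanism consistent
#' with missingness driven by low expression.
#'
#' @param latent Numeric vector of latent log-abundances.
#' @param midpoint Latent value at 50% detection.
#' @param slope Logistic steepness, > 0.
#' @param seed Integer seed for the Bernoulli draws.
#' @return List with `observed` (quantities, `NA` where missing) and
#'   `missing` (logical mask).
#' @export
applyDetection <- function(latent, midpoint, slope, seed) {
    if (!is.finite(slope) || slope <= 0) stop("slope must be > 0")
    set.seed(as.integer(seed))
    .detect(latent, midpoint, slope)
}

## core detection draw; caller controls the RNG state
.detect <- function(latent, midpoint, slope) {
    p <- stats::plogis((latent - midpoint) * slope)
    missing <- stats::runif(length(latent)) >= p
    observed <- exp(latent)
    observed[missing] <- NA_real_
    if (is.matrix(latent)) {
        dim(observed) <- dim(latent); dimnames(observed) <- dimnames(latent)
        dim(missing) <- dim(latent); dimnames(missing) <- dimnames(latent)
    }
    list(observed = observed, missing = missing)
}

.randomProteinSequence <- function(len) {
    paste(sample(.AA, len, replace = TRUE), collapse = "")
}

## chain/fragment/anaphylatoxin annotation for one protein, mimicking
## processed complement proteins (beta | alpha [| gamma] chains, an
## anaphylatoxin nested at the alpha-chain N-terminus, optional
## a/b fragments subdividing the alpha chain)
.randomRegions <- function(len, nChains, anaphylatoxin, fragments, symbol) {
    names3 <- c("beta chain", "alpha chain", "gamma chain")
    cuts <- sort(sample(seq(40L, len - 40L), nChains - 1L))
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, len)
    regions <- data.frame(name = names3[seq_len(nChains)], kind = "chain",
                          start = starts, end = ends,
                          stringsAsFactors = FALSE)
    aStart <- starts[2L]; aEnd <- ends[2L]
    if (anaphylatoxin) {
        spanEnd <- min(aStart + 73L, aEnd)
        regions <- rbind(regions,
                         data.frame(name = paste0(symbol, "a"),
                                    kind = "anaphylatoxin",
                                    start = aStart, end = spanEnd))
    }
    if (fragments && aEnd - aStart > 80L) {
        mid <- aStart + (aEnd - aStart) %/% 2L
        regions <- rbind(regions,
                         data.frame(name = c("a fragment", "b fragment"),
                                    kind = "fragment",
                                    start = c(aStart, mid + 1L),
                                    end = c(mid, aEnd)))
    }
    regions
}

#' Generate a synthetic EV-peptide cohort with ground truth
#'
#' Draws protein sequences with chain/anaphylatoxin annotations,
#' peptides as exact substrings, latent log-abundances with
#' protein-level shared random effects, applies the group abundance
#' shifts and the logistic detection mechanism, and builds a surface
#' marker table driven by designated differential peptides. Abundance
#' effects are planted only on peptides comfortably above the detection
#' limit (mean latent abundance at least 5 latent-SD above the
#' detection midpoint, so they stay fully observed even when shifted
#' down) so that abundance signal expresses in quantities; detection-level signal is planted
#' separately on informative-missing peptides, whose detection midpoint
#' is centred at the peptide's own mean and offset by
#' `informativeShift / 2` in opposite directions per group.
#'
#' @param config A [syntheticConfig()] object.
#' @return List with components `experiment`
#'   ([PeptideExperiment-class], gravimetric basis), `markers`
#'   (long-format data.frame: sample_id, marker, size_class,
#'   percentage), `truth` (differential peptide ids with directions,
#'   informative-missing ids, marker links), `proteins`
#'   ([Biostrings::AAStringSet]) and `regions` (region annotation set,
#'   1-based inclusive coordinates).
#' @examples
#' cohort <- generateCohort(syntheticConfig(nProteins = 20, seed = 7))
#' cohort$experiment
#' @export
generateCohort <- function(config = syntheticConfig()) {
    if (!inherits(config, "SyntheticConfig"))
        stop("configuration error: use syntheticConfig()")
    cfg <- config
    nS <- 2L * cfg$nPerGroup

    ## stage 1: cohort structure, proteins, peptides, regions
    set.seed(.deriveSeed(cfg$seed, 1L))
    sampleIds <- c(sprintf("SL%02d", seq_len(cfg$nPerGroup)),
                   sprintf("LL%02d", seq_len(cfg$nPerGroup)))
    group <- factor(rep(.GROUP_LEVELS, each = cfg$nPerGroup),
                    levels = .GROUP_LEVELS)
    annotation <- data.frame(
        sample_id = sampleIds, group = group,
        volume_for_20ug = cfg$volumeFor20ug,
        age = pmin(80L, pmax(72L, round(stats::rnorm(nS, 77.2, 1.7)))),
        sex = rep_len(c("F", "M"), nS),
        race = rep_len(c("Black", "White"), nS),
        stringsAsFactors = FALSE)

    symbols <- sprintf("PROT%03d", seq_len(cfg$nProteins))
    protLen <- sample(250:600, cfg$nProteins, replace = TRUE)
    protSeq <- vapply(protLen, .randomProteinSequence, character(1))
    names(protSeq) <- symbols
    nChains <- sample(2:3, cfg$nProteins, replace = TRUE)
    hasAna <- stats::runif(cfg$nProteins) < 0.3
    hasFrag <- stats::runif(cfg$nProteins) < 0.2
    regions <- lapply(seq_len(cfg$nProteins), function(i)
        list(length = protLen[i],
             regions = .randomRegions(protLen[i], nChains[i], hasAna[i],
                                      hasFrag[i], symbols[i])))
    names(regions) <- symbols

    nPepPerProt <- if (cfg$fixedPeptidesPerProtein)
        rep(as.integer(round(cfg$peptidesPerProtein)), cfg$nProteins)
    else
        1L + stats::rpois(cfg$nProteins, cfg$peptidesPerProtein - 1)
    protOf <- rep(seq_len(cfg$nProteins), nPepPerProt)
    nP <- length(protOf)
    pepLen <- sample(8:18, nP, replace = TRUE)
    pepStart <- vapply(seq_len(nP), function(i)
        sample.int(protLen[protOf[i]] - pepLen[i] + 1L, 1L), integer(1))
    pepSeq <- substr(protSeq[protOf], pepStart, pepStart + pepLen - 1L)
    ordinal <- unlist(lapply(nPepPerProt, seq_len), use.names = FALSE)
    modified <- stats::runif(nP) < 0.1
    pepIds <- paste0(symbols[protOf], "__", ordinal,
                     ifelse(modified, "ox", ""))
    mu <- stats::rnorm(nP, 0, cfg$peptideMeanSd)

    ## stage 2: planted effects (exact counts from config fractions)
    set.seed(.deriveSeed(cfg$seed, 2L))
    nDiff <- round(cfg$fracDifferential * nP)
    eligible <- which(mu - cfg$detectionMidpoint >= 5)
    if (nDiff > length(eligible))
        stop("configuration error: too few well-detected peptides to plant ",
             nDiff, " differential effects")
    diffIdx <- sort(sample(eligible, nDiff))
    diffDir <- rep_len(c("higher_in_long", "lower_in_long"), nDiff)
    nInf <- round(cfg$fracInformativeMissing * nP)
    infPool <- setdiff(seq_len(nP), diffIdx)
    if (nInf > length(infPool))
        stop("configuration error: too few peptides left for informative ",
             "missingness")
    infIdx <- sort(sample(infPool, nInf))
    infOrient <- rep_len(c(1, -1), nInf)  # +1: long-lived detected more

    ## stage 3: latent abundances and detection
    set.seed(.deriveSeed(cfg$seed, 3L))
    delta <- numeric(nP)
    delta[diffIdx] <- ifelse(diffDir == "higher_in_long",
                             cfg$effectSize, -cfg$effectSize)
    isLong <- group == "long_lived"
    protEff <- matrix(stats::rnorm(cfg$nProteins * nS, 0, cfg$proteinEffectSd),
                      cfg$nProteins, nS)
    latent <- mu + outer(delta, as.numeric(isLong)) + protEff[protOf, ] +
        matrix(stats::rnorm(nP * nS, 0, cfg$residualSd), nP, nS)
    dimnames(latent) <- list(pepIds, sampleIds)

    midpoint <- matrix(cfg$detectionMidpoint, nP, nS)
    if (nInf > 0) {
        off <- outer(infOrient * cfg$informativeShift / 2,
                     ifelse(isLong, -1, 1))
        midpoint[infIdx, ] <- mu[infIdx] + off
    }
    det <- .detect(latent, midpoint, cfg$detectionSlope)

    pe <- PeptideExperiment(
        quant = det$observed, sampleData = annotation,
        peptideData = data.frame(protein = symbols[protOf],
                                 sequence = pepSeq, ordinal = ordinal,
                                 modified = modified,
                                 stringsAsFactors = FALSE),
        basis = "gravimetric")

    ## stage 4: surface markers linked to complete differential peptides
    set.seed(.deriveSeed(cfg$seed, 4L))
    markerNames <- sprintf("MK%02d", seq_len(cfg$nMarkers))
    completeDiff <- diffIdx[rowSums(det$missing[diffIdx, , drop = FALSE]) == 0]
    ## a marker-defined EV subpopulation carries its cargo coherently:
    ## each marker tracks same-direction differential peptides
    dirOf <- diffDir[match(completeDiff, diffIdx)]
    pools <- list(completeDiff[dirOf == "higher_in_long"],
                  completeDiff[dirOf == "lower_in_long"])
    pools <- pools[lengths(pools) >= cfg$linkedPeptidesPerMarker]
    canLink <- length(pools) > 0 && cfg$nMarkers > 0
    links <- list()
    markerRows <- vector("list", cfg$nMarkers * 3L)
    k <- 0L
    for (mi in seq_along(markerNames)) {
        m <- markerNames[mi]
        if (canLink) {
            pool <- pools[[1L + (mi - 1L) %% length(pools)]]
            lk <- sort(sample(pool, cfg$linkedPeptidesPerMarker))
            links[[m]] <- pepIds[lk]
            sig <- as.numeric(scale(colMeans(latent[lk, , drop = FALSE])))
        } else {
            sig <- numeric(nS)
        }
        s <- if (canLink) cfg$markerLinkStrength else 0
        for (sc in c("LEV", "MEV", "SEV")) {
            z <- s * sig + sqrt(1 - s^2) * stats::rnorm(nS)
            k <- k + 1L
            markerRows[[k]] <- data.frame(
                sample_id = sampleIds, marker = m, size_class = sc,
                percentage = pmin(100, pmax(0, 40 + 15 * z)),
                stringsAsFactors = FALSE)
        }
    }
    markers <- do.call(rbind, markerRows)
    if (is.null(markers))
        markers <- data.frame(sample_id = character(), marker = character(),
                              size_class = character(),
                              percentage = numeric())

    truth <- list(
        differential = data.frame(peptide_id = pepIds[diffIdx],
                                  direction = diffDir,
                                  stringsAsFactors = FALSE),
        informative_missing = data.frame(
            peptide_id = pepIds[infIdx],
            orientation = ifelse(infOrient > 0, "higher_in_long",
                                 "lower_in_long"),
            stringsAsFactors = FALSE),
        marker_links = links)

    list(experiment = pe, markers = markers, truth = truth,
         proteins = Biostrings::AAStringSet(protSeq), regions = regions,
         config = cfg)
}
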