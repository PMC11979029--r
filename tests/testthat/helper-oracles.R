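## Brute-force oracles, deliberately independent of the implementation
## paths they check.

## two-sided rank-sum p by full enumeration of all group labelings
oracleRankSumP <- function(x, y) {
    pooled <- c(x, y)
    m <- length(x)
    n <- length(pooled)
    uStat <- function(idx) {
        xs <- pooled[idx]; ys <- pooled[-idx]
        sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
    }
    u0 <- uStat(seq_len(m))
    us <- apply(utils::combn(n, m), 2, uStat)
    centre <- m * (n - m) / 2
    mean(abs(us - centre) >= abs(u0 - centre) - 1e-9)
}

## BH step-up by its definition: largest k with p_(k) <= k q / m
oracleBH <- function(p, q) {
    m <- length(p)
    o <- order(p)
    ok <- which(p[o] <= seq_len(m) * q / m)
    rej <- logical(m)
    if (length(ok)) rej[o[seq_len(max(ok))]] <- TRUE
    rej
}

## AUC by explicit pair counting
oracleAUC <- function(scores, labels) {
    pos <- scores[labels]; neg <- scores[!labels]
    tot <- 0
    for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
}

## tie-free Spearman rho via the d^2 rank formula
oracleSpearmanRho <- function(x, y) {
    d <- rank(x) - rank(y)
    n <- length(x)
    1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

.allPerms <- function(n) {
    if (n == 1L) return(matrix(1L))
    sub <- .allPerms(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k) {
        rest <- seq_len(n)[-k]
        cbind(k, matrix(rest[sub], nrow(sub)))
    }))
}

## exact two-sided permutation p for |rho|, small n
oracleSpearmanPermP <- function(x, y) {
    rho0 <- abs(stats::cor(x, y, method = "spearman"))
    perms <- .allPerms(length(y))
    rhos <- apply(perms, 1, function(i)
        abs(stats::cor(x, y[i], method = "spearman")))
    mean(rhos >= rho0 - 1e-12)
}

## Pearson chi-squared closed form for a 2x2 table
oracleChi2 <- function(a, b, c, d) {
    n <- a + b + c + d
    n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

## small hand-buildable experiment: quant is peptide x sample
toyExperiment <- function(quant, groups, volume = 5, protein = NULL) {
    ann <- data.frame(group = groups, volume_for_20ug = volume,
                      row.names = colnames(quant))
    pd <- if (!is.null(protein)) data.frame(protein = protein) else NULL
    PeptideExperiment(quant, ann, peptideData = pd)
}
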