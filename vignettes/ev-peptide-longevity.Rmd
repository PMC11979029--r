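---
title: "Missingness-stratified EV peptide analysis and longevity prediction: methods"
author: "evlongevity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Missingness-stratified EV peptide analysis and longevity prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its statistical methods: the
model behind each stage, the assumptions those models make, the
parameters that matter and why their defaults are what they are, and
the places where the design was genuinely open and a choice had to be
made.

## The data model

The central object is a `PeptideExperiment`, a `SummarizedExperiment`
whose `quant` assay holds a peptide x sample matrix of non-negative
label-free quantification (LFQ) values with `NA` marking peptides not
detected in a sample. Two conventions are enforced throughout:

* **Missing is not zero.** An observed quantity of exactly 0 stays
  observed. LFQ missingness is informative — a peptide below the
  detection limit produces no value at all — and conflating the two
  destroys the signal the missingness track and the binary encoding
  exploit.
* **The basis flag flips once.** Quantities arrive on a gravimetric
  (per-ug EV protein) basis and are converted to a volumetric
  (per-ul plasma) basis by `value / volume_for_20ug * 2`, where
  `volume_for_20ug` (ul) is stored per sample and the factor 2 undoes
  a twofold urea dilution. Converting an already-volumetric table is
  an error rather than a silent no-op, so double application cannot
  occur. The conversion is per-sample because each sample has its own
  dilution bookkeeping; with a volume constant across samples it is a
  common rescaling, and all rank-based analyses are invariant to it
  (a property the tests assert).

No log transform is applied before the rank tests — ranks are
invariant to monotone transforms — and the predictive module
standardizes features instead.

## Dual-track differential analysis

Peptides are stratified by the missingness profile: *complete* means
missing rate exactly 0% in both groups; everything else is
*incomplete*. The two sets partition the peptidome and are analysed on
separate tracks:

* **Quantitative track** (complete peptides): two-sided Wilcoxon
  rank-sum test per peptide. The p-value is exact by enumeration when
  the combined sample size is at most 14 and there are no ties;
  otherwise the normal approximation with tie correction and
  continuity correction applies. The bound is documented so p-values
  are bit-for-bit reproducible; at the study's 24+24 size the
  approximate branch always applies. Direction for rejected peptides
  is the sign of (long-lived median − short-lived median), consistent
  with the rank test.
* **Missingness track** (incomplete peptides): Pearson chi-squared
  with 1 df on the 2x2 missing/observed x group table, without
  continuity correction — the plain reading of "chi-squared test",
  with Yates' correction deliberately omitted (it is conservative for
  balanced designs of this size and the choice is a single documented
  place in the code). A lower missing rate in the long-lived group is
  interpreted as higher abundance there. Tables with a zero margin
  inside the analysed set (a peptide observed everywhere after
  subsetting, or observed nowhere) are excluded and reported, never
  patched with pseudo-counts: a pseudo-count would manufacture a
  p-value for a contrast the data cannot inform.

Benjamini–Hochberg FDR control at q = 0.01 is applied **separately
within each track**, mirroring the two separate FDR statements of the
design this package implements; a joint-family option exists behind
`family = "joint"` for users who prefer one family. Family separation
is load-bearing: adding peptides to one track never changes the other
track's q-values (tested as an invariant).

Rollups count rejected peptides and their **distinct** parent proteins
in four categories (quantitative higher/lower, missingness
higher/lower abundance in long-lived); a protein contributing to two
categories is counted once per category, so category protein counts do
not sum to a distinct-protein total by construction.

## Longevity prediction

Three encodings of the volumetric table are supported: complete
peptides as continuous features; incomplete peptides as binary
observed (1) / missing (0) indicators; and all peptides with missing
values imputed as zero. The cohort is split 2:1 into discovery and
holdout, stratified by group — 16+16 discovery and 8+8 holdout at the
24+24 design size — and the holdout samples are never touched during
fitting or selection, enforced by sample-id bookkeeping that raises an
error on overlap.

The classifier is L1-penalized (lasso) logistic regression. The
original study defers its classifier and feature-selection algorithm
to supplementary material that is not part of this package's inputs;
penalized logistic regression with nested cross-validation was chosen
as a transparent, sparse, fully seedable procedure, and the package
makes **no claim of algorithmic fidelity** to the original modeling —
nor any attempt to recover specific published peptide predictors,
which would require the original cohort data. Details that affect
reproducibility:

* Continuous features are z-scored with discovery-sample statistics
  (stored in the model and re-applied at prediction time, so holdout
  data cannot leak into the standardization); binary features stay
  0/1.
* Zero-variance features are dropped up front. If nothing remains the
  degenerate model scores every sample identically and reports CV AUC
  0.5 with an empty selection.
* The penalty path comes from a single `glmnet` fit on all discovery
  samples; repeated stratified k-fold CV (default 5 folds, 10
  repeats) evaluates the mean held-fold rank AUC along that shared
  path; the chosen penalty maximizes mean AUC with ties broken toward
  the **larger** penalty (the sparser model). The final model is the
  refit on all discovery samples at that penalty, and its nonzero
  coefficients are the selected peptides.
* AUC is the rank formulation — (concordant + 0.5 x tied) / all
  positive-negative pairs — so tied scores are handled exactly and a
  constant scorer is 0.5 by definition.

Peptide ids follow the `SYMBOL__<n>[ox]` convention, with `ox`
marking an oxidized variant; id comparison is case-insensitive (ids
differing only in symbol case denote the same peptide) while raw forms
are preserved.

## Peptide-to-region mapping

Protein coordinates are 1-based inclusive — the protein
sequence-feature convention — and the region file declares this
explicitly to preclude BED-style half-open confusion. The ordinal in
`SYMBOL__N` is treated as an opaque identifier, **not** a residue
position: localization is by exact sequence match only, reporting
every match site (including overlapping occurrences). Every region
with at least one residue of overlap is attached with its overlap
fraction (overlapping residues / peptide length); nested regions such
as an anaphylatoxin inside an alpha chain are all reported and full
containment is flagged. Per-region direction summaries count a
peptide in each region it overlaps, using the first match site unless
all sites are requested — multi-site matches are rare for tryptic-
length peptides and the first-site rule keeps counts stable.

## Surface-marker statistics

Marker percentages (per marker and LEV/MEV/SEV size class, in
[0, 100]) are compared between groups with the same rank-sum test,
flagged at raw p < 0.05 **without** multiplicity adjustment — this
module's significance convention, unlike the FDR-controlled proteomic
tracks — with BH available behind a flag. Spearman correlations
against longevity-associated peptides (rejected on either track, with
a per-track breakdown emitted) use pairwise-complete samples per
peptide, skipping pairs with fewer than 3 observations; a correlation
counts as significant-positive when p < 0.05 and rho > 0.

## The synthetic cohort generator

The generator defines the conditions under which the pipeline's
operating characteristics are measured. Its structure:

* Latent log-abundance of peptide p in sample s is
  `mu_p + delta_p 1[long] + a_{prot(p),s} + e_{ps}`, with per-peptide
  means `mu_p ~ N(0, 2^2)`, a protein-level random effect shared by
  all peptides of a protein (SD sqrt(0.3)) and residual SD sqrt(0.7),
  so the total within-group SD is 1 and `effectSize` is a
  standardized shift. The protein effect exists because rollup counts
  (peptides *and* distinct proteins) are only non-trivial when
  peptides of one protein correlate.
* Detection is a logistic curve on the latent value: observed with
  probability `plogis((x - midpoint) * slope)`; observed entries carry
  `exp(x)` (positive quantity scale), unobserved entries are `NA`.
  This is the simplest monotone MNAR mechanism consistent with
  missingness caused by low expression. Defaults `midpoint = -3`,
  `slope = 2` together with the `mu_p` spread were calibrated so that
  at 48 samples roughly half the peptidome is fully observed and
  essentially none is entirely unobserved — the split the published
  data structure shows (1834 complete vs 1861 incomplete peptides) —
  rather than to any test outcome.
* Abundance effects (`fracDifferential`, default 5%; `effectSize`,
  default 1.5 SD) are planted only on peptides whose mean is at least
  5 latent-SD above the detection midpoint, so the effect expresses
  in quantities rather than in detection and survives a downward
  group shift without demoting the peptide to the incomplete stratum.
  This reflects a structural property of the dual-track design: a
  peptide with one or two missing values is excluded from the
  quantitative track yet carries almost no chi-squared power, so
  effects planted there are invisible to any analysis — and real
  discovered peptides are, by construction, ones where the design has
  power.
* Informative missingness (`fracInformativeMissing`, default 5%) is
  planted by giving selected peptides a detection midpoint centred at
  their own mean (detection hovers near 50%) and offset by
  `informativeShift/2 = 1` latent-SD in opposite directions per
  group, yielding per-sample detection probabilities near 0.78 vs
  0.22 — recoverable by the chi-squared track and by the binary
  encoding, which is the design's key qualitative claim reproduced in
  silico.
* Markers are driven by same-direction complete differential peptides
  (a marker-defined EV subpopulation carries its cargo coherently;
  mixing directions would cancel the composite signal):
  `z = strength * signal + sqrt(1 - strength^2) * noise`, mapped to a
  percentage as `clip(40 + 15 z, 0, 100)`, with `strength = 0.8` by
  default.
* One root seed governs everything through documented additive
  sub-seed offsets per stage; identical configs and seeds give
  bit-identical cohorts, and all fixture files round-trip losslessly
  (quantities are written with 17 significant digits).

What the generator does **not** emulate: real LFQ intensity
distributions (no published distributional description exists for
these data — all generator distributions are stand-ins), retention
times or spectra, batch and run-order effects, peptide-level variance
heterogeneity, shared-peptide protein inference ambiguity, and any
dependence between markers and peptides beyond the planted linear
links. Passing tests therefore demonstrate that the pipeline recovers
the structure it assumes, not that real plasma EV data satisfy those
assumptions.

## Baseline table and published counts

The package ships the published per-group means, SDs and sample sizes
of the 48-participant cohort baseline (demographics, complete blood
counts, physical-function scores) and recomputes the group comparisons
with a pooled-variance two-sample t-test on those summaries
(`n1 + n2 - 2` df, two-sided; Welch behind a flag — whether the
original tests pooled variances is unstated, and pooled is the default
reading of "standard t-test"). Because the stored inputs are rounded
to two decimals, recomputed p-values match published ones only to
rounding accuracy: about 1e-3 where group SDs are similar, and up to
1e-2 where one SD is given with little precision relative to its
magnitude (the age row). Published p-values themselves are not stored
in the package. The published peptidome counts (total, immune, muscle,
and the four differential categories) are shipped as a plain-text
input table for percentage-share computations.

## Problem sizes used by the tests

The operating characteristics are estimated at sizes chosen to make
the checks stable while keeping a full test run fast on one CPU: 200
null cohorts (~1050 peptides, 24+24 samples) for the false-discovery
proportion of both tracks; 100 cohorts for planted-effect sensitivity
and realized FDR; 6 detection-signal and 50 pure-noise cohorts for the
holdout-AUC bands (with 3 and 2 CV repeats respectively — the CV
repeat count affects penalty-selection stability, not the null
distribution of holdout AUC); exhaustive enumeration oracles up to
total n = 10 (rank-sum) and n = 9 (Spearman permutation null).
`scripts/acceptance.R` re-runs the same computations from scratch
under a caller-supplied seed.

## Known limitations

* The missingness track's chi-squared p-values are asymptotic;
  for very sparse 2x2 tables they are approximate, and the null FDP
  simulations are the evidence that BH on them still controls the
  false discovery proportion at this design size.
* The quantitative track's complete-case rule discards peptides with
  even a single missing value; the resulting dead zone between the
  tracks is a property of the published design, not of this
  implementation, and the zero-imputed encoding is the only stage
  that sees those peptides' quantities.
* With 8+8 holdout samples the holdout AUC is coarse (1/64 grid);
  single-cohort holdout AUCs should be read accordingly, which is why
  the acceptance quantities average over seeds.
* The classifier is a stand-in for unavailable original modeling
  details; selected-peptide identities are not comparable across
  classifiers and are out of scope for validation.
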