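---
title: "Node-stratified evaluation of prognostic gene signatures: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Node-stratified evaluation of prognostic gene signatures: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prognode)
```

## The problem

Axillary lymph-node (LN) status is the strongest clinical prognostic variable
in ER-positive breast cancer, yet commercial prognostic gene signatures differ
in which nodal populations they were developed on. A signature trained only on
node-negative disease can capture biology (for example proliferation) that
drives relapse in LN- tumours but carries little signal in LN+ tumours, where
other programs (for example anti-tumour immune response) dominate outcome.
`prognode` implements an in-silico workbench for exactly this question: score a
cohort with several signatures, evaluate each one separately in the LN- and
LN+ strata, discover a new signature on outcome classes, and probe the
stratum-specific biology with gene-set enrichment -- all exercisable end to end
on synthetic cohorts whose generating truth is known.

## Cohort preparation

Inputs are assumed to be RMA-normalised log2 intensities (probes or genes by
samples) plus a clinical table with ER, HER2 and LN status and
distant-metastasis-free survival (DMFS, months, with an event flag).
Preparation proceeds in four steps.

**Z-standardization.** Each feature is centred and scaled across samples,
`z = (x - mean) / sd`, using the sample SD (`n - 1`). This mimics how
assay-style scores are transported onto microarray data: all three scores are
computed on the Z scale, so they are centred near zero rather than on the
commercial reporting ranges. Zero-variance rows cannot be standardized and are
dropped (recorded in a report attribute) rather than set to zero, so no
downstream correlation or weighted average ever divides by zero.

**HER2 calling.** HER2+ tumours are removed because HER2 is a poor prognostic
factor in both strata and such patients are treated differently. When HER2
status is not annotated, it is called from the array's HER2 probes: a sample
is positive when *any* designated probe is overexpressed. Per probe, a
two-component Gaussian mixture (unequal variances, via `mclust`) is fitted and
a sample is positive when its posterior membership in the upper-mean component
exceeds 0.5. A forced two-component fit on unimodal data produces two
overlapping pseudo-components, so the mixture call is trusted only when the
components are genuinely separated -- Ashman's
`D = |mu1 - mu2| / sqrt((s1^2 + s2^2) / 2) >= 2`, the usual bimodality bar;
otherwise the call falls back to a conservative `mean + 2 SD` outlier
threshold. On a clearly bimodal probe (modes 5 component-SDs apart) the two
rules agree; the fallback matters exactly when there is no HER2-high
subpopulation to find.

**Filtering.** The analysis cohort is ER+ and not HER2+. Removal counts are
attributed ER-first (a sample that is both ER- and HER2+ counts against the ER
criterion), deterministically.

**Probe collapse.** Where several probes map to one gene, the gene's Z row is
the mean of its probes' Z rows. The alternative -- keeping the most variable
probe -- was rejected because it makes scores discontinuous under small
perturbations of synthetic probe sets; averaging Z rows is linear and keeps
every downstream score well defined. Genes with no probe present are reported,
and scoring functions abort (naming the gene) rather than silently
renormalising when a required gene is absent.

## The three scores

All three scores consume a gene-keyed, Z-standardized matrix.

**Weighted-group recurrence-score index** (`oncotype_rs`). The 16 prognostic
genes are organised in 7 functional groups (GRB7, ER, proliferation, invasion,
and three singletons). Each group score is a fixed weighted mean of member
Z values and the index is the published linear combination
`0.47*GRB7 - 0.34*ER + 1.04*proliferation + 0.10*invasion + 0.05*CD68
- 0.08*GSTM1 - 0.07*BAG1`. Housekeeping normalisation does not apply to
RMA-processed input and is omitted, as are the commercial group floors and the
0-100 rescaling: on the Z scale the index is roughly centred on zero, and
floors tuned to qRT-PCR reference-normalised units would be arbitrary here.
Higher values indicate worse prognosis.

**Subtype-correlation risk-of-recurrence score** (`prosigna_ror`). For each
sample, the Spearman correlation of its gene profile to each intrinsic-subtype
centroid is combined with fixed coefficients
(`-0.34 LumA + 0.23 LumB + 0.12 Her2 + 0.05 Basal`). This is the
correlation-only ("ROR-S"-like) variant: no gross-proliferation or tumour-size
term. Because it is rank-based it is invariant to any monotone per-sample
transform. Six genes absent from the U133A-era arrays (ANLN, NUF2/CDCA1,
CXXC5, FOXC1, TMEM45B, UBE2T) are excluded by default, leaving 44 genes; the
source text reports 45 available probesets while naming 6 exclusions from 50
genes, a one-gene discrepancy the fixture documents but does not resolve.
The bundled centroid *values* are synthetic stand-ins (the published matrix is
not redistributable here); the gene list, subtype set, exclusion list and
combination coefficients are the published ones, and nothing the package
validates quantitatively depends on the centroid entries.

**Directional mean-Z index** (`directional_mean_index`). The mean Z over
good-outcome genes minus the mean Z over poor-outcome genes, so the index
correlates positively with survival (orientation `higher_is_better`). The
bundled 58-gene signature is the literal transcription of the published
per-pathway table; deduplication yields 34 good + 24 poor genes, whereas the
source text counts 33 + 24 = 57. One gene (NAT10) is printed in both a
low-risk and a high-risk row; the signature fixture assigns it the high-risk
direction, which keeps the published count of 24 unique high-risk genes exact.
Both totals are reported rather than reconciled. If a signature carries only
one direction (which a discovery run restricted to one stratum can
legitimately produce), the missing side contributes a zero mean -- the
empty-average convention -- while a direction the signature declares but the
matrix lacks is an error.

## Survival evaluation

Scores are evaluated per stratum (LN-, LN+, optionally combined) with three
statistics.

**Cox proportional hazards** (`cox_fit`). The score is standardized to unit SD
before the fit, so hazard ratios are per SD of score and comparable across
signatures whose native scales differ by orders of magnitude; the reporting
convention (per-SD, native orientation, orientation recorded alongside) is
stated in every result because published HRs rarely say which scale they are
on. The fit itself uses `survival::coxph` with the Efron tie correction
(better than Breslow with discretised follow-up times), Wald confidence
intervals and p-values.

**Harrell's concordance** (`concordance_index`). Over comparable pairs -- the
member with the strictly earlier time has an event -- the fraction where the
risk-oriented score is higher for the earlier event, ties counting one half.
Protective scores are negated first, so C > 0.5 always means "prognostic in
the claimed direction". Implemented by direct pair enumeration (vectorised),
which the test suite checks against both brute-force loops and
`survival::concordance`.

**Median-split Kaplan-Meier** (`km_median_split`). Groups are
`score >= median` versus below, with ties deterministically assigned to the
high-score group; product-limit curves are computed in closed form and the
two-group log-rank test comes from `survival::survdiff`. A split that leaves
a group empty, or a stratum with no events, is an error rather than a silent
degenerate answer.

## Signature discovery

Discovery follows the nearest-shrunken-centroids (PAM) recipe on two outcome
classes.

**Outcome classes.** `event` = distant metastasis within 120 months;
`event_free` = metastasis-free with follow-up reaching 120 months (an event
after the horizon counts as event-free at 10 years). Samples censored before
120 months are excluded from training: they cannot be assigned a 10-year
class, and imputing them either way would bias the centroids. This censoring
rule is a package decision -- the procedure it reimplements does not state
one.

**Shrunken centroids** (`nsc_train`). For gene g and class k,
`d_kg = (xbar_kg - xbar_g) / (m_k (s_g + s0))` with pooled within-class SD
`s_g`, fudge `s0 = median(s_g)` and `m_k = sqrt(1/n_k - 1/n)` (the variance
factor of a class mean minus the overall mean). Soft-thresholding by the
shrinkage parameter delta, `d'_kg = sign(d) max(|d| - delta, 0)`, performs the
embedded feature selection; a gene survives when any class keeps `|d'| > 0`.
Prediction minimises the diagonal-covariance discriminant
`sum_g (x_g - xbar'_kg)^2 / (s_g + s0)^2 - 2 log pi_k`, with priors set to
observed class proportions and ties broken toward the first class level.

**Threshold choice** (`nsc_cv`). 10-fold stratified cross-validation of
held-out misclassification over 30 evenly spaced delta values from 0 to the
full-data `max |d_kg|` (the procedure's source names no grid). The chosen
delta minimises CV error with ties broken toward the *larger* delta -- fewer
genes -- a deliberate parsimony rule where the source does not state one
(min-error rather than the 1-SE rule; with the tie-break toward sparsity the
two rarely differ on the simulated cohorts). Fold assignment is stratified by
class and fixed by a recorded seed, so a CV result is reproducible
bit-for-bit.

**Direction assignment** (`derive_signature`). A surviving gene is `poor` when
its event-class shrunken centroid exceeds its overall centroid, else `good`;
the derived signature feeds the directional mean-Z index, mirroring how the
original index was built from its feature-selection stage.

## Gene-set enrichment

The enrichment engine follows the classic two-class weighted
Kolmogorov-Smirnov design. Genes are ranked by signal-to-noise
`(mu_A - mu_B) / (sigma_A + sigma_B)` with each class SD floored at
`max(0.2 |class mean|, 0.2)` (the standard guard against near-constant genes),
ties broken by symbol so the ranking is deterministic. Walking the ranked
list, set members add `|metric|^p / sum_hits |metric|^p` and non-members
subtract `1/(N - N_H)`; the enrichment score is the signed maximum-magnitude
excursion of the running sum, which necessarily returns to zero at the end of
the list. The weighting exponent defaults to `p = 1` and significance uses
phenotype permutation (class labels permuted, the whole ranking recomputed),
the defaults of the reference implementation of this algorithm;
`NES = ES / mean(|permuted ES| of the same sign)` and the nominal p is the
fraction of same-sign permuted scores at least as extreme. The plain-fraction
p can be zero at finite permutation counts and is slightly anti-conservative;
it is kept because it is the conventional definition. Enrichment runs
separately within the LN- and LN+ strata on the same 10-year outcome classes
used for discovery. Gene sets are read from standard GMT files; no gene-set
database is bundled.

## The synthetic cohort generator

`simulate_cohort` produces ER+/HER2- cohorts with known truth, built to
emulate the study design this package replays: 10-year DMFS follow-up with
right censoring, a stated LN+ fraction, and expression driven by latent
programs whose hazard effects differ by nodal stratum.

* **Programs.** Four latent activities per sample (standard normal):
  proliferation, immune, epigenetic, EMT. Member genes reuse real signature
  symbols (the proliferation program overlaps the recurrence-score and
  subtype signatures' proliferation genes; immune/epigenetic/EMT members come
  from the directional signature), and the gene universe embeds every bundled
  signature gene plus numbered filler genes, so all three signatures can be
  scored on synthetic data.
* **Expression.** `baseline + loading * activity + noise`, with per-gene
  baselines uniform on 6-10 (log2-like), loadings uniform on 0.7-1.3 and
  Gaussian noise with SD 0.5 -- values chosen to give informative genes
  roughly 0.9 correlation with their program, a realistic array
  signal-to-noise.
* **Survival.** Hazard is Weibull baseline times `exp(eta)` with
  `eta = sum_p effect_p[stratum] * activity_p`; event times are drawn by
  inverting the survival function. Shape 1.2 (mild ageing rather than
  memoryless exponential) and scale 220 months give a null cohort roughly a
  third of samples a 10-year event, echoing the DMFS range of the cohorts the
  study tabulates. Administrative censoring at 120 months fixes the 10-year
  endpoint; independent exponential dropout (default 0.001/month) adds
  realistic early censoring.
* **Node-dependent defaults.** LN+ fraction 0.4 (the training cohort's value);
  effects plant the study's central phenomenon -- immune protection only in
  LN+ (`-0.8` per SD) and adverse proliferation/epigenetic programs weighted
  toward LN- (`+0.8`/`+0.6` vs `+0.3`/`+0.1`), with EMT adverse mainly in LN+.
* **Truth.** Activities, linear predictors, uncensored event times, loadings
  and the informative-gene list (with marginal directions) are recorded, and a
  cohort is bit-for-bit reproducible from its seed.

What the generator does *not* emulate: probe-level .CEL intensities and RMA,
batch and platform effects, correlated program activities, non-proportional
hazards, and treatment effects. Tests passing on synthetic cohorts therefore
certify the statistical machinery and the stratum-transfer phenomenon, not
clinical performance of any signature on real tumours.

An optional probe layer (`make_probe_layer`) expands each gene into 1-k probes
(constant per-probe offset + noise) and appends two designated HER2 probes
with a configurable HER2-high contaminant subpopulation, to exercise probe
collapse and the mixture-based HER2 call.

## Numerical and design choices

* Sample SD (`n - 1`) throughout; Z rows are validated to mean 0 / SD 1
  within 1e-9.
* Cox fits: Efron ties, convergence tolerance 1e-9, at most 50 iterations;
  non-convergence raises a diagnostic error.
* Median ties at the KM cut go to the high-score group; ER-before-HER2
  attribution of filter removals; prediction ties to the first class level;
  CV-error ties to the larger shrinkage threshold; ranking ties by symbol --
  every tie-break in the pipeline is deterministic, and every stochastic step
  takes an explicit seed, so reports are reproducible byte for byte.
* Errors are classed conditions (`prognode_missing_feature`,
  `prognode_empty_result`, ...) so callers can distinguish missing fixtures
  from degenerate statistics.

The test suite sizes simulations to what the statistics need rather than to
cohort realism: calibration checks use 100 null replicates of n = 400 (CI
coverage, concordance at chance), 50 replicates of n = 500 for log-hazard
recovery, 200 null gene sets at 200 permutations for enrichment calibration,
and a 600-train / 400-test pair for the cross-cohort discovery transfer, with
planted per-SD effects of magnitude 1.0 (strongly prognostic biology,
consistent with concordances of 0.62-0.85 in the study this replays).

## Known limitations

* The subtype centroid values are synthetic stand-ins; absolute ROR values are
  therefore not comparable to any published assay output, although all
  rank-based and mechanical properties hold.
* Discovery does not reproduce the original 57-gene membership -- that would
  require the original probe-level data and software vintage; the bundled
  signature fixture plays that role.
* Multivariable models with clinical covariates, time-dependent effects, FDR
  across gene-set collections and leading-edge analysis are out of scope.
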