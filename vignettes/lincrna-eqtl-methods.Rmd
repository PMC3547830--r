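---
title: "Methods: cis-eQTL mapping for lincRNA expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cis-eQTL mapping for lincRNA expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `linceqtl`, the
parameters that matter, the synthetic-data generator the test suite runs
on, and the numerical and design choices made where the design was
genuinely open. It states no empirical result that the package's tests and
acceptance script do not themselves compute.

## The analysis model

LincRNAs — spliced non-coding transcripts over 200 nt between
protein-coding genes — are captured on whole-genome expression arrays by a
subset of probes. The package asks whether common SNPs control the
expression these probes measure, locally: a probe–SNP pair is *cis* when
the SNP lies within 250 kb of the probe alignment center (boundary
included), the probe center being `floor((start + end) / 2)` of its
0-based half-open alignment interval (the rounding direction is a package
convention; the convention matters only for odd-length intervals).

Association is the midrank Spearman rank correlation between allele
dosage (0/1/2 counts of the alternate allele) and intensity. Rank-based
testing is the natural choice for array intensities: it is invariant
under any strictly monotone transform of expression (a property the test
suite asserts), so it is insensitive to the exact normalization scale and
robust to heavy tails at low abundance. Two-sided p-values use the
t-approximation with `n − 2` degrees of freedom; below 10 samples the
permutation null is enumerated exactly. The signed normal-equivalent
`z = qnorm(1 − p/2) · sign(rho)` carries the allelic direction with
respect to the counted allele, and is what replication concordance
compares.

### Permutation FDR

The multiple-testing unit is, by default, the probe, with each probe's
minimum p over its cis window as its statistic. The null distribution
comes from shuffling the expression matrix's sample labels as whole
columns — this breaks genotype–expression coupling while preserving the
probe–probe correlation structure, which a per-probe shuffle would
destroy. With `B` permutations, the estimated FDR at candidate threshold
`t` is the mean number of null units at or below `t` divided by the
observed count there, and the reported threshold is the largest *observed*
p value whose estimated FDR is at or below the nominal level: a step
function over observed p values, deliberately without interpolation, so
the procedure is exactly reproducible from the recorded threshold. An
empty significant set (threshold 0) is a valid outcome.

Because pair counts and probe counts are both of interest, a pooled
per-pair variant (`unit = "pair"`) is implemented alongside the probe-level
default; the probe-level min-p statistic is the default because the
declared unit of discovery downstream (replication, specificity,
enrichment) is the probe.

One caveat the test suite had to respect: when every planted effect is
equally strong, the threshold step function collapses onto the smallest
significant observed p, far below where a marginal effect would put it.
Cohort data produce a continuum of effect sizes, so calibration and
specificity tests plant a spread of betas rather than a single value.

### Replication, specificity, tissues

Replication re-tests only discovery-significant units, applying the same
permutation FDR restricted to those pairs in the second cohort, after
harmonizing allele codings (ref/alt swaps flip dosage to `2 − d`;
irreconcilable SNPs are dropped and logged). Direction concordance is the
sign product of discovery and replication z for the discovery top pair.
Transcript-class specificity holds the significance threshold fixed and
asks, per lincRNA top-eQTL SNP, whether any protein-coding probe is
associated at that same threshold; shared SNPs are split into same- and
opposite-direction and flagged when they are also the strongest eQTL of a
coding probe. Tissue comparison intersects per-tissue significant unit
sets and classes units as single-, multi-, or all-tissue.

### LD proxies, GWAS intersection, enrichment

With unphased genotypes, LD is the composite (dosage-correlation) r² —
the squared Pearson correlation of dosage vectors — rather than haplotype
r²; the analysis panel itself serves as the LD reference. Proxy search
uses r² ≥ 0.8 by default within 500 kb; whether the 0.8 boundary is
included is not decidable from first principles, so it is configurable
(`strict`), with the inclusive form as default. Perfect proxies are
r² = 1 within 1e-12. GWAS intersection filters the catalog to reported
P < 9.9×10⁻⁶ (strictly), then matches each top eQTL SNP or any of its
proxies by identity; catalog SNPs absent from the panel can only match by
identity and are logged.

Regulatory enrichment uses set-level hits: a top SNP together with its
perfect proxies counts once however many of them fall in the track, which
avoids double-counting LD. The fold is the query-set hit fraction over
the background in-track fraction, the background being the analysis SNP
panel (the enrichment denominator of the original tooling is not
published; using the panel keeps observed and permuted folds exactly
comparable, which is what the significance estimate needs). Significance
re-runs the entire selection — re-map, top probes by min p, top SNP per
probe, perfect-proxy expansion — under each expression permutation and
fits a normal distribution to the log permuted folds by maximum
likelihood (1/n variance); the one-sided p is the upper tail of the log
observed fold. Zero permuted folds are replaced by half the smallest
positive fold before the log, and the substitution is recorded in the
result; all-zero null folds yield a not-estimable sentinel instead of a
number.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `window` | 250,000 | bp | cis-window half-width from probe center, boundary inclusive |
| `level` | 0.05 | — | nominal FDR |
| `n_perm` | 100 | — | permutations for FDR and enrichment nulls |
| `min_n` | 30 | samples | minimum after pairwise deletion; below this the t-approximation and the rank test itself are fragile |
| `min_genotype_count` | 3 | samples | smallest observed genotype group; guards against a handful of rare homozygotes driving a rank correlation |
| `exact_below` | 10 | samples | exact permutation enumeration cutoff |
| `r2` proxy threshold | 0.8 (≥) | — | proxy definition; `strict` toggles the boundary |
| proxy `max_distance` | 500,000 | bp | LD search radius |
| `gwas_p` | 9.9e-6 | — | catalog inclusion threshold (strictly below) |
| `tss_window` | 5,000 | bp | TSS-proximal half-width in SNP classification |
| `remove_pcs` | 0 | components | expression PC correction; the appropriate count is cohort-specific, so none are removed by default on synthetic data |

The sample-size rules (`min_n`, `min_genotype_count`) are not published
constants of the reference design; they are conventional values in eQTL
practice, exposed as arguments and applied identically to observed and
permuted scans so the FDR comparison stays internally consistent.

## The synthetic-data generator

`simulation_spec()` defaults define the study conditions the test suite
and acceptance script run at: 200 samples, 2,000 SNPs, 200 probes on one
chromosome (10 Mb), 50 planted cis-effects of 0.8 intensity units per
allele copy against unit-SD Gaussian noise, LD blocks of 10 SNPs with
copy probability 0.8, MAF drawn per block from (0.05, 0.5], and a lincRNA
fraction of one half with the lincRNA class baseline 0.25 intensity units
below the protein-coding baseline of 6.92 — the class means mirroring the
reported blood-array abundance gap (6.67 vs 6.92). These sizes keep a
full 100-permutation study around two seconds on one CPU while leaving
~100 cis SNPs per probe, enough for the min-p statistic to behave as it
does at cohort scale.

Genotypes are Hardy–Weinberg draws; LD uses a block-copy construction in
which each SNP copies the previous block member's dosage per sample with
probability `ld_decay`, else redraws at the block's MAF. Sharing one MAF
per block keeps every SNP's marginal frequency at its drawn MAF, and
gives the closed-form population correlation `ld_decay^d` at in-block
distance `d` — the quantity the generator tests check against brute-force
simulation. Probe class baselines are deterministic per class, so the
noiseless limit of the class mean difference is exactly
`abundance_shift`; probe-to-probe mean variation then comes from noise
and planted effects only. Tissue subsets are drawn once from the sample
universe and shared across tissues, as in multi-tissue designs sampled
from one cohort, and effects can be restricted to a tissue subset.

The generator does **not** emulate population structure or relatedness,
imputation uncertainty, array-specific intensity artifacts, missing
genotypes, probe cross-hybridization, or realistic gene geometry (its
transcripts are two-exon toys built around the probes). Passing tests
therefore demonstrate the correctness and calibration of the *procedures*
under the stated statistical structure — not robustness to those
real-data complications. The paper-scale headline counts (thousands of
significant pairs, specific replication percentages) depend on cohort
data that is not distributable and are not targets of the synthetic runs.

The effect size and noise level are not estimates of anything published —
the reference analysis reports no per-eQTL betas — they are chosen once
so that a 200-sample study has high but not saturating power
(per-pair Spearman rho ≈ 0.4), which is the informative regime for
calibration tests.

## Numerical choices

* P values are clamped into `(0, 1]` (`.Machine$double.xmin` floor) so
  logs and z-scores stay finite at rho = ±1.
* Ties: dosage and expression ranks are midranks throughout; the exact
  enumeration compares `|rho|` with a 1e-12 slack so ties in the
  permutation distribution count as at-least-as-extreme.
* Quantile normalization maps ties to the mean of their target quantile
  values (via `limma::normalizeQuantiles(ties = TRUE)`); an all-constant
  column collapses to the target mean with a warning. The operation is
  idempotent to 1e-12.
* PC removal subtracts the rank-k SVD reconstruction of the row-centered
  matrix; residuals are orthogonal to removed components to 1e-8. With
  `protect_genetic = TRUE`, components whose sample scores have maximal
  dosage r² above `protect_r2` (default 0.1) are retained, so genetically
  driven expression structure survives correction.
* Matched-probe selection is greedy nearest-neighbour without
  replacement in standardized (mean, SD) space, processing reference
  probes in probe-id order for determinism. Matching on the mean (not the
  median) is the default, with the statistic exposed as an argument. The
  test suite bounds the greedy solution against exhaustive optimal
  assignment on tiny instances — enumeration, rather than a dedicated
  assignment solver, is deliberate: at the instance sizes where the bound
  is informative, enumeration is exact and dependency-free.
* "Strongest eQTL" tie-breaking is fully deterministic: smallest p, then
  largest |rho|, then smallest position, then SNP id.
* SNP location classification assigns exactly one category with
  precedence exonic → intronic → TSS-proximal → intergenic: a SNP inside
  a transcript is described by its position in that transcript, and the
  TSS-proximal class captures the promoter-flank signal outside gene
  bodies. TSS is the first transcribed base (span start on `+`, span end
  − 1 on `-`).
* Coordinates are 0-based half-open internally everywhere; SNP map files
  are 1-based and converted on read; BED stays native. Overlap requires
  at least one shared base.
* Every stochastic routine takes one master seed and derives per-purpose
  streams (map vs dosages vs noise vs each permutation) by salted
  counters, recorded in results; a replication cohort is generated by
  re-seeding only the dosage and noise streams, preserving the SNP map,
  probes and planted truth.

## Problem sizes in the checks

The acceptance script averages the empirical false-discovery proportion
over 20 replicate studies at the default conditions above. The test
suite's calibration blocks use 10–24 replicates at 60–200 samples with
40–100 permutations; oracle-equivalence blocks use instances up to 10⁴
elements against quadratic scans and up to 9! permutations against exact
enumeration. These sizes were chosen so the whole suite runs in about a
minute on one CPU while keeping Monte-Carlo error well inside the asserted
tolerances.

## Known limitations

* The permutation null assumes exchangeable samples; confounding that
  couples genotype and expression (population structure, batch aligned
  with genotype) would inflate both observed and null statistics and is
  out of scope here.
* Composite r² understates haplotype r² slightly under
  Hardy–Weinberg deviations; for proxy search on synthetic HWE data the
  difference is immaterial, but results on real data would inherit the
  panel's quality.
* The pooled per-pair FDR variant treats pairs as exchangeable although
  pairs within a probe are correlated through the shared expression
  vector; it is provided for comparison, not as the default inference.
* `run_study()` is sequential and in-memory; matrices beyond roughly
  10⁴ probes × 10⁴ SNPs per chromosome would need a chunked scan.
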