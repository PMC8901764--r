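---
title: "Methods: the shared-locus lipolysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the shared-locus lipolysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipoloci)
```

## The question and the model

Adipocyte lipolysis is a plausible mediator between genetic variation and
body-fat phenotypes: high spontaneous (basal) and low
catecholamine-stimulated lipolysis accompany higher body weight in clinical
cohorts. `lipoloci` formalizes the resulting in-silico screen. A trait index
SNP is a *shared locus* when it is nominally associated with a lipolysis
phenotype and, for BMI, the effect directions fit that physiology: the
BMI-raising allele should raise spontaneous lipolysis (concordant) and
lower stimulated lipolysis (discordant). For WHRadjBMI no direction is
imposed, because the relationship between lipolysis in a single abdominal
subcutaneous depot and whole-body fat distribution is not well enough
understood to predict a sign.

The cascade is: trait panel → rsID lookup in the lipolysis GWAS → allele
harmonization → nominal filter (p < 0.05, strict, uncorrected) → direction
rule → adipose eQTL join (FDR-passing pairs only) → hASC expression filter
(> 10 TPM at some differentiation time point, strict) → allele-level
congruence classification against observed siRNA knockdowns → candidate
prioritization. The nominal, uncorrected threshold is deliberate: the
screen trades specificity for sensitivity and relies on the orthogonal
eQTL, expression and functional filters downstream, plus the panel-wide
binomial enrichment test, to control the overall story.

## Harmonization

Two records for the same rsID are aligned to a common effect allele. Allele
letters resolve plain swaps; under `strand_mode = "mrbase"` a set matching
only after complementation is strand-corrected. Palindromic (A/T, C/G)
SNPs cannot be resolved by letters at all, so they are oriented by
frequency — the alt-allele frequencies are forced to the same side of
0.5 — and dropped when the minor-allele frequency exceeds 0.3 in either
record, the conventional threshold below which frequency orientation is
reliable. The overlap scan defaults to `strand_mode = "literal"` (trust
rsID and printed alleles): lookup tables joined from the same reference
build normally share an orientation convention, and literal matching avoids
manufacturing spurious strand corrections. Instrument building for MR
defaults to `"mrbase"`, the convention of two-sample MR platforms. Both
modes are available on every entry point.

Frequency discrepancies between cohorts are warned about above 0.2 but
never cause a drop outside the palindrome rule — the packaged tables
themselves show cross-cohort frequency differences of a few percent, which
are expected between population samples.

A record with beta exactly 0 has no direction (`direction_class = "null"`)
and can never satisfy a direction rule nor enter a direction tally; its
sign is undefined, not evidence.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | nominal p threshold on the phenotype association, strict `<` |
| `palindrome_maf_threshold` | 0.3 | MAF above which palindromic SNPs are dropped |
| `freq_warn` | 0.2 | aligned frequency discrepancy that triggers a warning |
| `threshold_tpm` | 10 | hASC detection threshold, strict `>`, tags per million |
| `strand_mode` | scan `"literal"`, MR `"mrbase"` | strand policy |
| `bandwidth_factor` | 1 | multiplier on the modified Silverman bandwidth (weighted mode) |
| `boot_reps` | 1000 | bootstrap replicates for median/mode/Egger-bootstrap SEs |

## Congruence classification

For each (SNP, gene) pair the *lipolysis-up* allele (positive aligned beta
on the phenotype) is compared with the eQTL high-expression allele. Equal
alleles predict a positive regulator, whose knockdown should decrease the
phenotype; unequal alleles a negative regulator. Observed knockdown
directions of `none` or `unknown` leave congruence `unknown` rather than
`false`: a null in a single siRNA screen is weak evidence against a
prediction. Zero lipolysis betas make the classification undefined and are
flagged with a warning. For WHRadjBMI the triangle is evaluated only
between lipolysis, expression and knockdown — the trait side carries no
direction constraint, consistent with the scan.

Prioritization orders candidates by (1) hASC detection, (2) congruent
knockdown, (3) no lipid-accumulation effect — a knockdown that changes
glycerol without changing lipid content argues for a direct lipolysis
effect rather than one secondary to disturbed adipogenesis — then
alphabetically as an explicit tie-break.

## Mendelian randomization suite

Instruments are hit SNPs aligned to their exposure-increasing allele, with
missing standard errors inferred from beta and p via the two-sided normal
Wald relation (appropriate for linear-regression GWAS at large n). The
estimators:

* **Wald ratio** for a single SNP; first-order delta-method SE
  `se_Y / |b_X|`.
* **IVW**, fixed-effect: the zero-intercept WLS slope with weights
  `1/se_Y^2`; Cochran's Q reported, and a multiplicative random-effects
  variant (`random_effects = TRUE`) inflates the SE by
  `sqrt(max(1, Q/(L-1)))`. Fixed-effect is the default because the
  platform the estimates are styled on uses it and because the package's
  instrument panels are small.
* **MR-Egger**: WLS with intercept after orienting all `b_X >= 0` (the
  standard convention that makes the intercept interpretable as average
  directional pleiotropy); t inference on L − 2 df; the SE is floored at
  its fixed-effect value by truncating the residual SD at 1. The bootstrap
  variant resamples instruments with replacement and reports a percentile
  CI; an exact fit (residual SD 0) falls back to the analytic zero SEs.
* **Weighted median** of the per-SNP Wald ratios with inverse-variance
  weights from the second-order delta method; linear interpolation at the
  50% cumulative-weight point; SE from a parametric bootstrap (SD of
  resampled estimates).
* **Weighted mode**: argmax of a weighted normal-kernel density of the
  ratios, bandwidth `0.9 min(sd, mad) L^(-1/5)` times `bandwidth_factor`;
  when the MAD degenerates to 0 (many identical ratios) the SD alone sets
  the bandwidth, and fully identical ratios return that ratio directly.
  `nome = TRUE` drops the exposure-error term from the weights. SE is the
  MAD of parametric-bootstrap estimates, the robust convention for a mode.
* **I²_GX** measures instrument-strength adequacy for Egger (the NOME
  assumption): `max(0, (Q_GX - (L-1))/Q_GX)` over the absolute exposure
  effects with weights `1/se_X^2`, returning 0 when the effects have zero
  dispersion.

All estimators are invariant to re-orienting any single SNP's alleles, and
all bootstraps are reproducible from an explicit seed.

## The simulator

`simulate_cohort()` emulates exactly the data structure the pipeline
consumes: two independent GWAS samples with per-SNP effects under a
mediation model (`beta_Y = tau * gamma + alpha`), standardized-trait
sampling noise `se = 1/sqrt(2 n p (1-p))` (exact for a variance-1 trait,
the usual summary-statistic convention), optional balanced or directional
pleiotropy, a null-instrument fraction, eQTL high alleles tied to a
simulated expression-effect sign, and expression profiles with an exact
detected fraction. The outcome table is written in a random ref/alt
orientation with random strand flips for non-palindromic SNPs, so the
harmonization path is exercised rather than bypassed; the generating truth
records the canonical orientation for recovery oracles.

What it does **not** emulate: linkage disequilibrium (index SNPs are
treated as independent, matching the use of pruned panels), genotype-level
data, winner's-curse selection of the panel, population stratification, or
sample overlap between the two GWAS. Tests passing on simulated cohorts
therefore validate the estimators and plumbing under the stated sampling
model, not robustness to those real-data complications.

Default study conditions: 50–100 SNPs, sample sizes 10^5 in both samples,
`tau = 0.2`, `gamma_sd = 0.05` (strong instruments: typical per-SNP F well
above 100, matching genome-wide-significant index panels), MAF uniform on
(0.05, 0.5). Very strong instruments can underflow the two-sided normal
p-value, so generated p-values are clamped at the smallest positive
normalized double rather than 0, preserving the `0 < p` invariant.

## Numerical and design choices

* p-threshold comparisons are strict (`<`), as is the 10 TPM expression
  rule (`>`), so boundary values are excluded on both filters.
* The binomial enrichment test is the one-sided exact tail
  `P(X >= k | n, 1/2)` — the alternative is "more consistent than chance",
  never two-sided.
* Duplicate rsIDs in one input keep the first row with a warning; index
  panels are expected to be unique.
* Loci are counted as distinct rsIDs across phenotype hit lists, not as
  physical windows; this matches how index-SNP panels define loci.
* WHRadjBMI association tables may carry betas without p-values; every
  WHRadjBMI operation works from betas alone, and MR (which needs outcome
  SEs) is skipped with an explicit report note instead of guessing.
* Report writing is deterministic: fixed column order, rows sorted by
  chromosome, position, rsID.
* Test and acceptance studies use 200 seeds for effect-recovery means,
  1,000 simulations for type-I error, and 50-instrument cohorts — sizes at
  which the Monte-Carlo SE of the checked quantities is several times
  smaller than the asserted bands.

## Limitations

LD-proxy substitution is not implemented: replacing a missing SNP by a
proxy at r² ≥ 0.8 requires an external LD reference panel, which this
package deliberately does not bundle; SNPs absent from the phenotype GWAS
are counted and reported, not imputed. Colocalization statistics are out of
scope — eQTL support is presence/absence of an FDR-passing pair, which
cannot distinguish shared causal variants from coincidental overlap.
Whether an eQTL's lead SNP coincides with the trait index SNP is not
assessed. The congruence logic treats the eQTL high allele as a fixed
label; ties or ambiguous expression signs in the source data are flagged,
not resolved.

## A fixture run

```{r fixture}
report <- run_pipeline(pipeline_config(mode = "fixture",
                                       fixture = "bmi_shared",
                                       boot_reps = 200))
report
```

```{r candidates}
subset(report$candidates, detected_in_hascs,
       select = c(gene, snp_id, phenotype, regulator_prediction,
                  congruent_with_knockdown))
```
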