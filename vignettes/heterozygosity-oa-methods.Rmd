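---
title: "Methods: genome-wide heterozygosity and osteoarthritis risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide heterozygosity and osteoarthritis risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the model

Osteoarthritis (OA) is highly polygenic: risk is spread over very many
variants of small effect. That makes a *genome-wide* summary of an
individual's genetic diversity a natural predictor to try. The
heterozygosity–fitness-correlation literature suggests that individuals
with higher multilocus heterozygosity tend to have better health outcomes;
`hetoa` implements the case-control version of that test for end-stage hip
and knee OA.

Two per-individual statistics are computed from biallelic autosomal SNP
genotypes (alt-allele counts 0/1/2 with missing calls kept as `NA`):

* **HetRate** — the number of heterozygous genotypes divided by the number
  of genotypes homozygous for the alternative allele,
  $\mathrm{HetRate}_i = n^{het}_i / n^{homalt}_i$. This is the package
  default because it is the definition the analysis is built around; a
  `denominator = "hom_all"` option divides by *all* homozygous genotypes
  instead, the convention of most per-sample heterozygosity tooling. The
  two are monotone transforms of each other at fixed variant count, and
  the tested contract (the direction and per-SD scale of the association)
  is insensitive to the choice.
* **HetExcess** — the relative excess of observed over expected
  heterozygosity, $(H^{obs}_i - H^{exp}_i)/H^{exp}_i$, where
  $H^{obs}_i$ is the fraction of sample $i$'s non-missing autosomal sites
  that are heterozygous and
  $H^{exp}_i = \overline{2 p_j (1-p_j)}$ over the same sites, with $p_j$
  the cohort allele frequency. HetExcess is exactly $-\hat F_i$, the
  negative of the method-of-moments inbreeding coefficient, which is why
  the synthetic-data generator is parameterized by $F$.

Both metrics are standardized to z-scores across the full analysis set
(cases and controls together) *before* any model is fitted, so every
reported effect is an odds ratio per standard deviation. Subgroup (hip,
knee) models reuse the full-set z-scores rather than re-standardizing;
re-standardizing per subgroup would silently change the effect scale
between cells of the result grid (a config flag restores that behaviour
for users who want it).

The association model is plain logistic regression,

$$\mathrm{logit}\, P(\text{case}_i) = \beta_0 + \beta_z z_i +
  \boldsymbol\gamma^\top \mathbf{c}_i,$$

with $z_i$ the z-scored metric and $\mathbf{c}_i$ optional covariates
(age, sex coded female = 0 / male = 1, BMI, optionally diabetes).
`exp(beta_z)` is the OR per SD; the 95% CI is the Wald interval
$\exp(\beta_z \pm 1.96\,\mathrm{SE})$, matching the OR (CI) presentation
convention of this literature. No multiple-testing correction is applied
across the 12-cell grid (2 metrics × 2 MAF strata × 3 subgroups): each
cell is interpreted at $\alpha = 0.05$, as in the study designs this
package reproduces. Rows with missing covariate values are dropped
listwise per regression, with counts logged.

## Quality control

Filters run in a fixed order, each variant attributed to the first filter
that removes it:

| step | rule | default |
|---|---|---|
| user exclusions | externally supplied ids (e.g. ancestry outliers) | none |
| duplicates | pairwise IBS ≥ threshold over mutually non-missing calls | 0.95 |
| sex discordance | recorded female with X het rate < min, or male > max | 0.05 / 0.10 |
| missingness | per-variant missing rate strictly > threshold removed | 0.05 |
| HWE | exact-test p < threshold removed | 1e-6 |
| MAF | variants retained only if MAF strictly > threshold | 0.01 |

Comparator conventions are strict on both sides ("MAF > 0.01" keeps, "> 5%
missing" removes), so a variant exactly at a threshold is kept by the
missingness filter and removed by the MAF filter. The HWE test is the
exact conditional test (log-space recurrence over heterozygote counts, no
mid-p); it is the standard QC choice because the chi-square approximation
misbehaves at low minor-allele counts, exactly where QC matters. The HWE
threshold (1e-6) and its scope (all samples) are conventional genome-wide
defaults — the underlying study designs do not state theirs — and both are
exposed in `qc_config()`. Allele frequencies for the MAF filter and for
$H^{exp}$ are computed on the post-sample-QC combined case+control set.

Variant-level filters act on autosomes only: testing HWE on X with
hemizygous males present is a guaranteed false positive, and every
downstream heterozygosity statistic is autosome-only anyway (male X
hemizygosity would otherwise make sex a structural confounder of
$H^{obs}$). X variants are carried through for the sex check.

Duplicate removal keeps the member of each pair with fewer missing calls
(ties: the lexicographically smaller id). Pairs sharing fewer than 50
called variants are skipped with a warning — IBS on so few sites is
noise. For large panels an evenly spaced 400-variant screen (margin 0.10
below the threshold) prunes the pair list before exact IBS is computed;
an exact duplicate cannot be lost by the screen at these margins.

## The synthetic cohort generator

The raw cohort data behind the published analyses are not deposited, so
the package ships a generator that reproduces the *statistical structure*
the analysis assumes, with recorded ground truth:

* Minor-allele frequencies from Uniform(0.05, 0.5) (or a folded Beta).
* Genotypes from the inbreeding model
  $P(\text{het}) = 2pq(1-F_i)$, $P(\text{hom alt}) = p^2 + F_i pq$,
  $P(\text{hom ref}) = q^2 + F_i pq$, independently per sample × variant.
  Under this model $E[H^{obs}_i] = (1-F_i) H^{exp}$, so HetExcess
  recovers $-F_i$ — the central recovery test. Negative $F$ (outbreeding)
  is clamped per variant to keep the probabilities valid.
* Per-sample $F$ from a truncated normal; the cohort default is
  mean 0.01, SD 0.01 — weak inbreeding variation, the regime a mostly
  outbred clinic-based cohort plausibly occupies.
* Covariates: age ~ N(62, 9²) years and BMI ~ N(32, 6²) kg/m², each tied
  to the heterozygosity propensity $-F$ by a bivariate-normal
  construction with target correlations −0.089 and +0.091 — the
  magnitudes the reference cohort reports; sex ~ Bernoulli(0.56 female),
  diabetes ~ Bernoulli(0.15).
* Disease status from the logistic model above with
  $s = z(-F)$ as the propensity, so `beta_het` is directly a per-SD
  log-odds; the default `log(0.65)` matches the protective effect size
  the package is designed to detect. The intercept is tuned against the
  realized uniform draws (a monotone step function), which hits target
  case *counts* exactly — the by-count presets produce exactly 559/118
  and 2,019/2,029 cohorts.
* Injectable QC violations: random missingness; heterozygote-deficit
  variants (regenerated at $F = 0.8$, detectable with power ≈ 1 at
  n ≥ 500); exact duplicate samples; recorded-sex swaps; plus a sex-aware
  X block (males hemizygous, females under HWE) so the sex check has
  signal. All injections land in a truth registry for recall tests.

All draws flow from named substreams of one master seed, so changing one
count does not shift unrelated draws, and every output is byte-identical
under a fixed seed.

What the generator deliberately does **not** emulate: linkage
disequilibrium (variants are independent; LD changes the *variance* of
genome-wide heterozygosity but not its expectation, and independence
keeps closed-form checks available), population stratification,
imputation error, and array batch structure. Passing tests on synthetic
cohorts therefore demonstrate that the statistics and models are computed
correctly and recover known generative parameters — not that the
epidemiological association is robust to confounding by ancestry or
genotyping platform in real data.

## Numerical choices and degenerate inputs

* The HWE exact test works in log space with a recurrence over attainable
  heterozygote counts; the p-value sums probabilities ≤ the observed
  one with a relative tolerance of 1e-12 to absorb roundoff ties.
  Monomorphic variants return p = 1 (a single attainable configuration).
* Logistic fits use base R's IRLS (`glm.fit`, tolerance 1e-10, max 100
  iterations); SEs come from the observed information at the optimum.
  Complete separation is reported as `converged = FALSE` (detected by
  pinned fitted probabilities with diverging slopes), never as a crash.
* $H^{exp}$ applies the small-sample correction $2N_j/(2N_j-1)$ to
  $2p_jq_j$ by default, matching standard per-sample expected-homozygosity
  tooling; this also makes HetExcess mean-zero under $F = 0$, since the
  plug-in $2\hat p\hat q$ is otherwise biased low by exactly that factor.
  A flag disables it.
* Samples with an undefined statistic (zero HetRate denominator, zero
  $H^{exp}$, or no non-missing calls) are dropped from *both* metrics, so
  HetRate and HetExcess models always share one analysis set.
* z-scoring a constant vector is an error, not a silent zero.
* `write_table` emits 6 significant digits in deterministic row order, so
  repeated runs diff clean.

## Problem sizes

The shipped analyses and tests run at desk scale, chosen so that the
z-scored metrics correlate > 0.95 with the generative propensity (keeping
attenuation of recovered ORs small) while the full suite stays fast:
cohorts of 250–2,000 samples at 2,000–20,000 SNPs, 500 replicates for the
type-I-error calibration (300 samples × 2,000 SNPs each), 300 replicates
for CI coverage. At the cohort defaults (5,000 SNPs, F SD 0.01) the
heterozygosity metrics are noisy proxies of $F$, so observed
covariate–metric correlations attenuate from the target ±0.09 towards
±0.05 — visible in `analysis/03_heterozygosity.R` — which is itself a
faithful property of finite-panel heterozygosity estimates.

## Known limitations

* HetRate's default denominator (hom-alt genotypes only) makes it
  allele-frequency-dependent; that is by design (the companion metric
  HetExcess is the frequency-free one), but comparisons across panels
  with different frequency spectra should use HetExcess.
* The replication design (no covariates, all female) is reproduced as a
  config preset; the package does not model the genotyping/imputation
  differences between discovery and replication platforms.
* Relatedness handling stops at exact duplicates; no kinship estimation.
* Population-structure outlier removal is a hook (`exclude_samples` in
  `qc_config()`), not an implementation.
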