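---
title: "Cross-disorder polygenic scoring: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-disorder polygenic scoring: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Schizophrenia (SCZ) and bipolar disorder (BPD) share a substantial part of
their common-variant genetic architecture while differing in others, and
the two parts appear to pull cognition-related outcomes in opposite
directions.  `crossprs` implements the analytical pipeline for studying
this with polygenic risk scores (PRSs) in a population cohort: genotype
and sample quality control, construction of eight PRSs that decompose the
cross-disorder architecture, and association of those scores with disease
status, educational attainment and cognitive aging, with a
liability-threshold simulator supplying fully synthetic inputs so the
whole pipeline is testable end to end.

# The eight scores

Each PRS is an additive score $s_i = \sum_j g_{ij}\,\beta_j$ over
effect-allele dosages $g_{ij}$ and per-variant weights $\beta_j$ from a
discovery GWAS, Z-normalized over the QC-passed unrelated cohort.  Four
weight sources define the four direct scores:

* **SCZ** and **BPD** — standard case-control GWAS of each disorder;
* **SCZ+BPD** — a GWAS treating SCZ and BPD cases as one phenotype
  against controls (the shared axis);
* **SCZvsBPD** — a case-only GWAS of SCZ cases against BPD cases, in
  which any effect common to both disorders cancels (the
  disorder-contrast axis).

The remaining four come from the *sign-concordance split*: restricting
the SCZ weights to variants present in both disorders' GWASs, variants
whose SCZ and BPD effects share a strict sign form `SCZ_concordant`,
variants with strictly opposite signs form `SCZ_discordant`, and
symmetrically for BPD.  Variants with a zero effect in either source
have no defined sign and are dropped (the published concordant plus
discordant counts fall short of the full set, confirming such drops), as
are variants absent from the other GWAS.  By construction the raw score
of the full set equals the sum of the concordant, discordant and dropped
subsets, an identity the test suite checks to $10^{-10}$ per sample.

Weight files are consumed in the PRS-CS output dialect (CHR, SNP, BP,
A1, A2, EFFECT; header optional).  Bayesian continuous-shrinkage
re-weighting itself is out of scope: externally shrunk weights are read
verbatim, and a simple p-value-thresholding derivation is provided for
the synthetic path.  Alignment to the target panel matches on
(chromosome, position), negates effects for swapped alleles, resolves
complement pairs as strand flips, and drops strand-ambiguous (A/T, C/G),
unmatched and allele-incompatible variants with recorded reasons;
aligning an already-aligned set is a no-op.

# Quality control

Thresholds default to the values used on the study cohort: variant
missing fraction > 5% (the conventional reading of "call rate < 5%",
since the literal one would discard nearly complete variants), MAF <
0.001, Hardy-Weinberg exact-test p < 1e-5, imputation info < 0.7 (a
metadata filter; imputation itself is not performed), sample missing
rate > 2%, heterozygosity outside 5 SD of the cohort mean, and PI-HAT >
0.1875 for relatedness pruning with duplicates booked separately at
PI-HAT > 0.95.  Filters run in a fixed order (missingness, MAF, HWE,
info for variants; external exclusions, missingness, heterozygosity,
duplicates, relatedness for samples) and every stage is recorded in an
exclusion ledger whose counts are conserved by construction, so a
published filtering narrative can be replayed and audited from its
printed counts alone.

The HWE test is the conditional exact test: the p-value sums the
probabilities of all heterozygote counts (given the allele counts) no
more probable than the observed one, evaluated in log space by the
stable ratio recurrence; the suite checks it against a direct
log-factorial enumeration to $10^{-12}$ for totals up to 200.

**Relatedness.** Pairwise IBD probabilities are estimated from
identity-by-state (IBS) class counts weighted by allele frequencies.
The classical PLINK-style moment cascade solves the three linear moment
equations and clamps the result to the probability simplex.  At the
marker counts a desk-scale analysis uses (around $10^4$ independent
common variants) that cascade has an unrelated-pair PI-HAT standard
deviation near 0.014, and clamping negative noise to zero adds a bias
of roughly +0.016, so a few percent of truly unrelated pairs exceed
0.05.  The package therefore uses the cascade as a screen and starting
value, and re-estimates any pair above the pruning threshold (and every
explicitly requested pair) by maximizing the multinomial IBS-class
likelihood over $(P_{IBD=0},P_{IBD=1},P_{IBD=2})$ on the simplex
(gradient BFGS on a softmax parameterization).  The likelihood estimator
respects the boundary, recovers duplicates at 1.0 and parent-offspring
pairs at 0.500 essentially exactly, and drives unrelated noise to zero.
Relatedness pruning is greedy: repeatedly remove the sample in the most
flagged pairs, ties broken by higher missingness then lexicographically
larger id, so chains (A-B, B-C) lose only the shared member.  Missing
genotypes shrink the per-pair locus count with moment expectations
rescaled proportionally, which assumes missingness is unsystematic
across loci.

The IBD variant set is a light, deterministic subset (MAF >= 0.05,
missingness <= 1%, thinned by stride to at most 50,000), since the
source analysis does not state its set and moment estimators need
common variants.  Ancestry inference is out of scope; an externally
supplied exclusion list mirrors any non-target-ancestry removal, and a
PCA helper (standardized dosages, deterministic signs via the
largest-magnitude loading) provides stratification covariates when none
are supplied.

# Association models

Four model families are fitted per outcome: Model 1, the SCZ and BPD
scores jointly (a flag switches to separate fits, since "independent
effects" admits either reading); Model 2, the shared SCZ+BPD score;
Model 3, the SCZvsBPD contrast; Model 4, the four split scores jointly.
With four families the overall 0.05 level is Bonferroni-corrected to
0.0125, and no further correction is applied across outcomes or
predictors, mirroring the source design.

Outcome-specific samples and covariates follow the published footnotes:
disease models exclude every reporter of the other disorder (the
published case counts — 176 SCZ, 695 BPD against 105,919 controls —
show dual reporters were excluded from both disease analyses, so that
rule is used) and adjust for sex, age, chip batch and 20 stratification
dimensions; education and MMSE models exclude all SCZ/BPD reporters and
the missing/illiterate/self-study education codes, and add birth cohort
(five decade bands as a categorical factor alongside linear age; rank
deficiency, if any, is handled by dropping aliased covariates with a
warning, never a predictor silently); MMSE models add education level
and are restricted to age >= 60 with a baseline score; the MMSE-change
model adds follow-up duration.  Cognitive deficit is MMSE strictly
below 24.

Education uses a proportional-odds cumulative-logit fit (`MASS::polr`
with a tight optimizer tolerance), oriented so OR > 1 means higher
attainment per SD of score.  The proportional-odds assumption is not
formally tested, matching the single-OR reporting convention.  With
only two observed categories the same likelihood is maximized directly
(BFGS with analytic gradient), which the suite exploits as an oracle:
the two-level ordinal OR must match the binary logistic OR to $10^{-6}$.
Disease models report the incremental Nagelkerke pseudo-$R^2$,
$R^2_N = \frac{1 - (L_0/L)^{2/n}}{1 - L_0^{2/n}}$, as the difference
between the covariates-plus-score and covariates-only models (both
against the intercept-only null); the suite verifies the value against
independently Newton-maximized likelihoods to $10^{-10}$ and its
invariance to affine covariate rescaling.  All intervals are Wald, the
standard convention for OR (95% CI) grids at these sample sizes.  The
inter-score correlation matrix is computed over the subsample reporting
neither disorder.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
not any particular cohort's raw data:

* **Variants.** `m_variants` independent biallelic variants (no LD; the
  scoring is additive per variant and LD-free simulation keeps every
  oracle closed-form), allele frequencies uniform on `maf_range`,
  strand-unambiguous allele pairs only, deterministic panel from the
  seed.
* **Architecture.** Per-variant shared, SCZ-specific and BPD-specific
  effects drawn from zero-mean normals scaled so each component
  contributes its configured liability-scale variance; trait effects
  are exact sums of components, so the genetic correlation is
  $h^2_{sh}/\sqrt{(h^2_{sh}+h^2_{scz})(h^2_{sh}+h^2_{bpd})}$ (0.75 at
  the defaults 0.3/0.1/0.1, bracketing published SCZ-BPD estimates) and
  the sign-concordant fraction follows the bivariate-normal orthant
  probability $1/2 + \arcsin(\rho)/\pi$.
* **Disease.** Liability-threshold: genetic value plus normal residual,
  total variance 1 (the realized genetic value is rescaled to its
  configured SD so the threshold quantile delivers the configured
  prevalence even at modest variant counts), case iff liability exceeds
  the quantile of prevalence 0.2% (SCZ) / 0.7% (BPD), the approximate
  self-report rates in a community biobank.
* **Discovery GWAS.** Summary statistics are simulated directly on the
  per-allele log-odds scale as the true contrast effect plus normal
  noise with $se = 1/\sqrt{2f(1-f)N_{eff}}$,
  $N_{eff} = 4/(1/n_1 + 1/n_2)$ — first-two-moment behavior of the four
  designs at desk-scale cost rather than simulating discovery cohorts
  individual by individual.  Sample sizes default to the published
  discovery designs (SCZ 67,390/94,015; BPD 41,917/371,549; combined
  53,555/54,065; case-only 23,585 vs 15,270).  The combined-phenotype
  effect is the case-share-weighted mean of the two disorder effects;
  the case-only contrast is their difference, in which the shared
  component cancels exactly.
* **Phenotypes.** Age uniform on 30-70 (the recruitment window), 63.5%
  female, chip batch at the published two-chip proportions, 20
  synthesized stratification covariates.  Latent education is a linear
  loading on the standardized (shared, SCZ-specific, BPD-specific)
  components plus unit noise, cut at the published five-level marginal
  proportions (4.4/7.1/29.1/48.1/11.3%), with small independent
  probabilities of illiterate/self-study/missing codes at their
  published rates; the linear latent link is a modeling choice, not an
  estimate.  Baseline MMSE exists only at age >= 60 (mean 27.6, residual
  SD 3.8, clamped to integers 0-30); about 23% of that subsample gets a
  follow-up after a normal(3.9, 1.1) positive duration, with the change
  loaded on the components (residual SD 3.4).
* **Default loadings.** Education loads +0.10 on the shared component,
  −0.06 on SCZ-specific and +0.02 on BPD-specific (per SD of component
  on the latent scale); MMSE −0.02/−0.10/+0.10; MMSE change 0/−0.25/0.
  Signs mirror the published direction pattern (shared raises
  education, the SCZ-specific axis lowers education and predicts MMSE
  decline).  Magnitudes are chosen so the realized, instrument-scale
  effects sit at the published order: the MMSE-change loading of −0.25,
  after rounding/ceiling attenuation (~0.7) and score-proxy shrinkage,
  yields an observed slope of about −0.12 points per SD of the contrast
  score, matching the published −0.125.  Loadings are configuration
  values, not fitted quantities.

Determinism is a contract: every stochastic operation draws from its
own seed stream derived from the configuration seed, so identical
configurations reproduce byte-identical fixtures regardless of call
order, and `replicate` arguments open independent streams over the same
variant panel for replication designs.

What the generator does *not* emulate — linkage disequilibrium,
imputation error, array batch artifacts, ancestry admixture, selection
into the cohort — bounds what passing tests show: they validate the
statistical machinery (filters, estimators, fits, bookkeeping) under
the model's own assumptions, not robustness to real-data pathologies.

# Problem sizes and numerical choices

Simulation-backed checks run at stated sizes chosen to balance power
against desk-scale compute: null calibration of the education ordinal
test uses 400 replicates at n = 50,000 with a compact covariate set
(sex and age; the synthesized stratification covariates are
exchangeable noise by construction, so omitting them leaves the Wald
test's null distribution unchanged while keeping 400 proportional-odds
fits affordable, warm-started from the first fit's solution);
directional recovery uses 50 replicates at n = 50,000 and m = 1,000
with fresh architecture, summary statistics, disease and phenotype
draws over a fixed genotype panel; the concordant-vs-discordant
shared-signal comparison runs at n = 20,000 and m = 4,000 (the
contrast is decisive at this size and the memory footprint stays modest);
smaller calibration loops (logistic and linear type-I error, CI
coverage) use n of a few thousand with tolerance bands widened to their
binomial noise.  Degenerate inputs have defined behavior throughout:
monomorphic variants give HWE p = 1, zero heterozygosity SD flags no
outliers, constant scores raise a degenerate-score error rather than
dividing by zero, perfect separation yields a flagged result row, and
empty analysis samples abort with the ledger attached.

# Reproducing the synthetic study

`run_pipeline()` (or the `inst/cli/crossprs` script) drives
simulate → qc → score → associate under a YAML configuration with every
threshold surfaced and validated, writes the interchange files (VCF,
dosage TSV + PLINK-style sidecar, summary-statistic and phenotype TSVs,
score and split-report TSVs, ledger JSON) plus a report shaped like the
published disease-prediction, association-grid and correlation
summaries, and records per-stage input/output digests in a run manifest
so reruns skip unchanged stages and corrupted intermediates are
recomputed stage-locally.  `scripts/acceptance.R` recomputes the
package's headline quantities from scratch at a given seed.

# Known limitations

Weights are consumed as given — no LD-aware shrinkage, clumping or
multi-ancestry blending; the simulator's LD-free, single-ancestry
design means PRS transferability questions cannot be studied with it;
the moment/likelihood IBD estimator assumes unlinked markers and no
inbreeding; self-report misclassification of disease status is not
modeled; and the all-pairs IBD stage scales quadratically in samples,
so cohorts beyond a few thousand samples should supply a thinned
variant set or precomputed relatedness.
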