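---
title: "Methods: multi-cohort eQTL discovery, replication, and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cohort eQTL discovery, replication, and diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqtlrep)
```

# The analysis framework

`eqtlrep` implements a discovery-and-replication framework for expression
quantitative trait loci (eQTLs) across several independent cohorts of bulk
expression data. One cohort serves as the discovery panel; associations found
there are re-tested — same gene, same SNP — in the remaining panels, and the
framework quantifies how much of the observed non-replication is explained by
statistical power, winner's curse, hybridization artifacts, and properties of
the probes and SNPs involved.

## Phenotype model and covariate adjustment

Each expression trait (a probeset: one or more co-correlated microarray
probes) is modelled on the log2 scale as

\[
y \sim m + A + C + R + I + W + SV_{1..k} + e,
\]

with intercept \(m\), age \(A\), sex \(C\) (male = 1), one or more ancestry
covariates \(R\), technical-replicate grouping \(I\), probe grouping \(W\),
surrogate variables \(SV\), and residual \(e\). The crossed random effects
\(I\) and \(W\) are approximated by averaging technical replicates within
individuals and centering probes before averaging into probesets. For
balanced designs (the common case on arrays, where every sample has the same
replicate count and every probe is measured on every sample) this leaves the
fixed-effect estimates identical to the mixed-model fit while reducing each
gene to one ordinary least-squares fit, which is what makes genome-wide
adjustment and repeated simulation practical. The residuals of this fit are
the phenotypes for all downstream scans; they are exactly orthogonal to every
fitted covariate column.

Hidden structure (batch, environment, cell-type composition) is estimated by
a permutation-thresholded singular value decomposition of the
gene-standardized residual matrix: each component's variance share is
compared with its null distribution over within-gene permutations of the
residuals, components are retained while their empirical p-value stays below
\(\alpha = 0.05\) (stopping at the first failure), and retained scores are
re-orthogonalized against the known covariates. This estimator recovers
planted low-rank confounding reliably in the package's tests; it is not
claimed to reproduce any particular surrogate-variable count on real data,
where the amount of hidden structure is an empirical quantity.

To blunt outliers and residual population stratification, each gene's
adjusted values can be inverse-normal transformed within populations using
Blom offsets, \(\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)\); the transform is
rank-based and therefore invariant to any monotone rescaling of the data.
The offset choice matters only in the third decimal of the transformed
values and is fixed rather than configurable.

## Single-SNP Bayes factors

Association is measured by the Bayes factor of the additive single-SNP
regression \(y = \mu + a g + \varepsilon\) against the intercept-only model,
with a flat prior on \(\mu\), Jeffreys prior on \(\sigma^2\), and
\(a \sim N(0, \sigma_a^2 \sigma^2)\). With centered sums
\(S_{yy}, S_{gy}, S_{gg}\),

\[
\mathrm{BF}(\sigma_a) = \big(1 + \sigma_a^2 S_{gg}\big)^{-1/2}
\left(\frac{S_{yy}}{S_{yy} - S_{gy}^2/(S_{gg} + \sigma_a^{-2})}\right)^{(n-1)/2},
\]

averaged with equal weights over the prior scale grid
\(\sigma_a \in \{0.05, 0.2, 0.4\}\) and reported as log10. Because the effect
prior scales with the residual standard deviation, the Bayes factor is
location- and scale-invariant in \(y\). The grid is configurable
(`bf_prior_spec()`); the default mirrors a standard weak/moderate/strong
effect-scale mixture for log2 expression data. The closed form is verified in
the tests against an adaptive-quadrature oracle to \(10^{-6}\). Dominance
terms are deliberately out of scope: dosages enter additively, which is the
appropriate model for mean-imputed genotypes.

Cis scans test all SNPs with minor allele frequency at least 1% within
250 kb of the transcription start site (TSS), signed so that negative
distances are 5' of the gene; trans scans test SNPs on other chromosomes.
The best SNP per gene is the log10-BF maximizer, with ties broken
deterministically by genomic coordinate and then SNP identifier.

## The replication criterion and its null

A discovery association **replicates** in a panel when the same SNP, tested
against the same gene in that panel's adjusted data, has a two-sided t-test
p-value below 0.05 (strict) and a coefficient of the same sign. For a
false-positive discovery the replication coefficient is sign-symmetric, so
the null replication rate is \(0.05 \times 1/2 = 0.025\) per panel, the null
sign-concordance rate is \(1/2\) per panel and \(3/4\) in at least one of two
panels. These facts give the concordance-only adjustments: an observed
concordance rate \(c\) converts to an adjusted replication estimate
\(1 - 2(1 - c)\) for a single panel and \(1 - 4(1 - c)\) under the
either-of-two standard, floored at zero. Both the null rates and the
adjustment arithmetic are verified by simulation in the test suite.

Records whose discovery SNP is absent or monomorphic in a replication panel
are flagged untested and excluded from rate denominators; "either" and
"both" rates are computed only over records tested in all panels so that
denominators match across curves. LD-proxy fallback for absent SNPs is
deliberately not implemented.

## Matched resampling and winner's curse

To build a power baseline, the framework samples demographically matched
subsets of the discovery panel (for each target individual, one source
individual of the same sex and population with age within ±3 years, drawn
without replacement within a set; 100 sets by default) and recomputes each
discovery association on every subset. A randomized augmenting-path matching
guarantees a complete without-replacement set whenever one exists.
Replication within a subset is defined exactly as across panels. Because the
subsets are drawn from the discovery panel itself, the resampled coefficient
is positively correlated with the full-panel one, so the baseline's null
rate sits somewhat above the independent-sample 0.025 — an intrinsic
property of any within-panel resampling design, worth remembering when
comparing the baseline with cross-panel rates.

The winner's-curse diagnostic bins each resample by the ratio of the
full-panel to the resampled coefficient, within discovery-BF strata. Draws
in which the coefficient shrank (ratio above one) emulate the replication of
an effect whose discovery estimate was inflated; a high replication rate in
those bins for strong discoveries is evidence that selection bias alone
cannot explain observed non-replication. For null genes this table is
necessarily not flat: a small ratio means the subset coefficient happened to
grow, which is exactly when the subset test is significant.

## Probe artifacts and replication determinants

An in-probe polymorphism can change hybridization efficiency
allele-specifically and thereby create a false eQTL that fails to replicate
on a platform whose probes avoid that variant. Probes are annotated against
a variant catalog by interval overlap (0-based half-open probe intervals;
VCF positions converted on read; offsets measured from the probe's 5' end,
with the rightmost covered base at offset zero for minus-strand probes). The
attribution analysis compares replication of records with and without
in-probe variants per BF stratum and reports the attributable fraction on
the non-replication scale,
\((\text{nonrep}_{\text{with}} - \text{nonrep}_{\text{without}}) /
\text{nonrep}_{\text{with}}\), together with a logistic test of the
probe-SNP-by-BF interaction. Determinants of replication (BF, |TSS
distance|, expression level and coefficient of variation, MAF, imputation
flag, probe-SNP count and interactions) are modelled by logistic regression
with optional AIC-stepwise selection and per-term likelihood-ratio
p-values; complete separation is detected and the model is refit with a
small ridge penalty and flagged.

## The reporter mixed model

Haplotype-specific reporter (luciferase) assays are analysed with
\(\text{luminescence} = \text{haplotype} + (1 \mid \text{prep}) +
\varepsilon\): a fixed haplotype effect and a random intercept per vector
preparation, fit by REML through the profiled one-dimensional deviance in
the variance ratio, with the zero-variance boundary checked explicitly. On
balanced designs the variance components coincide with the hierarchical
ANOVA method-of-moments estimators, and the fit agrees with a
general-purpose mixed-model implementation on unbalanced designs (both are
test oracles).

The haplotype term's default p-value is a GLS F test with containment
denominator degrees of freedom (preparations minus haplotypes), which is the
exact nested-ANOVA test under balance and remains valid for any between-prep
variance. A likelihood-ratio chi-squared p-value is also returned, but with
the standard three-preparation design only four denominator degrees of
freedom exist, and the chi-squared reference is then badly anticonservative
(its nominal 0.001 corresponds to a true level of roughly 0.01–0.03
depending on the prep variance); it should be treated as descriptive. The
flip side of exactness is power: at \(\alpha = 0.001\) the valid test needs
\(F(1,4) > 74\), so a haplotype shift of three residual standard deviations
(noncentrality about 6.6) is detected well under half the time, and shifts
of about six residual standard deviations are needed for ~90% power at the
3-preparation, 4-replicate design. Detecting subtler shifts requires more
preparations, not more transfection replicates.

# The synthetic-data generator

Every stage is exercised end to end on data from `simulate_multi_study()`,
which emulates the statistical structure the analysis assumes: three cohorts
of unequal size (206/60/266 by default) with disjoint samples; shared cis
and trans genetic effects; panel-specific hidden confounders; age and sex
effects with sex-affected genes enriched on chromosome X; a minority
non-European population per panel; technical replicates (2/2/1); and
platform-specific probe maps whose probes target different exons and whose
probe-variant overlap fractions differ by platform (0.274/0.191/0.274 by
default, matching typical Agilent vs Illumina designs).

Key generator mechanics:

* **Genotypes** are drawn as two independent haplotypes per individual.
  Adjacent-SNP linkage comes from first-order copying of the latent uniform
  variate (copy probability `ld_decay`, reset at chromosome boundaries),
  which preserves every SNP's exact marginal frequency — and therefore
  Hardy-Weinberg calibration — while giving tunable adjacent correlation.
  A configurable fraction of SNPs is reported as fractional dosages, the
  hard call shrunk toward twice the allele frequency by a per-SNP quality
  factor in [0.7, 1], emulating mean-imputed genotypes without implementing
  imputation. Genetic effects on expression act on the true hard calls;
  analyses see the dosages, so imputed SNPs carry realistic attenuation.
* **Variance bookkeeping is exact.** Per gene, the total variance solves
  \(T(1 - f_{cis} - f_{trans} - f_{conf}) = v_{age} + v_{sex} +
  \sigma_e^2\), so the reported cis/trans/confounder/demographic/noise
  fractions sum to one identically, and effect sizes are derived from the
  target fractions. Parameter-recovery tests assert realized fractions
  against these targets.
* **Confounders** are standard-normal scores (samples) with sparse loadings
  (a configurable fraction of genes loaded) scaled to absorb a fixed
  fraction of each loaded gene's variance. Defaults (5 confounders per
  panel, 40% of variance on 80% of genes) represent the heavily structured
  residual covariance typical of array studies, where surrogate-variable
  counts in the dozens are routine.
* **Probe artifacts** decrease intensity with the artifact-allele count
  (mismatch lowers hybridization efficiency); artifact probes are placed so
  the variant lies inside the probe interval, and artifact flags are drawn
  independently per platform, which is what makes artifact-driven eQTLs
  platform-discordant.
* **Reporter plates** follow the 3-preparations-by-4-replicates design (12
  measurements per haplotype), with a per-preparation random intercept.

What the generator does **not** emulate: realistic human LD maps or allele
frequency spectra, hemizygosity on chromosome X, genotype-correlated
confounding (population stratification of expression), array-image level
artifacts, or inter-platform probe-sequence differences beyond exon choice
and artifact flags. Passing tests therefore demonstrate the statistical
machinery's correctness and calibration under the planted model, not
performance on any particular real dataset; headline real-data quantities
(discovery counts, cross-cohort replication percentages) are properties of
real cohorts and are not targets here.

## A note on measuring the benefit of surrogate variables

With panel-specific, genotype-independent confounders, comparing
"replication rate over each arm's own BF>5 set" between SVA-on and SVA-off
pipelines is confounded by selection severity: the unadjusted arm can only
discover effects that are strong on the raw scale, and those replicate near
ceiling, while the adjusted arm additionally admits weaker (but real)
effects. The stable directional readouts — and the ones the package's
acceptance checks use — are paired: the adjusted analysis finds strictly
more true cis eQTLs at the same BF threshold, and strictly more of its true
discoveries replicate in at least one other panel. Both hold in essentially
every seeded run under the default confounded conditions.

# Problem sizes and numerical choices

The test suite and examples run the full pipeline at reduced but
non-degenerate sizes (typically 40–200 genes, 6–10 SNPs per gene, panels of
40–266 samples), which keeps a complete three-panel analysis to a few
seconds while leaving every mechanism observable; the generator scales to
larger designs linearly in genes × SNPs × samples. Numerical specifics worth
knowing:

* The exact Hardy-Weinberg test enumerates heterozygote counts in log-space
  and includes outcomes with probability equal to the observed one (within a
  relative tolerance of \(10^{-12}\)); it is verified against an independent
  enumeration oracle for every genotype triple with \(n \le 50\).
* Storey q-values use the tail estimator \(\hat\pi_0(\lambda)\) smoothed by
  a cubic polynomial over \(\lambda \in \{0.05, \dots, 0.95\}\), evaluated
  at the largest \(\lambda\) and clipped to \((0, 1]\); with fewer than 100
  p-values the smoother is unstable and \(\pi_0 = 1\) is used, which makes
  the q-values exactly Benjamini-Hochberg.
* Dixon's outlier screen uses the classical one-sided 5% critical table for
  \(n \le 30\) and a simulation-calibrated extension grid (interpolated in
  \(1/n\)) beyond it; flags are advisory, mirroring how array QC screens are
  used in practice.
* Probeset construction clusters a gene's probes by complete linkage on
  \(1 - r\) and cuts at 0.5. Complete linkage is chosen deliberately: it is
  the only standard linkage that guarantees every within-probeset pairwise
  correlation is at least 0.5 after the cut.
* Filter order in genotype QC is fixed (call rate, then Hardy-Weinberg on
  hard calls only, then MAF) and each SNP is counted against the first
  filter it fails, so QC reports reconcile exactly.
* Best-SNP ties (e.g. SNPs with identical dosage columns) are broken by
  genomic coordinate, then lexicographic SNP id, making scans invariant to
  input order.
* All randomness flows through explicit integer seeds; every generator and
  pipeline output is a pure function of (inputs, configuration, seed).

# Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  simulation = simulation_config(n_genes = 80, seed = 7),
  compare_sva = TRUE, resample_sets = 50, seed = 7)
res <- run_pipeline(cfg)
res
res$report$n_bf_over_threshold          # discoveries at log10 BF > 5
res$report$replication_rate_either      # fraction replicating in >= 1 panel
replication_rate_curve(res$records, bf_grid = 0:10)
```

# Known limitations

The covariate model's replicate/probe averaging is exact only for balanced
designs; strongly unbalanced replicate structures would need the full
crossed mixed model. Replication requires the identical SNP in the
replication panel (no LD-proxy matching). The surrogate-variable estimator
assumes confounders are uncorrelated with the genotypes being tested. The
reporter model's valid haplotype test has limited power at the standard
three-preparation design, as quantified above.
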