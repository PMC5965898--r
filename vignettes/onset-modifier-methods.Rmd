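---
title: "Methods: modifier analysis of Huntington's disease age at onset in family clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modifier analysis of HD age at onset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onsetmod)
```

# Scope

`onsetmod` implements the analysis chain used in modifier studies of
Huntington's disease (HD) age at onset in founder family clusters: a
synthetic-cohort generator with known ground truth, the residual
age-at-onset phenotype, method-of-moments relatedness and family
reconstruction, kinship-corrected mixed-model association with conditional,
extreme-dichotomous, stratified and meta-analyses, polygenic modification
scoring, trio-based reconstruction of a consensus disease haplotype, and an
allele-specific CRISPR PAM scan. This vignette documents the models, the
parameters that matter, and the design decisions taken where the design was
genuinely open.

# The phenotype: residual age at onset

HD is caused by an expanded CAG repeat in *HTT*; longer repeats hasten motor
onset, and in carriers of two expanded alleles onset tracks the longer allele
(full dominance). The onset model is log-linear with population-specific
intercepts and a shared slope:

$$\ln(\text{onset}_i) = \beta_{0,\text{pop}(i)} + \beta_1 \,
\text{CAG}^{\text{long}}_i + \varepsilon_i .$$

`fit_onset_model()` estimates it by ordinary least squares;
`residual_onset()` back-transforms the fitted values to the natural scale and
subtracts them from observed onset, so a positive residual means onset later
than expected for that CAG length. Residuals are computed on the years scale
by default (the log scale is available via `scale = "log"`); no
small-sample correction is applied to the back-transform, matching the plain
`exp()` of the fitted log prediction. `dominance_check()` augments the
regression with the shorter expanded allele among biallelic (CAG > 35/35)
subjects; under dominance of the longer allele its coefficient is
indistinguishable from zero.

# The synthetic-cohort generator

`simulate_cohort()` emulates the structure of a Venezuelan-style HD founder
cluster. Its defaults are the study conditions and are not tuned per
analysis:

* **374 affected subjects in 22 families**, with one family holding ~55% of
  subjects (weights `c(0.55, rest equal)`), mirroring a dominant kindred of
  218/374. Families are built breadth-first: an affected founder marries in
  an unaffected founder spouse; affected children are ascertained and marry
  in new founder spouses, with sibship sizes `1 + Poisson(mean_children - 1)`
  (default mean 3).
* **Genotypes**: founder haplotypes are Bernoulli draws from per-site
  alternate-allele frequencies (uniform on 0.05–0.5 by default, optionally
  population-perturbed by `freq_divergence`); gametes are formed with
  independent per-adjacent-site crossovers (`recomb_rate`, default 0.01, no
  interference), restarting at chromosome boundaries. A `panel` argument
  re-uses a previous simulation's variant panel so that training and transfer
  cohorts share SNPs.
* **Disease haplotype**: one founder chromosome per family carries the
  expansion; affected children are ascertained to receive the
  disease-carrying chromosome at a disease locus (`disease_locus_index`,
  default the middle SNP of chromosome 1), by conditioning the meiosis path
  there — the label swap leaves the crossover process unchanged by symmetry.
  This is what makes trios of one HD parent share a disease haplotype, as a
  real nuclear HD family does.
* **CAG**: founder expansions uniform on 40–55; transmissions take a ±1 step
  with probability 0.05 (instability is modelled minimally); the normal
  allele is ~19 repeats; with probability 0.032 (≈12/374) a subject carries a
  second expanded allele.
* **Onset**: `exp(intercept_pop + slope * CAG_long + eps)` plus the summed
  planted modifier effects in **years**. Defaults: slope −0.05 log-years per
  repeat; intercepts 5.87 (earlier-onset population) and 6.00, which put mean
  onset near 35.5 years at the mean expanded CAG of ~46 and make the gap
  ~5 years at CAG 46; `eps` is Gaussian on the log scale (the distribution of
  onset noise is not identified by the data we emulate; log-normal keeps
  onset positive and is the conventional choice), default sd 0.1.
* **Planted modifiers** (`planted_modifier()`): additive year-per-allele
  effects, optionally restricted to one population, emulating common
  modifiers of ~−2.8 years/allele and rarer ones of ~−6 years/allele.
* **Error injection** (`inject_errors()`): after ground truth is recorded,
  calls are blanked with `missing_rate` and otherwise flipped with
  `genotype_error_rate`; every altered cell is logged and the two logs are
  disjoint.

Ground truth records phased haplotypes, the pedigree, the per-subject
modifier contribution in years, and all injected perturbations, so every
downstream stage has an exact oracle.

What the generator does **not** emulate: reference-panel linkage
disequilibrium, the X chromosome, imputation error, genotyping batch
effects, and ascertainment subtleties of onset recording. Passing tests on
this generator show the estimators are correct under idealized Mendelian
data, not that real-cohort results would be reproduced.

One interaction deserves note: because transmitted expansions are nearly
constant within a family, expanded CAG behaves almost like a family label,
so any family-clustered quantity (including modifier dosages) correlates
with CAG across ~20 families. The onset-model fit then absorbs part of a
planted modifier's signal. For this reason the *generative variance
explained* used when checking polygenic-score recovery is defined as the
R² that the true planted contribution attains **in the residual phenotype**
(`lm(residual ~ truth)`), not as the raw variance ratio of the planted
component, which overstates what any score can recover.

# Relatedness

`estimate_ibd_all()` is a method-of-moments estimator of the IBD-state
probabilities (Z0, Z1, Z2) from identity-by-state counts and allele
frequencies estimated from the cohort itself (the natural choice when no
external reference is available). Per-pair missing sites are skipped;
monomorphic sites are dropped; pairs with fewer than 500 informative sites
carry a warning flag. Estimates are reported raw and projected onto the
probability simplex (clip at zero, renormalize); PI_HAT = Z1/2 + Z2. No
finite-sample frequency corrections are applied — with cohort-estimated
frequencies from ≥100 subjects the bias is far below the estimator's
sampling noise at 10,000 SNPs (unrelated pairs: raw PI_HAT within ±0.05).

`classify_relationship()` assigns the nearest expected (Z0, Z1, Z2) centroid
(duplicate, parent-child, full sibling, second degree, unrelated) —
deterministic and testable, in place of rectangle gating.
`build_families()` takes the connected components of the PI_HAT > 0.125
graph (first cousins or closer), which is the fixed point of exhaustive
pair merging; families are numbered by decreasing size with ties broken by
smallest member id. `compute_kinship()` builds the centered genomic
relationship matrix `K = Xc Xc' / p` with per-variant mean imputation (a
standardized construction is available); `compute_ancestry_components()`
returns the top principal components of the centered dosages with signs
fixed by the largest-magnitude loading.

# Mixed-model association

`run_lmm_gwas()` fits, per SNP, the single-variance-component linear mixed
model

$$y = W\alpha + g\beta + u + e,\qquad u \sim N(0, \sigma^2_g K),\quad
e \sim N(0, \sigma^2_e I).$$

The variance ratio $\lambda = \sigma^2_g/\sigma^2_e$ is estimated **once**
under the covariates-only null model, by 1-D maximum-likelihood profiling on
$\log\lambda$ after eigendecomposition of $K$ (REML optional); each SNP is
then tested by a Wald test under generalized least squares at that ratio,
with the residual variance re-estimated per SNP and a t reference
distribution. This is the standard two-step approximation to a per-SNP
variance-component fit; it is exact under the null and differs negligibly at
modifier effect sizes, while reducing **exactly** to OLS when `kinship =
NULL` (or `K = I`) — a property the test suite asserts against a
normal-equations oracle at 1e-6 relative tolerance. SNPs are tested only
above the minor-allele-frequency threshold (default MAF > 5%); constant or
covariate-collinear SNPs are skipped.

The secondary analyses reuse the same engine. `conditional_scan()` adds a
top SNP's dosage as a fixed covariate (perfect-LD tags and the SNP itself
drop out by collinearity). `extreme_dichotomous()` labels the
`floor(n * 0.10)` earliest and latest residual-onset subjects 0/1 (stable
tie-break by residual then subject id), drops the middle, and by default
keeps the kinship mixed model on the 0/1 label; a plain logistic engine is
available since both descriptions fit the source procedure, and neither is
asserted to be the original computation. `stratified_interaction_scan()`
splits the cohort into carriers and non-carriers of a stratifying SNP's
minor allele and dichotomizes the top/bottom 40% within each stratum.
`exclude_and_rerun()` repeats the scan on a sample subset for stability
checks. `meta_analyze()` is inverse-variance fixed-effects with allele
flipping (combined SE = `(sum 1/se_i^2)^(-1/2)`); `genomic_inflation()` is
the median method, `median(qchisq(1 - p, 1)) / 0.4549`.

`build_modifier_score()` selects independent SNPs at suggestive significance
(default p < 1e-5) greedily in ascending p, where independence means outside
a 1 Mb window or genotype r² < 0.2 within it (the source states only
"independent"; these are conventional defaults). `apply_modifier_score()`
sums effect-allele counts times training effect sizes;
`evaluate_score()` reports the score's incremental R² over covariates and
its p-value in a linear model on residual onset.

# Trio phasing and the consensus disease haplotype

Each father–mother–child trio is processed independently, even when the same
parents appear in several trios. Sites are excluded when (1) all three
genotypes are missing, (2) all three members are identically heterozygous,
or (3) a Mendelian error is detected. Mendelian errors are screened only
under three completeness patterns — complete trio; complete child with
missingness confined to one parent; one missing child allele with complete
parents — and a site is flagged only when **no** assignment of transmitted
alleles is consistent, with missing alleles acting as wildcards over the
site's alleles. Errors masked by other missingness patterns are deliberately
not flagged (they are logically undetectable or outside the screen) and are
instead caught, if at all, when multiple phased haplotypes are merged.

Phasing itself is deterministic rule-based deduction: at each usable site
the allele the designated parent transmitted is reported only when the three
genotypes force it; after triple-heterozygote exclusion every phaseable site
is forced, so a statistical phaser is unnecessary and oracle tests are
exact. `merge_consensus()` then applies the support rule per site: at least
two agreeing phased calls give the consensus allele; two or more calls with
any disagreement give `'?'`; fewer than two calls give `'N'`. Coverage is
the fraction of determined sites, and `determined + N + ? = total` always.
With deterministic phasing, `'?'` can only arise from genotype errors that
evade the Mendelian screen; the category is kept as specified.
`assign_tag_haplotypes()` names chromosomes from a configurable tag-SNP
dictionary (hap.01…hap.16 style), `family_disease_haplotype()` assigns each
family the modal name (ties flagged, lowest number wins), and
`encode_repeat_structure()` gives the codon run-length encoding of the
repeat region (e.g. 45×CAG, 1×CAA, 1×CAG, 1×CCG, 1×CCA, 7×CCG, 2×CCT).

All coordinates are 0-based half-open internally; VCF output converts to
1-based.

# Allele-specific PAM discovery

`build_haplotype_sequence()` substitutes SNVs into a reference window, masks
undetermined calls as `N`, writes deletions as `-` to keep the coordinate
frame, and skips insertions with a warning (sites overlapping gaps are not
callable). `find_pam_altering_sites()` scans both strands of two
coordinate-aligned haplotypes for SpCas9 NGG PAMs (CCN on the plus strand
for minus-strand PAMs) and reports sites where the PAM exists on haplotype A
but not at the homologous position of haplotype B, with the causative
difference and the 20-nt protospacer 5' of the PAM on the PAM strand.
Windows containing `N` or `-` are skipped. Variants that alter the
protospacer rather than the PAM are out of scope by default. Output is
ordered by position then strand, and both a site count and a variant count
can be derived (a variant can create PAMs on both strands; the table keeps
them distinct). `propose_excision_pairs()` enumerates ordered site pairs
whose span contains all requested features (e.g. the transcription start
site and first exons), ranked by span length.

# Numerical choices and problem sizes

* Likelihood profiling searches $\log\lambda \in [-12, 12]$ with
  `optimize()`; kinship eigenvalues are clipped at zero, and the matrix is
  PSD-projected (with a warning) only if an eigenvalue falls below −1e−8.
* Dichotomization ties are broken by stable sort on (residual, subject id).
* Family numbering, site ordering and PAM-site ordering are all
  deterministic so identical seeds give byte-identical outputs.
* The test-suite problem sizes are chosen to finish on a single CPU in
  minutes while keeping every statistical check well-powered: calibration of
  the genomic inflation factor uses 50,000 SNPs × 374 subjects; modifier
  detection uses 20 replicate cohorts of 374 subjects × 2,000 SNPs;
  IBD calibration uses 200 pairs at 10,000 SNPs; the PAM oracle comparison
  uses 1,000 random 500-nt haplotype pairs.

# Known limitations

* Independent Bernoulli crossovers produce no interference and no realistic
  LD decay; IBD and kinship behave correctly, but fine-scale LD-dependent
  behaviour (tag-SNP structure, imputation) is out of scope.
* The two-step (null-model) variance-ratio estimate slightly attenuates
  per-SNP Wald statistics for very large single-SNP effects relative to a
  per-SNP fit, and the kinship matrix includes the tested SNP (no
  leave-one-chromosome-out), which mildly shrinks large planted effects —
  both visible only at effect sizes far above those of realistic modifiers.
* On the years scale the residual's variance grows with predicted onset, so
  plain OLS p-values in score evaluation are exact only asymptotically;
  simulation shows the size distortion at the study scale is within Monte
  Carlo noise of nominal.
* The dichotomous analyses expose both a kinship-mixed-model engine and a
  plain logistic engine because the source procedure is ambiguous between
  them; results agree in direction but not numerically.
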