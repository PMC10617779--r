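---
title: "Multiscale donor–recipient mismatch analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale donor–recipient mismatch analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DRmismatch)
```

# The problem

After kidney transplantation, the recipient's immune system surveys the
graft for protein products it has never seen. Classical HLA matching
captures only part of this antigenic distance: at millions of non-HLA
polymorphic sites the donor may carry an allele the recipient lacks, and
each such site is a potential minor histocompatibility antigen — or, for
intronic variants, a potential regulatory difference. `DRmismatch`
quantifies this donor-to-recipient genetic mismatch at several genomic
scales and screens it against long-term death-censored graft loss
(DCGL), with death treated as censoring.

# The mismatch model

## Variant level

For a biallelic variant with donor genotype $g_D \in \{0,1,2\}$ and
recipient genotype $g_R \in \{0,1,2\}$ (ALT-allele counts), a mismatch
occurs when the donor carries an allele **absent** from the recipient.
The number of introduced ("alien") allele copies defines the category:

| $g_D \backslash g_R$ | 0 (hom REF) | 1 (het) | 2 (hom ALT) |
|---|---|---|---|
| 0 | none | none | double (REF) |
| 1 | single (ALT) | none | single (REF) |
| 2 | double (ALT) | none | none |

A heterozygous recipient carries both alleles, so it can never receive
an alien allele — the table's middle column. The relation is
asymmetric: `variantMismatch(1, 0)` introduces the ALT allele while
`variantMismatch(0, 1)` introduces nothing. "Any mismatch" collapses
single and double into one 0/1 indicator. Missing genotypes propagate
to a MISSING call and are skipped (never imputed) downstream.

## Gene, class and genome-wide scales

Coarser scores sum the per-variant 0/1 indicator (presence/absence, not
the allele count) over a variant set: an annotated gene region
(introns included — the motivating risk variants are intronic), a
functional class (exonic, non-exonic, transmembrane-nonsynonymous), or
all QC-passing variants outside the MHC. Raw sums depend on platform
and imputation density, so each scale is normalized by the cohort
interquartile range of the raw scores:
$S_{\text{norm}} = S_{\text{raw}} / \mathrm{IQR}(S_{\text{raw}})$.
IQR normalization is a positive rescaling — it preserves pair ordering
and correlations — and makes scores comparable across cohorts typed on
different platforms. Quantiles use the linear-interpolation convention
(R type 7) by default; the convention is configurable because published
descriptions rarely state it.

Two variant sets matter. The genome-wide score uses **all** QC-passing
non-MHC variants. The gene- and variant-level screens additionally drop
variants whose any-mismatch frequency across pairs is below 5%
(`mismatchFrequencyFilter`): a variant mismatched in almost no pairs
cannot carry association signal and only adds noise. A variant at
exactly the 5% boundary is kept.

## Quality control

`applyQC` applies, in a fixed order so reports are deterministic:
imputation INFO score < 0.4, missing rate > 0.05, monomorphic, MAF
< 0.01, Hardy–Weinberg exact-test p < 1e-6, and MHC-interval exclusion
(chr6:28866528–33775446, hg19, 1-based inclusive). Each removed variant
is attributed to the first filter it fails, so
input = surviving + sum(removed) always reconciles. The HWE exact test
sums, conditional on the allele counts, the probabilities of all
heterozygote configurations no more likely than the observed one; it is
checked in the test suite against full enumeration for every
configuration with up to 50 genotypes. Published pipelines rarely state
which sample set HWE used; the default here is all samples, with
options for recipients only or recipients plus living donors (donors
and recipients are largely unrelated samples from the same populations,
so pooling is the default). Genotypes with imputation posterior below
0.95 are set missing at VCF read time; masking can only introduce
missingness, never change a retained call.

## Kinship validation

A genome-wide mismatch score should be, in effect, a rescaled genetic
distance: lowest for living-related donors, higher for unrelated
same-ancestry pairs, highest for cross-ancestry pairs. The package
therefore ships the classical method-of-moments identity-by-descent
estimator (`estimatePibd`): per-site identity-by-state counts are
compared with their expectations under IBD state 0/1/2 given allele
frequencies, giving $\hat\pi = \hat k_1/2 + \hat k_2$, truncated to
[0, 1] and restricted to common variants (MAF ≥ 0.05). The synthetic
cohort's closed loop checks both directions: $\hat\pi$ recovers the
planted kinship, and the normalized score falls with it.

One caveat worth stating precisely: with the study-like relatedness mix
(70% of pairs at true IBD exactly 0), rank correlations between score
and *true* IBD are ceiling-limited. A tie block of fraction $t$ of $n$
observations caps the attainable |Spearman| at
$\sqrt{1-(t^3n^3-tn)/(n^3-n)}$ — about 0.81 at $t=0.7$ — no matter how
perfectly the score orders the pairs; the Pearson correlation, which
has no such ceiling, is the better summary under these conditions.

# Survival association

All survival models are Cox proportional-hazards fits (delegated to the
`survival` package, Efron tie handling by default, Breslow by flag),
with Kaplan–Meier curves and log-rank tests for group displays. The
test suite anchors the fits to an independent grid-search maximization
of the written-out partial likelihood and to the classical identity
between the two-group log-rank statistic and the Cox score test.
Confidence intervals are Wald: $\exp(\beta \pm 1.96\,\mathrm{se})$.
Pairs with missing covariates are dropped listwise. Non-convergent or
separated fits are flagged, never silently reported.

## The gene-level screen

Each gene's raw mismatch score is tested as the exposure in a
multivariable Cox model adjusting the genome-wide normalized score, HLA
mismatch, induction therapy and donor status, under four scenarios:
{any, double} mismatch × {all pairs, intra-European pairs}. A gene is a
candidate when it is nominally significant in **all four** scenarios —
an intersection filter, deliberately used instead of a genome-wide
multiplicity correction, mirroring the screening practice this package
reproduces. Thresholds: p ≤ 0.01 isolates top candidates; p ≤ 0.05
gives an extended candidate list. This is documented as
faithful-to-practice, not as the best possible error control; BH
correction is applied only on the expression side, where it belongs to
the original analyses. Candidate gene lists can be collapsed with
`aggregateGeneScore` into one aggregate exposure plus its
"remaining genome" complement, to show that the candidates carry a
disproportionate share of the association.

## The variant-level screen and the haplotype block

Within a locus of interest, each variant's any-mismatch indicator is
screened under four scenarios: adjusted for the tag-SNP risk-mismatch
indicator on all pairs, and restricted to the tag-non-risk stratum,
each on the full cohort and the intra-ancestry subset. Variants
significant in all four are candidate members of a haplotype block.

`buildBlock` reduces the candidates to a clique with pairwise
$r^2 \ge 0.99$ (greedy removal of the least-connected member; ties
broken by genomic position, earliest kept) and verifies every retained
member has $r^2 < 0.5$ with the tag SNP — the block must be a haplotype
distinct from the tag's. Two-locus $r^2$ comes from EM haplotype
frequency estimation on unphased genotypes (only double heterozygotes
are ambiguous; convergence at 1e-10 or 1000 iterations), checked
against the phased closed form wherever phase is forced.

Member alleles are oriented onto a common haplotype by the sign of the
pairwise disequilibrium coefficient; the orientation with cohort
frequency below 0.5 is the **minor haplotype** (ties resolve toward the
first member's ALT allele). Per-sample minor-haplotype dosage is the
strict majority vote of the member SNPs' minor-allele counts: published
block analyses never state how disagreeing imputed members were
resolved, so the rule here is explicit — a sample with more than half
its members missing, or with no strict majority (e.g. a 15/15 split),
is MISSING, and the discordance rate (fraction of non-missing members
outvoted) is reported.

## Directionality

Treating the block as one biallelic locus, each pair falls in exactly
one class: `TAG_RISK` (tag-SNP risk mismatch — risk allele carried by
the donor, recipient homozygous non-risk), which takes precedence over
everything so that tag-risk pairs are analyzed apart;
`MINOR_INTRODUCING` (donor introduces the minor haplotype allele into a
homozygous-major recipient); `MAJOR_INTRODUCING` (the reverse); else
`OTHER`. The precedence changes group sizes and is therefore stated
prominently. Dosage effects use the alien-allele count (0/1/2) as a
numeric Cox exposure.

# Expression analyses

The cis-eQTL model is ordinary least squares of log2(TPM+1) expression
on allele dosage plus age, sex and ancestry, with a t-test on the
dosage coefficient. This deliberately replaces moderated (empirical
Bayes) statistics: at the expression cohort sizes in view (~90
samples), variance moderation changes almost nothing, and plain OLS
keeps the estimator transparent. Transcriptome-wide runs are
BH-adjusted. Seed-gene coexpression is Pearson correlation against all
other genes with BH adjustment, calling genes at |r| ≥ 0.6 and adjusted
p ≤ 0.05 (both configurable, with an optional positive-only
restriction); the seed is excluded from its own output and
zero-variance genes are skipped with a warning.

# The synthetic cohort generator

Real transplant-cohort genotypes are protected data, so the package is
exercised end-to-end on synthetic cohorts whose every planted parameter
the pipeline can try to recover. What the generator emulates, and its
defaults (chosen once to echo the study structure it models):

* **Cohort**: 385 pairs, ~13% DCGL event rate, 1,824-day administrative
  horizon with Uniform(0, 2×horizon) dropout censoring; ~50% living
  donors.
* **Ancestry**: three populations (EUR 70%, AFR 20%, EAS 10%) under the
  Balding–Nichols model — ancestral frequency p₀ ~ Uniform(0.05, 0.95),
  per-ancestry frequency Beta(p₀(1−F)/F, (1−p₀)(1−F)/F) with F = 0.1 —
  so inter-ancestry pairs have elevated mismatch, as in real cohorts.
* **Kinship**: pairs at expected IBD 0 / 0.25 / 0.5 in proportions
  70/20/10 (deceased or unrelated-living donors vs living-related
  donors). Sharing is locus-independent per haplotype (Bernoulli with
  probability equal to the expected fraction), not segment-based: this
  reproduces π̂ and score–kinship structure exactly but makes no
  attempt at realistic genome-wide LD decay. LD exists only inside the
  constructed block.
* **Causal block**: 30 SNPs drawn intact from a two-haplotype pool
  (within-block r² ≈ 1; the block is inherited as a single locus under
  relatedness so its LD survives), with per-ancestry minor-haplotype
  frequencies (EUR 0.37, AFR 0.15, EAS 0.62 — echoing the wide
  population range of the motivating haplotype) and a configurable
  recombinant fraction. Member REF/ALT orientation is randomized so the
  orientation logic is genuinely exercised. A tag SNP is drawn
  independently of the block pool (r² < 0.5 by construction); its ALT
  allele is the risk allele.
* **Hazard**: exponential event times with rate
  λ₀·exp(β_gw·S̃ + β_gene·G̃ + β_minor·1[minor-introducing] +
  β_tag·1[tag-risk]), where S̃ is the centered normalized genome-wide
  score computed by the package's own scoring rule (closed loop), and
  G̃ the centered alien-allele count in a designated causal gene — the
  antigenic dose doubles under a double mismatch, which is why the
  generator counts alleles while the screens use the 0/1 indicator.
  Defaults β_gw = log 1.46, β_minor = β_tag = log 2, β_gene = 0. λ₀ is
  calibrated by bisection so the expected event rate matches the target
  within 0.1 percentage points; the exponential baseline satisfies
  proportional hazards exactly, so Cox recovery tests are not biased by
  model misspecification.
* **Expression**: one cis-regulated target gene (intercept 5, effect
  0.5 per minor allele, small age/sex effects, unit Gaussian noise on
  the log2(TPM+1) scale, floored at 0), a planted 50-gene coexpression
  module at r = 0.8 to the target, and independent noise genes; 91
  expression samples by default.

All randomness flows from the single config seed; `emitCohort` writes
VCF/TSV/BED inputs that are byte-identical across runs with the same
config.

**What passing closed-loop tests does and does not show.** Recovery on
these cohorts demonstrates that the estimators are consistent with
their own generative assumptions at realistic sizes. Real data differ
in ways the generator deliberately omits: genome-wide LD decay,
segment-structured IBD, imputation-error correlation, population-
specific MAF spectra, informative censoring, and unmodeled confounding
between ancestry and clinical covariates. Results on real cohorts
depend on those features; the tests here certify the machinery, not the
biology.

# Numerical and design choices

* Multiallelic VCF records are rejected, not decomposed: the mismatch
  definition is stated on allele presence and no decomposition rule
  would be canonical.
* Biallelic genotypes, coordinates and regions live in standard
  Bioconductor containers (`GRanges`); BED I/O preserves the 0-based
  half-open convention on disk.
* Missing calls are excluded from score sums without rescaling by
  default; optional per-pair rescaling by n_total/n_nonmissing exists
  but is off, since upstream imputation normally leaves little
  missingness.
* EM for r² initializes at uniform haplotype frequencies; monomorphic
  input is an explicit error (LD undefined).
* The screens are deterministic given input order, and permuting gene
  order permutes nothing but row order of the results.
* Test and example problem sizes (e.g. 200–400 pairs, 2,000–20,000
  variants, 501 genes with ~30 common variants each) were chosen as the
  smallest sizes at which the planted effects are comfortably
  detectable by design, keeping the full suite runnable on a laptop
  core; gene sizes mirror the tens-to-hundreds of common SNPs real
  gene loci carry.

# Known limitations

* Power at realistic event rates is finite and worth computing before
  trusting a null: with ~13% events at 400 pairs (≈52 events), a
  hazard ratio of 2 confined to a ~20% subgroup sits near the
  detectability edge of a multi-group log-rank test — the 90%-power
  detectable effect is roughly HR 3 ((1.96+1.28)/√(52·0.2·0.8) ≈ 1.1
  on the log scale). Closed-loop survival checks at these sizes should
  be read with that arithmetic in mind.
* No phasing or imputation: genotype posteriors are consumed, never
  produced; dosage for partially missing blocks relies on the majority
  vote.
* HLA mismatch is an input covariate, never computed; copy-number
  variation is handled only through a tag SNP.
* The intersection-across-scenarios screening criterion controls no
  formal family-wise error rate — it reproduces the practice it
  models and should be followed by replication, as in the original
  studies.
* The generator's locus-independent IBD model cannot support analyses
  that need realistic IBD segment lengths.
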