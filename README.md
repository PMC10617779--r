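# DRmismatch

Multiscale donor–recipient (D-R) genetic mismatch analysis for
transplant cohorts.

In kidney transplantation, genetic differences between donor and
recipient outside the HLA region contribute to long-term graft loss:
every biallelic site where the donor carries an allele the recipient
lacks is a potential minor histocompatibility antigen or regulatory
mismatch. `DRmismatch` implements the full analysis chain for screening
such mismatches against death-censored graft loss (DCGL):

* **Genotype QC** for imputed data: INFO score, missing rate,
  monomorphism, MAF, Hardy–Weinberg exact test (checked against full
  enumeration), MHC exclusion, and genotype-posterior masking.
* **Mismatch scoring.** At a variant, donor genotype $g_D$ mismatches
  recipient genotype $g_R$ when the donor carries an allele absent from
  the recipient; the count of introduced alleles classifies it as a
  single or double mismatch, and a heterozygous recipient can never be
  mismatched. Gene-level, functional-class and genome-wide scores sum
  the 0/1 indicator over the corresponding variant sets; each scale is
  normalized by the cohort IQR of raw scores,
  $S_{norm} = S_{raw}/\mathrm{IQR}(S_{raw})$.
* **Kinship**: method-of-moments identity-by-descent ($\hat\pi$) for
  validating the genome-wide score against relatedness.
* **Survival screens** (Cox proportional hazards via the `survival`
  package; Kaplan–Meier + log-rank): gene-level screening under four
  scenarios ({any, double} mismatch × {all, intra-ancestry pairs}) with
  an intersection criterion, variant-level screening within a locus
  (tag-SNP-adjusted and tag-non-risk-stratified), aggregate multi-gene
  scores, and haplotype-mismatch dosage trends.
* **Haplotype blocks**: EM-based two-locus $r^2$ from unphased
  genotypes, greedy clique construction at $r^2 \ge 0.99$ with
  exclusion of variants linked ($r^2 \ge 0.5$) to a tag SNP, per-sample
  minor-haplotype dosage by strict majority vote, and per-pair
  directionality classes (TAG_RISK ≻ MINOR_INTRODUCING ≻
  MAJOR_INTRODUCING ≻ OTHER).
* **Expression**: additive-model cis-eQTL tests of allele dosage on
  log2(TPM+1) expression and seed-gene coexpression (Pearson |r| ≥ 0.6,
  BH-adjusted p ≤ 0.05).
* **Synthetic cohorts**: a fully seeded generator of paired genotypes
  with ancestry structure (Balding–Nichols), kinship, a planted
  near-perfect-LD 30-SNP haplotype plus unlinked tag SNP,
  proportional-hazards outcomes calibrated to a target event rate, and
  cis-regulated expression — so the entire pipeline is testable with no
  access to protected cohort data.

## Worked example

```r
library(DRmismatch)

## a synthetic 150-pair cohort with a planted 30-SNP haplotype
cfg <- cohortConfig(nPairs = 150L, nVariants = 2031L, nGenes = 60L,
                    seed = 7L)
sim <- simulateCohort(cfg)
sim$genotypes
#> GenotypeMatrix: 300 samples x 2031 variants
#>   chromosomes: chr1, chr2
#>   missing calls: 0.00%
sim$cohort
#> PairCohort: 150 donor-recipient pairs
#>   events: 13 (8.7%)
#>   living donors: 69
#>   median follow-up: 1343.4 days

## genome-wide mismatch score, IQR-normalized
tab <- buildMismatchTable(sim$genotypes, sim$cohort)
gw  <- genomeWideScore(tab)
gw
#> ScoreTable [genome_wide, mode=any]: 150 pairs
#>   raw median: 551.5  IQR: 155.25

## association of the normalized score with graft loss
p <- pairData(sim$cohort)
fitCox(p$follow_time, p$event, data.frame(score = normScores(gw)))
#> CoxFit (efron ties): n=150, events=13
#>   term  beta  hr   se    z     p lower95 upper95
#>  score 0.994 2.7 0.55 1.81 0.071   0.918    7.94

## recover the planted haplotype block and classify directionality
blk <- buildBlock(sim$genotypes, sim$truth$blockMembers,
                  r2In = 0.99, tagVariant = "tagSNP", r2Out = 0.5)
blk
#> HaplotypeBlock: 30 member variants
#>   minor haplotype frequency: 0.357
#>   tag variant (excluded): tagSNP
#>   dosage called for 300 of 300 samples
```

(Numbers shown are the output of this exact script; the point estimate
at 150 pairs is noisy — the acceptance script below runs the same
analyses at full cohort size.)

The same chain runs file-based — VCF + TSV + BED in, TSVs out — via
`runPipeline()` or the thin CLI in `inst/scripts/drmismatch.R`:

```sh
Rscript inst/scripts/drmismatch.R all --out results/demo --seed 7
```

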