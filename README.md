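# pedrecomb

Individual recombination rate from pedigreed SNP data: crossover
detection, linkage maps, heritability, association and haplotype sharing
— with a gene-dropping meiosis simulator so every stage is testable
against known truth.

## The problem

In a pedigreed population genotyped on a SNP array, each meiosis of a
**focal individual (FID)** can be scored for crossovers: within a
five-member subpedigree (FID, its two parents, one offspring, the
offspring's other parent) the grandparental origin of transmitted
alleles is determined marker by marker, and each switch of origin along
a chromosome is a crossover. The per-gamete sum over autosomes — the
**autosomal crossover count (ACC)** — is a heritable individual
phenotype. This package implements the full analysis chain for such
data:

1. **Detection** — subpedigree construction, Mendelian-consistency
   masking (opposing homozygotes set missing; pairs with >0.1%
   mismatching loci dropped), single-locus phasing, crossover calling,
   and two double-crossover QC filters (single-SNP origin runs removed;
   runs with log10 span distance 2.5 SD below the mean removed).
2. **Linkage maps** — two-point recombination fractions from phase-known
   gametes, Kosambi distances `d = 25 ln((1+2r)/(1−2r))`, sex-specific
   and sex-averaged maps, iterative removal of markers >3 cM from both
   neighbours.
3. **Landscape** — crossover probability per 1-Mb bin (conserving each
   chromosome's total exactly), AIC-selected distance-to-telomere models
   with sex interactions, GC and SNP-density covariates, and broad-scale
   chromosome-length regressions.
4. **Variance components** — REML animal models `y = Xb + Z1 a + Zr ur + e`
   with genomic (GCTA-style, `1 + F` diagonal) or pedigree relationship
   matrices, permanent-environment effects, `h² = V_A / V_P`, LRTs, and
   bivariate male/female models for the cross-sex genetic correlation.
5. **GWAS** — per-SNP genotype-factor Wald tests inside the animal
   model, genomic control `λ`, an LD-based effective number of tests
   (`threshold = α / n_eff`), SNP variance `V_SNP = 2pqα²`, and a
   trans-only mode (ACC minus the focal SNP's own chromosome).
6. **Regional heritability** — sliding-window GRMs (150/50/20 SNPs,
   half-overlap) fitted against a rest-of-genome GRM, LRT-tested with an
   overlap-aware Bonferroni threshold.
7. **Haplotype sharing** — 6-SNP core haplotypes perfectly tagging a
   focal allele, and the bp distance to the first downstream mismatch
   between populations.
8. **Simulation** — gene dropping with sex-specific genetic maps, male
   subtelomeric elevation, optional crossover interference
   (gamma-renewal), a polygenic + major-QTL architecture for ACC, and a
   detection-validation harness that regresses detected on true ACC
   across repeated simulations.

## Worked example

Simulate a three-generation population, then fit the animal model to the
true per-gamete crossover counts of the focal (middle-generation)
parents:

```r
library(pedrecomb)

cfg <- sim_config(seed = 42, n_founders = 200, offspring_per_pair = c(2, 4),
                  interference_nu = 8)     # 26 autosomes, ~2k SNPs
ped <- simulate_pedigree(cfg)              # 800 individuals
gd  <- gene_drop(ped, cfg)                 # genotypes + true crossovers

gen <- setNames(ped$generation, as.character(ped$id))
tr  <- gd$truth[gen[gd$truth$parent] == 1, ]   # meioses of the focal parents

fit <- fit_animal_model(tr$acc_true, tr$parent,
                        fixed = data.frame(sex = tr$parent_sex),
                        relationship = pedigree_nrm(ped), pe = TRUE)
fit
```

```
Animal model: 800 observations, 200 individuals, logL = -1607.786
 component  variance       se boundary
  additive  4.604304 1.159392    FALSE
        pe  0.000000 0.000000     TRUE
  residual 25.330451 1.437783    FALSE
h2 = 0.1538 (SE 0.0356), V_P = 29.935
```

The simulator draws a polygenic ACC architecture with heritability 0.145
and phenotypic variance 29.56 by default; the model recovers both within
sampling error (h² = 0.154 ± 0.036, V_P = 29.9), with the
permanent-environment variance on its zero boundary as simulated. For
crossover *detection* (rather than truth-based analysis), run
`build_subpedigrees()` → `mendelian_qc()` → `detect_crossovers()` on an
array-density panel; `validation_run()` quantifies how accurate detection
is at a given marker density before you trust detected counts as
phenotypes.

The `analysis/` directory holds the full narrative workflow as numbered
scripts (simulate → validate/detect → maps → landscape → heritability →
GWAS → regional heritability → haplotype sharing), each a thin driver
over the package functions that prints what it finds and writes tables
under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_detect_crossovers.R
# ... through analysis/08_haplotype_sharing.R
```

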