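---
title: "Estimating and dissecting individual recombination rate from pedigreed SNP data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and dissecting individual recombination rate from pedigreed SNP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`pedrecomb` estimates individual autosomal recombination rates in a
pedigreed, SNP-genotyped population and dissects their genetic
architecture. This vignette explains the models and procedures, the
choices behind their defaults, and what the built-in simulator does and
does not emulate.

## The phenotype: autosomal crossover count

The unit of observation is a single meiosis: the gamete a **focal
individual** (FID) transmitted to one offspring. For each FID-offspring
pair we require a five-member *subpedigree* — the FID, both of its
parents, the offspring, and the offspring's other parent — with all five
genotyped. This structure lets the transmitted allele at each SNP be
established from single-locus rules (a homozygous offspring received that
allele; a heterozygous offspring with a homozygous mate received the
allele the mate could not have given), and, where the FID is heterozygous
and its parents' genotypes single out one assignment, the *grandparental
origin* of the transmitted allele. A switch of grandparental origin
between adjacent informative SNPs is a crossover; the per-gamete sum over
autosomes is the **autosomal crossover count (ACC)**, the analysis
phenotype. Subpedigrees containing the same animal twice (e.g.
father–daughter matings) are discarded, and opposing-homozygote
(Mendelian-inconsistent) genotype pairs are masked in both members, with
pairs exceeding 0.1% mismatching loci removed entirely.

Phasing errors show up as spurious *double crossovers*. Two filters
remove them: internal origin runs of a single SNP are deleted (a genuine
double crossover flanking one SNP is overwhelmingly unlikely under
crossover interference), and internal runs whose physical span falls more
than 2.5 SD below the pooled mean of log10 span distance are deleted.
Both filters can only reduce ACC. Terminal runs are never filtered: a run
touching a chromosome end is not flanked by two crossovers.

Single-locus phasing is deliberate. Multipoint phasers extract more
informative markers, but their output is not reproducible from first
principles in a compact implementation; here every origin call follows
from four genotypes by enumerable rules (the test suite compares the
implementation against a brute-force enumeration of all genotype
configurations). The cost — a smaller informative marker set — is
quantified, not assumed: the validation harness (below) measures the
detection accuracy that the chosen marker density actually delivers.

## Linkage maps and the recombination landscape

With phase-known gametes, the recombination fraction of each adjacent
marker interval is the discordance frequency among gametes informative at
both ends — the sufficient statistic once phase is known, replacing
iterative multipoint maximum likelihood. Distances are Kosambi
centimorgans, `d = 25 ln((1+2r)/(1-2r))`. Markers more than 3 cM from
*both* neighbours are treated as misplaced and removed, re-estimating
until none remain; terminal markers are exempt (they have one
neighbour). Intervals with no jointly informative gametes are bridged
with 0 cM and flagged.

Fine-scale structure is summarised as crossover probability per 1-Mb bin:
each interval's `r` is allocated to bins in proportion to base-pair
overlap (`r x N_boundary / N_adjSNP` at a boundary, extended
proportionally for intervals spanning several bins), which conserves the
per-chromosome total exactly. Bin probability is then modelled as a
Gaussian linear function of distance to the nearest telomere — candidate
transforms linear, inverse, quadratic, cubic and log10, chosen by AIC —
with sex as main effect and in interaction, plus SNPs per bin and GC
content. Distance is measured from the bin midpoint (symmetric choice;
the convention is not fixed by common usage) and is capped at 60 Mb.
Broad-scale structure is summarised by linear regression of map length on
physical length, an inverse-x regression of cM/Mb on length (obligate
crossing over makes small chromosomes recombine faster per Mb), and the
male-on-female map-length regression.

## Variance components and heritability

ACC is modelled per gamete with an animal model,

y = Xb + Z1 a + Zr ur + e,

with sex and the genomic inbreeding coefficient as fixed effects, an
additive genetic effect `a` whose covariance is a relationship matrix
times `V_A`, an individual-identity (permanent environment) effect for
repeated measures, and residual. The genomic relationship matrix uses the
standard frequency-standardised cross-products with the genomic
inbreeding measure on the diagonal (diagonal `1 + F`); the pedigree
numerator relationship matrix comes from the tabular method. Heritability
is `V_A` over the sum of all estimated variance components.

REML is maximised directly (bounded quasi-Newton on the variance scale)
rather than by average-information iterations. Because every random
effect in these models is defined at the individual level while the
residual acts per gamete, the restricted likelihood factorises exactly
into within-individual contrasts (residual only) and individual means
(covariance `sum_k s_k K_k + s_e diag(1/n_i)`), reducing a
several-thousand-gamete model to a few-hundred-dimensional one. The
implementation is verified against the balanced half-sib ANOVA closed
form to 1e-6 and against a dense-matrix REML on repeated-measures
designs. Convergence uses a relative-tolerance of 1e-10; variance
components are bounded below by zero and flagged when they end on the
boundary (a boundary regional estimate masks its LRT p-value, since such
a comparison is uninformative). Standard errors come from the inverse
numerical Hessian; the heritability SE uses the delta method. LRTs for
random effects use the plain chi-square reference with 1 df by default,
with the 50:50 boundary mixture available as an option.

The bivariate male/female model estimates sex-specific `V_A` and the
cross-sex additive correlation `r_A` (cross-covariance
`r_A sqrt(V_Am V_Af)` scaled by relatedness); constrained fits at
`r_A = 0`, `r_A = 0.999` and equal `V_A` provide the 1-df LRTs.

At a few thousand markers a GRM's entries carry sampling noise comparable
to the relatedness signal of a wild pedigree, attenuating heritability
estimates; this is why array-scale marker counts (tens of thousands) are
needed before GRM- and pedigree-based estimates coincide. The package's
own demonstration analyses therefore quote the pedigree-matrix estimate
alongside the GRM one, and the two are tested for agreement on a
sib-structured design where the signal dominates.

## GWAS, genomic control and multiple testing

Each SNP enters the animal model as a fixed genotype factor with two or
three observed levels, tested by a joint Wald chi-square (df = classes -
1). By default the variance components are estimated once under the null
model and held fixed across SNPs, making each per-SNP test a GLS fit on
the collapsed scale (the familiar two-stage shortcut); full per-SNP REML
re-estimation is available via `method = "refit"`. The relationship
matrix defaults to the pedigree NRM for speed, with a GRM accepted.

The genomic-control parameter is the median Wald statistic over its null
median; 1-df statistics are mapped to the 2-df scale through their
p-value quantiles before pooling, and correction is applied only when
`lambda > 1`. The multiple-testing threshold is `alpha / n_eff`, where
each SNP past the first contributes `sqrt(1 - max r2)` with the preceding
(up to) 49 SNPs of its chromosome — the two limiting cases (independent
SNPs count fully; 50 duplicated SNPs count once) pin down the scheme. The
variance explained by a SNP is `2pq alpha^2` with
`alpha = a + d(p - q)`; the test suite checks this against the
brute-force additive variance of the Hardy–Weinberg class means.
Trans-only association replaces the response with ACC minus the focal
SNP's own chromosome count, separating genome-wide rate modifiers from
linkage with locally polymorphic recombination landscapes.

## Regional heritability

Additive variance is partitioned into a sliding-window GRM (default 20
SNPs, overlapping by half) plus the GRM of all remaining autosomal
markers, alongside the permanent-environment and residual terms. The
complement GRM is derived from the marker-average identity
`A_all m_all = A_win m_win + A_rest m_rest`, so a scan costs one
whole-genome GRM plus one small GRM per window. Significance is by LRT
against the model without the regional term, Bonferroni-corrected by half
the window count (each region is modelled twice). Because window GRMs
carry marker-sampling noise of their own, the partitioned model's total
phenotypic variance agrees with the single-GRM fit only to within a few
percent — exact equality is not attainable and not asserted.

## Haplotype sharing

For a focal SNP, core haplotypes of six SNPs on its proximal side are
enumerated and retained only if every carrier bears the same focal allele
(tagging purity 1). Sharing between populations is the bp distance from
the core to the first mismatching SNP downstream, over all
cross-population carrier pairs; pairs identical to the region edge are
reported as censored at the last compared SNP rather than resolved
either way, and summary means are reported both over uncensored pairs and
overall. Window placement and walk direction are parameters: the default
(proximal core, downstream walk) reflects the subtelomeric use case where
only one direction is available.

## The meiosis simulator

Everything above is testable against truth because the package carries a
gene-dropping simulator. A configurable pedigree (founders, generations,
litter sizes) is populated with founder haplotypes drawn from per-SNP
allele frequencies (optionally as mosaics of a small ancestral pool, to
create background LD); meioses are simulated with explicit crossovers
and the true count and positions of every meiosis are recorded.

The genome template is 26 autosomes totalling ~2.45 Gb with a
largest-to-smallest ramp matching a sheep-like karyotype. Default map
lengths are 2860 cM (female) and 1.31 times that (male), allocated as an
obligate 100 cM baseline per chromosome plus a length-proportional
remainder; male crossover density is elevated threefold within 18 Mb of
chromosome ends, producing the male subtelomeric excess characteristic of
this system.

Two count models are available. With `interference_nu = 1`, counts are
Poisson, optionally in obligate form `1 + Poisson(cM/100 - 1)`, and
positions are uniform on the cM scale. With `nu > 1`, crossovers follow a
stationary gamma-renewal process with shape `nu` on the cM scale
(interference); the renewal process then governs the count itself, and
the obligate flag is inactive — near-regular spacing already makes
crossover-free chromosomes rare, and imposing a floor of one per
chromosome would truncate the latent scale (see below).

Individual variation enters through a latent per-gamete rate
`mu_sex + g + q + e`, with `g` a pedigree-correlated polygenic value of
variance `V_A`, `q` an optional additive QTL deviation (optionally
sex-limited, centred on the population mean dosage, with a forceable
allele frequency), and `e ~ N(0, V_R)` per gamete. Under the obligate
Poisson model the latent rate scales only the non-obligate part of the
expectation; under the renewal model it scales the whole intensity. Given
a target phenotypic variance and heritability (defaults 29.56 and 0.145),
the constructor derives `V_A` and `V_R` after subtracting the
count-sampling variance the chosen model contributes; for the renewal
model that variance is calibrated by a short fixed-seed Monte-Carlo run,
because chromosome maps are only about one mean inter-crossover spacing
long and the asymptotic value `mean/nu` understates the edge effects.

One modelling consequence is worth spelling out: a gamete-level obligate
count model bounds ACC below by the chromosome number, so a female-like
mean of ~28.6 crossovers over 26 autosomes leaves almost no room for
latent variance — the scaling clamps for a third of gametes and the
realised variance collapses. Biologically, obligate crossing over holds at
the bivalent, not the chromatid, and transmitted-gamete counts do fall
below the chromosome number. The interference model reproduces the
intended means and variances in both sexes and is therefore used for the
simulated study conditions in the demonstration analyses and acceptance
checks, while the Poisson/obligate path remains the simple default for
small structural examples.

### The detection-validation harness

`validation_run()` repeats gene-dropping over a single pedigree (marker
map and allele frequencies held fixed across replicates) and runs the
full detection pipeline each time, regressing detected on true ACC per
simulation (across gametes) and per gamete (across simulations). Gametes
with per-gamete adjusted R^2 at or below 0.95 are flagged as
systematically unreliable and excluded from the reported per-simulation
accuracy, mirroring how such gametes are removed from downstream analyses
in practice.

The harness preset (`sim_config_validation()`) uses a three-generation
pedigree yielding ~208 phase-informative gametes, zero genotyping error,
interference shape 8 and SNP density 24 per Mb (~59k markers). The
density is higher than a 50K array because single-locus phasing renders
roughly a quarter of markers informative, whereas a multipoint phaser
recovers origin for most heterozygous sites; matching the *informative*
marker spacing, not the raw count, is what makes accuracies comparable.
Under these conditions the population-level detection accuracy exceeds
0.99: the per-simulation adjusted R^2 over retained gametes averages
about 0.992-0.993, with individual replicates spanning roughly
0.989-0.995 (at ~200 gametes each per-replicate estimate carries
sampling noise of about +/-0.002) and 5-10% of gametes flagged. At
association-scale density (~1 SNP per 1.2 Mb)
detection is far sparser, which is why the demonstration analyses
simulate genotypes for the genetics stages at low density but analyse the
true counts, citing the validation result as the licence to do so.

### What the simulator does not emulate

Founder haplotypes are (by default) in linkage equilibrium; real chips
carry extensive LD, which matters for the effective-number-of-tests
correction and haplotype sharing (a block-LD founder mode exists for
those). There is no mutation, no selection, no X chromosome or
pseudoautosomal region, no genotyping batch structure, and crossover
positions ignore hotspot-scale structure below the subtelomeric-window
resolution. Genotyping error is i.i.d. across calls, unlike real
cluster-calling artefacts. Passing tests on these simulations therefore
demonstrates correctness of the algorithms under the stated generative
model, not robustness to every artefact of real array data.

## Problem sizes

The demonstration analyses and acceptance checks run at what a single
desk machine handles comfortably: detection validation on ~208 gametes
by ~59k markers over 10 replicates; variance-component and association
analyses on ~3,200 gametes from 800 focal individuals at ~2k markers;
regional scans fitted per window on a few hundred individuals. These
sizes keep every check within minutes while leaving the estimators in
the regime where their sampling theory applies.
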