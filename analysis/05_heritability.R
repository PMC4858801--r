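#!/usr/bin/env Rscript
# Stage 5: variance components of ACC. Univariate animal model with sex
# and genomic inbreeding as fixed effects, additive genetic (pedigree NRM
# and GRM) and permanent-environment random effects; LRT for the additive
# term; bivariate male/female model for the cross-sex genetic correlation.
#
# The phenotype is the true simulated ACC of the genetics dataset: the
# mapping-stage validation established that detected ACC tracks truth with
# adjusted R^2 > 0.99 at array marker density, so the genetics dataset is
# simulated at association-scale density and analysed on the true counts.

suppressPackageStartupMessages(library(pedrecomb))

ped <- read_pedigree("results/data/genetics_pedigree.tsv")
panel <- read_genotypes_tsv("results/data/genetics")
truth <- as.data.frame(data.table::fread("results/data/genetics_truth.tsv"))

truth$parent <- as.character(truth$parent)
gen <- setNames(ped$generation, as.character(ped$id))
tr <- truth[gen[truth$parent] == 1, ]       # focal individuals with genotyped parents
fids <- sort(unique(tr$parent))

grm <- compute_grm(panel, ids = fids, drop_monomorphic = TRUE)
fhat <- attr(grm, "F_hat")
nrm <- pedigree_nrm(ped)[fids, fids]
fixed <- data.frame(sex = tr$parent_sex, fhat = fhat[tr$parent])

fitN <- fit_animal_model(tr$acc_true, tr$parent, fixed = fixed,
                         relationship = nrm, pe = TRUE)
fitG <- fit_animal_model(tr$acc_true, tr$parent, fixed = fixed,
                         relationship = grm, pe = TRUE)
red <- fit_animal_model(tr$acc_true, tr$parent, fixed = fixed,
                        relationship = NULL, pe = TRUE)
lrt <- lrt_random_effect(fitN, red)

message(sprintf("pedigree NRM: h2 = %.3f (SE %.3f), V_P = %.2f, P(h2) = %.2e",
                fitN$h2, fitN$h2_se, fitN$V_P, lrt$p))
message(sprintf("genomic GRM:  h2 = %.3f (SE %.3f), V_P = %.2f  (GRM at %d SNPs; marker-sampling noise attenuates)",
                fitG$h2, fitG$h2_se, fitG$V_P, attr(grm, "n_markers")))
sex_eff <- fitN$wald[fitN$wald$term == "sexM", ]
message(sprintf("male - female ACC: %.2f (SE %.2f) crossovers per gamete",
                sex_eff$estimate, sex_eff$se))

bt <- bivariate_acc_tests(tr$acc_true, tr$parent, tr$parent_sex, nrm)
message(sprintf("bivariate: V_A male %.2f, female %.2f; r_A = %.2f (SE %.2f)",
                bt$free$estimates$V_A_m, bt$free$estimates$V_A_f,
                bt$free$estimates$r_A, bt$free$estimates$r_A_se))
message(paste(capture.output(print(bt$tests, digits = 3)), collapse = "\n"))

comp <- rbind(cbind(matrix_ = "NRM", fitN$components),
              cbind(matrix_ = "GRM", fitG$components))
data.table::fwrite(comp, "results/variance_components.tsv", sep = "\t")
data.table::fwrite(bt$tests, "results/bivariate_tests.tsv", sep = "\t")
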