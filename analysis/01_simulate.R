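#!/usr/bin/env Rscript
# Stage 1 -- simulate the study population.
#
# Generates a synthetic herd with known ground truth: SNP genotypes in
# Hardy-Weinberg proportions, CH4 emissions (g/kg DMI) plus five heritable
# microbial-gene abundances genomically correlated with CH4, five
# non-heritable filler features, a cross-classified experiment x breed x diet
# design, and a compositional count table whose ALR transform recovers the
# latent traits. Everything downstream reads from results/data/.

library(rumenGS)

outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

n_traits <- 6                       # CH4 + 5 heritable microbial features
# single-factor genetic architecture: loadings on the CH4 genetic factor give
# a positive-semi-definite correlation matrix with the intended r_gCH4 values
loadings <- c(1, -0.90, -0.85, -0.80, 0.60, 0.00)
rg <- tcrossprod(loadings); diag(rg) <- 1

cfg <- sim_config(
  n_animals = 300, n_snps = 1000, n_traits = n_traits,
  h2_true = c(0.33, 0.50, 0.45, 0.40, 0.35, 0.13),
  rg_true = rg, seed = 20220412
)
herd <- simulate_herd(cfg, n_filler_features = 5)

write_genotypes_raw(herd$genotypes, outdir)
write_traits_tsv(herd$traits, file.path(outdir, "traits.tsv"))
write_abundance_tsv(herd$abundance, file.path(outdir, "abundance.tsv"))
write_ground_truth(herd$ground_truth, file.path(outdir, "ground_truth.txt"))

message(sprintf("simulated %d animals x %d SNPs; %d features at depths %s-%s",
                cfg$n_animals, cfg$n_snps, length(herd$abundance$feature_ids),
                format(cfg$depth_range[1], big.mark = ","),
                format(cfg$depth_range[2], big.mark = ",")))
message("true h2: ", paste(round(diag(cfg$G0_true) /
        (diag(cfg$G0_true) + diag(cfg$R0_true)), 2), collapse = " "))
message("wrote ", outdir)
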