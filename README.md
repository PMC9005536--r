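# rumenGS

Host-genomic analysis of rumen microbiome traits and microbiome-driven
genomic selection against methane emissions.

Cattle differ genetically in the rumen microbial community they host. When
the abundance of a microbial genus, metagenome-assembled genome (RUG) or
microbial KEGG-orthologue gene is heritable on the host side **and**
host-genomically correlated with methane output (CH4, g/kg dry-matter
intake), breeders can select low-emission animals from rumen metagenome
profiles alone — no respiration chambers required. `rumenGS` implements that
complete analysis chain for quantitative geneticists and microbiome
researchers, together with a ground-truth simulator that makes every stage
testable.

## What the package does

* **Compositional preparation** — relative abundances, core-feature
  filtering (present in all samples, mean RA > 0.001%), geometric
  Bayesian-multiplicative replacement of count zeros, additive and centred
  log-ratio transforms, and reference diagnostics (occupancy, log-ratio
  variance, Procrustes correlation against the full log-ratio geometry).
* **Genomics** — SNP QC (call rate >= 95%, Hardy-Weinberg chi-square
  p >= 1e-4, MAF >= 0.05, sample call rate >= 90%) and the VanRaden genomic
  relationship matrix `G = WW' / (2 sum p(1-p))`.
* **Bayesian GBLUP** — a Gibbs sampler for the animal model
  `y = Xb + Zg + e` with `g ~ N(0, G_RM sigma_g^2)` (univariate), its
  bivariate form `g ~ N(0, G_RM (x) G0)` for host-genomic correlations
  `r_g = G0[1,2]/sqrt(G0[1,1] G0[2,2])`, and multi-trait prediction with
  fixed (co)variances and missing records. Posterior medians, HPD95%
  intervals, P0 sign probabilities, Geweke Z, time-series Monte-Carlo SE,
  DIC model comparison (evidence when the genomic model wins by >= 20
  points) and Laplace-Metropolis Bayes factors corrected by prior odds
  1/n-tests (evidence when corrected BF > 3).
* **Selection machinery** — truncation selection intensities, the correlated
  response `R = i h_j r_g sigma_gCH4`, breeding-panel selection (occupancy,
  RA >= 0.01%, significant h2, P0 >= 0.95, cap 30), assembly of the
  (CH4 + panel) covariance matrices from pairwise bivariate fits with
  eigenvalue bending (tolerance 0.001), the three prediction scenarios
  (measured CH4 only / microbiome only with CH4 treated as missing / both),
  per-animal accuracies `sqrt(1 - sd_i^2/(g_ii sigma2))`, and
  response-to-selection posterior distributions at 1-50% selected.
* **Co-abundance network** — deregressed GEBVs, Pearson edges > 0.70,
  degree >= 2 filtering, kNN-ranked retention of 80% of edges, and Markov
  clustering (inflation 2, granularity 2).
* **Simulator** — genotypes in Hardy-Weinberg proportions, multi-trait
  genetic architectures on an experiment x breed x diet design, and
  compositional count tables (logistic-normal-multinomial with log-uniform
  sequencing depths and RUG-style zero inflation) whose ALR transform
  recovers the simulated heritable traits.

## Worked example

```r
library(rumenGS)

# a herd with known ground truth: CH4 (h2 = 0.33) plus one microbial trait
# (h2 = 0.40) host-genomically correlated with CH4 at r_g = -0.8
cfg <- sim_config(n_animals = 500, n_snps = 1000, n_traits = 2,
                  h2_true = c(0.33, 0.40), rg_true = -0.8, seed = 42)
herd <- simulate_traits(simulate_genotypes(cfg), cfg)
grm  <- herd$ground_truth$grm

fit <- fit_univariate(herd$traits$CH4, herd$traits$fixed, grm,
                      n_iter = 20000, burn_in = 4000, thin = 10, seed = 1)
heritability_from_samples(fit)
#> median 0.2502  HPD95% [0.0668, 0.4224]  P0 1.000  (n = 1600)

biv <- fit_bivariate(as.matrix(herd$traits[, c("CH4", "micro1")]),
                     herd$traits$fixed, grm,
                     n_iter = 20000, burn_in = 4000, thin = 10, seed = 2)
posterior_summary(biv$rg_samples)
#> median -0.8358  HPD95% [-0.9978, -0.5724]  P0 1.000  (n = 1600)

selection_intensity(c(0.30, 0.10, 0.01))
#> [1] 1.158975 1.754983 2.665214
```

The CH4 heritability comes back at 0.25 against the simulated 0.33, with an
HPD95% interval [0.07, 0.42] that shows the genuine uncertainty of a
500-animal design; the host-genomic correlation is recovered at -0.84
against the simulated -0.8 with P0 = 1, i.e. the sign is certain; and the
selection intensities are the analytic truncation values for selecting the
best 30/10/1% of the population.

## The analysis workflow

`analysis/` holds the study workflow as numbered, sequential scripts; each
reads its predecessors' outputs under `results/` (stage 1 and 2 outputs are
regenerated on the fly, so run the scripts in order):

```sh
Rscript analysis/01_simulate.R             # synthetic herd with ground truth
Rscript analysis/02_transform.R            # core filter, reference pick, ALR
Rscript analysis/03_genomic_parameters.R   # h2, DIC/BF gates, r_gCH4, P0
Rscript analysis/04_selection.R            # panel, bending, scenarios, response
Rscript analysis/05_network.R              # dGEBV co-abundance network + MCL
```

On the committed demo herd (300 animals, 1000 SNPs, 5 heritable microbial
features plus 5 non-heritable fillers), stage 3 estimates CH4 h2 at 0.35
(HPD95% [0.07, 0.60]), flags 3 microbial traits as significantly heritable
(both DIC and corrected-BF gates) and 4 as host-genomically correlated with
CH4 at P0 >= 0.95 — with no filler feature passing the combined gates. Stage
4 reproduces the study's central finding on synthetic data: mean prediction
accuracy for CH4 genomic values rises from 0.65 (measured CH4 only) to 0.81
(microbiome abundances only, CH4 treated as missing) and 0.88 (both
combined), and the response to selection grows with selection intensity
exactly along the breeder's equation. The methods vignette
(`vignettes/microbiome-driven-selection.Rmd`) documents the models, priors,
numerical choices and the simulator's assumptions.

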