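---
title: "Host-genomic analysis of rumen microbiome traits and microbiome-driven selection for methane"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host-genomic analysis of rumen microbiome traits and microbiome-driven selection for methane}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumenGS)
```

## The scientific problem

Ruminal methanogenesis is carried out by the microbial community of the
rumen, and part of the variation in that community is under control of the
host's genome. If the abundances of specific microbial genera, metagenome-
assembled genomes (RUGs) or microbial KEGG-orthologue genes are (i) heritable
on the host side and (ii) host-genomically correlated with methane output
(CH4, g/kg dry-matter intake), then selecting hosts on those microbial
abundances changes CH4 emissions without ever measuring CH4 in respiration
chambers. `rumenGS` implements the full chain of analyses needed to evaluate
that strategy: compositional preparation of metagenomic abundances, Bayesian
GBLUP estimation of genomic parameters, significance gates, correlated
response, multi-trait prediction scenarios, and a co-abundance network of
deregressed genomic effects — together with a simulator that generates all of
it with known ground truth.

## The models

**Univariate animal model.** For a phenotype vector $y$ (CH4 or one
log-ratio-transformed microbial abundance),

$$y = Xb + Zg + e, \qquad
  g \mid G_{RM}, \sigma_g^2 \sim N(0,\, G_{RM}\sigma_g^2), \qquad
  e \sim N(0,\, I\sigma_e^2),$$

where $b$ holds the combined experiment x breed x diet fixed effect and
$G_{RM} = W'W / (2\sum_n p_n(1-p_n))$ is the VanRaden genomic relationship
matrix with genotypes centred by twice the allele frequency. Genomic
heritability is $h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)$, computed per
posterior draw. Estimates are reported as the posterior median with the
shortest 95% interval (HPD95%), and classified lowly (< 0.20), moderately
(0.20–0.40) or highly (> 0.40) heritable.

**Bivariate model.** For CH4 paired with one microbial trait,
$g \sim N(0, G_{RM}\otimes G_0)$ and $e \sim N(0, I\otimes R_0)$ with 2 x 2
$G_0$, $R_0$. The host-genomic correlation is
$r_g = G_0[1,2]/\sqrt{G_0[1,1]\,G_0[2,2]}$ per draw; its confidence measure is
$P_0$, the posterior probability that $r_g$ shares the sign of its median,
with $P_0 \ge 0.95$ declaring significance.

**Significance of the genomic effect** combines two gates computed from the
full and reduced (no genetic effect) univariate models: the deviance
information criterion, significant when $\Delta DIC \le -20$, and a Bayes
factor from Laplace–Metropolis marginal-likelihood approximations, corrected
by prior odds $1/n_{tests}$ and significant when the corrected BF exceeds 3.
The exact marginal-likelihood approximation is an implementation choice (the
genetic effects are integrated out analytically through the GRM eigenbasis,
and the Laplace correction uses the posterior draws of $(b, \log\sigma_g^2,
\log\sigma_e^2)$); Bayes factors from different approximations need not agree
numerically, which is why the corrected-BF gate is always reported alongside
the DIC gate.

## Compositional preparation

Metagenomic abundances are relative by construction, so all genomic analyses
run on log-ratio coordinates.

* `relative_abundance()` closes each sample to one.
* `filter_core()` keeps genera/genes present in every sample with mean
  relative abundance above 0.001% (stored as the fraction `1e-5`; all RA
  thresholds in the package are fractions, never percentages, to remove a
  silent 100x error class). RUG coverages instead use an occupancy rule at a
  1x coverage cutoff.
* `gbm_zero_replace()` imputes count zeros Bayesian-multiplicatively: the
  posterior proportion of a zero cell under a Dirichlet prior replaces it,
  and non-zero parts are multiplicatively rescaled so each sample keeps its
  total and all ratios between originally non-zero parts. The prior is
  centred on the dataset-level geometric-mean composition with per-sample
  strength $s_i = \sqrt{n_i}$; both are explicit arguments. This is our
  parameterisation of the geometric Bayesian-multiplicative family — the
  constant is documented rather than hidden, and can be overridden.
* `alr_transform()` maps to $\ln(x_j/x_{ref})$, $j \ne ref$;
  `clr_transform()` centres each sample's log abundances on their log
  geometric mean (used for RUGs, where no single reference is present in all
  animals).

**Choosing the ALR reference.** `reference_diagnostics()` scores candidates
on occupancy, mean RA, log-ratio variance (summarised as the mean over
non-reference parts of the across-sample variance of $\ln(x_j/x_{cand})$ —
the aggregation is our convention, reported per candidate with its quartile),
and the Procrustes correlation between the sample configuration in the full
pairwise-log-ratio geometry and in the ALR(candidate) geometry. The full
geometry is computed through CLR coordinates, whose inter-sample Euclidean
distances equal the all-pairwise-log-ratio distances up to the constant
$\sqrt{J}$ — an exact identity, not an approximation. Procrustes alignment
(centring, orthogonal rotation, isotropic scaling) comes from `vegan`.

## The Gibbs sampler

One engine (`gibbs_gblup()`) drives the univariate, bivariate and multi-trait
fits. Its numerical structure:

* The GRM is blended with the identity, $G^* = 0.99\,G_{RM} + 0.01\,I$
  (configurable), and eigendecomposed once: $G^* = U D U'$. Writing $g = Ua$
  makes the rows of $a$ independent, $a_i \sim N(0, d_i G_0)$, and because
  $U$ is orthogonal the entire sampler runs in the eigenbasis without ever
  forming $g$ except at saving points.
* Within an iteration a simultaneous diagonalisation of $(R_0^{-1},
  G_0^{-1})$ renders the full conditional of the transformed genetic effects
  diagonal with precision $1 + \lambda_j / d_i$, so the draw vectorises
  across all animals and traits at once.
* Missing phenotypes are data-augmented from the conditional residual
  distribution of their missingness pattern. A trait missing in **every**
  record under fixed (co)variances (the microbiome-only prediction scenario)
  is handled differently: the observed sub-model is fitted and the phantom
  trait's genetic effects are reconstructed from the exact between-trait
  conditional $a_{i,mis} \mid a_{i,obs} \sim N(T a_{i,obs},\, d_i S_c)$.
  Besides being faster, this avoids a genuine impropriety: with a flat prior
  and no records, the phantom trait's fixed effects have no posterior.
* **Priors.** Fixed effects are flat. For the (co)variance components we use
  the flat improper limit of the scaled-inverse-chi-square / inverse-Wishart
  families, giving conditional posteriors with df $= n - t - 1$. The
  Jeffreys-type $\nu = 0$ alternative (density $|\Sigma|^{-(t+1)/2}$) puts
  non-integrable mass at singular matrices; in practice the chain then
  ratchets onto $\sigma_g^2 = 0$ or $|r_g| = 1$ and is numerically absorbed
  there. The flat prior keeps the boundary density finite and the chain
  mixes through it. A PSD projection guard (eigenvalue floor at
  $10^{-10}\times$ the largest eigenvalue, with a warning counter in
  `n_psd_projections`) protects against residual round-off.
* Inverse-Wishart draws use the Bartlett decomposition, which is positive
  definite by construction even for ill-conditioned scale matrices.
* Besides plain posterior means of the genomic values, the engine
  accumulates Rao-Blackwellised means (`gebv_mean_rb`): the conditional mean
  of the genetic effects at every post-burn-in sweep. With fixed variance
  components these converge to the mixed-model-equation solution orders of
  magnitude faster than the draw averages, which is what the oracle-
  equivalence tests check (agreement within `1e-3` at $n = 50$).
* Fixed-effect levels with fewer than two records are merged into the
  reference level with a warning.

Default desk-scale settings are 100,000 iterations, 20,000 burn-in, thinning
100; `paper_settings = TRUE` restores the full-length 1,000,000 / 200,000 /
100 chain. Convergence checks follow standard practice: `geweke_z()` (first
10% vs last 50%, AR-fit spectral variance) and `mcse_timeseries()`
(batch-means Monte-Carlo SE, with the ratio `sd/MCSE` reported against the
x10 rule). The Geweke statistic is reported on its natural N(0,1) scale.

## Selection machinery

* `selection_intensity(p)` is the infinite-population truncation intensity
  $\varphi(z_p)/p$; selecting the best 30/20/10/5/1% gives
  1.1590/1.400/1.755/2.063/2.665.
* `correlated_response()` evaluates, per posterior draw, $R = i\, h_j\, r_g\,
  \sigma_{gCH4}$ — the expected CH4 change per generation when selection acts
  on microbial trait $j$ (own-performance selection).
* `select_breeding_panel()` applies the panel gates (present in all animals,
  mean RA at or above 0.01%, significant $h^2$, $P_0 \ge 0.95$) and, when
  more candidates qualify than the cap (default 30), keeps the largest
  $|r_{gCH4}|$ first with higher $h^2$ breaking ties. The ranking rule is our
  choice and is recorded on the returned object.
* `assemble_covariance()` builds the (CH4 + panel) matrices from all pairwise
  bivariate fits: off-diagonals are pairwise posterior medians of the
  covariances; each diagonal is the mean over that trait's fits of its
  per-fit median variance (that mean rule is stated for CH4; we apply the
  same convention to the other traits, where the source is silent).
* `bend_matrix()` floors eigenvalues below the tolerance (default 0.001) and
  reconstructs; it is idempotent and logs the eigenvalue range and the
  maximum element change.
* `predict_scenarios()` runs multi-trait GBLUP with the bent matrices held
  fixed: scenario 1 uses measured CH4 only, scenario 2 treats every CH4
  record as missing and predicts from the microbial traits alone, scenario 3
  uses both. Per-animal accuracy is
  $\sqrt{1 - sd_i^2/(g_{RM,ii}\,\sigma^2_{CH4})}$, clipped at zero with a
  warning when round-off pushes the ratio above one.
* `response_to_selection()` selects, per retained draw and selected fraction,
  the `floor(p n)` animals with the lowest CH4 genomic value (ties broken by
  stable animal order) and reports `mean(all) - mean(selected)`. Because the
  breeding goal is CH4 *reduction*, responses are stored as positive
  reductions; the sign convention is deliberate and documented here.
  Percent-of-mean conversion requires an explicit CH4 mean — there is no
  default.
* `deregress_gebv()` divides each GEBV by its reliability (accuracy squared,
  floored at 0.01); the deregression formula is our documented choice, as
  the source analyses name only the software used.

## Co-abundance network

`build_graph()` connects microbial traits whose dGEBVs have Pearson
correlation strictly above 0.70 — the signed correlation by default (an
absolute-value mode exists), matching the stated "> 0.70" rule. Nodes with
degree below 2 are removed once, after thresholding (not iterated to a
2-core; `min_degree` can be reapplied by the caller who wants the core).
`prune_knn_edges()` lets each node mark its k = 10 strongest edges as
preferred, ranks edges by (preferred-by-both, preferred-by-one, weight,
stable order) and keeps the top 80% — the published tool's internal ranking
is not public, so this rule is ours and is rank-consistency-tested.
`mcl_cluster()` is a from-scratch Markov clustering: self-loops at each
node's maximum incident weight, column-stochastic normalisation, expansion
power 2, inflation 2, convergence when the maximum element change drops
below 1e-6 (cap 200 iterations), attractor-based cluster read-off, and
dissolution of clusters below the granularity (2 nodes).

## The simulator

`sim_config()` defaults are the study conditions: 359 animals, 36,780
autosomal SNPs, MAF in [0.05, 0.5], CH4 heritability 0.33, a host-genomic
correlation of -0.8 between CH4 and a microbial trait, a 2-experiment x
4-breed x 2-diet cross-classified design with diet the dominant effect, and
17.7% zero inflation for RUG-like coverages. Genotypes are independent SNPs
in Hardy-Weinberg proportions (no linkage disequilibrium — GRM-based
inference does not need it); breeding values are drawn from
$N(0, G_{RM}\otimes G_0)$ using the realized GRM; fixed effects are additive
shifts on the combined factor. Microbiome tables are generated as the
inverse of the ALR transform — a logistic-normal-multinomial model, which is
our modelling choice since the true abundance distribution is unknown —
with per-sample sequencing depths drawn log-uniformly (default 1e5 to 1e6
reads) to emulate heteroscedastic closure, and, in RUG mode, coverages
below 1 zeroed (one coverage unit per 1000 reads of depth) plus random
unobserved features.

What passing tests on these data do **not** show about real rumen data:
taxonomic assignment error, linkage disequilibrium and population structure,
overdispersion beyond the logistic-normal-multinomial, diet-by-genome
interactions, and laboratory batch effects are all absent from the
generator. Recovery results should be read as "the machinery is correct",
not "real data will estimate this precisely".

## Numerical choices and degenerate inputs

* GRM blending weight 0.01; stabilised matrix is always positive definite.
* All-zero samples are rejected by name; zero entries block log-ratio
  transforms with a pointer to `gbm_zero_replace()`.
* Bending tolerance 0.001 on the eigenvalue scale; asymmetric input errors.
* HWE test is the 1-df chi-square without continuity correction; monomorphic
  SNPs pass HWE (and are removed by the MAF filter).
* Missing genotypes are mean-imputed (2p) after QC, before GRM centring.
* Per-fit seeds in the pipeline derive deterministically from the master
  seed and the trait-pair label, so results are independent of execution
  order.

## Problem sizes used by the test suite

The replicated checks run at deliberately desk-scale sizes chosen as the
smallest that leave the properties clearly resolvable: heritability recovery
at n = 500 animals x 1000 SNPs with 20,000-iteration chains (20 replicates),
genomic-correlation recovery at n = 1000 (20 replicates), null calibrations
at n = 500, scenario comparisons at n = 250 with 11 traits (10 replicates),
and oracle equivalences at n = 30-50. A cross-check with maximum-likelihood
estimation on identical data shows the posterior median's replicate-level
standard deviation (~0.088 for h2 at these sizes) matches the likelihood
information bound, i.e. the spread in those suites is a property of the
design size, not of the sampler.

## Identification and attenuation caveats

Two empirical observations from the synthetic studies deserve emphasis.
First, with mutually unrelated animals the GRM's eigenvalue spread — the
source of information about $\sigma_g^2$ — shrinks as $n/m$ falls
(Marchenko–Pastur), and under the flat variance prior weakly identified
heritability posteriors are pulled upward. Real cattle populations derive
identification from family and breed structure that the independent-SNP
generator deliberately omits, so synthetic designs should keep $n/m$
moderate (the workflow uses 300 animals x 1000 SNPs). Second, correlations
between deregressed GEBVs attenuate roughly as
$r_g \times rel_j \times rel_k$; crossing the network's 0.70 edge threshold
therefore requires reliabilities near 0.85, beyond what an unrelated-animal
design of demonstration size can give. The network machinery is validated on
planted dGEBV block structure, while the workflow reports the (honestly
empty) thresholded graph for the demo herd.

## Known limitations

* Bayes-factor values depend on the marginal-likelihood approximation;
  only the gate (corrected BF > 3 together with the DIC rule) is intended to
  be portable.
* The deregression is a reliability division, not a full parent-average
  removal; with a GRM-only design and own-performance records this is the
  natural reduction, but dGEBVs from pedigree-based pipelines would differ.
* The MCL implementation targets the published algorithm's defaults; cluster
  boundaries on weakly modular graphs can differ from other MCL codes in
  ties.
* No REML engine is provided; the Bayesian fits are the single estimation
  path.
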