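# Synthetic-data generator: genotypes in Hardy-Weinberg proportions,
# multi-trait genetic architectures on a cross-classified fixed-effect
# design, and compositional microbiome count tables with known ground truth.

#' Build a genetic (co)variance pair from heritabilities and correlations
#'
#' Convenience constructor: with unit phenotypic variances,
#' `G0[i,j] = rg[i,j] * sqrt(h2_i h2_j)` and `R0 = diag(1 - h2)` (optionally
#' with residual correlations).
#'
#' @param h2 vector of per-trait heritabilities in (0, 1).
#' @param rg genetic correlation matrix (or scalar for 2 traits).
#' @param re residual correlation matrix (default: identity).
#' @return list with `G0` and `R0`.
#' @export
make_covariances <- function(h2, rg = NULL, re = NULL) {
  t <- length(h2)
  if (any(h2 < 0 | h2 >= 1)) stop("h2 must be in [0, 1)")
  if (is.null(rg)) rg <- diag(t)
  if (length(rg) == 1L && t == 2L) rg <- matrix(c(1, rg, rg, 1), 2)
  if (is.null(re)) re <- diag(t)
  G0 <- rg * tcrossprod(sqrt(h2))
  R0 <- re * tcrossprod(sqrt(1 - h2))
  list(G0 = G0, R0 = R0)
}

#' Simulation configuration
#'
#' Study-condition defaults: 359 animals (the study's metagenomics
#' population), 36,780 autosomal SNPs (its post-QC marker count), MAF in
#' [0.05, 0.5], two traits (trait 1 = CH4 in g/kg DMI, h2 = 0.33) with a
#' host-genomic correlation of -0.8, a 2-experiment x 4-breed x 2-diet fixed
#' design with diet the dominant effect, log-uniform sequencing depths, and
#' 17.7% zero inflation for RUG-like coverages.
#'
#' @param n_animals,n_snps population and marker-panel size.
#' @param maf_range allele-frequency interval, inside [0, 0.5].
#' @param n_traits number of traits (trait 1 = CH4).
#' @param h2_true per-trait heritabilities (used when `G0_true` not given).
#' @param rg_true genetic correlation (scalar for 2 traits, or matrix).
#' @param G0_true,R0_true explicit t x t (co)variance matrices; override
#'   `h2_true` / `rg_true`.
#' @param fixed_design named list of per-factor level-effect vectors
#'   (additive shifts on trait 1's scale; applied to every trait).
#' @param depth_range sequencing-depth interval (reads per sample).
#' @param zero_inflation probability a RUG-like feature is unobserved.
#' @param seed integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_animals = 359, n_snps = 36780,
                       maf_range = c(0.05, 0.5), n_traits = 2,
                       h2_true = rep(0.33, n_traits), rg_true = -0.8,
                       G0_true = NULL, R0_true = NULL,
                       fixed_design = list(
                         experiment = c(0, 0.4),
                         breed = c(0, 0.2, -0.2, 0.1),
                         diet = c(0, 0.8)),
                       depth_range = c(1e5, 1e6),
                       zero_inflation = 0.177, seed = NULL) {
  if (n_animals < 2 || n_snps < 1) stop("need >= 2 animals and >= 1 SNP")
  if (length(maf_range) != 2 || any(maf_range < 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an interval within [0, 0.5]")
  if (n_traits < 1) stop("n_traits must be >= 1")
  if (is.null(G0_true) || is.null(R0_true)) {
    cv <- make_covariances(h2_true,
                           if (n_traits > 1) rg_true else NULL)
    G0_true <- G0_true %||% cv$G0
    R0_true <- R0_true %||% cv$R0
  }
  G0_true <- as.matrix(G0_true); R0_true <- as.matrix(R0_true)
  stop_if_not_symmetric(G0_true, name = "G0_true")
  stop_if_not_symmetric(R0_true, name = "R0_true")
  if (!is_psd(G0_true) || !is_psd(R0_true))
    stop("G0_true and R0_true must be positive semi-definite")
  if (nrow(G0_true) != n_traits || nrow(R0_true) != n_traits)
    stop("covariance matrices must be n_traits x n_traits")
  if (any(depth_range <= 0)) stop("sequencing depths must be positive")
  if (zero_inflation < 0 || zero_inflation >= 1)
    stop("zero_inflation must be in [0, 1)")
  structure(list(n_animals = n_animals, n_snps = n_snps,
                 maf_range = maf_range, n_traits = n_traits,
                 G0_true = G0_true, R0_true = R0_true,
                 fixed_design = fixed_design, depth_range = depth_range,
                 zero_inflation = zero_inflation, seed = seed),
            class = "sim_config")
}

#' Simulate SNP genotypes in Hardy-Weinberg proportions
#'
#' Per-SNP allele frequencies are drawn uniformly from `maf_range`; genotypes
#' are `Binomial(2, p)` per animal (independent SNPs). Chromosome labels cycle
#' over 29 autosomes.
#'
#' @param config a [sim_config()].
#' @return a [genotype_matrix()] with attribute `"true_freq"`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  p <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])
  x <- matrix(stats::rbinom(config$n_animals * config$n_snps, 2,
                            rep(p, each = config$n_animals)),
              config$n_animals, config$n_snps)
  map <- data.frame(snp = paste0("snp", seq_len(config$n_snps)),
                    chr = as.character(rep_len(1:29, config$n_snps)),
                    pos = seq_len(config$n_snps) * 1000L)
  g <- genotype_matrix(x, animal_ids = paste0("A", seq_len(config$n_animals)),
                       snp_ids = map$snp, map = map)
  attr(g, "true_freq") <- p
  g
}

#' Simulate multi-trait phenotypes with known genetic architecture
#'
#' True breeding values are drawn from `N(0, G_RM (x) G0_true)` using the
#' genotypes' own GRM; residuals are iid per animal with covariance
#' `R0_true`; fixed effects are additive shifts on the cross-classified
#' experiment x breed x diet design; `y = Xb + g + e`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param config a [sim_config()].
#' @return list with `traits` (data.frame: `animal`, one column per trait
#'   (CH4 first), the design factors and the combined `fixed` factor) and
#'   `ground_truth` (list: `g_true`, `b_true`, `h2_true`, `rg_true`,
#'   `G0_true`, `R0_true`, `grm`).
#' @export
simulate_traits <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "sim_config"))
  n <- nrow(genotypes$values)
  t <- config$n_traits
  grm <- build_grm(genotypes)
  eg <- eigen(grm$matrix, symmetric = TRUE)
  rootG <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  cG0 <- if (all(config$G0_true == 0)) matrix(0, t, t) else {
    e0 <- eigen(config$G0_true, symmetric = TRUE)
    e0$vectors %*% (sqrt(pmax(e0$values, 0)) * t(e0$vectors))
  }
  g_true <- rootG %*% matrix(stats::rnorm(n * t), n, t) %*% cG0
  eR <- eigen(config$R0_true, symmetric = TRUE)
  cR0 <- eR$vectors %*% (sqrt(pmax(eR$values, 0)) * t(eR$vectors))
  e <- matrix(stats::rnorm(n * t), n, t) %*% cR0
  fd <- config$fixed_design
  lv <- lapply(fd, function(eff) sample(seq_along(eff), n, replace = TRUE))
  shift <- rowSums(vapply(names(fd), function(f) fd[[f]][lv[[f]]], numeric(n)))
  y <- shift + g_true + e
  trait_names <- c("CH4", if (t > 1) paste0("micro", seq_len(t - 1)))
  colnames(y) <- trait_names
  colnames(g_true) <- trait_names
  factors <- lapply(names(fd), function(f)
    factor(paste0(substr(f, 1, 1), lv[[f]])))
  names(factors) <- names(fd)
  combined <- droplevels(interaction(factors, drop = TRUE))
  traits <- data.frame(animal = genotypes$animal_ids, y, factors,
                       fixed = combined, stringsAsFactors = FALSE)
  h2_true <- diag(config$G0_true) / (diag(config$G0_true) + diag(config$R0_true))
  dcov <- sqrt(diag(config$G0_true))
  rg_true <- if (all(dcov > 0)) config$G0_true / tcrossprod(dcov) else
    diag(t)
  list(traits = traits,
       ground_truth = list(g_true = g_true, b_true = fd, h2_true = h2_true,
                           rg_true = rg_true, G0_true = config$G0_true,
                           R0_true = config$R0_true, grm = grm))
}

#' Simulate compositional microbiome counts from latent log-ratios
#'
#' The generative inverse of the additive log-ratio transform: per sample the
#' latent ALR coordinates are mapped to proportions (exponentiate, append the
#' reference, close to one) and counts are drawn multinomially at a
#' log-uniform sequencing depth from `depth_range`. In RUG mode the counts
#' are rescaled to coverage-like values (one coverage unit per 1000 reads of
#' depth), coverages below 1 are zeroed, and features are additionally
#' unobserved with probability `zero_inflation`.
#'
#' @param latent_alr n x (J-1) matrix of latent ALR values.
#' @param config a [sim_config()] (depths, zero inflation).
#' @param mode `"gene"`, `"genus"` (counts) or `"rug"` (coverages).
#' @param reference_id name of the appended reference feature.
#' @return an [abundance_table()]; attribute `"depths"` holds the drawn
#'   per-sample depths.
#' @export
simulate_microbiome_counts <- function(latent_alr, config,
                                       mode = c("gene", "genus", "rug"),
                                       reference_id = "ref") {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "sim_config"))
  latent_alr <- as.matrix(latent_alr)
  if (any(!is.finite(latent_alr))) stop("latent ALR values must be finite")
  if (any(config$depth_range <= 0)) stop("sequencing depths must be positive")
  n <- nrow(latent_alr)
  if (is.null(colnames(latent_alr)))
    colnames(latent_alr) <- paste0("feat", seq_len(ncol(latent_alr)))
  props <- inverse_alr(latent_alr, reference_id = reference_id)
  depths <- round(exp(stats::runif(n, log(config$depth_range[1]),
                                   log(config$depth_range[2]))))
  counts <- t(vapply(seq_len(n), function(i)
    as.numeric(stats::rmultinom(1, depths[i], props[i, ])),
    numeric(ncol(props))))
  dimnames(counts) <- list(paste0("S", seq_len(n)), colnames(props))
  if (mode == "rug") {
    cov_mat <- counts / (depths / 1000)          # one coverage unit / 1000 reads
    cov_mat[cov_mat < 1] <- 0
    if (config$zero_inflation > 0) {
      drop <- matrix(stats::runif(length(cov_mat)) < config$zero_inflation,
                     nrow(cov_mat))
      cov_mat[drop] <- 0
    }
    out <- abundance_table(cov_mat, feature_class = "RUG")
  } else {
    out <- abundance_table(counts,
                           feature_class = if (mode == "genus") "genus" else "gene")
  }
  attr(out, "depths") <- depths
  out
}

#' Simulate a full synthetic herd
#'
#' Genotypes, multi-trait phenotypes (CH4 first) and a microbiome count table
#' whose ALR-transform recovers the simulated heritable microbial traits
#' (each latent microbial trait becomes one ALR coordinate; extra
#' non-heritable filler features are appended).
#'
#' @param config a [sim_config()].
#' @param n_filler_features extra compositional features with non-heritable
#'   latent variation (default 5).
#' @return list: `genotypes`, `traits`, `ground_truth`, `abundance`
#'   (an [abundance_table()]), `reference_id`.
#' @export
simulate_herd <- function(config, n_filler_features = 5) {
  stopifnot(inherits(config, "sim_config"))
  geno <- simulate_genotypes(config)
  sim <- simulate_traits(geno, config)
  n <- config$n_animals
  micro <- as.matrix(sim$traits[, grep("^micro", names(sim$traits)),
                                drop = FALSE])
  filler <- matrix(stats::rnorm(n * n_filler_features, sd = 0.5), n,
                   dimnames = list(NULL, paste0("filler", seq_len(n_filler_features))))
  latent <- cbind(micro, filler)
  ab <- simulate_microbiome_counts(latent, config, mode = "gene")
  c(list(genotypes = geno, abundance = ab, reference_id = "ref"), sim)
}
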