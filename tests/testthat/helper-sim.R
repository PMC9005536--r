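# shared fixture builders (all generated in code, nothing on disk)

# small herd with one or more traits; returns traits + ground truth + grm
quick_herd <- function(n = 120, m = 300, h2 = 0.4, rg = NULL, seed = 1) {
  t <- length(h2)
  cfg <- sim_config(n_animals = n, n_snps = m, n_traits = t, h2_true = h2,
                    rg_true = rg, seed = seed)
  g <- simulate_genotypes(cfg)
  st <- simulate_traits(g, cfg)
  c(st, list(genotypes = g, config = cfg, grm = st$ground_truth$grm))
}

# columns with an exact target correlation, for threshold-semantics tests
exact_cor_pair <- function(n, rho, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n); z <- stats::rnorm(n)
  x <- (x - mean(x)) / stats::sd(x)
  z <- stats::residuals(stats::lm(z ~ x))
  z <- (z - mean(z)) / stats::sd(z)
  cbind(a = x, b = rho * x + sqrt(1 - rho^2) * z)
}

# minimal mcmc_fit stub with prescribed GEBV summaries / draws
fake_fit <- function(gebv_mean, gebv_sd, sigma2_g = 1,
                     gebv_draws = NULL, trait_names = "trait1") {
  n <- length(gebv_mean)
  ns <- if (is.null(gebv_draws)) 200L else nrow(gebv_draws)
  samples <- cbind(G_1_1 = rep(sigma2_g, ns), R_1_1 = rep(1, ns))
  structure(list(
    samples = samples,
    gebv_mean = matrix(gebv_mean, n, 1),
    gebv_sd = matrix(gebv_sd, n, 1),
    gebv = stats::setNames(list(if (is.null(gebv_draws))
      matrix(rep(gebv_mean, each = ns), ns, n) else gebv_draws), trait_names),
    trait_names = trait_names, n_traits = 1L, n = n, n_saved = ns,
    include_genetic = TRUE
  ), class = "mcmc_fit")
}
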