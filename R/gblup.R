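# User-facing model fits, convergence diagnostics, model comparison and
# GEBV post-processing.

# Build a fixed-effect design matrix from a factor / data.frame / matrix,
# merging factor levels with fewer than 2 records into the reference level.
fixed_design_matrix <- function(fixed, n) {
  if (is.null(fixed)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  if (is.matrix(fixed)) {
    if (nrow(fixed) != n) stop("fixed-effect matrix has wrong number of rows")
    return(fixed)
  }
  f <- droplevels(as.factor(fixed))
  if (length(f) != n) stop("fixed-effect factor has wrong length")
  tab <- table(f)
  rare <- names(tab)[tab < 2]
  if (length(rare)) {
    warning("fixed-effect level(s) with < 2 records merged into the reference: ",
            paste(rare, collapse = ", "))
    levels(f)[levels(f) %in% rare] <- levels(f)[1L]
    f <- droplevels(f)
  }
  stats::model.matrix(~f)
}

mcmc_settings <- function(n_iter, burn_in, thin, paper_settings) {
  if (isTRUE(paper_settings)) list(n_iter = 1000000L, burn_in = 200000L, thin = 100L)
  else list(n_iter = n_iter, burn_in = burn_in, thin = thin)
}

#' Univariate GBLUP animal model via Gibbs sampling
#'
#' Fits `y = Xb + g + e` with `g ~ N(0, G_RM sigma_g^2)` and
#' `e ~ N(0, I sigma_e^2)`; flat prior on `b` and flat improper priors on the
#' variances (see [gibbs_gblup()]). Defaults are
#' desk-scale MCMC settings; `paper_settings = TRUE` restores the full-length
#' chain (1,000,000 iterations, 200,000 burn-in, thinning 100).
#'
#' @param y numeric phenotype vector (NA allowed).
#' @param fixed combined fixed-effect factor (e.g. experiment x breed x diet),
#'   a design matrix, or `NULL` for intercept only.
#' @param grm a [build_grm()] object or symmetric matrix.
#' @param n_iter,burn_in,thin MCMC settings (defaults 100000 / 20000 / 100).
#' @param seed integer seed.
#' @param paper_settings use the full-length chain settings.
#' @param blend GRM identity blending weight.
#' @param sigma2_g,sigma2_e optionally hold a variance fixed.
#' @return an `mcmc_fit` (see [gibbs_gblup()]).
#' @export
fit_univariate <- function(y, fixed = NULL, grm, n_iter = 100000,
                           burn_in = 20000, thin = 100, seed = NULL,
                           paper_settings = FALSE, blend = 0.01,
                           sigma2_g = NULL, sigma2_e = NULL) {
  y <- as.numeric(y)
  s <- mcmc_settings(n_iter, burn_in, thin, paper_settings)
  X <- fixed_design_matrix(fixed, length(y))
  gibbs_gblup(matrix(y, dimnames = list(NULL, "trait1")), X, grm,
              n_iter = s$n_iter, burn_in = s$burn_in, thin = s$thin,
              seed = seed, blend = blend,
              G0_fixed = if (!is.null(sigma2_g)) matrix(sigma2_g),
              R0_fixed = if (!is.null(sigma2_e)) matrix(sigma2_e))
}

#' Reduced model without the host-genomic effect
#'
#' Fits `y = Xb + e` only; the comparison model for [dic_compare()] and
#' [bayes_factor()].
#'
#' @inheritParams fit_univariate
#' @return an `mcmc_fit` with `include_genetic = FALSE`.
#' @export
fit_null <- function(y, fixed = NULL, n_iter = 100000, burn_in = 20000,
                     thin = 100, seed = NULL, paper_settings = FALSE) {
  y <- as.numeric(y)
  s <- mcmc_settings(n_iter, burn_in, thin, paper_settings)
  X <- fixed_design_matrix(fixed, length(y))
  gibbs_gblup(matrix(y, dimnames = list(NULL, "trait1")), X, grm = NULL,
              n_iter = s$n_iter, burn_in = s$burn_in, thin = s$thin,
              seed = seed, include_genetic = FALSE)
}

#' Bivariate GBLUP animal model via Gibbs sampling
#'
#' Two-trait animal model with genetic covariance `G_RM (x) G0` and residual
#' `I (x) R0` (2 x 2 inverse-Wishart full conditionals); per-trait missing
#' records handled by data augmentation. The host-genomic correlation is
#' computed per retained draw as `G0[1,2] / sqrt(G0[1,1] G0[2,2])`.
#'
#' @param Y n x 2 matrix of phenotypes (NA allowed).
#' @inheritParams fit_univariate
#' @return an `mcmc_fit` with an extra element `rg_samples`.
#' @export
fit_bivariate <- function(Y, fixed = NULL, grm, n_iter = 100000,
                          burn_in = 20000, thin = 100, seed = NULL,
                          paper_settings = FALSE, blend = 0.01) {
  Y <- as.matrix(Y)
  if (ncol(Y) != 2L) stop("Y must have exactly 2 trait columns")
  s <- mcmc_settings(n_iter, burn_in, thin, paper_settings)
  X <- fixed_design_matrix(fixed, nrow(Y))
  fit <- gibbs_gblup(Y, X, grm, n_iter = s$n_iter, burn_in = s$burn_in,
                     thin = s$thin, seed = seed, blend = blend)
  fit$rg_samples <- rg_from_fit(fit)
  fit
}

#' Multi-trait GBLUP with fixed (co)variance components
#'
#' Gibbs sampling over the location parameters (fixed effects, genetic
#' effects, missing records) with `G0` and `R0` held fixed — the machinery of
#' the genomic-prediction scenarios, which assume the previously estimated and
#' bent (co)variance matrices.
#'
#' @param Y n x t phenotype matrix (NA = missing record).
#' @param G0,R0 fixed t x t genetic and residual (co)variance matrices.
#' @param store_traits trait indices whose genetic-effect draws are retained.
#' @inheritParams fit_univariate
#' @return an `mcmc_fit`.
#' @export
fit_multitrait <- function(Y, fixed = NULL, grm, G0, R0, n_iter = 20000,
                           burn_in = 4000, thin = 20, seed = NULL,
                           blend = 0.01, store_traits = 1L) {
  Y <- as.matrix(Y)
  stop_if_not_symmetric(as.matrix(G0), name = "G0")
  stop_if_not_symmetric(as.matrix(R0), name = "R0")
  X <- fixed_design_matrix(fixed, nrow(Y))
  gibbs_gblup(Y, X, grm, n_iter = n_iter, burn_in = burn_in, thin = thin,
              seed = seed, blend = blend, G0_fixed = as.matrix(G0),
              R0_fixed = as.matrix(R0), store_traits = store_traits)
}

# per-draw genetic correlation between two traits of a fit
rg_from_fit <- function(fit, i = 1L, j = 2L) {
  s <- fit$samples
  lo <- min(i, j); hi <- max(i, j)
  s[, sprintf("G_%d_%d", lo, hi)] /
    sqrt(s[, sprintf("G_%d_%d", i, i)] * s[, sprintf("G_%d_%d", j, j)])
}

#' Posterior summary of a fitted parameter
#'
#' Convenience access to [posterior_summary()] for named parameters of an
#' `mcmc_fit`: any (co)variance column (e.g. `"G_1_1"`), `"h2"` (per-draw
#' `sigma_g^2 / (sigma_g^2 + sigma_e^2)` for a trait) or `"rg"` (per-draw
#' genetic correlation between traits 1 and 2).
#'
#' @param fit an `mcmc_fit`.
#' @param parameter parameter name as above.
#' @param trait trait index for `"h2"`.
#' @return a [posterior_summary()].
#' @export
summarize_fit <- function(fit, parameter, trait = 1L) {
  stopifnot(inherits(fit, "mcmc_fit"))
  x <- if (parameter == "h2") h2_samples(fit, trait)
       else if (parameter == "rg") rg_from_fit(fit)
       else if (parameter %in% colnames(fit$samples)) fit$samples[, parameter]
       else stop("unknown parameter '", parameter, "'")
  posterior_summary(x)
}

h2_samples <- function(fit, trait = 1L) {
  sg <- fit$samples[, sprintf("G_%d_%d", trait, trait)]
  se <- fit$samples[, sprintf("R_%d_%d", trait, trait)]
  sg / (sg + se)
}

#' Genomic heritability from posterior samples
#'
#' Per-draw `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)`, summarised as median,
#' HPD95% and P0, and classified on the study's bands: lowly (< 0.20),
#' moderately (0.20-0.40) or highly (> 0.40) heritable.
#'
#' @param fit an `mcmc_fit` with a genetic component.
#' @param trait trait index.
#' @return a [posterior_summary()] with extra fields `samples` and `class`.
#' @export
heritability_from_samples <- function(fit, trait = 1L) {
  h2 <- h2_samples(fit, trait)
  out <- posterior_summary(h2)
  out$samples <- h2
  out$class <- classify_h2(out$median)
  out
}

#' @rdname heritability_from_samples
#' @param h2 a heritability value.
#' @export
classify_h2 <- function(h2) {
  ifelse(h2 < 0.20, "lowly heritable",
         ifelse(h2 > 0.40, "highly heritable", "moderately heritable"))
}

#' Geweke convergence Z score
#'
#' Compares the mean of the first `frac1` of a chain with the mean of the
#' last `frac2`, using spectral-density-at-zero variance estimates (AR-fit
#' estimator), as a stationarity check.
#'
#' @param chain numeric vector of >= 100 MCMC samples.
#' @param frac1,frac2 fractions of the chain compared (defaults 0.1 and 0.5).
#' @return Z statistic (approximately N(0,1) under stationarity); `NaN` with a
#'   warning for a constant chain.
#' @export
geweke_z <- function(chain, frac1 = 0.1, frac2 = 0.5) {
  chain <- as.numeric(chain)
  n <- length(chain)
  if (n < 100L) stop("chain too short (< 100)")
  if (stats::var(chain) == 0) {
    warning("constant chain: Geweke Z undefined")
    return(NaN)
  }
  x1 <- chain[seq_len(floor(frac1 * n))]
  x2 <- chain[(n - floor(frac2 * n) + 1L):n]
  (mean(x1) - mean(x2)) / sqrt(spectrum0_ar(x1) / length(x1) +
                               spectrum0_ar(x2) / length(x2))
}

# spectral density at frequency zero via an AR fit
spectrum0_ar <- function(x) {
  x <- as.numeric(x)
  if (stats::var(x) == 0) return(0)
  fit <- stats::ar(x, aic = TRUE)
  if (!length(fit$ar)) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Time-series Monte-Carlo standard error
#'
#' Batch-means MCSE of a chain's mean, plus the ratio `sd(chain) / MCSE`
#' checked against the study's rule that the Monte-Carlo error be at least
#' 10 times smaller than the posterior standard deviation.
#'
#' @param chain numeric vector of >= 100 MCMC samples.
#' @param n_batches number of batches (default ~ sqrt(length)).
#' @return list with `mcse`, `ratio` (`sd / mcse`; `NA` for a constant chain)
#'   and `constant` flag.
#' @export
mcse_timeseries <- function(chain, n_batches = NULL) {
  chain <- as.numeric(chain)
  n <- length(chain)
  if (n < 100L) stop("chain too short (< 100)")
  if (stats::var(chain) == 0)
    return(list(mcse = 0, ratio = NA_real_, constant = TRUE))
  nb <- n_batches %||% floor(sqrt(n))
  m <- floor(n / nb)
  bm <- vapply(seq_len(nb), function(b) mean(chain[((b - 1) * m + 1):(b * m)]),
               numeric(1))
  mcse <- stats::sd(bm) / sqrt(nb)
  list(mcse = mcse, ratio = stats::sd(chain) / mcse, constant = FALSE)
}

#' Deviance information criterion of a fit
#'
#' `DIC = Dbar + pD` with `pD = Dbar - D(theta_bar)`, where `Dbar` is the
#' posterior mean deviance and `D(theta_bar)` the deviance at the posterior
#' means of the location and residual parameters.
#'
#' @param fit an `mcmc_fit`.
#' @return list with `dic`, `dbar`, `pd`.
#' @export
dic_value <- function(fit) {
  stopifnot(inherits(fit, "mcmc_fit"))
  dbar <- mean(fit$deviance)
  pd <- dbar - fit$dev_at_mean
  list(dic = dbar + pd, dbar = dbar, pd = pd)
}

#' DIC comparison of the genomic model against the reduced model
#'
#' Evidence of a host-genomic effect is declared when the DIC of the full
#' model is at least 20 points lower than that of the reduced
#' (no-genetic-effect) model.
#'
#' @param fit_full,fit_reduced `mcmc_fit`s on identical data.
#' @param delta_threshold significance threshold on `dic_full - dic_reduced`
#'   (default -20).
#' @return list with `dic_full`, `dic_reduced`, `delta`, `significant`.
#' @export
dic_compare <- function(fit_full, fit_reduced, delta_threshold = -20) {
  if (max(abs(fit_full$data_checksum - fit_reduced$data_checksum)) > 1e-6)
    stop("fits are not on identical data")
  df <- dic_value(fit_full); dr <- dic_value(fit_reduced)
  delta <- df$dic - dr$dic
  list(dic_full = df$dic, dic_reduced = dr$dic, delta = delta,
       significant = delta <= delta_threshold)
}

#' Laplace-Metropolis estimate of a log marginal likelihood
#'
#' `log mL ~= (P/2) log(2 pi) + 0.5 log|Sigma_hat| + log post(theta*)`, with
#' `Sigma_hat` the covariance of the posterior draws and `theta*` the draw
#' maximising the (unnormalised) log posterior.
#'
#' @param draws matrix of posterior draws (rows = draws).
#' @param log_post function of a parameter vector returning the log of the
#'   unnormalised posterior (log-likelihood + log-prior).
#' @return the estimated log marginal likelihood.
#' @export
laplace_metropolis_logml <- function(draws, log_post) {
  draws <- as.matrix(draws)
  lp <- apply(draws, 1, log_post)
  sig <- stats::cov(draws)
  ld <- tryCatch(2 * sum(log(diag(chol(sig)))), error = function(e) NA_real_)
  if (is.na(ld)) {
    warning("degenerate posterior covariance; falling back to its diagonal")
    ld <- sum(log(pmax(diag(sig), .Machine$double.eps)))
  }
  0.5 * ncol(draws) * log(2 * pi) + 0.5 * ld + max(lp)
}

#' Bayes factor for the host-genomic effect, with prior-odds correction
#'
#' Approximates the marginal likelihoods of the full (genomic) and reduced
#' univariate models by Laplace-Metropolis over `(b, log variance
#' components)`, with the genetic effects integrated out analytically through
#' the GRM eigendecomposition, and corrects the Bayes factor for multiple
#' testing by prior odds `1 / n_tests` (the study used n = 2473; evidence is
#' declared when the corrected BF exceeds 3).
#'
#' @param fit_full univariate `mcmc_fit` with genetic effect (complete records).
#' @param fit_reduced matching [fit_null()] fit.
#' @param n_tests number of hypothesis tests performed.
#' @return list with `bf_raw`, `bf_corrected`, `log_ml_full`,
#'   `log_ml_reduced`, `significant` (`bf_corrected > 3`).
#' @export
bayes_factor <- function(fit_full, fit_reduced, n_tests = 2473) {
  if (is.null(fit_full$eigen_data))
    stop("Bayes factor needs a univariate full fit without missing records")
  if (max(abs(fit_full$data_checksum - fit_reduced$data_checksum)) > 1e-6)
    stop("fits are not on identical data")
  ed <- fit_full$eigen_data
  p <- ncol(ed$UtX)
  # integrated likelihood of the full model: y | b, sg2, se2 ~ N(Xb, G* sg2 + I se2)
  ll_full <- function(theta) {
    b <- theta[seq_len(p)]
    v <- ed$d * exp(theta[p + 1]) + exp(theta[p + 2])
    r <- ed$Uty - ed$UtX %*% b
    -0.5 * sum(log(2 * pi * v) + r^2 / v)
  }
  draws_full <- cbind(fit_full$b_samples,
                      log(fit_full$samples[, "G_1_1"]),
                      log(fit_full$samples[, "R_1_1"]))
  y <- fit_reduced$raw_data$y; X <- fit_reduced$raw_data$X
  ll_red <- function(theta) {
    b <- theta[seq_len(ncol(X))]
    v <- exp(theta[ncol(X) + 1])
    r <- y - X %*% b
    -0.5 * sum(log(2 * pi * v) + r^2 / v)
  }
  draws_red <- cbind(fit_reduced$b_samples, log(fit_reduced$samples[, "R_1_1"]))
  lml_f <- laplace_metropolis_logml(draws_full, ll_full)
  lml_r <- laplace_metropolis_logml(draws_red, ll_red)
  bf <- exp(lml_f - lml_r)
  list(bf_raw = bf, bf_corrected = bf / n_tests, log_ml_full = lml_f,
       log_ml_reduced = lml_r, significant = (bf / n_tests) > 3)
}

#' Deregressed genomic estimated breeding values
#'
#' `dGEBV_i = GEBV_i / r_i^2`, with reliability `r_i^2` the squared
#' per-animal accuracy `sqrt(1 - sd_i^2 / (g_RMii sigma_g^2))`. Animals with
#' reliability below `reliability_floor` are excluded (`NA`) and flagged.
#'
#' @param fit an `mcmc_fit` with a genetic component.
#' @param grm the [build_grm()] used in the fit.
#' @param trait trait index.
#' @param sigma2_g genomic variance; default: posterior median of the trait's
#'   genetic variance in `fit`.
#' @param reliability_floor minimum reliability (default 0.01).
#' @return numeric vector of dGEBVs (`NA` where excluded), with attribute
#'   `"excluded"` giving the excluded indices.
#' @export
deregress_gebv <- function(fit, grm, trait = 1L, sigma2_g = NULL,
                           reliability_floor = 0.01) {
  stopifnot(inherits(fit, "mcmc_fit"))
  gd <- if (inherits(grm, "grm")) diag(grm$matrix) else diag(as.matrix(grm))
  sigma2_g <- sigma2_g %||%
    stats::median(fit$samples[, sprintf("G_%d_%d", trait, trait)])
  acc <- accuracy(fit$gebv_sd[, trait], gd, sigma2_g)
  rel <- acc^2
  excl <- which(rel < reliability_floor)
  if (length(excl))
    warning(length(excl), " animal(s) below the reliability floor excluded")
  out <- fit$gebv_mean[, trait] / rel
  out[excl] <- NA_real_
  attr(out, "excluded") <- excl
  out
}

#' Per-group posterior distributions of the genomic variance
#'
#' For each retained MCMC draw, the empirical variance of the sampled genetic
#' effects within each group (e.g. breed or diet), giving per-group marginal
#' posterior distributions of the genomic variance in the spirit of the
#' variance-partition approach of Sorensen and colleagues.
#'
#' @param fit an `mcmc_fit` storing genetic-effect draws for `trait`.
#' @param groups factor of length n assigning animals to groups.
#' @param trait trait index (must be among the fit's stored traits).
#' @return list with `draws` (matrix, retained draws x groups), `summaries`
#'   (list of [posterior_summary()] per group) and `hpd_overlap` (logical
#'   matrix: do the groups' 95% HPD intervals overlap pairwise).
#' @export
group_genomic_variance <- function(fit, groups, trait = 1L) {
  stopifnot(inherits(fit, "mcmc_fit"))
  tn <- fit$trait_names[trait]
  if (!tn %in% names(fit$gebv))
    stop("genetic-effect draws for trait ", trait, " were not stored")
  gmat <- fit$gebv[[tn]]
  groups <- as.factor(groups)
  if (length(groups) != ncol(gmat)) stop("groups length must equal n animals")
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small))
    warning("singleton group(s) excluded: ", paste(small, collapse = ", "))
  keep <- setdiff(levels(groups), small)
  draws <- vapply(keep, function(gl) {
    idx <- which(groups == gl)
    apply(gmat[, idx, drop = FALSE], 1, stats::var)
  }, numeric(nrow(gmat)))
  colnames(draws) <- keep
  summaries <- lapply(keep, function(gl) posterior_summary(draws[, gl],
                                                           min_n = 2))
  names(summaries) <- keep
  k <- length(keep)
  ov <- matrix(TRUE, k, k, dimnames = list(keep, keep))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    a <- summaries[[i]]$hpd; b <- summaries[[j]]$hpd
    ov[i, j] <- a[1] <= b[2] && b[1] <= a[2]
  }
  list(draws = draws, summaries = summaries, hpd_overlap = ov)
}
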