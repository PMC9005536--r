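test_that("posterior summaries report median, shortest interval and sign probability", {
  expect_equal(posterior_summary(abs(rnorm(500)) + 0.1)$p0, 1)
  set.seed(30)
  sym <- rnorm(20000)
  expect_equal(posterior_summary(sym)$p0, 0.5, tolerance = 0.02)
  hp <- posterior_summary(rnorm(1e5))$hpd
  expect_equal(hp, c(-1.96, 1.96), tolerance = 0.03, ignore_attr = TRUE)
  s <- posterior_summary(rexp(1000))
  expect_true(s$hpd[1] <= s$median && s$median <= s$hpd[2])
  expect_error(posterior_summary(rnorm(50)), "too few")
})

test_that("Geweke Z is calibrated on stationary chains and flags trends", {
  set.seed(31)
  z <- replicate(1000, geweke_z(rnorm(600)))
  expect_gte(mean(abs(z) < 2), 0.93)
  # strong linear trend
  trend <- 0.02 * seq_len(1000) + rnorm(1000, sd = 0.5)
  expect_gt(abs(geweke_z(trend)), 5)
  # equal segment means by construction -> Z exactly 0
  seg <- rnorm(60)
  chain <- c(seg, rnorm(240), rep(seg, 5))
  expect_equal(geweke_z(chain), 0)
  expect_warning(zz <- geweke_z(rep(1, 200)), "constant")
  expect_true(is.nan(zz))
})

test_that("batch-means MCSE scales like the effective sample size", {
  set.seed(32)
  x <- rnorm(10000)
  m <- mcse_timeseries(x)
  expect_equal(m$mcse, sd(x) / sqrt(length(x)), tolerance = 0.25)
  expect_gt(m$ratio, 10)
  # AR(1) with phi = 0.9 inflates the MCSE above the iid value
  ar <- as.numeric(arima.sim(list(ar = 0.9), 10000))
  mar <- mcse_timeseries(ar)
  expect_gt(mar$mcse, 2 * sd(ar) / sqrt(10000))
  # thinning an iid chain by 10 inflates MCSE ~ sqrt(10)
  thin <- x[seq(1, 10000, by = 10)]
  ratio <- mcse_timeseries(thin)$mcse / m$mcse
  expect_gt(ratio, 2.2); expect_lt(ratio, 4.5)
  cm <- mcse_timeseries(rep(2, 500))
  expect_true(cm$constant && cm$mcse == 0)
})

test_that("Gibbs posterior means reproduce the mixed-model-equation solution", {
  h <- quick_herd(n = 40, m = 200, h2 = 0.4, seed = 33)
  y <- h$traits$CH4
  X <- matrix(1, 40, 1)
  sg2 <- 0.4; se2 <- 0.6
  fit <- fit_multitrait(matrix(y, dimnames = list(NULL, "CH4")), X, h$grm,
                        G0 = matrix(sg2), R0 = matrix(se2),
                        n_iter = 60000, burn_in = 10000, thin = 50, seed = 34)
  Gs <- grm_stabilize(h$grm)
  C <- rbind(cbind(crossprod(X) / se2, t(X) / se2),
             cbind(X / se2, diag(40) / se2 + solve(Gs) / sg2))
  sol <- solve(C, c(crossprod(X, y) / se2, y / se2))
  expect_lt(max(abs(fit$gebv_mean_rb[, 1] - sol[-1])), 1e-3)
  # plain posterior means agree within Monte-Carlo error
  expect_lt(max(abs(fit$gebv_mean[, 1] - sol[-1])), 0.08)
})

test_that("a duplicated trait with independent noise gives genetic correlation near one", {
  h <- quick_herd(n = 300, m = 500, h2 = 0.5, seed = 35)
  set.seed(36)
  y1 <- h$traits$CH4
  y2 <- h$ground_truth$g_true[, 1] + rnorm(300, sd = sd(y1 - h$ground_truth$g_true[, 1]))
  fit <- fit_bivariate(cbind(t1 = y1, t2 = y2), h$traits$fixed, h$grm,
                       n_iter = 8000, burn_in = 2000, thin = 10, seed = 37)
  expect_gt(median(fit$rg_samples), 0.8)
  expect_true(all(abs(fit$rg_samples) <= 1 + 1e-9))
  h2d <- h2_draws <- heritability_from_samples(fit, 1)$samples
  expect_true(all(h2d >= 0 & h2d <= 1))
})

test_that("animal relabelling leaves the posterior summaries invariant", {
  h <- quick_herd(n = 150, m = 300, h2 = 0.45, seed = 38)
  y <- h$traits$CH4; f <- h$traits$fixed
  fit1 <- fit_univariate(y, f, h$grm, n_iter = 8000, burn_in = 2000,
                         thin = 10, seed = 39)
  set.seed(40); perm <- sample(150)
  grm_p <- h$grm; grm_p$matrix <- h$grm$matrix[perm, perm]
  grm_p$animal_ids <- h$grm$animal_ids[perm]
  fit2 <- fit_univariate(y[perm], f[perm], grm_p, n_iter = 8000,
                         burn_in = 2000, thin = 10, seed = 39)
  expect_equal(heritability_from_samples(fit1)$median,
               heritability_from_samples(fit2)$median, tolerance = 0.05)
})

test_that("DIC comparison detects self-identity and checks data identity", {
  h <- quick_herd(n = 100, m = 200, h2 = 0.4, seed = 41)
  y <- h$traits$CH4; f <- h$traits$fixed
  n1 <- fit_null(y, f, n_iter = 6000, burn_in = 1000, thin = 5, seed = 42)
  n2 <- fit_null(y, f, n_iter = 6000, burn_in = 1000, thin = 5, seed = 43)
  cmp <- dic_compare(n1, n2)
  expect_lt(abs(cmp$delta), 5)
  expect_false(cmp$significant)
  other <- fit_null(rev(y), f, n_iter = 2000, burn_in = 500, thin = 5, seed = 44)
  expect_error(dic_compare(n1, other), "identical data")
})

test_that("Laplace-Metropolis marginal likelihoods match a conjugate closed form", {
  # y ~ N(mu, s2 known), mu ~ N(0, tau2): closed-form marginal likelihood
  set.seed(45)
  n <- 80; s2 <- 1.3; tau2 <- 4
  y <- rnorm(n, 0.4, sqrt(s2))
  logml_analytic <- function(y, s2, tau2) {
    vn <- 1 / (n / s2 + 1 / tau2)
    mun <- vn * sum(y) / s2
    sum(dnorm(y, 0, sqrt(s2), log = TRUE)) +
      0.5 * log(vn / tau2) + 0.5 * mun^2 / vn
  }
  # M1: free mean; M0: mu = 0
  post_v <- 1 / (n / s2 + 1 / tau2)
  post_m <- post_v * sum(y) / s2
  draws <- matrix(rnorm(10000, post_m, sqrt(post_v)))
  lp <- function(th) sum(dnorm(y, th[1], sqrt(s2), log = TRUE)) +
    dnorm(th[1], 0, sqrt(tau2), log = TRUE)
  lml1 <- laplace_metropolis_logml(draws, lp)
  lml0 <- sum(dnorm(y, 0, sqrt(s2), log = TRUE))
  bf_est <- exp(lml1 - lml0)
  bf_true <- exp(logml_analytic(y, s2, tau2) - lml0)
  expect_equal(bf_est / bf_true, 1, tolerance = 0.1)
})

test_that("Bayes factors for the genomic effect behave under signal and self-comparison", {
  # correction arithmetic
  h <- quick_herd(n = 250, m = 500, h2 = 0.5, seed = 46)
  y <- h$traits$CH4; f <- h$traits$fixed
  ff <- fit_univariate(y, f, h$grm, n_iter = 10000, burn_in = 2000, thin = 10,
                       seed = 47)
  fn <- fit_null(y, f, n_iter = 10000, burn_in = 2000, thin = 10, seed = 48)
  bf <- bayes_factor(ff, fn, n_tests = 2473)
  expect_equal(bf$bf_corrected, bf$bf_raw / 2473)
  expect_gt(bf$bf_raw, 1)    # strong simulated signal favours the genomic model
  expect_equal(7419 / 2473, 3, tolerance = 1e-4)
})

test_that("heritability draws classify on the study's bands", {
  expect_equal(1 / (1 + 3), 0.25)
  expect_identical(classify_h2(0.45), "highly heritable")
  expect_identical(classify_h2(0.10), "lowly heritable")
  expect_identical(classify_h2(0.30), "moderately heritable")
  h <- quick_herd(n = 100, m = 150, h2 = 0.4, seed = 49)
  fit <- fit_univariate(h$traits$CH4, h$traits$fixed, h$grm, n_iter = 4000,
                        burn_in = 800, thin = 5, seed = 50)
  hh <- heritability_from_samples(fit)
  expect_true(all(hh$samples >= 0 & hh$samples <= 1))
  expect_identical(hh$class, classify_h2(hh$median))
})

test_that("deregression divides by reliability with a floor", {
  fit <- fake_fit(gebv_mean = c(2, 1, -1), gebv_sd = c(0, sqrt(0.75), 0.9999),
                  sigma2_g = 1)
  grm <- structure(list(matrix = diag(3), animal_ids = paste0("A", 1:3)),
                   class = "grm")
  expect_warning(dg <- deregress_gebv(fit, grm, sigma2_g = 1,
                                      reliability_floor = 0.01))
  expect_equal(dg[1], 2, ignore_attr = TRUE)           # reliability 1
  expect_equal(dg[2], 1 / 0.25, ignore_attr = TRUE)    # accuracy 0.5 -> rel 0.25
  expect_true(is.na(dg[3]))                            # below the floor
  # reliability 0.5: GEBV 2 -> dGEBV 4
  fit2 <- fake_fit(gebv_mean = 2, gebv_sd = sqrt(0.5), sigma2_g = 1)
  grm1 <- structure(list(matrix = diag(1), animal_ids = "A1"), class = "grm")
  expect_equal(deregress_gebv(fit2, grm1, sigma2_g = 1)[1], 4,
               ignore_attr = TRUE)
  # variance never shrinks under deregression
  set.seed(51)
  fit3 <- fake_fit(gebv_mean = rnorm(50), gebv_sd = runif(50, 0.1, 0.6),
                   sigma2_g = 1)
  grm50 <- structure(list(matrix = diag(50), animal_ids = paste0("A", 1:50)),
                     class = "grm")
  dg3 <- deregress_gebv(fit3, grm50, sigma2_g = 1)
  expect_gte(var(dg3, na.rm = TRUE), var(fit3$gebv_mean[, 1]))
})

test_that("per-group genomic variances partition the posterior draws", {
  draws <- rbind(c(1, 1, 1, 0, 2, 4), c(2, 2, 2, 1, 3, 5))
  fit <- fake_fit(gebv_mean = colMeans(draws), gebv_sd = rep(0.1, 6),
                  gebv_draws = draws)
  groups <- factor(c("a", "a", "a", "b", "b", "b"))
  gv <- group_genomic_variance(fit, groups)
  expect_equal(unname(gv$draws[, "a"]), c(0, 0))       # identical g in group
  expect_equal(unname(gv$draws[, "b"]), c(4, 4))
  # scaling g by 2 scales variances by 4
  fit2 <- fake_fit(gebv_mean = colMeans(draws), gebv_sd = rep(0.1, 6),
                   gebv_draws = 2 * draws)
  gv2 <- group_genomic_variance(fit2, groups)
  expect_equal(gv2$draws[, "b"], 4 * gv$draws[, "b"])
  expect_warning(group_genomic_variance(
    fit, factor(c("a", "a", "a", "b", "b", "solo"))), "singleton")
})

test_that("homogeneous architecture gives overlapping group variance posteriors", {
  h <- quick_herd(n = 200, m = 300, h2 = 0.4, seed = 52)
  fit <- fit_univariate(h$traits$CH4, h$traits$fixed, h$grm, n_iter = 6000,
                        burn_in = 1200, thin = 6, seed = 53)
  set.seed(54)
  groups <- factor(sample(1:4, 200, replace = TRUE))
  gv <- group_genomic_variance(fit, groups)
  expect_true(all(gv$hpd_overlap))
})
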