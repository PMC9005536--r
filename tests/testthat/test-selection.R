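test_that("selection intensity follows the truncated-normal formula", {
  expect_equal(selection_intensity(0.30), dnorm(qnorm(0.7)) / 0.3)
  expect_equal(selection_intensity(1), 0)
  expect_error(selection_intensity(0), "fraction")
  expect_error(selection_intensity(1.2), "fraction")
  # monotone decreasing in the selected fraction
  p <- seq(0.01, 1, by = 0.01)
  expect_true(all(diff(selection_intensity(p)) < 0))
})

test_that("correlated response multiplies intensity, accuracy-root, correlation and sd", {
  r1 <- correlated_response(1, 1, 1, 1)
  expect_equal(r1$median, 1)
  r0 <- correlated_response(2, rep(0.7, 200), rep(0, 200), 1.5)
  expect_equal(r0$median, 0)
  r <- correlated_response(1.159, 0.5, -0.8, 2)
  expect_equal(r$median, -0.9272, tolerance = 1e-4)
  rp <- correlated_response(1.159, rep(0.5, 150), rep(-0.8, 150), 2,
                            ch4_mean = 20)
  expect_equal(rp$pct_of_mean, 100 * -0.9272 / 20, tolerance = 1e-3)
  expect_error(correlated_response(1, rep(0.5, 10), rep(0.1, 9), 1),
               "mismatched")
})

test_that("covariance assembly pools pairwise medians with the CH4 mean rule", {
  mk_fit <- function(traits, g11, g22, g12, r11, r22, r12, n = 400) {
    structure(list(
      samples = cbind(G_1_1 = rep(g11, n), G_1_2 = rep(g12, n),
                      G_2_2 = rep(g22, n), R_1_1 = rep(r11, n),
                      R_1_2 = rep(r12, n), R_2_2 = rep(r22, n)),
      trait_names = traits), class = "mcmc_fit")
  }
  # t = 2: matrices equal the single fit's medians
  f12 <- mk_fit(c("CH4", "m1"), 0.4, 0.3, -0.2, 0.6, 0.7, 0.1)
  cov2 <- assemble_covariance(list("CH4|m1" = f12), c("CH4", "m1"))
  expect_equal(cov2$G0, matrix(c(0.4, -0.2, -0.2, 0.3), 2,
                               dimnames = list(c("CH4", "m1"), c("CH4", "m1"))))
  # t = 3: CH4 diagonal is the mean of its per-fit medians
  f13 <- mk_fit(c("CH4", "m2"), 0.5, 0.35, -0.1, 0.6, 0.8, 0.05)
  f23 <- mk_fit(c("m1", "m2"), 0.32, 0.36, 0.15, 0.71, 0.79, 0.02)
  cov3 <- assemble_covariance(list("CH4|m1" = f12, "CH4|m2" = f13,
                                   "m1|m2" = f23), c("CH4", "m1", "m2"))
  expect_equal(cov3$G0["CH4", "CH4"], mean(c(0.4, 0.5)))
  expect_equal(cov3$G0["m1", "m1"], mean(c(0.3, 0.32)))
  expect_equal(cov3$G0["CH4", "m2"], -0.1)
  expect_equal(cov3$G0, t(cov3$G0))
  expect_error(assemble_covariance(list("CH4|m1" = f12), c("CH4", "m1", "m2")),
               "missing bivariate fit")
})

test_that("bending floors eigenvalues at the tolerance and is idempotent", {
  ok <- diag(c(1, 2))
  expect_equal(bend_matrix(ok), ok, ignore_attr = TRUE)
  expect_false(attr(bend_matrix(ok), "bending_log")$bent)
  m <- matrix(c(1, 1.2, 1.2, 1), 2)   # eigenvalues 2.2 and -0.2
  b <- bend_matrix(m, 0.001)
  ev <- eigen(b, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(min(ev), 0.001, tolerance = 1e-10)
  expect_lt(max(abs(b - t(b))), 1e-12)
  lg <- attr(b, "bending_log")
  expect_lte(max(abs(b - m)), lg$max_abs_change + 1e-12)
  # idempotent
  b2 <- bend_matrix(b, 0.001)
  expect_equal(unclass(b2), unclass(b), tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(bend_matrix(matrix(c(1, 2, 3, 4), 2)), "symmetric")
})

test_that("accuracy follows the posterior-sd formula with clipping", {
  expect_equal(accuracy(0, 1, 1), 1)
  expect_equal(accuracy(1, 1, 1), 0)
  expect_equal(accuracy(sqrt(0.75), 1, 1), 0.5)
  expect_warning(a <- accuracy(2, 1, 1), "clipped")
  expect_equal(a, 0)
  # anti-monotone in sd
  sds <- seq(0, 1, by = 0.1)
  expect_true(all(diff(accuracy(sds, 1, 1)) < 0))
})

test_that("response to selection selects the lowest tail per draw", {
  # all equal -> zero response
  flat <- matrix(1.7, 50, 20)
  r <- response_to_selection(flat, fractions = c(0.1, 0.5))
  expect_equal(r$median, c(0, 0))
  # non-degenerate draws -> strictly positive reduction on every draw
  set.seed(60)
  draws <- matrix(rnorm(50 * 40), 50, 40)
  r2 <- response_to_selection(draws, fractions = 0.2)
  expect_true(all(attr(r2, "draws") > 0))
  expect_error(response_to_selection(draws, fractions = 0.01),
               "zero animals")
})

test_that("truncation response on true breeding values matches the breeder's equation", {
  set.seed(61)
  sigma_g <- 1.8
  gv <- matrix(rnorm(2e5, 0, sigma_g), 1)
  r <- response_to_selection(gv, fractions = c(0.01, 0.10, 0.30))
  expect_equal(r$median / (selection_intensity(c(0.01, 0.10, 0.30)) * sigma_g),
               rep(1, 3), tolerance = 0.05, ignore_attr = TRUE)
})

test_that("breeding panel filters on occupancy, RA, significance and P0, with capped ranking", {
  cand <- data.frame(
    trait = paste0("t", 1:5),
    occupancy = c(1, 1, 0.9, 1, 1),
    mean_ra = c(2e-4, 5e-4, 3e-4, 5e-6, 1e-3),
    h2_significant = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    p0 = c(0.99, 0.97, 0.99, 0.99, 0.99),
    rg_median = c(-0.8, 0.7, -0.9, 0.6, -0.95),
    h2_median = c(0.4, 0.3, 0.5, 0.2, 0.6))
  panel <- select_breeding_panel(cand)
  expect_setequal(panel$trait, c("t1", "t2"))
  none <- select_breeding_panel(transform(cand, p0 = 0.5))
  expect_equal(nrow(none), 0)
  # cap keeps the highest |rg| first
  many <- data.frame(trait = paste0("g", 1:6), occupancy = 1, mean_ra = 1e-3,
                     h2_significant = TRUE, p0 = 0.99,
                     rg_median = c(0.6, -0.9, 0.7, -0.85, 0.65, 0.75),
                     h2_median = 0.3)
  capped <- select_breeding_panel(many, max_size = 3)
  expect_setequal(capped$trait, c("g2", "g4", "g6"))
  expect_true(attr(capped, "cap_applied"))
})

test_that("independent indicator traits leave scenario 3 equal to CH4-only prediction", {
  h <- quick_herd(n = 120, m = 250, h2 = c(0.4, 0.4, 0.4),
                  rg = diag(3), seed = 62)
  Y <- as.matrix(h$traits[, c("CH4", "micro1", "micro2")])
  cv <- make_covariances(c(0.4, 0.4, 0.4), diag(3))
  s1 <- predict_scenarios(Y, h$traits$fixed, h$grm, cv, 1,
                          n_iter = 20000, burn_in = 4000, thin = 20, seed = 63)
  expect_warning(
    s3 <- predict_scenarios(Y, h$traits$fixed, h$grm, cv, 3,
                            n_iter = 20000, burn_in = 4000, thin = 20,
                            seed = 63),
    "no information")
  expect_lt(max(abs(s1$animals$gebv_mean - s3$animals$gebv_mean)), 0.12)
  expect_equal(s1$mean_accuracy, s3$mean_accuracy, tolerance = 0.05)
})
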