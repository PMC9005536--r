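test_that("relative abundance closes each sample to one and rejects empty samples", {
  tab <- abundance_table(matrix(c(2, 3, 5, 1, 1, 8), 2, byrow = TRUE),
                         feature_ids = c("a", "b", "c"))
  ra <- relative_abundance(tab)
  expect_equal(ra$values[1, ], c(a = 0.2, b = 0.3, c = 0.5))
  expect_equal(unname(rowSums(ra$values)), c(1, 1))
  # single feature: RA is identically 1
  one <- abundance_table(matrix(c(4, 7), 2, 1), feature_ids = "only")
  expect_equal(unname(relative_abundance(one)$values[, 1]), c(1, 1))
  # random tables close to 1
  set.seed(1)
  rnd <- abundance_table(matrix(rpois(60, 20) + 1, 6, 10))
  expect_equal(unname(rowSums(relative_abundance(rnd)$values)), rep(1, 6))
  bad <- abundance_table(matrix(c(1, 0, 2, 0), 2), sample_ids = c("s1", "s2"))
  expect_error(relative_abundance(bad), "s2")
})

test_that("core filtering applies presence and mean-RA rules", {
  # 4 samples x 3 features; feature 'b' absent in one sample
  v <- matrix(c(10, 5, 30,
                12, 0, 25,
                 9, 6, 40,
                11, 7, 33), 4, 3, byrow = TRUE)
  tab <- abundance_table(v, feature_ids = c("a", "b", "c"))
  kept <- filter_core(tab, min_mean_ra = 0, require_all_samples = TRUE)
  expect_setequal(kept$feature_ids, c("a", "c"))
  # all features pass: identity
  allpass <- filter_core(abundance_table(v + 1), min_mean_ra = 0)
  expect_equal(allpass$values, abundance_table(v + 1)$values)
  # RUG-style occupancy at >= 1x coverage: feature at coverage >= 1 in only 2
  # of 4 samples is dropped at a 3-sample cutoff
  rv <- matrix(c(2.0, 0.5, 1.5,
                 1.2, 0.8, 2.5,
                 0.3, 1.6, 1.9,
                 1.4, 0.2, 3.0), 4, 3, byrow = TRUE)
  rtab <- abundance_table(rv, feature_ids = c("r1", "r2", "r3"),
                          feature_class = "RUG")
  kept_r <- filter_core(rtab, min_mean_ra = 0, require_all_samples = FALSE,
                        min_occupancy = 3, presence_cutoff = 1)
  expect_setequal(kept_r$feature_ids, c("r1", "r3"))
  # mean-RA rule is strictly greater-than
  expect_lt(ncol(filter_core(tab, min_mean_ra = 0.5,
                             require_all_samples = FALSE)$values), 3)
})

test_that("Bayesian-multiplicative zero replacement preserves totals and non-zero ratios", {
  pos <- abundance_table(matrix(c(5, 3, 2, 1, 8, 6), 2, byrow = TRUE))
  expect_identical(gbm_zero_replace(pos)$values, pos$values)

  v <- matrix(c(0, 3, 5, 9,
                2, 0, 8, 4,
                1, 1, 1, 1), 3, 4, byrow = TRUE)
  tab <- abundance_table(v, feature_ids = letters[1:4])
  out <- gbm_zero_replace(tab)
  expect_true(all(out$values > 0))
  expect_equal(rowSums(out$values), rowSums(v), tolerance = 1e-9,
               ignore_attr = TRUE)
  # ratios between originally non-zero parts preserved within each sample
  expect_equal(out$values[1, "c"] / out$values[1, "b"], 5 / 3)
  expect_equal(out$values[2, "d"] / out$values[2, "a"], 4 / 2)

  # entry-wise agreement with a direct evaluation of the posterior formula:
  # zero cell -> n_i * s_i t_j / (n_i + s_i); non-zero -> x_ij (1 - sum repl)
  tot <- rowSums(v)
  p <- v / tot
  gm <- apply(p, 2, function(col) exp(mean(log(col[col > 0]))))
  tj <- gm / sum(gm)
  s <- sqrt(tot)
  expected <- v
  for (i in 1:3) {
    repl <- s[i] * tj / (tot[i] + s[i])
    zm <- sum(repl[v[i, ] == 0])
    expected[i, ] <- ifelse(v[i, ] == 0, repl * tot[i], v[i, ] * (1 - zm))
  }
  expect_equal(unname(out$values), unname(expected), tolerance = 1e-8)

  allzero <- abundance_table(matrix(c(1, 0, 2, 0), 2),
                             sample_ids = c("s1", "s2"))
  expect_error(gbm_zero_replace(allzero), "s2")
})

test_that("ALR matches hand arithmetic, is scale invariant and inverts exactly", {
  tab <- abundance_table(matrix(c(0.2, 0.3, 0.5), 1),
                         feature_ids = c("a", "b", "c"))
  out <- alr_transform(tab, "c")
  expect_equal(unname(out$values[1, ]), c(log(0.4), log(0.6)),
               tolerance = 1e-12)
  # x_j = x_ref -> 0
  eq <- abundance_table(matrix(c(3, 3, 3), 1), feature_ids = c("a", "b", "c"))
  expect_equal(unname(alr_transform(eq, "c")$values[1, ]), c(0, 0))
  # per-sample rescaling leaves the ALR row unchanged
  set.seed(2)
  v <- matrix(runif(40) + 0.1, 4, 10)
  t1 <- abundance_table(v); t2 <- abundance_table(v * c(3, 0.5, 10, 1e4))
  expect_equal(alr_transform(t1, t1$feature_ids[10])$values,
               alr_transform(t2, t1$feature_ids[10])$values,
               tolerance = 1e-10)
  # round trip to relative abundances
  ra <- relative_abundance(t1)$values
  back <- inverse_alr(alr_transform(t1, t1$feature_ids[10]))
  expect_equal(unname(back[, colnames(ra)]), unname(ra), tolerance = 1e-10)
  # zero reference names the offending sample
  vz <- v; vz[2, 10] <- 0
  expect_error(alr_transform(abundance_table(vz), t1$feature_ids[10]), "S2")
})

test_that("CLR centres rows on the log geometric mean", {
  tab <- abundance_table(matrix(c(1, 2, 4), 1), feature_ids = c("x", "y", "z"))
  expect_equal(unname(clr_transform(tab)$values[1, ]),
               c(log(0.5), 0, log(2)), tolerance = 1e-12)
  eq <- abundance_table(matrix(rep(5, 6), 2), feature_ids = letters[1:3])
  expect_true(all(clr_transform(eq)$values == 0))
  set.seed(3)
  rnd <- abundance_table(matrix(runif(50) + 0.1, 5, 10))
  out <- clr_transform(rnd)
  expect_true(all(abs(rowSums(out$values)) < 1e-10))
  # CLR is invariant to per-sample scaling
  scl <- abundance_table(rnd$values * c(2, 5, 0.1, 7, 100))
  expect_equal(clr_transform(scl)$values, out$values, tolerance = 1e-10)
  withzero <- abundance_table(matrix(c(1, 0, 2, 3, 4, 5), 2))
  expect_error(clr_transform(withzero), "gbm_zero_replace")
})

test_that("reference diagnostics score occupancy, log-ratio variance and Procrustes fit", {
  # two parts: the single log-ratio spans both geometries exactly
  set.seed(4)
  t2 <- abundance_table(matrix(runif(20) + 0.5, 10, 2),
                        feature_ids = c("u", "v"))
  d2 <- reference_diagnostics(t2)
  expect_equal(d2$procrustes_correlation, c(1, 1), tolerance = 1e-8)
  # a candidate proportional to another part has zero pairwise log-ratio
  # variance with it
  v <- matrix(runif(30) + 0.2, 10, 3)
  v[, 3] <- 2.5 * v[, 1]
  tp <- abundance_table(v, feature_ids = c("p", "q", "pcopy"))
  dd <- reference_diagnostics(tp, "pcopy")
  lr <- log(v[, 1] / v[, 3])
  expect_equal(var(lr), 0, tolerance = 1e-12)
  expect_true(dd$logratio_variance >= 0)
  # absent candidate is disqualified with a reason
  da <- reference_diagnostics(tp, "nope")
  expect_false(is.na(da$disqualified))
})
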