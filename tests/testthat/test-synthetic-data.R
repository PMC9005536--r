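test_that("genotype simulation honours allele frequencies, HWE and the seed", {
  cfg <- sim_config(n_animals = 10000, n_snps = 50, maf_range = c(0.5, 0.5),
                    n_traits = 1, seed = 20)
  g <- simulate_genotypes(cfg)
  expect_equal(mean(colMeans(g$values) / 2), 0.5, tolerance = 0.01)
  # same seed twice: bit-identical
  g2 <- simulate_genotypes(cfg)
  expect_identical(g$values, g2$values)
  # heterozygote fraction at p = 0.3 matches the binomial probability
  cfg3 <- sim_config(n_animals = 5000, n_snps = 20, maf_range = c(0.3, 0.3),
                     n_traits = 1, seed = 21)
  g3 <- simulate_genotypes(cfg3)
  het <- mean(g3$values == 1)
  se <- sqrt(0.42 * 0.58 / length(g3$values))
  expect_lt(abs(het - 2 * 0.3 * 0.7), 4 * se)
  expect_error(sim_config(maf_range = c(0.1, 0.7)), "maf_range")
})

test_that("trait simulation respects the generative (co)variance structure", {
  # degenerate case: no genetic variance
  cfg0 <- sim_config(n_animals = 800, n_snps = 100, n_traits = 1,
                     G0_true = matrix(0), R0_true = matrix(0.8), seed = 22)
  g0 <- simulate_genotypes(cfg0)
  st0 <- simulate_traits(g0, cfg0)
  expect_true(all(st0$ground_truth$g_true == 0))
  resid <- st0$traits$CH4 -
    ave(st0$traits$CH4, st0$traits$fixed)          # remove fixed shifts
  k <- nlevels(droplevels(st0$traits$fixed))
  expect_lt(abs(var(resid) * 800 / (800 - k) - 0.8), 0.1)
  # perfect genetic correlation forces identical ranking of breeding values
  cv <- make_covariances(c(0.4, 0.4), rg = 1)
  cfg1 <- sim_config(n_animals = 150, n_snps = 200, n_traits = 2,
                     G0_true = cv$G0, R0_true = cv$R0, seed = 23)
  st1 <- simulate_traits(simulate_genotypes(cfg1), cfg1)
  expect_equal(cor(st1$ground_truth$g_true[, 1], st1$ground_truth$g_true[, 2],
                   method = "spearman"), 1)
  expect_error(sim_config(n_traits = 2, G0_true = matrix(c(1, 2, 2, 1), 2),
                          R0_true = diag(2)), "positive semi-definite")
})

test_that("realized heritability matches the nominal value at large n", {
  cfg <- sim_config(n_animals = 2000, n_snps = 400, n_traits = 1,
                    h2_true = 0.33, seed = 24)
  st <- simulate_traits(simulate_genotypes(cfg), cfg)
  gv <- st$ground_truth$g_true[, 1]
  ev <- st$traits$CH4 - gv -
    ave(st$traits$CH4 - gv, st$traits$fixed)
  h2_emp <- var(gv) / (var(gv) + var(ev))
  expect_lt(abs(h2_emp - 0.33), 0.03)
})

test_that("microbiome counts invert the ALR generatively", {
  cfg <- sim_config(n_animals = 30, n_snps = 50, n_traits = 1,
                    depth_range = c(5e4, 2e5), seed = 25)
  set.seed(25)
  latent <- matrix(rnorm(30 * 5), 30, 5,
                   dimnames = list(NULL, paste0("f", 1:5)))
  tab <- simulate_microbiome_counts(latent, cfg, mode = "gene")
  depths <- attr(tab, "depths")
  expect_equal(unname(rowSums(tab$values)), as.numeric(depths))
  # all-zero latent row: expected proportions uniform over the J parts
  cfg_u <- sim_config(n_animals = 400, n_snps = 50, n_traits = 1,
                      depth_range = c(1e4, 1e4), seed = 26)
  tab_u <- simulate_microbiome_counts(matrix(0, 400, 3), cfg_u)
  expect_equal(unname(colMeans(tab_u$values / rowSums(tab_u$values))),
               rep(0.25, 4), tolerance = 0.005)
  # high depth: ALR of realized proportions recovers the latent row
  cfg_d <- sim_config(n_animals = 50, n_snps = 50, n_traits = 1,
                      depth_range = c(1e6, 1e6), seed = 27)
  lat_row <- matrix(rep(c(0.5, -0.3, 1.1), each = 50), 50, 3,
                    dimnames = list(NULL, c("x", "y", "z")))
  tab_d <- simulate_microbiome_counts(lat_row, cfg_d)
  alr_back <- alr_transform(gbm_zero_replace(tab_d), "ref")
  expect_lt(max(abs(sweep(alr_back$values, 2, c(0.5, -0.3, 1.1)))), 0.01)
  expect_error(simulate_microbiome_counts(
    latent, sim_config(depth_range = c(-1, 10))), "positive")
  # RUG mode zero-inflates
  cfg_r <- sim_config(n_animals = 30, n_snps = 50, n_traits = 1,
                      zero_inflation = 0.3, depth_range = c(1e5, 1e5),
                      seed = 28)
  tab_r <- simulate_microbiome_counts(latent, cfg_r, mode = "rug")
  expect_identical(tab_r$feature_class, "RUG")
  expect_gt(mean(tab_r$values == 0), 0.2)
})

test_that("simulation writers and readers round-trip", {
  dir <- withr::local_tempdir()
  h <- quick_herd(n = 25, m = 12, h2 = 0.4, seed = 29)
  paths <- write_genotypes_raw(h$genotypes, dir)
  g2 <- read_genotypes_raw(paths[1], paths[2])
  expect_equal(g2$values, h$genotypes$values, ignore_attr = TRUE)
  expect_equal(g2$map$chr, h$genotypes$map$chr)
  tsv <- file.path(dir, "tr.tsv")
  write_traits_tsv(h$traits, tsv)
  tr <- read_traits_tsv(tsv)
  expect_equal(tr$CH4, h$traits$CH4, tolerance = 1e-8)
  ab <- abundance_table(matrix(rpois(20, 30) + 1, 4, 5))
  abp <- file.path(dir, "ab.tsv")
  write_abundance_tsv(ab, abp)
  ab2 <- read_abundance_tsv(abp)
  expect_equal(ab2$values, ab$values, ignore_attr = TRUE)
  gt <- file.path(dir, "gt.txt")
  write_ground_truth(h$ground_truth, gt)
  expect_true(file.exists(gt) && file.exists(paste0(gt, ".gtrue.tsv")))
  expect_match(readLines(gt)[1], "h2_true")
})

test_that("PLINK .ped/.map reading codes the minor allele count", {
  dir <- withr::local_tempdir()
  ped <- c("F1 A1 0 0 0 -9 A A A G",
           "F1 A2 0 0 0 -9 A G G G",
           "F1 A3 0 0 0 -9 A A 0 0")
  map <- c("1 snp1 0 100", "1 snp2 0 200")
  writeLines(ped, file.path(dir, "t.ped"))
  writeLines(map, file.path(dir, "t.map"))
  g <- read_genotypes_ped(file.path(dir, "t.ped"), file.path(dir, "t.map"))
  # snp1: G is minor (freq 1/6) -> counts 0, 1, 0
  expect_equal(unname(g$values[, "snp1"]), c(0, 1, 0))
  # snp2: A minor (1/4), missing pair -> NA
  expect_equal(unname(g$values[, "snp2"]), c(1, 0, NA))
})
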