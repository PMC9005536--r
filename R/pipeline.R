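# End-to-end orchestration: simulate/ingest -> log-ratio transform -> GRM ->
# univariate fits -> bivariate fits vs CH4 -> significance table -> breeding
# panel -> covariance assembly + bending -> prediction scenarios -> response
# distributions -> dGEBV co-abundance network.

#' Declarative configuration for a full run
#'
#' All thresholds default to the study's values: core mean-RA cutoff 0.001%
#' (`1e-5`), panel RA cutoff 0.01% (`1e-4`), DIC delta <= -20, corrected
#' Bayes factor > 3, P0 >= 0.95, bending tolerance 0.001, selected fractions
#' 1/5/10/20/30/40/50%. Unknown keys (top-level or nested) are rejected.
#'
#' @param simulation named list of [sim_config()] arguments (`NULL` to read
#'   files instead).
#' @param input named list of file paths (`genotypes_raw`, `genotypes_map`,
#'   `abundance`, `traits`) when not simulating.
#' @param thresholds named list: `core_min_ra`, `panel_min_ra`, `dic_delta`,
#'   `bf_corrected`, `p0`, `bend_tolerance`.
#' @param mcmc named list: `n_iter`, `burn_in`, `thin` (desk-scale defaults).
#' @param scenario_fractions selected fractions for the response curves.
#' @param alr_reference feature ID, or `"auto"` to pick by
#'   [reference_diagnostics()].
#' @param panel_max_size cap on the breeding panel (default 30).
#' @param network named list: `threshold`, `min_degree`, `keep_fraction`,
#'   `knn_k`, `inflation`, `min_cluster_size`.
#' @param n_tests number of hypothesis tests for the Bayes-factor prior odds
#'   (`NULL`: the number of microbial traits analysed).
#' @param seed master seed; every stage derives its own seed from it.
#' @param outdir output directory for the per-stage TSVs and manifest.
#' @return object of class `run_config`.
#' @export
run_config <- function(simulation = list(), input = list(),
                       thresholds = list(), mcmc = list(),
                       scenario_fractions = c(0.01, 0.05, 0.10, 0.20, 0.30,
                                              0.40, 0.50),
                       alr_reference = "auto", panel_max_size = 30,
                       network = list(), n_tests = NULL, seed = 1,
                       outdir = tempfile("rumenGS_run_")) {
  thr_def <- list(core_min_ra = 1e-5, panel_min_ra = 1e-4, dic_delta = -20,
                  bf_corrected = 3, p0 = 0.95, bend_tolerance = 0.001)
  mcmc_def <- list(n_iter = 20000, burn_in = 4000, thin = 20)
  net_def <- list(threshold = 0.70, min_degree = 2, keep_fraction = 0.80,
                  knn_k = 10, inflation = 2, min_cluster_size = 2)
  in_def <- list(genotypes_raw = NULL, genotypes_map = NULL, abundance = NULL,
                 traits = NULL)
  check_keys <- function(x, allowed, what) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) stop("unknown ", what, " key(s): ", paste(bad, collapse = ", "))
  }
  check_keys(thresholds, names(thr_def), "thresholds")
  check_keys(mcmc, names(mcmc_def), "mcmc")
  check_keys(network, names(net_def), "network")
  check_keys(input, names(in_def), "input")
  check_keys(simulation, names(formals(sim_config)), "simulation")
  structure(list(
    simulation = simulation, input = utils::modifyList(in_def, input),
    thresholds = utils::modifyList(thr_def, thresholds),
    mcmc = utils::modifyList(mcmc_def, mcmc),
    scenario_fractions = scenario_fractions, alr_reference = alr_reference,
    panel_max_size = panel_max_size,
    network = utils::modifyList(net_def, network),
    n_tests = n_tests, seed = seed, outdir = outdir
  ), class = "run_config")
}

# pick an ALR reference: present everywhere, low log-ratio variance,
# high Procrustes correlation with the full log-ratio geometry
auto_reference <- function(table) {
  diag <- reference_diagnostics(table)
  ok <- diag[diag$occupancy >= 1, , drop = FALSE]
  if (!nrow(ok)) stop("no candidate reference present in all samples")
  ok$score <- ok$procrustes_correlation - 0.5 * rank(ok$logratio_variance) /
    nrow(ok)
  ok$candidate[which.max(ok$score)]
}

write_stage <- function(df, outdir, name) {
  utils::write.table(df, file.path(outdir, paste0(name, ".tsv")), sep = "\t",
                     row.names = FALSE, quote = FALSE)
}

#' Run the full analysis workflow
#'
#' Executes every stage from data (simulated or read from files) to the
#' response-to-selection distributions and the dGEBV co-abundance network,
#' writing one TSV per stage plus a reproducibility manifest to
#' `config$outdir`. All randomness derives from `config$seed`, so reruns with
#' the same configuration reproduce all outputs.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage messages.
#' @return invisibly, a list with every stage's objects: `data`,
#'   `transformed`, `grm`, `significance` (the master table), `panel`,
#'   `covariance`, `scenarios`, `responses`, `network`, `manifest`.
#' @export
run_full <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage_times <- c()
  tick <- function(name) {
    stage_times[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
  }

  ## stage 1: data
  if (length(config$simulation)) {
    scfg <- do.call(sim_config,
                    utils::modifyList(config$simulation,
                                      list(seed = derive_seed(config$seed, "sim"))))
    herd <- simulate_herd(scfg)
    say("simulated %d animals, %d SNPs, %d features", scfg$n_animals,
        scfg$n_snps, length(herd$abundance$feature_ids))
    write_traits_tsv(herd$traits, file.path(config$outdir, "traits.tsv"))
    write_abundance_tsv(herd$abundance, file.path(config$outdir, "abundance.tsv"))
    write_ground_truth(herd$ground_truth,
                       file.path(config$outdir, "ground_truth.txt"))
  } else {
    inp <- config$input
    if (is.null(inp$genotypes_raw) || is.null(inp$abundance) || is.null(inp$traits))
      stop("either a simulation block or input paths are required")
    herd <- list(
      genotypes = read_genotypes_raw(inp$genotypes_raw, inp$genotypes_map),
      abundance = read_abundance_tsv(inp$abundance),
      traits = read_traits_tsv(inp$traits)
    )
    herd$traits$fixed <- as.factor(herd$traits$fixed)
  }
  tick("data")

  ## stage 2: compositional transform
  core <- filter_core(herd$abundance, min_mean_ra = config$thresholds$core_min_ra)
  if (any(core$values == 0)) core <- gbm_zero_replace(core)
  ref <- if (identical(config$alr_reference, "auto")) {
    if (!is.null(herd$reference_id) &&
        herd$reference_id %in% core$feature_ids) herd$reference_id
    else auto_reference(core)
  } else config$alr_reference
  trans <- alr_transform(core, ref)
  say("ALR transform on %d features (reference: %s)", ncol(trans$values), ref)
  write_transformed_tsv(trans, file.path(config$outdir, "transformed.tsv"))
  tick("compositional")

  ## stage 3: GRM
  qc <- snp_qc(herd$genotypes)
  grm <- build_grm(qc)
  write_grm_tsv(grm, file.path(config$outdir, "grm.tsv"))
  tick("grm")

  ## stage 4-6: univariate + bivariate fits, significance master table
  y_ch4 <- herd$traits$CH4
  fixed <- herd$traits$fixed
  mc <- config$mcmc
  micro_names <- colnames(trans$values)
  n_tests <- config$n_tests %||% length(micro_names)
  fit_ch4 <- fit_univariate(y_ch4, fixed, grm, n_iter = mc$n_iter,
                            burn_in = mc$burn_in, thin = mc$thin,
                            seed = derive_seed(config$seed, "uni_CH4"))
  sigma_g_ch4 <- sqrt(fit_ch4$samples[, "G_1_1"])
  i30 <- selection_intensity(0.30)
  rows <- list()
  fits_uni <- list(CH4 = fit_ch4)
  occupancy <- colMeans(herd$abundance$values[, micro_names, drop = FALSE] > 0)
  mean_ra <- colMeans(relative_abundance(herd$abundance)$values[, micro_names,
                                                                drop = FALSE])
  for (tr in micro_names) {
    y <- trans$values[, tr]
    sfit <- fit_univariate(y, fixed, grm, n_iter = mc$n_iter,
                           burn_in = mc$burn_in, thin = mc$thin,
                           seed = derive_seed(config$seed, paste0("uni_", tr)))
    nfit <- fit_null(y, fixed, n_iter = mc$n_iter, burn_in = mc$burn_in,
                     thin = mc$thin,
                     seed = derive_seed(config$seed, paste0("null_", tr)))
    cmp <- dic_compare(sfit, nfit, config$thresholds$dic_delta)
    bf <- bayes_factor(sfit, nfit, n_tests)
    h2 <- heritability_from_samples(sfit)
    bfit <- fit_bivariate(cbind(CH4 = y_ch4, trait = y), fixed, grm,
                          n_iter = mc$n_iter, burn_in = mc$burn_in,
                          thin = mc$thin,
                          seed = derive_seed(config$seed, paste0("biv_", tr)))
    rg <- posterior_summary(bfit$rg_samples)
    resp <- correlated_response(i30, sqrt(h2$samples),
                                bfit$rg_samples, sigma_g_ch4)
    fits_uni[[tr]] <- sfit
    rows[[tr]] <- data.frame(
      trait = tr, occupancy = occupancy[[tr]], mean_ra = mean_ra[[tr]],
      h2_median = h2$median, h2_hpd_lower = h2$hpd[1], h2_hpd_upper = h2$hpd[2],
      h2_class = h2$class, dic_delta = cmp$delta,
      bf_corrected = bf$bf_corrected,
      h2_significant = cmp$significant && bf$significant,
      rg_median = rg$median, rg_hpd_lower = rg$hpd[1], rg_hpd_upper = rg$hpd[2],
      p0 = rg$p0, rg_significant = rg$p0 >= config$thresholds$p0,
      response_i30_median = resp$median, response_i30_p0 = resp$p0
    )
  }
  significance <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  write_stage(significance, config$outdir, "significance")
  say("significance table: %d / %d traits with significant h2, %d with P0 >= %.2f",
      sum(significance$h2_significant), nrow(significance),
      sum(significance$rg_significant), config$thresholds$p0)
  tick("fits")

  ## stage 7: breeding panel
  panel <- select_breeding_panel(
    significance[significance$rg_significant, , drop = FALSE] |>
      (\(d) data.frame(trait = d$trait, occupancy = d$occupancy,
                       mean_ra = d$mean_ra, h2_significant = d$h2_significant,
                       p0 = d$p0, rg_median = d$rg_median,
                       h2_median = d$h2_median))(),
    min_mean_ra = config$thresholds$panel_min_ra,
    min_p0 = config$thresholds$p0, max_size = config$panel_max_size)
  write_stage(panel, config$outdir, "panel")
  say("breeding panel: %d microbial traits", nrow(panel))
  tick("panel")

  result <- list(data = herd, transformed = trans, grm = grm,
                 fits_uni = fits_uni, significance = significance,
                 panel = panel)

  if (nrow(panel) >= 1) {
    ## stage 8: pairwise covariances among CH4 + panel, assembly, bending
    traits_all <- c("CH4", panel$trait)
    Yall <- cbind(CH4 = y_ch4,
                  trans$values[, panel$trait, drop = FALSE])
    pairs <- utils::combn(traits_all, 2)
    pw <- list()
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      key <- paste(a, b, sep = "|")
      pw[[key]] <- fit_bivariate(Yall[, c(a, b)], fixed, grm,
                                 n_iter = mc$n_iter, burn_in = mc$burn_in,
                                 thin = mc$thin,
                                 seed = derive_seed(config$seed, key))
    }
    cov_est <- assemble_covariance(pw, traits_all)
    G0b <- bend_matrix(cov_est$G0, config$thresholds$bend_tolerance)
    R0b <- bend_matrix(cov_est$R0, config$thresholds$bend_tolerance)
    cov_bent <- list(G0 = G0b, R0 = R0b, trait_names = traits_all)
    say("covariance assembly: %d x %d, bending %s",
        length(traits_all), length(traits_all),
        if (attr(G0b, "bending_log")$bent) "applied" else "not needed")
    tick("covariance")

    ## stage 9-10: scenarios and responses
    scen <- lapply(1:3, function(s)
      predict_scenarios(Yall, fixed, grm, cov_bent, scenario = s,
                        n_iter = mc$n_iter, burn_in = mc$burn_in,
                        thin = max(1L, mc$thin %/% 2L),
                        seed = derive_seed(config$seed, paste0("scen", s))))
    acc <- data.frame(scenario = 1:3,
                      mean_accuracy = vapply(scen, function(s) s$mean_accuracy,
                                             numeric(1)))
    write_stage(acc, config$outdir, "scenario_accuracy")
    responses <- do.call(rbind, lapply(1:3, function(s) {
      r <- response_to_selection(scen[[s]], config$scenario_fractions)
      cbind(scenario = s, r)
    }))
    write_stage(responses, config$outdir, "responses")
    say("mean accuracies: scenario 1 = %.3f, 2 = %.3f, 3 = %.3f",
        acc$mean_accuracy[1], acc$mean_accuracy[2], acc$mean_accuracy[3])
    tick("scenarios")
    result$covariance <- cov_bent
    result$scenarios <- scen
    result$responses <- responses
  } else {
    say("empty breeding panel: scenario stages skipped")
  }

  ## stage 11: dGEBV co-abundance network over all microbial traits
  if (length(micro_names) >= 3) {
    dg <- vapply(micro_names, function(tr)
      deregress_gebv(fits_uni[[tr]], grm), numeric(length(grm$animal_ids)))
    net <- build_graph(dg, threshold = config$network$threshold,
                       min_degree = config$network$min_degree)
    if (nrow(net$edges) > 0) {
      net <- prune_knn_edges(net, config$network$keep_fraction,
                             config$network$knn_k)
      net <- mcl_cluster(net, inflation = config$network$inflation,
                         min_cluster_size = config$network$min_cluster_size)
      say("network: %d nodes, %d edges, %d clusters", nrow(net$nodes),
          nrow(net$edges), length(unique(stats::na.omit(net$nodes$cluster))))
    } else say("network: no edges above the correlation threshold")
    write_graph_tsv(net, file.path(config$outdir, "network_edges.tsv"),
                    file.path(config$outdir, "network_nodes.tsv"))
    result$network <- net
    tick("network")
  }

  ## manifest
  manifest <- c(
    seed = config$seed,
    mcmc = paste(unlist(config$mcmc), collapse = "/"),
    thresholds = paste(names(config$thresholds),
                       unlist(config$thresholds), sep = "=", collapse = ";"),
    n_animals = length(grm$animal_ids),
    n_microbial_traits = length(micro_names),
    data_checksum = sprintf("%.6f", sum(herd$traits$CH4^2, na.rm = TRUE) +
                              sum(herd$abundance$values)),
    stage_seconds = paste(names(stage_times), unlist(stage_times),
                          sep = "=", collapse = ";")
  )
  writeLines(paste(names(manifest), manifest, sep = "\t"),
             file.path(config$outdir, "manifest.txt"))
  result$manifest <- manifest
  invisible(result)
}
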