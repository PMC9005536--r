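#' Sample-by-feature abundance table
#'
#' Container for microbial abundance data: counts (genera, KEGG-orthologue
#' genes) or coverages (metagenome-assembled uncultured genomes, "RUGs").
#' Rows are samples (animals), columns are features.
#'
#' @param values non-negative numeric matrix, samples x features.
#' @param sample_ids,feature_ids unique identifiers; default to dimnames.
#' @param feature_class one of `"genus"`, `"RUG"`, `"gene"`.
#' @param process_label optional character vector (per feature) with the
#'   biological-process class of a microbial gene (e.g. "CH4 metabolism").
#' @return object of class `abundance_table`.
#' @export
abundance_table <- function(values, sample_ids = rownames(values),
                            feature_ids = colnames(values),
                            feature_class = c("genus", "RUG", "gene"),
                            process_label = NULL) {
  values <- as.matrix(values)
  feature_class <- match.arg(feature_class)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(ncol(values)))
  if (anyDuplicated(sample_ids)) stop("sample IDs must be unique")
  if (anyDuplicated(feature_ids)) stop("feature IDs must be unique")
  if (length(sample_ids) != nrow(values) || length(feature_ids) != ncol(values))
    stop("ID lengths do not match matrix dimensions")
  if (any(!is.finite(values)) || any(values < 0))
    stop("abundance values must be finite and non-negative")
  if (!is.null(process_label) && length(process_label) != ncol(values))
    stop("process_label must have one entry per feature")
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 feature_ids = feature_ids, feature_class = feature_class,
                 process_label = process_label),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d %s features\n",
              nrow(x$values), ncol(x$values), x$feature_class))
  invisible(x)
}

#' Relative abundances
#'
#' Divides each feature by the total per sample, so every sample row sums
#' to one.
#'
#' @param table an [abundance_table()].
#' @return an `abundance_table` of relative abundances.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  tot <- rowSums(table$values)
  if (any(tot <= 0)) {
    bad <- table$sample_ids[tot <= 0]
    stop("sample(s) with zero total abundance: ", paste(bad, collapse = ", "))
  }
  out <- table
  out$values <- table$values / tot
  out
}

#' Core-feature filtering
#'
#' Keeps features meeting an occupancy criterion and a mean relative-abundance
#' criterion. For genera and genes the study design keeps features present in
#' all samples with mean RA above a cutoff (0.001% => `1e-5`); for RUGs an
#' occupancy count at a coverage cutoff is used instead
#' (`min_occupancy` samples with coverage >= `presence_cutoff`).
#'
#' @param table an [abundance_table()].
#' @param min_mean_ra minimum mean relative abundance, as a fraction
#'   (the study's "RA > 0.001%" is `1e-5`). Strictly greater-than.
#' @param require_all_samples if `TRUE`, keep only features present
#'   (value > `presence_cutoff` threshold semantics below) in every sample.
#' @param min_occupancy minimum number of samples in which the feature must be
#'   present; ignored when `NULL`.
#' @param presence_cutoff a feature counts as present in a sample when its
#'   value is >= this cutoff if > 0, or > 0 when the cutoff is 0 (default).
#'   RUG coverage filtering uses `presence_cutoff = 1` ("1x coverage").
#' @return filtered `abundance_table`; attribute `"retained_cumulative_ra"`
#'   holds the fraction of total abundance the retained features represent.
#' @export
filter_core <- function(table, min_mean_ra = 1e-5, require_all_samples = TRUE,
                        min_occupancy = NULL, presence_cutoff = 0) {
  stopifnot(inherits(table, "abundance_table"))
  if (min_mean_ra < 0 || min_mean_ra >= 1) stop("min_mean_ra must be in [0, 1)")
  ra <- relative_abundance(table)$values
  present <- if (presence_cutoff > 0) table$values >= presence_cutoff
             else table$values > 0
  occ <- colSums(present)
  keep <- colMeans(ra) > min_mean_ra
  if (isTRUE(require_all_samples)) keep <- keep & (occ == nrow(table$values))
  if (!is.null(min_occupancy)) keep <- keep & (occ >= min_occupancy)
  if (!any(keep)) warning("no features survive core filtering")
  out <- table
  out$values <- table$values[, keep, drop = FALSE]
  out$feature_ids <- table$feature_ids[keep]
  if (!is.null(table$process_label)) out$process_label <- table$process_label[keep]
  attr(out, "retained_cumulative_ra") <- mean(rowSums(ra[, keep, drop = FALSE]))
  out
}

#' Bayesian-multiplicative replacement of count zeros
#'
#' Replaces zeros in a count/coverage composition by the posterior expectation
#' of the multinomial probability under a Dirichlet prior, then rescales the
#' non-zero parts multiplicatively so each sample keeps its original total and
#' the ratios between originally non-zero parts are preserved (geometric
#' Bayesian-multiplicative replacement).
#'
#' The Dirichlet prior for sample i is `s_i * t`, where `t` is the normalised
#' dataset-level geometric mean of the observed (non-zero) proportions of each
#' part and `s_i = sqrt(n_i)` with `n_i` the sample total; both are
#' overridable. The posterior proportion imputed for a zero cell is
#' `s_i * t_j / (n_i + s_i)`.
#'
#' @param table an [abundance_table()] of counts or coverages.
#' @param strength per-sample prior strength `s_i`; default `sqrt(rowSums)`.
#' @param prior_means prior expected composition `t` (length J, positive);
#'   default: normalised geometric mean of observed proportions.
#' @return strictly positive `abundance_table` with unchanged row totals.
#' @export
gbm_zero_replace <- function(table, strength = NULL, prior_means = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  x <- table$values
  tot <- rowSums(x)
  if (any(tot <= 0)) {
    stop("sample(s) with all-zero counts: ",
         paste(table$sample_ids[tot <= 0], collapse = ", "))
  }
  if (!any(x == 0)) return(table)
  p <- x / tot
  if (is.null(prior_means)) {
    # geometric mean of the observed (non-zero) proportions of each part;
    # parts never observed get the smallest observed prior mass
    gm <- apply(p, 2, function(col) {
      nz <- col[col > 0]
      if (!length(nz)) NA_real_ else exp(mean(log(nz)))
    })
    if (all(is.na(gm))) stop("cannot form a prior: table is all zeros")
    gm[is.na(gm)] <- min(gm, na.rm = TRUE)
    prior_means <- gm / sum(gm)
  } else {
    if (length(prior_means) != ncol(x) || any(prior_means <= 0))
      stop("prior_means must be positive, one per feature")
    prior_means <- prior_means / sum(prior_means)
  }
  s <- strength %||% sqrt(tot)
  if (length(s) == 1L) s <- rep(s, nrow(x))
  # posterior proportion for zero cells: s_i t_j / (n_i + s_i)
  repl_p <- outer(s / (tot + s), prior_means)
  zero <- x == 0
  out <- x
  zero_mass <- rowSums(repl_p * zero)
  if (any(zero_mass >= 1))
    stop("imputed zero mass reaches the whole composition; lower the prior strength")
  out[zero] <- (repl_p * tot)[zero]
  adj <- 1 - zero_mass                       # multiplicative adjustment of non-zeros
  out[!zero] <- (x * adj)[!zero]
  res <- table
  res$values <- out
  res
}

#' New transformed-table container
#'
#' @param values real matrix, samples x parts.
#' @param kind `"alr"` or `"clr"`.
#' @param reference_id the ALR reference feature (ALR only).
#' @return object of class `transformed_table`.
#' @keywords internal
transformed_table <- function(values, kind, reference_id = NULL) {
  structure(list(values = values, kind = kind, reference_id = reference_id),
            class = "transformed_table")
}

#' @export
print.transformed_table <- function(x, ...) {
  cat(sprintf("transformed_table (%s%s): %d samples x %d parts\n",
              x$kind, if (!is.null(x$reference_id)) paste0(", ref = ", x$reference_id) else "",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Additive log-ratio transform
#'
#' `ln(x_j) - ln(x_ref)` for every part j other than the chosen reference,
#' giving J-1 unconstrained coordinates per sample. Scale-invariant per
#' sample, so counts, coverages and relative abundances give identical output.
#'
#' @param table strictly positive [abundance_table()].
#' @param reference_id feature ID used as denominator.
#' @return a `transformed_table` with J-1 columns.
#' @export
alr_transform <- function(table, reference_id) {
  stopifnot(inherits(table, "abundance_table"))
  if (!reference_id %in% table$feature_ids)
    stop("reference feature '", reference_id, "' not in table")
  ref <- table$values[, reference_id]
  if (any(ref <= 0)) {
    bad <- table$sample_ids[ref <= 0][1L]
    stop("reference '", reference_id, "' is zero/missing in sample ", bad)
  }
  if (any(table$values <= 0))
    stop("ALR needs strictly positive values; run gbm_zero_replace() first")
  keep <- setdiff(table$feature_ids, reference_id)
  v <- log(table$values[, keep, drop = FALSE]) - log(ref)
  transformed_table(v, "alr", reference_id)
}

#' Inverse additive log-ratio transform
#'
#' Maps ALR coordinates back to a composition (relative abundances) by
#' exponentiating, appending the reference part, and closing to one.
#'
#' @param transformed a `transformed_table` of kind `"alr"`, or a plain matrix.
#' @param reference_id name for the reconstructed reference column.
#' @return matrix of relative abundances (J columns, rows sum to 1).
#' @export
inverse_alr <- function(transformed, reference_id = NULL) {
  v <- if (inherits(transformed, "transformed_table")) {
    if (transformed$kind != "alr") stop("not an ALR table")
    reference_id <- reference_id %||% transformed$reference_id
    transformed$values
  } else as.matrix(transformed)
  e <- cbind(exp(v), 1)
  colnames(e) <- c(colnames(v), reference_id %||% "ref")
  e / rowSums(e)
}

#' Centred log-ratio transform
#'
#' `ln(x_j) - mean_j ln(x_j)`: each sample's log abundances centred on their
#' log geometric mean, so every row sums to zero.
#'
#' @param table strictly positive [abundance_table()].
#' @return a `transformed_table` with J columns.
#' @export
clr_transform <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (any(table$values <= 0))
    stop("CLR needs strictly positive values; run gbm_zero_replace() first")
  lv <- log(table$values)
  transformed_table(lv - rowMeans(lv), "clr")
}

#' Diagnostics for choosing an ALR reference
#'
#' Scores candidate reference features on the criteria used to pick a
#' denominator for the additive log-ratio transform: occupancy, mean relative
#' abundance, low log-ratio variance (mean over the other parts j of the
#' across-sample variance of `ln(x_j / x_cand)`), the quartile of that
#' variance among all candidates (1 = lowest 25%), and the Procrustes
#' correlation between the sample configuration in the full pairwise
#' log-ratio geometry and in the ALR(candidate) geometry. The full geometry
#' is computed through the CLR coordinates, whose inter-sample distances equal
#' the all-pairwise-log-ratio distances up to the constant factor sqrt(J).
#'
#' @param table strictly positive [abundance_table()].
#' @param candidates feature IDs to score (default: all features).
#' @return data.frame with one row per candidate: `occupancy` (fraction of
#'   samples where present), `mean_ra`, `logratio_variance`,
#'   `lrv_quartile`, `procrustes_correlation`.
#' @export
reference_diagnostics <- function(table, candidates = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  if (any(table$values <= 0))
    stop("reference diagnostics need strictly positive values")
  candidates <- candidates %||% table$feature_ids
  ra <- relative_abundance(table)$values
  lv <- log(table$values)
  clr <- lv - rowMeans(lv)
  # principal coordinates of the full log-ratio geometry (CLR is isometric
  # to it up to sqrt(J)); drop negligible dimensions
  pc_full <- stats::prcomp(clr, center = TRUE)$x
  keep_dim <- which(apply(pc_full, 2, stats::sd) > 1e-12)
  pc_full <- pc_full[, keep_dim, drop = FALSE]
  # all-candidate log-ratio variances for the quartile ranking
  lrv_all <- vapply(table$feature_ids, function(fid) {
    lr <- lv - lv[, fid]
    mean(apply(lr[, setdiff(colnames(lv), fid), drop = FALSE], 2, stats::var))
  }, numeric(1))
  qcut <- stats::quantile(lrv_all, c(0.25, 0.5, 0.75))
  res <- lapply(candidates, function(fid) {
    if (!fid %in% table$feature_ids)
      return(data.frame(candidate = fid, occupancy = 0, mean_ra = NA_real_,
                        logratio_variance = NA_real_, lrv_quartile = NA_integer_,
                        procrustes_correlation = NA_real_,
                        disqualified = "absent from table"))
    alr <- log(table$values[, setdiff(table$feature_ids, fid), drop = FALSE]) -
      lv[, fid]
    # vegan pads the lower-dimensional configuration with zero axes and says
    # so; that is the expected geometry here, not a problem
    pr <- withCallingHandlers(
      vegan::procrustes(pc_full, alr, symmetric = TRUE),
      warning = function(w) {
        if (grepl("fewer axes", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    data.frame(
      candidate = fid,
      occupancy = mean(table$values[, fid] > 0),
      mean_ra = mean(ra[, fid]),
      logratio_variance = lrv_all[[fid]],
      lrv_quartile = 1L + sum(lrv_all[[fid]] > qcut),
      procrustes_correlation = sqrt(max(0, 1 - pr$ss)),
      disqualified = NA_character_
    )
  })
  do.call(rbind, res)
}
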