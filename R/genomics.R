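#' Genotype matrix container
#'
#' Animals x SNPs matrix coded 0/1/2 (count of one allele), `NA` for missing
#' calls, with a SNP map carrying chromosome and position.
#'
#' @param values numeric matrix, animals x SNPs, entries in `{0, 1, 2, NA}`.
#' @param animal_ids,snp_ids identifiers; default to dimnames.
#' @param map data.frame with columns `snp`, `chr`, `pos`; defaults to
#'   consecutive positions on chromosome 1.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, animal_ids = rownames(values),
                            snp_ids = colnames(values), map = NULL) {
  values <- as.matrix(values)
  if (is.null(animal_ids)) animal_ids <- paste0("A", seq_len(nrow(values)))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(values)))
  if (anyDuplicated(animal_ids) || anyDuplicated(snp_ids))
    stop("animal and SNP IDs must be unique")
  ok <- values %in% c(0, 1, 2) | is.na(values)
  if (!all(ok)) stop("genotypes must be coded 0/1/2 or NA")
  if (is.null(map)) {
    map <- data.frame(snp = snp_ids, chr = "1",
                      pos = seq_len(ncol(values)), stringsAsFactors = FALSE)
  }
  if (!all(c("snp", "chr", "pos") %in% names(map)))
    stop("map needs columns snp, chr, pos")
  map <- map[match(snp_ids, map$snp), ]
  dimnames(values) <- list(animal_ids, snp_ids)
  structure(list(values = values, animal_ids = animal_ids, snp_ids = snp_ids,
                 map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d animals x %d SNPs (%.2f%% missing)\n",
              nrow(x$values), ncol(x$values), 100 * mean(is.na(x$values))))
  invisible(x)
}

# 1-df chi-square test of Hardy-Weinberg proportions, no continuity correction
hwe_pvalue <- function(geno) {
  g <- geno[!is.na(geno)]
  n <- length(g)
  if (n == 0L) return(NA_real_)
  p <- mean(g) / 2
  if (p <= 0 || p >= 1) return(1)           # monomorphic: no testable deviation
  obs <- c(sum(g == 0), sum(g == 1), sum(g == 2))
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((obs - expd)^2 / expd)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' SNP and sample quality control
#'
#' Applies the study's marker QC in order: drop non-autosomal or unmapped
#' SNPs; drop SNPs with call rate below `call_rate_min`, Hardy-Weinberg exact
#' deviation (1-df chi-square) with p below `hwe_p_min`, or minor allele
#' frequency below `maf_min`; then drop samples with call rate below
#' `sample_call_rate_min`.
#'
#' @param g a [genotype_matrix()]. Chromosome labels that are positive
#'   integers are treated as autosomes; anything else (X, Y, MT, 0, NA) is
#'   removed, as are SNPs with non-positive or missing positions.
#' @param call_rate_min,hwe_p_min,maf_min,sample_call_rate_min thresholds
#'   (defaults: 0.95, 1e-4, 0.05, 0.90). Kept when >= threshold (call rates,
#'   MAF, HWE p).
#' @return filtered `genotype_matrix` with attribute `"qc_report"` giving the
#'   number removed by each filter.
#' @export
snp_qc <- function(g, call_rate_min = 0.95, hwe_p_min = 1e-4,
                   maf_min = 0.05, sample_call_rate_min = 0.90) {
  stopifnot(inherits(g, "genotype_matrix"))
  thr <- c(call_rate_min, hwe_p_min, maf_min, sample_call_rate_min)
  if (any(thr < 0 | thr > 1)) stop("QC thresholds must be in [0, 1]")
  x <- g$values
  chr <- suppressWarnings(as.integer(as.character(g$map$chr)))
  autosomal <- !is.na(chr) & chr > 0 & !is.na(g$map$pos) & g$map$pos > 0
  report <- c(non_autosomal = sum(!autosomal))
  x <- x[, autosomal, drop = FALSE]
  cr <- colMeans(!is.na(x))
  pass_cr <- cr >= call_rate_min
  report["low_call_rate"] <- sum(!pass_cr)
  x <- x[, pass_cr, drop = FALSE]
  hwe <- apply(x, 2, hwe_pvalue)
  pass_hwe <- hwe >= hwe_p_min
  report["hwe_deviation"] <- sum(!pass_hwe)
  x <- x[, pass_hwe, drop = FALSE]
  p <- colMeans(x, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  pass_maf <- maf >= maf_min
  report["low_maf"] <- sum(!pass_maf)
  x <- x[, pass_maf, drop = FALSE]
  if (ncol(x) == 0L) stop("no SNPs survive QC")
  scr <- rowMeans(!is.na(x))
  keep_s <- scr >= sample_call_rate_min
  report["low_sample_call_rate"] <- sum(!keep_s)
  x <- x[keep_s, , drop = FALSE]
  if (nrow(x) == 0L) stop("no samples survive QC")
  out <- genotype_matrix(x, animal_ids = rownames(x), snp_ids = colnames(x),
                         map = g$map[g$map$snp %in% colnames(x), ])
  attr(out, "qc_report") <- report
  out
}

#' Allele frequencies from a genotype matrix
#'
#' `p_n = mean(genotype_n) / 2` over non-missing calls, computed in the whole
#' genotyped population.
#'
#' @param g a [genotype_matrix()].
#' @return named numeric vector of per-SNP allele frequencies.
#' @export
allele_frequencies <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  n_obs <- colSums(!is.na(g$values))
  if (any(n_obs == 0L))
    stop("SNP(s) with no non-missing calls: ",
         paste(g$snp_ids[n_obs == 0L], collapse = ", "))
  colMeans(g$values, na.rm = TRUE) / 2
}

#' Genomic relationship matrix (VanRaden)
#'
#' `G = W W' / (2 * sum p_n (1 - p_n))` where `W` holds genotypes centred by
#' twice the allele frequency. Missing genotypes are mean-imputed (`2 p_n`)
#' before centring.
#'
#' @param g a QC'd [genotype_matrix()].
#' @return object of class `grm`: list with the symmetric `matrix`,
#'   `animal_ids`, and the `denominator` `2 * sum p(1-p)`.
#' @export
build_grm <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  p <- allele_frequencies(g)
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all SNPs monomorphic: GRM denominator is zero")
  w <- sweep(g$values, 2, 2 * p)
  w[is.na(w)] <- 0                            # mean imputation after centring
  m <- tcrossprod(w) / denom
  m <- (m + t(m)) / 2
  structure(list(matrix = m, animal_ids = g$animal_ids, denominator = denom),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d animals, mean diagonal %.3f\n",
              nrow(x$matrix), mean(diag(x$matrix))))
  invisible(x)
}

#' Blend a GRM towards the identity for numerical stability
#'
#' `G* = (1 - blend) G + blend I`, guaranteeing positive definiteness before
#' the Gibbs sampler factorises it.
#'
#' @param grm a [build_grm()] result or plain symmetric matrix.
#' @param blend weight on the identity (default 0.01).
#' @return matrix of the same dimension.
#' @export
grm_stabilize <- function(grm, blend = 0.01) {
  m <- if (inherits(grm, "grm")) grm$matrix else as.matrix(grm)
  stop_if_not_symmetric(m, name = "GRM")
  (1 - blend) * m + blend * diag(nrow(m))
}
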