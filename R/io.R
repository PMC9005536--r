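# Readers and writers for the plain-text dialects used throughout:
# PLINK .raw / .ped / .map genotypes, TSV abundance and trait tables, and a
# key-value ground-truth file.

#' Write genotypes as PLINK .raw-style TSV plus a .map-style SNP table
#'
#' @param g a [genotype_matrix()].
#' @param dir output directory (created if needed).
#' @param prefix file prefix (default "genotypes").
#' @return invisibly, the two file paths.
#' @export
write_genotypes_raw <- function(g, dir, prefix = "genotypes") {
  stopifnot(inherits(g, "genotype_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  raw_path <- file.path(dir, paste0(prefix, ".raw"))
  map_path <- file.path(dir, paste0(prefix, ".map"))
  df <- data.frame(FID = g$animal_ids, IID = g$animal_ids, PAT = 0, MAT = 0,
                   SEX = 0, PHENOTYPE = -9, g$values, check.names = FALSE)
  utils::write.table(df, raw_path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(g$map[, c("chr", "snp", "pos")], map_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(raw_path, map_path))
}

#' Read genotypes from a PLINK .raw-style TSV
#'
#' Accepts the dialect written by [write_genotypes_raw()] (or PLINK
#' `--recode A`): FID/IID (+ optional PAT/MAT/SEX/PHENOTYPE) followed by one
#' 0/1/2 column per SNP. `NA` marks missing calls.
#'
#' @param path .raw file path.
#' @param map_path optional .map path (chr/snp/pos columns, with or without
#'   header).
#' @return a [genotype_matrix()].
#' @export
read_genotypes_raw <- function(path, map_path = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"), names(df))
  snps <- setdiff(names(df), meta)
  x <- as.matrix(df[, snps, drop = FALSE])
  ids <- if ("IID" %in% meta) as.character(df$IID) else paste0("A", seq_len(nrow(x)))
  map <- if (!is.null(map_path)) read_map(map_path) else NULL
  genotype_matrix(x, animal_ids = ids, snp_ids = snps, map = map)
}

read_map <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("chr", first, ignore.case = TRUE)
  m <- utils::read.table(path, header = has_header, sep = "",
                         stringsAsFactors = FALSE)
  if (!has_header) {
    # PLINK order: chr, snp, cM, pos (cM optional)
    names(m)[1:2] <- c("chr", "snp")
    names(m)[ncol(m)] <- "pos"
  }
  m$chr <- as.character(m$chr)
  m[, c("snp", "chr", "pos")]
}

#' Read genotypes from PLINK .ped/.map text files
#'
#' Two allele columns per SNP ("0" = missing); genotypes are recoded as the
#' count of the minor allele at each SNP (ties broken by allele order of
#' appearance).
#'
#' @param ped_path,map_path file paths.
#' @return a [genotype_matrix()].
#' @export
read_genotypes_ped <- function(ped_path, map_path) {
  ped <- utils::read.table(ped_path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE, colClasses = "character")
  map <- read_map(map_path)
  n_snps <- (ncol(ped) - 6L) / 2L
  if (n_snps != nrow(map)) stop(".ped and .map disagree on SNP count")
  ids <- ped[[2]]
  x <- matrix(NA_real_, nrow(ped), n_snps)
  for (j in seq_len(n_snps)) {
    a1 <- ped[[6L + 2L * j - 1L]]
    a2 <- ped[[6L + 2L * j]]
    alle <- c(a1, a2)
    alle <- alle[alle != "0"]
    if (!length(alle)) next
    tab <- sort(table(alle))                   # minor allele first
    minor <- names(tab)[1L]
    cnt <- (a1 == minor) + (a2 == minor)
    cnt[a1 == "0" | a2 == "0"] <- NA_real_
    x[, j] <- cnt
  }
  genotype_matrix(x, animal_ids = ids, snp_ids = map$snp, map = map)
}

#' Write / read an abundance table as TSV
#'
#' First column `sample`, remaining columns features. A `# feature_class:`
#' comment line records the feature class.
#'
#' @param table an [abundance_table()].
#' @param path file path.
#' @return invisibly, `path`.
#' @export
write_abundance_tsv <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# feature_class: ", table$feature_class), con)
  df <- data.frame(sample = table$sample_ids, table$values, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @export
read_abundance_tsv <- function(path) {
  lines <- readLines(path)
  fclass <- "gene"
  meta <- grep("^#", lines)
  cl_line <- grep("^# feature_class:", lines, value = TRUE)
  if (length(cl_line)) fclass <- trimws(sub("^# feature_class:", "", cl_line[1]))
  df <- utils::read.table(text = lines[setdiff(seq_along(lines), meta)],
                          header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  abundance_table(as.matrix(df[, -1, drop = FALSE]),
                  sample_ids = as.character(df$sample),
                  feature_class = fclass)
}

#' Write / read a transformed table with its sidecar metadata header
#'
#' @param tt a `transformed_table`.
#' @param path file path.
#' @return invisibly, `path`.
#' @export
write_transformed_tsv <- function(tt, path) {
  stopifnot(inherits(tt, "transformed_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# transform: ", tt$kind), con)
  if (!is.null(tt$reference_id))
    writeLines(paste0("# reference: ", tt$reference_id), con)
  df <- data.frame(sample = rownames(tt$values) %||%
                     paste0("S", seq_len(nrow(tt$values))),
                   tt$values, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read the phenotype + fixed-effect table
#'
#' @param traits data.frame as produced by [simulate_traits()].
#' @param path file path.
#' @return invisibly, `path`.
#' @export
write_traits_tsv <- function(traits, path) {
  utils::write.table(traits, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traits_tsv
#' @export
read_traits_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write simulation ground truth as a structured key-value text file
#'
#' Scalars and vectors are written one `key<TAB>values` line each; matrices
#' one row per line as `key[i]`. True breeding values go to a companion TSV
#' (`<path>.gtrue.tsv`).
#'
#' @param ground_truth the `ground_truth` element of [simulate_traits()].
#' @param path file path.
#' @return invisibly, `path`.
#' @export
write_ground_truth <- function(ground_truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  kv <- function(key, vals) writeLines(paste(c(key, format(vals, digits = 10)),
                                             collapse = "\t"), con)
  kv("h2_true", ground_truth$h2_true)
  for (i in seq_len(nrow(ground_truth$rg_true)))
    kv(paste0("rg_true[", i, "]"), ground_truth$rg_true[i, ])
  for (i in seq_len(nrow(ground_truth$G0_true)))
    kv(paste0("G0_true[", i, "]"), ground_truth$G0_true[i, ])
  for (i in seq_len(nrow(ground_truth$R0_true)))
    kv(paste0("R0_true[", i, "]"), ground_truth$R0_true[i, ])
  for (f in names(ground_truth$b_true))
    kv(paste0("b_true.", f), ground_truth$b_true[[f]])
  utils::write.table(ground_truth$g_true, paste0(path, ".gtrue.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a GRM as TSV with an ID sidecar
#'
#' @param grm a [build_grm()] result.
#' @param path matrix TSV path; IDs go to `<path>.ids`.
#' @return invisibly, `path`.
#' @export
write_grm_tsv <- function(grm, path) {
  stopifnot(inherits(grm, "grm"))
  utils::write.table(grm$matrix, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  writeLines(grm$animal_ids, paste0(path, ".ids"))
  invisible(path)
}
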