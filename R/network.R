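# Co-abundance network of deregressed host genomic effects: correlation
# thresholding, degree filtering, kNN-ranked edge pruning and Markov
# clustering.

#' Build the dGEBV co-abundance graph
#'
#' Connects microbial traits (nodes) whose deregressed genomic effects have a
#' Pearson correlation above `threshold` across animals, then removes nodes
#' with degree below `min_degree` (applied once, after thresholding). By
#' default the signed correlation is used (`r > 0.70`); set `use_abs = TRUE`
#' to edge on `|r|`.
#'
#' @param dgebv_matrix animals x traits matrix of deregressed genomic effects.
#' @param threshold correlation threshold (default 0.70, strict `>`).
#' @param min_degree minimum node degree kept (default 2).
#' @param use_abs edge on absolute correlation instead of signed.
#' @param node_class optional per-trait class labels (genus / RUG / gene).
#' @return object of class `coabundance_graph`: `nodes` (data.frame `id`,
#'   `class`, `cluster`), `edges` (data.frame `from`, `to`, `weight`).
#' @export
build_graph <- function(dgebv_matrix, threshold = 0.70, min_degree = 2,
                        use_abs = FALSE, node_class = NULL) {
  m <- as.matrix(dgebv_matrix)
  if (ncol(m) < 3L) stop("need at least 3 traits to build a network")
  if (is.null(colnames(m))) colnames(m) <- paste0("T", seq_len(ncol(m)))
  if (!is.null(node_class)) names(node_class) <- colnames(m)
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0 | is.na(sds))) {
    warning("constant dGEBV column(s) excluded: ",
            paste(colnames(m)[sds == 0 | is.na(sds)], collapse = ", "))
    m <- m[, sds > 0 & !is.na(sds), drop = FALSE]
  }
  cc <- stats::cor(m, use = "pairwise.complete.obs")
  crit <- if (use_abs) abs(cc) else cc
  idx <- which(upper.tri(crit) & crit > threshold, arr.ind = TRUE)
  edges <- data.frame(from = colnames(m)[idx[, 1]], to = colnames(m)[idx[, 2]],
                      weight = cc[idx], stringsAsFactors = FALSE)
  deg <- table(factor(c(edges$from, edges$to), levels = colnames(m)))
  keep_nodes <- names(deg)[deg >= min_degree]
  edges <- edges[edges$from %in% keep_nodes & edges$to %in% keep_nodes, ,
                 drop = FALSE]
  nodes <- data.frame(id = keep_nodes,
                      class = if (is.null(node_class))
                        rep(NA_character_, length(keep_nodes))
                      else unname(node_class[keep_nodes]),
                      cluster = rep(NA_integer_, length(keep_nodes)),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "coabundance_graph")
}

#' @export
print.coabundance_graph <- function(x, ...) {
  nc <- sum(!is.na(unique(x$nodes$cluster)))
  cat(sprintf("coabundance_graph: %d nodes, %d edges%s\n",
              nrow(x$nodes), nrow(x$edges),
              if (nc > 0) sprintf(", %d clusters", nc) else ""))
  invisible(x)
}

#' Prune edges by k-nearest-neighbour ranking
#'
#' Each node marks its `k` strongest incident edges as preferred; edges are
#' then ranked by (preferred by both endpoints, preferred by one, weight,
#' stable edge order) and the top `keep_fraction` are retained globally.
#'
#' @param g a `coabundance_graph`.
#' @param keep_fraction fraction of edges kept (default 0.80).
#' @param k neighbourhood size (default 10).
#' @return the pruned graph; attribute `"edge_rank"` on the edges records the
#'   ranking used.
#' @export
prune_knn_edges <- function(g, keep_fraction = 0.80, k = 10) {
  stopifnot(inherits(g, "coabundance_graph"))
  e <- g$edges
  m <- nrow(e)
  if (m == 0L || keep_fraction >= 1) return(g)
  pref <- integer(m)
  for (v in g$nodes$id) {
    inc <- which(e$from == v | e$to == v)
    top <- inc[order(-abs(e$weight[inc]), inc)][seq_len(min(k, length(inc)))]
    pref[top] <- pref[top] + 1L
  }
  rank_ord <- order(-pref, -abs(e$weight), seq_len(m))
  keep_n <- floor(keep_fraction * m + 1e-9)
  kept <- sort(rank_ord[seq_len(keep_n)])
  out <- g
  out$edges <- e[kept, , drop = FALSE]
  attr(out$edges, "edge_rank") <- rank_ord
  out
}

# adjacency matrix (weights, zero diagonal) from a coabundance_graph
graph_adjacency <- function(g) {
  ids <- g$nodes$id
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(g$edges)) {
    w <- abs(g$edges$weight)
    A[cbind(g$edges$from, g$edges$to)] <- w
    A[cbind(g$edges$to, g$edges$from)] <- w
  }
  A
}

#' Markov clustering of the co-abundance graph
#'
#' Flow-simulation clustering: the column-stochastic transition matrix is
#' alternately expanded (matrix power) and inflated (elementwise power with
#' column renormalisation) until convergence; clusters are read off the
#' attractor rows of the limit matrix. Self-loops with weight equal to each
#' node's maximum incident weight are added first (standard regularisation).
#' Clusters smaller than `min_cluster_size` (the granularity) are dissolved
#' to unclustered (`NA`).
#'
#' @param g a `coabundance_graph`.
#' @param inflation inflation exponent (default 2).
#' @param expansion expansion power (default 2).
#' @param min_cluster_size minimum cluster size kept (default 2).
#' @param tol convergence tolerance on the max element change (default 1e-6).
#' @param max_iter iteration cap (default 200); non-convergence warns and
#'   returns the partial result (attribute `"converged"` = FALSE).
#' @return the graph with `nodes$cluster` filled in (cluster ids 1..K, `NA`
#'   for unclustered nodes).
#' @export
mcl_cluster <- function(g, inflation = 2, expansion = 2, min_cluster_size = 2,
                        tol = 1e-6, max_iter = 200) {
  stopifnot(inherits(g, "coabundance_graph"))
  n <- nrow(g$nodes)
  if (n == 0L) stop("empty graph")
  A <- graph_adjacency(g)
  loop <- apply(A, 1, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Mexp <- M
    for (e in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- Mexp^inflation
    Minf[Minf < 1e-14] <- 0
    Minf <- sweep(Minf, 2, colSums(Minf), "/")
    if (max(abs(Minf - M)) < tol) {
      M <- Minf
      converged <- TRUE
      break
    }
    M <- Minf
  }
  if (!converged) warning("MCL did not converge in ", max_iter,
                          " iterations; returning partial clustering")
  # attractors: rows with non-negligible diagonal; each attractor row's
  # support is a cluster; overlapping attractor rows are merged
  attractors <- which(diag(M) > tol)
  membership <- rep(NA_integer_, n)
  cl_id <- 0L
  for (i in attractors) {
    support <- which(M[i, ] > tol)
    existing <- unique(stats::na.omit(membership[support]))
    if (length(existing)) {
      membership[support] <- existing[1L]
      if (length(existing) > 1L)
        membership[membership %in% existing[-1L]] <- existing[1L]
    } else {
      cl_id <- cl_id + 1L
      membership[support] <- cl_id
    }
  }
  # any node not reached by an attractor row joins its strongest column target
  for (j in which(is.na(membership))) {
    tgt <- which.max(M[, j])
    membership[j] <- membership[tgt]
  }
  # renumber and dissolve small clusters
  sizes <- table(membership)
  small <- as.integer(names(sizes)[sizes < min_cluster_size])
  membership[membership %in% small] <- NA_integer_
  membership <- as.integer(factor(membership))
  out <- g
  out$nodes$cluster <- membership
  attr(out, "converged") <- converged
  attr(out, "mcl_iterations") <- it
  out
}

#' Write a graph as an edge-list TSV and a node/cluster TSV
#'
#' @param g a `coabundance_graph`.
#' @param edge_file,node_file output paths.
#' @return invisibly, the two paths.
#' @export
write_graph_tsv <- function(g, edge_file, node_file) {
  utils::write.table(g$edges, edge_file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(g$nodes, node_file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(edge_file, node_file))
}
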