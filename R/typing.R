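#' Louvain-Jaccard clustering of cells
#'
#' Builds a k-nearest-neighbour graph on normalised expression (Euclidean
#' distance), reweights edges by the Jaccard overlap of the two cells'
#' neighbour sets (shared-nearest-neighbour weighting), and partitions the
#' graph with Louvain community detection under a fixed seed.
#'
#' @param norm Cells x genes normalised matrix.
#' @param k_neighbors Neighbourhood size (default 15).
#' @param resolution Louvain resolution (default 1).
#' @param seed RNG seed for the (stochastic) Louvain pass.
#' @return Integer vector of cluster ids (1-based).
#' @export
louvain_jaccard_cluster <- function(norm, k_neighbors = 15, resolution = 1,
                                    seed = 1L) {
  n <- nrow(norm)
  if (k_neighbors < 2) stop("k_neighbors must be >= 2")
  if (n <= k_neighbors) stop("fewer cells than k_neighbors")
  d <- as.matrix(stats::dist(norm))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k_neighbors)]))
  # candidate edges: union of directed kNN relations
  ei <- rep(seq_len(n), k_neighbors)
  ej <- as.vector(nn)
  swap <- ei > ej
  tmp <- ei[swap]; ei[swap] <- ej[swap]; ej[swap] <- tmp
  key <- (ei - 1) * n + ej
  keep <- !duplicated(key)
  ei <- ei[keep]; ej <- ej[keep]
  # Jaccard of neighbour sets (including self, as in SNN graphs)
  sets <- lapply(seq_len(n), function(i) c(i, nn[i, ]))
  w <- vapply(seq_along(ei), function(k) {
    a <- sets[[ei[k]]]; b <- sets[[ej[k]]]
    inter <- length(intersect(a, b))
    inter / (2 * (k_neighbors + 1) - inter)
  }, numeric(1))
  pos <- w > 0
  g <- igraph::graph_from_edgelist(cbind(ei[pos], ej[pos]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$weight <- w[pos]
  memb <- with_local_seed(seed, igraph::membership(
    igraph::cluster_louvain(g, resolution = resolution)))
  as.integer(memb)
}

#' Assign cell types to clusters from a marker panel
#'
#' For each cluster, each candidate type is scored by the mean over its
#' marker genes of the cluster's mean normalised expression relative to the
#' population mean (so highly expressed genes do not dominate). The top type
#' is assigned unless it fails to exceed the runner-up by a relative margin,
#' in which case the cluster is labelled `"Unknown"`.
#'
#' @param clusters Integer cluster ids per cell.
#' @param norm Cells x genes normalised matrix.
#' @param panel Named list mapping type label to marker gene names.
#' @param min_margin Required relative advantage of the top score over the
#'   runner-up (default 0.05); a tie always yields `"Unknown"`.
#' @return List with `type` (per-cell labels) and `cluster_type` (per-cluster
#'   labels, named by cluster id).
#' @export
assign_cluster_types <- function(clusters, norm, panel, min_margin = 0.05) {
  if (length(panel) == 0) stop("empty marker panel")
  genes <- colnames(norm)
  panel <- lapply(panel, intersect, genes)
  if (any(lengths(panel) == 0)) stop("marker panel contains types with no panel genes")
  pop_mean <- colMeans(norm)
  eps <- 1e-6
  ids <- sort(unique(clusters))
  cluster_type <- stats::setNames(character(length(ids)), ids)
  for (cl in ids) {
    cl_mean <- colMeans(norm[clusters == cl, , drop = FALSE])
    rel <- (cl_mean + eps) / (pop_mean + eps)
    score <- vapply(panel, function(m) mean(rel[m]), numeric(1))
    o <- order(score, decreasing = TRUE)
    top <- score[o[1]]
    second <- if (length(score) > 1) score[o[2]] else 0
    cluster_type[as.character(cl)] <-
      if (top > second * (1 + min_margin)) names(panel)[o[1]] else "Unknown"
  }
  list(type = unname(cluster_type[as.character(clusters)]),
       cluster_type = cluster_type)
}

#' Cell-type expression enrichment profiles
#'
#' For each type and gene, the mean normalised expression within the type is
#' divided by the mean over the whole population and log2-transformed, with a
#' pseudocount added to both means to avoid log of zero.
#'
#' @param norm Cells x genes normalised matrix.
#' @param types Per-cell type labels.
#' @param eps Pseudocount (default 1e-6).
#' @return Types x genes matrix of log2 enrichments.
#' @export
enrichment_profile <- function(norm, types, eps = 1e-6) {
  stopifnot(length(types) == nrow(norm))
  pop_mean <- colMeans(norm)
  tl <- sort(unique(types))
  E <- t(vapply(tl, function(t) {
    log2((colMeans(norm[types == t, , drop = FALSE]) + eps) / (pop_mean + eps))
  }, numeric(ncol(norm))))
  rownames(E) <- tl
  E
}

#' Call hematopoietic stem cells from Mecom and Kit counts
#'
#' The Mecom threshold is the 99.95th percentile (linear interpolation) of
#' raw Mecom molecule counts over all retained cells; a cell is an HSC if its
#' Mecom count strictly exceeds the threshold and its Kit count is at least
#' 1. When counts come from several genotypes the threshold is computed per
#' genotype dataset.
#'
#' @param cm A `mf_cellmatrix` (raw counts are used) or a counts matrix.
#' @param mecom_gene,kit_gene Marker gene names.
#' @param percentile Percentile (0-100) defining the threshold.
#' @param by Optional per-cell grouping (e.g. genotype) within which the
#'   threshold is computed; default is one dataset.
#' @return Logical HSC flag per cell.
#' @export
call_hscs <- function(cm, mecom_gene = "Mecom", kit_gene = "Kit",
                      percentile = 99.95, by = NULL) {
  counts <- if (is.matrix(cm)) cm else cm$counts
  for (g in c(mecom_gene, kit_gene)) {
    if (!g %in% colnames(counts)) stop(sprintf("gene '%s' not in panel", g))
  }
  if (is.null(by)) by <- rep(1L, nrow(counts))
  mecom <- counts[, mecom_gene]
  kit <- counts[, kit_gene]
  flag <- logical(nrow(counts))
  for (grp in unique(by)) {
    sel <- by == grp
    thr <- stats::quantile(mecom[sel], percentile / 100, type = 7, names = FALSE)
    flag[sel] <- mecom[sel] > thr & kit[sel] >= 1
  }
  flag
}
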