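#' Build the spatial neighbourhood graph
#'
#' Two cells are neighbours when their centroids are strictly less than
#' `radius_um` apart. Candidate pairs are found with a bucket-grid spatial
#' index, so construction is near-linear in cell number.
#'
#' @param centroids_um n x 2 matrix of cell centroids in micrometres.
#' @param radius_um Neighbourhood radius (default 20).
#' @return A `mf_graph` data frame of edges `i`, `j` (i < j), `dist`, with
#'   attributes `n_cells` and `radius_um`.
#' @export
build_neighbor_graph <- function(centroids_um, radius_um = 20) {
  centroids_um <- as.matrix(centroids_um)
  n <- nrow(centroids_um)
  ei <- integer(0); ej <- integer(0); ed <- numeric(0)
  if (n >= 2 && radius_um > 0) {
    x <- centroids_um[, 1]; y <- centroids_um[, 2]
    cw <- radius_um
    ix <- floor((x - min(x)) / cw); iy <- floor((y - min(y)) / cw)
    nx <- max(ix) + 1L
    bucket <- split(seq_len(n), iy * nx + ix)
    bkey <- as.numeric(names(bucket))
    pairs_i <- list(); pairs_j <- list(); k <- 0L
    for (b in seq_along(bucket)) {
      key <- bkey[b]
      bx <- key %% nx; by <- key %/% nx
      members <- bucket[[b]]
      # same bucket pairs
      if (length(members) > 1) {
        cmb <- utils::combn(members, 2)
        k <- k + 1L; pairs_i[[k]] <- cmb[1, ]; pairs_j[[k]] <- cmb[2, ]
      }
      # half of the 8-neighbourhood to avoid duplicates
      for (d in list(c(1, 0), c(-1, 1), c(0, 1), c(1, 1))) {
        qx <- bx + d[1]; qy <- by + d[2]
        if (qx < 0 || qx >= nx) next
        bidx <- match(qy * nx + qx, bkey)
        if (is.na(bidx)) next
        nb <- bucket[[bidx]]
        if (length(nb) && length(members)) {
          k <- k + 1L
          pairs_i[[k]] <- rep(members, each = length(nb))
          pairs_j[[k]] <- rep(nb, times = length(members))
        }
      }
    }
    if (k > 0) {
      pi_ <- unlist(pairs_i); pj_ <- unlist(pairs_j)
      dd <- sqrt((x[pi_] - x[pj_])^2 + (y[pi_] - y[pj_])^2)
      keep <- dd < radius_um
      pi_ <- pi_[keep]; pj_ <- pj_[keep]; dd <- dd[keep]
      swap <- pi_ > pj_
      tmp <- pi_[swap]; pi_[swap] <- pj_[swap]; pj_[swap] <- tmp
      o <- order(pi_, pj_)
      ei <- pi_[o]; ej <- pj_[o]; ed <- dd[o]
    }
  }
  g <- data.frame(i = ei, j = ej, dist = ed)
  attr(g, "n_cells") <- n
  attr(g, "radius_um") <- radius_um
  class(g) <- c("mf_graph", "data.frame")
  g
}

#' Cell-type pair-proximity enrichment
#'
#' Measures, over all neighbour pairs (< 20 um by default), the probability of
#' observing each unordered cell-type pair, and normalises it by the
#' probability expected from randomly pairing cells given type abundances:
#' `2 f_a f_b` for distinct types and `f_a^2` for self pairs. The log2 of the
#' ratio is the enrichment fold. Each pair receives a chi-square test
#' (1 df, Yates-corrected 2x2 of observed vs expected edge counts) and
#' Benjamini-Hochberg correction across pairs. With
#' `include_self_pairs = FALSE`, self edges are removed first and the null
#' renormalised over non-self pairs: `P(a,b) = 2 f_a f_b / (1 - sum_t f_t^2)`.
#'
#' @param graph A `mf_graph` from [build_neighbor_graph()].
#' @param types Per-cell type labels (all cells, not just those with edges).
#' @param include_self_pairs Keep same-type pairs in the analysis?
#' @param yates Apply the continuity correction in the chi-square test.
#' @return A `PairEnrichmentTable` data frame: `type_a`, `type_b`,
#'   `observed_pairs`, `expected_probability`, `observed_probability`,
#'   `log2_enrichment`, `chi2_p`, `fdr_q`. Pairs involving a type with no
#'   cells are reported with NA statistics.
#' @export
pair_enrichment <- function(graph, types, include_self_pairs = TRUE,
                            yates = TRUE) {
  n <- attr(graph, "n_cells")
  stopifnot(length(types) == n)
  tl <- sort(unique(types))
  f <- as.numeric(table(factor(types, levels = tl))) / n
  ta <- types[graph$i]; tb <- types[graph$j]
  if (!include_self_pairs) {
    keep <- ta != tb
    ta <- ta[keep]; tb <- tb[keep]
  }
  total <- length(ta)
  pairs <- expand.grid(a = seq_along(tl), b = seq_along(tl))
  pairs <- pairs[pairs$a <= pairs$b, ]
  if (!include_self_pairs) pairs <- pairs[pairs$a < pairs$b, ]
  lo <- pmin(ta, tb); hi <- pmax(ta, tb)
  obs <- mapply(function(a, b) sum(lo == tl[a] & hi == tl[b]),
                pairs$a, pairs$b)
  p_exp <- ifelse(pairs$a == pairs$b, f[pairs$a]^2, 2 * f[pairs$a] * f[pairs$b])
  if (!include_self_pairs) p_exp <- p_exp / (1 - sum(f^2))
  p_obs <- if (total > 0) obs / total else rep(NA_real_, nrow(pairs))
  defined <- f[pairs$a] > 0 & f[pairs$b] > 0 & total > 0
  l2 <- ifelse(defined, log2(p_obs / p_exp), NA_real_)
  chi_p <- rep(NA_real_, nrow(pairs))
  for (k in which(defined)) {
    e <- p_exp[k] * total
    chi_p[k] <- tryCatch(
      chi2_2x2_yates(obs[k], total - obs[k], e, total - e, yates = yates)$p,
      error = function(cond) NA_real_)
  }
  q <- rep(NA_real_, nrow(pairs))
  q[!is.na(chi_p)] <- bh_fdr(chi_p[!is.na(chi_p)])
  out <- data.frame(type_a = tl[pairs$a], type_b = tl[pairs$b],
                    observed_pairs = as.integer(obs),
                    expected_probability = p_exp,
                    observed_probability = p_obs,
                    log2_enrichment = l2, chi2_p = chi_p, fdr_q = q,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Flag enrichments reproducible across biological replicates
#'
#' A type pair is reproducible when it is positively enriched and significant
#' (FDR-adjusted P below `p_cut` by default) in at least `min_replicates` of
#' the per-replicate enrichment tables.
#'
#' @param per_replicate_tables List of [pair_enrichment()] tables over the
#'   same type panel.
#' @param p_cut Significance cutoff (default 0.01).
#' @param min_replicates Minimum number of replicates (default 3).
#' @param use_adjusted Test `fdr_q` (default) rather than raw `chi2_p`.
#' @return Data frame `type_a`, `type_b`, `n_significant`, `reproducible`.
#' @export
reproducible_enrichments <- function(per_replicate_tables, p_cut = 0.01,
                                     min_replicates = 3, use_adjusted = TRUE) {
  if (length(per_replicate_tables) < min_replicates) {
    stop("fewer replicate tables than min_replicates")
  }
  base <- per_replicate_tables[[1]][, c("type_a", "type_b")]
  hits <- sapply(per_replicate_tables, function(tb) {
    stopifnot(identical(tb$type_a, base$type_a), identical(tb$type_b, base$type_b))
    p <- if (use_adjusted) tb$fdr_q else tb$chi2_p
    !is.na(p) & p < p_cut & !is.na(tb$log2_enrichment) & tb$log2_enrichment > 0
  })
  base$n_significant <- as.integer(rowSums(hits))
  base$reproducible <- base$n_significant >= min_replicates
  base
}

#' Define stem-cell niches
#'
#' A niche is the set of cells whose centroids lie strictly within
#' `radius_um` of an HSC, excluding the central HSC itself (another HSC in
#' range is a member).
#'
#' @param hsc_flags Logical HSC flag per cell.
#' @param centroids_um n x 2 centroid matrix (um).
#' @param radius_um Niche radius (default 20).
#' @return A `NicheSet` list: `members` (list per HSC of member cell
#'   indices, named by HSC index), `niche_cells` (union of members),
#'   `non_niche_cells` (cells in no niche and not HSCs), `hsc_ids`.
#' @export
define_niches <- function(hsc_flags, centroids_um, radius_um = 20) {
  n <- nrow(centroids_um)
  stopifnot(length(hsc_flags) == n)
  hsc_ids <- which(hsc_flags)
  g <- build_neighbor_graph(centroids_um, radius_um)
  nbr <- edge_adjacency_list(g, n)
  members <- lapply(hsc_ids, function(h) sort(nbr[[h]]))
  names(members) <- hsc_ids
  niche_cells <- sort(unique(unlist(members)))
  structure(list(members = members, niche_cells = niche_cells,
                 non_niche_cells = setdiff(seq_len(n),
                                           union(niche_cells, hsc_ids)),
                 hsc_ids = hsc_ids),
            class = "mf_nicheset")
}

#' Niche cell-type composition tests
#'
#' For each cell type, compares the proportion of that type among niche cells
#' with its proportion in the overall population, using a Yates-corrected
#' 2x2 chi-square test on the counts.
#'
#' @param niche_set A `NicheSet` from [define_niches()].
#' @param types Per-cell type labels.
#' @return Data frame `type`, `n_niche`, `niche_total`, `n_overall`,
#'   `overall_total`, `prop_niche`, `prop_overall`, `chi2_p`.
#' @export
niche_composition <- function(niche_set, types) {
  niche <- niche_set$niche_cells
  if (length(niche) == 0) stop("empty niche set")
  tl <- sort(unique(types))
  nt <- length(niche); n_all <- length(types)
  out <- data.frame(type = tl,
                    n_niche = vapply(tl, function(t) sum(types[niche] == t), 0L),
                    niche_total = nt,
                    n_overall = vapply(tl, function(t) sum(types == t), 0L),
                    overall_total = n_all, stringsAsFactors = FALSE)
  out$prop_niche <- out$n_niche / nt
  out$prop_overall <- out$n_overall / n_all
  out$chi2_p <- vapply(seq_len(nrow(out)), function(k) {
    tryCatch(chi2_2x2_yates(out$n_niche[k], nt - out$n_niche[k],
                            out$n_overall[k], n_all - out$n_overall[k])$p,
             error = function(cond) NA_real_)
  }, numeric(1))
  rownames(out) <- NULL
  out
}

#' Fraction of cells in direct contact with another cell group
#'
#' Two segmented cells touch when one cell's pixels, dilated by `dilate_px`
#' pixels (8-connectivity), overlap the other's pixels. Returns the fraction
#' of group-a cells touching at least one group-b cell. With watershed masks
#' that keep a 1 px background boundary between adjacent cells, a dilation of
#' 2 px detects cells sharing a boundary line.
#'
#' @param mask A `mf_mask`.
#' @param group_a_cells,group_b_cells Label ids of the two groups.
#' @param dilate_px Dilation radius in pixels (default 1).
#' @return Fraction in [0, 1].
#' @export
contact_fraction <- function(mask, group_a_cells, group_b_cells, dilate_px = 1) {
  if (length(group_a_cells) == 0) stop("group_a is empty")
  pairs <- touching_label_pairs(mask$labels, dilate_px)
  in_contact <- union(
    pairs[pairs[, 1] %in% group_a_cells & pairs[, 2] %in% group_b_cells, 1],
    pairs[pairs[, 2] %in% group_a_cells & pairs[, 1] %in% group_b_cells, 2])
  length(intersect(group_a_cells, in_contact)) / length(group_a_cells)
}

# all unordered label pairs with Chebyshev gap <= d (i.e. labels whose pixels
# come within the (2d+1)x(2d+1) neighbourhood of each other)
touching_label_pairs <- function(lab, d = 1) {
  H <- nrow(lab); W <- ncol(lab)
  res <- list(); k <- 0L
  for (dx in -d:d) for (dy in -d:d) {
    if (dx == 0 && dy == 0) next
    r1 <- max(1, 1 - dy):min(H, H - dy)
    c1 <- max(1, 1 - dx):min(W, W - dx)
    a <- lab[r1, c1]; b <- lab[r1 + dy, c1 + dx]
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) {
      k <- k + 1L
      res[[k]] <- unique(cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel])))
    }
  }
  if (k == 0) return(matrix(0L, 0, 2))
  unique(do.call(rbind, res))
}
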