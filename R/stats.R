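#' Yates-corrected chi-square test for a 2x2 table
#'
#' Computes the continuity-corrected chi-square statistic
#' \deqn{\chi^2 = N (|ad - bc| - N/2)^2 / [(a+b)(c+d)(a+c)(b+d)]}
#' with the correction term floored at zero, and the upper-tail P value on
#' 1 degree of freedom. Non-integer (expected) counts are accepted.
#'
#' @param a,b,c,d Table cells, row-wise: comparison of proportion
#'   `a / (a + b)` against `c / (c + d)`.
#' @param yates Apply the continuity correction (default TRUE).
#' @return List with `statistic` and `p`.
#' @export
chi2_2x2_yates <- function(a, b, c, d, yates = TRUE) {
  if (any(c(a, b, c, d) < 0)) stop("negative cell count")
  N <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("zero margin in 2x2 table")
  delta <- abs(a * d - b * c)
  if (yates) delta <- max(0, delta - N / 2)
  stat <- N * delta^2 / prod(margins)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Welch's t-test from summary statistics
#'
#' Unpaired two-sample t-test without the equal-variance assumption, computed
#' from group means, standard deviations and sizes, with Welch-Satterthwaite
#' degrees of freedom and a two-sided P value.
#'
#' @param m1,s1,n1 Mean, standard deviation and size of group 1.
#' @param m2,s2,n2 Same for group 2.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (s1 <= 0 || s2 <= 0) stop("standard deviations must be positive")
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  tval <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = tval, df = df,
       p = 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted P values, monotone in the P value ranks and capped at 1.
#'
#' @param p_values Numeric vector of raw P values in [0, 1].
#' @return Adjusted q values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) stop("p values outside [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact P by enumeration of all group assignments when the pooled sample has
#' at most 20 observations (midranks handle ties); otherwise the tie-corrected
#' normal approximation with continuity correction.
#'
#' @param x,y Numeric samples.
#' @return Two-sided P value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  if (n <= 20) {
    combos <- utils::combn(n, n1)
    w_all <- colSums(matrix(r[combos], nrow = n1))
    # two-sided: total probability of rank sums at least as extreme
    mu <- n1 * (n + 1) / 2
    p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
    return(min(1, p))
  }
  suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
}

#' Differential expression with a replicate-reproducibility filter
#'
#' Per gene, computes the log2 fold change of pseudocounted group means and a
#' two-sided Wilcoxon rank-sum P over the full data, with Benjamini-Hochberg
#' adjustment across genes; then repeats the computation within each of two
#' replicate groups. A gene is a significant DEG only when it passes in the
#' total data (fold change of at least 2 either way and adjusted P < 0.05)
#' and in both replicate groups (P < 0.1 with a fold-change direction
#' consistent with the total); genes failing in either replicate group are
#' treated as unreproducible.
#'
#' @param norm Cells x genes normalised matrix.
#' @param group_a_cells,group_b_cells Disjoint row indices of the two
#'   conditions.
#' @param replicates Per-cell replicate ids.
#' @param replicate_split List of two non-empty vectors of replicate ids
#'   partitioning the replicates; defaults to first half / second half of the
#'   sorted ids.
#' @param fc_cut Total-data fold-change cutoff (default 2).
#' @param p_total_cut Adjusted-P cutoff on the total data (default 0.05).
#' @param p_rep_cut Raw-P cutoff within each replicate group (default 0.1).
#' @param eps Pseudocount on group means, in normalised units (default 0.1).
#' @return A `DEGTable` data frame: `gene`, `log2_fold_change`, `p_total`,
#'   `q_total`, `p_group1`, `p_group2`, `direction_consistent`, `significant`.
#' @export
deg_analysis <- function(norm, group_a_cells, group_b_cells, replicates,
                         replicate_split = NULL, fc_cut = 2,
                         p_total_cut = 0.05, p_rep_cut = 0.1, eps = 0.1) {
  if (length(group_a_cells) == 0 || length(group_b_cells) == 0)
    stop("both condition groups must be non-empty")
  if (length(intersect(group_a_cells, group_b_cells)))
    stop("condition groups must be disjoint")
  stopifnot(length(replicates) == nrow(norm))
  if (is.null(replicate_split)) {
    ids <- sort(unique(replicates[c(group_a_cells, group_b_cells)]))
    if (length(ids) < 2) stop("need at least 2 replicates to form replicate groups")
    half <- ceiling(length(ids) / 2)
    replicate_split <- list(ids[seq_len(half)], ids[-seq_len(half)])
  }
  if (length(replicate_split[[1]]) == 0 || length(replicate_split[[2]]) == 0)
    stop("replicate groups must be non-empty")

  test_subset <- function(a_cells, b_cells) {
    A <- norm[a_cells, , drop = FALSE]; B <- norm[b_cells, , drop = FALSE]
    l2fc <- log2((colMeans(A) + eps) / (colMeans(B) + eps))
    p <- vapply(seq_len(ncol(norm)), function(g)
      wilcoxon_rank_sum(A[, g], B[, g]), numeric(1))
    list(l2fc = l2fc, p = p)
  }
  total <- test_subset(group_a_cells, group_b_cells)
  grp <- lapply(replicate_split, function(ids) {
    a <- group_a_cells[replicates[group_a_cells] %in% ids]
    b <- group_b_cells[replicates[group_b_cells] %in% ids]
    if (length(a) == 0 || length(b) == 0) stop("a replicate group has no cells")
    test_subset(a, b)
  })
  q_total <- bh_fdr(total$p)
  dir_ok <- sign(grp[[1]]$l2fc) == sign(total$l2fc) &
            sign(grp[[2]]$l2fc) == sign(total$l2fc)
  out <- data.frame(
    gene = colnames(norm),
    log2_fold_change = unname(total$l2fc),
    p_total = total$p, q_total = q_total,
    p_group1 = grp[[1]]$p, p_group2 = grp[[2]]$p,
    direction_consistent = unname(dir_ok), stringsAsFactors = FALSE)
  out$significant <- abs(out$log2_fold_change) >= log2(fc_cut) &
    out$q_total < p_total_cut & out$p_group1 < p_rep_cut &
    out$p_group2 < p_rep_cut & out$direction_consistent
  rownames(out) <- NULL
  out
}

#' Niche gene to cell-type-marker co-expression screen
#'
#' Correlates each candidate niche gene with every marker gene across
#' individual niche cells (Pearson). For each (niche gene, cell type), the
#' highest correlation over that type's markers is kept; P values are
#' Benjamini-Hochberg adjusted over all tested gene-marker pairs, and records
#' with `r > r_cut` and adjusted P below `q_cut` are reported.
#'
#' @param norm_niche Niche cells x genes normalised matrix (>= 3 cells).
#' @param panel Named list mapping cell type to marker gene names.
#' @param niche_gene_list Candidate niche genes to screen.
#' @param r_cut,q_cut Reporting cutoffs (defaults 0.1 and 0.05).
#' @return List with `records` (reported `niche_gene`, `cell_type`,
#'   `best_marker`, `r`, `q`), `all_pairs` (every tested pair), and
#'   `skipped` (constant gene vectors).
#' @export
niche_correlation_screen <- function(norm_niche, panel, niche_gene_list,
                                     r_cut = 0.1, q_cut = 0.05) {
  if (nrow(norm_niche) < 3) stop("need at least 3 niche cells")
  genes <- colnames(norm_niche)
  panel <- lapply(panel, intersect, genes)
  niche_gene_list <- intersect(niche_gene_list, genes)
  skipped <- character(0)
  rows <- list(); k <- 0L
  for (ct in names(panel)) {
    for (mk in panel[[ct]]) {
      for (ng in setdiff(niche_gene_list, mk)) {
        xv <- norm_niche[, ng]; yv <- norm_niche[, mk]
        if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
          skipped <- c(skipped, paste(ng, mk, sep = "~"))
          next
        }
        ct_res <- stats::cor.test(xv, yv, method = "pearson")
        k <- k + 1L
        rows[[k]] <- data.frame(niche_gene = ng, cell_type = ct, marker = mk,
                                r = unname(ct_res$estimate), p = ct_res$p.value,
                                stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0) {
    return(list(records = data.frame(), all_pairs = data.frame(),
                skipped = unique(skipped)))
  }
  all_pairs <- do.call(rbind, rows)
  all_pairs$q <- bh_fdr(all_pairs$p)
  # best marker per (niche gene, type)
  key <- paste(all_pairs$niche_gene, all_pairs$cell_type, sep = "\r")
  best <- unsplit(lapply(split(seq_len(nrow(all_pairs)), key), function(ix) {
    rep(ix[which.max(all_pairs$r[ix])], length(ix))
  }), key)
  rec <- all_pairs[unique(best), , drop = FALSE]
  rec <- rec[rec$r > r_cut & rec$q < q_cut, , drop = FALSE]
  names(rec)[names(rec) == "marker"] <- "best_marker"
  rownames(rec) <- NULL
  list(records = rec[, c("niche_gene", "cell_type", "best_marker", "r", "q")],
       all_pairs = all_pairs, skipped = unique(skipped))
}
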