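#' Gene-level quality control against a bulk expression reference
#'
#' Compares total molecule counts per gene with bulk RNA-seq FPKM values by
#' Pearson correlation (by default on log10(x + 1) scales). The dataset is
#' usable only if the correlation exceeds `min_r`; genes on the explicit
#' exclusion list are flagged as failing QC regardless.
#'
#' @param total_counts_per_gene Named numeric vector of summed counts.
#' @param bulk_fpkm Named numeric vector of FPKM values for the same genes.
#' @param min_r Minimum dataset-level correlation (default 0.7).
#' @param exclusion_list Gene names to exclude a priori (e.g. species whose
#'   imaging counts are inconsistent with bulk data).
#' @param log_transform Correlate on log10(x + 1) scales (default TRUE).
#' @return List with `r`, `dataset_pass`, and named logical `qc_pass`.
#' @export
gene_qc <- function(total_counts_per_gene, bulk_fpkm, min_r = 0.7,
                    exclusion_list = character(0), log_transform = TRUE) {
  genes <- names(total_counts_per_gene)
  if (is.null(genes) || is.null(names(bulk_fpkm))) stop("vectors must be named")
  common <- intersect(genes, names(bulk_fpkm))
  if (length(common) < 3) stop("fewer than 3 genes shared with the bulk reference")
  x <- total_counts_per_gene[common]
  y <- bulk_fpkm[common]
  if (all(x == 0)) stop("all-zero count vector: correlation undefined")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector: correlation undefined")
  if (log_transform) { x <- log10(x + 1); y <- log10(y + 1) }
  r <- stats::cor(x, y)
  qc_pass <- stats::setNames(!(genes %in% exclusion_list), genes)
  list(r = r, dataset_pass = r > min_r, qc_pass = qc_pass)
}

#' Remove cells with too few detected molecules
#'
#' Cells with fewer than `min_total` molecules across the panel are dropped;
#' a cell with exactly `min_total` is retained.
#'
#' @param cm A `mf_cellmatrix` (or a bare counts matrix).
#' @param min_total Minimum total molecule count (default 10).
#' @return Object of the same kind restricted to retained cells.
#' @export
filter_low_count_cells <- function(cm, min_total = 10) {
  if (is.matrix(cm)) return(cm[rowSums(cm) >= min_total, , drop = FALSE])
  keep <- rowSums(cm$counts) >= min_total
  new_cellmatrix(cm$counts[keep, , drop = FALSE],
                 cm$cells[keep, , drop = FALSE], cm$genes,
                 if (!is.null(cm$norm)) cm$norm[keep, , drop = FALSE])
}

#' Normalise per-cell expression to molecules per thousand
#'
#' Each gene's count is divided by the cell's total count over all labelled
#' species and multiplied by 1,000, so normalised values are proportional to
#' within-cell composition and rows sum to 1,000.
#'
#' @param cm A `mf_cellmatrix` (or a bare counts matrix).
#' @return A `mf_cellmatrix` with `norm` filled in (or the normalised
#'   matrix).
#' @export
normalize_cells <- function(cm) {
  counts <- if (is.matrix(cm)) cm else cm$counts
  tot <- rowSums(counts)
  if (any(tot == 0)) stop("cells with zero total count: filter before normalising")
  norm <- 1000 * counts / tot
  if (is.matrix(cm)) return(norm)
  new_cellmatrix(cm$counts, cm$cells, cm$genes, norm)
}
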