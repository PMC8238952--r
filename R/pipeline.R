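#' End-to-end synthetic MERFISH niche analysis
#'
#' Runs the full workflow on one or more simulated tissue scenes (biological
#' replicates): scene simulation, bead-based drift correction, pixel-based
#' decoding, watershed segmentation, area / edge / low-count filtering,
#' gene-level QC against a pseudo-bulk reference, per-cell normalisation,
#' Louvain-Jaccard clustering with marker-based typing, stem-cell calling,
#' neighbourhood pair enrichment, niche definition and composition tests,
#' direct-contact analysis, niche-versus-non-niche differential expression,
#' and the niche co-expression screen. All stages run under seeds derived
#' from the scene configs, so a rerun reproduces every table.
#'
#' @param configs A `mf_scene_config` or list of them (one per replicate).
#' @param codebook Optional shared `mf_codebook`.
#' @param panel Marker panel for typing (default [default_marker_panel()]).
#' @param output_dir Optional directory; when given, result tables are
#'   written as TSV and a JSON run manifest is recorded.
#' @param threshold_quantile Bit-image binarisation quantile.
#' @param k_neighbors,min_margin Clustering / typing parameters.
#' @param niche_radius_um Neighbourhood and niche radius (um).
#' @param min_area,max_area Segment area filter (pixels).
#' @param seg_seed_depth Watershed seed depth.
#' @return A `mf_run` list with per-stage results: `cellmatrix` (pooled,
#'   normalised), `qc`, `clusters`, `typing`, `hsc_flags`, `graph`,
#'   `enrichment`, `per_replicate_enrichment`, `niches`, `composition`,
#'   `contact`, `deg`, `correlation`, `per_replicate` (scene-level
#'   intermediates), and `manifest`.
#' @export
run_end_to_end <- function(configs, codebook = NULL,
                           panel = default_marker_panel(),
                           output_dir = NULL, threshold_quantile = 0.999,
                           k_neighbors = 15, min_margin = 0.05,
                           niche_radius_um = 20, min_area = 2500,
                           max_area = 20000, seg_seed_depth = 0.1) {
  if (inherits(configs, "mf_scene_config")) configs <- list(configs)
  if (is.null(codebook)) {
    codebook <- build_mhd4_codebook(colnames(configs[[1]]$mean_expression),
                                    seed = configs[[1]]$seed)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  per_rep <- vector("list", length(configs))
  mats <- vector("list", length(configs))
  for (r in seq_along(configs)) {
    cfg <- configs[[r]]
    scene <- stage("simulate", simulate_scene(cfg, codebook))
    offsets <- stage("drift", correct_drift(scene$bead_stack))
    spots <- stage("decode", decode_image_stack(
      scene$bit_stack, codebook, threshold_quantile = threshold_quantile,
      offsets = offsets, pixel_size = cfg$pixel_size, fov_id = r))
    mask <- stage("segment", segment_cells(scene$membrane,
                                           seed_depth = seg_seed_depth,
                                           pixel_size = cfg$pixel_size))
    mask <- stage("filter", remove_edge_cells(
      filter_cells(mask, min_area = min_area, max_area = max_area)))
    cm <- stage("quantify", assign_spots(spots, mask, gene_names = codebook$name[!codebook$is_blank]))
    cm$cells$replicate_id <- r
    per_rep[[r]] <- list(scene = scene, offsets = offsets, spots = spots,
                         mask = mask, cellmatrix = cm)
    mats[[r]] <- cm
  }

  counts <- do.call(rbind, lapply(mats, function(m) m$counts))
  cells <- do.call(rbind, lapply(mats, function(m) m$cells))
  cells$global_id <- seq_len(nrow(cells))
  genes <- mats[[1]]$genes
  cm_all <- new_cellmatrix(counts, cells, genes)
  cm_all <- stage("cell filter", filter_low_count_cells(cm_all, min_total = 10))

  # pseudo-bulk reference from the generator's ground-truth counts
  bulk <- colSums(do.call(rbind, lapply(per_rep, function(x) x$scene$counts)))
  qc <- stage("gene QC", gene_qc(colSums(cm_all$counts), bulk))
  cm_all <- stage("normalize", normalize_cells(cm_all))

  clusters <- stage("cluster", louvain_jaccard_cluster(
    cm_all$norm, k_neighbors = k_neighbors, seed = configs[[1]]$seed))
  typing <- stage("typing", assign_cluster_types(clusters, cm_all$norm, panel,
                                                 min_margin = min_margin))
  hsc <- stage("HSC call", call_hscs(cm_all))

  centroids <- as.matrix(cm_all$cells[, c("x_um", "y_um")])
  # replicates imaged separately: keep neighbourhoods within a replicate by
  # offsetting fields far apart in a shared frame
  offset_x <- (cm_all$cells$replicate_id - 1) * 10 * max(centroids[, 1], 1)
  centroids[, 1] <- centroids[, 1] + offset_x
  graph <- stage("graph", build_neighbor_graph(centroids, niche_radius_um))
  enr <- stage("enrichment", pair_enrichment(graph, typing$type,
                                             include_self_pairs = FALSE))
  per_rep_enr <- lapply(seq_along(configs), function(r) {
    sel <- cm_all$cells$replicate_id == r
    g <- build_neighbor_graph(centroids[sel, , drop = FALSE], niche_radius_um)
    pair_enrichment(g, typing$type[sel], include_self_pairs = FALSE)
  })

  niches <- stage("niches", if (any(hsc)) {
    define_niches(hsc, centroids, niche_radius_um)
  } else NULL)
  composition <- if (!is.null(niches) && length(niches$niche_cells)) {
    stage("composition", niche_composition(niches, typing$type))
  } else NULL
  contact <- if (any(hsc)) {
    rep1 <- cm_all$cells$replicate_id == 1
    a <- cm_all$cells$id[hsc & rep1]
    b <- cm_all$cells$id[typing$type %in% c("AEC", "SEC") & !hsc & rep1]
    if (length(a) && length(b)) {
      stage("contact", contact_fraction(per_rep[[1]]$mask, a, b, dilate_px = 2))
    } else NA_real_
  } else NA_real_

  deg <- NULL
  if (!is.null(niches) && length(niches$niche_cells) >= 5 &&
      length(configs) >= 2) {
    deg <- stage("DEG", deg_analysis(
      cm_all$norm, niches$niche_cells, niches$non_niche_cells,
      replicates = cm_all$cells$replicate_id))
  }
  correlation <- NULL
  if (!is.null(niches) && length(niches$niche_cells) >= 3) {
    correlation <- stage("correlation screen", niche_correlation_screen(
      cm_all$norm[niches$niche_cells, , drop = FALSE], panel,
      niche_gene_list = genes))
  }

  manifest <- list(
    n_replicates = length(configs),
    seeds = vapply(configs, `[[`, integer(1), "seed"),
    parameters = list(threshold_quantile = threshold_quantile,
                      k_neighbors = k_neighbors, min_margin = min_margin,
                      niche_radius_um = niche_radius_um, min_area = min_area,
                      max_area = max_area, seg_seed_depth = seg_seed_depth),
    n_genes = length(genes),
    n_decoded_molecules = sum(vapply(per_rep, function(x) nrow(x$spots), 0)),
    n_segmented_cells = sum(vapply(per_rep, function(x) nrow(x$mask$cells), 0)),
    n_retained_cells = nrow(cm_all$counts),
    n_hscs = sum(hsc),
    qc_r = qc$r)

  run <- structure(list(cellmatrix = cm_all, qc = qc, clusters = clusters,
                        typing = typing, hsc_flags = hsc, graph = graph,
                        enrichment = enr, per_replicate_enrichment = per_rep_enr,
                        niches = niches, composition = composition,
                        contact = contact, deg = deg, correlation = correlation,
                        per_replicate = per_rep, manifest = manifest,
                        codebook = codebook),
                   class = "mf_run")
  if (!is.null(output_dir)) write_run(run, output_dir)
  run
}

#' @export
print.mf_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0("MERFISH run: %d replicate(s), %d molecules decoded, ",
                     "%d cells retained, %d HSC(s), bulk QC r = %.3f\n"),
              m$n_replicates, m$n_decoded_molecules, m$n_retained_cells,
              m$n_hscs, m$qc_r))
  invisible(x)
}

#' Write the result bundle of a run
#'
#' Writes every result table as TSV plus a JSON manifest into a directory.
#'
#' @param run A `mf_run`.
#' @param output_dir Directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_run <- function(run, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) utils::write.table(
    df, file.path(output_dir, paste0(name, ".tsv")), sep = "\t",
    quote = FALSE, row.names = FALSE)
  cm <- run$cellmatrix
  meta <- cm$cells
  meta$cluster <- run$clusters
  meta$type <- run$typing$type
  meta$is_hsc <- run$hsc_flags
  tsv(meta, "cells")
  tsv(data.frame(gene = cm$genes, total_count = colSums(cm$counts),
                 qc_pass = run$qc$qc_pass[cm$genes]), "genes")
  tsv(run$enrichment, "pair_enrichment")
  if (!is.null(run$composition)) tsv(run$composition, "niche_composition")
  if (!is.null(run$deg)) tsv(run$deg, "deg")
  if (!is.null(run$correlation) && nrow(run$correlation$records))
    tsv(run$correlation$records, "niche_correlations")
  if (!is.null(run$niches)) {
    pairs <- do.call(rbind, lapply(names(run$niches$members), function(h)
      if (length(run$niches$members[[h]]))
        data.frame(hsc_id = as.integer(h), member_id = run$niches$members[[h]])))
    if (!is.null(pairs)) tsv(pairs, "niche_members")
  }
  write_codebook(run$codebook, file.path(output_dir, "codebook.json"))
  jsonlite::write_json(run$manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}
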