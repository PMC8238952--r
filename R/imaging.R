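#' Estimate per-round stage drift from fiducial beads
#'
#' Cross-correlates each round's bead image against round 1 (the reference)
#' via FFT and returns the integer-pixel translation `(dx, dy)` that
#' maximises the correlation, with `x` = columns and `y` = rows. Offsets are
#' reported in the convention "round r image = reference shifted by
#' (dx, dy)", so subtracting the offset realigns a round to the reference.
#'
#' @param bead_images List of bead image matrices, one per imaging round;
#'   the first is the reference.
#' @return Integer matrix with one row per round and columns `dx`, `dy`;
#'   row 1 is `(0, 0)`.
#' @export
correct_drift <- function(bead_images) {
  if (length(bead_images) < 1) stop("need at least one bead image")
  ref <- bead_images[[1]]
  if (all(ref == ref[1])) stop("reference bead image is blank")
  Fref <- stats::fft(ref)
  out <- matrix(0L, length(bead_images), 2,
                dimnames = list(NULL, c("dx", "dy")))
  for (r in seq_along(bead_images)) {
    if (r == 1) next
    img <- bead_images[[r]]
    if (!all(dim(img) == dim(ref))) stop("bead image shape mismatch")
    if (all(img == img[1])) stop(sprintf("bead image for round %d is blank", r))
    cc <- Re(stats::fft(Conj(Fref) * stats::fft(img), inverse = TRUE))
    pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    dy <- pk[1] - 1L; dx <- pk[2] - 1L
    # unwrap: shifts beyond half the field are negative
    if (dy > nrow(ref) / 2) dy <- dy - nrow(ref)
    if (dx > ncol(ref) / 2) dx <- dx - ncol(ref)
    out[r, ] <- c(dx, dy)
  }
  out
}

#' Decode a drift-corrected bit stack into a molecule table
#'
#' Pixel-based decoding: each bit image is normalised by its own high
#' intensity quantile and binarised; every pixel's 16-bit on/off vector is
#' matched to the codebook allowing up to one bit error; adjacent pixels
#' decoding to the same gene are merged by 4-connected components into one
#' molecule at the component centroid (single-pixel components are kept).
#'
#' @param bit_stack List of 16 bit-image matrices (same shape).
#' @param codebook A `mf_codebook`.
#' @param threshold_quantile Quantile used both to normalise and to binarise
#'   each bit image (default 0.999); images whose quantile is 0 fall back to
#'   "any positive pixel is on".
#' @param offsets Optional per-round `(dx, dy)` matrix from [correct_drift()];
#'   each round is realigned by subtracting its offset before decoding.
#' @param pixel_size Pixel size in nanometres, to report positions in um.
#' @param fov_id Field-of-view identifier stored with each molecule.
#' @param max_errors Maximum correctable bit errors (0 or 1).
#' @return A `SpotTable` data frame: `gene`, `x_um`, `y_um`, `n_pixels`,
#'   `fov_id`.
#' @export
decode_image_stack <- function(bit_stack, codebook, threshold_quantile = 0.999,
                               offsets = NULL, pixel_size = 107.9,
                               fov_id = 1L, max_errors = 1L) {
  dims <- lapply(bit_stack, dim)
  if (length(unique(dims)) != 1) stop("bit images differ in shape")
  H <- dims[[1]][1]; W <- dims[[1]][2]
  n_bits <- length(bit_stack)
  um_per_px <- pixel_size / 1000

  bin <- matrix(FALSE, H * W, n_bits)
  for (b in seq_len(n_bits)) {
    img <- bit_stack[[b]]
    if (!is.null(offsets)) img <- shift_image(img, -offsets[b, 1], -offsets[b, 2])
    q <- stats::quantile(img, threshold_quantile, names = FALSE)
    bin[, b] <- if (q > 0) img >= q else img > 0
  }
  decoded <- decode_bit_rows(bin * 1L, codebook, max_errors = max_errors)
  hits <- which(!is.na(decoded))
  empty <- data.frame(gene = character(0), x_um = numeric(0), y_um = numeric(0),
                      n_pixels = integer(0), fov_id = integer(0))
  if (length(hits) == 0) return(empty)

  rows <- ((hits - 1L) %% H) + 1L
  cols <- ((hits - 1L) %/% H) + 1L
  out <- vector("list", 0)
  for (g in unique(decoded[hits])) {
    sel <- decoded[hits] == g
    comp <- label_components_4(rows[sel], cols[sel], H)
    cx <- tapply(cols[sel], comp, mean)
    cy <- tapply(rows[sel], comp, mean)
    np <- tabulate(comp)
    out[[length(out) + 1]] <- data.frame(
      gene = g, x_um = (as.numeric(cx) - 0.5) * um_per_px,
      y_um = (as.numeric(cy) - 0.5) * um_per_px,
      n_pixels = np, fov_id = as.integer(fov_id), stringsAsFactors = FALSE)
  }
  spots <- do.call(rbind, out)
  rownames(spots) <- NULL
  spots
}

# 4-connected components over a sparse set of (row, col) pixels; returns
# component id per pixel. Uses an igraph over adjacency edges.
label_components_4 <- function(rows, cols, H) {
  n <- length(rows)
  if (n == 0) return(integer(0))
  idx <- (cols - 1L) * H + rows
  pos <- match(idx, idx)  # identity; used for lookup below
  right <- match(idx + H, idx)
  down <- match(idx + 1L, idx)
  down[rows == H] <- NA  # don't wrap across column ends
  e <- rbind(cbind(seq_len(n), right), cbind(seq_len(n), down))
  e <- e[!is.na(e[, 2]), , drop = FALSE]
  if (nrow(e) == 0) return(seq_len(n))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  as.integer(igraph::components(g)$membership)
}

#' Segment cells by watershed on a membrane image
#'
#' Treats membrane intensity as topography: the image is inverted so cell
#' interiors become peaks, and a tolerance-based watershed (EBImage) grows
#' one region per intensity maximum deeper than `seed_depth`. Pixels where
#' adjacent regions meet are assigned to background (label 0), leaving a
#' ~1 px boundary line between cells. A constant image has no intensity
#' maxima to flood from and deterministically yields zero labels.
#'
#' @param membrane_image 2D numeric matrix.
#' @param seed_depth Minimum basin depth for a watershed seed (tolerance).
#' @param pixel_size Pixel size in nanometres (for centroid coordinates).
#' @param smooth_sigma Gaussian pre-smoothing bandwidth in pixels (default 3);
#'   suppresses shot-noise maxima that would seed spurious basins. Set to 0
#'   to disable.
#' @return A `mf_mask`: list with `labels` (integer matrix, 0 = background)
#'   and `cells` (data frame `id`, `area_px`, `x_um`, `y_um`), plus
#'   `pixel_size`.
#' @export
segment_cells <- function(membrane_image, seed_depth = 0.1, pixel_size = 107.9,
                          smooth_sigma = 2) {
  img <- membrane_image
  if (smooth_sigma > 0 && min(dim(img)) > 8 * smooth_sigma) {
    img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                             sigma = smooth_sigma))
  }
  inv <- max(img) - img
  ws <- EBImage::watershed(EBImage::Image(inv), tolerance = seed_depth, ext = 1)
  lab <- matrix(as.integer(EBImage::imageData(ws)), nrow(membrane_image))
  # carve boundaries: zero any pixel whose right/down neighbour has another label
  H <- nrow(lab); W <- ncol(lab)
  bnd <- matrix(FALSE, H, W)
  dv <- lab[-H, ] != lab[-1, ] & lab[-H, ] > 0L & lab[-1, ] > 0L
  bnd[-H, ][dv] <- TRUE
  dh <- lab[, -W] != lab[, -1] & lab[, -W] > 0L & lab[, -1] > 0L
  bnd[, -W][dh] <- TRUE
  lab[bnd] <- 0L
  new_mask(lab, pixel_size)
}

new_mask <- function(lab, pixel_size) {
  lab <- relabel_contiguous(lab)
  um_per_px <- pixel_size / 1000
  ids <- seq_len(max(lab, 0L))
  if (length(ids) && max(lab) > 0) {
    px <- which(lab > 0L)
    l <- lab[px]
    r <- ((px - 1L) %% nrow(lab)) + 1L
    c <- ((px - 1L) %/% nrow(lab)) + 1L
    cells <- data.frame(
      id = ids,
      area_px = as.integer(tabulate(l, nbins = length(ids))),
      x_um = as.numeric(tapply(c, factor(l, levels = ids), mean) - 0.5) * um_per_px,
      y_um = as.numeric(tapply(r, factor(l, levels = ids), mean) - 0.5) * um_per_px)
  } else {
    cells <- data.frame(id = integer(0), area_px = integer(0),
                        x_um = numeric(0), y_um = numeric(0))
  }
  structure(list(labels = lab, cells = cells, pixel_size = pixel_size),
            class = "mf_mask")
}

relabel_contiguous <- function(lab) {
  u <- sort(unique(lab[lab > 0L]))
  if (length(u) == 0) return(lab)
  lab[lab > 0L] <- match(lab[lab > 0L], u)
  lab
}

#' @export
print.mf_mask <- function(x, ...) {
  cat(sprintf("cell mask: %d labels over %dx%d px\n",
              nrow(x$cells), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Remove implausibly small or large segmented regions
#'
#' Regions smaller than `min_area` or larger than `max_area` pixels are set to
#' background; regions of exactly `min_area` or `max_area` pixels are kept
#' (strict inequalities). The defaults correspond to empty regions and
#' non-cell particles at a 107.9 nm pixel size.
#'
#' @param mask A `mf_mask`.
#' @param min_area,max_area Area bounds in pixels.
#' @return A filtered, relabelled `mf_mask`.
#' @export
filter_cells <- function(mask, min_area = 2500, max_area = 20000) {
  drop <- mask$cells$id[mask$cells$area_px < min_area |
                        mask$cells$area_px > max_area]
  drop_labels(mask, drop)
}

#' Remove cells touching the field-of-view edge
#'
#' Any label with a pixel in the first/last row or column is removed, since
#' such cells are only partially observed.
#'
#' @param mask A `mf_mask`.
#' @return A filtered, relabelled `mf_mask`.
#' @export
remove_edge_cells <- function(mask) {
  lab <- mask$labels
  edge <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  drop_labels(mask, setdiff(edge, 0L))
}

drop_labels <- function(mask, drop) {
  if (length(drop)) {
    lab <- mask$labels
    lab[lab %in% drop] <- 0L
    return(new_mask(lab, mask$pixel_size))
  }
  mask
}

#' Assign decoded molecules to segmented cells
#'
#' Each molecule is added to the count of the label under its centroid pixel;
#' molecules over background (label 0) are discarded.
#'
#' @param spots A `SpotTable` from [decode_image_stack()].
#' @param mask A `mf_mask` sharing the spot coordinate frame.
#' @param gene_names Gene panel defining the count matrix columns; defaults
#'   to the genes present in `spots`.
#' @return A `mf_cellmatrix`: list with `counts` (cells x genes integers),
#'   `cells` metadata (id, area_px, x_um, y_um, fov_id, replicate_id,
#'   genotype), `genes`, and `norm` (NULL until [normalize_cells()]).
#' @export
assign_spots <- function(spots, mask, gene_names = NULL) {
  if (is.null(gene_names)) gene_names <- sort(unique(spots$gene))
  um_per_px <- mask$pixel_size / 1000
  H <- nrow(mask$labels); W <- ncol(mask$labels)
  col <- pmin(W, pmax(1L, floor(spots$x_um / um_per_px) + 1L))
  row <- pmin(H, pmax(1L, floor(spots$y_um / um_per_px) + 1L))
  lab <- mask$labels[cbind(row, col)]
  keep <- lab > 0L & spots$gene %in% gene_names
  counts <- matrix(0L, nrow(mask$cells), length(gene_names),
                   dimnames = list(NULL, gene_names))
  if (any(keep)) {
    tab <- table(factor(lab[keep], levels = mask$cells$id),
                 factor(spots$gene[keep], levels = gene_names))
    counts[] <- as.integer(tab)
  }
  cells <- mask$cells
  cells$fov_id <- if (nrow(spots)) spots$fov_id[1] else 1L
  cells$replicate_id <- 1L
  cells$genotype <- "WT"
  new_cellmatrix(counts, cells, gene_names)
}

new_cellmatrix <- function(counts, cells, genes, norm = NULL) {
  structure(list(counts = counts, cells = cells, genes = genes, norm = norm),
            class = "mf_cellmatrix")
}

#' @export
print.mf_cellmatrix <- function(x, ...) {
  cat(sprintf("cell x gene matrix: %d cells, %d genes, %s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$norm)) "raw" else "normalised"))
  invisible(x)
}

#' Read / write image stacks as TIFF
#'
#' Thin wrappers over the `tiff` package for interoperating with real imaging
#' data; intensities are scaled to the unit range on write.
#'
#' @param paths Character vector of TIFF file paths.
#' @return `read_image_stack` returns a list of matrices.
#' @export
read_image_stack <- function(paths) {
  if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' required")
  lapply(paths, function(p) {
    x <- tiff::readTIFF(p)
    if (length(dim(x)) == 3) x <- x[, , 1]
    x
  })
}

#' @rdname read_image_stack
#' @param images List of image matrices.
#' @export
write_image_stack <- function(images, paths) {
  if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' required")
  for (i in seq_along(images)) {
    img <- images[[i]]
    m <- max(img)
    tiff::writeTIFF(if (m > 0) img / m else img, paths[i], bits.per.sample = 16)
  }
  invisible(paths)
}
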