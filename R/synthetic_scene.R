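#' Configuration for a synthetic tissue scene
#'
#' Describes a dense 2D tissue of contiguous cells: cell count and packing,
#' cell types with abundances and pairwise spatial affinities, a per-type mean
#' expression matrix with negative-binomial count noise, a rare
#' hematopoietic-stem-cell (HSC) type marked by Mecom and Kit, and the imaging
#' parameters (pixel size, per-bit spot dropout and false-positive rates,
#' per-round stage drift) used when rendering membrane / bit / bead images.
#'
#' Defaults emulate E14.5 fetal liver: eight major cell types plus a rare HSC
#' type, erythroid-dominated abundances, endothelial cells near 5% of the
#' population, and cells packed at roughly 10 um spacing.
#'
#' @param n_cells Number of cells.
#' @param field_size Field of view as `c(width, height)` in micrometres.
#' @param pixel_size Camera pixel size in nanometres (default 107.9).
#' @param min_separation Minimum centre-to-centre cell distance (um).
#' @param type_names Cell type labels.
#' @param type_fractions Expected type abundances (must sum to 1).
#' @param affinity Symmetric types x types matrix of pairwise log-attraction
#'   weights; 0 means spatially neutral.
#' @param mean_expression Types x genes matrix of expected molecule counts per
#'   cell; column names are the gene panel.
#' @param dispersion Negative-binomial size parameter (variance =
#'   mean + mean^2 / dispersion); `Inf` gives Poisson counts.
#' @param hsc_type_name Name of the rare stem-cell type.
#' @param spot_dropout_rate Probability that a true "on" bit of a molecule
#'   yields no spot in that bit image.
#' @param spot_false_positive_rate Per-pixel per-bit probability of a spurious
#'   spot.
#' @param drift_per_round Stage drift `c(dx, dy)` in pixels added per imaging
#'   round (cumulative).
#' @param n_beads Number of fiducial beads rendered for drift correction.
#' @param gibbs_sweeps Sweeps of the affinity (Potts-style) relabeling sampler.
#' @param seed Integer seed; the full scene is reproducible given the config.
#' @return A validated `mf_scene_config` list.
#' @export
scene_config <- function(n_cells = 150,
                         field_size = c(150, 150),
                         pixel_size = 107.9,
                         min_separation = 8,
                         type_names = NULL,
                         type_fractions = NULL,
                         affinity = NULL,
                         mean_expression = NULL,
                         dispersion = 10,
                         hsc_type_name = "HSC",
                         spot_dropout_rate = 0.05,
                         spot_false_positive_rate = 1e-6,
                         drift_per_round = c(0, 0),
                         n_beads = 40,
                         gibbs_sweeps = 20,
                         seed = 1L) {
  if (is.null(type_names)) type_names <- names(default_type_fractions())
  if (is.null(type_fractions)) {
    tf <- default_type_fractions()
    if (!all(type_names %in% names(tf))) {
      type_fractions <- rep(1 / length(type_names), length(type_names))
    } else type_fractions <- unname(tf[type_names])
  }
  if (is.null(affinity)) {
    affinity <- matrix(0, length(type_names), length(type_names),
                       dimnames = list(type_names, type_names))
  }
  if (is.null(mean_expression)) {
    mean_expression <- default_mean_expression(type_names)
  }
  cfg <- list(n_cells = as.integer(n_cells), field_size = field_size,
              pixel_size = pixel_size, min_separation = min_separation,
              type_names = type_names, type_fractions = type_fractions,
              affinity = affinity, mean_expression = mean_expression,
              dispersion = dispersion, hsc_type_name = hsc_type_name,
              spot_dropout_rate = spot_dropout_rate,
              spot_false_positive_rate = spot_false_positive_rate,
              drift_per_round = drift_per_round, n_beads = as.integer(n_beads),
              gibbs_sweeps = as.integer(gibbs_sweeps), seed = as.integer(seed))
  class(cfg) <- "mf_scene_config"
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  stopifnot(length(cfg$field_size) == 2, all(cfg$field_size > 0),
            cfg$pixel_size > 0, cfg$min_separation >= 0)
  if (abs(sum(cfg$type_fractions) - 1) > 1e-8) stop("type_fractions must sum to 1")
  if (length(cfg$type_fractions) != length(cfg$type_names))
    stop("type_fractions length mismatch")
  if (!isTRUE(all.equal(cfg$affinity, t(cfg$affinity))))
    stop("affinity matrix must be symmetric")
  if (any(cfg$mean_expression < 0)) stop("mean_expression must be non-negative")
  if (!all(rownames(cfg$mean_expression) == cfg$type_names))
    stop("mean_expression rows must match type_names")
  for (r in c(cfg$spot_dropout_rate, cfg$spot_false_positive_rate)) {
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  }
  invisible(cfg)
}

# fetal-liver-like type abundances: erythroid-dominated, endothelium ~5%,
# erythroid progenitors ~10%, HSCs rare
default_type_fractions <- function() {
  c(AEC = 0.02, SEC = 0.03, hepatocyte = 0.15, macrophage = 0.05,
    MK = 0.02, myeloid = 0.13, erythroid_progenitor = 0.10,
    erythroid = 0.498, HSC = 0.002)
}

#' Default marker panel
#'
#' Canonical marker genes per cell type used both by the expression simulator
#' and by marker-based cluster typing.
#' @return Named list mapping type label to marker gene names.
#' @export
default_marker_panel <- function() {
  list(
    AEC = c("Fstl1", "Pdgfra", "Notch3"),
    SEC = c("Flt4", "Stab2", "Lyve1"),
    hepatocyte = c("Alb", "Afp"),
    macrophage = c("Adgre1", "Csf1r"),
    MK = c("Pf4", "Itga2b"),
    myeloid = c("Mpo", "Elane"),
    erythroid_progenitor = c("Gata1", "Klf1"),
    erythroid = c("Hba-a1", "Gypa"),
    HSC = c("Mecom", "Kit")
  )
}

# marker genes high in their own type, low elsewhere, plus shared background
# genes; HSCs also express Kit (progenitor marker) as in vivo
default_mean_expression <- function(type_names) {
  panel <- default_marker_panel()
  if (!all(type_names %in% names(panel))) {
    genes <- paste0("gene", seq_len(3 * length(type_names)))
    M <- matrix(0.2, length(type_names), length(genes),
                dimnames = list(type_names, genes))
    for (i in seq_along(type_names)) M[i, (3 * i - 2):(3 * i)] <- 12
    return(M)
  }
  markers <- unique(unlist(panel[type_names]))
  background <- c("Actb", "Gapdh", "Ptma", "Npm1", "Eef1a1", "Rpl13")
  genes <- c(markers, background)
  M <- matrix(0.3, length(type_names), length(genes),
              dimnames = list(type_names, genes))
  M[, background] <- 6
  for (t in type_names) M[t, panel[[t]]] <- 15
  if ("HSC" %in% type_names && "Kit" %in% genes) M["HSC", "Kit"] <- 15
  if ("erythroid_progenitor" %in% type_names && "Kit" %in% genes)
    M["erythroid_progenitor", "Kit"] <- 8
  M
}

#' Sample non-overlapping cell centre positions
#'
#' Dart-throwing Poisson-disk sampling: uniform candidate positions are
#' accepted if at least `min_separation` from every accepted cell, using a
#' bucket grid for neighbour lookup.
#'
#' @param config A `mf_scene_config`.
#' @param max_tries Candidate draws per cell before giving up.
#' @return `n_cells` x 2 matrix of (x, y) positions in micrometres.
#' @export
sample_cell_positions <- function(config, max_tries = 200L) {
  n <- config$n_cells
  w <- config$field_size[1]; h <- config$field_size[2]
  s <- config$min_separation
  # disk-packing area bound (each accepted point excludes a radius-s/2 disk)
  if (n * pi * (s / 2)^2 > w * h) stop("infeasible packing: too many cells for field")
  with_local_seed(config$seed, {
    pos <- matrix(NA_real_, n, 2)
    cell_w <- max(s, 1e-6)
    nx <- max(1L, ceiling(w / cell_w)); ny <- max(1L, ceiling(h / cell_w))
    grid <- vector("list", nx * ny)
    gidx <- function(x, y) {
      ix <- pmin(nx, pmax(1L, ceiling(x / cell_w)))
      iy <- pmin(ny, pmax(1L, ceiling(y / cell_w)))
      (iy - 1L) * nx + ix
    }
    placed <- 0L
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        x <- runif(1, 0, w); y <- runif(1, 0, h)
        ix <- ceiling(x / cell_w); iy <- ceiling(y / cell_w)
        near <- integer(0)
        for (dx in -1:1) for (dy in -1:1) {
          jx <- ix + dx; jy <- iy + dy
          if (jx >= 1 && jx <= nx && jy >= 1 && jy <= ny)
            near <- c(near, grid[[(jy - 1L) * nx + jx]])
        }
        if (length(near) == 0 ||
            min((pos[near, 1] - x)^2 + (pos[near, 2] - y)^2) >= s^2) {
          placed <- placed + 1L
          pos[i, ] <- c(x, y)
          g <- gidx(x, y)
          grid[[g]] <- c(grid[[g]], i)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop(sprintf("could not place cell %d after %d tries", i, max_tries))
    }
    colnames(pos) <- c("x", "y")
    pos
  })
}

#' Assign cell types with pairwise spatial affinity
#'
#' Potts-style Gibbs relabeling on the 20-um neighbourhood graph:
#' after an independent initialisation from `type_fractions`, each sweep
#' revisits every cell and redraws its type with probability proportional to
#' `fraction_t * exp(sum over neighbours j of affinity[t, type_j])`.
#' With a zero affinity matrix, labels are independent draws from
#' `type_fractions`.
#'
#' @param positions Cell positions (um), as from [sample_cell_positions()].
#' @param config A `mf_scene_config`.
#' @param radius_um Interaction radius for the neighbourhood graph.
#' @return Character vector of per-cell type labels.
#' @export
assign_types_with_affinity <- function(positions, config, radius_um = 20) {
  n <- nrow(positions)
  tn <- config$type_names
  with_local_seed(config$seed + 1L, {
    types <- sample(tn, n, replace = TRUE, prob = config$type_fractions)
    if (all(config$affinity == 0) || config$gibbs_sweeps == 0L) return(types)
    g <- build_neighbor_graph(positions, radius_um = radius_um)
    nbr <- edge_adjacency_list(g, n)
    logf <- log(config$type_fractions)
    A <- config$affinity
    for (sweep in seq_len(config$gibbs_sweeps)) {
      for (i in seq_len(n)) {
        js <- nbr[[i]]
        if (length(js)) {
          cnt <- tabulate(match(types[js], tn), nbins = length(tn))
          logp <- logf + as.vector(A %*% cnt)
        } else logp <- logf
        p <- exp(logp - max(logp))
        types[i] <- sample(tn, 1, prob = p)
      }
    }
    types
  })
}

edge_adjacency_list <- function(graph_edges, n) {
  nbr <- vector("list", n)
  if (nrow(graph_edges)) {
    sp <- split(c(graph_edges$j, graph_edges$i), c(graph_edges$i, graph_edges$j))
    nbr[as.integer(names(sp))] <- sp
  }
  nbr
}

#' Sample per-cell gene counts
#'
#' Draws counts from a negative binomial with type-specific means from
#' `mean_expression` and the configured dispersion (`Inf` gives Poisson).
#'
#' @param types Per-cell type labels.
#' @param config A `mf_scene_config`.
#' @return Cells x genes integer matrix.
#' @export
sample_expression <- function(types, config) {
  M <- config$mean_expression
  if (!all(types %in% rownames(M))) stop("mean_expression missing some types")
  mu <- M[types, , drop = FALSE]
  with_local_seed(config$seed + 2L, {
    counts <-
      if (is.infinite(config$dispersion)) rpois(length(mu), lambda = mu)
      else rnbinom(length(mu), mu = mu, size = config$dispersion)
    counts <- matrix(as.integer(counts), nrow(mu), ncol(mu),
                     dimnames = list(NULL, colnames(M)))
    counts
  })
}

#' Render a scene into membrane, bit-stack and bead images
#'
#' Cell territories are the Voronoi cells of the sampled centres. The
#' membrane channel shows bright ridges (width ~2 px) along territory
#' boundaries. Each molecule is placed uniformly inside its cell's territory
#' and contributes a Gaussian spot to every bit image where its gene's barcode
#' is 1, with independent per-molecule-per-bit dropout; per-pixel false
#' positives are added at the configured rate. Each imaging round (one per
#' bit) is translated by the cumulative stage drift, as is the fiducial-bead
#' channel.
#'
#' @param positions,types,counts As produced by the sampling steps.
#' @param config A `mf_scene_config`.
#' @param codebook A `mf_codebook` covering all genes in `counts`.
#' @return A `mf_scene` list: `positions`, `types`, `counts`, `molecules`
#'   (data frame gene/x_um/y_um/cell), `territory` (true label image),
#'   `membrane`, `bit_stack` (list of 16 matrices), `bead_stack`, `config`,
#'   `codebook`.
#' @export
render_scene <- function(positions, types, counts, config, codebook) {
  genes <- colnames(counts)
  if (!all(genes %in% codebook$name)) stop("codebook does not cover all genes")
  px_nm <- config$pixel_size
  um_per_px <- px_nm / 1000
  W <- max(2L, as.integer(round(config$field_size[1] / um_per_px)))
  H <- max(2L, as.integer(round(config$field_size[2] / um_per_px)))

  with_local_seed(config$seed + 3L, {
    # territory image: nearest centre per pixel (1-NN; seeded because exact
    # ties are broken at random); matrix is rows=y, cols=x
    ctr_px <- cbind(positions[, 1] / um_per_px, positions[, 2] / um_per_px)
    gx <- (seq_len(W) - 0.5); gy <- (seq_len(H) - 0.5)
    pix <- cbind(rep(gx, each = H), rep(gy, times = W))
    lab <- as.integer(class::knn1(ctr_px, pix, factor(seq_len(nrow(positions)))))
    territory <- matrix(lab, H, W)

    # membrane ridges: pixels whose 4-neighbour has a different label
    membrane_mask <- boundary_mask(territory)
    B <- barcode_matrix(codebook)[genes, , drop = FALSE]
    n_bits <- ncol(B)

    membrane <- matrix(0.1, H, W) + matrix(abs(rnorm(H * W, 0, 0.02)), H, W)
    membrane[membrane_mask] <- 1 + rnorm(sum(membrane_mask), 0, 0.05)

    # molecules: uniform over each cell's territory pixels
    pix_by_cell <- split(seq_len(H * W), lab)
    mol_cell <- rep(seq_len(nrow(counts)), rowSums(counts))
    mol_gene <- unlist(lapply(seq_len(nrow(counts)), function(i)
      rep.int(genes, counts[i, ])), use.names = FALSE)
    keep <- !is.na(match(as.character(mol_cell), names(pix_by_cell)))
    mol_cell <- mol_cell[keep]; mol_gene <- mol_gene[keep]
    mol_pix <- vapply(mol_cell, function(i) {
      px <- pix_by_cell[[as.character(i)]]
      px[sample.int(length(px), 1)]
    }, integer(1))
    mol_row <- ((mol_pix - 1L) %% H) + 1L
    mol_col <- ((mol_pix - 1L) %/% H) + 1L
    molecules <- data.frame(
      gene = mol_gene,
      x_um = (mol_col - 0.5) * um_per_px,
      y_um = (mol_row - 0.5) * um_per_px,
      cell = mol_cell, stringsAsFactors = FALSE)

    bit_of_mol <- B[match(mol_gene, genes), , drop = FALSE]
    bit_stack <- vector("list", n_bits)
    for (b in seq_len(n_bits)) {
      img <- matrix(0, H, W)
      on <- which(bit_of_mol[, b] == 1L)
      if (length(on)) {
        lit <- on[runif(length(on)) >= config$spot_dropout_rate]
        img <- add_gaussian_spots(img, mol_row[lit], mol_col[lit],
                                  sigma = 1, amplitude = 1)
      }
      n_fp <- rbinom(1, H * W, config$spot_false_positive_rate)
      if (n_fp > 0) {
        fp <- sample.int(H * W, n_fp)
        img <- add_gaussian_spots(img, ((fp - 1L) %% H) + 1L,
                                  ((fp - 1L) %/% H) + 1L, sigma = 1, amplitude = 1)
      }
      shift <- round((b - 1L) * config$drift_per_round)
      bit_stack[[b]] <- shift_image(img, shift[1], shift[2])
    }

    bead_base <- matrix(0, H, W)
    bead_r <- sample.int(H, config$n_beads, replace = TRUE)
    bead_c <- sample.int(W, config$n_beads, replace = TRUE)
    bead_base <- add_gaussian_spots(bead_base, bead_r, bead_c,
                                    sigma = 1.2, amplitude = 2)
    bead_stack <- lapply(seq_len(n_bits), function(b) {
      shift <- round((b - 1L) * config$drift_per_round)
      shift_image(bead_base, shift[1], shift[2])
    })

    scene <- list(positions = positions, types = types, counts = counts,
                  molecules = molecules, territory = territory,
                  membrane = membrane, bit_stack = bit_stack,
                  bead_stack = bead_stack, config = config, codebook = codebook)
    class(scene) <- "mf_scene"
    scene
  })
}

# pixels adjacent (4-connectivity) to a different territory label, widened to
# ~2 px by marking both sides of every label change
boundary_mask <- function(territory) {
  H <- nrow(territory); W <- ncol(territory)
  m <- matrix(FALSE, H, W)
  dv <- territory[-H, ] != territory[-1, ]
  m[-H, ][dv] <- TRUE; m[-1, ][dv] <- TRUE
  dh <- territory[, -W] != territory[, -1]
  m[, -W][dh] <- TRUE; m[, -1][dh] <- TRUE
  m
}

# stamp unit-height Gaussian kernels centred at (rows, cols) onto img
add_gaussian_spots <- function(img, rows, cols, sigma = 1, amplitude = 1) {
  if (length(rows) == 0) return(img)
  r <- max(1L, ceiling(2.5 * sigma))
  off <- -r:r
  kern <- amplitude * exp(-(outer(off^2, off^2, "+")) / (2 * sigma^2))
  H <- nrow(img); W <- ncol(img)
  for (k in seq_along(rows)) {
    rr <- rows[k] + off; cc <- cols[k] + off
    rok <- rr >= 1 & rr <= H; cok <- cc >= 1 & cc <= W
    img[rr[rok], cc[cok]] <- img[rr[rok], cc[cok]] + kern[rok, cok]
  }
  img
}

# translate an image by (dx, dy) pixels (x = columns, y = rows), zero fill
shift_image <- function(img, dx, dy) {
  dx <- as.integer(round(dx)); dy <- as.integer(round(dy))
  if (dx == 0 && dy == 0) return(img)
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  src_r <- seq_len(H) - dy; src_c <- seq_len(W) - dx
  rok <- src_r >= 1 & src_r <= H; cok <- src_c >= 1 & src_c <= W
  out[rok, cok] <- img[src_r[rok], src_c[cok]]
  out
}

#' Simulate a complete ground-truth scene
#'
#' Convenience wrapper running position sampling, affinity-aware type
#' assignment, count sampling and image rendering under one config.
#'
#' @param config A `mf_scene_config`.
#' @param codebook Optional `mf_codebook`; by default one is built over the
#'   config's gene panel.
#' @return A `mf_scene` (see [render_scene()]).
#' @export
simulate_scene <- function(config = scene_config(), codebook = NULL) {
  if (is.null(codebook)) {
    codebook <- build_mhd4_codebook(colnames(config$mean_expression),
                                    seed = config$seed)
  }
  pos <- sample_cell_positions(config)
  types <- assign_types_with_affinity(pos, config)
  counts <- sample_expression(types, config)
  render_scene(pos, types, counts, config, codebook)
}

#' @export
print.mf_scene <- function(x, ...) {
  cat(sprintf("MERFISH scene: %d cells, %d genes, %d molecules, %dx%d px\n",
              nrow(x$positions), ncol(x$counts), nrow(x$molecules),
              nrow(x$membrane), ncol(x$membrane)))
  invisible(x)
}
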