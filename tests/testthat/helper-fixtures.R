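# shared fixtures built in code

tiny_codebook <- function(genes = paste0("g", 1:12), seed = 1) {
  build_mhd4_codebook(genes, seed = seed)
}

# small scene config used across imaging tests; balanced types keep every
# cluster populated at low cell numbers
small_scene_config <- function(n_cells = 40, field = 80, seed = 3, ...) {
  tn <- c("AEC", "SEC", "hepatocyte", "macrophage", "MK", "myeloid",
          "erythroid_progenitor", "erythroid", "HSC")
  scene_config(n_cells = n_cells, field_size = c(field, field),
               type_names = tn, type_fractions = rep(1 / 9, 9),
               seed = seed, ...)
}

# brute-force pair-proximity oracle: all-pairs distances, direct probability
# computation; mirrors the documented null model independently of the
# package's grid-indexed implementation
brute_pair_enrichment <- function(pos, types, radius = 20,
                                  include_self = TRUE) {
  n <- nrow(pos)
  tl <- sort(unique(types))
  f <- as.numeric(table(factor(types, levels = tl))) / n
  edges <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((pos[i, ] - pos[j, ])^2)) < radius) {
      edges <- rbind(edges, c(i, j))
    }
  }
  ta <- types[edges[, 1]]; tb <- types[edges[, 2]]
  if (!include_self) {
    keep <- ta != tb
    ta <- ta[keep]; tb <- tb[keep]
  }
  total <- length(ta)
  out <- NULL
  for (a in seq_along(tl)) for (b in a:length(tl)) {
    if (!include_self && a == b) next
    obs <- sum((ta == tl[a] & tb == tl[b]) | (ta == tl[b] & tb == tl[a]))
    pe <- if (a == b) f[a]^2 else 2 * f[a] * f[b]
    if (!include_self) pe <- pe / (1 - sum(f^2))
    out <- rbind(out, data.frame(type_a = tl[a], type_b = tl[b],
                                 observed_pairs = obs,
                                 expected_probability = pe,
                                 log2_enrichment = log2((obs / total) / pe)))
  }
  out
}
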