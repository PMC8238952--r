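test_that("neighbour graph uses a strict 20-um radius", {
  pos <- rbind(c(0, 0), c(19.9, 0), c(100, 100), c(100, 120))
  g <- build_neighbor_graph(pos)
  expect_equal(nrow(g), 1)
  expect_equal(c(g$i, g$j), c(1, 2))
  # exactly 20 um apart: no edge; three collinear cells at 0/10/20: 2 edges
  line <- cbind(c(0, 10, 20), 0)
  g2 <- build_neighbor_graph(line)
  expect_equal(nrow(g2), 2)
  expect_equal(nrow(build_neighbor_graph(pos, radius_um = 0)), 0)
})

test_that("grid-indexed graph matches brute force on random scenes", {
  set.seed(50)
  for (rep in 1:5) {
    n <- 300
    pos <- cbind(runif(n, 0, 150), runif(n, 0, 150))
    g <- build_neighbor_graph(pos)
    d <- as.matrix(dist(pos))
    truth <- which(d < 20 & upper.tri(d), arr.ind = TRUE)
    expect_equal(nrow(g), nrow(truth))
    got <- paste(g$i, g$j)
    want <- paste(pmin(truth[, 1], truth[, 2]), pmax(truth[, 1], truth[, 2]))
    expect_setequal(got, want)
  }
})

test_that("pair enrichment reproduces the hand-computed collinear example", {
  pos <- cbind(c(0, 10, 20), 0)
  types <- c("A", "B", "A")
  enr <- pair_enrichment(build_neighbor_graph(pos), types)
  ab <- enr[enr$type_a == "A" & enr$type_b == "B", ]
  expect_equal(ab$observed_pairs, 2L)
  expect_equal(ab$observed_probability, 1)
  expect_equal(ab$expected_probability, 4 / 9)
  expect_equal(ab$log2_enrichment, log2(9 / 4))
})

test_that("pair enrichment equals the brute-force oracle on small scenes", {
  set.seed(60)
  for (rep in 1:5) {
    n <- 40
    pos <- cbind(runif(n, 0, 60), runif(n, 0, 60))
    types <- sample(c("A", "B", "C"), n, replace = TRUE)
    for (self in c(TRUE, FALSE)) {
      got <- pair_enrichment(build_neighbor_graph(pos), types,
                             include_self_pairs = self)
      want <- brute_pair_enrichment(pos, types, include_self = self)
      m <- merge(got, want, by = c("type_a", "type_b"),
                 suffixes = c("", ".oracle"))
      expect_equal(nrow(m), nrow(got))
      expect_equal(m$observed_pairs, m$observed_pairs.oracle)
      expect_equal(m$expected_probability, m$expected_probability.oracle,
                   tolerance = 1e-12)
      expect_equal(m$log2_enrichment, m$log2_enrichment.oracle,
                   tolerance = 1e-12)
    }
  }
})

test_that("expected pair probabilities are a proper distribution", {
  set.seed(61)
  pos <- cbind(runif(200, 0, 100), runif(200, 0, 100))
  types <- sample(c("A", "B", "C", "D"), 200, replace = TRUE)
  g <- build_neighbor_graph(pos)
  full <- pair_enrichment(g, types, include_self_pairs = TRUE)
  expect_equal(sum(full$expected_probability), 1, tolerance = 1e-12)
  noself <- pair_enrichment(g, types, include_self_pairs = FALSE)
  expect_equal(sum(noself$expected_probability), 1, tolerance = 1e-12)
  expect_false(any(noself$type_a == noself$type_b))
  expect_equal(sum(full$observed_pairs), nrow(g))
})

test_that("FDR of pair enrichment is controlled under the independent null", {
  rates <- vapply(1:20, function(seed) {
    set.seed(200 + seed)
    n <- 1500
    pos <- cbind(runif(n, 0, 600), runif(n, 0, 600))
    types <- sample(paste0("t", 1:5), n, replace = TRUE)
    enr <- pair_enrichment(build_neighbor_graph(pos), types)
    mean(enr$fdr_q < 0.01, na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(rates), 0.01)
})

test_that("zero-cell types are reported as undefined rather than dropped", {
  pos <- cbind(c(0, 5, 10), 0)
  types <- factor(c("A", "A", "B"), levels = c("A", "B", "C"))
  g <- build_neighbor_graph(pos)
  enr <- pair_enrichment(g, as.character(types))
  expect_false(any(enr$type_a == "C" | enr$type_b == "C"))
  # with an explicit all-type table via factor levels, keep NA convention:
  enr2 <- pair_enrichment(g, c("A", "A", "B"))
  expect_true(all(!is.na(enr2$log2_enrichment)))
})

test_that("reproducibility flags require 3 significant replicates", {
  base <- data.frame(type_a = c("A", "A"), type_b = c("A", "B"))
  mk <- function(q1, q2, l1 = 1, l2 = 1) {
    cbind(base, chi2_p = c(q1, q2), fdr_q = c(q1, q2),
          log2_enrichment = c(l1, l2))
  }
  tabs <- list(mk(0.001, 0.001), mk(0.001, 0.02), mk(0.005, 0.001),
               mk(0.2, 0.001))
  rep_flags <- reproducible_enrichments(tabs)
  expect_equal(rep_flags$reproducible, c(TRUE, TRUE))
  # significant in only 2 of 4
  tabs2 <- list(mk(0.001, 0.5), mk(0.001, 0.5), mk(0.5, 0.5), mk(0.5, 0.5))
  expect_equal(reproducible_enrichments(tabs2)$reproducible, c(FALSE, FALSE))
  # P = 0.02 everywhere misses the 0.01 bar
  tabs3 <- rep(list(mk(0.02, 0.02)), 4)
  expect_equal(reproducible_enrichments(tabs3)$reproducible, c(FALSE, FALSE))
  # negative enrichment never counts
  tabs4 <- rep(list(mk(0.001, 0.001, l1 = -2, l2 = -2)), 4)
  expect_equal(reproducible_enrichments(tabs4)$reproducible, c(FALSE, FALSE))
  expect_error(reproducible_enrichments(tabs[1:2]), "fewer replicate")
})

test_that("niches contain strictly-within-radius cells, excluding the HSC", {
  pos <- rbind(c(0, 0), c(10, 0), c(25, 0), c(3, 0), c(100, 100))
  hsc <- c(TRUE, FALSE, FALSE, TRUE, FALSE)
  ns <- define_niches(hsc, pos)
  expect_equal(ns$members[["1"]], c(2, 4))
  expect_equal(ns$members[["4"]], c(1, 2))  # two HSCs see each other
  expect_setequal(ns$niche_cells, c(1, 2, 4))
  expect_equal(ns$non_niche_cells, c(3, 5))
  # isolated HSC has an empty niche
  iso <- define_niches(c(FALSE, FALSE, FALSE, FALSE, TRUE), pos)
  expect_equal(length(iso$members[["5"]]), 0)
  # permutation of cell order permutes memberships consistently
  perm <- c(3, 1, 5, 2, 4)
  ns_p <- define_niches(hsc[perm], pos[perm, ])
  orig_sets <- lapply(ns$members, function(m) sort(match(m, perm)))
  perm_sets <- lapply(ns_p$members, sort)
  expect_setequal(unname(perm_sets), unname(orig_sets))
})

test_that("niche composition reproduces published contingency statistics", {
  # synthesise labels so that niche vs overall counts match the published
  # tables, then verify the chi-square P values
  wt <- chi2_2x2_yates(21, 254 - 21, 5876, 112392 - 5876)
  expect_equal(round(wt$p, 4), 0.0422)
  # through the niche_composition interface on a small constructed scene
  pos <- rbind(c(0, 0), c(5, 0), c(10, 0), c(15, 0), c(60, 0), c(70, 0))
  hsc <- c(TRUE, rep(FALSE, 5))
  types <- c("HSC", "EC", "EC", "ery", "EC", "ery")
  ns <- define_niches(hsc, pos)
  comp <- niche_composition(ns, types)
  ec <- comp[comp$type == "EC", ]
  expect_equal(ec$n_niche, 2L)       # cells at 5 and 10 um
  expect_equal(ec$niche_total, 3L)
  expect_equal(ec$n_overall, 3L)
  # identical proportions: statistic near zero
  flat <- niche_composition(ns, rep(c("x", "y"), 3))
  expect_true(all(flat$chi2_p > 0.5, na.rm = TRUE))
  expect_error(niche_composition(list(niche_cells = integer(0)), types),
               "empty")
})

test_that("contact fractions follow the dilation-overlap rule", {
  lab <- matrix(0L, 30, 60)
  lab[5:15, 5:15] <- 1L
  lab[5:15, 16:26] <- 2L    # shares a boundary with 1
  lab[5:15, 40:50] <- 3L    # far from everything
  mask <- merfishniche:::new_mask(lab, 1000)
  expect_equal(contact_fraction(mask, 1, 2), 1.0)
  expect_equal(contact_fraction(mask, 1, 3), 0.0)
  expect_equal(contact_fraction(mask, c(1, 3), 2), 0.5)
  # separated by > 2 px of background: no contact even at dilation 2
  lab2 <- matrix(0L, 20, 20)
  lab2[2:8, 2:8] <- 1L
  lab2[2:8, 13:19] <- 2L
  mask2 <- merfishniche:::new_mask(lab2, 1000)
  expect_equal(contact_fraction(mask2, 1, 2, dilate_px = 2), 0.0)
  expect_error(contact_fraction(mask, integer(0), 2), "empty")
})

test_that("every stem cell seeded adjacent to an endothelial cell touches one", {
  # checkerboard of HSC/EC squares sharing boundaries
  lab <- matrix(0L, 40, 40)
  ids <- 0L
  for (r in 0:3) for (c in 0:3) {
    ids <- ids + 1L
    lab[(r * 10 + 1):(r * 10 + 10), (c * 10 + 1):(c * 10 + 10)] <- ids
  }
  mask <- merfishniche:::new_mask(lab, 1000)
  hsc_ids <- which(seq_len(16) %% 2 == 1)
  ec_ids <- which(seq_len(16) %% 2 == 0)
  expect_equal(contact_fraction(mask, hsc_ids, ec_ids), 1.0)
})
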