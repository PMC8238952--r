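test_that("drift correction recovers planted integer translations", {
  set.seed(1)
  ref <- matrix(0, 120, 120)
  ref <- merfishniche:::add_gaussian_spots(
    ref, sample(20:100, 25), sample(20:100, 25), sigma = 1.2, amplitude = 2)
  shifted <- merfishniche:::shift_image(ref, 3, -2)
  off <- correct_drift(list(ref, shifted))
  expect_equal(off[1, ], c(dx = 0, dy = 0))
  expect_equal(off[2, ], c(dx = 3, dy = -2))
  # cumulative shifts
  off3 <- correct_drift(list(ref, merfishniche:::shift_image(ref, 0, 5),
                             merfishniche:::shift_image(ref, 0, 10)))
  expect_equal(off3[, "dy"], c(0, 5, 10))
  # identical images: all zero
  expect_true(all(correct_drift(list(ref, ref, ref)) == 0))
  # large shifts up to a quarter of the field
  off4 <- correct_drift(list(ref, merfishniche:::shift_image(ref, 30, -30)))
  expect_equal(off4[2, ], c(dx = 30, dy = -30))
  expect_error(correct_drift(list(matrix(0, 5, 5))), "blank")
})

test_that("noiseless scenes decode nearly perfectly with accurate positions", {
  cfg <- small_scene_config(n_cells = 20, field = 60, seed = 12,
                            spot_dropout_rate = 0, spot_false_positive_rate = 0)
  sc <- simulate_scene(cfg)
  spots <- decode_image_stack(sc$bit_stack, sc$codebook,
                              pixel_size = cfg$pixel_size)
  expect_gte(nrow(spots) / nrow(sc$molecules), 0.99)
  # each decoded molecule sits within 2 px of a true molecule of that gene
  um <- cfg$pixel_size / 1000
  ok <- vapply(seq_len(nrow(spots)), function(k) {
    tr <- sc$molecules[sc$molecules$gene == spots$gene[k], ]
    nrow(tr) > 0 && min(sqrt((tr$x_um - spots$x_um[k])^2 +
                             (tr$y_um - spots$y_um[k])^2)) <= 2 * um
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})

test_that("one fully dropped bit image is rescued by error correction", {
  cfg <- small_scene_config(n_cells = 10, field = 40, seed = 13,
                            spot_dropout_rate = 0, spot_false_positive_rate = 0)
  sc <- simulate_scene(cfg)
  stack <- sc$bit_stack
  stack[[4]][] <- 0
  spots <- decode_image_stack(stack, sc$codebook, pixel_size = cfg$pixel_size)
  B <- barcode_matrix(sc$codebook)
  affected <- rownames(B)[B[, 4] == 1]
  n_true <- sum(sc$molecules$gene %in% affected)
  n_rec <- sum(spots$gene %in% affected)
  expect_gte(n_rec / n_true, 0.9)
  # empty stack decodes to an empty table
  empty <- lapply(1:16, function(i) matrix(0, 30, 30))
  expect_equal(nrow(decode_image_stack(empty, sc$codebook)), 0)
  bad <- stack; bad[[2]] <- matrix(0, 3, 3)
  expect_error(decode_image_stack(bad, sc$codebook), "shape")
})

test_that("decoding corrects for planted drift when offsets are supplied", {
  cfg <- small_scene_config(n_cells = 10, field = 40, seed = 14,
                            spot_dropout_rate = 0, spot_false_positive_rate = 0,
                            drift_per_round = c(1, -1))
  sc <- simulate_scene(cfg)
  off <- correct_drift(sc$bead_stack)
  expect_equal(off[2, ], c(dx = 1, dy = -1))
  expect_equal(off[16, ], c(dx = 15, dy = -15))
  spots <- decode_image_stack(sc$bit_stack, sc$codebook, offsets = off,
                              pixel_size = cfg$pixel_size)
  expect_gte(nrow(spots) / nrow(sc$molecules), 0.9)
  # without correction decoding mostly fails
  uncorrected <- decode_image_stack(sc$bit_stack, sc$codebook,
                                    pixel_size = cfg$pixel_size)
  expect_lt(nrow(uncorrected), 0.3 * nrow(sc$molecules))
})

test_that("watershed recovers rendered cells and their centroids", {
  cfg <- small_scene_config(n_cells = 2, field = 25, seed = 15)
  sc <- simulate_scene(cfg)
  mask <- segment_cells(sc$membrane, pixel_size = cfg$pixel_size)
  expect_equal(nrow(mask$cells), 2)
  for (i in 1:2) {
    lab_at_center <- mask$labels[round(sc$positions[i, 2] / 0.1079),
                                 round(sc$positions[i, 1] / 0.1079)]
    expect_gt(lab_at_center, 0)
  }
  # constant image: no seeds, zero labels (documented degenerate behaviour)
  flat <- segment_cells(matrix(1, 50, 50))
  expect_equal(nrow(flat$cells), 0)
  # larger scene: label count within 5%, centroid error < 3 um
  cfg2 <- small_scene_config(n_cells = 100, field = 120, seed = 16)
  sc2 <- simulate_scene(cfg2)
  mask2 <- segment_cells(sc2$membrane, pixel_size = cfg2$pixel_size)
  expect_lte(abs(nrow(mask2$cells) - 100), 5)
  err <- vapply(seq_len(nrow(mask2$cells)), function(i) {
    min(sqrt((sc2$positions[, 1] - mask2$cells$x_um[i])^2 +
             (sc2$positions[, 2] - mask2$cells$y_um[i])^2))
  }, numeric(1))
  expect_lt(mean(err), 3)
})

test_that("area filter applies strict inequalities at both bounds", {
  lab <- matrix(0L, 260, 460)
  lab[2:51, 2:51] <- 1L            # 2500 px: retained
  lab[2:49, 61:110] <- 2L          # 2400 px: removed
  lab[61:210, 61:194] <- 3L        # 20100 px: removed
  lab[61:160, 201:211] <- 4L       # 1100 px: removed
  lab[170:219, 221:260] <- 5L      # 2000 px: removed
  lab[2:101, 281:340] <- 6L        # 6000 px: retained
  mask <- merfishniche:::new_mask(lab, 107.9)
  filt <- filter_cells(mask)
  expect_equal(sort(filt$cells$area_px), c(2500, 6000))
  # idempotent
  expect_equal(filter_cells(filt)$cells, filt$cells)
})

test_that("edge-cell removal drops labels touching any border", {
  lab <- matrix(0L, 40, 40)
  lab[1:5, 10:14] <- 1L      # touches top row
  lab[20:24, 1:4] <- 2L      # touches left column
  lab[15:19, 15:19] <- 3L    # interior
  lab[36:40, 30:34] <- 4L    # touches bottom row
  mask <- merfishniche:::new_mask(lab, 107.9)
  kept <- remove_edge_cells(mask)
  expect_equal(nrow(kept$cells), 1)
  expect_equal(kept$cells$area_px, 25L)
  # idempotent and total removal
  expect_equal(remove_edge_cells(kept)$cells, kept$cells)
  all_edge <- matrix(1L, 10, 10)
  expect_equal(nrow(remove_edge_cells(merfishniche:::new_mask(all_edge, 107.9))$cells), 0)
})

test_that("spot assignment counts molecules under their centroid label", {
  lab <- matrix(0L, 20, 20)
  lab[2:10, 2:10] <- 1L
  lab[12:19, 12:19] <- 2L
  mask <- merfishniche:::new_mask(lab, 1000)  # 1 um pixels
  spots <- data.frame(gene = c("a", "a", "b", "b"),
                      x_um = c(5, 5, 15, 0.2), y_um = c(5, 6, 15, 0.2),
                      n_pixels = 1L, fov_id = 1L)
  cm <- assign_spots(spots, mask, gene_names = c("a", "b"))
  expect_equal(cm$counts[1, ], c(a = 2L, b = 0L))
  expect_equal(cm$counts[2, ], c(a = 0L, b = 1L))
  # background molecule discarded: conservation with deficit
  expect_equal(sum(cm$counts), 3)
})

test_that("counts from a noiseless scene match ground truth closely", {
  cfg <- small_scene_config(n_cells = 25, field = 65, seed = 18,
                            spot_dropout_rate = 0, spot_false_positive_rate = 0)
  sc <- simulate_scene(cfg)
  spots <- decode_image_stack(sc$bit_stack, sc$codebook,
                              pixel_size = cfg$pixel_size)
  mask <- segment_cells(sc$membrane, pixel_size = cfg$pixel_size)
  cm <- assign_spots(spots, mask, gene_names = sc$codebook$name)
  expect_lte(sum(cm$counts), nrow(spots))
  # match each segmented cell to the nearest true cell and compare counts
  agree <- vapply(seq_len(nrow(cm$cells)), function(i) {
    tr <- which.min((sc$positions[, 1] - cm$cells$x_um[i])^2 +
                    (sc$positions[, 2] - cm$cells$y_um[i])^2)
    truth <- sc$counts[tr, colnames(cm$counts)]
    sum(pmin(cm$counts[i, ], truth)) / max(1, sum(truth))
  }, numeric(1))
  expect_gte(mean(agree), 0.95)
})
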