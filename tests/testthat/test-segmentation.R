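test_that("thresholding follows the strict full-scale convention", {
  zero <- matrix(0, 10, 10)
  expect_false(any(threshold_foreground(zero)))
  one_px <- matrix(0, 10, 10); one_px[5, 5] <- 1
  m <- threshold_foreground(one_px, threshold_config(min_region_px = 1))
  expect_equal(which(m), which(one_px == 1))
  at_thresh <- matrix(0.0196, 10, 10)
  expect_false(any(threshold_foreground(at_thresh)))  # strict >
  expect_error(threshold_foreground(matrix(NaN, 2, 2)), "non-finite")
})

test_that("raising the threshold never adds foreground pixels", {
  withr::with_seed(42, {
    for (i in 1:5) {
      img <- matrix(runif(400), 20, 20)
      lo <- threshold_foreground(img, threshold_config(0.2))
      hi <- threshold_foreground(img, threshold_config(0.5))
      expect_true(all(lo | !hi))
    }
  })
})

test_that("debris smaller than min_region_px is removed", {
  img <- matrix(0, 20, 20)
  img[2, 2] <- 1                      # 1-px speck
  img[10:14, 10:14] <- 1              # 25-px block
  m <- threshold_foreground(img, threshold_config(min_region_px = 5))
  expect_false(m[2, 2])
  expect_equal(sum(m), 25)
})

test_that("nucleus detection recovers isolated noiseless nuclei", {
  sp <- scene_spec(image_shape = c(256, 256), n_nuclei = 3, noise_sd = 0,
                   seed = 7)
  sc <- generate_nuclei_scene(sp)
  det <- detect_nuclei(sc$image)
  expect_equal(nrow(det), 3)
  nuc <- sc$truth$nuclei[order(sc$truth$nuclei$row, sc$truth$nuclei$col), ]
  expect_true(all(abs(det$row - nuc$row) <= 2))
  expect_true(all(abs(det$col - nuc$col) <= 2))
  expect_equal(count_cells(sc$image), 3)

  flat <- matrix(0.05, 128, 128)
  expect_equal(nrow(detect_nuclei(flat)), 0)
  expect_equal(count_cells(flat), 0)
})

test_that("dense-scene detection has high recall and precision", {
  sp <- scene_spec(image_shape = c(1024, 1024), n_nuclei = 300,
                   noise_sd = 0.07, seed = 11)  # SNR = peak/noise = 10
  sc <- generate_nuclei_scene(sp)
  det <- detect_nuclei(sc$image)
  tr <- sc$truth$nuclei
  d2 <- outer(det$row, tr$row, "-")^2 + outer(det$col, tr$col, "-")^2
  hit <- d2 <= matrix(tr$radius, nrow(det), nrow(tr), byrow = TRUE)^2
  expect_gte(mean(apply(hit, 2, any)), 0.98)  # recall
  expect_gte(mean(apply(hit, 1, any)), 0.98)  # precision
})

test_that("under-segmentation is flagged by seed multiplicity", {
  m1 <- disc_mask(40, 60, 20, 15, 8) | disc_mask(40, 60, 20, 45, 8)
  lab <- label_regions(m1)
  seeds <- data.frame(nucleus_id = 1:2, row = c(20, 20), col = c(15, 45))
  expect_length(find_undersegmented(lab, seeds), 0)

  m2 <- disc_mask(40, 60, 20, 22, 10) | disc_mask(40, 60, 20, 34, 10)
  lab2 <- label_regions(m2)
  expect_equal(as.integer(find_undersegmented(
    lab2, data.frame(nucleus_id = 1:2, row = c(20, 20), col = c(22, 34)))),
    1L)
  # three seeds in one blob: flagged once
  expect_length(find_undersegmented(
    lab2, data.frame(nucleus_id = 1:3, row = c(20, 20, 20),
                     col = c(22, 28, 34))), 1)
  # a seed on background is recorded as unassigned, not an error
  res <- find_undersegmented(
    lab2, data.frame(nucleus_id = 1:2, row = c(0, 20), col = c(0, 28)))
  expect_equal(attr(res, "unassigned"), 1L)
})

test_that("flood fill splits touching discs at the perpendicular bisector", {
  mask <- disc_mask(30, 40, 14, 11, 10) | disc_mask(30, 40, 14, 24, 10)
  seeds <- data.frame(nucleus_id = 1:2, row = c(14, 14), col = c(11, 24))
  sp <- split_by_seeded_flood_fill(mask, seeds)
  expect_equal(nrow(sp$regions), 2)
  expect_equal(sum(sp$regions$area_px), sum(mask))
  # centers 13 apart (odd): on the center row the split falls at the
  # perpendicular bisector between columns 17/18 (0-based 16/17)
  ctr <- sp$labels[15, ][mask[15, ]]
  cols <- which(mask[15, ]) - 1L
  expect_true(all(ctr[cols <= 17] == 1))
  expect_true(all(ctr[cols >= 18] == 2))
  expect_identical(sp$labels, oracle_flood_fill(mask, seeds))
})

test_that("degenerate duplicate seeds are rejected", {
  mask <- disc_mask(20, 20, 10, 10, 6)
  seeds <- data.frame(nucleus_id = 1:2, row = c(10, 10), col = c(10, 10))
  expect_error(split_by_seeded_flood_fill(mask, seeds), "degenerate")
})

test_that("background seeds snap within 3 px or fail", {
  mask <- disc_mask(30, 30, 14, 14, 6)
  near <- data.frame(nucleus_id = 1, row = 14, col = 22)  # 2 px off the rim
  sp <- split_by_seeded_flood_fill(mask, near)
  expect_equal(nrow(sp$regions), 1)
  far <- data.frame(nucleus_id = 1, row = 0, col = 0)
  expect_error(split_by_seeded_flood_fill(mask, far), "3 px")
})

test_that("symmetric dumbbells split into equal halves with id tie-break", {
  # two 9x9 blocks joined by a 3-wide bridge; mirror-symmetric seeds
  mask <- matrix(FALSE, 21, 43)
  mask[6:14, 3:11] <- TRUE
  mask[6:14, 33:41] <- TRUE
  mask[9:11, 11:33] <- TRUE
  seeds <- data.frame(nucleus_id = 1:2, row = c(10, 10), col = c(6, 36))
  sp <- split_by_seeded_flood_fill(mask, seeds)
  a <- sp$regions$area_px
  # equidistant bridge column goes to the lower id
  expect_equal(a[1] - a[2], 3)
  expect_identical(sp$labels, oracle_flood_fill(mask, seeds))
})

test_that("flood fill equals the brute-force relaxation oracle", {
  for (i in 1:10) {
    mask <- random_blob_mask(100 + i)
    n_seeds <- 2 + (i %% 3)
    seeds <- sample_seeds_on_mask(mask, n_seeds, 200 + i)
    if (anyDuplicated(seeds[, c("row", "col")])) next
    sp <- split_by_seeded_flood_fill(mask, seeds)
    expect_identical(sp$labels, oracle_flood_fill(mask, seeds))
    # partition properties: exhaustive over reachable pixels, one seed each
    expect_equal(sum(sp$regions$area_px), sum(sp$labels > 0))
    on_seed <- sp$labels[cbind(seeds$row + 1L, seeds$col + 1L)]
    expect_equal(on_seed, seq_len(n_seeds))
  }
})

test_that("segment_cells splits merged pairs back into seeded regions", {
  sp <- scene_spec(image_shape = c(1500, 1500), noise_sd = 0,
                   overlap_fraction = 0.2, seed = 14)
  cs <- generate_cell_scene(sp, cell_shape_spec(n_round = 25,
                                                n_fibroblast = 25))
  seeds <- data.frame(nucleus_id = cs$truth$nuclei$nucleus_id,
                      row = cs$truth$nuclei$row,
                      col = cs$truth$nuclei$col)
  mask <- threshold_foreground(cs$cell_image)
  lab0 <- label_regions(mask)
  merged <- find_undersegmented(lab0, seeds)
  expect_gte(length(merged), 1)
  seg <- segment_cells(cs$cell_image, cs$nucleus_image)
  # every truth nucleus center ends up in its own region
  reg <- seg$labels[cbind(seeds$row + 1L, seeds$col + 1L)]
  expect_equal(length(unique(reg[reg > 0])), sum(reg > 0))
  expect_true(any(seg$regions$was_split))
})
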