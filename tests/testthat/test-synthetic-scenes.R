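test_that("noiseless nuclei scenes place local maxima at truth centers", {
  sp <- scene_spec(image_shape = c(256, 256), n_nuclei = 3, noise_sd = 0,
                   seed = 7)
  sc <- generate_nuclei_scene(sp)
  expect_equal(nrow(sc$truth$nuclei), 3)
  expect_true(all(sc$image >= 0 & sc$image <= 1))
  for (k in 1:3) {
    r <- sc$truth$nuclei$row[k] + 1L
    c <- sc$truth$nuclei$col[k] + 1L
    patch <- sc$image[(r - 2):(r + 2), (c - 2):(c + 2)]
    expect_equal(max(patch), sc$image[r, c])
  }
})

test_that("scene generation is bit-identical for identical seeds", {
  sp <- scene_spec(image_shape = c(128, 128), n_nuclei = 5, seed = 7)
  expect_identical(generate_nuclei_scene(sp), generate_nuclei_scene(sp))
  f1 <- generate_foci_scene(scene_spec(image_shape = c(256, 256),
                                       n_nuclei = 8, seed = 3),
                            foci_spec(foci_per_nucleus = 3))
  f2 <- generate_foci_scene(scene_spec(image_shape = c(256, 256),
                                       n_nuclei = 8, seed = 3),
                            foci_spec(foci_per_nucleus = 3))
  expect_identical(f1, f2)
})

test_that("large scenes keep all nucleus centers >= radius from border", {
  sp <- scene_spec(image_shape = c(2048, 2048), n_nuclei = 300, seed = 2)
  sc <- generate_nuclei_scene(sp)
  nuc <- sc$truth$nuclei
  expect_equal(nrow(nuc), 300)
  expect_true(all(nuc$row >= nuc$radius - 1 & nuc$col >= nuc$radius - 1))
  expect_true(all(nuc$row <= 2047 - nuc$radius + 1 &
                    nuc$col <= 2047 - nuc$radius + 1))
  expect_false(anyDuplicated(nuc[, c("row", "col")]) > 0)
})

test_that("infeasible nucleus packing raises a placement error", {
  sp <- scene_spec(image_shape = c(64, 64), n_nuclei = 50, seed = 1)
  expect_error(generate_nuclei_scene(sp), "placement error")
})

test_that("cell scene families are separable by true eccentricity", {
  sp <- scene_spec(image_shape = c(1400, 1400), noise_sd = 0, seed = 9)
  cs <- generate_cell_scene(sp, cell_shape_spec(n_round = 50,
                                                n_fibroblast = 50))
  cells <- cs$truth$cells
  expect_equal(sum(cells$family == "round"), 50)
  expect_true(max(cells$target_eccentricity[cells$family == "round"]) <
                min(cells$target_eccentricity[cells$family == "fibroblast"]))
})

test_that("cell scene foreground components match cells and merge pairs", {
  sp0 <- scene_spec(image_shape = c(1400, 1400), noise_sd = 0,
                    overlap_fraction = 0, seed = 4)
  cs0 <- generate_cell_scene(sp0, cell_shape_spec(n_round = 30,
                                                  n_fibroblast = 30))
  mask <- cs0$cell_image > 0.1
  expect_equal(max(label_regions(mask)), 60)

  sp2 <- scene_spec(image_shape = c(2048, 2048), noise_sd = 0,
                    overlap_fraction = 0.2, seed = 4)
  cs2 <- generate_cell_scene(sp2, cell_shape_spec(n_round = 50,
                                                  n_fibroblast = 50))
  lab <- label_regions(cs2$cell_image > 0.1)
  expect_equal(max(lab), 100 - 10)  # 10 touching pairs merge
  nuc <- cs2$truth$nuclei
  reg_of_nuc <- lab[cbind(nuc$row + 1L, nuc$col + 1L)]
  expect_equal(sum(table(reg_of_nuc) == 2), 10)
})

test_that("foci scenes honor counts, mitotic flags and containment", {
  sp <- scene_spec(image_shape = c(700, 700), n_nuclei = 20, noise_sd = 0,
                   seed = 8)
  fs <- generate_foci_scene(sp, foci_spec(foci_per_nucleus = 5,
                                          mitotic_fraction = 0))
  expect_equal(nrow(fs$truth$foci), 100)
  # every focus center lies inside its nucleus disc
  m <- merge(fs$truth$foci, fs$truth$nuclei, by = "nucleus_id")
  d <- sqrt((m$row.x - m$row.y)^2 + (m$col.x - m$col.y)^2)
  expect_true(all(d <= m$radius))

  fs0 <- generate_foci_scene(sp, foci_spec(foci_per_nucleus = 0))
  expect_equal(nrow(fs0$truth$foci), 0)
  expect_lt(max(fs0$foci_image), 0.1)  # background + noise only

  spm <- scene_spec(image_shape = c(1800, 1800), n_nuclei = 200,
                    noise_sd = 0.02, seed = 8)
  fsm <- generate_foci_scene(spm, foci_spec(foci_per_nucleus = 2,
                                            mitotic_fraction = 0.1))
  expect_equal(sum(fsm$truth$nuclei$is_mitotic), 20)
  mit_ids <- fsm$truth$nuclei$nucleus_id[fsm$truth$nuclei$is_mitotic]
  expect_equal(sum(fsm$truth$foci$nucleus_id %in% mit_ids), 0)
})

test_that("mitotic nuclei render bright and small versus interphase", {
  sp <- scene_spec(image_shape = c(1200, 1200), n_nuclei = 100,
                   noise_sd = 0, seed = 12)
  fs <- generate_foci_scene(sp, foci_spec(mitotic_fraction = 0.1))
  lab <- truth_nucleus_labels(fs$truth$nuclei, c(1200, 1200))
  rois <- nucleus_rois(lab, fs$dapi_image)
  mit <- fs$truth$nuclei$is_mitotic[rois$nucleus]
  expect_gte(min(rois$mean_intensity[mit]) /
               mean(rois$mean_intensity[!mit]), 2)
  expect_lte(max(rois$area_px[mit]) / mean(rois$area_px[!mit]), 0.5)
})

test_that("noiseless scene ground truth is recovered by ideal operators", {
  sp <- scene_spec(image_shape = c(512, 512), n_nuclei = 10, noise_sd = 0,
                   seed = 21)
  sc <- generate_nuclei_scene(sp)
  lab <- label_regions(sc$image > sp$background_level + 0.01)
  tab <- region_table(lab)
  expect_equal(nrow(tab), 10)
  # centroid of each connected component recovers the truth center
  nuc <- sc$truth$nuclei
  for (k in seq_len(nrow(tab))) {
    d <- sqrt((tab$centroid_row[k] - nuc$row)^2 +
                (tab$centroid_col[k] - nuc$col)^2)
    expect_lt(min(d), 1)
  }
})

test_that("dose-response generator matches the model closed form", {
  p <- ll4_params(b = 1.5, c = 0.05, d = 1, e = 0.317)
  tab <- generate_dose_response(p, c(0.02, 0.1, 0.317, 1, 10), 0, 2, 1)
  mid <- tab$viability[tab$dose_uM == 0.317]
  expect_equal(mid, rep((0.05 + 1) / 2, 2))   # 0.525 at x = e
  lo <- generate_dose_response(p, c(1e-8, 1), 0, 1, 1)
  expect_equal(lo$viability[1], 1, tolerance = 1e-6)  # x -> 0+ gives d
  expect_identical(generate_dose_response(p, c(1, 2, 4), 0.05, 3, 9),
                   generate_dose_response(p, c(1, 2, 4), 0.05, 3, 9))
  expect_error(generate_dose_response(p, c(2, 1), 0, 1, 1), "increasing")
})

test_that("growth generator doubles on schedule", {
  g <- generate_growth_counts(5000, 21, c(0, 21), 0, 1, 1)
  expect_equal(g$count, c(5000, 10000))
  g0 <- generate_growth_counts(5000, 26.5, c(0, 53), 0, 1, 1)
  expect_equal(g0$count, c(5000, 20000))
})

test_that("gel profiles split signal mass at the stated fraction", {
  lane0 <- generate_gel_profile(0, noise_sd = 0, baseline = 0, seed = 1)
  ws <- attr(lane0, "well_span")
  expect_equal(sum(lane0$intensity[lane0$position > ws[2]]), 0)
  lane5 <- generate_gel_profile(0.5, noise_sd = 0, baseline = 0, seed = 1)
  below <- sum(lane5$intensity[lane5$position > ws[2]])
  inside <- sum(lane5$intensity[lane5$position <= ws[2]])
  expect_equal(below, inside, tolerance = 1e-10)
})

test_that("wound pairs close by the stated fraction", {
  full <- generate_wound_pair(10000, 1)
  expect_equal(sum(!full$mask_t24), 0)
  none <- generate_wound_pair(10000, 0)
  expect_equal(sum(!none$mask_t0), sum(!none$mask_t24))
  part <- generate_wound_pair(10000, 0.6)
  expect_equal(sum(!part$mask_t0), 10000)
  expect_equal(sum(!part$mask_t24), 4000, tolerance = 0.01)
})
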