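make_foci_fixture <- function(n_nuclei = 30, foci_per_nucleus = 5,
                              mitotic_fraction = 0, noise_sd = 0.02,
                              seed = 5, shape = 600) {
  sp <- scene_spec(image_shape = c(shape, shape), n_nuclei = n_nuclei,
                   noise_sd = noise_sd, seed = seed)
  fs <- generate_foci_scene(sp, foci_spec(
    foci_per_nucleus = foci_per_nucleus,
    mitotic_fraction = mitotic_fraction))
  fs$labels <- truth_nucleus_labels(fs$truth$nuclei, c(shape, shape))
  fs
}

test_that("planted foci are counted exactly per nucleus", {
  fs <- make_foci_fixture()
  det <- detect_foci(fs$foci_image, fs$labels)
  counts <- table(factor(det$nucleus, levels = fs$truth$nuclei$nucleus_id))
  truth <- table(factor(fs$truth$foci$nucleus_id,
                        levels = fs$truth$nuclei$nucleus_id))
  expect_equal(as.integer(counts), as.integer(truth))
  # every reported focus lies inside its nucleus pixel set
  expect_true(all(fs$labels[cbind(det$row + 1L, det$col + 1L)] ==
                    det$nucleus))
})

test_that("flat-intensity nuclei yield zero foci", {
  labels <- matrix(0L, 80, 80)
  labels[30:50, 30:50] <- 1L
  flat <- matrix(0.3, 80, 80)
  det <- detect_foci(flat, labels)
  expect_equal(nrow(det), 0)
})

test_that("adding one planted focus increases the count by exactly one", {
  fs <- make_foci_fixture(n_nuclei = 10, foci_per_nucleus = 2, seed = 9,
                          shape = 400)
  det0 <- detect_foci(fs$foci_image, fs$labels)
  # plant one extra focus in some nucleus, >= 6 px from its existing foci
  pick <- NULL
  for (k in seq_len(nrow(fs$truth$nuclei))) {
    nuc <- fs$truth$nuclei[k, ]
    own <- fs$truth$foci[fs$truth$foci$nucleus_id == nuc$nucleus_id, ]
    w <- floor(0.7 * nuc$radius)
    cand <- expand.grid(row = (nuc$row - w):(nuc$row + w),
                        col = (nuc$col - w):(nuc$col + w))
    d_nuc <- sqrt((cand$row - nuc$row)^2 + (cand$col - nuc$col)^2)
    d_foc <- apply(cand, 1, function(p)
      min(sqrt((own$row - p[1])^2 + (own$col - p[2])^2)))
    ok <- d_nuc <= 0.7 * nuc$radius & d_foc >= 6
    if (any(ok)) { pick <- cand[which(ok)[1], ]; break }
  }
  expect_false(is.null(pick))
  img <- fs$foci_image
  w <- 5; sig <- 1.5
  rr <- (pick$row - w):(pick$row + w); cc <- (pick$col - w):(pick$col + w)
  d2 <- outer((rr - pick$row)^2, (cc - pick$col)^2, "+")
  img[rr + 1, cc + 1] <- pmin(1, img[rr + 1, cc + 1] +
                                0.6 * exp(-d2 / (2 * sig^2)))
  det1 <- detect_foci(img, fs$labels)
  n0 <- sum(det0$nucleus == nuc$nucleus_id)
  n1 <- sum(det1$nucleus == nuc$nucleus_id)
  expect_equal(n1, n0 + 1)
})

test_that("nuclei smaller than the LoG kernel are skipped with a reason", {
  labels <- matrix(0L, 60, 60)
  labels[10:12, 10:12] <- 1L          # tiny 3x3 nucleus
  labels[30:50, 30:50] <- 2L
  img <- matrix(0.05, 60, 60)
  det <- detect_foci(img, labels)
  sk <- attr(det, "skipped")
  expect_equal(sk$nucleus, 1L)
  expect_match(sk$reason, "kernel")
})

test_that("the mitotic filter excludes exactly the rendered mitoses", {
  fs <- make_foci_fixture(n_nuclei = 200, foci_per_nucleus = 2,
                          mitotic_fraction = 0.1, seed = 13, shape = 1800)
  rois <- nucleus_rois(fs$labels, fs$dapi_image)
  flt <- filter_mitotic(rois)
  truth_mit <- fs$truth$nuclei$nucleus_id[fs$truth$nuclei$is_mitotic]
  expect_setequal(flt$excluded$nucleus, truth_mit)
  expect_equal(nrow(flt$kept) + nrow(flt$excluded), nrow(rois))
})

test_that("degenerate or extreme filter settings exclude nothing", {
  rois <- data.frame(nucleus = 1:10, area_px = 100,
                     mean_intensity = 0.4, total_intensity = 40)
  flt <- filter_mitotic(rois)
  expect_equal(nrow(flt$excluded), 0)  # identical nuclei
  varied <- data.frame(nucleus = 1:10, area_px = c(rep(100, 9), 20),
                       mean_intensity = c(rep(0.3, 9), 0.95),
                       total_intensity = 30)
  none <- filter_mitotic(varied, mitotic_filter_config(
    intensity_factor = Inf))
  expect_equal(nrow(none$excluded), 0)
  some <- filter_mitotic(varied)
  expect_equal(some$excluded$nucleus, 10L)
  expect_warning(filter_mitotic(rois[1, ]), "single nucleus")
})

test_that("the exclusion step never changes kept-nucleus counts", {
  fs <- make_foci_fixture(n_nuclei = 50, foci_per_nucleus = 3,
                          mitotic_fraction = 0.1, seed = 17, shape = 900)
  rois <- nucleus_rois(fs$labels, fs$dapi_image)
  flt <- filter_mitotic(rois)
  det_all <- detect_foci(fs$foci_image, fs$labels)
  keep_lab <- fs$labels
  keep_lab[!(fs$labels %in% flt$kept$nucleus)] <- 0L
  det_kept <- detect_foci(fs$foci_image, keep_lab)
  for (id in flt$kept$nucleus) {
    expect_equal(sum(det_kept$nucleus == id), sum(det_all$nucleus == id))
  }
})

test_that("foci tables aggregate correctly and honor exclusions", {
  det <- data.frame(nucleus = c(2L, 2L, 3L, 3L, 3L, 3L),
                    row = 0L, col = 0L, sigma = 1, peak = 0.5)
  kept <- data.frame(nucleus = 1:3, area_px = 100, mean_intensity = 0.3,
                     total_intensity = 30)
  tab <- tabulate_foci(det, kept, condition = "wt")
  expect_equal(tab$per_nucleus$n_foci, c(0L, 2L, 4L))
  expect_equal(tab$by_condition$mean_foci, 2)
  expect_equal(tab$by_condition$sd_foci, 2)
  expect_true(tab$by_condition$low_n)

  excl <- data.frame(nucleus = 9L, area_px = 30, mean_intensity = 0.9,
                     total_intensity = 27, exclusion_reason = "mitotic")
  det2 <- rbind(det, data.frame(nucleus = rep(9L, 50), row = 0L, col = 0L,
                                sigma = 1, peak = 0.5))
  tab2 <- tabulate_foci(det2, kept, excl, condition = "wt")
  expect_equal(tab2$by_condition$mean_foci, 2)  # unchanged by excluded
  expect_error(tabulate_foci(det2, kept, condition = "wt"), "unknown")
})

test_that("condition means are recovered for Poisson foci loads", {
  build <- function(lambda, seed) {
    # larger nuclei and a capped sampler keep high Poisson draws packable
    sp <- scene_spec(image_shape = c(1400, 1400), n_nuclei = 100,
                     nucleus_radius_range = c(12, 15),
                     noise_sd = 0.02, seed = seed)
    fs <- generate_foci_scene(sp, foci_spec(
      foci_per_nucleus = function(n) pmin(rpois(n, lambda), 10),
      min_separation = 4.5))
    fs$labels <- truth_nucleus_labels(fs$truth$nuclei, c(1400, 1400))
    fs
  }
  fa <- build(2, 19); fb <- build(8, 23)
  rois_a <- nucleus_rois(fa$labels, fa$dapi_image)
  rois_b <- nucleus_rois(fb$labels, fb$dapi_image)
  det_a <- detect_foci(fa$foci_image, fa$labels)
  det_b <- detect_foci(fb$foci_image, fb$labels)
  tab <- tabulate_foci(rbind(det_a,
                             transform(det_b, nucleus = nucleus + 1000)),
                       rbind(rois_a,
                             transform(rois_b, nucleus = nucleus + 1000)),
                       condition = rep(c("ko", "wt"), each = 100))
  m <- tab$by_condition
  expect_lt(abs(m$mean_foci[m$condition == "ko"] - 2) / 2, 0.1)
  expect_lt(abs(m$mean_foci[m$condition == "wt"] - 8) / 8, 0.1)
})

test_that("the foci pipeline is deterministic", {
  fs <- make_foci_fixture(n_nuclei = 12, foci_per_nucleus = 4, seed = 29,
                          shape = 400)
  d1 <- detect_foci(fs$foci_image, fs$labels)
  d2 <- detect_foci(fs$foci_image, fs$labels)
  expect_identical(d1, d2)
})
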