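# Image segmentation: foreground thresholding, nucleus detection for counting
# and seeding, under-segmentation detection and seeded flood-fill splitting.
#
# Convention: images are numeric matrices in [0,1], origin top-left, pixel
# (row, col) 0-based in every tabular interface; internal matrices use R's
# 1-based indexing.

#' Threshold configuration
#'
#' The foreground threshold is expressed as a fraction of the maximum
#' possible (full-scale) intensity, i.e. 0.0196 means "1.96% of full scale":
#' 0.0196 on the normalized `[0, 1]` scale, 5.0 on an 8-bit image. Comparison
#' is strict (`>`).
#'
#' @param fraction_of_max threshold as a fraction of full scale, in (0, 1).
#' @param connectivity pixel connectivity for regions, 4 or 8.
#' @param min_region_px regions smaller than this many pixels are dropped as
#'   debris.
#' @return a `threshold_config` list.
#' @export
threshold_config <- function(fraction_of_max = 0.0196, connectivity = 8,
                             min_region_px = 1) {
  if (!(fraction_of_max > 0 && fraction_of_max < 1))
    stop2("fraction_of_max must be in (0, 1)")
  if (!connectivity %in% c(4, 8)) stop2("connectivity must be 4 or 8")
  if (!is_count(min_region_px)) stop2("min_region_px must be a count")
  structure(list(fraction_of_max = fraction_of_max,
                 connectivity = as.integer(connectivity),
                 min_region_px = as.integer(min_region_px)),
            class = "threshold_config")
}

#' Extract foreground pixels by full-scale thresholding
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param cfg a [threshold_config()].
#' @return logical matrix of the same shape; `TRUE` where
#'   `img > fraction_of_max`, with connected regions smaller than
#'   `min_region_px` removed.
#' @export
threshold_foreground <- function(img, cfg = threshold_config()) {
  check_image(img)
  mask <- img > cfg$fraction_of_max
  if (cfg$min_region_px > 1L && any(mask)) {
    lab <- .cc_label(mask, cfg$connectivity)
    sizes <- tabulate(lab[lab > 0L])
    small <- which(sizes < cfg$min_region_px)
    if (length(small)) mask[lab %in% small] <- FALSE
  }
  mask
}

#' Label connected foreground regions
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix: 0 = background, k >= 1 = region k. Labels are
#'   contiguous and assigned in deterministic row-major scan order.
#' @export
label_regions <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), is.logical(mask))
  .cc_label(mask, as.integer(connectivity))
}

#' Per-region summary of a label matrix
#'
#' @param labels integer label matrix (0 = background).
#' @return data.frame with `region`, `area_px`, `centroid_row`,
#'   `centroid_col` (0-based pixel coordinates).
#' @export
region_table <- function(labels) {
  idx <- which(labels > 0L, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(region = integer(), area_px = integer(),
                      centroid_row = numeric(), centroid_col = numeric()))
  }
  lab <- labels[labels > 0L]
  area <- tabulate(lab)
  rsum <- vapply(split(idx[, 1L] - 1, lab), sum, 0)
  csum <- vapply(split(idx[, 2L] - 1, lab), sum, 0)
  ids <- as.integer(names(rsum))
  o <- order(ids)
  data.frame(region = ids[o], area_px = area[ids[o]],
             centroid_row = (rsum / area[ids])[o],
             centroid_col = (csum / area[ids])[o],
             row.names = NULL)
}

#' Detect nuclei as LoG blobs
#'
#' Multiscale Laplacian-of-Gaussian blob detection of nuclei; the detected
#' centers double as seed points for flood-fill splitting. Defaults suit
#' nuclei of 8--12 px radius rendered with a Gaussian radial profile.
#'
#' @param img DAPI/nucleus-channel image, numeric matrix in `[0, 1]`.
#' @param min_sigma,max_sigma LoG scale range (px).
#' @param n_scales number of scales.
#' @param detect_threshold minimum scale-normalized LoG response.
#' @return data.frame of seed points: `nucleus_id`, 0-based `row`, `col`,
#'   `sigma`, `response`, sorted by (row, col); ids follow that order.
#' @export
detect_nuclei <- function(img, min_sigma = 3, max_sigma = 8, n_scales = 6,
                          detect_threshold = 0.1) {
  det <- detect_blobs(img, min_sigma, max_sigma, n_scales, detect_threshold)
  if (nrow(det)) det <- cbind(nucleus_id = seq_len(nrow(det)), det)
  else det <- cbind(nucleus_id = integer(), det)
  det
}

#' Count cells in an image
#'
#' Cell count per image, measured as the number of detected nucleus blobs.
#'
#' @inheritParams detect_nuclei
#' @return integer count.
#' @export
count_cells <- function(img, min_sigma = 3, max_sigma = 8, n_scales = 6,
                        detect_threshold = 0.1) {
  nrow(detect_nuclei(img, min_sigma, max_sigma, n_scales, detect_threshold))
}

seed_matrix <- function(seeds) {
  if (is.data.frame(seeds)) {
    stopifnot(all(c("row", "col") %in% names(seeds)))
    cbind(seeds$row, seeds$col)
  } else {
    m <- as.matrix(seeds)
    stopifnot(ncol(m) == 2)
    m
  }
}

#' Find under-segmented regions
#'
#' A region is under-segmented when it overlaps two or more nucleus seed
#' points.
#'
#' @param labels integer label matrix.
#' @param seeds data.frame with 0-based `row`, `col` (e.g. from
#'   [detect_nuclei()]).
#' @return integer vector of region ids containing >= 2 seeds. Seeds falling
#'   on background are recorded in attribute `"unassigned"` (their indices).
#' @export
find_undersegmented <- function(labels, seeds) {
  sm <- seed_matrix(seeds)
  reg <- labels[cbind(sm[, 1L] + 1L, sm[, 2L] + 1L)]
  counts <- table(reg[reg > 0L])
  out <- as.integer(names(counts)[counts >= 2L])
  attr(out, "unassigned") <- which(reg == 0L)
  out
}

# snap 0-based seed coords onto the mask within a Chebyshev radius of 3 px
# (nearest Euclidean foreground pixel; ties broken by row, then col)
snap_seeds <- function(mask, sm) {
  for (i in seq_len(nrow(sm))) {
    r <- sm[i, 1L] + 1L; c <- sm[i, 2L] + 1L
    if (mask[r, c]) next
    rr <- max(1L, r - 3L):min(nrow(mask), r + 3L)
    cc <- max(1L, c - 3L):min(ncol(mask), c + 3L)
    sub <- which(mask[rr, cc, drop = FALSE], arr.ind = TRUE)
    if (!nrow(sub)) {
      stop2("seed ", i, " lies on background with no foreground within 3 px")
    }
    cand <- cbind(rr[sub[, 1L]], cc[sub[, 2L]])
    d2 <- (cand[, 1L] - r)^2 + (cand[, 2L] - c)^2
    best <- order(d2, cand[, 1L], cand[, 2L])[1L]
    sm[i, ] <- cand[best, ] - 1L
  }
  sm
}

#' Split a foreground mask by seeded flood fill
#'
#' Simultaneous multi-source region growing over the foreground: every
#' foreground pixel reachable from a seed is assigned to the seed with the
#' smallest geodesic (within-mask) distance, measured in 8-neighbour hops of
#' unit cost; equidistant pixels go to the seed with the lowest id. Seeds on
#' background are snapped to the nearest foreground pixel within 3 px.
#'
#' @param mask logical foreground matrix.
#' @param seeds data.frame with 0-based `row`, `col` and optionally
#'   `nucleus_id` (defining the tie-break order; defaults to row order).
#' @return object of class `labeled_regions`: list with `labels` (integer
#'   matrix) and `regions` (data.frame: `region`, `area_px`, `centroid_row`,
#'   `centroid_col`, `seed_id`, `was_split`).
#' @export
split_by_seeded_flood_fill <- function(mask, seeds) {
  stopifnot(is.matrix(mask), is.logical(mask))
  sm <- seed_matrix(seeds)
  ids <- if (is.data.frame(seeds) && "nucleus_id" %in% names(seeds))
    seeds$nucleus_id else seq_len(nrow(sm))
  ord <- order(ids)
  sm <- sm[ord, , drop = FALSE]
  ids <- ids[ord]
  if (nrow(sm) < 1L) stop2("at least one seed is required")
  sm <- snap_seeds(mask, sm)
  if (anyDuplicated(sm))
    stop2("degenerate seeds: two seeds resolve to the same pixel")
  lab <- .flood_fill_label(mask, as.integer(sm[, 1L]), as.integer(sm[, 2L]))
  tab <- region_table(lab)
  tab$seed_id <- ids[tab$region]
  tab$was_split <- nrow(sm) > 1L
  structure(list(labels = lab, regions = tab), class = "labeled_regions")
}

#' @export
print.labeled_regions <- function(x, ...) {
  cat("labeled_regions:", nrow(x$regions), "regions,",
      sum(x$regions$area_px), "foreground px\n")
  print(head(x$regions, 10))
  invisible(x)
}

#' Segment a cell image with nucleus-seeded splitting
#'
#' Full segmentation pipeline: threshold the cell channel, label connected
#' regions, detect nuclei in the nucleus channel, flag regions overlapped by
#' multiple nuclei as under-segmented and split those by seeded flood fill.
#'
#' @param cell_img cell-body channel, numeric matrix in `[0, 1]`.
#' @param nucleus_img nucleus channel, same shape.
#' @param cfg a [threshold_config()].
#' @param ... passed to [detect_nuclei()].
#' @return a `labeled_regions` object; `regions$seed_id` is `NA` for regions
#'   without a seed (debris), `was_split` marks regions created by splitting.
#' @export
segment_cells <- function(cell_img, nucleus_img, cfg = threshold_config(),
                          ...) {
  mask <- threshold_foreground(cell_img, cfg)
  lab <- label_regions(mask, cfg$connectivity)
  seeds <- detect_nuclei(nucleus_img, ...)
  if (!nrow(seeds)) {
    tab <- region_table(lab)
    tab$seed_id <- NA_integer_
    tab$was_split <- FALSE
    return(structure(list(labels = lab, regions = tab),
                     class = "labeled_regions"))
  }
  seed_reg <- lab[cbind(seeds$row + 1L, seeds$col + 1L)]
  multi <- find_undersegmented(lab, seeds)
  out <- matrix(0L, nrow(lab), ncol(lab))
  recs <- list()
  next_id <- 0L
  for (rid in sort(unique(lab[lab > 0L]))) {
    rmask <- lab == rid
    s_here <- which(seed_reg == rid)
    if (rid %in% multi) {
      sub <- split_by_seeded_flood_fill(rmask, seeds[s_here, , drop = FALSE])
      sublab <- sub$labels
      for (k in seq_len(nrow(sub$regions))) {
        next_id <- next_id + 1L
        out[sublab == sub$regions$region[k]] <- next_id
        recs[[next_id]] <- data.frame(region = next_id,
                                      seed_id = sub$regions$seed_id[k],
                                      was_split = TRUE)
      }
    } else {
      next_id <- next_id + 1L
      out[rmask] <- next_id
      recs[[next_id]] <- data.frame(
        region = next_id,
        seed_id = if (length(s_here)) seeds$nucleus_id[s_here[1L]]
                  else NA_integer_,
        was_split = FALSE)
    }
  }
  tab <- region_table(out)
  meta <- do.call(rbind, recs)
  tab <- merge(tab, meta, by = "region", sort = TRUE)
  structure(list(labels = out, regions = tab), class = "labeled_regions")
}
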