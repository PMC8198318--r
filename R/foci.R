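# Per-nucleus quantification of DNA-damage foci (gamma-H2AX / BRCA1 / RPA32
# type) with mitotic exclusion. Detection is nucleus-restricted multiscale
# LoG blob detection with a relative-contrast gate; counts are raw foci per
# nucleus.

#' Nucleus regions of interest from a label mask
#'
#' @param labels integer label matrix (0 = background), one label per
#'   nucleus.
#' @param dapi_img DAPI-channel image, same shape.
#' @return data.frame: `nucleus` (label id), `area_px`, `mean_intensity`,
#'   `total_intensity`.
#' @export
nucleus_rois <- function(labels, dapi_img) {
  check_image(dapi_img)
  stopifnot(all(dim(labels) == dim(dapi_img)))
  sel <- labels > 0L
  lab <- labels[sel]
  val <- dapi_img[sel]
  area <- tabulate(lab)
  tot <- vapply(split(val, lab), sum, 0)
  ids <- as.integer(names(tot))
  o <- order(ids)
  data.frame(nucleus = ids[o], area_px = area[ids[o]],
             mean_intensity = (tot / area[ids])[o],
             total_intensity = tot[o], row.names = NULL)
}

#' Mitotic-filter configuration
#'
#' A nucleus is flagged mitotic when its mean DAPI intensity exceeds
#' `intensity_factor` times the population median mean-intensity AND its
#' area is below `area_factor` times the population median area (condensed,
#' bright chromatin).
#'
#' @param intensity_factor multiplier on the median mean-intensity
#'   (default 2).
#' @param area_factor multiplier on the median area (default 0.5).
#' @return a `mitotic_filter_config` list.
#' @export
mitotic_filter_config <- function(intensity_factor = 2.0, area_factor = 0.5) {
  if (!(intensity_factor > 0) || !(area_factor > 0))
    stop2("factors must be > 0")
  structure(list(intensity_factor = intensity_factor,
                 area_factor = area_factor),
            class = "mitotic_filter_config")
}

#' Exclude mitotic nuclei
#'
#' @param rois data.frame from [nucleus_rois()].
#' @param cfg a [mitotic_filter_config()].
#' @return list with `kept` and `excluded` data.frames (the latter with an
#'   `exclusion_reason` column); the partition is exhaustive. With a single
#'   nucleus the medians are degenerate: nothing is excluded and a warning
#'   is raised.
#' @export
filter_mitotic <- function(rois, cfg = mitotic_filter_config()) {
  if (!nrow(rois)) stop2("need at least one nucleus")
  if (nrow(rois) == 1L) {
    warning("single nucleus: population medians are degenerate, ",
            "nothing excluded")
    return(list(kept = rois, excluded = rois[0, ]))
  }
  med_int <- median(rois$mean_intensity)
  med_area <- median(rois$area_px)
  mit <- rois$mean_intensity > cfg$intensity_factor * med_int &
    rois$area_px < cfg$area_factor * med_area
  excluded <- rois[mit, , drop = FALSE]
  if (nrow(excluded)) excluded$exclusion_reason <- "mitotic"
  else excluded$exclusion_reason <- character(0)
  list(kept = rois[!mit, , drop = FALSE], excluded = excluded)
}

#' Detect foci within nuclei
#'
#' Multiscale LoG blob detection restricted to each nucleus pixel set. A
#' blob is kept when its image peak exceeds the nucleus background (median
#' intensity within the nucleus) by at least
#' `rel_threshold * (nucleus max - median)`. Nuclei smaller than the
#' largest LoG kernel are skipped with a recorded reason.
#'
#' @param foci_img foci-channel image, numeric matrix in `[0, 1]`.
#' @param labels nucleus label matrix, same shape.
#' @param min_sigma,max_sigma LoG scale range for foci (px).
#' @param n_scales number of scales.
#' @param rel_threshold relative-contrast gate in `[0, 1]`.
#' @param detect_threshold minimum scale-normalized LoG response.
#' @return data.frame of detections: `nucleus`, 0-based `row`, `col`,
#'   `sigma`, `peak`, sorted by (row, col) within nucleus; skipped nuclei
#'   are listed in attribute `"skipped"`.
#' @export
detect_foci <- function(foci_img, labels, min_sigma = 1, max_sigma = 3,
                        n_scales = 4, rel_threshold = 0.5,
                        detect_threshold = 0.1) {
  check_image(foci_img, "foci_img")
  stopifnot(all(dim(labels) == dim(foci_img)))
  ids <- sort(unique(labels[labels > 0L]))
  pad <- as.integer(ceiling(3 * max_sigma)) + 1L
  out <- list()
  skipped <- data.frame(nucleus = integer(), reason = character())
  for (id in ids) {
    idx <- which(labels == id, arr.ind = TRUE)
    rr <- range(idx[, 1L]); cc <- range(idx[, 2L])
    # central lobe of the largest LoG kernel (zero crossings at sqrt(2) sigma)
    kernel_support <- as.integer(2 * ceiling(sqrt(2) * max_sigma) + 1)
    if (min(diff(rr), diff(cc)) + 1L < kernel_support) {
      skipped <- rbind(skipped, data.frame(
        nucleus = id, reason = "smaller than largest LoG kernel"))
      next
    }
    r0 <- max(1L, rr[1L] - pad); r1 <- min(nrow(foci_img), rr[2L] + pad)
    c0 <- max(1L, cc[1L] - pad); c1 <- min(ncol(foci_img), cc[2L] + pad)
    sub <- foci_img[r0:r1, c0:c1, drop = FALSE]
    det <- detect_blobs(sub, min_sigma, max_sigma, n_scales,
                        detect_threshold)
    if (!nrow(det)) next
    # back to full-image 1-based coords
    det$row_full <- det$row + r0
    det$col_full <- det$col + c0
    inside <- labels[cbind(det$row_full, det$col_full)] == id
    det <- det[inside, , drop = FALSE]
    if (!nrow(det)) next
    vals <- foci_img[idx]
    bg <- median(vals)
    gate <- bg + rel_threshold * (max(vals) - bg)
    det$peak <- foci_img[cbind(det$row_full, det$col_full)]
    det <- det[det$peak > gate, , drop = FALSE]
    if (!nrow(det)) next
    det <- det[order(det$row_full, det$col_full), , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      nucleus = id, row = det$row_full - 1L, col = det$col_full - 1L,
      sigma = det$sigma, peak = det$peak)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(nucleus = integer(), row = integer(), col = integer(),
               sigma = numeric(), peak = numeric())
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' Tabulate foci per nucleus and per condition
#'
#' @param detections data.frame from [detect_foci()] (columns `nucleus`,
#'   ...); every detection must reference a kept nucleus.
#' @param kept data.frame of analyzed nuclei (e.g. `filter_mitotic()$kept`).
#' @param excluded data.frame of excluded nuclei (may be empty); their
#'   detections never enter the aggregates.
#' @param condition single condition label or one per kept nucleus.
#' @param min_n conditions with fewer analyzed nuclei are flagged `low_n`
#'   (default 100).
#' @return object of class `foci_table`: list with `per_nucleus`
#'   (nucleus, condition, n_foci, excluded flag) and `by_condition`
#'   (condition, mean_foci, sd_foci, n_analyzed, low_n).
#' @export
tabulate_foci <- function(detections, kept, excluded = NULL,
                          condition = "all", min_n = 100) {
  stopifnot(is.data.frame(kept), "nucleus" %in% names(kept))
  excl_ids <- if (!is.null(excluded) && nrow(excluded)) excluded$nucleus
              else integer(0)
  bad <- setdiff(unique(detections$nucleus), c(kept$nucleus, excl_ids))
  if (length(bad))
    stop2("detections reference unknown nuclei: ",
          paste(head(bad, 5), collapse = ", "))
  if (length(condition) == 1L) condition <- rep(condition, nrow(kept))
  stopifnot(length(condition) == nrow(kept))
  counts <- table(factor(detections$nucleus, levels = kept$nucleus))
  per_nucleus <- data.frame(nucleus = kept$nucleus, condition = condition,
                            n_foci = as.integer(counts), excluded = FALSE)
  if (length(excl_ids)) {
    per_nucleus <- rbind(per_nucleus, data.frame(
      nucleus = excl_ids, condition = NA_character_,
      n_foci = NA_integer_, excluded = TRUE))
  }
  keep <- !per_nucleus$excluded
  by_condition <- do.call(rbind, lapply(
    unique(condition), function(cn) {
      v <- per_nucleus$n_foci[keep & per_nucleus$condition == cn]
      data.frame(condition = cn, mean_foci = mean(v),
                 sd_foci = sd(v), n_analyzed = length(v),
                 low_n = length(v) < min_n)
    }))
  structure(list(per_nucleus = per_nucleus, by_condition = by_condition),
            class = "foci_table")
}

#' @export
print.foci_table <- function(x, ...) {
  cat("foci_table:", sum(!x$per_nucleus$excluded), "nuclei analyzed,",
      sum(x$per_nucleus$excluded), "excluded\n")
  print(x$by_condition)
  invisible(x)
}
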