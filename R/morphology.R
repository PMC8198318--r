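# Cell shape metrics and density-based morphology classification.
#
# Eccentricity comes from the second-order central area moments; roundness is
# the isoperimetric ratio 4*pi*A / P^2 (1 for a circle), with the perimeter
# measured on a smoothed sub-pixel contour so that the estimate is
# asymptotically unbiased for smooth shapes.

region_coords <- function(region) {
  if (is.matrix(region) && is.logical(region)) {
    idx <- which(region, arr.ind = TRUE)
    if (!nrow(idx)) stop2("empty region")
    return(idx)
  }
  m <- as.matrix(region)
  if (!nrow(m) || ncol(m) != 2) stop2("region must be a mask or n x 2 coords")
  m
}

#' Eccentricity from second-order area moments
#'
#' Central moments mu20, mu02, mu11 of the pixel set give the covariance
#' eigenvalues `lambda1 >= lambda2`; eccentricity is
#' `sqrt(1 - lambda2/lambda1)`: 0 for a circle, approaching 1 for a line.
#'
#' @param region logical mask or n x 2 matrix of pixel (row, col) coords.
#' @return eccentricity in `[0, 1)`; a single-pixel region returns 0.
#' @export
compute_eccentricity <- function(region) {
  xy <- region_coords(region)
  n <- nrow(xy)
  if (n == 1L) return(0)
  r <- xy[, 1L] - mean(xy[, 1L])
  c <- xy[, 2L] - mean(xy[, 2L])
  mu20 <- mean(r^2); mu02 <- mean(c^2); mu11 <- mean(r * c)
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(0, tr^2 / 4 - det))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  if (l1 <= 0) return(0)
  sqrt(max(0, 1 - l2 / l1))
}

# marching-squares outer contour of a region mask at the 0.5 level,
# vertex-smoothed with a circular Gaussian window (sd in vertices ~ px)
smoothed_contour <- function(mask, sigma = 1) {
  pad <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask * 1
  cl <- grDevices::contourLines(seq_len(nrow(pad)), seq_len(ncol(pad)),
                                pad, levels = 0.5)
  ct <- cl[[which.max(vapply(cl, function(z) length(z$x), 1L))]]
  x <- ct$x; y <- ct$y
  n <- length(x)
  if (x[1L] == x[n] && y[1L] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1L }
  if (n > 3L && sigma > 0) {
    k <- max(1L, as.integer(ceiling(3 * sigma)))
    w <- dnorm(seq(-k, k), sd = sigma); w <- w / sum(w)
    xs <- ys <- numeric(n)
    for (i in seq_len(n)) {
      j <- ((i - 1L + seq(-k, k)) %% n) + 1L
      xs[i] <- sum(w * x[j]); ys[i] <- sum(w * y[j])
    }
    x <- xs; y <- ys
  }
  cbind(x, y)
}

#' Perimeter of a region
#'
#' Length of the outer marching-squares contour after Gaussian vertex
#' smoothing; rotation- and translation-invariant within ~3% for smooth
#' regions of radius >= 15 px. Holes are ignored.
#'
#' @param region logical mask or n x 2 pixel coordinate matrix.
#' @param smooth_sigma contour smoothing scale (vertices ~ px); default 1.
#' @return perimeter in px.
#' @export
compute_perimeter <- function(region, smooth_sigma = 1) {
  mask <- coords_to_mask(region)
  if (sum(mask) == 1L) return(4)  # single pixel: its crack boundary
  xy <- smoothed_contour(mask, smooth_sigma)
  dx <- diff(c(xy[, 1L], xy[1L, 1L]))
  dy <- diff(c(xy[, 2L], xy[1L, 2L]))
  sum(sqrt(dx^2 + dy^2))
}

coords_to_mask <- function(region) {
  if (is.matrix(region) && is.logical(region)) return(region)
  xy <- region_coords(region)
  xy <- cbind(xy[, 1L] - min(xy[, 1L]) + 1L, xy[, 2L] - min(xy[, 2L]) + 1L)
  m <- matrix(FALSE, max(xy[, 1L]), max(xy[, 2L]))
  m[xy] <- TRUE
  m
}

#' Isoperimetric roundness of a region
#'
#' `R = 4 * pi * A / P^2`, equal to 1 for a circle. (The dimensionless
#' isoperimetric form is used: a ratio `4*pi*A/P` would carry units of
#' length and could not be a "normalized" shape descriptor.)
#'
#' @inheritParams compute_perimeter
#' @return roundness, typically in (0, 1] with up to ~2% discretization
#'   overshoot possible for small discs.
#' @export
compute_roundness <- function(region, smooth_sigma = 1) {
  mask <- coords_to_mask(region)
  if (!any(mask)) stop2("empty region")
  lab <- .cc_label(mask, 8L)
  if (max(lab) > 1L)
    stop2("region is disconnected; split it before measuring roundness")
  a <- sum(mask)
  p <- compute_perimeter(mask, smooth_sigma)
  4 * pi * a / p^2
}

#' Shape metrics for every region of a label matrix
#'
#' @param labels integer label matrix (0 = background), e.g. from
#'   [segment_cells()] or a ground-truth cell mask.
#' @param min_area_px regions smaller than this are skipped.
#' @return data.frame: `cell` (label id), `area_px`, `perimeter_px`,
#'   `roundness`, `eccentricity`.
#' @export
compute_shape_metrics <- function(labels, min_area_px = 9) {
  ids <- sort(unique(labels[labels > 0L]))
  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[labels > 0L]
  by_id <- split(seq_len(nrow(idx)), lab)
  rows <- lapply(ids, function(id) {
    xy <- idx[by_id[[as.character(id)]], , drop = FALSE]
    if (nrow(xy) < min_area_px) return(NULL)
    mask <- coords_to_mask(xy)
    if (max(.cc_label(mask, 8L)) > 1L) return(NULL)  # disconnected debris
    data.frame(cell = id, area_px = nrow(xy),
               perimeter_px = compute_perimeter(mask),
               roundness = compute_roundness(mask),
               eccentricity = compute_eccentricity(xy))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cell = integer(), area_px = integer(),
                      perimeter_px = numeric(), roundness = numeric(),
                      eccentricity = numeric())
  rownames(out) <- NULL
  out
}

#' Morphology clustering configuration
#'
#' @param eps DBSCAN neighbourhood radius in the (roundness, eccentricity)
#'   plane. Both features already live in `[0, 1]`, so the radius is used
#'   unscaled.
#' @param min_samples minimum neighbourhood size (the point itself counts)
#'   for a core point.
#' @return a `morph_cluster_config` list.
#' @export
morph_cluster_config <- function(eps = 0.15, min_samples = 45) {
  if (!(eps > 0)) stop2("eps must be > 0")
  if (!is_count(min_samples) || min_samples < 1)
    stop2("min_samples must be a count >= 1")
  structure(list(eps = eps, min_samples = as.integer(min_samples)),
            class = "morph_cluster_config")
}

# classic DBSCAN with Euclidean metric; min_samples includes the point
# itself; returns 0 for noise, 1..k cluster labels in discovery order
dbscan_labels <- function(X, eps, min_samples) {
  n <- nrow(X)
  d2 <- cross_dist2(X, X)
  nb <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps^2))
  core <- vapply(nb, length, 1L) >= min_samples
  lab <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (lab[i] != 0L || !core[i]) next
    cl <- cl + 1L
    lab[i] <- cl
    frontier <- nb[[i]]
    while (length(frontier)) {
      j <- frontier[1L]; frontier <- frontier[-1L]
      if (lab[j] == 0L) {
        lab[j] <- cl
        if (core[j]) frontier <- c(frontier, nb[[j]][lab[nb[[j]]] == 0L])
      }
    }
  }
  lab
}

#' Classify cell morphology by DBSCAN
#'
#' Clusters cells in the (roundness, eccentricity) plane and maps clusters to
#' semantic labels by mean roundness: the cluster with the highest mean
#' roundness is `"round"`, the lowest is `"fibroblast"`; unclustered points
#' are `"noise"`. If more than two clusters are found the intermediate ones
#' keep labels `"cluster_k"` and a warning flag is set.
#'
#' @param metrics data.frame with columns `roundness` and `eccentricity`
#'   (e.g. from [compute_shape_metrics()]); other columns are carried
#'   through.
#' @param cfg a [morph_cluster_config()].
#' @return object of class `morphology_result`: `metrics` with added
#'   `cluster` (integer, 0 = noise) and `label` columns, plus `n_clusters`
#'   and `multi_cluster` flag.
#' @export
classify_morphology <- function(metrics, cfg = morph_cluster_config()) {
  stopifnot(all(c("roundness", "eccentricity") %in% names(metrics)))
  X <- cbind(metrics$roundness, metrics$eccentricity)
  if (nrow(X) < cfg$min_samples) {
    lab <- integer(nrow(X))
  } else {
    lab <- dbscan_labels(X, cfg$eps, cfg$min_samples)
  }
  k <- max(lab)
  sem <- rep("noise", nrow(X))
  if (k >= 1L) {
    mean_r <- vapply(seq_len(k), function(cl)
      mean(metrics$roundness[lab == cl]), 0)
    names_k <- paste0("cluster_", seq_len(k))
    if (k == 1L) {
      # a lone cluster takes the label matching its own mean roundness
      names_k <- if (mean_r >= 0.5) "round" else "fibroblast"
    } else {
      ord <- order(mean_r, decreasing = TRUE)
      names_k[ord[1L]] <- "round"
      names_k[ord[k]] <- "fibroblast"
    }
    sem[lab > 0L] <- names_k[lab[lab > 0L]]
  }
  out <- metrics
  out$cluster <- lab
  out$label <- sem
  structure(list(metrics = out, n_clusters = k, multi_cluster = k > 2L),
            class = "morphology_result")
}

#' @export
print.morphology_result <- function(x, ...) {
  cat("morphology_result:", nrow(x$metrics), "cells,",
      x$n_clusters, "clusters",
      if (x$multi_cluster) "(warning: >2 clusters)" else "", "\n")
  print(table(x$metrics$label))
  invisible(x)
}

#' Summarize morphology by condition
#'
#' Per condition: number of cells, fraction of round cells (noise excluded
#' from the denominator), mean and sd of roundness and eccentricity; plus all
#' pairwise relative changes in the round fraction.
#'
#' @param result a `morphology_result` from [classify_morphology()].
#' @param condition character/factor vector, one entry per cell in the
#'   result; a single value is recycled.
#' @return list with `by_condition` and `pairwise` data.frames; the
#'   `rel_change_round` column is `(f2 - f1) / f1` for conditions 1 vs 2.
#' @export
summarize_population <- function(result, condition = "all") {
  m <- result$metrics
  if (length(condition) == 1L) condition <- rep(condition, nrow(m))
  stopifnot(length(condition) == nrow(m))
  conds <- unique(condition)
  by_cond <- do.call(rbind, lapply(conds, function(cn) {
    sub <- m[condition == cn, , drop = FALSE]
    lbl <- sub$label[sub$label != "noise"]
    data.frame(condition = cn, n = nrow(sub),
               n_labelled = length(lbl),
               fraction_round = if (length(lbl)) mean(lbl == "round")
                                else NA_real_,
               mean_roundness = mean(sub$roundness),
               sd_roundness = sd(sub$roundness),
               mean_eccentricity = mean(sub$eccentricity),
               sd_eccentricity = sd(sub$eccentricity))
  }))
  pairs <- if (length(conds) >= 2L) {
    cmb <- utils::combn(conds, 2L)
    do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
      f1 <- by_cond$fraction_round[by_cond$condition == cmb[1L, i]]
      f2 <- by_cond$fraction_round[by_cond$condition == cmb[2L, i]]
      data.frame(condition_1 = cmb[1L, i], condition_2 = cmb[2L, i],
                 rel_change_round = (f2 - f1) / f1)
    }))
  } else {
    data.frame(condition_1 = character(), condition_2 = character(),
               rel_change_round = numeric())
  }
  list(by_condition = by_cond, pairwise = pairs)
}
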