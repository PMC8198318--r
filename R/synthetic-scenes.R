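# Synthetic fluorescence scenes with exact ground truth.
#
# The generators emulate the statistical structure the analysis assumes:
# DAPI-stained nuclei scenes of 250-500 nuclei per 2048 x 2048 field, nuclei
# rendered as Gaussian-profile discs (realistic LoG responses), punctate
# nuclear foci, condensed/bright mitotic nuclei, and cell bodies of two shape
# families. Every generator is a pure function of its spec + seed.

#' Nucleus scene specification
#'
#' Defaults describe the reference imaging condition: 2048 x 2048 fields
#' with ~300 nuclei of 8--12 px radius on a dim background.
#'
#' @param image_shape integer `(rows, cols)`.
#' @param n_nuclei number of nuclei (>= 1).
#' @param nucleus_radius_range radius range in px.
#' @param nucleus_peak_intensity peak intensity above background, fraction of
#'   full scale.
#' @param background_level background intensity fraction.
#' @param noise_sd additive Gaussian noise sd, fraction of full scale.
#' @param overlap_fraction fraction of nuclei placed in touching pairs.
#' @param seed RNG seed.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(image_shape = c(2048, 2048), n_nuclei = 300,
                       nucleus_radius_range = c(8, 12),
                       nucleus_peak_intensity = 0.7,
                       background_level = 0.05, noise_sd = 0.02,
                       overlap_fraction = 0, seed = 1) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 1))
  if (!is_count(n_nuclei) || n_nuclei < 1) stop2("n_nuclei must be >= 1")
  for (f in c(nucleus_peak_intensity, background_level, noise_sd))
    if (f < 0 || f > 1) stop2("intensity fields must be in [0, 1]")
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop2("overlap_fraction must be in [0, 1]")
  stopifnot(length(nucleus_radius_range) == 2,
            nucleus_radius_range[1] <= nucleus_radius_range[2],
            nucleus_radius_range[1] > 0)
  structure(list(image_shape = as.integer(image_shape),
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_radius_range = nucleus_radius_range,
                 nucleus_peak_intensity = nucleus_peak_intensity,
                 background_level = background_level, noise_sd = noise_sd,
                 overlap_fraction = overlap_fraction,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Foci specification
#'
#' @param foci_per_nucleus integer count, or a function `f(n)` returning `n`
#'   sampled counts (e.g. `function(n) rpois(n, 4)`).
#' @param focus_sigma Gaussian spot sd in px (must be smaller than the
#'   nucleus radius).
#' @param focus_peak spot peak intensity, fraction of full scale.
#' @param min_separation minimum pairwise distance between focus centers, px.
#' @param mitotic_fraction fraction of nuclei rendered condensed and bright.
#' @return a `foci_spec` list.
#' @export
foci_spec <- function(foci_per_nucleus = 4, focus_sigma = 1.5,
                      focus_peak = 0.6, min_separation = 6,
                      mitotic_fraction = 0) {
  if (!(min_separation > 0)) stop2("min_separation must be > 0")
  if (mitotic_fraction < 0 || mitotic_fraction > 1)
    stop2("mitotic_fraction must be in [0, 1]")
  if (focus_peak < 0 || focus_peak > 1) stop2("focus_peak must be in [0, 1]")
  structure(list(foci_per_nucleus = foci_per_nucleus,
                 focus_sigma = focus_sigma, focus_peak = focus_peak,
                 min_separation = min_separation,
                 mitotic_fraction = mitotic_fraction),
            class = "foci_spec")
}

#' Cell shape family specification
#'
#' Two shape families: `round` (low eccentricity) and `fibroblast`
#' (elongated). The round eccentricity range must lie strictly below the
#' fibroblast range.
#'
#' @param n_round,n_fibroblast cells per family.
#' @param round_ecc_range,fibroblast_ecc_range target eccentricity ranges.
#' @param area_range target cell area range, px^2.
#' @return a `cell_shape_spec` list.
#' @export
cell_shape_spec <- function(n_round = 100, n_fibroblast = 100,
                            round_ecc_range = c(0.05, 0.25),
                            fibroblast_ecc_range = c(0.85, 0.95),
                            area_range = c(1200, 2000)) {
  if (max(round_ecc_range) >= min(fibroblast_ecc_range))
    stop2("round eccentricity range must lie strictly below fibroblast range")
  stopifnot(n_round >= 1 || n_fibroblast >= 1,
            all(c(round_ecc_range, fibroblast_ecc_range) >= 0),
            all(c(round_ecc_range, fibroblast_ecc_range) < 1),
            all(area_range > 0))
  structure(list(n_round = as.integer(n_round),
                 n_fibroblast = as.integer(n_fibroblast),
                 round_ecc_range = round_ecc_range,
                 fibroblast_ecc_range = fibroblast_ecc_range,
                 area_range = area_range),
            class = "cell_shape_spec")
}

# add a Gaussian-profile disc (sigma = radius/2, truncated at 2.5 sigma)
# centered at 0-based (r0, c0)
add_gaussian_disc <- function(img, r0, c0, radius, peak) {
  sigma <- radius / 2
  w <- as.integer(ceiling(2.5 * sigma))
  rr <- max(0L, r0 - w):min(nrow(img) - 1L, r0 + w)
  cc <- max(0L, c0 - w):min(ncol(img) - 1L, c0 + w)
  d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  img[rr + 1L, cc + 1L] <- img[rr + 1L, cc + 1L] +
    peak * exp(-d2 / (2 * sigma^2)) * (d2 <= (2.5 * sigma)^2)
  img
}

add_flat_disc <- function(img, r0, c0, radius, level) {
  w <- as.integer(ceiling(radius))
  rr <- max(0L, r0 - w):min(nrow(img) - 1L, r0 + w)
  cc <- max(0L, c0 - w):min(ncol(img) - 1L, c0 + w)
  d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  patch <- img[rr + 1L, cc + 1L]
  patch[d2 <= radius^2] <- pmax(patch[d2 <= radius^2], level)
  img[rr + 1L, cc + 1L] <- patch
  img
}

# place n nuclei with the spec's overlap pairing; returns 0-based centers.
# Radii are sampled uniformly in the spec range; singles keep a clearance of
# r_i + r_j + 3 px, touching-pair partners sit at 0.75 * (r_i + r_j).
place_nuclei <- function(spec) {
  n <- spec$n_nuclei
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  radius <- runif(n, spec$nucleus_radius_range[1], spec$nucleus_radius_range[2])
  if (any(2 * radius + 2 > min(nr, nc)))
    stop2("placement error: nuclei do not fit in the image")
  n_pairs <- floor(spec$overlap_fraction * n / 2)
  rowv <- colv <- rep(NA_real_, n)
  mate <- rep(NA_integer_, n)
  placed_r <- placed_c <- placed_rad <- numeric(0)
  try_place <- function(rad, clear_extra, near = NULL, near_dist = NULL) {
    for (tr in 1:1000) {
      if (is.null(near)) {
        r0 <- runif(1, rad, nr - 1 - rad)
        c0 <- runif(1, rad, nc - 1 - rad)
      } else {
        th <- runif(1, 0, 2 * pi)
        r0 <- near[1] + near_dist * sin(th)
        c0 <- near[2] + near_dist * cos(th)
        if (r0 < rad || r0 > nr - 1 - rad || c0 < rad || c0 > nc - 1 - rad)
          next
      }
      if (length(placed_r)) {
        d <- sqrt((placed_r - r0)^2 + (placed_c - c0)^2)
        lim <- placed_rad + rad + clear_extra
        if (!is.null(near)) {
          # ignore the mate (it is the last placed nucleus)
          keep <- seq_along(d) != length(d)
          if (any(d[keep] < lim[keep])) next
        } else if (any(d < lim)) next
      }
      return(c(r0, c0))
    }
    stop2("placement error: could not place nucleus without overlap")
  }
  i <- 1L
  for (p in seq_len(n_pairs)) {
    a <- i; b <- i + 1L; i <- i + 2L
    # anchor needs clearance for its partner too
    pos <- try_place(radius[a] + 2 * radius[b], 3)
    rowv[a] <- pos[1]; colv[a] <- pos[2]
    placed_r <- c(placed_r, pos[1]); placed_c <- c(placed_c, pos[2])
    placed_rad <- c(placed_rad, radius[a])
    pos2 <- try_place(radius[b], 3, near = pos,
                      near_dist = 0.75 * (radius[a] + radius[b]))
    rowv[b] <- pos2[1]; colv[b] <- pos2[2]
    mate[a] <- b; mate[b] <- a
    placed_r <- c(placed_r, pos2[1]); placed_c <- c(placed_c, pos2[2])
    placed_rad <- c(placed_rad, radius[b])
  }
  while (i <= n) {
    pos <- try_place(radius[i], 3)
    rowv[i] <- pos[1]; colv[i] <- pos[2]
    placed_r <- c(placed_r, pos[1]); placed_c <- c(placed_c, pos[2])
    placed_rad <- c(placed_rad, radius[i])
    i <- i + 1L
  }
  data.frame(nucleus_id = seq_len(n), row = round(rowv), col = round(colv),
             radius = radius, mate = mate)
}

#' Generate a nuclei-only scene
#'
#' Renders `n_nuclei` Gaussian-profile discs on a flat background with
#' additive Gaussian noise. All nucleus centers lie at least one radius from
#' the image border.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (matrix in `[0, 1]`) and `truth` (list with a
#'   `nuclei` data.frame: `nucleus_id`, 0-based `row`/`col`, `radius`,
#'   `is_mitotic`).
#' @export
generate_nuclei_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  local_seed(spec$seed, {
    nuc <- place_nuclei(spec)
    img <- matrix(spec$background_level,
                  spec$image_shape[1], spec$image_shape[2])
    for (k in seq_len(nrow(nuc))) {
      img <- add_gaussian_disc(img, nuc$row[k], nuc$col[k], nuc$radius[k],
                               spec$nucleus_peak_intensity)
    }
    if (spec$noise_sd > 0)
      img <- img + matrix(rnorm(length(img), 0, spec$noise_sd), nrow(img))
    nuc$is_mitotic <- FALSE
    list(image = clip01(img),
         truth = list(nuclei = nuc[, c("nucleus_id", "row", "col", "radius",
                                       "is_mitotic")]))
  })
}

# mean intensity of the truncated Gaussian radial profile over the nucleus
# disc: (2 sigma^2 / r^2) (1 - exp(-r^2 / 2 sigma^2)) with sigma = r/2
interphase_mean_factor <- 0.5 * (1 - exp(-2))

#' Generate a DAPI + foci two-channel scene
#'
#' Non-mitotic nuclei carry the sampled number of Gaussian spots in the foci
#' channel, pairwise separated by at least `min_separation`. Mitotic nuclei
#' are rendered condensed (0.55x radius, ~0.3x area) and bright (flat
#' disc at >= 2x the interphase mean intensity) and carry no foci.
#'
#' @param spec a [scene_spec()].
#' @param foci a [foci_spec()].
#' @return list with `dapi_image`, `foci_image` and `truth` (list of `nuclei`
#'   and `foci` data.frames; 0-based coordinates).
#' @export
generate_foci_scene <- function(spec = scene_spec(), foci = foci_spec()) {
  stopifnot(inherits(spec, "scene_spec"), inherits(foci, "foci_spec"))
  if (foci$focus_sigma >= spec$nucleus_radius_range[1])
    stop2("focus_sigma must be smaller than the nucleus radius")
  local_seed(spec$seed, {
    nuc <- place_nuclei(spec)
    n <- nrow(nuc)
    n_mit <- round(foci$mitotic_fraction * n)
    mit <- if (n_mit > 0) sample(n, n_mit) else integer(0)
    nuc$is_mitotic <- seq_len(n) %in% mit

    dapi <- matrix(spec$background_level,
                   spec$image_shape[1], spec$image_shape[2])
    mitotic_level <- min(1, 2.5 * interphase_mean_factor *
                            spec$nucleus_peak_intensity +
                            spec$background_level)
    nuc$rendered_radius <- ifelse(nuc$is_mitotic, 0.55 * nuc$radius,
                                  nuc$radius)
    for (k in seq_len(n)) {
      if (nuc$is_mitotic[k]) {
        dapi <- add_flat_disc(dapi, nuc$row[k], nuc$col[k],
                              nuc$rendered_radius[k], mitotic_level)
      } else {
        dapi <- add_gaussian_disc(dapi, nuc$row[k], nuc$col[k],
                                  nuc$radius[k], spec$nucleus_peak_intensity)
      }
    }

    counts <- if (is.function(foci$foci_per_nucleus)) {
      k <- foci$foci_per_nucleus(n)
      stopifnot(length(k) == n, all(k >= 0))
      as.integer(round(k))
    } else rep(as.integer(foci$foci_per_nucleus), n)
    counts[nuc$is_mitotic] <- 0L

    fimg <- matrix(0.02, spec$image_shape[1], spec$image_shape[2])
    frows <- list()
    for (k in seq_len(n)) {
      kk <- counts[k]
      if (kk == 0L) next
      rmax <- 0.8 * nuc$radius[k]
      pts <- NULL
      for (restart in 1:200) {
        pts <- matrix(numeric(0), 0, 2)
        for (j in seq_len(kk)) {
          placed <- FALSE
          for (tr in 1:50) {
            th <- runif(1, 0, 2 * pi); rr <- rmax * sqrt(runif(1))
            p <- c(nuc$row[k] + rr * sin(th), nuc$col[k] + rr * cos(th))
            if (nrow(pts) &&
                min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) <
                  foci$min_separation^2) next
            pts <- rbind(pts, p)
            placed <- TRUE
            break
          }
          if (!placed) break
        }
        if (nrow(pts) == kk) break
      }
      if (nrow(pts) < kk)
        stop2("placement error: foci incompatible with nucleus area/",
              "min_separation")
      for (j in seq_len(kk)) {
        fimg <- add_gaussian_disc(fimg, round(pts[j, 1]), round(pts[j, 2]),
                                  2 * foci$focus_sigma, foci$focus_peak)
      }
      frows[[length(frows) + 1L]] <- data.frame(
        nucleus_id = nuc$nucleus_id[k], row = round(pts[, 1]),
        col = round(pts[, 2]), peak = foci$focus_peak)
    }
    if (spec$noise_sd > 0) {
      dapi <- dapi + matrix(rnorm(length(dapi), 0, spec$noise_sd), nrow(dapi))
      fimg <- fimg + matrix(rnorm(length(fimg), 0, spec$noise_sd), nrow(fimg))
    }
    ftab <- if (length(frows)) do.call(rbind, frows) else
      data.frame(nucleus_id = integer(), row = numeric(), col = numeric(),
                 peak = numeric())
    list(dapi_image = clip01(dapi), foci_image = clip01(fimg),
         truth = list(nuclei = nuc[, c("nucleus_id", "row", "col", "radius",
                                       "rendered_radius", "is_mitotic")],
                      foci = ftab))
  })
}

#' Rasterize ground-truth nucleus labels
#'
#' Builds an integer label matrix of nucleus discs from a generator's
#' ground-truth table (using the rendered radius, which is condensed for
#' mitotic nuclei), for oracle-based testing without running segmentation.
#'
#' @param nuclei `truth$nuclei` data.frame from a scene generator.
#' @param image_shape integer `(rows, cols)`.
#' @return integer label matrix; labels equal `nucleus_id`.
#' @export
truth_nucleus_labels <- function(nuclei, image_shape) {
  lab <- matrix(0L, image_shape[1], image_shape[2])
  rad <- if ("rendered_radius" %in% names(nuclei)) nuclei$rendered_radius
         else nuclei$radius
  for (k in seq_len(nrow(nuclei))) {
    w <- as.integer(ceiling(rad[k]))
    rr <- max(0L, nuclei$row[k] - w):min(image_shape[1] - 1L,
                                         nuclei$row[k] + w)
    cc <- max(0L, nuclei$col[k] - w):min(image_shape[2] - 1L,
                                         nuclei$col[k] + w)
    d2 <- outer((rr - nuclei$row[k])^2, (cc - nuclei$col[k])^2, "+")
    sel <- which(d2 <= rad[k]^2, arr.ind = TRUE)
    lab[cbind(rr[sel[, 1L]] + 1L, cc[sel[, 2L]] + 1L)] <-
      nuclei$nucleus_id[k]
  }
  lab
}

rasterize_ellipse <- function(r0, c0, a, b, theta, shape) {
  w <- as.integer(ceiling(a))
  rr <- max(0L, r0 - w):min(shape[1] - 1L, r0 + w)
  cc <- max(0L, c0 - w):min(shape[2] - 1L, c0 + w)
  dr <- outer(rr - r0, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - c0)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  cbind(rr[idx[, 1L]], cc[idx[, 2L]])  # 0-based
}

#' Generate a two-family cell scene
#'
#' Cells are filled ellipses with true eccentricity sampled in the family's
#' range, laid out on a jittered grid; a stated fraction of cells is placed
#' in touching pairs so the foreground merges into one blob (exercising
#' under-segmentation splitting). Each cell carries one nucleus at its
#' center.
#'
#' @param spec a [scene_spec()]; `overlap_fraction` sets the touching-pair
#'   fraction and `image_shape` must be large enough for the grid layout.
#' @param shapes a [cell_shape_spec()].
#' @return list with `cell_image`, `nucleus_image`, `truth` (list of `cells`
#'   data.frame with family/target geometry, `cell_labels` truth label
#'   matrix, and `nuclei` data.frame).
#' @export
generate_cell_scene <- function(spec = scene_spec(), shapes = cell_shape_spec()) {
  stopifnot(inherits(spec, "scene_spec"), inherits(shapes, "cell_shape_spec"))
  n <- shapes$n_round + shapes$n_fibroblast
  if (n < 1) stop2("need at least one cell")
  local_seed(spec$seed, {
    fam <- sample(c(rep("round", shapes$n_round),
                    rep("fibroblast", shapes$n_fibroblast)))
    ecc <- numeric(n)
    ecc[fam == "round"] <- runif(sum(fam == "round"),
                                 shapes$round_ecc_range[1],
                                 shapes$round_ecc_range[2])
    ecc[fam == "fibroblast"] <- runif(sum(fam == "fibroblast"),
                                      shapes$fibroblast_ecc_range[1],
                                      shapes$fibroblast_ecc_range[2])
    area <- runif(n, shapes$area_range[1], shapes$area_range[2])
    ratio <- sqrt(1 - ecc^2)            # b / a
    a <- sqrt(area / (pi * ratio))
    b <- ratio * a
    theta <- runif(n, 0, pi)

    n_pairs <- floor(spec$overlap_fraction * n / 2)
    # slot side: one cell (or one touching pair) fits with margin
    pair_pad <- if (n_pairs > 0) 0.85 * max(b) else 0
    slot <- 2 * ceiling(max(a) + pair_pad) + 8
    g_r <- floor(spec$image_shape[1] / slot)
    g_c <- floor(spec$image_shape[2] / slot)
    n_slots <- n - n_pairs              # pairs share a slot
    if (g_r * g_c < n_slots)
      stop2("placement error: image_shape too small for ", n, " cells")
    slots <- sample(g_r * g_c, n_slots)
    centers <- matrix(NA_real_, n, 2)
    slot_center <- function(s) {
      gr <- (s - 1) %/% g_c; gc <- (s - 1) %% g_c
      c(gr * slot + slot / 2, gc * slot + slot / 2)
    }
    i <- 1L; si <- 1L
    pair_first <- integer(0)
    for (p in seq_len(n_pairs)) {
      ctr <- slot_center(slots[si]); si <- si + 1L
      th <- runif(1, 0, 2 * pi)
      d <- 0.85 * (b[i] + b[i + 1L])
      centers[i, ] <- ctr - d / 2 * c(sin(th), cos(th)) + runif(2, -2, 2)
      centers[i + 1L, ] <- centers[i, ] + d * c(sin(th), cos(th))
      pair_first <- c(pair_first, i)
      i <- i + 2L
    }
    while (i <= n) {
      ctr <- slot_center(slots[si]); si <- si + 1L
      centers[i, ] <- ctr + runif(2, -2, 2)
      i <- i + 1L
    }

    cell_labels <- matrix(0L, spec$image_shape[1], spec$image_shape[2])
    cell_img <- matrix(0.02, spec$image_shape[1], spec$image_shape[2])
    nuc_img <- matrix(0.02, spec$image_shape[1], spec$image_shape[2])
    nuc_radius <- pmax(3, 0.45 * b)
    cells <- data.frame(cell_id = seq_len(n), family = fam,
                        row = round(centers[, 1]), col = round(centers[, 2]),
                        semi_major = a, semi_minor = b, angle = theta,
                        target_area = area, target_eccentricity = ecc,
                        nucleus_radius = nuc_radius)
    for (k in seq_len(n)) {
      px <- rasterize_ellipse(cells$row[k], cells$col[k], a[k], b[k],
                              theta[k], spec$image_shape)
      cell_labels[px + 1L] <- k
      cell_img[px + 1L] <- 0.45 + 0.1 * runif(1)
      nuc_img <- add_gaussian_disc(nuc_img, cells$row[k], cells$col[k],
                                   nuc_radius[k],
                                   spec$nucleus_peak_intensity)
    }
    if (spec$noise_sd > 0) {
      cell_img <- cell_img +
        matrix(rnorm(length(cell_img), 0, spec$noise_sd), nrow(cell_img))
      nuc_img <- nuc_img +
        matrix(rnorm(length(nuc_img), 0, spec$noise_sd), nrow(nuc_img))
    }
    nuclei <- data.frame(nucleus_id = seq_len(n), row = cells$row,
                         col = cells$col, radius = nuc_radius,
                         is_mitotic = FALSE)
    list(cell_image = clip01(cell_img), nucleus_image = clip01(nuc_img),
         truth = list(cells = cells, cell_labels = cell_labels,
                      nuclei = nuclei))
  })
}
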