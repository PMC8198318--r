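# Multiscale Laplacian-of-Gaussian (LoG) blob detection.
#
# Images are numeric matrices in [0,1], indexed (row, col) from the top-left,
# 0-based coordinates in all tabular outputs. Bright blobs give positive
# scale-normalized responses -sigma^2 * Laplacian(Gaussian * image).

gaussian_kernel_1d <- function(sigma) {
  k <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- dnorm(seq(-k, k), sd = sigma)
  w / sum(w)
}

# convolve each column with kernel w, replicating edge values
conv_cols <- function(m, w) {
  k <- (length(w) - 1L) / 2L
  mp <- rbind(m[rep(1L, k), , drop = FALSE], m,
              m[rep(nrow(m), k), , drop = FALSE])
  out <- stats::filter(mp, w, sides = 2)
  matrix(as.numeric(out[(k + 1L):(k + nrow(m)), , drop = FALSE]),
         nrow = nrow(m))
}

#' Gaussian smoothing of an image
#'
#' Separable Gaussian convolution with edge replication.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param sigma Gaussian standard deviation in pixels.
#' @return numeric matrix of the same shape.
#' @export
blur_gaussian <- function(img, sigma) {
  stopifnot(is.matrix(img), sigma > 0)
  w <- gaussian_kernel_1d(sigma)
  t(conv_cols(t(conv_cols(img, w)), w))
}

# 4-neighbour discrete Laplacian with replicated edges
laplacian <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up    <- m[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  down  <- m[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  left  <- m[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  right <- m[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  up + down + left + right - 4 * m
}

log_response <- function(img, sigma) {
  -sigma^2 * laplacian(blur_gaussian(img, sigma))
}

# strict local maxima of a matrix over the 8-neighbourhood
local_maxima <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  ok <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc, drop = FALSE]
    ok <- ok & (m > nb)
  }
  ok
}

#' Multiscale LoG blob detection
#'
#' Detects bright, approximately round spots as strict local maxima of the
#' scale-normalized Laplacian-of-Gaussian response across a geometric ladder
#' of scales, followed by non-maximum suppression of overlapping detections
#' (stronger response wins; the blob radius is `sqrt(2) * sigma`).
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param min_sigma,max_sigma scale range in pixels (`min_sigma < max_sigma`).
#' @param n_scales number of scales, geometrically spaced.
#' @param detect_threshold minimum scale-normalized response for a detection.
#' @return data.frame with 0-based `row`, `col`, plus `sigma` and `response`,
#'   sorted by (row, col).
#' @export
detect_blobs <- function(img, min_sigma, max_sigma, n_scales = 6,
                         detect_threshold = 0.1) {
  check_image(img)
  if (!(min_sigma > 0 && max_sigma > min_sigma))
    stop2("need 0 < min_sigma < max_sigma")
  sigmas <- exp(seq(log(min_sigma), log(max_sigma), length.out = n_scales))
  resp <- lapply(sigmas, function(s) log_response(img, s))
  cand <- list()
  for (i in seq_along(sigmas)) {
    m <- resp[[i]]
    ok <- local_maxima(m) & (m > detect_threshold)
    # require a maximum across adjacent scales as well
    if (i > 1L) ok <- ok & (m >= resp[[i - 1L]])
    if (i < length(sigmas)) ok <- ok & (m >= resp[[i + 1L]])
    idx <- which(ok, arr.ind = TRUE)
    if (nrow(idx)) {
      cand[[length(cand) + 1L]] <- data.frame(
        row = idx[, 1L] - 1L, col = idx[, 2L] - 1L,
        sigma = sigmas[i], response = m[idx])
    }
  }
  if (!length(cand)) {
    return(data.frame(row = integer(), col = integer(),
                      sigma = numeric(), response = numeric()))
  }
  det <- do.call(rbind, cand)
  det <- det[order(-det$response, det$row, det$col), , drop = FALSE]
  # non-maximum suppression: drop a weaker blob whose center falls within the
  # radius of an already-kept stronger blob (or vice versa)
  keep <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    ki <- which(keep)
    if (!length(ki)) { keep[i] <- TRUE; next }
    d2 <- (det$row[ki] - det$row[i])^2 + (det$col[ki] - det$col[i])^2
    rad <- pmax(det$sigma[ki], det$sigma[i]) * sqrt(2)
    keep[i] <- all(d2 >= rad^2)
  }
  det <- det[keep, , drop = FALSE]
  det <- det[order(det$row, det$col), , drop = FALSE]
  rownames(det) <- NULL
  det
}
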