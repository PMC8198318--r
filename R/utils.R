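# internal helpers shared across modules

stop2 <- function(...) stop(..., call. = FALSE)

check_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop2(arg, " must be a numeric matrix (rows x cols)")
  if (any(!is.finite(img)))
    stop2(arg, " contains non-finite pixel values")
  if (min(img) < 0 || max(img) > 1)
    stop2(arg, " must be normalized to [0, 1]")
  invisible(img)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x == round(x) && x >= 0

#' Evaluate an expression with a local, restorable RNG state
#'
#' All generators route their randomness through this wrapper so that every
#' call is a pure function of its arguments plus `seed`, and never perturbs
#' the caller's RNG stream.
#' @noRd
local_seed <- function(seed, code) {
  if (!is_count(seed)) stop2("seed must be a single non-negative integer")
  withr::with_seed(as.integer(seed), code)
}

# squared euclidean distances between rows of two 2-column matrices
cross_dist2 <- function(a, b) {
  outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
}

# significance stars matching the usual figure annotation convention
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
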